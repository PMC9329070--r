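# Independent oracles used across test files.

# Exact two-sided Mann-Whitney p by brute-force enumeration, computing U
# from pairwise comparisons (a different route than the rank-sum formula
# used by the implementation).
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  mu <- n1 * (n - n1) / 2
  u_obs <- u_of(x, y)
  idx <- utils::combn(n, n1)
  u_all <- apply(idx, 2, function(j) u_of(pooled[j], pooled[-j]))
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Textbook Welch statistic / Satterthwaite df / two-sided p.
welch_oracle <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Minimal hand-built measurement table: one bottle per layer, two
# timepoints, concentrations supplied as named lists compound -> c(t0, t1).
make_measurements <- function(series, layer = "SML", treatment = "PAH",
                              replicate = 1, times = c(0, 24)) {
  do.call(rbind, lapply(names(series), function(cp) {
    data.frame(compound = cp, layer = layer, treatment = treatment,
               replicate = replicate, time_h = times,
               conc_ng_L = series[[cp]])
  }))
}

# Small deterministic taxon table: counts given as a matrix with genus
# rownames; taxonomy derives one ASV per row.
make_taxon_table <- function(counts, genera = rownames(counts),
                             meta_extra = NULL) {
  taxa <- if (is.null(rownames(counts))) {
    sprintf("ASV_%02d", seq_len(nrow(counts)))
  } else {
    rownames(counts)
  }
  rownames(counts) <- taxa
  lineage <- ifelse(is.na(genera), "Bacteria;;;;;;",
                    paste0("Bacteria;P;C;O;F;", genera, ";"))
  tax <- data.frame(taxon_id = taxa, lineage = lineage,
                    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = colnames(counts), stringsAsFactors = FALSE)
  if (!is.null(meta_extra)) meta <- cbind(meta, meta_extra)
  taxon_table(counts, tax, meta)
}
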