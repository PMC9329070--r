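TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

normalize_genus <- function(x) tolower(trimws(x))

#' Parse SILVA-style lineage strings
#'
#' Splits semicolon-separated 7-rank lineages (domain..species), stripping
#' optional SILVA rank prefixes (`d__`, `p__`, ...). Missing or empty ranks
#' become `NA`.
#'
#' @param lineage Character vector of lineage strings.
#' @return Data frame with one column per rank.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- sub("^[a-z]__", "", trimws(p))
    p[p %in% c("", "NA", "unclassified", "Unclassified")] <- NA_character_
    length(p) <- length(TAXONOMIC_RANKS)
    p
  }, character(length(TAXONOMIC_RANKS))))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- TAXONOMIC_RANKS
  df
}

#' Construct a taxon table
#'
#' Bundles an ASV count matrix (taxa x samples), a per-taxon taxonomy and
#' per-sample metadata into a validated container used by the rarefaction,
#' relative-abundance and HCB-screening steps.
#'
#' @param counts Non-negative integer matrix, taxa in rows (rownames = taxon
#'   ids), samples in columns (colnames = sample ids).
#' @param taxonomy Data frame with a `taxon_id` column plus rank columns
#'   (`domain` ... `species`), or a `taxon_id`/`lineage` pair which is parsed
#'   via [parse_lineage()].
#' @param sample_meta Data frame with a `sample_id` column plus experiment
#'   factors (typically `layer`, `fraction`, `treatment`, `timepoint`,
#'   `replicate`).
#' @return An object of class `taxon_table`.
#' @export
taxon_table <- function(counts, taxonomy, sample_meta) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("counts must have taxon rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  stop_if_missing_cols(taxonomy, "taxon_id", "taxonomy table")
  if ("lineage" %in% names(taxonomy) &&
      !all(TAXONOMIC_RANKS %in% names(taxonomy))) {
    taxonomy <- cbind(taxonomy["taxon_id"], parse_lineage(taxonomy$lineage))
  }
  stop_if_missing_cols(taxonomy, c("taxon_id", "genus"), "taxonomy table")
  stop_if_missing_cols(sample_meta, "sample_id", "sample metadata")
  if (!setequal(taxonomy$taxon_id, rownames(counts)) ||
      nrow(taxonomy) != nrow(counts)) {
    stop("taxonomy rows must match count-matrix rows exactly", call. = FALSE)
  }
  if (!setequal(sample_meta$sample_id, colnames(counts)) ||
      nrow(sample_meta) != ncol(counts)) {
    stop("sample metadata rows must match count-matrix columns exactly",
         call. = FALSE)
  }
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$taxon_id), ,
                       drop = FALSE]
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(taxonomy) <- NULL
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_meta = sample_meta),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d taxa x %d samples (total %d reads)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read a taxon table from plain-text files
#'
#' @param counts_tsv TSV, first column taxon id, remaining columns sample
#'   counts.
#' @param taxonomy_tsv TSV with columns `taxon_id` and `lineage`.
#' @param meta_csv CSV with `sample_id` plus metadata columns.
#' @return A [taxon_table()].
#' @export
read_taxon_table <- function(counts_tsv, taxonomy_tsv, meta_csv) {
  cts <- utils::read.delim(counts_tsv, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(cts[, -1, drop = FALSE])
  rownames(mat) <- cts[[1]]
  tax <- utils::read.delim(taxonomy_tsv, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
  taxon_table(mat, tax, meta)
}

#' Subset the samples of a taxon table
#'
#' @param table A [taxon_table()].
#' @param keep Logical or index vector over samples (evaluated against
#'   `sample_meta` rows).
#' @return A [taxon_table()] with the selected samples.
#' @export
subset_samples <- function(table, keep) {
  stopifnot(inherits(table, "taxon_table"))
  taxon_table(table$counts[, keep, drop = FALSE], table$taxonomy,
              table$sample_meta[keep, , drop = FALSE])
}

#' Remove archaeal taxa
#'
#' Archaea are typically a negligible fraction of 16S V4-5 libraries from
#' surface seawater and are discarded before screening; the step is explicit
#' and optional.
#'
#' @param table A [taxon_table()].
#' @return A [taxon_table()] without taxa whose domain is `Archaea`.
#' @export
drop_archaea <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  keep <- is.na(table$taxonomy$domain) |
    tolower(table$taxonomy$domain) != "archaea"
  taxon_table(table$counts[keep, , drop = FALSE],
              table$taxonomy[keep, , drop = FALSE], table$sample_meta)
}

#' Rarefy a taxon table to a common depth
#'
#' Subsamples each sample's counts without replacement to `depth` reads
#' (via `vegan::rrarefy`), the standard normalisation before comparing
#' relative abundances across unevenly sequenced samples. Samples with fewer
#' than `depth` reads are dropped with a warning. Deterministic for a fixed
#' seed.
#'
#' @param table A [taxon_table()].
#' @param depth Target depth; `NULL` (default) uses the minimum sample sum.
#' @param seed Integer seed.
#' @return A rarefied [taxon_table()]; every column sums to `depth`.
#' @export
rarefy_table <- function(table, depth = NULL, seed = 1) {
  stopifnot(inherits(table, "taxon_table"))
  totals <- colSums(table$counts)
  depth <- depth %||% min(totals)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth",
                       call. = FALSE)
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(table$counts)[!keep], collapse = ", ")))
    table <- subset_samples(table, keep)
  }
  # vegan heuristically warns when a table has no singleton counts; that is
  # expected for simulated or pre-filtered tables, so silence just that
  rar <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(t(table$counts), depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w), fixed = TRUE)) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- table
  out$counts <- t(rar)
  storage.mode(out$counts) <- "integer"
  attr(out, "rarefaction_depth") <- depth
  attr(out, "rarefaction_seed") <- seed
  out
}

#' Relative abundances aggregated to a taxonomic rank
#'
#' @param table A [taxon_table()].
#' @param level Rank to aggregate to (default `"genus"`). Taxa unassigned at
#'   that rank are pooled into an `"unclassified"` bin.
#' @return Numeric matrix (groups x samples); every column sums to 1.
#' @export
relative_abundance <- function(table, level = "genus") {
  stopifnot(inherits(table, "taxon_table"))
  level <- match.arg(level, TAXONOMIC_RANKS)
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    stop("empty sample(s): ",
         paste(colnames(table$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  grp <- table$taxonomy[[level]]
  grp[is.na(grp)] <- "unclassified"
  agg <- rowsum(table$counts, group = grp)
  sweep(agg, 2, totals, "/")
}

#' Load a curated HCB genus list
#'
#' One genus per line, `#` comments allowed. Names are trimmed; matching is
#' case-insensitive.
#'
#' @param path Path to the list file.
#' @return Character vector of genus names (class `hcb_list`).
#' @export
load_hcb_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genera <- unique(lines[nzchar(lines)])
  if (length(genera) == 0L) stop("HCB list is empty", call. = FALSE)
  structure(genera, class = c("hcb_list", "character"))
}

#' Shipped HCB genus list
#'
#' The in-package list covers well-documented polar marine HCB genera
#' (Pseudoalteromonas, Sulfitobacter, Psychrobacter, Colwellia, Glaciecola,
#' Alteromonas, Thalassospira); genus-level matching assumes members of a
#' genus share hydrocarbon-degrading metabolism, which holds for most but
#' not all HCB taxa. Edit or extend via [load_hcb_list()].
#'
#' @return Character vector of genus names.
#' @export
default_hcb_list <- function() {
  load_hcb_list(system.file("extdata", "hcb_genera.txt", package = "pahfate",
                            mustWork = TRUE))
}

#' Filter a taxon table to HCB taxa
#'
#' Retains exactly the taxa whose genus matches the HCB list
#' (case-insensitive); genus-unassigned taxa never match.
#'
#' @param table A [taxon_table()].
#' @param hcb Character vector of genera (default [default_hcb_list()]).
#' @return A [taxon_table()] subset (possibly with zero taxa).
#' @export
filter_hcb <- function(table, hcb = default_hcb_list()) {
  stopifnot(inherits(table, "taxon_table"))
  keep <- normalize_genus(table$taxonomy$genus) %in% normalize_genus(hcb)
  keep[is.na(table$taxonomy$genus)] <- FALSE
  out <- taxon_table(table$counts[keep, , drop = FALSE],
                     table$taxonomy[keep, , drop = FALSE], table$sample_meta)
  attr(out, "hcb_list") <- hcb
  out
}

#' Treatment-vs-control enrichment screen
#'
#' Within each stratum (by default every layer x size-fraction combination),
#' compares per-taxon relative abundances between the two arms of `arm_var`
#' (default PAH treatment vs control): per-arm mean proportion, signed fold
#' change ([fold_change()] convention) and a Welch t-test p-value when both
#' arms have >= 2 replicates. Taxa absent from both arms of a stratum are
#' excluded; a zero mean in one arm is replaced, for the fold change only,
#' by half the smallest nonzero proportion observed in that stratum (a
#' documented pseudo-proportion, since a ratio is undefined at zero).
#'
#' @param table A [taxon_table()] (typically rarefied).
#' @param level Rank at which to aggregate (default `"genus"`).
#' @param strata Metadata columns defining strata (default
#'   `c("layer", "fraction")`).
#' @param arm_var Metadata column splitting each stratum into two arms.
#' @param arms Length-2 character: treatment arm first, reference arm second.
#' @param hcb Optional HCB genus list used to flag taxa.
#' @return Data frame with columns `taxon`, the stratum columns,
#'   `mean_treatment`, `mean_control`, `fold_change`, `p_value`,
#'   `n_treatment`, `n_control`, `is_hcb`.
#' @export
enrichment_screen <- function(table, level = "genus",
                              strata = c("layer", "fraction"),
                              arm_var = "treatment",
                              arms = c("PAH", "CONTROL"),
                              hcb = default_hcb_list()) {
  stopifnot(inherits(table, "taxon_table"), length(arms) == 2L)
  stop_if_missing_cols(table$sample_meta, c(strata, arm_var),
                       "sample metadata")
  props <- relative_abundance(table, level)
  meta <- table$sample_meta
  stratum_key <- interaction(meta[strata], drop = TRUE, sep = "/")
  out <- list()
  for (s in levels(stratum_key)) {
    sel <- stratum_key == s
    arm <- meta[[arm_var]][sel]
    if (!all(arms %in% arm)) {
      warning(sprintf("stratum %s lacks arm(s) %s; skipped", s,
                      paste(setdiff(arms, arm), collapse = ", ")))
      next
    }
    p <- props[, sel, drop = FALSE]
    trt <- p[, arm == arms[1], drop = FALSE]
    ctl <- p[, arm == arms[2], drop = FALSE]
    mt <- rowMeans(trt)
    mc <- rowMeans(ctl)
    present <- mt > 0 | mc > 0
    if (!any(present)) next
    pseudo <- min(p[p > 0]) / 2
    testable <- ncol(trt) >= 2L && ncol(ctl) >= 2L
    if (!testable) {
      warning(sprintf(
        "stratum %s has a single replicate in an arm; p-values omitted", s))
    }
    pvals <- rep(NA_real_, sum(present))
    if (testable) {
      idx <- which(present)
      for (i in seq_along(idx)) {
        pvals[i] <- tryCatch(
          t_test(trt[idx[i], ], ctl[idx[i], ])$p_value,
          error = function(e) NA_real_)
      }
    }
    sd_ <- meta[sel, strata, drop = FALSE][1, , drop = FALSE]
    res <- data.frame(taxon = rownames(p)[present], sd_, row.names = NULL)
    res$mean_treatment <- mt[present]
    res$mean_control <- mc[present]
    res$fold_change <- fold_change(pmax(mt[present], pseudo),
                                   pmax(mc[present], pseudo))
    res$p_value <- pvals
    res$n_treatment <- ncol(trt)
    res$n_control <- ncol(ctl)
    out[[s]] <- res
  }
  if (length(out) == 0L) stop("no testable strata", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$is_hcb <- normalize_genus(res$taxon) %in% normalize_genus(hcb)
  res
}
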