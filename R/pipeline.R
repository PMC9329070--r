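#' Layer comparison of removal rates
#'
#' Mann-Whitney tests between two layers on per-replicate removal rates,
#' either per compound (`mode = "per_compound"`) or pooled within each
#' molecular-weight class (`mode = "pooled"`, rates of all class compounds
#' and replicates combined). With two bottles per condition a per-compound
#' exact test cannot reach p < 0.05 (minimum two-sided p is 1/3), so
#' class-level pooling is how significance is assessed in practice.
#'
#' @param results A `removal_results` object from [compute_removal()].
#' @param layers Length-2 character vector of layers to compare.
#' @param treatment Treatment arm to compare within (default `"PAH"`).
#' @param mode `"pooled"` (default) or `"per_compound"`.
#' @param registry Registry supplying weight classes for pooling.
#' @return Data frame with the comparison unit (`weight_class` or
#'   `compound`), group sizes, U statistic, `p_value` and `method`.
#' @export
compare_layers <- function(results, layers = c("SML", "SSL"),
                           treatment = "PAH",
                           mode = c("pooled", "per_compound"),
                           registry = pah_registry()) {
  mode <- match.arg(mode)
  rr <- replicate_rates(results)
  rr <- rr[rr$treatment == treatment & rr$layer %in% layers, ]
  if (nrow(rr) == 0L) stop("no rates for requested layers/treatment",
                           call. = FALSE)
  rr$weight_class <- registry$weight_class[match(rr$compound, registry$name)]
  units <- if (mode == "pooled") {
    split(rr[!is.na(rr$weight_class), ],
          rr$weight_class[!is.na(rr$weight_class)])
  } else {
    split(rr, rr$compound)
  }
  out <- do.call(rbind, lapply(names(units), function(u) {
    g <- units[[u]]
    x <- g$rate[g$layer == layers[1]]
    y <- g$rate[g$layer == layers[2]]
    if (length(x) == 0L || length(y) == 0L) return(NULL)
    ht <- mann_whitney(x, y)
    data.frame(unit = u, n1 = ht$n1, n2 = ht$n2,
               statistic = ht$statistic, p_value = ht$p_value,
               method = ht$method, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rates stage: removal, attribution and layer comparison
#'
#' End-to-end dissolved-phase stage: per-compound removal results (raw and,
#' when a benchmark is given, benchmark-corrected), a pooled-HMW
#' pseudo-compound, class summaries and layer-comparison tests.
#'
#' @param measurements Long measurement table (see [compute_removal()]) or a
#'   path to such a CSV.
#' @param registry A `pah_registry`.
#' @param contexts Optional per-layer partition context(s) for sorption
#'   bounds.
#' @param benchmark Benchmark compound, or `NULL` to skip correction.
#' @param noise_threshold Passed to [attribute_removal()].
#' @param out_dir Optional directory; when given, `rates.csv` and
#'   `layer_tests.csv` are written there.
#' @return List with `rates` (removal results incl. `sum_HMW` rows),
#'   `rates_benchmarked` (or `NULL`), `class_summary`, `layer_tests_pooled`,
#'   `layer_tests_per_compound`.
#' @export
run_rates <- function(measurements, registry = pah_registry(),
                      contexts = NULL, benchmark = NULL,
                      noise_threshold = 2, out_dir = NULL) {
  if (is.character(measurements)) {
    measurements <- utils::read.csv(measurements, stringsAsFactors = FALSE)
  }
  stop_if_missing_cols(measurements,
                       c("compound", "layer", "treatment", "replicate",
                         "time_h", "conc_ng_L"), "measurement table")
  if (!is.null(benchmark) &&
      !benchmark %in% unique(measurements$compound)) {
    stop("benchmark compound '", benchmark,
         "' absent from the measurement table", call. = FALSE)
  }
  res <- compute_removal(measurements, registry, benchmark = NULL,
                         contexts = contexts,
                         noise_threshold = noise_threshold)
  res_bm <- if (!is.null(benchmark)) {
    compute_removal(measurements, registry, benchmark = benchmark,
                    contexts = contexts, noise_threshold = noise_threshold)
  }

  # pooled-HMW pseudo-compound; its sorption bound is the most conservative
  # (largest) single-compound bound in the class
  hmw_series <- sum_class_series(measurements, registry, "HMW")
  hmw_res <- compute_removal(hmw_series, registry, contexts = NULL,
                             noise_threshold = noise_threshold)
  if (!is.null(contexts)) {
    hmw_names <- registry$name[registry$weight_class == "HMW"]
    for (layer in names(contexts)) {
      ctx <- contexts[[layer]]
      if (inherits(ctx, "partition_context")) ctx <- list(t0 = ctx, t1 = ctx)
      b <- max(sorption_artifact_bound(
        registry$log_kow[registry$name %in% hmw_names], ctx$t0, ctx$t1))
      hmw_res$sorption_bound[hmw_res$layer == layer] <- b
    }
    hmw_res$attribution <- attribute_removal(hmw_res$percent_decrease,
                                             hmw_res$sorption_bound,
                                             noise_threshold)
  }
  hmw_res$weight_class <- "HMW"
  per_rep <- rbind(attr(res, "per_replicate"), attr(hmw_res, "per_replicate"))
  rates <- rbind(as.data.frame(res), as.data.frame(hmw_res))
  attr(rates, "per_replicate") <- per_rep
  class(rates) <- c("removal_results", "data.frame")

  out <- list(
    rates = rates,
    rates_benchmarked = res_bm,
    class_summary = summarize_by_class(res, registry),
    layer_tests_pooled = compare_layers(res, registry = registry,
                                        mode = "pooled"),
    layer_tests_per_compound = compare_layers(res, registry = registry,
                                              mode = "per_compound")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(out$rates),
                     file.path(out_dir, "rates.csv"), row.names = FALSE)
    utils::write.csv(out$layer_tests_pooled,
                     file.path(out_dir, "layer_tests.csv"), row.names = FALSE)
  }
  out
}

#' Screening stage: rarefaction and HCB enrichment
#'
#' Rarefies an ASV table, restricts it to the final timepoint, screens every
#' genus for treatment-vs-control enrichment and summarizes the total HCB
#' share per stratum and arm.
#'
#' @param table A [taxon_table()].
#' @param hcb HCB genus list (default [default_hcb_list()]).
#' @param depth Rarefaction depth; `NULL` = minimum sample sum.
#' @param seed Seed for the rarefaction subsampling.
#' @param remove_archaea Drop archaeal taxa first (default `TRUE`).
#' @param timepoint Timepoint to screen (default `"T24"`; ignored when the
#'   metadata has no `timepoint` column).
#' @param out_dir Optional output directory for `enrichment.csv`.
#' @return List with `screen` (per-genus enrichment table), `hcb_summary`
#'   (HCB share of the community per stratum and arm), `depth`, `seed`.
#' @export
run_screen <- function(table, hcb = default_hcb_list(), depth = NULL,
                       seed = 1, remove_archaea = TRUE, timepoint = "T24",
                       out_dir = NULL) {
  stopifnot(inherits(table, "taxon_table"))
  if (remove_archaea) table <- drop_archaea(table)
  rar <- rarefy_table(table, depth = depth, seed = seed)
  used_depth <- attr(rar, "rarefaction_depth")
  if (!is.null(timepoint) && "timepoint" %in% names(rar$sample_meta)) {
    rar <- subset_samples(rar, rar$sample_meta$timepoint == timepoint)
  }
  screen <- enrichment_screen(rar, hcb = hcb)

  hcb_tab <- filter_hcb(rar, hcb)
  meta <- rar$sample_meta
  hcb_share <- colSums(hcb_tab$counts) / colSums(rar$counts)
  key <- interaction(meta$layer, meta$fraction, meta$treatment, drop = TRUE)
  hcb_summary <- do.call(rbind, lapply(split(seq_along(hcb_share), key),
    function(i) {
      data.frame(layer = meta$layer[i[1]], fraction = meta$fraction[i[1]],
                 treatment = meta$treatment[i[1]], n = length(i),
                 hcb_share_mean = mean(hcb_share[i]))
    }))
  rownames(hcb_summary) <- NULL

  out <- list(screen = screen, hcb_summary = hcb_summary,
              depth = used_depth, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(screen, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
  }
  out
}

#' Combined plain-text report
#'
#' Writes a human-readable summary of the rates and screening stages with a
#' provenance block (package version, R version, seed, config hash), so that
#' re-running with identical inputs reproduces an identical file.
#'
#' @param rates Output of [run_rates()].
#' @param screen Output of [run_screen()], or `NULL`.
#' @param path Output file path.
#' @param seed Seed used upstream (recorded verbatim).
#' @param config Optional list recorded (hashed) in the provenance block.
#' @return The path, invisibly.
#' @export
run_report <- function(rates, screen = NULL, path, seed = NA, config = NULL) {
  if (is.null(rates$rates)) stop("rates stage output missing", call. = FALSE)
  cfg_hash <- if (is.null(config)) "none" else {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(yaml::as.yaml(config), tmp)
    unname(tools::md5sum(tmp))
  }
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  w <- function(...) writeLines(sprintf(...), con)
  w("# PAH incubation report")
  w("provenance: pahfate %s | R %s.%s | seed %s | config %s",
    as.character(utils::packageVersion("pahfate")), R.version$major,
    R.version$minor, as.character(seed), cfg_hash)
  w("")
  w("## Removal rates (ng/L/h) by class")
  cs <- rates$class_summary
  for (i in seq_len(nrow(cs))) {
    w("  %s %s %s: mean %.3f sd %.3f range [%.3f, %.3f] (n=%d)%s",
      cs$layer[i], cs$treatment[i], cs$weight_class[i], cs$rate_mean[i],
      cs$rate_sd[i], cs$rate_min[i], cs$rate_max[i], cs$n[i],
      if (cs$any_negative[i]) " [contains negative rates]" else "")
  }
  w("")
  w("## Layer comparisons (Mann-Whitney, pooled per class)")
  lt <- rates$layer_tests_pooled
  for (i in seq_len(nrow(lt))) {
    w("  %s: U = %.1f, p = %.4g (n = %d vs %d)%s", lt$unit[i],
      lt$statistic[i], lt$p_value[i], lt$n1[i], lt$n2[i],
      if (lt$p_value[i] < 0.05) " *" else "")
  }
  w("")
  w("## Attribution")
  r <- as.data.frame(rates$rates)
  for (i in which(r$treatment == "PAH")) {
    w("  %s / %s: %.1f%% decrease, sorption bound %.2f%% -> %s",
      r$compound[i], r$layer[i], r$percent_decrease[i],
      100 * r$sorption_bound[i], r$attribution[i])
  }
  if (!is.null(screen)) {
    w("")
    w("## HCB enrichment screen (rarefied to %d)", screen$depth)
    sc <- screen$screen[screen$screen$is_hcb, , drop = FALSE]
    sc <- sc[order(-abs(sc$fold_change)), ]
    for (i in seq_len(min(nrow(sc), 20L))) {
      w("  %s [%s/%s]: fold %+.2f, p = %s", sc$taxon[i], sc$layer[i],
        sc$fraction[i], sc$fold_change[i],
        ifelse(is.na(sc$p_value[i]), "NA", sprintf("%.3g", sc$p_value[i])))
    }
  }
  invisible(path)
}
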