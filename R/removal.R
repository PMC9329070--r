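#' Two-point dissolved-phase removal rate
#'
#' `(c_t0 - c_t1) / dt` in ng per litre per hour. Negative values (apparent
#' production) are preserved, not truncated; downstream summaries flag them.
#'
#' @param c_t0,c_t1 Quantified dissolved concentrations, ng/L. `NA` (e.g.
#'   below limit of quantification) is an error: a two-point rate is not
#'   computable from censored endpoints.
#' @param dt Elapsed time in hours (> 0, default 24).
#' @return Rate(s) in ng L^-1 h^-1.
#' @examples
#' removal_rate(200, 126.08, 24)
#' @export
removal_rate <- function(c_t0, c_t1, dt = 24) {
  if (any(dt <= 0)) stop("dt must be > 0", call. = FALSE)
  if (anyNA(c_t0) || anyNA(c_t1)) {
    stop("rate not computable: endpoint concentration missing or below LOQ",
         call. = FALSE)
  }
  (c_t0 - c_t1) / dt
}

#' Percent decrease between two concentrations
#'
#' @inheritParams removal_rate
#' @return `100 * (c_t0 - c_t1) / c_t0`; never exceeds 100 for non-negative
#'   concentrations.
#' @export
percent_decrease <- function(c_t0, c_t1) {
  if (any(c_t0 <= 0)) stop("initial concentration must be > 0", call. = FALSE)
  100 * (c_t0 - c_t1) / c_t0
}

#' Benchmark-compound correction of a concentration series
#'
#' Bottle-common losses (wall sorption, handling, extraction recovery) affect
#' every analyte in a bottle by a shared factor. Normalizing to a benchmark
#' compound cancels them: within each bottle, the scale factor
#' `s(t) = C_bench(t) / C_bench(t0)` is divided out of every compound's
#' concentration, so the corrected benchmark series is constant and any
#' compound that lost mass only through the common process shows zero
#' corrected removal. The benchmark should be a compound whose own removal
#' does not differ across the conditions being compared (phenanthrene in the
#' default workflow). The transformation is a per-bottle ratio
#' normalization; it removes multiplicative bottle-common artifacts exactly.
#'
#' @param measurements Long-format data frame with columns `compound`,
#'   `layer`, `treatment`, `replicate`, `time_h`, `conc_ng_L` (and optionally
#'   `below_loq`).
#' @param benchmark Benchmark compound name (default `"phenanthrene"`). Must
#'   be quantified and nonzero in every bottle at every timepoint.
#' @return The input data frame with `conc_ng_L` replaced by corrected
#'   values and an added `scale_factor` column.
#' @export
benchmark_correct <- function(measurements, benchmark = "phenanthrene") {
  stop_if_missing_cols(measurements,
                       c("compound", "layer", "treatment", "replicate",
                         "time_h", "conc_ng_L"),
                       "measurement table")
  m <- measurements
  key <- interaction(m$layer, m$treatment, m$replicate, drop = TRUE)
  out <- lapply(split(m, key), function(bottle) {
    b <- bottle[bottle$compound == benchmark, ]
    times <- sort(unique(bottle$time_h))
    if (nrow(b) == 0L || !all(times %in% b$time_h)) {
      stop(sprintf("benchmark '%s' missing at some timepoint in bottle %s/%s/%s",
                   benchmark, bottle$layer[1], bottle$treatment[1],
                   bottle$replicate[1]), call. = FALSE)
    }
    if (!is.null(b$below_loq) && any(b$below_loq)) {
      stop(sprintf("benchmark '%s' below LOQ in bottle %s/%s/%s", benchmark,
                   bottle$layer[1], bottle$treatment[1], bottle$replicate[1]),
           call. = FALSE)
    }
    bench <- tapply(b$conc_ng_L, b$time_h, mean)
    t0 <- as.character(min(times))
    if (any(bench <= 0)) {
      stop(sprintf("benchmark '%s' is zero in bottle %s/%s/%s", benchmark,
                   bottle$layer[1], bottle$treatment[1], bottle$replicate[1]),
           call. = FALSE)
    }
    s <- bench / bench[[t0]]
    bottle$scale_factor <- as.numeric(s[as.character(bottle$time_h)])
    bottle$conc_ng_L <- bottle$conc_ng_L / bottle$scale_factor
    bottle
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "benchmark") <- benchmark
  res
}

#' Attribute a dissolved-phase decrease to biodegradation or sorption
#'
#' Decision rule comparing the observed percent decrease with the sorption
#' re-partitioning bound from [sorption_artifact_bound()]:
#' `NO_REMOVAL` when the decrease does not exceed the noise threshold,
#' `SORPTION_POSSIBLE` when re-partitioning alone could produce it,
#' `BIODEGRADATION_DOMINANT` otherwise.
#'
#' @param percent_decrease Observed percent decrease (may be negative).
#' @param sorption_bound Fraction in `[0, 1]` from
#'   [sorption_artifact_bound()].
#' @param noise_threshold Percent decrease below which removal is not
#'   distinguishable from measurement noise (default 2).
#' @return Character vector of attribution verdicts.
#' @export
attribute_removal <- function(percent_decrease, sorption_bound,
                              noise_threshold = 2) {
  if (any(sorption_bound < 0 | sorption_bound > 1)) {
    stop("sorption_bound must be in [0, 1]", call. = FALSE)
  }
  # ties (decrease == bound) count as sorption-explainable; the 1e-9
  # tolerance guards the comparison against floating-point roundoff
  ifelse(percent_decrease <= noise_threshold, "NO_REMOVAL",
         ifelse(100 * sorption_bound >= percent_decrease * (1 - 1e-9),
                "SORPTION_POSSIBLE", "BIODEGRADATION_DOMINANT"))
}

#' Per-compound removal results from a measurement table
#'
#' Computes per-replicate two-point rates (first vs. last timepoint of each
#' bottle), summarizes them as mean and sd per compound, layer and treatment,
#' and attaches percent decreases, optional sorption bounds and attribution
#' verdicts.
#'
#' @inheritParams benchmark_correct
#' @param registry A `pah_registry` used for weight classes and, with
#'   `contexts`, log Kow values. Compounds absent from the registry are kept
#'   with `NA` weight class.
#' @param benchmark Benchmark compound name, or `NULL` (default) for raw,
#'   uncorrected rates.
#' @param contexts Optional named list, one element per layer, each either a
#'   single [partition_context()] (time-constant; sorption bound 0) or a
#'   `list(t0 = , t1 = )` pair of contexts. When `NULL`, sorption bounds are
#'   0.
#' @param noise_threshold Passed to [attribute_removal()].
#' @return A `removal_results` data frame with one row per
#'   compound/layer/treatment: `n_reps`, `rate_mean`, `rate_sd`,
#'   `percent_decrease`, `negative_rate`, `benchmarked`, `sorption_bound`,
#'   `attribution`, `weight_class`.
#' @examples
#' reg <- pah_registry()
#' sim <- simulate_incubation(incubation_design(reg),
#'                            fate_parameters(reg, noise_cv = 0), seed = 1)
#' head(compute_removal(sim, reg))
#' @export
compute_removal <- function(measurements, registry = pah_registry(),
                            benchmark = NULL, contexts = NULL,
                            noise_threshold = 2) {
  stop_if_missing_cols(measurements,
                       c("compound", "layer", "treatment", "replicate",
                         "time_h", "conc_ng_L"),
                       "measurement table")
  benchmarked <- !is.null(benchmark)
  if (benchmarked) {
    measurements <- benchmark_correct(measurements, benchmark)
  }
  m <- measurements
  if (!is.null(m$below_loq) && any(m$below_loq)) {
    stop("measurement table contains below-LOQ endpoints; two-point rates ",
         "are not computable for censored data", call. = FALSE)
  }
  key <- interaction(m$compound, m$layer, m$treatment, m$replicate,
                     drop = TRUE)
  per_rep <- do.call(rbind, lapply(split(m, key), function(g) {
    g <- g[order(g$time_h), ]
    if (length(unique(g$time_h)) < 2L) {
      stop(sprintf("need >= 2 timepoints for %s (%s/%s rep %s)",
                   g$compound[1], g$layer[1], g$treatment[1], g$replicate[1]),
           call. = FALSE)
    }
    c0 <- g$conc_ng_L[1]
    c1 <- g$conc_ng_L[nrow(g)]
    dt <- g$time_h[nrow(g)] - g$time_h[1]
    data.frame(compound = g$compound[1], layer = g$layer[1],
               treatment = g$treatment[1], replicate = g$replicate[1],
               dt_h = dt, rate = removal_rate(c0, c1, dt),
               pct = percent_decrease(c0, c1))
  }))
  rownames(per_rep) <- NULL

  skey <- interaction(per_rep$compound, per_rep$layer, per_rep$treatment,
                      drop = TRUE)
  res <- do.call(rbind, lapply(split(per_rep, skey), function(g) {
    data.frame(compound = g$compound[1], layer = g$layer[1],
               treatment = g$treatment[1], n_reps = nrow(g),
               rate_mean = mean(g$rate),
               rate_sd = if (nrow(g) > 1L) stats::sd(g$rate) else NA_real_,
               percent_decrease = mean(g$pct),
               negative_rate = mean(g$rate) < 0)
  }))
  rownames(res) <- NULL
  res$benchmarked <- benchmarked

  reg_idx <- match(res$compound, registry$name)
  res$weight_class <- registry$weight_class[reg_idx]
  res$sorption_bound <- 0
  if (!is.null(contexts)) {
    for (layer in names(contexts)) {
      ctx <- contexts[[layer]]
      if (inherits(ctx, "partition_context")) ctx <- list(t0 = ctx, t1 = ctx)
      sel <- res$layer == layer & !is.na(reg_idx)
      if (any(sel)) {
        res$sorption_bound[sel] <- sorption_artifact_bound(
          registry$log_kow[reg_idx[sel]], ctx$t0, ctx$t1)
      }
    }
  }
  res$attribution <- attribute_removal(res$percent_decrease,
                                       res$sorption_bound, noise_threshold)
  attr(res, "per_replicate") <- per_rep
  class(res) <- c("removal_results", "data.frame")
  res
}

#' Per-replicate rates underlying a removal-results table
#'
#' @param results A `removal_results` object from [compute_removal()].
#' @return Data frame with one row per compound/layer/treatment/replicate.
#' @export
replicate_rates <- function(results) {
  stopifnot(inherits(results, "removal_results"))
  attr(results, "per_replicate")
}

#' Summaries of removal rates by molecular-weight class
#'
#' @param results A `removal_results` data frame.
#' @param registry A `pah_registry` (used when `results` lacks weight
#'   classes).
#' @return Data frame of per (layer, treatment, weight_class) summaries:
#'   `n`, `rate_mean`, `rate_sd`, `rate_min`, `rate_max`,
#'   `any_negative`. Classes with no compounds are absent, not zero-filled.
#' @export
summarize_by_class <- function(results, registry = pah_registry()) {
  r <- as.data.frame(results)
  if (is.null(r$weight_class) || all(is.na(r$weight_class))) {
    r$weight_class <- registry$weight_class[match(r$compound, registry$name)]
  }
  r <- r[!is.na(r$weight_class), ]
  if (nrow(r) == 0L) stop("no classified compounds in results", call. = FALSE)
  key <- interaction(r$layer, r$treatment, r$weight_class, drop = TRUE)
  out <- do.call(rbind, lapply(split(r, key), function(g) {
    data.frame(layer = g$layer[1], treatment = g$treatment[1],
               weight_class = g$weight_class[1], n = nrow(g),
               rate_mean = mean(g$rate_mean),
               rate_sd = if (nrow(g) > 1L) stats::sd(g$rate_mean) else NA_real_,
               rate_min = min(g$rate_mean), rate_max = max(g$rate_mean),
               any_negative = any(g$rate_mean < 0))
  }))
  rownames(out) <- NULL
  out
}

#' Sum dissolved concentrations over a weight class
#'
#' Builds a pseudo-compound series (e.g. `sum_HMW`) by summing, per bottle
#' and timepoint, the concentrations of all registry compounds in a class.
#' Useful because class sums are how pooled removal is usually reported.
#'
#' @inheritParams compute_removal
#' @param weight_class `"HMW"` or `"LMW"`.
#' @return A measurement data frame with `compound = "sum_<class>"`.
#' @export
sum_class_series <- function(measurements, registry = pah_registry(),
                             weight_class = "HMW") {
  keep <- registry$name[registry$weight_class == weight_class &
                          !registry$volatile_excluded]
  m <- measurements[measurements$compound %in% keep, ]
  if (nrow(m) == 0L) stop("no compounds of class ", weight_class, call. = FALSE)
  agg <- stats::aggregate(conc_ng_L ~ layer + treatment + replicate + time_h,
                          data = m, FUN = sum)
  agg$compound <- paste0("sum_", weight_class)
  agg[, c("compound", "layer", "treatment", "replicate", "time_h",
          "conc_ng_L")]
}
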