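#' Incubation experimental design
#'
#' Describes the bottle layout of a two-timepoint spiked incubation: layers,
#' treatments, replicate bottles, timepoints and the nominal per-compound
#' spike. Control bottles start at in-situ background levels instead of the
#' spike; the background is given as a total dissolved PAH concentration per
#' layer, spread uniformly over the registry compounds. Abiotic controls
#' (HPLC-grade water, no biology) can be included as a pseudo-layer.
#'
#' @param registry A `pah_registry`; volatile-excluded compounds are omitted.
#' @param layers Character vector (default `c("SML", "SSL")`).
#' @param treatments Character vector (default `c("PAH", "CONTROL")`).
#' @param replicates Bottles per condition (default 2).
#' @param timepoints_h Sampling times in hours (default `c(0, 24)`).
#' @param spike_ng_L Nominal per-compound spike, ng/L (default 200).
#' @param control_total_ng_L Named per-layer total background dissolved PAH,
#'   ng/L (defaults typical of Antarctic coastal surface water).
#' @param abiotic_replicates Abiotic control bottles (default 2; 0 disables).
#' @return An `incubation_design` list.
#' @export
incubation_design <- function(registry = pah_registry(),
                              layers = c("SML", "SSL"),
                              treatments = c("PAH", "CONTROL"),
                              replicates = 2,
                              timepoints_h = c(0, 24),
                              spike_ng_L = 200,
                              control_total_ng_L = c(SML = 0.74, SSL = 3.63),
                              abiotic_replicates = 2) {
  stopifnot(inherits(registry, "pah_registry"))
  if (length(timepoints_h) < 2L) stop(">= 2 timepoints required", call. = FALSE)
  if (spike_ng_L < 0) stop("spike must be >= 0", call. = FALSE)
  if (!all(layers %in% names(control_total_ng_L)) &&
      "CONTROL" %in% treatments) {
    stop("control_total_ng_L must name every layer", call. = FALSE)
  }
  structure(list(
    registry = registry[!registry$volatile_excluded, , drop = FALSE],
    layers = layers, treatments = treatments, replicates = replicates,
    timepoints_h = sort(timepoints_h), spike_ng_L = spike_ng_L,
    control_total_ng_L = control_total_ng_L,
    abiotic_replicates = abiotic_replicates
  ), class = "incubation_design")
}

#' Fate parameters for the incubation simulator
#'
#' The generative model: in each bottle the total amount of a compound
#' decays first-order, `total(t) = C0 * exp(-(k_bio + k_wall) * t)`, and the
#' measured dissolved concentration is the equilibrium dissolved fraction of
#' that total (from the layer's [partition_context()]) times mean-one
#' lognormal measurement noise.
#'
#' @param registry A `pah_registry` (defines compound order for `k_bio`).
#' @param k_bio Either a single rate, or a matrix (compounds x layers,
#'   dimnames required) of first-order biodegradation constants, per hour.
#' @param k_wall Bottle-common first-order loss constant, per hour
#'   (default 0).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (default 0.1). The lognormal is parameterised to have
#'   mean exactly 1 and CV exactly `noise_cv`.
#' @param contexts Named list per layer: a single [partition_context()]
#'   (time-constant) or `list(t0 = , t1 = )`. Default: a context with zero
#'   biomass and DOC (dissolved fraction 1).
#' @return A `fate_parameters` list.
#' @export
fate_parameters <- function(registry = pah_registry(), k_bio = 0,
                            k_wall = 0, noise_cv = 0.1, contexts = NULL) {
  stopifnot(inherits(registry, "pah_registry"))
  reg <- registry[!registry$volatile_excluded, , drop = FALSE]
  if (is.matrix(k_bio)) {
    if (is.null(rownames(k_bio)) || is.null(colnames(k_bio))) {
      stop("k_bio matrix needs compound rownames and layer colnames",
           call. = FALSE)
    }
    if (!all(reg$name %in% rownames(k_bio))) {
      stop("k_bio matrix missing registry compound(s)", call. = FALSE)
    }
  } else if (length(k_bio) != 1L) {
    stop("k_bio must be a scalar or a compound x layer matrix", call. = FALSE)
  }
  if (any(k_bio < 0) || k_wall < 0) stop("rates must be >= 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(k_bio = k_bio, k_wall = k_wall, noise_cv = noise_cv,
                 contexts = contexts),
            class = "fate_parameters")
}

ctx_at <- function(contexts, layer, first) {
  if (is.null(contexts) || is.null(contexts[[layer]])) return(NULL)
  ctx <- contexts[[layer]]
  if (inherits(ctx, "partition_context")) return(ctx)
  if (first) ctx$t0 else ctx$t1
}

k_bio_for <- function(params, compound, layer) {
  if (is.matrix(params$k_bio)) {
    if (!layer %in% colnames(params$k_bio)) return(0)
    params$k_bio[compound, layer]
  } else {
    params$k_bio
  }
}

# Noise-free expected measurement grid for a design/parameter pair.
expected_measurements <- function(design, params) {
  reg <- design$registry
  rows <- list()
  conditions <- expand.grid(layer = design$layers,
                            treatment = design$treatments,
                            replicate = seq_len(design$replicates),
                            stringsAsFactors = FALSE)
  if (design$abiotic_replicates > 0) {
    conditions <- rbind(conditions,
                        expand.grid(layer = "ABIOTIC", treatment = "PAH",
                                    replicate = seq_len(design$abiotic_replicates),
                                    stringsAsFactors = FALSE))
  }
  tp <- design$timepoints_h
  first_tp <- min(tp)
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    abiotic <- cond$layer == "ABIOTIC"
    c0 <- if (cond$treatment == "PAH") design$spike_ng_L
          else design$control_total_ng_L[[cond$layer]] / nrow(reg)
    for (j in seq_len(nrow(reg))) {
      k <- if (abiotic) params$k_wall
           else k_bio_for(params, reg$name[j], cond$layer) + params$k_wall
      for (t in tp) {
        ctx <- if (abiotic) NULL
               else ctx_at(params$contexts, cond$layer, t == first_tp)
        fd <- if (is.null(ctx)) 1
              else compound_fractions(reg$log_kow[j], ctx)$f_dissolved
        rows[[length(rows) + 1L]] <- data.frame(
          compound = reg$name[j], layer = cond$layer,
          treatment = cond$treatment, replicate = cond$replicate,
          time_h = t, conc_ng_L = fd * c0 * exp(-k * t))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a spiked-incubation concentration table
#'
#' Generates the long-format measurement table the removal pipeline
#' consumes, under the generative model described in [fate_parameters()].
#' Deterministic for a fixed seed; noise draws follow the row order of the
#' output.
#'
#' @param design An [incubation_design()].
#' @param params A [fate_parameters()].
#' @param seed Integer seed.
#' @return Data frame with columns `compound`, `layer`, `treatment`,
#'   `replicate`, `time_h`, `conc_ng_L`, `below_loq` (always `FALSE` here).
#' @examples
#' reg <- pah_registry()
#' sim <- simulate_incubation(incubation_design(reg), fate_parameters(reg),
#'                            seed = 42)
#' head(sim)
#' @export
simulate_incubation <- function(design, params, seed = 1) {
  stopifnot(inherits(design, "incubation_design"),
            inherits(params, "fate_parameters"))
  out <- expected_measurements(design, params)
  if (params$noise_cv > 0) {
    sigma <- sqrt(log(1 + params$noise_cv^2))
    noise <- with_seed(seed,
      exp(stats::rnorm(nrow(out), mean = -sigma^2 / 2, sd = sigma)))
    out$conc_ng_L <- out$conc_ng_L * noise
  }
  out$below_loq <- FALSE
  out
}

#' Model-implied true removal rates
#'
#' The noise-free two-point dissolved-phase rate the estimator targets:
#' `(m(t0) - m(t_end)) / dt` of the expected measured concentration, per
#' compound, layer and treatment. This is the ground truth for recovery
#' tests of [compute_removal()].
#'
#' @inheritParams simulate_incubation
#' @return Data frame with `compound`, `layer`, `treatment`, `rate_true`.
#' @export
true_removal_rates <- function(design, params) {
  m <- expected_measurements(design, params)
  t0 <- min(design$timepoints_h)
  t1 <- max(design$timepoints_h)
  m <- m[m$replicate == 1 & m$time_h %in% c(t0, t1), ]
  key <- interaction(m$compound, m$layer, m$treatment, drop = TRUE)
  out <- do.call(rbind, lapply(split(m, key), function(g) {
    g <- g[order(g$time_h), ]
    data.frame(compound = g$compound[1], layer = g$layer[1],
               treatment = g$treatment[1],
               rate_true = (g$conc_ng_L[1] - g$conc_ng_L[2]) / (t1 - t0))
  }))
  rownames(out) <- NULL
  out
}
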