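#' Bioconcentration factor from hydrophobicity
#'
#' Equilibrium microorganism-water bioconcentration factor
#' `BCF = C_M / C_W = f_OM * Kow / delta`, where `f_OM` is the organic-matter
#' fraction of the biomass and `delta` the density of octanol. The BCF scales
#' linearly with Kow, i.e. exponentially with `log_kow`.
#'
#' @param log_kow Decimal log of the octanol-water partition constant.
#' @param f_om Organic-matter fraction of the sorbing biomass, in `[0, 1]`.
#' @param delta_octanol Density of octanol, kg/L (> 0; default 0.82).
#' @return BCF in L/kg organic matter.
#' @examples
#' bcf(6, f_om = 0.5, delta_octanol = 0.82)
#' @export
bcf <- function(log_kow, f_om = 1, delta_octanol = 0.82) {
  if (any(delta_octanol <= 0)) stop("delta_octanol must be > 0", call. = FALSE)
  if (any(f_om < 0 | f_om > 1)) stop("f_om must be in [0, 1]", call. = FALSE)
  f_om * 10^log_kow / delta_octanol
}

#' DOC-water partition coefficient
#'
#' Sorption to dissolved organic carbon is modelled with the common
#' approximation `K_DOC = 0.1 * Kow`.
#'
#' @inheritParams bcf
#' @return K_DOC in L/kg carbon.
#' @export
kdoc <- function(log_kow) {
  0.1 * 10^log_kow
}

#' Microbial biomass concentration from cell counts
#'
#' Converts flow-cytometry cell counts to kg organic matter per litre, using
#' a per-cell carbon content (default 20 fg C per cell, a standard value for
#' marine heterotrophic bacteria) and an organic-matter : organic-carbon
#' conversion ratio (default 2 g OM per g C).
#'
#' @param cells_per_L Cell abundance, cells/L (>= 0).
#' @param fg_c_per_cell Carbon content per cell in femtograms (default 20).
#' @param om_to_oc_ratio Grams organic matter per gram organic carbon
#'   (default 2, >= 1).
#' @return Biomass in kg organic matter / L.
#' @examples
#' biomass_from_cells(1e9, 20, om_to_oc_ratio = 1)  # 2e-8 kg/L
#' @export
biomass_from_cells <- function(cells_per_L, fg_c_per_cell = 20,
                               om_to_oc_ratio = 2) {
  if (any(cells_per_L < 0) || any(fg_c_per_cell < 0)) {
    stop("cell abundance and carbon content must be >= 0", call. = FALSE)
  }
  if (any(om_to_oc_ratio < 1)) {
    stop("om_to_oc_ratio must be >= 1", call. = FALSE)
  }
  cells_per_L * fg_c_per_cell * 1e-18 * om_to_oc_ratio
}

#' DOC mass concentration from a molar concentration
#'
#' @param doc_molar Dissolved organic carbon in micromolar carbon (>= 0).
#'   60 uM is a typical Antarctic surface-seawater value.
#' @return DOC in kg C / L.
#' @export
doc_mass_concentration <- function(doc_molar) {
  if (any(doc_molar < 0)) stop("doc_molar must be >= 0", call. = FALSE)
  doc_molar * 1e-6 * 12.011 * 1e-3
}

#' Assemble a partitioning context
#'
#' Bundles the biomass, DOC and physical constants needed by the three-pool
#' (dissolved / biota / DOC) equilibrium mass balance. Bacterial biomass is
#' derived from cell counts via [biomass_from_cells()]; phytoplankton biomass
#' (e.g. from net tows) enters as additional kg OM/L in the same pooled biota
#' compartment — no separate phytoplankton BCF is used.
#'
#' @param cells_per_L Bacterial abundance, cells/L.
#' @param fg_c_per_cell Carbon per cell, fg (default 20).
#' @param om_to_oc_ratio g OM per g C (default 2).
#' @param phyto_kgOM_per_L Phytoplankton biomass, kg OM/L (default 0).
#' @param doc_uM Dissolved organic carbon, uM C (default 60).
#' @param f_om Organic-matter fraction used in the BCF (default 1, since the
#'   biomass is already expressed on an organic-matter basis).
#' @param delta_octanol Density of octanol, kg/L (default 0.82).
#' @return An object of class `partition_context`.
#' @examples
#' ctx <- partition_context(cells_per_L = 3e8, phyto_kgOM_per_L = 1e-8)
#' ctx$biomass_kgOM_per_L
#' @export
partition_context <- function(cells_per_L = 0, fg_c_per_cell = 20,
                              om_to_oc_ratio = 2, phyto_kgOM_per_L = 0,
                              doc_uM = 60, f_om = 1, delta_octanol = 0.82) {
  if (phyto_kgOM_per_L < 0) stop("phyto_kgOM_per_L must be >= 0", call. = FALSE)
  ctx <- list(
    f_om = f_om,
    delta_octanol = delta_octanol,
    om_to_oc_ratio = om_to_oc_ratio,
    cells_per_L = cells_per_L,
    fg_c_per_cell = fg_c_per_cell,
    phyto_kgOM_per_L = phyto_kgOM_per_L,
    doc_uM = doc_uM,
    biomass_kgOM_per_L =
      biomass_from_cells(cells_per_L, fg_c_per_cell, om_to_oc_ratio) +
      phyto_kgOM_per_L,
    doc_kg_per_L = doc_mass_concentration(doc_uM)
  )
  # validates f_om / delta ranges
  invisible(bcf(0, ctx$f_om, ctx$delta_octanol))
  structure(ctx, class = "partition_context")
}

#' Equilibrium mass fractions over three pools
#'
#' Closes the BCF ratio into a mass balance over dissolved water, pooled
#' biota and DOC in a fixed volume:
#' `f_dissolved = 1 / (1 + BCF*B + K_DOC*D)`, with the sorbed fractions
#' `BCF*B*f_dissolved` and `K_DOC*D*f_dissolved`. The three fractions sum to
#' one exactly.
#'
#' @param bcf Bioconcentration factor, L/kg OM (vectorised).
#' @param biomass_kgOM_per_L Biota organic matter, kg/L.
#' @param kdoc DOC-water partition coefficient, L/kg C (vectorised with
#'   `bcf`).
#' @param doc_kg_per_L DOC, kg C/L.
#' @return Data frame with columns `f_dissolved`, `f_biota`, `f_doc`.
#' @examples
#' equilibrium_fractions(bcf = 1 / 2e-8, biomass_kgOM_per_L = 2e-8,
#'                       kdoc = 0, doc_kg_per_L = 0)  # 0.5 / 0.5 / 0
#' @export
equilibrium_fractions <- function(bcf, biomass_kgOM_per_L, kdoc, doc_kg_per_L) {
  if (any(bcf < 0) || any(kdoc < 0) || any(biomass_kgOM_per_L < 0) ||
      any(doc_kg_per_L < 0)) {
    stop("all partitioning inputs must be >= 0", call. = FALSE)
  }
  qb <- bcf * biomass_kgOM_per_L
  qd <- kdoc * doc_kg_per_L
  fd <- 1 / (1 + qb + qd)
  data.frame(f_dissolved = fd, f_biota = qb * fd, f_doc = qd * fd)
}

#' Equilibrium fractions for compounds in a context
#'
#' Convenience wrapper mapping `log_kow` values through [bcf()] and [kdoc()]
#' into [equilibrium_fractions()] for a given [partition_context()].
#'
#' @param log_kow Numeric vector of log Kow values, or a `pah_registry` whose
#'   `log_kow` column is used.
#' @param ctx A [partition_context()].
#' @return Data frame of fractions, one row per compound.
#' @export
compound_fractions <- function(log_kow, ctx) {
  stopifnot(inherits(ctx, "partition_context"))
  if (inherits(log_kow, "pah_registry")) log_kow <- log_kow$log_kow
  equilibrium_fractions(
    bcf = bcf(log_kow, ctx$f_om, ctx$delta_octanol),
    biomass_kgOM_per_L = ctx$biomass_kgOM_per_L,
    kdoc = kdoc(log_kow),
    doc_kg_per_L = ctx$doc_kg_per_L)
}

#' Upper bound on dissolved-phase decrease explained by re-partitioning
#'
#' If the organic-matter pools grow between two timepoints, part of an
#' apparent dissolved-phase decrease is sorption, not degradation. The bound
#' is `max(0, 1 - f_dissolved(t1) / f_dissolved(t0))`: the fractional
#' dissolved-phase decrease a pure re-equilibration would produce. It is zero
#' when the pools do not change, and floored at zero (a biomass decline
#' cannot explain a dissolved-phase decrease).
#'
#' @param log_kow log Kow value(s) or a `pah_registry`.
#' @param ctx_t0,ctx_t1 [partition_context()] at the initial and final
#'   timepoints.
#' @return Fraction(s) in `[0, 1]`.
#' @export
sorption_artifact_bound <- function(log_kow, ctx_t0, ctx_t1) {
  fd0 <- compound_fractions(log_kow, ctx_t0)$f_dissolved
  fd1 <- compound_fractions(log_kow, ctx_t1)$f_dissolved
  pmax(0, 1 - fd1 / fd0)
}
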