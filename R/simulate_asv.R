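DECOY_GENERA <- c("SAR11_clade", "Polaribacter", "Amylibacter",
                  "Planktomarina", "SUP05_cluster", "Octadecabacter",
                  "Lentimonas", "Luteolibacter", "Fluviicola", "Nitrincola",
                  "Polarimicrobium", "Aurantivirga")

#' Community scenario for the ASV-table simulator
#'
#' Describes a Dirichlet-multinomial amplicon community: a lognormal
#' baseline abundance profile over `n_taxa` ASVs, one ASV per HCB genus
#' (remaining taxa drawn from decoy marine genera, a few left
#' genus-unassigned), and a per-genus weight multiplier applied in the
#' PAH-exposed arm of selected layers. Within a sample, relative weights are
#' renormalized after enrichment and counts are drawn as
#' `DirichletMultinomial(depth, alpha = weights * dirichlet_concentration)`.
#'
#' Note that renormalization makes the observable relative-abundance fold of
#' an enriched genus smaller than the injected weight multiplier:
#' `fold_realized = f / (1 + (f - 1) * p0)` for baseline proportion `p0`
#' (see [true_enrichment_fold()]).
#'
#' @param n_taxa Number of ASVs (default 150).
#' @param hcb_genera HCB genus names to embed (default
#'   [default_hcb_list()]).
#' @param enrichment Named numeric vector of weight multipliers (> 0) applied
#'   to HCB genera in PAH arms, e.g. `c(Pseudoalteromonas = 8)`. Unnamed
#'   genera default to 1.
#' @param baseline_props Named vector of baseline proportions pinned for
#'   specific genera (default Pseudoalteromonas 3.7%, Sulfitobacter 4.4%,
#'   typical HCB levels in unexposed Antarctic surface water).
#' @param dirichlet_concentration Total Dirichlet concentration (default 50;
#'   moderate replicate-to-replicate overdispersion).
#' @param depth Reads per sample (default 30000).
#' @param layers,fractions,treatments Design factors.
#' @param replicates Samples per stratum arm (default 2).
#' @param timepoints Character timepoints (default `c("T0", "T24")`);
#'   enrichment acts only at the final timepoint.
#' @param enrich_layers Layers where enrichment acts (default `"SML"`).
#' @param baseline_sdlog Lognormal sd of the baseline profile (default 1.5).
#' @return A `community_scenario` list.
#' @export
community_scenario <- function(n_taxa = 150,
                               hcb_genera = default_hcb_list(),
                               enrichment = c(Pseudoalteromonas = 8),
                               baseline_props = c(Pseudoalteromonas = 0.037,
                                                  Sulfitobacter = 0.044),
                               dirichlet_concentration = 50,
                               depth = 30000,
                               layers = c("SML", "SSL"),
                               fractions = c("PA", "FL"),
                               treatments = c("PAH", "CONTROL"),
                               replicates = 2,
                               timepoints = c("T0", "T24"),
                               enrich_layers = "SML",
                               baseline_sdlog = 1.5) {
  if (any(enrichment <= 0)) stop("enrichment factors must be > 0",
                                 call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (n_taxa < length(hcb_genera) + 2L) {
    stop("n_taxa too small for the genus pool", call. = FALSE)
  }
  if (dirichlet_concentration <= 0) {
    stop("dirichlet_concentration must be > 0", call. = FALSE)
  }
  structure(list(n_taxa = n_taxa, hcb_genera = as.character(hcb_genera),
                 enrichment = enrichment, baseline_props = baseline_props,
                 dirichlet_concentration = dirichlet_concentration,
                 depth = depth, layers = layers, fractions = fractions,
                 treatments = treatments, replicates = replicates,
                 timepoints = timepoints, enrich_layers = enrich_layers,
                 baseline_sdlog = baseline_sdlog),
            class = "community_scenario")
}

scenario_weights <- function(scenario) {
  n <- scenario$n_taxa
  genera <- character(n)
  ng <- length(scenario$hcb_genera)
  genera[seq_len(ng)] <- scenario$hcb_genera
  genera[(ng + 1):n] <- sample(DECOY_GENERA, n - ng, replace = TRUE)
  # leave a small tail genus-unassigned, as in real SILVA classifications
  unassigned <- seq(n - max(2L, n %/% 30) + 1L, n)
  genera[unassigned] <- NA_character_
  w <- stats::rlnorm(n, meanlog = 0, sdlog = scenario$baseline_sdlog)
  # pin requested genera to fixed baseline proportions
  for (g in names(scenario$baseline_props)) {
    idx <- which(!is.na(genera) & genera == g)
    if (length(idx) == 0L) next
    p <- scenario$baseline_props[[g]]
    rest <- sum(w[-idx])
    w[idx] <- p * rest / (1 - p) / length(idx)
  }
  list(weights = w / sum(w), genera = genera)
}

#' Simulate an ASV count table
#'
#' Draws a [taxon_table()] under a [community_scenario()]: one sample per
#' (layer, fraction, treatment, replicate, timepoint) cell, with HCB
#' enrichment applied in PAH arms of the enrichment layers at the final
#' timepoint. Deterministic for a fixed seed.
#'
#' @param scenario A [community_scenario()].
#' @param seed Integer seed.
#' @return A [taxon_table()] with SILVA-style taxonomy strings and sample
#'   metadata columns `layer`, `fraction`, `treatment`, `timepoint`,
#'   `replicate`.
#' @export
simulate_asv_table <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "community_scenario"))
  with_seed(seed, {
    base <- scenario_weights(scenario)
    taxa <- sprintf("ASV_%04d", seq_len(scenario$n_taxa))
    design <- expand.grid(layer = scenario$layers,
                          fraction = scenario$fractions,
                          treatment = scenario$treatments,
                          replicate = seq_len(scenario$replicates),
                          timepoint = scenario$timepoints,
                          stringsAsFactors = FALSE)
    design$sample_id <- sprintf("%s_%s_%s_%s_R%d", design$layer,
                                design$fraction, design$treatment,
                                design$timepoint, design$replicate)
    final_tp <- scenario$timepoints[length(scenario$timepoints)]
    counts <- matrix(0L, nrow = scenario$n_taxa, ncol = nrow(design),
                     dimnames = list(taxa, design$sample_id))
    for (i in seq_len(nrow(design))) {
      w <- base$weights
      enriched_here <- design$treatment[i] == "PAH" &&
        design$timepoint[i] == final_tp &&
        design$layer[i] %in% scenario$enrich_layers
      if (enriched_here) {
        for (g in names(scenario$enrichment)) {
          idx <- which(!is.na(base$genera) & base$genera == g)
          w[idx] <- w[idx] * scenario$enrichment[[g]]
        }
      }
      w <- w / sum(w)
      alpha <- w * scenario$dirichlet_concentration
      gam <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      # guard: all-zero gamma draws are astronomically unlikely but fatal
      if (sum(gam) == 0) gam <- w
      counts[, i] <- stats::rmultinom(1, scenario$depth, gam / sum(gam))[, 1]
    }
    lineage_for <- function(genus) {
      if (is.na(genus)) return("Bacteria;Proteobacteria;;;;;")
      paste("Bacteria", "Proteobacteria", "Gammaproteobacteria",
            "Alteromonadales", paste0(genus, "aceae"), genus, "", sep = ";")
    }
    taxonomy <- data.frame(
      taxon_id = taxa,
      lineage = vapply(base$genera, lineage_for, character(1)),
      stringsAsFactors = FALSE)
    taxon_table(counts, taxonomy,
                design[, c("sample_id", "layer", "fraction", "treatment",
                           "timepoint", "replicate")])
  })
}

#' Realized relative-abundance fold of an enriched genus
#'
#' The model-implied observable fold change of a single enriched genus under
#' a [community_scenario()]: applying weight multiplier `f` to a genus at
#' baseline proportion `p0` and renormalizing yields relative abundance
#' `f * p0 / (1 + (f - 1) * p0)`, i.e. a fold of `f / (1 + (f - 1) * p0)`.
#' Requires the genus's baseline proportion to be pinned in
#' `baseline_props` and no other genus to be enriched.
#'
#' @param scenario A [community_scenario()].
#' @param genus Genus name (default the single enriched genus).
#' @return The realized fold change (>= 1 for `f >= 1`).
#' @export
true_enrichment_fold <- function(scenario,
                                 genus = names(scenario$enrichment)[1]) {
  stopifnot(inherits(scenario, "community_scenario"))
  enriched <- names(scenario$enrichment)[scenario$enrichment != 1]
  if (length(enriched) > 1L) {
    stop("closed form only available for a single enriched genus",
         call. = FALSE)
  }
  f <- scenario$enrichment[[genus]] %||% 1
  p0 <- scenario$baseline_props[[genus]]
  if (is.null(p0)) {
    stop("baseline proportion for ", genus, " is not pinned", call. = FALSE)
  }
  f / (1 + (f - 1) * p0)
}
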