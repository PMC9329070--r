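test_that("conservation: no loss processes, no noise, constant series", {
  reg <- pah_registry()
  design <- incubation_design(reg, treatments = "PAH",
                              abiotic_replicates = 0)
  params <- fate_parameters(reg, k_bio = 0, k_wall = 0, noise_cv = 0)
  sim <- simulate_incubation(design, params, seed = 1)
  expect_true(all(sim$conc_ng_L == design$spike_ng_L))

  # with a partitioning context, both timepoints equal the dissolved share
  ctx <- list(SML = partition_context(cells_per_L = 3e8),
              SSL = partition_context(cells_per_L = 3e8))
  params2 <- fate_parameters(reg, k_bio = 0, noise_cv = 0, contexts = ctx)
  sim2 <- simulate_incubation(design, params2, seed = 1)
  fd <- compound_fractions(reg, ctx$SML)$f_dissolved
  for (i in seq_len(nrow(reg))) {
    got <- sim2$conc_ng_L[sim2$compound == reg$name[i] & sim2$layer == "SML"]
    expect_equal(got, rep(200 * fd[i], length(got)))
  }
})

test_that("round trip: a 52.2% programmed decrease is recovered exactly", {
  reg <- pah_registry()
  k <- -log(1 - 0.522) / 24
  design <- incubation_design(reg, treatments = "PAH",
                              abiotic_replicates = 0)
  params <- fate_parameters(reg, k_bio = k, noise_cv = 0)
  res <- compute_removal(simulate_incubation(design, params, seed = 3), reg)
  expect_true(all(abs(res$percent_decrease - 52.2) < 1e-9))
})

test_that("common wall loss vanishes after benchmark correction", {
  reg <- pah_registry()
  design <- incubation_design(reg, treatments = "PAH",
                              abiotic_replicates = 0)
  params <- fate_parameters(reg, k_bio = 0, k_wall = 0.01, noise_cv = 0)
  sim <- simulate_incubation(design, params, seed = 2)
  raw <- compute_removal(sim, reg)
  expect_true(all(raw$rate_mean > 0))  # wall loss looks like removal raw...
  corr <- compute_removal(sim, reg, benchmark = "phenanthrene")
  expect_true(all(abs(corr$rate_mean) < 1e-9))  # ...and cancels corrected
})

test_that("simulators are byte-identical under a fixed seed", {
  sc <- scenario_paper_like()
  s1 <- simulate_incubation(sc$design, sc$fate, seed = 99)
  s2 <- simulate_incubation(sc$design, sc$fate, seed = 99)
  expect_identical(s1, s2)
  expect_false(identical(
    s1$conc_ng_L, simulate_incubation(sc$design, sc$fate, seed = 100)$conc_ng_L))

  t1 <- simulate_asv_table(sc$community, seed = 41)
  t2 <- simulate_asv_table(sc$community, seed = 41)
  expect_identical(t1, t2)
})

test_that("measurement noise is mean-one", {
  reg <- pah_registry()
  design <- incubation_design(reg[reg$name == "pyrene", ],
                              layers = "SML", treatments = "PAH",
                              replicates = 2500, abiotic_replicates = 0)
  params <- fate_parameters(reg, k_bio = 0, noise_cv = 0.1)
  sim <- simulate_incubation(design, params, seed = 12)
  expect_equal(nrow(sim), 5000)  # 2500 bottles x 2 timepoints, 1 compound
  expect_lt(abs(mean(sim$conc_ng_L) / 200 - 1), 0.005)
  expect_equal(sd(sim$conc_ng_L) / mean(sim$conc_ng_L), 0.1,
               tolerance = 0.05)
})

test_that("mass is monotone non-increasing in time without noise", {
  reg <- pah_registry()
  design <- incubation_design(reg, timepoints_h = c(0, 6, 12, 24),
                              treatments = "PAH", abiotic_replicates = 0)
  sc <- scenario_paper_like(noise_cv = 0)
  sim <- simulate_incubation(design, sc$fate, seed = 1)
  key <- interaction(sim$compound, sim$layer, sim$replicate, drop = TRUE)
  for (g in split(sim, key)) {
    g <- g[order(g$time_h), ]
    expect_true(all(diff(g$conc_ng_L) <= 1e-12))
  }
})

test_that("paper-like truth matches its rate targets and layer pattern", {
  sc <- scenario_paper_like(noise_cv = 0)
  tr <- true_removal_rates(sc$design, sc$fate)
  pah <- tr[tr$treatment == "PAH" & tr$layer %in% c("SML", "SSL"), ]
  expect_equal(pah$rate_true[pah$layer == "SML"][
    order(pah$compound[pah$layer == "SML"])],
    unname(sc$rate_targets[sort(rownames(sc$rate_targets)), "SML"]),
    tolerance = 1e-9)
  hmw <- rownames(sc$rate_targets)[
    pah_registry()$weight_class[match(rownames(sc$rate_targets),
                                      pah_registry()$name)] == "HMW"]
  expect_true(all(sc$rate_targets[hmw, "SSL"] == 0))
  expect_equal(mean(sc$rate_targets[hmw, "SML"]), 1.685)
})

test_that("ASV simulator respects depth, metadata and degenerate cases", {
  scn <- community_scenario(n_taxa = 40, depth = 500, replicates = 2)
  tt <- simulate_asv_table(scn, seed = 5)
  expect_true(all(colSums(tt$counts) == 500))
  expect_equal(nrow(tt$sample_meta), 2 * 2 * 2 * 2 * 2)
  expect_true(all(c("layer", "fraction", "treatment", "timepoint")
                  %in% names(tt$sample_meta)))

  one <- simulate_asv_table(community_scenario(n_taxa = 40, depth = 1),
                            seed = 5)
  expect_true(all(colSums(one$counts) == 1))
})

test_that("an unenriched scenario is exchangeable between arms", {
  scn <- community_scenario(n_taxa = 60, depth = 5000, replicates = 3,
                            enrichment = c(Pseudoalteromonas = 1))
  folds <- vapply(1:15, function(s) {
    tt <- simulate_asv_table(scn, seed = 300 + s)
    tt <- subset_samples(tt, tt$sample_meta$timepoint == "T24")
    scr <- enrichment_screen(tt)
    scr$fold_change[scr$taxon == "Pseudoalteromonas" & scr$layer == "SML" &
                      scr$fraction == "PA"]
  }, numeric(1))
  expect_lt(abs(median(folds)), 1.6)
})

test_that("realized enrichment fold accounts for renormalization", {
  scn <- community_scenario(enrichment = c(Pseudoalteromonas = 8))
  expect_equal(true_enrichment_fold(scn), 8 / (1 + 7 * 0.037))
  expect_lt(true_enrichment_fold(scn), 8)
  flat <- community_scenario(enrichment = c(Pseudoalteromonas = 1))
  expect_equal(true_enrichment_fold(flat), 1)
})

test_that("generator rejects invalid parameters", {
  reg <- pah_registry()
  expect_error(fate_parameters(reg, k_bio = -1), ">= 0")
  expect_error(fate_parameters(reg, noise_cv = -0.1), ">= 0")
  expect_error(incubation_design(reg, timepoints_h = 0), "2 timepoints")
  expect_error(community_scenario(enrichment = c(X = 0)), "> 0")
  expect_error(community_scenario(depth = 0), "depth")
})
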