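test_that("two-point rates and percent decreases", {
  expect_equal(removal_rate(200, 126.08, 24), 3.08)
  expect_equal(removal_rate(100, 100, 24), 0)
  expect_equal(removal_rate(100, 110, 24), -10 / 24)  # preserved, not clipped
  expect_error(removal_rate(100, 50, 0), "dt")
  expect_error(removal_rate(NA, 50, 24), "LOQ")

  expect_equal(percent_decrease(100, 47.8), 52.2)
  expect_equal(percent_decrease(37, 37), 0)
  expect_equal(percent_decrease(100, 0), 100)
  expect_error(percent_decrease(0, 10), "> 0")
})

test_that("rates are linear in concentration (scale equivariance)", {
  set.seed(4)
  c0 <- runif(20, 50, 250); c1 <- runif(20, 0, 250)
  expect_equal(removal_rate(7 * c0, 7 * c1, 24), 7 * removal_rate(c0, c1, 24))
})

test_that("benchmark correction cancels bottle-common losses exactly", {
  reg <- pah_registry()
  series <- setNames(lapply(reg$name, function(n) c(200, 200 * 0.8)),
                     reg$name)
  m <- make_measurements(series)
  corr <- benchmark_correct(m, "phenanthrene")
  res <- compute_removal(m, reg, benchmark = "phenanthrene")
  expect_true(all(abs(res$rate_mean) < 1e-9))
  # the benchmark's own corrected series is constant at its t0 value
  bench <- corr[corr$compound == "phenanthrene", ]
  expect_equal(bench$conc_ng_L, c(200, 200))
})

test_that("benchmark correction rescales by the benchmark's depletion", {
  m <- make_measurements(list(target = c(200, 100),
                              phenanthrene = c(100, 80)))
  corr <- benchmark_correct(m)
  expect_equal(corr$conc_ng_L[corr$compound == "target" & corr$time_h == 24],
               125)
  res <- compute_removal(m, benchmark = "phenanthrene")
  expect_equal(res$rate_mean[res$compound == "target"], (200 - 125) / 24)
})

test_that("a common multiplicative loss leaves corrected rates unchanged", {
  reg <- pah_registry()
  set.seed(8)
  base <- setNames(lapply(reg$name, function(n) {
    c0 <- runif(1, 100, 250)
    c(c0, c0 * runif(1, 0.3, 1))
  }), reg$name)
  m1 <- make_measurements(base)
  lambda <- 0.71
  m2 <- m1
  m2$conc_ng_L[m2$time_h == 24] <- m2$conc_ng_L[m2$time_h == 24] * lambda
  r1 <- compute_removal(m1, reg, benchmark = "phenanthrene")
  r2 <- compute_removal(m2, reg, benchmark = "phenanthrene")
  expect_equal(r1$rate_mean, r2$rate_mean, tolerance = 1e-9)
})

test_that("benchmark failures are loud", {
  m <- make_measurements(list(target = c(200, 100)))
  expect_error(benchmark_correct(m), "missing")
  m2 <- make_measurements(list(target = c(200, 100),
                               phenanthrene = c(100, 0)))
  expect_error(benchmark_correct(m2), "zero")
})

test_that("noiseless first-order decay is recovered to closed form", {
  reg <- pah_registry()
  k <- 0.02
  design <- incubation_design(reg, treatments = "PAH",
                              abiotic_replicates = 0)
  params <- fate_parameters(reg, k_bio = k, noise_cv = 0)
  sim <- simulate_incubation(design, params, seed = 1)
  res <- compute_removal(sim, reg)
  expected <- 200 * (1 - exp(-k * 24)) / 24
  expect_true(all(abs(res$rate_mean - expected) < 1e-9))
})

test_that("attribution rule orders noise, sorption and biodegradation", {
  expect_equal(attribute_removal(52.2, 0.09), "BIODEGRADATION_DOMINANT")
  expect_equal(attribute_removal(0, 0.09), "NO_REMOVAL")
  expect_equal(attribute_removal(-4, 0), "NO_REMOVAL")
  expect_equal(attribute_removal(1.5, 0.09), "NO_REMOVAL")
  expect_equal(attribute_removal(5, 0.09), "SORPTION_POSSIBLE")
  expect_error(attribute_removal(10, 1.5), "sorption_bound")
})

test_that("class summaries aggregate per layer and class", {
  m <- rbind(
    make_measurements(list(pyrene = c(200, 200 - 0.29 * 24),
                           chrysene = c(200, 200 - 3.08 * 24),
                           fluorene = c(200, 190))))
  res <- compute_removal(m)
  cs <- summarize_by_class(res)
  hmw <- cs[cs$weight_class == "HMW", ]
  expect_equal(hmw$rate_mean, 1.685)
  expect_equal(c(hmw$rate_min, hmw$rate_max), c(0.29, 3.08))
  lmw <- cs[cs$weight_class == "LMW", ]
  expect_equal(lmw$n, 1)
  expect_equal(lmw$rate_mean, 10 / 24)  # single compound: summary == itself
  expect_true(is.na(lmw$rate_sd))

  # all-negative class is flagged, not hidden
  m2 <- make_measurements(list(fluorene = c(100, 120)))
  cs2 <- summarize_by_class(compute_removal(m2))
  expect_true(cs2$any_negative)
  expect_lt(cs2$rate_mean, 0)
})

test_that("replicates summarize as mean and sd", {
  m <- rbind(make_measurements(list(pyrene = c(200, 150)), replicate = 1),
             make_measurements(list(pyrene = c(200, 140)), replicate = 2))
  res <- compute_removal(m)
  rr <- replicate_rates(res)
  expect_equal(nrow(rr), 2)
  expect_equal(res$n_reps, 2)
  expect_equal(res$rate_mean, mean(rr$rate))
  expect_equal(res$rate_sd, sd(rr$rate))
})

test_that("class sums build a pooled pseudo-compound series", {
  m <- make_measurements(list(pyrene = c(200, 150), chrysene = c(100, 80),
                              fluorene = c(50, 40)))
  s <- sum_class_series(m, weight_class = "HMW")
  expect_equal(sort(s$conc_ng_L), c(230, 300))
  expect_equal(unique(s$compound), "sum_HMW")
})
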