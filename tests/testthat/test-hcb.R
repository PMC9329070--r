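test_that("lineage parsing strips SILVA prefixes and pads ranks", {
  lin <- parse_lineage(c(
    "d__Bacteria;p__Proteobacteria;c__Gamma;o__Alteromonadales;f__X;g__Colwellia;s__",
    "Bacteria;Bacteroidota",
    "Bacteria;;;;;unclassified;"))
  expect_equal(lin$genus, c("Colwellia", NA, NA))
  expect_equal(lin$domain, c("Bacteria", "Bacteria", "Bacteria"))
  expect_equal(ncol(lin), 7)
})

test_that("taxon table validates shapes and count types", {
  cts <- matrix(1:4, 2, dimnames = list(c("ASV_01", "ASV_02"), c("s1", "s2")))
  tax <- data.frame(taxon_id = c("ASV_01", "ASV_02"),
                    lineage = c("Bacteria;P;C;O;F;G1;", "Bacteria;P;C;O;F;G2;"))
  meta <- data.frame(sample_id = c("s1", "s2"))
  tt <- taxon_table(cts, tax, meta)
  expect_s3_class(tt, "taxon_table")
  expect_equal(tt$taxonomy$genus, c("G1", "G2"))

  expect_error(taxon_table(cts, tax[1, ], meta), "taxonomy rows")
  expect_error(taxon_table(cts, tax, meta[1, , drop = FALSE]), "metadata rows")
  bad <- cts; bad[1] <- -1
  expect_error(taxon_table(bad, tax, meta), "non-negative")
})

test_that("rarefaction hits the target depth deterministically", {
  set.seed(30)
  cts <- matrix(rpois(60, 40), nrow = 6,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  tt <- make_taxon_table(cts, genera = paste0("G", 1:6))
  depth <- min(colSums(cts)) - 5
  r1 <- rarefy_table(tt, depth = depth, seed = 7)
  r2 <- rarefy_table(tt, depth = depth, seed = 7)
  expect_true(all(colSums(r1$counts) == depth))
  expect_identical(r1$counts, r2$counts)  # fixed seed, bit-identical
  expect_false(identical(r1$counts,
                         rarefy_table(tt, depth = depth, seed = 8)$counts))
  # a sample already at the target depth is passed through unchanged
  at_depth <- rarefy_table(tt, depth = min(colSums(cts)), seed = 1)
  j <- which(colSums(cts) == min(colSums(cts)))[1]
  expect_identical(at_depth$counts[, j], cts[, j])
})

test_that("samples below depth are dropped with a warning", {
  cts <- cbind(s1 = c(50L, 50L), s2 = c(2L, 1L))
  rownames(cts) <- c("t1", "t2")
  tt <- make_taxon_table(cts, genera = c("G1", "G2"))
  expect_warning(r <- rarefy_table(tt, depth = 20, seed = 1), "dropping")
  expect_equal(colnames(r$counts), "s1")
  expect_error(rarefy_table(tt, depth = 1000, seed = 1), "below")
  expect_error(rarefy_table(tt, depth = 0), ">= 1")
})

test_that("rarefaction preserves expected proportions", {
  cts <- cbind(s1 = c(3000L, 7000L))
  rownames(cts) <- c("t1", "t2")
  tt <- make_taxon_table(cts, genera = c("G1", "G2"))
  props <- vapply(1:50, function(s) {
    r <- rarefy_table(tt, depth = 1000, seed = s)
    r$counts["t1", 1] / 1000
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.3), 0.01)
})

test_that("relative abundance aggregates ranks and pools unassigned taxa", {
  cts <- cbind(s1 = c(30L, 70L, 0L), s2 = c(10L, 10L, 20L))
  rownames(cts) <- paste0("t", 1:3)
  tt <- make_taxon_table(cts, genera = c("GA", "GB", NA))
  p <- relative_abundance(tt)
  expect_equal(colSums(p), c(s1 = 1, s2 = 1))
  expect_equal(p["GA", "s1"], 0.3)
  expect_equal(p["GB", "s1"], 0.7)
  expect_equal(p["unclassified", "s2"], 0.5)

  # same genus across several ASVs is pooled
  tt2 <- make_taxon_table(cts, genera = c("GA", "GA", "GB"))
  expect_equal(relative_abundance(tt2)["GA", "s1"], 1)

  empty <- cbind(s1 = c(1L, 1L, 1L), s2 = c(0L, 0L, 0L))
  rownames(empty) <- paste0("t", 1:3)
  tt3 <- make_taxon_table(empty, genera = c("GA", "GB", "GC"))
  expect_error(relative_abundance(tt3), "empty sample")
})

test_that("HCB filtering matches at genus level, case-insensitively", {
  cts <- matrix(5L, 4, 2,
                dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  tt <- make_taxon_table(cts, genera = c("Sulfitobacter", "SAR11_clade",
                                         "pseudoalteromonas", NA))
  hcb <- default_hcb_list()
  kept <- filter_hcb(tt, hcb)
  expect_equal(nrow(kept$counts), 2)  # Sulfitobacter + Pseudoalteromonas
  expect_equal(nrow(filter_hcb(tt, character(0))$counts), 0)

  # filtering is pointwise: union of disjoint lists == union of filters
  a <- filter_hcb(tt, "Sulfitobacter")
  b <- filter_hcb(tt, "SAR11_clade")
  both <- filter_hcb(tt, c("Sulfitobacter", "SAR11_clade"))
  expect_setequal(c(rownames(a$counts), rownames(b$counts)),
                  rownames(both$counts))
})

test_that("shipped HCB list loads with comments stripped", {
  hcb <- default_hcb_list()
  expect_true(all(c("Pseudoalteromonas", "Sulfitobacter", "Colwellia",
                    "Psychrobacter", "Glaciecola", "Alteromonas",
                    "Thalassospira") %in% hcb))
  tmp <- withr::local_tempfile(lines = c("# comment", "", "GenusA  ",
                                         "GenusB # trailing"))
  expect_setequal(load_hcb_list(tmp), c("GenusA", "GenusB"))
  empty <- withr::local_tempfile(lines = "# nothing")
  expect_error(load_hcb_list(empty), "empty")
})

test_that("archaea can be dropped before screening", {
  cts <- matrix(5L, 2, 2, dimnames = list(c("t1", "t2"), c("s1", "s2")))
  tax <- data.frame(taxon_id = c("t1", "t2"),
                    lineage = c("Archaea;Crenarchaeota;;;;GX;",
                                "Bacteria;P;C;O;F;GY;"))
  tt <- taxon_table(cts, tax, data.frame(sample_id = c("s1", "s2")))
  expect_equal(rownames(drop_archaea(tt)$counts), "t2")
})

test_that("enrichment screen computes per-stratum folds and p-values", {
  meta <- data.frame(layer = "SML", fraction = "PA",
                     treatment = rep(c("PAH", "CONTROL"), each = 3))
  cts <- rbind(
    flat   = c(100L, 100L, 100L, 100L, 100L, 100L),
    up     = c(300L, 310L, 290L, 100L, 105L, 95L),
    absent = c(0L, 0L, 0L, 0L, 0L, 0L),
    onearm = c(40L, 45L, 50L, 0L, 0L, 0L))
  colnames(cts) <- paste0("s", 1:6)
  tt <- make_taxon_table(cts, genera = c("Flat", "Up", "Absent", "Onearm"),
                         meta_extra = meta)
  scr <- enrichment_screen(tt, hcb = "Up")
  expect_false("Absent" %in% scr$taxon)  # absent from both arms
  up <- scr[scr$taxon == "Up", ]
  expect_gt(up$fold_change, 1)
  expect_lt(up$p_value, 0.05)
  expect_true(up$is_hcb)
  # constant counts still deplete in relative terms when another taxon
  # blooms: compositional closure
  flat <- scr[scr$taxon == "Flat", ]
  expect_lt(flat$fold_change, -1)
  # zero in one arm: finite fold via the stratum pseudo-proportion
  onearm <- scr[scr$taxon == "Onearm", ]
  expect_true(is.finite(onearm$fold_change))
  expect_gt(onearm$fold_change, 1)
})

test_that("screen warns on unbalanced or untestable strata", {
  meta <- data.frame(layer = "SML", fraction = "PA",
                     treatment = c("PAH", "CONTROL"))
  cts <- matrix(c(10L, 20L, 30L, 40L), 2,
                dimnames = list(c("t1", "t2"), c("s1", "s2")))
  tt <- make_taxon_table(cts, genera = c("G1", "G2"), meta_extra = meta)
  expect_warning(scr <- enrichment_screen(tt), "single replicate")
  expect_true(all(is.na(scr$p_value)))
  expect_false(any(is.na(scr$fold_change)))

  meta2 <- data.frame(layer = "SML", fraction = "PA",
                      treatment = c("PAH", "PAH"))
  tt2 <- make_taxon_table(cts, genera = c("G1", "G2"), meta_extra = meta2)
  expect_warning(expect_error(enrichment_screen(tt2), "no testable"),
                 "lacks arm")
})
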