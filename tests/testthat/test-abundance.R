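test_that("sample QC drops exactly the depleted samples", {
  m <- matrix(c(4999L, 0L, 5001L, 0L, 6000L, 100L), nrow = 3, byrow = TRUE,
              dimnames = list(c("low", "edge", "ok"), c("taxA", "SPIKE_1")))
  ct <- count_table(m, spike_ids = "SPIKE_1")
  kept <- qc_filter_samples(ct, quiet = TRUE)
  # 4999 dropped; exactly 5000 would also drop (strict >), 5001 kept
  expect_setequal(rownames(kept$counts), c("edge", "ok"))
  expect_identical(qc_filter_samples(ct, min_reads = 0, quiet = TRUE)$counts,
                   ct$counts)
  expect_error(qc_filter_samples(ct, min_reads = 1e7), "all samples removed")
})

test_that("relative abundance normalizes over bacterial taxa only", {
  m <- matrix(c(10L, 30L, 0L, 90L, 0L, 10L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "SPIKE_1")))
  ct <- count_table(m, spike_ids = "SPIKE_1")
  rel <- relative_abundance(ct)
  expect_equal(rel["s1", ], c(A = 0.25, B = 0.75))
  expect_equal(rel["s2", ], c(A = 1, B = 0))  # spike reads excluded
  # scale invariance
  ct7 <- count_table(m * 7L, spike_ids = "SPIKE_1")
  expect_equal(relative_abundance(ct7), rel)
  expect_error(relative_abundance(count_table(
    matrix(0L, 1, 1, dimnames = list("s", "A")))), "zero bacterial reads")
})

test_that("quantitative abundance follows the spike arithmetic", {
  m <- matrix(c(100L, 500L), 1, dimnames = list("s1", c("A", "SPIKE_1")))
  ct <- count_table(m, spike_ids = "SPIKE_1")
  meta <- data.frame(sample_id = "s1", subject_id = "m1", time_h = 1,
                     group = "g", mass_g = 0.02, spike_copies = 1e6)
  q <- quantitative_abundance(ct, meta)
  # 100 / 500 * 1e6 / 0.02 = 1e7 copies per gram
  expect_equal(unname(q$quant[1, "A"]), 1e7)
  expect_equal(unname(q$total_copies_per_g), 1e7)
  # depth invariance: doubling all counts (spike included) leaves Q unchanged
  q2 <- quantitative_abundance(count_table(m * 2L, spike_ids = "SPIKE_1"), meta)
  expect_equal(q2$quant, q$quant)
  # doubling spike reads only halves Q
  m3 <- m; m3[, "SPIKE_1"] <- 1000L
  q3 <- quantitative_abundance(count_table(m3, spike_ids = "SPIKE_1"), meta)
  expect_equal(q3$quant, q$quant / 2)
  # halving mass doubles copies per gram
  meta_h <- meta; meta_h$mass_g <- 0.01
  q4 <- quantitative_abundance(ct, meta_h)
  expect_equal(q4$quant, q$quant * 2)
  # error paths
  m0 <- m; m0[, "SPIKE_1"] <- 0L
  expect_error(quantitative_abundance(count_table(m0, spike_ids = "SPIKE_1"),
                                      meta), "zero spike reads.*s1")
  expect_error(quantitative_abundance(count_table(m), meta), "no spike")
})

test_that("taxon filter applies both thresholds and is idempotent", {
  rel <- matrix(c(0.0005, 0.9995, 0, 0.0005, 0.9995, 0, 0.0005, 0.8995, 0.1),
                nrow = 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), c("rare", "common", "patchy")))
  # mean(rare) = 5e-4 < 1e-3 -> removed; patchy present in 1/3 > 10% -> kept
  expect_setequal(filter_taxa(rel), c("common", "patchy"))
  # prevalence uses detection: high-abundance taxon present in 9% of samples
  rel2 <- cbind(matrix(rep(c(0.5, 0.5), 100), ncol = 2, byrow = TRUE,
                       dimnames = list(paste0("s", 1:100), c("A", "B"))),
                burst = c(rep(0, 91), rep(0.9, 9)) / 1)
  rel2 <- rel2 / rowSums(rel2)
  expect_false("burst" %in% filter_taxa(rel2))
  # identity at zero thresholds, idempotence otherwise
  expect_setequal(filter_taxa(rel, 0, 0), colnames(rel))
  keep <- filter_taxa(rel)
  expect_setequal(filter_taxa(rel[, keep, drop = FALSE]), keep)
  expect_error(filter_taxa(rel, mean_min = 2), "no taxa")
})

test_that("taxonomic collapse sums within ranks and conserves totals", {
  tab <- matrix(c(0.2, 0.3, 0.5, 0.1, 0.1, 0.8), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  taxo <- data.frame(taxon_id = c("g1", "g2", "g3"),
                     phylum = c("P1", "P1", "P2"),
                     genus = c("g1", "g2", NA), stringsAsFactors = FALSE)
  ph <- collapse_taxonomy(tab, taxo, "phylum")
  expect_equal(ph[, "P1"], c(s1 = 0.5, s2 = 0.2))
  expect_equal(rowSums(ph), rowSums(tab))
  gen <- collapse_taxonomy(tab, taxo, "genus")
  expect_true("Unknown" %in% colnames(gen))
  expect_error(collapse_taxonomy(tab, taxo, "species"), "rank 'species'")
})

test_that("phase modes 12 h apart produce antiphase phylum curves", {
  d <- small_dataset()  # phase modes at ZT6 / ZT18, phyla track the modes
  rel <- relative_abundance(d$counts)
  ph <- collapse_taxonomy(rel, d$taxonomy, "phylum")
  meta_c <- d$meta[d$meta$group == "control", ]
  f_day <- fit_cosinor(meta_c$time_h, ph[meta_c$sample_id, "Phylum_day"])
  f_night <- fit_cosinor(meta_c$time_h, ph[meta_c$sample_id, "Phylum_night"])
  expect_lt(f_day$p_value, 0.01)
  expect_lt(f_night$p_value, 0.01)
  dphi <- abs(f_day$phase_h - f_night$phase_h)
  expect_lt(abs(min(dphi, 24 - dphi) - 12), 3)
})
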