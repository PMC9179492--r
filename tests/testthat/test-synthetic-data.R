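test_that("noise-free planted loci are recovered exactly by the scan", {
  cfg <- sim_config(seed = 11, n_snp = 60, n_pa = 60, n_specific = 10,
                    linked_spec = list(), missing_rate = 0,
                    genotype_error_rate = 0)
  ds <- simulate_dataset(cfg)
  spec_ids <- ds$truth$locus_id[ds$truth$label == "specific"]
  expect_length(spec_ids, 10)
  combined <- dart_geno(dplyr::bind_rows(dart_meta(ds$snp), dart_meta(ds$pa)),
                        rbind(dart_calls(ds$snp), dart_calls(ds$pa)))
  scan <- run_scan(combined, ds$sheet, scan_config(scope = "pooled"))
  xy <- scan$locus_stats[scan$locus_stats$system == "XY", ]
  expect_setequal(xy$locus_id[xy$tier == "specific"], spec_ids)
})

test_that("the generator is deterministic under its seed", {
  cfg <- sim_config(seed = 77, n_snp = 40, n_pa = 40, n_specific = 10,
                    linked_spec = list(c(10, 0.2)))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(dart_calls(a$snp), dart_calls(b$snp))
  expect_identical(dart_calls(a$pa), dart_calls(b$pa))
  expect_identical(a$truth, b$truth)
  expect_identical(a$sheet, b$sheet)
})

test_that("linked loci converge to carrier frequencies (1 - r, r)", {
  cfg <- sim_config(seed = 19, n_males = 5000, n_females = 5000,
                    n_snp = 10, n_pa = 10, n_specific = 0,
                    linked_spec = list(c(20, 0.1)),
                    missing_rate = 0, genotype_error_rate = 0)
  ds <- simulate_dataset(cfg)
  combined <- dart_geno(dplyr::bind_rows(dart_meta(ds$snp), dart_meta(ds$pa)),
                        rbind(dart_calls(ds$snp), dart_calls(ds$pa)))
  cf <- carrier_frequencies(combined, ds$sheet)
  linked <- cf[combined$locus_id %in%
                 ds$truth$locus_id[ds$truth$label == "linked_r0.1"], ]
  expect_equal(mean(linked$f_carrier_male), 0.9, tolerance = 0.01)
  expect_equal(mean(linked$f_carrier_female), 0.1, tolerance = 0.01)
})

test_that("moderately linked loci classify into the matching tier band", {
  cfg <- sim_config(seed = 23, n_males = 200, n_females = 200,
                    n_snp = 100, n_pa = 100, n_specific = 0,
                    linked_spec = list(c(200, 0.1)),
                    missing_rate = 0, genotype_error_rate = 0)
  ds <- simulate_dataset(cfg)
  combined <- dart_geno(dplyr::bind_rows(dart_meta(ds$snp), dart_meta(ds$pa)),
                        rbind(dart_calls(ds$snp), dart_calls(ds$pa)))
  scan <- run_scan(combined, ds$sheet, scan_config(scope = "pooled"))
  xy <- scan$locus_stats[scan$locus_stats$system == "XY", ]
  planted <- xy[xy$locus_id %in%
                  ds$truth$locus_id[ds$truth$label == "linked_r0.1"], ]
  # with true frequencies (0.9, 0.1), loci straddle the linked_80/linked_90
  # boundary but stay inside the linked band
  expect_gte(mean(planted$tier %in% c("linked_80", "linked_90", "specific")),
             0.95)
  expect_equal(mean(planted$f_carrier_male), 0.9, tolerance = 0.015)
})

test_that("null matrices are fair-coin unless told otherwise", {
  g <- simulate_null_matrix(10, 500, carrier_prob = 1.0, seed = 5)
  expect_true(all(dart_calls(g) == 1L))
  g2 <- simulate_null_matrix(20, 2000, seed = 5)
  expect_equal(mean(dart_calls(g2)), 0.5, tolerance = 0.02)
})

test_that("fabricated alignment hits reconstruct truth under the filters", {
  cfg <- sim_config(seed = 31, n_snp = 30, n_pa = 30, n_specific = 10,
                    linked_spec = list(c(10, 0.1)))
  ds <- simulate_dataset(cfg)
  hits <- simulate_alignment_hits(ds$truth, seed = 1)
  asn <- filter_and_assign(hits)
  expect_equal(nrow(asn), nrow(ds$truth))
  merged <- dplyr::inner_join(tibble::as_tibble(asn), ds$truth, by = "locus_id")
  expect_equal(merged$chromosome.x, merged$chromosome.y)
  expect_equal(merged$position.x, merged$position.y)

  # decoys below the identity filter are never assigned
  noisy <- simulate_alignment_hits(ds$truth, off_target_rate = 1,
                                   decoy_identity = 94, seed = 2)
  asn2 <- filter_and_assign(noisy)
  merged2 <- dplyr::inner_join(tibble::as_tibble(asn2), ds$truth, by = "locus_id")
  expect_equal(merged2$chromosome.x, merged2$chromosome.y)

  # decoys passing the filters still lose on bit score
  noisy3 <- simulate_alignment_hits(ds$truth, off_target_rate = 1,
                                    decoy_identity = 98, seed = 3)
  asn3 <- filter_and_assign(noisy3)
  merged3 <- dplyr::inner_join(tibble::as_tibble(asn3), ds$truth, by = "locus_id")
  expect_equal(merged3$position.x, merged3$position.y)
})

test_that("planted loci sit inside the declared sex-determining interval", {
  cfg <- sim_config(seed = 41, n_snp = 50, n_pa = 50, n_specific = 20,
                    linked_spec = list(c(20, 0.1), c(20, 0.3)))
  ds <- simulate_dataset(cfg)
  planted <- ds$truth[ds$truth$label != "autosomal", ]
  expect_true(all(planted$chromosome == "BSP9"))
  expect_true(all(planted$position >= 26285178 & planted$position <= 31930103))
  # one label per locus
  expect_equal(anyDuplicated(ds$truth$locus_id), 0)
})

test_that("repeat fabrication keeps counts exact regardless of seed", {
  iv <- tibble::tibble(chromosome = "BSP9", start = 1000, end = 1e6)
  counts <- c("Ty3/Gypsy" = 11, Helitron = 7, unclassified = 3)
  a <- region_composition(simulate_repeat_annotation(counts, iv, seed = 1), iv)
  b <- region_composition(simulate_repeat_annotation(counts, iv, seed = 99), iv)
  expect_equal(a$fragments, b$fragments)
  expect_equal(attr(a, "total_fragments"), 21)
  zero <- simulate_repeat_annotation(c("Ty3/Gypsy" = 0), iv, seed = 1)
  expect_equal(nrow(zero), 0)
})

test_that("the polygenic mode assigns sex from the switch-locus liability", {
  cfg <- sim_config(seed = 57, n_snp = 20, n_pa = 20, n_specific = 0,
                    linked_spec = list(), sd_system = "PSD")
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$sheet$sex %in% c("male", "female")))
  expect_gt(sum(ds$sheet$sex == "male"), 5)
  expect_gt(sum(ds$sheet$sex == "female"), 5)
})
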