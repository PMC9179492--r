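test_that("carrier frequencies are computed over called individuals only", {
  sheet <- make_sheet(40, 35)
  calls <- matrix(c(rep(1L, 40), rep(0L, 35)), nrow = 1)
  g <- make_pa_geno(calls, sheet)
  cf <- carrier_frequencies(g, sheet)
  expect_equal(cf$f_carrier_male, 1.0)
  expect_equal(cf$f_carrier_female, 0.0)
  expect_equal(cf$n_called_male, 40)
  expect_equal(cf$n_called_female, 35)

  sheet2 <- make_sheet(10, 10)
  snp <- matrix(c(rep(1L, 9), 0L, 1L, rep(0L, 9)), nrow = 1)
  g2 <- make_snp_geno(snp, sheet2)
  cf2 <- carrier_frequencies(g2, sheet2)
  expect_equal(cf2$f_carrier_male, 0.9)
  expect_equal(cf2$f_carrier_female, 0.1)

  all_f_missing <- matrix(c(rep(1L, 10), rep(NA, 10)), nrow = 1)
  cf3 <- carrier_frequencies(make_pa_geno(all_f_missing, sheet2), sheet2)
  expect_true(cf3$uninformative)
})

test_that("tier classification matches the threshold definitions", {
  cfg <- scan_config()
  expect_equal(classify_locus(1.0, 0.0, cfg, "XY"), "specific")
  expect_equal(classify_locus(0.9, 0.1, cfg, "XY"), "linked_90")
  expect_equal(classify_locus(0.85, 0.12, cfg, "XY"), "linked_80")
  expect_equal(classify_locus(0.5, 0.5, cfg, "XY"), "none")
  # ZW mirrors the sexes
  expect_equal(classify_locus(0.0, 1.0, cfg, "ZW"), "specific")
  expect_equal(classify_locus(1.0, 0.0, cfg, "ZW"), "none")
  # near-perfect is not specific: exactly (1, 0) is required
  expect_equal(classify_locus(0.999, 0.0, cfg, "XY"), "linked_90")
})

test_that("tier sets are nested and classification is the highest passed tier", {
  cfg <- scan_config()
  grid <- expand.grid(f_m = seq(0, 1, 0.05), f_f = seq(0, 1, 0.05))
  tier <- classify_locus(grid$f_m, grid$f_f, cfg, "XY")
  passes <- function(t) grid$f_m >= t - 1e-9 & grid$f_f <= 1 - t + 1e-9
  sets <- lapply(c(0.7, 0.8, 0.9), passes)
  expect_true(all(sets[[3]] <= sets[[2]]), all(sets[[2]] <= sets[[1]]))
  expected <- rep("none", nrow(grid))
  expected[sets[[1]]] <- "linked_70"
  expected[sets[[2]]] <- "linked_80"
  expected[sets[[3]]] <- "linked_90"
  expected[grid$f_m == 1 & grid$f_f == 0] <- "specific"
  expect_equal(tier, expected)
})

test_that("trend test reproduces the closed-form 2x2 statistic", {
  res <- catt(4, 1, 1, 4)
  expect_equal(res$chi2, 3.6)
  expect_equal(res$p, pchisq(3.6, 1, lower.tail = FALSE))
  # no trend
  expect_equal(catt(3, 7, 6, 14)$chi2, 0)
  # perfect association attains the maximum chi2 = N
  expect_equal(catt(40, 0, 0, 35)$chi2, 75)
  # degenerate margins are flagged undefined
  expect_true(is.na(catt(5, 0, 5, 0)$chi2))
})

test_that("genotype-trend variant agrees with the standard trend test", {
  withr::with_seed(5, {
    for (i in 1:20) {
      counts <- matrix(rpois(6, 8) + 1, nrow = 2)
      ours <- catt_trend(counts, scores = 0:2)
      ref <- suppressWarnings(
        stats::prop.trend.test(counts[1, ], colSums(counts), score = 0:2))
      expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("PIC and expected heterozygosity match their closed forms", {
  res <- pic(c(0.5, 0.5))
  expect_equal(res$pic_botstein, 0.375)
  expect_equal(res$expected_heterozygosity, 0.5)
  mono <- pic(1.0)
  expect_equal(mono$pic_botstein, 0)
  expect_equal(mono$expected_heterozygosity, 0)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  # biallelic expected heterozygosity is maximized at 0.5
  p <- seq(0.01, 0.99, 0.01)
  he <- vapply(p, function(q) pic(c(q, 1 - q))$expected_heterozygosity, 0)
  expect_lte(max(he), 0.5)
  expect_equal(max(he), 0.5)
})

test_that("Hamming distance counts mutually-called differing positions", {
  expect_equal(hamming_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(hamming_distance(c(1, 0, 1), c(0, 1, 0)), 1)
  expect_equal(hamming_distance(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, NA)), 0.5)
  expect_true(is.na(hamming_distance(c(NA, 1), c(0, NA))))
  expect_error(hamming_distance(1:3, 1:2), "length")
})

test_that("Hamming distance equals a brute-force pair counter", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(5:40, 1)
      x <- sample(c(0:2, NA), n, replace = TRUE)
      y <- sample(c(0:2, NA), n, replace = TRUE)
      expect_identical(hamming_distance(x, y), oracle_hamming(x, y))
    }
  })
})

test_that("distance summaries separate between- and within-sex strata", {
  fx <- male_specific_cohort(n_males = 6, n_females = 5, n_specific = 8,
                             n_autosomal = 0)
  D <- pairwise_hamming(fx$geno)
  ds <- distance_summary(D, fx$sheet)
  expect_equal(ds$mean[ds$stratum == "between_sexes"], 1.0)
  expect_equal(ds$mean[ds$stratum == "within_males"], 0.0)
  expect_equal(ds$mean[ds$stratum == "within_females"], 0.0)
  expect_equal(ds$n_pairs, c(30, 15, 10))

  # one sample per sex: between defined by the single pair, within undefined
  sheet1 <- make_sheet(1, 1)
  D1 <- pairwise_hamming(make_pa_geno(matrix(c(1L, 0L, 1L, 1L), 2), sheet1))
  ds1 <- distance_summary(D1, sheet1)
  expect_equal(ds1$mean[ds1$stratum == "between_sexes"], 0.5)
  expect_true(is.na(ds1$mean[ds1$stratum == "within_males"]))
})

test_that("random 50/50 calls give between-sex distances near one half", {
  withr::with_seed(77, {
    sheet <- make_sheet(10, 10)
    calls <- matrix(rbinom(2000 * 20, 1, 0.5), nrow = 2000)
    D <- pairwise_hamming(make_pa_geno(calls, sheet))
    ds <- distance_summary(D, sheet)
    # binomial expectation: mean 0.5, per-pair sd ~ sqrt(0.25/2000)
    expect_equal(ds$mean[ds$stratum == "between_sexes"], 0.5, tolerance = 0.01)
  })
})

test_that("heterozygosity tier comparison behaves at the null and degenerate cases", {
  # identical constant groups -> H = 0, p = 1
  stats_df <- tibble::tibble(system = "XY",
                             tier = rep(c("linked_70", "linked_80", "linked_90"), each = 4),
                             expected_heterozygosity = 0.3)
  res <- tier_comparison(stats_df)
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)

  # two groups with fully separated ranks attain the closed-form maximum
  sep <- tibble::tibble(system = "XY",
                        tier = rep(c("linked_70", "specific"), each = 5),
                        expected_heterozygosity = c(1:5, 11:15) / 20)
  res2 <- tier_comparison(sep)
  n1 <- 5; n2 <- 5; N <- n1 + n2
  r1 <- mean(1:5); r2 <- mean(6:10)
  H_max <- 12 / (N * (N + 1)) * (n1 * (r1 - (N + 1) / 2)^2 + n2 * (r2 - (N + 1) / 2)^2)
  expect_equal(res2$H, H_max)
})

test_that("tier comparison rejects at the nominal rate under the null", {
  withr::with_seed(12, {
    reps <- 2000
    rej <- 0
    for (i in seq_len(reps)) {
      df <- tibble::tibble(system = "XY",
                           tier = rep(c("linked_70", "linked_80", "linked_90"), each = 15),
                           expected_heterozygosity = runif(45))
      if (tier_comparison(df)$p < 0.05) rej <- rej + 1
    }
    # 99% binomial band around 0.05 for 400 draws
    expect_gt(rej / reps, 0.05 - 2.576 * sqrt(0.05 * 0.95 / reps))
    expect_lt(rej / reps, 0.05 + 2.576 * sqrt(0.05 * 0.95 / reps))
  })
})

test_that("spurious-linkage model follows 0.5^n", {
  expect_equal(spurious_probability(1), 0.5)
  expect_equal(spurious_probability(10), 9.765625e-4)
  expect_error(spurious_probability(0), "at least 1")
  expect_equal(expected_spurious(1000, 10), 1000 * 2^-10)
  expect_equal(expected_spurious(1000, 10, two_sided = TRUE), 2000 * 2^-10)
})

test_that("the scan recovers planted loci and respects XY/ZW symmetry", {
  fx <- male_specific_cohort(n_specific = 10, n_autosomal = 40, seed = 3)
  scan <- run_scan(fx$geno, fx$sheet, scan_config(scope = "pooled"))
  xy <- scan$locus_stats[scan$locus_stats$system == "XY", ]
  zw <- scan$locus_stats[scan$locus_stats$system == "ZW", ]
  expect_setequal(xy$locus_id[xy$tier == "specific"], fx$specific_ids)
  expect_equal(sum(zw$tier == "specific"), 0)

  # planted female-specific loci are detected only under ZW
  sheet_sw <- fx$sheet
  sheet_sw$sex <- ifelse(sheet_sw$sex == "male", "female", "male")
  scan_sw <- run_scan(fx$geno, sheet_sw, scan_config(scope = "pooled"))
  zw_sw <- scan_sw$locus_stats[scan_sw$locus_stats$system == "ZW", ]
  xy_sw <- scan_sw$locus_stats[scan_sw$locus_stats$system == "XY", ]
  # relabelling every sample's sex swaps the XY and ZW outputs exactly
  expect_equal(zw_sw$tier, xy$tier)
  expect_equal(xy_sw$tier, zw$tier)
  expect_setequal(zw_sw$locus_id[zw_sw$tier == "specific"], fx$specific_ids)
})

test_that("the low-call gate stops sparsely called loci from classifying", {
  sheet <- make_sheet(10, 10)
  calls <- matrix(NA_integer_, 1, 20)
  calls[1, 1] <- 1L            # one called male, carrier
  calls[1, 11:20] <- 0L        # all females called, non-carrier
  g <- make_pa_geno(calls, sheet)
  scan <- run_scan(g, sheet, scan_config(scope = "pooled"))
  expect_true(all(scan$locus_stats$tier == "none"))
  expect_true(all(scan$locus_stats$low_call))
})

test_that("populations with a single sex are skipped with a warning", {
  sheet <- make_sheet(4, 4, populations = c("P1", "P1", "P1", "P2"))
  # P2 ends up with one male and one female; make it single-sex
  sheet$population_id <- c("P1", "P1", "P1", "P2", "P1", "P1", "P1", "P1")
  g <- make_pa_geno(matrix(1L, 3, 8), sheet)
  expect_warning(run_scan(g, sheet, scan_config(scope = "per_population")),
                 "single sex")
})

test_that("per-locus statistics carry CATT and heterozygosity values", {
  fx <- male_specific_cohort(n_males = 20, n_females = 20, n_specific = 5,
                             n_autosomal = 20, seed = 8)
  scan <- run_scan(fx$geno, fx$sheet, scan_config(scope = "pooled"))
  xy <- scan$locus_stats[scan$locus_stats$system == "XY", ]
  spec <- xy[xy$locus_id %in% fx$specific_ids, ]
  # perfect association attains chi2 = N
  expect_equal(spec$catt_chi2, rep(40, 5))
  expect_true(all(spec$catt_p < 1e-9))
  expect_true(all(xy$expected_heterozygosity >= 0 & xy$expected_heterozygosity <= 0.5))
  expect_true(all(xy$pic_botstein <= 0.375 + 1e-12))
})
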