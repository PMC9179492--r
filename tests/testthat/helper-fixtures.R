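# small in-code fixtures shared across the suite

make_sheet <- function(n_males, n_females, populations = "POP_A") {
  n <- n_males + n_females
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    sex = c(rep("male", n_males), rep("female", n_females)),
    population_id = rep_len(populations, n))
}

make_pa_geno <- function(calls, sheet, locus_ids = NULL) {
  calls <- as.matrix(calls)
  colnames(calls) <- sheet$sample_id
  if (is.null(locus_ids)) locus_ids <- sprintf("PA%04d", seq_len(nrow(calls)))
  dart_geno(tibble::tibble(locus_id = locus_ids, marker_type = "PA"), calls)
}

make_snp_geno <- function(calls, sheet, locus_ids = NULL) {
  calls <- as.matrix(calls)
  colnames(calls) <- sheet$sample_id
  if (is.null(locus_ids)) locus_ids <- sprintf("SNP%04d", seq_len(nrow(calls)))
  dart_geno(tibble::tibble(locus_id = locus_ids, marker_type = "SNP"), calls)
}

# a PA cohort with planted male-specific loci on a background of
# fair-coin autosomal loci
male_specific_cohort <- function(n_males = 40, n_females = 35,
                                 n_specific = 10, n_autosomal = 50,
                                 seed = 42) {
  withr::with_seed(seed, {
    sheet <- make_sheet(n_males, n_females)
    n <- n_males + n_females
    spec <- matrix(rep(c(rep(1L, n_males), rep(0L, n_females)), each = n_specific),
                   nrow = n_specific)
    calls <- if (n_autosomal > 0) {
      rbind(spec, matrix(rbinom(n_autosomal * n, 1, 0.5), nrow = n_autosomal))
    } else spec
    geno <- make_pa_geno(calls, sheet)
    list(geno = geno, sheet = sheet,
         specific_ids = geno$locus_id[seq_len(n_specific)])
  })
}

reorder_geno <- function(g, idx) {
  dart_geno(dart_meta(g)[idx, , drop = FALSE],
            dart_calls(g)[idx, , drop = FALSE])
}

# closed-form 2x2 trend chi-square, written independently of the package
oracle_catt_2x2 <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force Hamming distance: position-by-position count
oracle_hamming <- function(x, y) {
  n_cmp <- 0L; n_diff <- 0L
  for (i in seq_along(x)) {
    if (!is.na(x[i]) && !is.na(y[i])) {
      n_cmp <- n_cmp + 1L
      if (x[i] != y[i]) n_diff <- n_diff + 1L
    }
  }
  if (n_cmp == 0) NA_real_ else n_diff / n_cmp
}
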