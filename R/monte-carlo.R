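# Subsampling reproducibility: how often does each candidate locus keep
# its classification when only a random fraction of the cohort is used?

#' Monte Carlo subsampling configuration
#'
#' @param reps Number of random subsamples (default 100,000; desk-scale
#'   analyses and tests use far fewer).
#' @param subsample_fraction Fraction of individuals drawn per replicate
#'   (default 0.10), without replacement.
#' @param stratified_by_sex Draw the fraction within each sex, rounding
#'   up per sex (default `TRUE`); otherwise sample individuals freely.
#' @param with_replacement Sample with replacement (default `FALSE`).
#' @param min_per_sex Minimum males and females a subsample must contain
#'   (default 2); violating configurations error before any replicate.
#' @param seed Integer RNG seed, recorded in the output (mandatory).
#' @return An `mc_config` list.
#' @export
mc_config <- function(reps = 100000, subsample_fraction = 0.10,
                      stratified_by_sex = TRUE, with_replacement = FALSE,
                      min_per_sex = 2, seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility", call. = FALSE)
  stopifnot(reps >= 1, subsample_fraction > 0, subsample_fraction < 1,
            min_per_sex >= 1)
  structure(list(reps = as.integer(reps),
                 subsample_fraction = subsample_fraction,
                 stratified_by_sex = stratified_by_sex,
                 with_replacement = with_replacement,
                 min_per_sex = as.integer(min_per_sex),
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' Subsampling reproducibility of sex-linkage classifications
#'
#' Repeatedly draws a random subsample of the cohort, recomputes carrier
#' frequencies within it, reclassifies every locus, and reports for each
#' locus the fraction of replicates in which it classifies as
#' sex-specific and in which it reaches at least the lowest linked tier.
#'
#' @param geno A QC-passed genotype table.
#' @param sheet A sample sheet covering the table's samples.
#' @param scan_config A [scan_config()]; the classification is run under
#'   a single hypothesis (`"both"` falls back to `"XY"` with a message).
#' @param mc_config An [mc_config()].
#' @return A tibble of class `mc_report` with columns `locus_id`,
#'   `marker_type`, `detection_frequency_specific`,
#'   `detection_frequency_linked` plus attributes `config` (echo) and
#'   `subsample_sizes`. Deterministic given the seed; the replicate
#'   random stream does not depend on locus order.
#' @export
subsample_reproducibility <- function(geno, sheet,
                                      scan_config = dartsex::scan_config(),
                                      mc_config) {
  stopifnot(inherits(mc_config, "mc_config"))
  system <- scan_config$system
  if (system == "both") {
    message("subsampling runs under a single hypothesis; using XY")
    system <- "XY"
  }
  samples <- dart_samples(geno)
  sex <- sheet$sex[match(samples, sheet$sample_id)]
  males <- which(sex == "male"); females <- which(sex == "female")
  frac <- mc_config$subsample_fraction
  if (mc_config$stratified_by_sex) {
    k_m <- ceiling(frac * length(males))
    k_f <- ceiling(frac * length(females))
    if (k_m < mc_config$min_per_sex || k_f < mc_config$min_per_sex) {
      stop(sprintf(
        "subsample of %d males / %d females violates min_per_sex = %d",
        k_m, k_f, mc_config$min_per_sex), call. = FALSE)
    }
  } else {
    k_all <- ceiling(frac * length(samples))
    if (k_all < 2 * mc_config$min_per_sex) {
      stop("unstratified subsample too small to satisfy min_per_sex", call. = FALSE)
    }
    k_m <- k_f <- NA_integer_
  }

  carr <- .carrier_matrix(geno, scan_config$presence_rule_snp)
  called <- !is.na(carr)
  carr0 <- carr; carr0[!called] <- FALSE
  thr <- scan_config$tier_thresholds
  min_thr <- min(thr)
  min_frac <- scan_config$min_called_fraction_per_sex
  n_loci <- nrow(carr)
  hits_specific <- integer(n_loci)
  hits_linked <- integer(n_loci)
  used <- 0L

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(mc_config$seed)

  for (r in seq_len(mc_config$reps)) {
    if (mc_config$stratified_by_sex) {
      im <- sample(males, k_m, replace = mc_config$with_replacement)
      iff <- sample(females, k_f, replace = mc_config$with_replacement)
    } else {
      pick <- sample(seq_along(samples), k_all,
                     replace = mc_config$with_replacement)
      im <- pick[pick %in% males]; iff <- pick[pick %in% females]
      if (length(im) < mc_config$min_per_sex ||
          length(iff) < mc_config$min_per_sex) next
    }
    n_cm <- rowSums(called[, im, drop = FALSE])
    n_cf <- rowSums(called[, iff, drop = FALSE])
    f_m <- rowSums(carr0[, im, drop = FALSE]) / n_cm
    f_f <- rowSums(carr0[, iff, drop = FALSE]) / n_cf
    if (system == "ZW") { tmp <- f_m; f_m <- f_f; f_f <- tmp }
    gate <- n_cm >= min_frac * length(im) & n_cf >= min_frac * length(iff) &
      n_cm > 0 & n_cf > 0
    spec <- gate & !is.na(f_m) & !is.na(f_f) & f_m == 1 & f_f == 0
    linked <- gate & !is.na(f_m) & !is.na(f_f) &
      f_m >= min_thr - 1e-9 & f_f <= 1 - min_thr + 1e-9
    hits_specific <- hits_specific + spec
    hits_linked <- hits_linked + linked
    used <- used + 1L
  }

  out <- tibble::tibble(
    locus_id = geno$locus_id,
    marker_type = geno$marker_type,
    detection_frequency_specific = unname(hits_specific / used),
    detection_frequency_linked = unname(hits_linked / used))
  attr(out, "config") <- mc_config
  attr(out, "system") <- system
  attr(out, "replicates_used") <- used
  attr(out, "subsample_sizes") <- c(males = k_m, females = k_f)
  class(out) <- c("mc_report", class(out))
  out
}

#' Plot the per-locus subsampling detection spectrum
#'
#' @param object An `mc_report` from [subsample_reproducibility()].
#' @param ... Unused.
#' @return A ggplot object: histogram of per-locus detection frequencies.
#' @export
autoplot.mc_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            dplyr::starts_with("detection_frequency"),
                            names_to = "classification", values_to = "frequency",
                            names_prefix = "detection_frequency_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(ggplot2::vars(.data$classification)) +
    ggplot2::labs(x = "detection frequency over subsamples", y = "loci") +
    ggplot2::theme_minimal()
}

#' Write a subsampling report as TSV
#' @param report An `mc_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mc_report <- function(report, path) {
  readr::write_tsv(tibble::as_tibble(report), path, progress = FALSE)
  invisible(path)
}
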