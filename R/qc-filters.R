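#' Marker quality-control configuration
#'
#' Thresholds applied to per-locus quality metadata before the sex scan.
#' All comparisons are strict (`>`): a locus passes a criterion only when
#' its metric exceeds the threshold. Call rate is always recomputed from
#' the calls; the remaining metrics come from file metadata and may be
#' unavailable, in which case `strictness` decides the locus's fate for
#' that criterion. Allele balance applies to SNP loci only.
#'
#' @param min_reproducibility Reproducibility threshold on the 0-1 scale
#'   (default 0.95).
#' @param min_depth Mean sequencing-depth threshold (default 5).
#' @param min_allele_balance Allele-balance threshold for SNP loci
#'   (default 0.9).
#' @param min_call_rate Call-rate threshold (default 0.8).
#' @param strictness `"pass_if_unavailable"` (default) or
#'   `"drop_if_unavailable"`: what to do when a metadata metric is `NA`.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_reproducibility = 0.95, min_depth = 5,
                      min_allele_balance = 0.9, min_call_rate = 0.8,
                      strictness = c("pass_if_unavailable", "drop_if_unavailable")) {
  strictness <- match.arg(strictness)
  stopifnot(min_reproducibility >= 0, min_reproducibility <= 1,
            min_depth >= 0,
            min_allele_balance >= 0, min_allele_balance <= 1,
            min_call_rate >= 0, min_call_rate <= 1)
  structure(list(min_reproducibility = min_reproducibility,
                 min_depth = min_depth,
                 min_allele_balance = min_allele_balance,
                 min_call_rate = min_call_rate,
                 strictness = strictness),
            class = "qc_config")
}

#' Apply marker quality filters
#'
#' Filters a genotype table on reproducibility, mean depth, allele balance
#' (SNP loci only) and call rate. Call rate is recomputed from the calls
#' rather than trusted from metadata. Filtering is idempotent and
#' monotone: raising any threshold never enlarges the retained set.
#'
#' @param geno A genotype table (see [dart_geno()]).
#' @param config A [qc_config()].
#' @return A list with elements `matrix` (the filtered genotype table) and
#'   `report` (per-locus pass/fail tibble with an overall summary in
#'   `attr(report, "summary")`).
#' @export
apply_qc <- function(geno, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  meta <- dart_meta(geno)
  cr <- call_rate(geno)
  pass_if <- config$strictness == "pass_if_unavailable"
  check <- function(x, thr) ifelse(is.na(x), pass_if, x > thr)
  report <- tibble::tibble(
    locus_id = meta$locus_id,
    marker_type = meta$marker_type,
    pass_reproducibility = check(meta$reproducibility, config$min_reproducibility),
    pass_depth = check(meta$depth, config$min_depth),
    # allele balance is a SNP-only criterion; PA loci are exempt
    pass_allele_balance = ifelse(meta$marker_type == "PA", TRUE,
                                 check(meta$allele_balance, config$min_allele_balance)),
    call_rate = cr,
    pass_call_rate = cr > config$min_call_rate)
  report$pass <- report$pass_reproducibility & report$pass_depth &
    report$pass_allele_balance & report$pass_call_rate
  kept <- as_dart_geno(geno[report$pass, , drop = FALSE])
  kept$call_rate <- cr[report$pass]
  summary <- tibble::tibble(
    criterion = c("reproducibility", "depth", "allele_balance", "call_rate", "overall"),
    threshold = c(config$min_reproducibility, config$min_depth,
                  config$min_allele_balance, config$min_call_rate, NA_real_),
    n_fail = c(sum(!report$pass_reproducibility), sum(!report$pass_depth),
               sum(!report$pass_allele_balance), sum(!report$pass_call_rate),
               sum(!report$pass)),
    n_pass = nrow(report) - .data$n_fail)
  attr(report, "summary") <- summary
  attr(report, "config") <- config
  list(matrix = kept, report = report)
}

#' Write a QC report as TSV plus a JSON summary
#'
#' @param qc The list returned by [apply_qc()].
#' @param path_tsv Per-locus report destination (TSV).
#' @param path_json Summary destination (JSON); defaults to `path_tsv`
#'   with a `.json` extension.
#' @return `path_tsv`, invisibly.
#' @export
write_qc_report <- function(qc, path_tsv,
                            path_json = sub("\\.tsv$", ".json", path_tsv)) {
  readr::write_tsv(qc$report, path_tsv, progress = FALSE)
  summary <- attr(qc$report, "summary")
  config <- attr(qc$report, "config")
  jsonlite::write_json(list(config = unclass(config), summary = summary),
                       path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}
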