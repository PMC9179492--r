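#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# metadata columns every genotype table carries, in order
.dart_meta_cols <- c("locus_id", "marker_type", "reproducibility", "depth",
                     "allele_balance", "call_rate")

#' Construct a genotype table
#'
#' A genotype table is a tibble with one row per locus: six locus-metadata
#' columns (`locus_id`, `marker_type`, `reproducibility`, `depth`,
#' `allele_balance`, `call_rate`) followed by one integer column per sample.
#' SNP loci are coded 0 (reference homozygote), 1 (heterozygote),
#' 2 (alternate homozygote); presence/absence (PA) loci 0 (fragment absent),
#' 1 (fragment present). Missing calls are `NA`.
#'
#' @param meta Data frame of locus metadata. Must contain `locus_id`
#'   (unique) and `marker_type` (`"SNP"` or `"PA"`); the quality-metric
#'   columns are filled with `NA` when absent.
#' @param calls Integer matrix, loci in rows and samples in columns, with
#'   column names giving the sample ids.
#' @return A tibble of class `dart_geno`.
#' @export
dart_geno <- function(meta, calls) {
  meta <- as_tibble(meta)
  if (!all(c("locus_id", "marker_type") %in% names(meta))) {
    stop("`meta` must contain columns `locus_id` and `marker_type`", call. = FALSE)
  }
  if (anyDuplicated(meta$locus_id)) {
    dup <- unique(meta$locus_id[duplicated(meta$locus_id)])
    stop("duplicated locus_id: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!all(meta$marker_type %in% c("SNP", "PA"))) {
    stop("marker_type must be 'SNP' or 'PA'", call. = FALSE)
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(colnames(calls))) {
    stop("`calls` must have sample ids as column names", call. = FALSE)
  }
  if (nrow(calls) != nrow(meta)) {
    stop("`meta` and `calls` disagree on the number of loci", call. = FALSE)
  }
  legal <- ifelse(meta$marker_type == "SNP", 2L, 1L)
  bad <- which(sweep(calls, 1, legal, ">") | calls < 0L, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("illegal call code at locus '%s', sample '%s'",
                 meta$locus_id[bad[1, 1]], colnames(calls)[bad[1, 2]]),
         call. = FALSE)
  }
  for (col in setdiff(.dart_meta_cols, names(meta))) meta[[col]] <- NA_real_
  out <- dplyr::bind_cols(meta[.dart_meta_cols], as_tibble(calls))
  class(out) <- c("dart_geno", class(tibble()))
  out
}

#' Extract the calls matrix from a genotype table
#'
#' @param geno A genotype table (see [dart_geno()]).
#' @return Integer matrix, loci x samples, rownames = locus ids.
#' @export
dart_calls <- function(geno) {
  m <- as.matrix(geno[dart_samples(geno)])
  storage.mode(m) <- "integer"
  rownames(m) <- geno$locus_id
  m
}

#' Sample ids of a genotype table
#' @param geno A genotype table.
#' @return Character vector of sample ids, in column order.
#' @export
dart_samples <- function(geno) setdiff(names(geno), .dart_meta_cols)

#' Locus metadata of a genotype table
#' @param geno A genotype table.
#' @return Tibble of per-locus metadata.
#' @export
dart_meta <- function(geno) as_tibble(geno)[.dart_meta_cols]

# rebuild the dart_geno class after dplyr verbs stripped it
as_dart_geno <- function(x) {
  class(x) <- c("dart_geno", class(tibble()))
  x
}

#' Recompute per-locus call rate from the calls themselves
#'
#' Call rate is the fraction of samples with a non-missing call at the
#' locus; it is always recomputable from the matrix and never trusted from
#' file metadata.
#'
#' @param geno A genotype table.
#' @return Numeric vector of call rates in `[0, 1]`, one per locus.
#' @export
call_rate <- function(geno) {
  calls <- dart_calls(geno)
  rowMeans(!is.na(calls))
}
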