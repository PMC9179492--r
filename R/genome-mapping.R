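# Chromosome assignment of candidate loci from tabular alignment hits,
# sex-determining-region interval detection, and per-chromosome counts.

.blast_cols <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end", "e_value",
                 "bit_score")

#' Read alignment hits in BLAST tabular format (outfmt 6)
#'
#' Twelve tab-separated columns per line, no header. Minus-strand hits
#' (subject start greater than subject end) are normalized to ordered
#' coordinates with `strand = "-"`.
#'
#' @param path Tabular hits file.
#' @return Tibble of hits with the standard 12 columns plus `strand`;
#'   `s_start <= s_end` always holds after normalization.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    return(tibble::as_tibble(stats::setNames(
      rep(list(character(0)), 12), .blast_cols)) |>
        dplyr::mutate(dplyr::across(3:12, as.numeric), strand = character(0)))
  }
  fields <- stringr::str_split(lines, "\t")
  n_fields <- lengths(fields)
  if (any(n_fields < 12)) {
    stop("malformed alignment line ", which(n_fields < 12)[1],
         ": expected at least 12 tab-separated columns", call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  hits <- tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.numeric(m[, 4]),
    mismatches = as.numeric(m[, 5]), gap_opens = as.numeric(m[, 6]),
    q_start = as.numeric(m[, 7]), q_end = as.numeric(m[, 8]),
    s_start = as.numeric(m[, 9]), s_end = as.numeric(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]))
  bad <- which(is.na(hits$percent_identity) | is.na(hits$s_start) |
                 is.na(hits$s_end) | is.na(hits$bit_score))
  if (length(bad) > 0) {
    stop("malformed alignment line ", bad[1], ": non-numeric field",
         call. = FALSE)
  }
  minus <- hits$s_start > hits$s_end
  hits$strand <- ifelse(minus, "-", "+")
  tmp <- hits$s_start[minus]
  hits$s_start[minus] <- hits$s_end[minus]
  hits$s_end[minus] <- tmp
  hits
}

#' Filter hits and assign each locus to a chromosome
#'
#' Keeps hits with identity strictly above `min_identity` (percent scale)
#' and alignment length strictly above `min_length`, then picks one best
#' hit per locus: maximal bit score, ties broken by lower e-value, then
#' longer alignment, then lexicographic subject id. The assigned position
#' is the midpoint of the subject interval (rounded down to an integer
#' base pair).
#'
#' @param hits Tibble from [read_blast_tab()].
#' @param min_identity Identity threshold, percent (default 95, strict `>`).
#' @param min_length Alignment-length threshold, bp (default 65, strict `>`).
#' @return Tibble of class `chrom_assignment` with one row per placed
#'   locus: `locus_id`, `chromosome`, `position`, `strand`, best-hit
#'   stats. Loci present in `hits` but with no surviving hit are listed
#'   in `attr(, "unplaced")`.
#' @export
filter_and_assign <- function(hits, min_identity = 95, min_length = 65) {
  eligible <- hits |>
    dplyr::filter(.data$percent_identity > min_identity,
                  .data$alignment_length > min_length)
  assignment <- eligible |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bit_score),
                   .data$e_value, dplyr::desc(.data$alignment_length),
                   .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
    dplyr::transmute(locus_id = .data$query_id,
                     chromosome = .data$subject_id,
                     position = floor((.data$s_start + .data$s_end) / 2),
                     strand = .data$strand,
                     percent_identity = .data$percent_identity,
                     alignment_length = .data$alignment_length,
                     e_value = .data$e_value,
                     bit_score = .data$bit_score)
  attr(assignment, "unplaced") <- setdiff(unique(hits$query_id),
                                          assignment$locus_id)
  class(assignment) <- c("chrom_assignment", class(assignment))
  assignment
}

#' Cross-tabulate chromosome assignments by classification tier
#'
#' @param assignment A `chrom_assignment` tibble.
#' @param classifications Tibble with columns `locus_id` and `tier`
#'   (e.g. the per-locus stats of one scan scope/system).
#' @return Tibble of (`chromosome`, `tier`, `n_loci`, `percent`), the
#'   percentage being of all loci in that tier (3 decimals). Classified
#'   loci without an assignment count under chromosome `"unplaced"`.
#' @export
chromosome_counts <- function(assignment, classifications) {
  joined <- classifications |>
    dplyr::select("locus_id", "tier") |>
    dplyr::left_join(tibble::as_tibble(assignment)[c("locus_id", "chromosome")],
                     by = "locus_id") |>
    dplyr::mutate(chromosome = dplyr::coalesce(.data$chromosome, "unplaced"))
  joined |>
    dplyr::count(.data$chromosome, .data$tier, name = "n_loci") |>
    dplyr::group_by(.data$tier) |>
    dplyr::mutate(percent = round(100 * .data$n_loci / sum(.data$n_loci), 3)) |>
    dplyr::ungroup()
}

#' Minimal interval spanned by placed loci (sex-determining region)
#'
#' @param assignment A `chrom_assignment` tibble, typically restricted to
#'   the loci of one tier; all rows must lie on one chromosome (pass
#'   `chromosome` to select it when the assignment spans several).
#' @param chromosome Optional chromosome to restrict to.
#' @return A one-row tibble: `chromosome`, `start`, `end` (1-based
#'   inclusive), `span_bp = end - start + 1`, `span_mb` (one decimal),
#'   `n_loci`.
#' @export
sdr_interval <- function(assignment, chromosome = NULL) {
  df <- tibble::as_tibble(assignment)
  if (!is.null(chromosome)) df <- df[df$chromosome == chromosome, ]
  if (nrow(df) == 0) stop("no placed loci on the requested chromosome", call. = FALSE)
  if (length(unique(df$chromosome)) > 1) {
    stop("assignment spans several chromosomes; pass `chromosome`", call. = FALSE)
  }
  start <- min(df$position); end <- max(df$position)
  tibble::tibble(chromosome = df$chromosome[1], start = start, end = end,
                 span_bp = end - start + 1,
                 span_mb = round((end - start + 1) / 1e6, 1),
                 n_loci = nrow(df))
}

#' Count assigned loci inside an interval
#'
#' @param assignment A `chrom_assignment` tibble.
#' @param interval A one-row interval tibble (as from [sdr_interval()])
#'   with `chromosome`, `start`, `end`.
#' @return A one-row tibble: `n_inside`, `n_chromosome` (loci assigned to
#'   that chromosome), `fraction`, `percent` (3 decimals).
#' @export
loci_in_region <- function(assignment, interval) {
  stopifnot(nrow(interval) == 1, interval$start <= interval$end)
  df <- tibble::as_tibble(assignment)
  on_chrom <- df[df$chromosome == interval$chromosome, ]
  inside <- on_chrom$position >= interval$start & on_chrom$position <= interval$end
  n_chr <- nrow(on_chrom)
  frac <- if (n_chr > 0) sum(inside) / n_chr else 0
  tibble::tibble(n_inside = sum(inside), n_chromosome = n_chr,
                 fraction = frac, percent = round(100 * frac, 3))
}

#' Write chromosome assignments as a BED file
#'
#' BED is 0-based half-open: a 1-based position p becomes the interval
#' `[p - 1, p)`. Unplaced loci are omitted (their count is messaged).
#'
#' @param assignment A `chrom_assignment` tibble.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_karyotype_bed <- function(assignment, path) {
  df <- tibble::as_tibble(assignment)
  unplaced <- attr(assignment, "unplaced")
  if (length(unplaced) > 0) {
    message(length(unplaced), " unplaced loci omitted from BED output")
  }
  bed <- tibble::tibble(chrom = df$chromosome,
                        chromStart = as.integer(df$position - 1),
                        chromEnd = as.integer(df$position),
                        name = df$locus_id,
                        score = pmin(1000L, as.integer(round(df$bit_score))),
                        strand = df$strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
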