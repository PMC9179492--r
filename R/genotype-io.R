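# Readers/writers for the comma-separated DArT-style dialects.
# Reading is gzip-transparent via readr. Missing symbols are configurable
# on read (default "-", "", "NA"); "-" is always written.

.default_missing <- c("-", "", "NA")

# read a raw CSV and split it into locus id / metadata / sample columns.
# col_map maps canonical metadata names to file column names.
.read_dart_raw <- function(path, col_map) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (nrow(raw) == 0) stop("empty genotype file: ", path, call. = FALSE)
  id_col <- col_map[["locus_id"]]
  if (!id_col %in% names(raw)) {
    stop("locus id column '", id_col, "' not found in ", path, call. = FALSE)
  }
  meta_cols <- col_map[names(col_map) != "locus_id"]
  meta_cols <- meta_cols[meta_cols %in% names(raw)]
  sample_cols <- setdiff(names(raw), c(id_col, unname(meta_cols)))
  if (length(sample_cols) == 0) stop("no sample columns found in ", path, call. = FALSE)
  cells <- as.matrix(raw[sample_cols])
  list(raw = raw, id_col = id_col, meta_cols = meta_cols,
       sample_cols = sample_cols, cells = cells)
}

.parse_cells <- function(values, legal, missing_symbols, locus_id, sample_ids) {
  out <- rep(NA_integer_, length(values))
  is_missing <- values %in% missing_symbols | is.na(values)
  ok <- values %in% as.character(legal)
  bad <- !is_missing & !ok
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("illegal call symbol '%s' at locus '%s', sample '%s'",
                 values[i], locus_id, sample_ids[i]), call. = FALSE)
  }
  out[ok] <- as.integer(values[ok])
  out
}

.numeric_meta <- function(raw, meta_cols, missing_symbols) {
  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in c("reproducibility", "depth", "allele_balance", "call_rate")) {
    if (canon %in% names(meta_cols)) {
      v <- raw[[meta_cols[[canon]]]]
      v[v %in% missing_symbols] <- NA
      out[[canon]] <- suppressWarnings(as.numeric(v))
    } else {
      out[[canon]] <- NA_real_
    }
  }
  out
}

#' Read a DArT-style SNP genotype file
#'
#' Supports the common two-row dialect (one pair of consecutive rows per
#' locus: a reference-allele row then an alternate-allele row, each cell
#' scoring presence of that allele) and a one-row dialect with genotype
#' codes 0/1/2 directly. Two-row pairs decode as (1,0) = reference
#' homozygote, (1,1) = heterozygote, (0,1) = alternate homozygote; a pair
#' with a missing member — or (0,0), where neither allele was observed —
#' is a missing call.
#'
#' @param path CSV file (optionally gzip-compressed). The header names the
#'   samples; non-sample columns are identified through `col_map`.
#' @param dialect `"two_row"` (default) or `"one_row"`.
#' @param missing_symbols Cell values treated as missing.
#' @param col_map Named character vector mapping the canonical metadata
#'   names (`locus_id`, `reproducibility`, `depth`, `allele_balance`,
#'   `call_rate`) to the file's column names; metadata columns absent from
#'   the file are recorded as unavailable.
#' @return A genotype table (see [dart_geno()]) with `marker_type = "SNP"`.
#' @export
read_dart_snp <- function(path, dialect = c("two_row", "one_row"),
                          missing_symbols = .default_missing,
                          col_map = c(locus_id = "locus_id",
                                      reproducibility = "reproducibility",
                                      depth = "depth",
                                      allele_balance = "allele_balance",
                                      call_rate = "call_rate")) {
  dialect <- match.arg(dialect)
  parts <- .read_dart_raw(path, col_map)
  raw <- parts$raw
  ids <- raw[[parts$id_col]]
  if (dialect == "one_row") {
    calls <- matrix(NA_integer_, nrow(raw), length(parts$sample_cols),
                    dimnames = list(NULL, parts$sample_cols))
    for (i in seq_len(nrow(raw))) {
      calls[i, ] <- .parse_cells(parts$cells[i, ],
                                 0:2, missing_symbols, ids[i], parts$sample_cols)
    }
    meta <- dplyr::bind_cols(tibble::tibble(locus_id = ids, marker_type = "SNP"),
                             .numeric_meta(raw, parts$meta_cols, missing_symbols))
    return(dart_geno(meta, calls))
  }
  # two_row: consecutive pairs must share a locus id
  if (nrow(raw) %% 2 != 0) {
    stop("two_row dialect requires an even row count; last locus '",
         ids[nrow(raw)], "' is unpaired", call. = FALSE)
  }
  ref_idx <- seq(1, nrow(raw), by = 2)
  alt_idx <- ref_idx + 1
  mism <- ids[ref_idx] != ids[alt_idx]
  if (any(mism)) {
    stop("two_row pairing broken at locus '", ids[ref_idx][mism][1],
         "': rows do not pair by locus id", call. = FALSE)
  }
  n_loci <- length(ref_idx)
  calls <- matrix(NA_integer_, n_loci, length(parts$sample_cols),
                  dimnames = list(NULL, parts$sample_cols))
  for (k in seq_len(n_loci)) {
    ref <- .parse_cells(parts$cells[ref_idx[k], ],
                        0:1, missing_symbols, ids[ref_idx[k]], parts$sample_cols)
    alt <- .parse_cells(parts$cells[alt_idx[k], ],
                        0:1, missing_symbols, ids[ref_idx[k]], parts$sample_cols)
    g <- rep(NA_integer_, length(ref))
    both <- !is.na(ref) & !is.na(alt)
    g[both & ref == 1 & alt == 0] <- 0L
    g[both & ref == 1 & alt == 1] <- 1L
    g[both & ref == 0 & alt == 1] <- 2L
    calls[k, ] <- g   # (0,0) and missing members stay NA
  }
  meta_raw <- raw[ref_idx, , drop = FALSE]
  meta <- dplyr::bind_cols(
    tibble::tibble(locus_id = ids[ref_idx], marker_type = "SNP"),
    .numeric_meta(meta_raw, parts$meta_cols, missing_symbols))
  dart_geno(meta, calls)
}

#' Read a SilicoDArT-style presence/absence genotype file
#'
#' One row per locus; cells score restriction-fragment presence (1),
#' absence (0), or missing.
#'
#' @inheritParams read_dart_snp
#' @return A genotype table with `marker_type = "PA"`.
#' @export
read_dart_pa <- function(path, missing_symbols = .default_missing,
                         col_map = c(locus_id = "locus_id",
                                     reproducibility = "reproducibility",
                                     depth = "depth",
                                     allele_balance = "allele_balance",
                                     call_rate = "call_rate")) {
  parts <- .read_dart_raw(path, col_map)
  raw <- parts$raw
  ids <- raw[[parts$id_col]]
  calls <- matrix(NA_integer_, nrow(raw), length(parts$sample_cols),
                  dimnames = list(NULL, parts$sample_cols))
  for (i in seq_len(nrow(raw))) {
    calls[i, ] <- .parse_cells(parts$cells[i, ],
                               0:1, missing_symbols, ids[i], parts$sample_cols)
  }
  meta <- dplyr::bind_cols(tibble::tibble(locus_id = ids, marker_type = "PA"),
                           .numeric_meta(raw, parts$meta_cols, missing_symbols))
  dart_geno(meta, calls)
}

#' Read a sample sheet
#'
#' @param path CSV file with columns `sample_id`, `sex`, `population_id`.
#' @param sex_tokens Named character vector mapping file tokens to the
#'   sexes `male`, `female`, `unknown`.
#' @return Tibble with columns `sample_id`, `sex`
#'   (`"male"`/`"female"`/`"unknown"`), `population_id`.
#' @export
read_sample_sheet <- function(path, sex_tokens = c(M = "male", F = "female",
                                                   U = "unknown")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "sex", "population_id")
  if (!all(need %in% names(raw)) || nrow(raw) == 0) {
    stop("sample sheet must have columns sample_id, sex, population_id and at least one row",
         call. = FALSE)
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !(raw$sex %in% names(sex_tokens))
  if (any(bad)) {
    stop("unrecognized sex token '", raw$sex[bad][1], "' at row ",
         which(bad)[1], " (sample ", raw$sample_id[bad][1], ")", call. = FALSE)
  }
  if (any(is.na(raw$population_id) | raw$population_id == "")) {
    stop("population_id must be non-empty for every sample", call. = FALSE)
  }
  tibble::tibble(sample_id = raw$sample_id,
                 sex = unname(sex_tokens[raw$sex]),
                 population_id = raw$population_id)
}

#' Write a genotype table to CSV
#'
#' SNP tables are written in the two-row dialect, PA tables one row per
#' locus; missing calls are written as `-`. Reading the file back
#' reproduces the table exactly (calls, order, metadata).
#'
#' @param geno A genotype table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dart_matrix <- function(geno, path) {
  calls <- dart_calls(geno)
  meta <- dart_meta(geno)
  fmt <- function(m) {
    m <- format(m, trim = TRUE, scientific = FALSE)
    m[is.na(calls) | m == "NA"] <- "-"
    m
  }
  meta_chr <- meta[c("locus_id", "reproducibility", "depth", "allele_balance",
                     "call_rate")]
  if (all(meta$marker_type == "SNP")) {
    ref <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
    alt <- ref
    ref[] <- ifelse(is.na(calls), NA_integer_, ifelse(calls <= 1L, 1L, 0L))
    alt[] <- ifelse(is.na(calls), NA_integer_, ifelse(calls >= 1L, 1L, 0L))
    ref_chr <- fmt(ref); alt_chr <- fmt(alt)
    n <- nrow(calls)
    idx <- rep(seq_len(n), each = 2)
    body <- matrix(NA_character_, 2 * n, ncol(calls), dimnames = list(NULL, colnames(calls)))
    body[seq(1, 2 * n, 2), ] <- ref_chr
    body[seq(2, 2 * n, 2), ] <- alt_chr
    out <- dplyr::bind_cols(meta_chr[idx, ], as_tibble(body))
  } else if (all(meta$marker_type == "PA")) {
    out <- dplyr::bind_cols(meta_chr, as_tibble(fmt(calls)))
  } else {
    stop("mixed SNP/PA tables cannot be written to a single file", call. = FALSE)
  }
  readr::write_csv(out, path, na = "-", progress = FALSE)
  invisible(path)
}

#' Write a sample sheet to CSV
#' @param sheet A sample sheet tibble.
#' @param path Output CSV path.
#' @param sex_tokens Mapping used in reverse to encode the sex column.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path, sex_tokens = c(M = "male", F = "female",
                                                           U = "unknown")) {
  inv <- stats::setNames(names(sex_tokens), sex_tokens)
  out <- tibble::tibble(sample_id = sheet$sample_id,
                        sex = unname(inv[sheet$sex]),
                        population_id = sheet$population_id)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
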