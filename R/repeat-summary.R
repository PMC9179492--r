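# Repeat-class composition of a genomic region from an existing repeat
# annotation (RepeatMasker .out dialect or a simple 5-column TSV).

# declared class hierarchy: subclass -> top-level class
.repeat_hierarchy <- c(
  "Ty3/Gypsy" = "LTR retrotransposon",
  "Ty1/Copia" = "LTR retrotransposon",
  "LINE" = "Non-LTR retrotransposon",
  "Helitron" = "DNA transposon",
  "Polinton" = "DNA transposon",
  "TIR" = "DNA transposon",
  "unclassified" = "Repeat region (unclassified)")

# map a RepeatMasker class/family label to (class, subclass)
.map_rm_label <- function(label) {
  label <- as.character(label)
  sub <- dplyr::case_when(
    stringr::str_detect(label, stringr::regex("gypsy", ignore_case = TRUE)) ~ "Ty3/Gypsy",
    stringr::str_detect(label, stringr::regex("copia", ignore_case = TRUE)) ~ "Ty1/Copia",
    stringr::str_starts(label, "LINE") ~ "LINE",
    stringr::str_detect(label, stringr::regex("helitron", ignore_case = TRUE)) ~ "Helitron",
    stringr::str_detect(label, stringr::regex("maverick|polinton", ignore_case = TRUE)) ~ "Polinton",
    stringr::str_starts(label, "DNA") | stringr::str_starts(label, "RC") ~ "TIR",
    TRUE ~ "unclassified")
  tibble::tibble(repeat_class = unname(.repeat_hierarchy[sub]),
                 repeat_subclass = sub)
}

#' Read a repeat annotation table
#'
#' Two dialects: the RepeatMasker `.out` format (three header lines,
#' whitespace-separated columns; the query, begin, end and class/family
#' columns are consumed) and a simple headered TSV with columns
#' `chromosome`, `start`, `end`, `repeat_class`, `repeat_subclass`.
#' Class labels are normalized through the declared hierarchy (LTR
#' retrotransposon: Ty3/Gypsy, Ty1/Copia; Non-LTR: LINE; DNA transposon:
#' Helitron, Polinton, TIR); unknown labels map to unclassified.
#'
#' @param path Annotation file.
#' @param dialect `"repeatmasker_out"` or `"simple_tsv"`.
#' @return Tibble with columns `chromosome`, `start`, `end` (1-based bp),
#'   `repeat_class`, `repeat_subclass`.
#' @export
read_repeat_table <- function(path, dialect = c("repeatmasker_out", "simple_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "simple_tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(
      chromosome = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), repeat_class = readr::col_character(),
      repeat_subclass = readr::col_character()), progress = FALSE)
    bad <- which(is.na(raw$start) | is.na(raw$end) | raw$start > raw$end |
                   is.na(raw$repeat_class) | raw$repeat_class == "")
    if (length(bad) > 0) {
      stop("malformed repeat annotation row ", bad[1] + 1, call. = FALSE)
    }
    known <- raw$repeat_subclass %in% names(.repeat_hierarchy)
    raw$repeat_subclass[!known] <- "unclassified"
    raw$repeat_class <- unname(.repeat_hierarchy[raw$repeat_subclass])
    return(raw)
  }
  lines <- readr::read_lines(path, progress = FALSE)
  # RepeatMasker .out: two header lines + one blank line before data
  body <- lines[-seq_len(min(3, length(lines)))]
  body <- body[stringr::str_trim(body) != ""]
  if (length(body) == 0) {
    return(tibble::tibble(chromosome = character(0), start = numeric(0),
                          end = numeric(0), repeat_class = character(0),
                          repeat_subclass = character(0)))
  }
  fields <- stringr::str_split(stringr::str_trim(body), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < 11)) {
    stop("malformed RepeatMasker row at data line ", which(n_fields < 11)[1],
         call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[c(5, 6, 7, 11)], character(4)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad) > 0) {
    stop("malformed RepeatMasker row at data line ", bad[1], call. = FALSE)
  }
  mapped <- .map_rm_label(m[, 4])
  tibble::tibble(chromosome = m[, 1], start = start, end = end,
                 repeat_class = mapped$repeat_class,
                 repeat_subclass = mapped$repeat_subclass)
}

#' Repeat-class composition of a genomic interval
#'
#' Counts annotation fragments whose midpoint lies inside the interval
#' and tabulates fragment counts and percentages per class and subclass.
#' Percentages use the grand total of top-level class fragments as the
#' denominator and are rounded to 2 decimals.
#'
#' @param annotation Tibble from [read_repeat_table()].
#' @param interval One-row tibble with `chromosome`, `start`, `end`
#'   (e.g. from [sdr_interval()]).
#' @return Tibble with columns `level` (`"class"`/`"subclass"`), `name`,
#'   `parent_class`, `fragments`, `percentage`. An empty region yields a
#'   zero table with `attr(, "empty") = TRUE`.
#' @export
region_composition <- function(annotation, interval) {
  stopifnot(nrow(interval) == 1)
  mid <- floor((annotation$start + annotation$end) / 2)
  inside <- annotation$chromosome == interval$chromosome &
    mid >= interval$start & mid <= interval$end
  ann <- annotation[inside, , drop = FALSE]
  class_levels <- unique(unname(.repeat_hierarchy))
  sub_levels <- names(.repeat_hierarchy)
  class_counts <- table(factor(ann$repeat_class, levels = class_levels))
  sub_counts <- table(factor(ann$repeat_subclass, levels = sub_levels))
  total <- sum(class_counts)
  pct <- function(n) if (total > 0) round(100 * n / total, 2) else 0
  classes <- tibble::tibble(level = "class", name = class_levels,
                            parent_class = NA_character_,
                            fragments = as.integer(class_counts[class_levels]),
                            percentage = pct(as.integer(class_counts[class_levels])))
  subs <- tibble::tibble(level = "subclass", name = sub_levels,
                         parent_class = unname(.repeat_hierarchy[sub_levels]),
                         fragments = as.integer(sub_counts[sub_levels]),
                         percentage = pct(as.integer(sub_counts[sub_levels])))
  subs <- subs[subs$name != "unclassified", ]  # rolled up in its class row
  out <- dplyr::bind_rows(classes, subs)
  attr(out, "total_fragments") <- total
  attr(out, "empty") <- total == 0
  out
}

#' Write a composition table as TSV plus JSON
#' @param composition Tibble from [region_composition()].
#' @param path_tsv Output TSV path.
#' @param path_json Output JSON path; defaults to `path_tsv` with `.json`.
#' @return `path_tsv`, invisibly.
#' @export
write_composition <- function(composition, path_tsv,
                              path_json = sub("\\.tsv$", ".json", path_tsv)) {
  readr::write_tsv(composition, path_tsv, progress = FALSE)
  jsonlite::write_json(list(total_fragments = attr(composition, "total_fragments"),
                            table = composition),
                       path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}
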