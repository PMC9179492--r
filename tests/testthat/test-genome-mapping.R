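blast_line <- function(q, s, ident, len, sstart, send, evalue, bits) {
  paste(q, s, ident, len, 1, 0, 1, len, sstart, send, evalue, bits, sep = "\t")
}

test_that("tabular alignment hits parse, with minus-strand normalization", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(blast_line("L1", "chr9", 98.5, 69, 100, 168, 1e-30, 130),
               blast_line("L2", "chr2", 97.0, 69, 500, 400, 1e-20, 120)), path)
  hits <- read_blast_tab(path)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$s_start[2], 400)
  expect_equal(hits$s_end[2], 500)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(nrow(read_blast_tab(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(blast_line("L1", "chr9", 98.5, 69, 100, 168, 1e-30, 130),
               "L2\tchr2\tonly-three"), bad)
  expect_error(read_blast_tab(bad), "line 2")
})

test_that("assignment filters are strict and the best-hit cascade holds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    blast_line("A", "chr9", 96.0, 70, 100, 169, 1e-25, 120),   # eligible
    blast_line("B", "chr9", 94.9, 200, 100, 299, 1e-40, 300),  # identity too low
    blast_line("C", "chr9", 99.0, 65, 100, 164, 1e-30, 130),   # length not > 65
    blast_line("D", "chr1", 98.0, 70, 100, 169, 1e-25, 120),   # loses on bit score
    blast_line("D", "chr2", 98.0, 70, 100, 169, 1e-25, 110),
    blast_line("E", "chr3", 98.0, 70, 100, 169, 1e-30, 120),   # wins on e-value
    blast_line("E", "chr4", 98.0, 70, 100, 169, 1e-20, 120)), path)
  asn <- filter_and_assign(read_blast_tab(path))
  expect_setequal(asn$locus_id, c("A", "D", "E"))
  expect_setequal(attr(asn, "unplaced"), c("B", "C"))
  expect_equal(asn$chromosome[asn$locus_id == "D"], "chr1")
  expect_equal(asn$chromosome[asn$locus_id == "E"], "chr3")
  expect_true(all(asn$percent_identity > 95 & asn$alignment_length > 65))
})

test_that("chromosome counts reconstruct a planted 71/1/1 split", {
  asn <- tibble::tibble(
    locus_id = sprintf("L%02d", 1:73),
    chromosome = c(rep("BSP9", 71), "BSP7", "BSP19"),
    position = 1e6 + 1:73, strand = "+",
    percent_identity = 99, alignment_length = 69,
    e_value = 1e-30, bit_score = 130)
  cls <- tibble::tibble(locus_id = sprintf("L%02d", 1:74),
                        tier = c(rep("specific", 73), "linked_90"))
  counts <- chromosome_counts(asn, cls)
  spec <- counts[counts$tier == "specific", ]
  expect_equal(spec$n_loci[spec$chromosome == "BSP9"], 71)
  expect_equal(spec$n_loci[spec$chromosome == "BSP7"], 1)
  expect_equal(spec$n_loci[spec$chromosome == "BSP19"], 1)
  # the classified-but-unplaced locus lands in the unplaced row
  expect_equal(counts$n_loci[counts$chromosome == "unplaced"], 1)
  # 128 of 1033 off-chromosome loci print as 12.391%
  cls2 <- tibble::tibble(locus_id = sprintf("M%04d", 1:1033), tier = "linked")
  asn2 <- tibble::tibble(locus_id = cls2$locus_id,
                         chromosome = c(rep("BSP9", 905), rep("other", 128)),
                         position = 1, strand = "+", percent_identity = 99,
                         alignment_length = 69, e_value = 0, bit_score = 1)
  counts2 <- chromosome_counts(asn2, cls2)
  expect_equal(counts2$percent[counts2$chromosome == "other"], 12.391)
})

test_that("interval detection spans the placed loci", {
  asn <- tibble::tibble(locus_id = c("a", "b"), chromosome = "BSP9",
                        position = c(26285178, 31930103))
  iv <- sdr_interval(asn)
  expect_equal(iv$start, 26285178)
  expect_equal(iv$end, 31930103)
  expect_equal(iv$span_bp, 5644926)
  expect_equal(iv$span_mb, 5.6)

  single <- sdr_interval(tibble::tibble(locus_id = "a", chromosome = "c",
                                        position = 10))
  expect_equal(single$span_bp, 1)

  multi <- tibble::tibble(locus_id = c("a", "b", "c"), chromosome = "c",
                          position = c(100, 250, 400))
  iv3 <- sdr_interval(multi)
  expect_equal(c(iv3$start, iv3$end, iv3$span_bp), c(100, 400, 301))
  # invariant to order and duplicated positions
  iv4 <- sdr_interval(multi[c(3, 1, 2, 2), ])
  expect_equal(iv4[c("start", "end", "span_bp")], iv3[c("start", "end", "span_bp")])
  expect_error(sdr_interval(multi, chromosome = "elsewhere"), "no placed loci")
})

test_that("region membership counts and percentages follow the interval", {
  iv <- tibble::tibble(chromosome = "BSP9", start = 1000, end = 2000)
  asn <- tibble::tibble(locus_id = sprintf("L%03d", 1:905),
                        chromosome = "BSP9",
                        position = c(seq(1000, 2000, length.out = 461),
                                     seq(3000, 4000, length.out = 444)))
  res <- loci_in_region(asn, iv)
  expect_equal(res$n_inside, 461)
  expect_equal(res$n_chromosome, 905)
  expect_equal(res$percent, 50.939)
  # interval covering everything -> fraction 1; disjoint interval -> 0
  all_iv <- tibble::tibble(chromosome = "BSP9", start = 1, end = 1e7)
  expect_equal(loci_in_region(asn, all_iv)$fraction, 1)
  none_iv <- tibble::tibble(chromosome = "BSP9", start = 5e6, end = 6e6)
  expect_equal(loci_in_region(asn, none_iv)$n_inside, 0)
})

test_that("BED export uses 0-based half-open coordinates and round-trips", {
  asn <- tibble::tibble(locus_id = c("L1", "L2"), chromosome = "BSP9",
                        position = c(26285178, 500), strand = c("+", "-"),
                        percent_identity = 99, alignment_length = 69,
                        e_value = 1e-30, bit_score = 130)
  attr(asn, "unplaced") <- "L3"
  path <- withr::local_tempfile(fileext = ".bed")
  expect_message(write_karyotype_bed(asn, path), "1 unplaced")
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         show_col_types = FALSE)
  expect_equal(bed$start[1], 26285177)
  expect_equal(bed$end[1], 26285178)
  expect_equal(bed$start + 1, asn$position)   # positions recoverable
  expect_equal(bed$strand, c("+", "-"))
})
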