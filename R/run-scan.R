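# Full scan driver: carrier frequencies -> tier classification -> CATT /
# PIC / heterozygosity -> per-tier Hamming distance summaries, per
# population and pooled, under the XY and/or ZW hypothesis.

.scan_one_scope <- function(geno, sheet, config, population, systems) {
  samples <- dart_samples(geno)
  sex <- sheet$sex[match(samples, sheet$sample_id)]
  n_males <- sum(sex == "male"); n_females <- sum(sex == "female")
  cf <- carrier_frequencies(geno, sheet, config)
  c_m <- round(cf$f_carrier_male * cf$n_called_male)
  c_f <- round(cf$f_carrier_female * cf$n_called_female)
  ct <- .catt_vec(c_m, cf$n_called_male - c_m, c_f, cf$n_called_female - c_f)

  # allele-frequency based informativeness, computed within this scope
  calls <- dart_calls(geno)
  n_called <- rowSums(!is.na(calls))
  n_het <- rowSums(calls == 1L, na.rm = TRUE)
  is_snp <- cf$marker_type == "SNP"
  n_ref_alleles <- 2 * rowSums(calls == 0L, na.rm = TRUE) + n_het
  p_ref <- ifelse(n_called > 0, n_ref_alleles / (2 * n_called), NA_real_)
  f_absent <- rowSums(calls == 0L, na.rm = TRUE) / pmax(n_called, 1)
  # PA loci are dominant: allele frequency of the null allele estimated as
  # sqrt(freq(absent)) under Hardy-Weinberg
  p1 <- ifelse(is_snp, p_ref, 1 - sqrt(pmin(f_absent, 1)))
  p1 <- pmin(pmax(p1, 0), 1)
  s2 <- p1^2 + (1 - p1)^2
  he <- 1 - s2
  pic_b <- 1 - s2 - (s2^2 - (p1^4 + (1 - p1)^4))
  ho <- ifelse(is_snp & n_called > 0, n_het / n_called, NA_real_)

  gate <- !cf$uninformative &
    cf$n_called_male >= config$min_called_fraction_per_sex * n_males &
    cf$n_called_female >= config$min_called_fraction_per_sex * n_females

  stats <- purrr::map_dfr(systems, function(sys) {
    tier <- rep("none", nrow(cf))
    tier[gate] <- classify_locus(cf$f_carrier_male[gate],
                                 cf$f_carrier_female[gate], config, sys)
    dplyr::bind_cols(
      tibble::tibble(population = population, system = sys),
      cf,
      tibble::tibble(tier = tier, low_call = !gate,
                     catt_chi2 = ct$chi2, catt_p = ct$p,
                     pic_botstein = pic_b, expected_heterozygosity = he,
                     observed_heterozygosity = ho))
  })

  distances <- purrr::map_dfr(systems, function(sys) {
    sys_stats <- stats[stats$system == sys, ]
    tiers <- setdiff(unique(sys_stats$tier), "none")
    purrr::map_dfr(tiers, function(t) {
      idx <- which(sys_stats$tier == t)
      D <- pairwise_hamming(as_dart_geno(geno[idx, , drop = FALSE]))
      distance_summary(D, sheet) |>
        dplyr::mutate(population = population, system = sys, tier = t,
                      n_loci = length(idx), .before = 1)
    })
  })
  list(stats = stats, distances = distances,
       n_males = n_males, n_females = n_females)
}

#' Run the full sex-linkage scan
#'
#' Classifies every locus into sex-specificity tiers under the configured
#' sex-determination hypotheses and computes per-locus informativeness
#' statistics (Cochran-Armitage trend test on carrier counts, Botstein
#' PIC, expected and observed heterozygosity) together with per-tier
#' Hamming distance summaries, pooled over all samples and/or within each
#' population.
#'
#' @param geno A QC-passed genotype table.
#' @param sheet A sample sheet covering the table's samples.
#' @param config A [scan_config()].
#' @return An object of class `sex_scan`: a list with `locus_stats`
#'   (per locus x population x system tibble), `tier_counts`,
#'   `distances`, `cohort` (per-population sex counts) and `config`.
#'   Populations containing only one sex are skipped with a warning.
#' @seealso [tidy.sex_scan()], [glance.sex_scan()], [autoplot.sex_scan()]
#' @export
run_scan <- function(geno, sheet, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  samples <- dart_samples(geno)
  sheet <- sheet[sheet$sample_id %in% samples, , drop = FALSE]
  systems <- if (config$system == "both") c("XY", "ZW") else config$system
  scopes <- list()
  if (config$scope %in% c("pooled", "both")) scopes[["pooled"]] <- samples
  if (config$scope %in% c("per_population", "both")) {
    for (pop in unique(sheet$population_id)) {
      scopes[[pop]] <- sheet$sample_id[sheet$population_id == pop]
    }
  }
  results <- list()
  cohort <- list()
  for (name in names(scopes)) {
    ids <- scopes[[name]]
    sub_sex <- sheet$sex[match(ids, sheet$sample_id)]
    if (sum(sub_sex == "male") == 0 || sum(sub_sex == "female") == 0) {
      warning("population '", name, "' has a single sex; skipped", call. = FALSE)
      next
    }
    sub <- as_dart_geno(geno[c(.dart_meta_cols, ids)])
    res <- .scan_one_scope(sub, sheet, config, name, systems)
    results[[name]] <- res
    cohort[[name]] <- tibble::tibble(population = name, n_males = res$n_males,
                                     n_females = res$n_females)
  }
  if (length(results) == 0) stop("no scannable sample scope", call. = FALSE)
  locus_stats <- purrr::map_dfr(results, "stats")
  distances <- purrr::map_dfr(results, "distances")
  tier_counts <- locus_stats |>
    dplyr::filter(.data$tier != "none") |>
    dplyr::count(.data$population, .data$system, .data$marker_type, .data$tier,
                 name = "n_loci")
  structure(list(locus_stats = locus_stats, tier_counts = tier_counts,
                 distances = distances,
                 cohort = dplyr::bind_rows(cohort), config = config),
            class = "sex_scan")
}

#' @export
print.sex_scan <- function(x, ...) {
  cat("Sex-linkage scan\n")
  cat(sprintf("  cohort: %d males, %d females across %d scope(s)\n",
              max(x$cohort$n_males), max(x$cohort$n_females), nrow(x$cohort)))
  cat(sprintf("  loci scanned: %d\n",
              length(unique(x$locus_stats$locus_id))))
  counts <- x$tier_counts[x$tier_counts$population == x$cohort$population[1], ]
  if (nrow(counts) > 0) {
    cat("  tier counts (first scope):\n")
    print(as.data.frame(counts), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy per-locus scan statistics
#'
#' @param x A `sex_scan` object.
#' @param ... Unused.
#' @return The per-locus tibble (one row per locus, scope, and system).
#' @export
tidy.sex_scan <- function(x, ...) x$locus_stats

#' One-row scan summary
#'
#' @param x A `sex_scan` object.
#' @param ... Unused.
#' @return A one-row tibble with cohort sizes and pooled tier counts.
#' @export
glance.sex_scan <- function(x, ...) {
  pooled <- x$locus_stats[x$locus_stats$population == "pooled", ]
  if (nrow(pooled) == 0) pooled <- x$locus_stats
  is_pooled <- x$cohort$population == "pooled"
  n_m <- if (any(is_pooled)) x$cohort$n_males[is_pooled] else sum(x$cohort$n_males)
  n_f <- if (any(is_pooled)) x$cohort$n_females[is_pooled] else sum(x$cohort$n_females)
  count_tier <- function(sys, t) sum(pooled$system == sys & pooled$tier == t)
  tibble::tibble(
    n_loci = length(unique(x$locus_stats$locus_id)),
    n_males = n_m,
    n_females = n_f,
    n_specific_xy = count_tier("XY", "specific"),
    n_specific_zw = count_tier("ZW", "specific"),
    n_linked_xy = sum(pooled$system == "XY" &
                        startsWith(pooled$tier, "linked")),
    n_linked_zw = sum(pooled$system == "ZW" &
                        startsWith(pooled$tier, "linked")))
}

#' Plot tier counts of a scan
#'
#' Bar chart of the number of loci per sex-linkage tier, faceted by
#' scope and sex-determination hypothesis.
#'
#' @param object A `sex_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sex_scan <- function(object, ...) {
  df <- object$tier_counts
  df$tier <- factor(df$tier, levels = rev(c(.tier_labels(object$config$tier_thresholds))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tier, y = .data$n_loci,
                                   fill = .data$marker_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$system),
                        cols = ggplot2::vars(.data$population)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "sex-linkage tier", y = "loci", fill = "marker") +
    ggplot2::theme_minimal()
}

#' Write scan results as TSV plus a JSON summary
#'
#' The TSV holds one row per locus per scope per system; the JSON mirrors
#' the per-population tier-count / distance-summary layout.
#'
#' @param scan A `sex_scan` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_result <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(scan$locus_stats, file.path(dir, "scan_locus_stats.tsv"),
                   progress = FALSE)
  readr::write_tsv(scan$distances, file.path(dir, "scan_distances.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(config = unclass(scan$config),
         cohort = scan$cohort,
         tier_counts = scan$tier_counts,
         distances = scan$distances),
    file.path(dir, "scan_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
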