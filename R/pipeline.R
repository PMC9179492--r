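# End-to-end driver: simulate (or read) -> QC -> scan -> subsampling ->
# chromosome mapping -> repeat composition, writing a run directory with
# machine-readable reports.

#' Pipeline configuration
#'
#' Bundles the stage configurations, paths and seed; round-trips through
#' a single YAML file so every run is reproducible from its config alone.
#'
#' @param out_dir Run directory for stage outputs.
#' @param seed Integer seed used by every stochastic stage.
#' @param simulate Use the synthetic generator (`TRUE`, default) or read
#'   `snp_path` / `pa_path` / `sheet_path` inputs.
#' @param snp_path,pa_path,sheet_path,hits_path,repeats_path Input files
#'   when `simulate = FALSE` (alignment hits and repeat annotations are
#'   fabricated from truth when simulating).
#' @param sim,qc,scan,mc Stage configurations ([sim_config()],
#'   [qc_config()], [scan_config()], [mc_config()]); `mc_reps` below is a
#'   convenience override.
#' @param mc_reps Subsampling replicates (default 1000 for a desk-scale
#'   run).
#' @param min_identity,min_length Mapping filters.
#' @param overwrite Allow writing into an existing run directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = TRUE,
                            snp_path = NULL, pa_path = NULL, sheet_path = NULL,
                            hits_path = NULL, repeats_path = NULL,
                            sim = sim_config(seed = seed),
                            qc = qc_config(),
                            scan = scan_config(),
                            mc_reps = 1000,
                            min_identity = 95, min_length = 65,
                            overwrite = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, snp_path = snp_path, pa_path = pa_path,
                 sheet_path = sheet_path, hits_path = hits_path,
                 repeats_path = repeats_path, sim = sim, qc = qc,
                 scan = scan, mc_reps = mc_reps,
                 min_identity = min_identity, min_length = min_length,
                 overwrite = overwrite),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML destination.
#' @return `path` invisibly, or the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$sim)
  qc <- do.call(qc_config, raw$qc)
  scan <- do.call(scan_config, c(
    raw$scan[c("system", "presence_rule_snp", "scope",
               "min_called_fraction_per_sex")],
    list(tier_thresholds = unlist(raw$scan$tier_thresholds))))
  keep <- setdiff(names(raw), c("sim", "qc", "scan"))
  do.call(pipeline_config, c(raw[keep], list(sim = sim, qc = qc, scan = scan)))
}

#' Run the full pipeline
#'
#' Executes simulate/read, quality filtering, the sex-linkage scan, the
#' Monte Carlo subsampling reproducibility test, chromosome mapping with
#' sex-determining-region detection, and the repeat-composition summary,
#' writing each stage's outputs plus a top-level `summary.json` into the
#' run directory. Rerunning with the same config and seed reproduces the
#' summary byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly; stage outputs on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  if (dir.exists(dir) && length(dir(dir)) > 0 && !config$overwrite) {
    stop("run directory ", dir, " is not empty; set overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # ---- inputs ----
  if (config$simulate) {
    ds <- simulate_dataset(config$sim)
    snp <- ds$snp; pa <- ds$pa; sheet <- ds$sheet; truth <- ds$truth
    write_dart_matrix(snp, file.path(dir, "snp_genotypes.csv"))
    write_dart_matrix(pa, file.path(dir, "pa_genotypes.csv"))
    write_sample_sheet(sheet, file.path(dir, "sample_sheet.csv"))
    readr::write_tsv(truth, file.path(dir, "sim_truth.tsv"), progress = FALSE)
  } else {
    for (p in c(config$snp_path, config$pa_path, config$sheet_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input not found: ", if (is.null(p)) "(unset path)" else p,
             call. = FALSE)
      }
    }
    snp <- read_dart_snp(config$snp_path)
    pa <- read_dart_pa(config$pa_path)
    sheet <- read_sample_sheet(config$sheet_path)
    truth <- NULL
  }

  # ---- QC ----
  qc_snp <- apply_qc(snp, config$qc)
  qc_pa <- apply_qc(pa, config$qc)
  write_qc_report(qc_snp, file.path(dir, "qc_snp.tsv"))
  write_qc_report(qc_pa, file.path(dir, "qc_pa.tsv"))
  combined <- as_dart_geno(dplyr::bind_rows(qc_snp$matrix, qc_pa$matrix))

  # ---- scan ----
  scan <- run_scan(combined, sheet, config$scan)
  write_scan_result(scan, dir)

  # ---- Monte Carlo subsampling ----
  mc_cfg <- mc_config(reps = config$mc_reps, seed = config$seed)
  single <- config$scan
  if (single$system == "both") single$system <- "XY"
  pooled <- scan$locus_stats[scan$locus_stats$population == "pooled" &
                               scan$locus_stats$system == single$system, ]
  candidates <- pooled$locus_id[pooled$tier != "none"]
  mc_input <- as_dart_geno(combined[combined$locus_id %in% candidates, ,
                                    drop = FALSE])
  mc <- if (nrow(mc_input) > 0) {
    subsample_reproducibility(mc_input, sheet, single, mc_cfg)
  } else NULL
  if (!is.null(mc)) write_mc_report(mc, file.path(dir, "mc_report.tsv"))

  # ---- mapping ----
  assignment <- interval <- region <- composition <- NULL
  if (config$simulate) {
    hits <- simulate_alignment_hits(truth[truth$locus_id %in% candidates, ],
                                    seed = config$seed)
  } else if (!is.null(config$hits_path)) {
    hits <- read_blast_tab(config$hits_path)
  } else hits <- NULL
  if (!is.null(hits) && nrow(hits) > 0) {
    assignment <- filter_and_assign(hits, config$min_identity, config$min_length)
    counts <- chromosome_counts(assignment, pooled)
    readr::write_tsv(counts, file.path(dir, "chromosome_counts.tsv"),
                     progress = FALSE)
    write_karyotype_bed(assignment, file.path(dir, "assignments.bed"))
    spec_ids <- pooled$locus_id[pooled$tier == "specific"]
    spec_asn <- assignment[assignment$locus_id %in% spec_ids, ]
    if (nrow(spec_asn) > 0) {
      main_chr <- names(sort(table(spec_asn$chromosome), decreasing = TRUE))[1]
      interval <- sdr_interval(spec_asn, chromosome = main_chr)
      region <- loci_in_region(assignment, interval)
    }
  }

  # ---- repeats ----
  if (!is.null(interval)) {
    ann <- if (config$simulate) {
      simulate_repeat_annotation(
        c("Ty3/Gypsy" = 807, "Ty1/Copia" = 351, LINE = 55, Helitron = 512,
          Polinton = 24, TIR = 109, unclassified = 520),
        interval, seed = config$seed)
    } else if (!is.null(config$repeats_path)) {
      read_repeat_table(config$repeats_path)
    } else NULL
    if (!is.null(ann)) {
      composition <- region_composition(ann, interval)
      write_composition(composition, file.path(dir, "repeat_composition.tsv"))
    }
  }

  # ---- summary ----
  n <- length(dart_samples(combined))
  summary <- list(
    version = as.character(utils::packageVersion("dartsex")),
    seed = config$seed,
    config = rapply(unclass(config), unclass, how = "replace"),
    cohort = scan$cohort,
    qc = list(snp = attr(qc_snp$report, "summary"),
              pa = attr(qc_pa$report, "summary")),
    tier_counts = scan$tier_counts,
    distances = scan$distances,
    spurious_model = list(
      n = n, P_i = spurious_probability(n),
      L = nrow(combined),
      expected_spurious = expected_spurious(nrow(combined), n)),
    mc = if (!is.null(mc)) list(
      replicates = attr(mc, "replicates_used"),
      mean_detection_specific = mean(mc$detection_frequency_specific),
      mean_detection_linked = mean(mc$detection_frequency_linked)),
    sdr_interval = interval,
    loci_in_region = region,
    repeat_composition = composition)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(summary)
}
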