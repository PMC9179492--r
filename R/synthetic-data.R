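# Synthetic cohort generator with full ground truth: planted
# sex-specific / partially sex-linked / autosomal loci, genotyping error
# and missingness, plus fabricated alignment-hit tables and repeat
# annotations, so every pipeline stage is testable without external data.

.default_populations <- c("POP_BSPG", "POP_BSPGIA", "POP_BSPGL",
                          "POP_BSPO", "POP_BSPW")

# run expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Defaults emulate the study cohort: 40 males and 35 females across five
#' commercial populations, with fully sex-specific loci and partially
#' sex-linked loci (recombination fraction r) planted inside a
#' sex-determining region on one chromosome, on a background of autosomal
#' loci, then symmetric genotyping error and missingness.
#'
#' @param n_males,n_females Cohort sizes (defaults 40 / 35).
#' @param populations Population ids; individuals are allocated
#'   round-robin so each population holds both sexes.
#' @param n_snp,n_pa Locus counts per marker type (defaults 2000 / 2000,
#'   a scaled-down stand-in for the full panel).
#' @param sd_system `"XY"`, `"ZW"`, or `"PSD"` (polygenic: sex set by a
#'   liability score over unlinked switch loci).
#' @param n_specific Number of fully sex-specific planted loci (split
#'   evenly between marker types).
#' @param linked_spec List of `c(count, r)` pairs for partially linked
#'   loci: carrier probability `1 - r` in the heterogametic sex, `r` in
#'   the other.
#' @param sdr_chromosome,sdr_interval Chromosome and 1-based bp range the
#'   planted loci occupy.
#' @param n_chromosomes Autosomal loci scatter over this many chromosomes.
#' @param missing_rate Per-cell missingness probability.
#' @param genotype_error_rate Per-cell error probability (state flip for
#'   PA; move to an adjacent genotype code for SNP).
#' @param carrier_prob_range Uniform range for autosomal PA carrier
#'   probabilities.
#' @param snp_maf_range Uniform range for autosomal SNP reference-allele
#'   frequencies (genotypes drawn under Hardy-Weinberg).
#' @param psd_weights Liability weights of the PSD switch loci.
#' @param seed Integer RNG seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_males = 40, n_females = 35,
                       populations = .default_populations,
                       n_snp = 2000, n_pa = 2000,
                       sd_system = c("XY", "ZW", "PSD"),
                       n_specific = 50,
                       linked_spec = list(c(50, 0.1), c(50, 0.2), c(50, 0.3)),
                       sdr_chromosome = "BSP9",
                       sdr_interval = c(26285178, 31930103),
                       n_chromosomes = 21,
                       missing_rate = 0.05,
                       genotype_error_rate = 0.01,
                       carrier_prob_range = c(0.1, 0.9),
                       snp_maf_range = c(0.05, 0.95),
                       psd_weights = c(1, 1, 0.5),
                       seed) {
  sd_system <- match.arg(sd_system)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  n_planted <- n_specific + sum(vapply(linked_spec, `[`, numeric(1), 1))
  stopifnot(n_males >= 1, n_females >= 1, n_snp + n_pa >= n_planted,
            missing_rate >= 0, missing_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            all(vapply(linked_spec, `[`, numeric(1), 2) >= 0),
            all(vapply(linked_spec, `[`, numeric(1), 2) <= 0.5),
            sdr_interval[1] <= sdr_interval[2])
  if (n_planted > (sdr_interval[2] - sdr_interval[1] + 1)) {
    stop("more planted loci than positions in the sex-determining interval",
         call. = FALSE)
  }
  structure(list(n_males = n_males, n_females = n_females,
                 populations = populations, n_snp = n_snp, n_pa = n_pa,
                 sd_system = sd_system, n_specific = n_specific,
                 linked_spec = linked_spec,
                 sdr_chromosome = sdr_chromosome,
                 sdr_interval = sdr_interval,
                 n_chromosomes = n_chromosomes,
                 missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 carrier_prob_range = carrier_prob_range,
                 snp_maf_range = snp_maf_range,
                 psd_weights = psd_weights,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# apply the error model and missingness to a calls matrix
.perturb_calls <- function(calls, marker_type, error_rate, missing_rate) {
  n <- length(calls)
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate)
    if (length(err) > 0) {
      v <- calls[err]
      if (marker_type == "PA") {
        calls[err] <- 1L - v
      } else {
        up <- stats::runif(length(err)) < 0.5
        new <- ifelse(v == 0L, 1L, ifelse(v == 2L, 1L, ifelse(up, 0L, 2L)))
        calls[err] <- as.integer(new)
      }
    }
  }
  if (missing_rate > 0) {
    calls[stats::runif(n) < missing_rate] <- NA_integer_
  }
  calls
}

.sim_meta <- function(ids, marker_type, n_loci) {
  ab <- if (identical(marker_type, "SNP")) {
    round(stats::runif(n_loci, 0.92, 1.0), 3)
  } else {
    rep(NA_real_, n_loci)
  }
  tibble::tibble(locus_id = ids, marker_type = marker_type,
                 reproducibility = round(stats::runif(n_loci, 0.96, 1.0), 3),
                 depth = round(stats::runif(n_loci, 6, 30), 1),
                 allele_balance = ab,
                 call_rate = NA_real_)
}

#' Simulate a genotyped cohort with ground truth
#'
#' Generates an SNP table, a PA table, a sample sheet, and a truth table
#' labelling every locus (`specific`, `linked_r<r>`, `autosomal`, or
#' `switch` in PSD mode) with its true chromosome and position. Specific
#' loci carry the marker state exactly in the heterogametic sex (SNP:
#' heterozygous in that sex, reference homozygous in the other); loci
#' linked at recombination fraction r carry it with probability 1 - r in
#' the heterogametic sex and r in the other; autosomal loci are
#' independent of sex. Genotyping error and missingness are then applied
#' independently per cell. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `snp`, `pa` (genotype tables), `sheet`
#'   (sample sheet tibble), and `truth`.
#' @export
simulate_dataset <- function(config = sim_config(seed = 1)) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_males + config$n_females
    sheet <- tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      sex = c(rep("male", config$n_males), rep("female", config$n_females)),
      population_id = NA_character_)
    # round-robin within each sex so every population holds both sexes
    sheet$population_id[sheet$sex == "male"] <-
      rep_len(config$populations, config$n_males)
    sheet$population_id[sheet$sex == "female"] <-
      rep_len(config$populations, config$n_females)

    if (config$sd_system == "PSD") {
      # liability model: unlinked switch loci vote on sex
      w <- config$psd_weights
      switch_carrier <- matrix(stats::rbinom(length(w) * n, 1, 0.5),
                               nrow = length(w))
      liability <- as.vector(t(switch_carrier) %*% w) +
        stats::rnorm(n, sd = 0.25)
      sheet$sex <- ifelse(liability > stats::median(liability), "male", "female")
    }
    is_male <- sheet$sex == "male"
    het <- if (config$sd_system == "ZW") !is_male else is_male

    linked_counts <- vapply(config$linked_spec, `[`, numeric(1), 1)
    linked_r <- vapply(config$linked_spec, `[`, numeric(1), 2)
    linked_labels <- if (length(linked_r) > 0) {
      rep(paste0("linked_r", linked_r), linked_counts)
    } else character(0)
    planted_labels <- c(rep("specific", config$n_specific), linked_labels)
    planted_r <- c(rep(0, config$n_specific), rep(linked_r, linked_counts))
    n_planted <- length(planted_labels)
    # split planted loci between the marker types as evenly as possible
    planted_type <- rep_len(c("SNP", "PA"), n_planted)

    sim_type <- function(marker_type, n_loci, prefix) {
      sel <- which(planted_type == marker_type)
      n_plant <- length(sel)
      n_auto <- n_loci - n_plant
      ids <- sprintf("%s%05d", prefix, seq_len(n_loci))
      labels <- c(planted_labels[sel], rep("autosomal", n_auto))
      rs <- c(planted_r[sel], rep(NA_real_, n_auto))
      calls <- matrix(0L, n_loci, n, dimnames = list(NULL, sheet$sample_id))
      for (k in seq_len(n_plant)) {
        carrier <- if (labels[k] == "specific") het else
          stats::runif(n) < ifelse(het, 1 - rs[k], rs[k])
        calls[k, ] <- if (marker_type == "PA") as.integer(carrier)
          else as.integer(carrier)  # SNP: sex-linked allele heterozygous
      }
      if (n_auto > 0) {
        rows <- n_plant + seq_len(n_auto)
        if (marker_type == "PA") {
          p <- stats::runif(n_auto, config$carrier_prob_range[1],
                            config$carrier_prob_range[2])
          calls[rows, ] <- matrix(
            stats::rbinom(n_auto * n, 1, rep(p, times = n)), nrow = n_auto)
        } else {
          p_ref <- stats::runif(n_auto, config$snp_maf_range[1],
                                config$snp_maf_range[2])
          alt <- 1 - p_ref
          calls[rows, ] <- matrix(
            stats::rbinom(n_auto * n, 2, rep(alt, times = n)), nrow = n_auto)
        }
      }
      pre_error <- calls
      calls <- matrix(.perturb_calls(as.vector(calls), marker_type,
                                     config$genotype_error_rate,
                                     config$missing_rate),
                      nrow = n_loci, dimnames = dimnames(calls))
      list(geno = dart_geno(.sim_meta(ids, marker_type, n_loci), calls),
           truth = tibble::tibble(locus_id = ids, marker_type = marker_type,
                                  label = labels, r = rs),
           pre_error = pre_error)
    }

    snp <- sim_type("SNP", config$n_snp, "SNP")
    pa <- sim_type("PA", config$n_pa, "PA")
    truth <- dplyr::bind_rows(snp$truth, pa$truth)

    # positions: planted loci inside the sex-determining interval,
    # autosomal loci scattered across the other chromosomes
    planted_idx <- which(truth$label != "autosomal")
    truth$chromosome <- sample(paste0("BSP", seq_len(config$n_chromosomes)),
                               nrow(truth), replace = TRUE)
    truth$position <- floor(stats::runif(nrow(truth), 1, 4e7))
    truth$chromosome[planted_idx] <- config$sdr_chromosome
    truth$position[planted_idx] <- sample(
      seq(config$sdr_interval[1], config$sdr_interval[2]),
      length(planted_idx))
    if (config$sd_system == "PSD") {
      # the switch loci are latent (not part of the genotyped panel);
      # record their existence for reference
      attr(truth, "psd_weights") <- config$psd_weights
    }
    list(snp = snp$geno, pa = pa$geno, sheet = sheet, truth = truth)
  })
}

#' Simulate a null presence/absence matrix
#'
#' Every cell is an independent Bernoulli carrier state — the null model
#' behind the spurious sex-linkage probability `0.5^n`.
#'
#' @param n_samples,n_loci Matrix dimensions.
#' @param carrier_prob Carrier probability per cell (default 0.5).
#' @param seed Integer RNG seed.
#' @return A PA genotype table.
#' @export
simulate_null_matrix <- function(n_samples, n_loci, carrier_prob = 0.5, seed) {
  stopifnot(n_samples >= 1, n_loci >= 1)
  .with_seed(seed, {
    calls <- matrix(stats::rbinom(n_loci * n_samples, 1, carrier_prob),
                    nrow = n_loci,
                    dimnames = list(NULL, sprintf("N%03d", seq_len(n_samples))))
    meta <- tibble::tibble(locus_id = sprintf("NL%07d", seq_len(n_loci)),
                           marker_type = "PA")
    dart_geno(meta, calls)
  })
}

#' Fabricate alignment hits for simulated loci
#'
#' Emits one true hit per locus at its true position (identity about 99,
#' alignment length 69) plus optional decoy hits that fail the mapping
#' filters or lose the best-hit contest.
#'
#' @param truth Truth table from [simulate_dataset()] (needs
#'   `locus_id`, `chromosome`, `position`).
#' @param off_target_rate Fraction of loci that also receive a decoy hit.
#' @param identity_jitter Half-width of uniform jitter on the true hit's
#'   identity (kept above the default 95 filter).
#' @param decoy_identity Identity of decoy hits (default 94, below the
#'   filter threshold).
#' @param seed Integer RNG seed.
#' @return A hits tibble in the layout of [read_blast_tab()].
#' @export
simulate_alignment_hits <- function(truth, off_target_rate = 0,
                                    identity_jitter = 0, decoy_identity = 94,
                                    seed = 1) {
  .with_seed(seed, {
    len <- 69
    half <- (len - 1) / 2
    ident <- pmin(100, 99 - stats::runif(nrow(truth), 0, identity_jitter))
    hits <- tibble::tibble(
      query_id = truth$locus_id, subject_id = truth$chromosome,
      percent_identity = round(ident, 2), alignment_length = len,
      mismatches = 1, gap_opens = 0, q_start = 1, q_end = len,
      s_start = truth$position - half, s_end = truth$position + half,
      e_value = 1e-30, bit_score = 130, strand = "+")
    if (off_target_rate > 0) {
      pick <- which(stats::runif(nrow(truth)) < off_target_rate)
      if (length(pick) > 0) {
        decoys <- hits[pick, ]
        decoys$subject_id <- sample(unique(truth$chromosome),
                                    length(pick), replace = TRUE)
        decoys$percent_identity <- decoy_identity
        decoys$bit_score <- 110
        decoys$e_value <- 1e-10
        hits <- dplyr::bind_rows(hits, decoys)
      }
    }
    hits
  })
}

#' Fabricate a repeat annotation with a prescribed composition
#'
#' Places exactly the requested number of fragments of each repeat
#' subclass uniformly inside the interval, so that [region_composition()]
#' on the full interval returns the input composition exactly; only the
#' fragment positions depend on the seed.
#'
#' @param composition Named integer vector of fragment counts keyed by
#'   repeat subclass (`Ty3/Gypsy`, `Ty1/Copia`, `LINE`, `Helitron`,
#'   `Polinton`, `TIR`, `unclassified`).
#' @param interval One-row tibble with `chromosome`, `start`, `end`.
#' @param seed Integer RNG seed.
#' @return A repeat-annotation tibble.
#' @export
simulate_repeat_annotation <- function(composition, interval, seed = 1) {
  stopifnot(all(names(composition) %in% names(.repeat_hierarchy)),
            all(composition >= 0), nrow(interval) == 1)
  .with_seed(seed, {
    subclass <- rep(names(composition), times = composition)
    n <- length(subclass)
    if (n == 0) {
      return(tibble::tibble(chromosome = character(0), start = numeric(0),
                            end = numeric(0), repeat_class = character(0),
                            repeat_subclass = character(0)))
    }
    # fragments of length 101 centred on a midpoint inside the interval
    mid <- floor(stats::runif(n, interval$start + 50, interval$end - 50))
    tibble::tibble(chromosome = interval$chromosome,
                   start = mid - 50, end = mid + 50,
                   repeat_class = unname(.repeat_hierarchy[subclass]),
                   repeat_subclass = subclass)
  })
}
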