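# Threshold classification of loci under XX/XY and ZZ/ZW hypotheses plus
# the locus informativeness statistics (CATT, PIC/heterozygosity, Hamming
# distances) and the spurious sex-linkage probability model.

#' Sex-scan configuration
#'
#' @param system Sex-determination hypothesis to scan under: `"XY"`
#'   (male-heterogametic), `"ZW"` (female-heterogametic), or `"both"`.
#' @param tier_thresholds Strictly increasing carrier-frequency thresholds
#'   ending at 1.0. The default `c(0.70, 0.80, 0.90, 1.00)` reproduces the
#'   30:70 / 20:80 / 10:90 / 0:100 filtering tiers: a locus passes tier t
#'   when at least a fraction t of the heterogametic sex carries the
#'   marker state and at most 1 - t of the other sex does. The 1.0 tier
#'   ("sex-specific") requires exactly (1.0, 0.0).
#' @param presence_rule_snp How a SNP genotype counts as "carrying" the
#'   marker state: `"alt_allele_present"` (heterozygote or alternate
#'   homozygote; default, since a Y-linked allele appears heterozygous in
#'   males), `"het_only"`, or `"alt_hom_only"`.
#' @param min_called_fraction_per_sex Minimum fraction of each sex that
#'   must be called at a locus for it to be classifiable (default 0.8);
#'   prevents a locus called in one male from becoming "sex-specific".
#' @param scope Compute statistics `"pooled"` over all samples,
#'   `"per_population"`, or `"both"`.
#' @return A `scan_config` list.
#' @export
scan_config <- function(system = c("both", "XY", "ZW"),
                        tier_thresholds = c(0.70, 0.80, 0.90, 1.00),
                        presence_rule_snp = c("alt_allele_present", "het_only",
                                              "alt_hom_only"),
                        min_called_fraction_per_sex = 0.8,
                        scope = c("both", "pooled", "per_population")) {
  system <- match.arg(system)
  presence_rule_snp <- match.arg(presence_rule_snp)
  scope <- match.arg(scope)
  tier_thresholds <- sort(tier_thresholds)
  stopifnot(length(tier_thresholds) >= 1,
            all(diff(tier_thresholds) > 0),
            tier_thresholds[length(tier_thresholds)] == 1,
            all(tier_thresholds > 0.5), all(tier_thresholds <= 1),
            min_called_fraction_per_sex >= 0, min_called_fraction_per_sex <= 1)
  structure(list(system = system, tier_thresholds = tier_thresholds,
                 presence_rule_snp = presence_rule_snp,
                 min_called_fraction_per_sex = min_called_fraction_per_sex,
                 scope = scope),
            class = "scan_config")
}

.tier_labels <- function(thresholds) {
  ifelse(thresholds == 1, "specific",
         paste0("linked_", round(100 * thresholds)))
}

# logical carrier matrix (loci x samples): TRUE = carries the marker
# state, FALSE = does not, NA = missing call
.carrier_matrix <- function(geno, presence_rule_snp) {
  calls <- dart_calls(geno)
  is_snp <- dart_meta(geno)$marker_type == "SNP"
  carr <- calls >= 1L            # PA: present; SNP alt_allele_present
  if (any(is_snp) && presence_rule_snp != "alt_allele_present") {
    snp_carr <- switch(presence_rule_snp,
                       het_only = calls == 1L,
                       alt_hom_only = calls == 2L)
    carr[is_snp, ] <- snp_carr[is_snp, ]
  }
  carr
}

#' Per-locus carrier frequencies by sex
#'
#' Computes, over called individuals only, the fraction of males and of
#' females carrying the marker state (fragment presence for PA loci; the
#' configured presence rule for SNP loci). Loci with no called individual
#' in either sex are flagged uninformative.
#'
#' @param geno A genotype table.
#' @param sheet A sample sheet covering the table's samples.
#' @param config A [scan_config()].
#' @return Tibble with columns `locus_id`, `marker_type`,
#'   `f_carrier_male`, `f_carrier_female`, `n_called_male`,
#'   `n_called_female`, `uninformative`.
#' @export
carrier_frequencies <- function(geno, sheet, config = scan_config()) {
  samples <- dart_samples(geno)
  missing <- setdiff(samples, sheet$sample_id)
  if (length(missing) > 0) {
    stop("samples absent from the sample sheet: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sex <- sheet$sex[match(samples, sheet$sample_id)]
  carr <- .carrier_matrix(geno, config$presence_rule_snp)
  males <- which(sex == "male"); females <- which(sex == "female")
  if (length(males) == 0 || length(females) == 0) {
    stop("sex-stratified statistics require at least one male and one female",
         call. = FALSE)
  }
  n_m <- unname(rowSums(!is.na(carr[, males, drop = FALSE])))
  n_f <- unname(rowSums(!is.na(carr[, females, drop = FALSE])))
  c_m <- unname(rowSums(carr[, males, drop = FALSE], na.rm = TRUE))
  c_f <- unname(rowSums(carr[, females, drop = FALSE], na.rm = TRUE))
  tibble::tibble(
    locus_id = geno$locus_id,
    marker_type = geno$marker_type,
    f_carrier_male = ifelse(n_m > 0, c_m / n_m, NA_real_),
    f_carrier_female = ifelse(n_f > 0, c_f / n_f, NA_real_),
    n_called_male = n_m,
    n_called_female = n_f,
    uninformative = n_m == 0 | n_f == 0)
}

#' Classify a locus into a sex-linkage tier
#'
#' Under the XY hypothesis a locus passes threshold t when the male
#' carrier frequency is at least t and the female carrier frequency at
#' most 1 - t; the ZW hypothesis mirrors the sexes. The returned tier is
#' the highest threshold passed; the 1.0 tier ("specific") additionally
#' requires frequencies of exactly 1.0 and 0.0.
#'
#' @param f_m,f_f Carrier frequencies in males and females (vectorized).
#' @param config A [scan_config()] supplying the tier thresholds.
#' @param system `"XY"` or `"ZW"`.
#' @return Character vector of tiers (`"specific"`, `"linked_90"`, ...,
#'   `"none"`); `NA` frequencies give `"none"`.
#' @export
classify_locus <- function(f_m, f_f, config = scan_config(), system = "XY") {
  stopifnot(system %in% c("XY", "ZW"))
  if (system == "XY") { f_het <- f_m; f_hom <- f_f } else { f_het <- f_f; f_hom <- f_m }
  thr <- config$tier_thresholds
  labels <- .tier_labels(thr)
  tier <- rep("none", length(f_het))
  eps <- 1e-9  # frequencies are count ratios; guard binary representation
  for (k in seq_along(thr)) {
    pass <- if (thr[k] == 1) {
      !is.na(f_het) & !is.na(f_hom) & f_het == 1 & f_hom == 0
    } else {
      !is.na(f_het) & !is.na(f_hom) &
        f_het >= thr[k] - eps & f_hom <= 1 - thr[k] + eps
    }
    tier[pass] <- labels[k]   # thresholds ascend, so the highest passed wins
  }
  tier
}

#' Cochran-Armitage trend test for a 2 x k table
#'
#' Score-based trend chi-square without continuity correction, with the
#' p-value from the upper tail of chi-square(1). For a 2 x 2
#' carrier/non-carrier table the statistic reduces to
#' N (ad - bc)^2 / (R1 R2 C1 C2).
#'
#' @param counts 2 x k matrix of non-negative counts; rows are the two
#'   sexes, columns the ordered genotype categories.
#' @param scores Numeric column scores (default `0:(k-1)`).
#' @return A list with `chi2`, `df` (always 1) and `p`; `chi2` is `NA`
#'   (flagged undefined) when a margin degenerates so the variance is 0.
#' @export
catt_trend <- function(counts, scores = seq_len(ncol(counts)) - 1) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, length(scores) == ncol(counts),
            all(counts >= 0))
  N <- sum(counts)
  R1 <- sum(counts[1, ]); R2 <- sum(counts[2, ])
  ck <- colSums(counts)
  if (N == 0 || R1 == 0 || R2 == 0) {
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_))
  }
  T_stat <- sum(scores * (counts[1, ] - ck * R1 / N))
  V <- R1 * R2 * (N * sum(scores^2 * ck) - sum(scores * ck)^2) / N^3
  if (V <= 0) return(list(chi2 = NA_real_, df = 1L, p = NA_real_))
  chi2 <- T_stat^2 / V
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Cochran-Armitage trend test for a 2 x 2 carrier table
#'
#' @param carriers_male,noncarriers_male Male carrier / non-carrier counts.
#' @param carriers_female,noncarriers_female Female counts.
#' @return As [catt_trend()].
#' @export
catt <- function(carriers_male, noncarriers_male,
                 carriers_female, noncarriers_female) {
  catt_trend(rbind(c(noncarriers_male, carriers_male),
                   c(noncarriers_female, carriers_female)),
             scores = c(0, 1))
}

# vectorized 2x2 trend chi-square over loci
.catt_vec <- function(a, b, c, d) {
  # a = male carriers, b = male non-carriers, c = female carriers,
  # d = female non-carriers
  N <- a + b + c + d
  num <- N * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den > 0, num / den, NA_real_)
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Polymorphic information content and expected heterozygosity
#'
#' The Botstein PIC, `1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`, is bounded
#' by 0.375 for a biallelic locus, while expected heterozygosity
#' `1 - sum(p^2)` is bounded by 0.5; both are reported.
#'
#' @param p Allele frequencies summing to 1 (tolerance 1e-9).
#' @return A list with `pic_botstein` and `expected_heterozygosity`.
#' @export
pic <- function(p) {
  if (abs(sum(p) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1 (got ", sum(p), ")", call. = FALSE)
  }
  s2 <- sum(p^2); s4 <- sum(p^4)
  list(pic_botstein = 1 - s2 - (s2^2 - s4),
       expected_heterozygosity = 1 - s2)
}

#' Hamming distance between two call vectors
#'
#' Proportion of mutually-called positions at which the calls differ.
#'
#' @param a,b Call vectors of equal length (`NA` = missing).
#' @return A fraction in `[0, 1]`, or `NA` when no position is
#'   mutually called.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("call vectors differ in length", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}

#' Pairwise Hamming distances between samples
#'
#' @param geno A genotype table (optionally restricted to a locus set).
#' @return Symmetric samples x samples matrix of pairwise Hamming
#'   distances; diagonal 0; `NA` for pairs with no mutually-called locus.
#' @export
pairwise_hamming <- function(geno) {
  calls <- dart_calls(geno)
  n <- ncol(calls)
  D <- matrix(0, n, n, dimnames = list(colnames(calls), colnames(calls)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- hamming_distance(calls[, i], calls[, j])
    }
  }
  D
}

#' Mean Hamming distances between and within the sexes
#'
#' Means and standard deviations over unordered sample pairs (no
#' self-pairs) in three strata: male-female, within males, within
#' females. A stratum with fewer than one pair is reported undefined.
#'
#' @param dist_matrix Symmetric distance matrix indexed by sample id.
#' @param sheet A sample sheet covering those samples.
#' @return Tibble with columns `stratum`, `mean`, `sd`, `n_pairs`.
#' @export
distance_summary <- function(dist_matrix, sheet) {
  ids <- rownames(dist_matrix)
  sex <- sheet$sex[match(ids, sheet$sample_id)]
  males <- which(sex == "male"); females <- which(sex == "female")
  pair_vals <- function(idx_a, idx_b = NULL) {
    if (is.null(idx_b)) {  # within-stratum pairs
      if (length(idx_a) < 2) return(numeric(0))
      d <- dist_matrix[idx_a, idx_a, drop = FALSE]
      d[upper.tri(d)]
    } else {
      as.vector(dist_matrix[idx_a, idx_b, drop = FALSE])
    }
  }
  strata <- list(between_sexes = pair_vals(males, females),
                 within_males = pair_vals(males),
                 within_females = pair_vals(females))
  purrr::imap_dfr(strata, function(v, name) {
    v <- v[!is.na(v)]
    tibble::tibble(stratum = name,
                   mean = if (length(v) >= 1) mean(v) else NA_real_,
                   sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                   n_pairs = length(v))
  })
}

#' Compare heterozygosity across sex-linkage tiers (Kruskal-Wallis)
#'
#' Rank-based Kruskal-Wallis test (with tie correction) of locus
#' heterozygosity across the tier groups of a scan, separately for each
#' sex-determination hypothesis (the XY scan groups male-pattern tiers,
#' the ZW scan female-pattern tiers).
#'
#' @param locus_stats Per-locus scan statistics (from [tidy()] on a scan
#'   or [run_scan()]'s `locus_stats`), containing `system`, `tier` and the
#'   value column.
#' @param value Name of the column tested (default
#'   `"expected_heterozygosity"`).
#' @return Tibble with columns `system`, `H`, `df`, `p`, `n_groups`,
#'   `n_loci`. Groups whose values are all identical give `H = 0`,
#'   `p = 1`.
#' @export
tier_comparison <- function(locus_stats, value = "expected_heterozygosity") {
  stats_by_system <- split(locus_stats, locus_stats$system)
  purrr::imap_dfr(stats_by_system, function(df, system) {
    df <- df[df$tier != "none" & !is.na(df[[value]]), ]
    groups <- unique(df$tier)
    if (length(groups) < 2) {
      return(tibble::tibble(system = system, H = NA_real_, df = NA_integer_,
                            p = NA_real_, n_groups = length(groups),
                            n_loci = nrow(df)))
    }
    vals <- df[[value]]
    if (length(unique(vals)) == 1) {
      return(tibble::tibble(system = system, H = 0, df = length(groups) - 1L,
                            p = 1, n_groups = length(groups), n_loci = nrow(df)))
    }
    kt <- stats::kruskal.test(vals, factor(df$tier))
    tibble::tibble(system = system, H = unname(kt$statistic),
                   df = unname(kt$parameter), p = kt$p.value,
                   n_groups = length(groups), n_loci = nrow(df))
  })
}

#' Probability of a spurious sex-specific pattern
#'
#' With n individuals sequenced at a locus and each individual showing
#' the sex-concordant state with probability 0.5 under the null, the
#' probability that the locus shows a perfect sex-specific pattern by
#' chance is `0.5^n`.
#'
#' @param n Number of individuals sequenced at the locus (`n >= 1`).
#' @return `0.5^n`.
#' @export
spurious_probability <- function(n) {
  stopifnot(length(n) >= 1)
  if (any(n < 1)) stop("n must be at least 1", call. = FALSE)
  0.5^n
}

#' Expected number of spurious sex-specific loci
#'
#' @param L Total number of loci tested.
#' @param n Individuals sequenced per locus.
#' @param two_sided Double the expectation to cover both the male- and
#'   female-specific pattern (default `FALSE`, matching the one-sided
#'   male-pattern convention).
#' @return `L * 0.5^n`, doubled when `two_sided`.
#' @export
expected_spurious <- function(L, n, two_sided = FALSE) {
  stopifnot(L >= 0)
  L * spurious_probability(n) * (if (two_sided) 2 else 1)
}
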