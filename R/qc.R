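# Variant-level quality control: imputation R2, call rate, minor allele
# frequency, and an exact Hardy-Weinberg equilibrium test. Filter order is
# fixed (r2 -> call rate -> maf -> hwe) so failure attribution is
# deterministic; the surviving variant set is order-independent.

#' QC thresholds
#'
#' Bundles the four variant-level cut-offs: minimum imputation R2 (0.3),
#' minimum minor allele frequency (1%), maximum missing genotype call rate
#' (10%), and the Hardy-Weinberg exact-test floor (P < 1e-6 fails).
#'
#' @param r2_min Minimum imputation R2 (variants below are discarded).
#' @param maf_min Minimum minor allele frequency.
#' @param missing_max Maximum fraction of missing genotype calls.
#' @param hwe_p_min Minimum Hardy-Weinberg exact P value.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(r2_min = 0.3, maf_min = 0.01,
                          missing_max = 0.10, hwe_p_min = 1e-6) {
  vals <- c(r2_min = r2_min, maf_min = maf_min,
            missing_max = missing_max, hwe_p_min = hwe_p_min)
  if (any(vals < 0 | vals > 1))
    stop("all QC thresholds must lie in [0, 1]")
  structure(as.list(vals), class = "qc_thresholds")
}

#' Minor allele frequency from a dosage column
#'
#' The ALT-allele frequency is estimated as `mean(dosages) / 2` over
#' non-missing entries; the minor allele frequency is its fold into
#' \[0, 0.5\].
#'
#' @param dosages Numeric vector of dosages in \[0, 2\], NA = missing.
#' @return The minor allele frequency.
#' @export
compute_maf <- function(dosages) {
  dosages <- dosages[!is.na(dosages)]
  if (length(dosages) == 0)
    stop("minor allele frequency is undefined: all dosages missing")
  p <- mean(dosages) / 2
  min(p, 1 - p)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' probability of each admissible heterozygote count (same parity as the
#' minor-allele total) is computed by recurrence, and the P value is the sum
#' of the probabilities of all configurations no more probable than the
#' observed one (probability-mass ordering). `midp = TRUE` gives the mid-P
#' variant, which subtracts half the probability of the observed
#' configuration.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative integer genotype counts.
#' @param midp Use the mid-P correction (default `FALSE`).
#' @return The exact P value, in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt, midp = FALSE) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype is required")
  rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  dist <- hwe_het_distribution(n, rare)
  p_obs <- dist$prob[match(n_het, dist$het)]
  # relative tolerance guards float ties in the mass ordering
  p <- sum(dist$prob[dist$prob <= p_obs * (1 + 1e-7)])
  if (midp) p <- p - 0.5 * p_obs
  min(p, 1)
}

# Conditional distribution of the heterozygote count given n genotypes and
# `rare` copies of the minor allele. Unnormalized weights follow the
# recurrence w(h+2)/w(h) = 4 * hom_rare(h) * hom_common(h) / ((h+1)(h+2)).
hwe_het_distribution <- function(n, rare) {
  h_max <- min(rare, 2 * n - rare)
  h0 <- rare %% 2
  if (h_max < h0) h_max <- h0   # degenerate: only one configuration
  hets <- seq(h0, h_max, by = 2)
  logw <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    hom_rare <- (rare - h) / 2
    hom_common <- (2 * n - rare - h) / 2
    logw[i] <- logw[i - 1] +
      log(4 * hom_rare * hom_common) - log((h + 1) * (h + 2))
  }
  w <- exp(logw - max(logw))
  list(het = hets, prob = w / sum(w))
}

#' Discretize dosages into genotype counts
#'
#' Maps each dosage within `tolerance` of 0, 1 or 2 to that hard call;
#' anything else (including missing) is uncallable and excluded from the
#' counts. Used to feed the HWE exact test with discrete genotypes.
#'
#' @param dosages Numeric dosage vector.
#' @param tolerance Half-width of the calling window, in (0, 0.5).
#' @return A list with integer `counts` `(n_hom_ref, n_het, n_hom_alt)` and
#'   `n_uncallable`.
#' @export
hard_calls_from_dosage <- function(dosages, tolerance = 0.1) {
  if (tolerance <= 0 || tolerance >= 0.5)
    stop("tolerance must lie in (0, 0.5)")
  ok <- !is.na(dosages)
  d <- dosages[ok]
  g <- round(d)
  called <- abs(d - g) <= tolerance
  counts <- c(n_hom_ref = sum(g[called] == 0),
              n_het = sum(g[called] == 1),
              n_hom_alt = sum(g[called] == 2))
  list(counts = counts, n_uncallable = sum(!called) + sum(!ok))
}

#' Apply variant-level QC filters
#'
#' Applies the four filters in the fixed order imputation R2, call rate,
#' minor allele frequency, Hardy-Weinberg; the verdict recorded for a
#' failing variant is the first failing rule. Call rate is computed on raw
#' missingness only; dosages that are merely uncallable as hard calls count
#' towards HWE exclusion but not against the call rate, keeping the two
#' filters independent. A variant without an annotated imputation R2 passes
#' the R2 rule when `assume_genotyped = TRUE` (default), the interpretation
#' being that unannotated variants were directly genotyped.
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()] object.
#' @param assume_genotyped Pass the R2 rule when R2 is missing.
#' @param hwe_samples Optional character vector of sample ids to restrict
#'   the HWE test to (default: all samples).
#' @param hwe_midp Use the mid-P HWE variant.
#' @return A list with `matrix` (the filtered `genotype_matrix`; variant
#'   order preserved) and `report` (a `data.frame`, one row per input
#'   variant: `variant_id`, `maf`, `call_rate`, `hwe_p`, `imputation_r2`,
#'   `verdict`).
#' @export
apply_variant_qc <- function(gm, thresholds = qc_thresholds(),
                             assume_genotyped = TRUE,
                             hwe_samples = NULL, hwe_midp = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$variants) == 0) stop("empty genotype matrix")
  if (!inherits(thresholds, "qc_thresholds"))
    stop("thresholds must be a qc_thresholds object")
  hwe_rows <- if (is.null(hwe_samples)) seq_along(gm$samples) else {
    idx <- match(hwe_samples, gm$samples)
    if (anyNA(idx)) stop("unknown sample id(s) in hwe_samples")
    idx
  }
  nvar <- nrow(gm$variants)
  maf <- call_rate <- hwe_p <- rep(NA_real_, nvar)
  verdict <- rep("pass", nvar)
  for (j in seq_len(nvar)) {
    d <- gm$dosages[, j]
    call_rate[j] <- mean(!is.na(d))
    maf[j] <- if (any(!is.na(d))) compute_maf(d) else NA_real_
    hc <- hard_calls_from_dosage(gm$dosages[hwe_rows, j])
    hwe_p[j] <- if (sum(hc$counts) >= 1)
      hwe_exact_test(hc$counts[1], hc$counts[2], hc$counts[3],
                     midp = hwe_midp) else NA_real_
    r2 <- gm$variants$imputation_r2[j]
    r2_ok <- if (is.na(r2)) assume_genotyped else r2 >= thresholds$r2_min
    verdict[j] <- if (!r2_ok) "fail_r2"
      else if (1 - call_rate[j] > thresholds$missing_max) "fail_callrate"
      else if (is.na(maf[j]) || maf[j] < thresholds$maf_min) "fail_maf"
      else if (!is.na(hwe_p[j]) && hwe_p[j] < thresholds$hwe_p_min) "fail_hwe"
      else "pass"
  }
  report <- data.frame(variant_id = gm$variants$variant_id, maf = maf,
                       call_rate = call_rate, hwe_p = hwe_p,
                       imputation_r2 = gm$variants$imputation_r2,
                       verdict = verdict, stringsAsFactors = FALSE)
  keep <- verdict == "pass"
  if (!any(keep)) stop("all variants removed by QC")
  list(matrix = subset_variants(gm, which(keep)), report = report)
}

#' Summarize a QC report
#'
#' @param report The `report` component of [apply_variant_qc()].
#' @return Named integer vector of counts per verdict class.
#' @export
qc_verdict_counts <- function(report) {
  lev <- c("pass", "fail_r2", "fail_callrate", "fail_maf", "fail_hwe")
  table(factor(report$verdict, levels = lev))
}
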