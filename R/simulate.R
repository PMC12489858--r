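# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: ~50 independent biallelic score SNPs in Hardy-Weinberg
# proportions with per-pathway effect-size scales matched to the published
# score dispersions, an elderly European cohort age/sex structure, AMD
# stages whose mean global PRS rises from controls to late AMD, and
# structural biomarkers whose odds depend on planted pathway scores. Decoy
# SNPs are injected to exercise every QC failure class.

#' Simulation configuration
#'
#' Defaults encode the study conditions of the cohort being emulated:
#' 556 participants (46 controls, 33 early, 404 intermediate, 73 late AMD),
#' age 71.6 +- 6.94 years truncated to \[55, 86\] with older mean age at
#' later stages, 34.9% male, ~50 score SNPs (complement 8, ECM 9, lipid 6,
#' ARMS2/HTRA1 2, untagged 25), per-pathway score standard deviations
#' matching the published intermediate-AMD dispersions, stage shifts of the
#' global PRS equal to the published adjusted stage estimates (early
#' +0.175, intermediate +0.405, late +0.481 versus controls), biomarker
#' prevalences RPD 23.8%, PA 47.8%, HRF 46.8%, iRORA 8.7%, cRORA 7.2%, and
#' planted logistic effects of the ARMS2/HTRA1 and ECM scores on RPD and of
#' the ARMS2/HTRA1 score on cRORA.
#'
#' @param n_samples Cohort size.
#' @param snps_per_pathway Named integer vector: SNP count per pathway tag
#'   plus `untagged`.
#' @param allele_freq_range Range the ALT-allele frequencies are drawn from.
#' @param score_sd Named vector of target per-pathway score standard
#'   deviations (per-SNP effect sizes are scaled so each pathway score has
#'   this SD in expectation).
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param stage_age_shift Named vector: mean age shift per stage (years,
#'   relative to the overall mean) planted via the stage assignment.
#' @param p_male Probability of male sex.
#' @param stage_props Named vector of stage proportions (sums to 1).
#' @param stage_shift Named vector: planted mean shift of the global PRS in
#'   each stage relative to the cohort mean of the "none" group.
#' @param biomarker_prevalence Named vector of target marginal prevalences
#'   within the intermediate-AMD group.
#' @param biomarker_effects Named list (by biomarker) of named vectors of
#'   logistic coefficients on centered true pathway scores.
#' @param decoy_counts Named integer vector: number of decoy SNPs per QC
#'   failure class (`low_r2`, `high_missing`, `hwe`, `rare`).
#' @param dosage_noise_sd SD of the imputation-style jitter added to hard
#'   genotypes (kept below the hard-call tolerance).
#' @param missing_rate Per-cell missingness of clean SNPs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 556,
                       snps_per_pathway = c(complement = 8L, ecm = 9L,
                                            lipid = 6L, arms2_htra1 = 2L,
                                            untagged = 25L),
                       allele_freq_range = c(0.05, 0.5),
                       score_sd = c(complement = 0.183, ecm = 0.126,
                                    lipid = 0.110, arms2_htra1 = 0.226,
                                    untagged = 0.261),
                       age_mean = 71.6, age_sd = 6.94,
                       age_range = c(55, 86),
                       stage_age_shift = c(none = -3.7, early = -0.2,
                                           intermediate = -0.1, late = 3.1),
                       p_male = 0.349,
                       stage_props = c(none = 46, early = 33,
                                       intermediate = 404, late = 73) / 556,
                       stage_shift = c(none = 0, early = 0.175,
                                       intermediate = 0.405, late = 0.481),
                       biomarker_prevalence = c(rpd = 0.238, pa = 0.478,
                                                hrf = 0.468, irora = 0.087,
                                                crora = 0.072),
                       biomarker_effects = list(
                         rpd = c(arms2_htra1 = 1.39, ecm = 2.06),
                         crora = c(arms2_htra1 = 2.62)),
                       decoy_counts = c(low_r2 = 2L, high_missing = 2L,
                                        hwe = 2L, rare = 2L),
                       dosage_noise_sd = 0.02,
                       missing_rate = 0.005) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (any(snps_per_pathway < 0) || sum(snps_per_pathway) < 1)
    stop("snps_per_pathway must be non-negative with at least one SNP")
  if (any(allele_freq_range <= 0) || any(allele_freq_range > 0.5))
    stop("allele frequencies must lie in (0, 0.5]")
  if (abs(sum(stage_props) - 1) > 1e-8)
    stop("stage_props must sum to 1")
  if (any(stage_props < 0) || any(p_male < 0 | p_male > 1) ||
      any(biomarker_prevalence < 0 | biomarker_prevalence > 1) ||
      any(missing_rate < 0 | missing_rate > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(decoy_counts < 0)) stop("decoy_counts must be non-negative")
  structure(list(n_samples = as.integer(n_samples),
                 snps_per_pathway = snps_per_pathway,
                 allele_freq_range = allele_freq_range,
                 score_sd = score_sd, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, stage_age_shift = stage_age_shift,
                 p_male = p_male, stage_props = stage_props,
                 stage_shift = stage_shift,
                 biomarker_prevalence = biomarker_prevalence,
                 biomarker_effects = biomarker_effects,
                 decoy_counts = decoy_counts,
                 dosage_noise_sd = dosage_noise_sd,
                 missing_rate = missing_rate),
            class = "sim_config")
}

# Allele pairs that are never strand-ambiguous (no A/T or C/G).
safe_allele_pairs <- function() {
  list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
       c("C", "A"), c("G", "A"), c("T", "C"), c("T", "G"))
}

#' Simulate a genotype matrix, scoring table and ground truth
#'
#' Draws independent biallelic SNPs (no LD) with genotypes ~
#' Binomial(2, p), i.e. in Hardy-Weinberg proportions, plus decoy SNPs
#' planted to fail each QC rule: `low_r2` (imputation R2 = 0.2),
#' `high_missing` (>10% missing cells, enforced exactly), `hwe`
#' (heterozygote deficit via an inbreeding-style distortion, F = 0.9) and
#' `rare` (ALT frequency 0.002). Per-SNP effect sizes are scaled so each
#' pathway score has its configured standard deviation; gene labels cycle
#' through the pathway registry so the scoring table is resolvable. About
#' 30% of the weight-table rows report the REF allele as effect allele, so
#' the alignment flip path is exercised. Everything is reproducible from
#' `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the single source of randomness.
#' @return A list: `matrix` (a [genotype_matrix()]), `weights` (a weight
#'   table), `truth` (per-variant true frequency/beta/decoy class and
#'   per-sample true pathway scores on the effect-allele scale).
#' @export
simulate_genotypes <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_samples
  spp <- config$snps_per_pathway
  k_clean <- sum(spp)
  reg <- pathway_registry()
  pathway <- rep(names(spp), spp)
  gene <- character(k_clean)
  for (pw in names(spp)) {
    idx <- which(pathway == pw)
    gene[idx] <- if (pw == "untagged")
      sprintf("LOC%04d", seq_along(idx)) else
      rep_len(reg[[pw]], length(idx))
  }
  pathway[pathway == "untagged"] <- ""
  dec <- config$decoy_counts
  k_dec <- sum(dec)
  decoy <- rep(c("", names(dec)), c(k_clean, dec))
  pathway <- c(pathway, rep("", k_dec))
  gene <- c(gene, sprintf("DECOY%02d", seq_len(k_dec)))
  k <- k_clean + k_dec

  freq <- runif(k, config$allele_freq_range[1], config$allele_freq_range[2])
  freq[decoy == "rare"] <- 0.002
  freq[decoy == "hwe"] <- 0.5
  # per-SNP |beta| chosen so each SNP contributes score_sd^2 / k_pathway
  # to its pathway's variance: beta^2 * 2p(1-p) = (sd / sqrt(k))^2;
  # decoys reuse the untagged scale (they never survive QC)
  pw_all <- c(rep(names(spp), spp), rep("untagged", k_dec))
  per_snp_sd <- unname(config$score_sd[pw_all] /
                         sqrt(pmax(config$snps_per_pathway[pw_all], 1)))
  beta <- sample(c(-1, 1), k, replace = TRUE) *
    per_snp_sd / sqrt(2 * freq * (1 - freq))

  pairs <- safe_allele_pairs()
  al <- pairs[sample.int(length(pairs), k, replace = TRUE)]
  ref <- vapply(al, `[`, "", 1)
  alt <- vapply(al, `[`, "", 2)
  vid <- sprintf("rs%07d", sample.int(9999999, k))
  effect_is_ref <- runif(k) < 0.3

  # genotypes: HWE binomial draws; the hwe decoys get a het deficit
  geno <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    if (decoy[j] == "hwe") {
      p <- freq[j]; f <- 0.9
      probs <- c(p^2 + f * p * (1 - p), 2 * p * (1 - p) * (1 - f),
                 (1 - p)^2 + f * p * (1 - p))
      geno[, j] <- sample(c(2L, 1L, 0L), n, replace = TRUE, prob = probs)
    } else {
      geno[, j] <- rbinom(n, 2, freq[j])
    }
  }

  # true pathway scores on the effect-allele scale, from clean genotypes
  eff_dose <- geno[, seq_len(k_clean), drop = FALSE]
  flip <- effect_is_ref[seq_len(k_clean)]
  eff_dose[, flip] <- 2L - eff_dose[, flip, drop = FALSE]
  samples <- sprintf("S%05d", seq_len(n))
  true_scores <- data.frame(sample_id = samples)
  pw_of_clean <- rep(names(spp), spp)
  for (pw in names(spp)) {
    idx <- which(pw_of_clean == pw)
    true_scores[[pw]] <- as.vector(
      eff_dose[, idx, drop = FALSE] %*% beta[idx])
  }
  true_scores$global <- rowSums(true_scores[, names(spp), drop = FALSE])

  # observed dosages: jitter + missingness
  dos <- geno + matrix(rnorm(n * k, 0, config$dosage_noise_sd), n, k)
  dos <- pmin(pmax(dos, 0), 2)
  miss <- matrix(runif(n * k) < config$missing_rate, n, k)
  for (j in which(decoy == "high_missing")) {
    n_miss <- ceiling(0.15 * n)
    miss[sample.int(n, n_miss), j] <- TRUE
  }
  dos[miss] <- NA_real_

  r2 <- runif(k, 0.85, 1)
  r2[runif(k) < 0.1] <- NA   # directly genotyped, no imputation R2
  r2[decoy == "low_r2"] <- 0.2

  ord <- sample.int(k)   # shuffle variant order
  variants <- data.frame(variant_id = vid, chrom = "1",
                         pos = sort(sample.int(2e8, k)),
                         ref_allele = ref, alt_allele = alt,
                         imputation_r2 = r2)[ord, ]
  gm <- genotype_matrix(dos[, ord, drop = FALSE], variants, samples)
  wt <- data.frame(variant_id = vid,
                   effect_allele = ifelse(effect_is_ref, ref, alt),
                   other_allele = ifelse(effect_is_ref, alt, ref),
                   beta = beta, gene_label = gene, pathway = pathway,
                   stringsAsFactors = FALSE)[ord, ]
  rownames(wt) <- NULL
  class(wt) <- c("weight_table", "data.frame")
  truth <- list(variants = data.frame(variant_id = vid, freq = freq,
                                      beta = beta, pathway = pathway,
                                      gene_label = gene, decoy = decoy,
                                      stringsAsFactors = FALSE)[ord, ],
                true_scores = true_scores, seed = seed)
  rownames(truth$variants) <- NULL
  list(matrix = gm, weights = wt, truth = truth)
}

# Stage assignment by a moment-calibrated multinomial logit on the true
# global PRS and on age: per-sample stage probabilities are
# softmax(log pi_s + a_s + t_s * (G - mean) + u_s * (age - mean)), with
# the age slopes fixed from the configured per-stage age shifts and the
# (a_s, t_s) of the non-reference stages solved numerically so that, for
# the realized sample, the expected stage proportions equal the targets
# and the expected conditional mean of G in stage s minus that of the
# reference stage equals the planted shift exactly.
assign_stages <- function(G, age, config) {
  stages <- names(config$stage_props)
  n <- length(G)
  if (length(stages) == 1)
    return(factor(rep(stages, n), levels = STAGE_LEVELS))
  Gc <- G - mean(G)
  Ac <- age - mean(age)
  u <- config$stage_age_shift[stages] / var(age)
  base <- log(config$stage_props[stages])
  vG <- var(G)
  k <- length(stages) - 1   # free stages (reference = first)
  probs_for <- function(par) {
    a <- c(0, par[seq_len(k)])
    t_s <- c(0, par[k + seq_len(k)])
    eta <- outer(Gc, t_s) + outer(Ac, u) +
      matrix(base + a, n, k + 1, byrow = TRUE)
    w <- exp(eta - apply(eta, 1, max))
    w / rowSums(w)
  }
  target_shift <- config$stage_shift[stages] -
    config$stage_shift[[stages[1]]]
  objective <- function(par) {
    P <- probs_for(par)
    prev <- colMeans(P)
    cm <- colSums(P * G) / colSums(P)
    sum((prev - config$stage_props[stages])^2) +
      sum(((cm - cm[1]) - target_shift)^2)
  }
  init <- c(config$stage_shift[stages[-1]]^2 / (2 * vG) * 0,
            config$stage_shift[stages[-1]] / vG)
  fit <- stats::optim(init, objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (fit$value > 1e-6)
    warning("stage-assignment calibration did not fully converge ",
            "(residual ", signif(fit$value, 3), ")")
  P <- probs_for(fit$par)
  idx <- apply(P, 1, function(p) sample.int(length(p), 1, prob = p))
  factor(stages[idx], levels = STAGE_LEVELS)
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# solve mean(plogis(b0 + eta)) = target for the intercept b0
calibrate_intercept <- function(eta, target) {
  f <- function(b0) mean(plogis(b0 + eta)) - target
  lo <- f(-25); hi <- f(25)
  if (lo > 0 || hi < 0)
    stop(sprintf(paste0("prevalence target %.3f unreachable; achievable ",
                        "range [%.4f, %.4f]"), target, lo + target,
                 hi + target))
  uniroot(f, c(-25, 25), tol = 1e-10)$root
}

#' Simulate phenotypes on top of a simulated genotype matrix
#'
#' Draws age from a truncated normal, sex as Bernoulli, assigns AMD stage
#' by exponential tilting of the stage proportions on the true global PRS
#' and on age — which plants the configured per-stage mean PRS shift and
#' age shift exactly (for Gaussian-like scores) while keeping the marginal
#' stage proportions — and then draws the five structural biomarkers for
#' intermediate-stage samples only, from logistic models on the centered
#' true pathway scores with intercepts calibrated numerically so the
#' marginal prevalences hit their targets. iRORA is drawn only among
#' cRORA-free samples (with a compensated rate so its marginal prevalence
#' still matches), which enforces the combined-model coding: a sample is
#' never in both atrophy groups.
#'
#' @param gm The simulated [genotype_matrix()].
#' @param weights The matching weight table.
#' @param config The [sim_config()] used for the genotypes.
#' @param seed Integer seed.
#' @param truth Truth record from [simulate_genotypes()]; if `NULL` the
#'   true pathway scores are recomputed from `gm` and `weights` (decoy
#'   variants included, missing dosages mean-imputed).
#' @return A list: `cohort` (a cohort table) and `truth` (input truth
#'   extended with planted stage shifts, biomarker coefficients, and the
#'   calibrated intercepts).
#' @export
simulate_phenotypes <- function(gm, weights, config = sim_config(),
                                seed = 1L, truth = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(seed + 1000003L)
  n <- length(gm$samples)
  if (is.null(truth)) {
    aligned <- impute_missing_dosage(align_effect_alleles(weights, gm))
    sm <- compute_all_scores(aligned)
    ts <- data.frame(sample_id = sm$sample_id,
                     complement = sm$c_prs, ecm = sm$e_prs,
                     lipid = sm$l_prs, arms2_htra1 = sm$ah_prs,
                     global = sm$global_prs)
  } else ts <- truth$true_scores

  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  sex <- factor(ifelse(runif(n) < config$p_male, "male", "female"),
                levels = c("female", "male"))

  stage <- assign_stages(ts$global, age, config)

  cohort <- data.frame(sample_id = gm$samples, age = age, sex = sex,
                       stage = stage, rpd = NA, pa = NA, hrf = NA,
                       irora = NA, crora = NA, stringsAsFactors = FALSE)
  int <- which(stage == "intermediate")
  intercepts <- c()
  if (length(int) > 0) {
    eta_for <- function(b) {
      eff <- config$biomarker_effects[[b]]
      eta <- numeric(length(int))
      for (pw in names(eff)) {
        s <- ts[[pw]][int]
        eta <- eta + eff[[pw]] * (s - mean(s))
      }
      eta
    }
    for (b in c("rpd", "pa", "hrf", "crora")) {
      eta <- eta_for(b)
      b0 <- calibrate_intercept(eta, config$biomarker_prevalence[[b]])
      intercepts[b] <- b0
      cohort[[b]][int] <- runif(length(int)) < plogis(b0 + eta)
    }
    # iRORA among cRORA-free samples, compensated for the masking
    q_c <- config$biomarker_prevalence[["crora"]]
    target_i <- config$biomarker_prevalence[["irora"]] / (1 - q_c)
    free <- int[!cohort$crora[int]]
    eta <- {
      eff <- config$biomarker_effects[["irora"]]
      e <- numeric(length(free))
      for (pw in names(eff)) {
        s <- ts[[pw]][free]
        e <- e + eff[[pw]] * (s - mean(s))
      }
      e
    }
    b0 <- calibrate_intercept(eta, target_i)
    intercepts["irora"] <- b0
    cohort$irora[int] <- FALSE
    cohort$irora[free] <- runif(length(free)) < plogis(b0 + eta)
  }
  class(cohort) <- c("cohort_table", "data.frame")
  truth <- c(truth, list(stage_shift = config$stage_shift,
                         biomarker_effects = config$biomarker_effects,
                         biomarker_intercepts = intercepts))
  list(cohort = cohort, truth = truth)
}

#' Write a simulated fixture to disk
#'
#' Emits `fixture.vcf` (with per-sample GT and DS fields and the
#' imputation R2 in INFO), `weights.tsv`, `phenotypes.csv` and, when a
#' truth record is supplied, `truth.json`, all readable back through the
#' package's readers.
#'
#' @param gm A [genotype_matrix()].
#' @param weights A weight table.
#' @param cohort A cohort table (same samples as `gm`).
#' @param out_dir Output directory (created if needed).
#' @param truth Optional truth record.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(gm, weights, cohort, out_dir, truth = NULL) {
  if (!setequal(gm$samples, cohort$sample_id) ||
      !all(gm$samples == cohort$sample_id))
    stop("sample ids of genotype matrix and cohort do not match")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(out_dir, "fixture.vcf")
  write_vcf(gm, vcf_path)
  wt_path <- file.path(out_dir, "weights.tsv")
  write_scoring_file(weights, wt_path)
  ph_path <- file.path(out_dir, "phenotypes.csv")
  write_phenotypes(cohort, ph_path)
  paths <- c(vcf = vcf_path, weights = wt_path, phenotypes = ph_path)
  if (!is.null(truth)) {
    tr_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, tr_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    paths <- c(paths, truth = tr_path)
  }
  invisible(paths)
}

# minimal single-chromosome VCF emitter (GT + DS, INFO R2)
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation R2\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  v <- gm$variants
  ord <- order(v$chrom, v$pos)
  for (j in ord) {
    d <- gm$dosages[, j]
    hard <- round(d)
    callable <- !is.na(d) & abs(d - hard) <= 0.1
    gt <- ifelse(is.na(d), "./.",
                 ifelse(callable, c("0/0", "0/1", "1/1")[hard + 1], "./."))
    ds <- ifelse(is.na(d), ".", formatC(d, digits = 6, format = "g"))
    info <- if (is.na(v$imputation_r2[j])) "." else
      paste0("R2=", formatC(v$imputation_r2[j], digits = 6, format = "g"))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j],
                       v$ref_allele[j], v$alt_allele[j], ".", "PASS",
                       info, "GT:DS", paste(gt, ds, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}
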