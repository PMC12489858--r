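# Shared fixtures and independent oracles for the test suite.
# All expected values asserted in the tests are either computed by these
# oracles or derived by hand from the stated formulas.

# --- tiny in-memory fixtures -------------------------------------------

# 3 samples x 4 variants, one per pathway flavour, effect allele == ALT
toy_matrix <- function() {
  dos <- matrix(c(0, 1, 2,
                  2, 1, 0,
                  1, 1, 1,
                  0, 0, 2), nrow = 3)
  genotype_matrix(
    dos,
    data.frame(variant_id = c("v1", "v2", "v3", "v4"),
               chrom = "1", pos = c(100L, 200L, 300L, 400L),
               ref_allele = c("G", "C", "A", "T"),
               alt_allele = c("A", "T", "G", "C"),
               imputation_r2 = c(0.99, 0.95, NA, 0.90)),
    c("S1", "S2", "S3"))
}

toy_weights <- function() {
  wt <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "T", "G", "C"),
                   other_allele = c("G", "C", "A", "T"),
                   beta = c(0.4, -0.2, 0.1, 0.3),
                   gene_label = c("CFH", "ARMS2/HTRA1", "MMP9", "LIPC"),
                   pathway = c("complement", "arms2_htra1", "ecm", "lipid"),
                   stringsAsFactors = FALSE)
  class(wt) <- c("weight_table", "data.frame")
  wt
}

toy_cohort <- function(n = 200, seed = 99) {
  set.seed(seed)
  stage <- factor(sample(c("none", "early", "intermediate", "late"), n,
                         replace = TRUE, prob = c(0.2, 0.1, 0.5, 0.2)),
                  levels = c("none", "early", "intermediate", "late"))
  d <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                  age = round(runif(n, 56, 85), 1),
                  sex = factor(sample(c("female", "male"), n, TRUE),
                               levels = c("female", "male")),
                  stage = stage, stringsAsFactors = FALSE)
  for (b in c("rpd", "pa", "hrf", "irora", "crora")) d[[b]] <- NA
  int <- d$stage == "intermediate"
  d$rpd[int] <- runif(sum(int)) < 0.25
  d$pa[int] <- runif(sum(int)) < 0.48
  d$hrf[int] <- runif(sum(int)) < 0.47
  d$crora[int] <- runif(sum(int)) < 0.1
  d$irora[int] <- !d$crora[int] & runif(sum(int)) < 0.1
  class(d) <- c("cohort_table", "data.frame")
  d
}

random_scores <- function(cohort, seed = 7) {
  set.seed(seed)
  s <- data.frame(sample_id = cohort$sample_id)
  for (nm in score_names()) s[[nm]] <- rnorm(nrow(cohort), 0, 0.3)
  class(s) <- c("score_matrix", "data.frame")
  s
}

# intermediate-only simulation (biomarker-model study conditions)
intermediate_config <- function(n) {
  sim_config(n_samples = n, stage_props = c(intermediate = 1),
             stage_shift = c(intermediate = 0),
             stage_age_shift = c(intermediate = 0))
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small hand-written VCF used by the reader tests
toy_vcf <- function(extra_records = character(), format = "GT:DS") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation R2\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "A", "B", "C"), collapse = "\t"))
  write_lines_tmp(c(header, extra_records), ".vcf")
}

# --- independent oracles ----------------------------------------------

# closed-form enumeration oracle for the HWE exact test: probabilities of
# every admissible heterozygote count from the log-factorial formula
# P(h | n, r) = n! / (hom_r! h! hom_c!) * 2^h * r! (2n-r)! / (2n)!
oracle_hwe_dist <- function(n, rare) {
  h_max <- min(rare, 2 * n - rare)
  hets <- seq(rare %% 2, max(h_max, rare %% 2), by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, 0)
  list(het = hets, prob = exp(logp))
}

oracle_hwe <- function(a, b, c) {
  n <- a + b + c
  rare <- min(2 * a + b, 2 * c + b)
  dist <- oracle_hwe_dist(n, rare)
  p_obs <- dist$prob[match(b, dist$het)]
  min(sum(dist$prob[dist$prob <= p_obs * (1 + 1e-7)]), 1)
}

# normal-equations OLS oracle (explicit inversion; small instances only)
oracle_ols <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(sigma2 * xtx_inv))
  list(beta = as.vector(beta), se = se,
       p = 2 * pt(-abs(as.vector(beta) / se), df))
}
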