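# The synthetic cohort generator: determinism, HWE sampling, decoy
# construction, phenotype planting, and fixture round trips.

test_that("identical seeds give bit-identical cohorts", {
  cfg <- sim_config(n_samples = 50)
  a <- simulate_genotypes(cfg, seed = 123)
  b <- simulate_genotypes(cfg, seed = 123)
  expect_identical(a$matrix$dosages, b$matrix$dosages)
  expect_identical(a$weights, b$weights)
  pa <- simulate_phenotypes(a$matrix, a$weights, cfg, seed = 123,
                            truth = a$truth)
  pb <- simulate_phenotypes(b$matrix, b$weights, cfg, seed = 123,
                            truth = b$truth)
  expect_identical(pa$cohort, pb$cohort)
  c <- simulate_genotypes(cfg, seed = 124)
  expect_false(identical(a$matrix$dosages, c$matrix$dosages))
})

test_that("genotypes are drawn in Hardy-Weinberg proportions", {
  cfg <- sim_config(n_samples = 50000,
                    snps_per_pathway = c(complement = 0, ecm = 0,
                                         lipid = 0, arms2_htra1 = 0,
                                         untagged = 1),
                    allele_freq_range = c(0.3, 0.3),
                    decoy_counts = c(low_r2 = 0, high_missing = 0,
                                     hwe = 0, rare = 0),
                    dosage_noise_sd = 1e-9, missing_rate = 0)
  sim <- simulate_genotypes(cfg, seed = 5)
  g <- round(as.vector(sim$matrix$dosages))
  n <- length(g)
  expected <- c(0.49, 0.42, 0.09)  # (1-p)^2, 2p(1-p), p^2 at p = 0.3
  for (k in 0:2) {
    obs <- mean(g == k)
    se <- sqrt(expected[k + 1] * (1 - expected[k + 1]) / n)
    expect_lt(abs(obs - expected[k + 1]), 3 * se)
  }
})

test_that("every decoy fails QC with its labelled verdict; clean SNPs pass", {
  cfg <- sim_config(n_samples = 2000)
  sim <- simulate_genotypes(cfg, seed = 17)
  qc <- apply_variant_qc(sim$matrix)
  rep <- merge(qc$report, sim$truth$variants[, c("variant_id", "decoy")])
  expected <- c(low_r2 = "fail_r2", high_missing = "fail_callrate",
                rare = "fail_maf", hwe = "fail_hwe")
  for (cls in names(expected)) {
    got <- rep$verdict[rep$decoy == cls]
    expect_true(all(got == expected[[cls]]),
                label = paste("decoy class", cls))
  }
  clean <- rep$verdict[rep$decoy == ""]
  expect_gte(mean(clean == "pass"), 0.99)
})

test_that("phenotypes respect ranges, coding and planted orderings", {
  cfg <- intermediate_config(5000)
  sim <- simulate_genotypes(cfg, seed = 29)
  ph <- simulate_phenotypes(sim$matrix, sim$weights, cfg, seed = 29,
                            truth = sim$truth)
  co <- ph$cohort
  expect_true(all(co$age >= 55 & co$age <= 86))
  expect_true(all(co$stage == "intermediate"))
  # combined atrophy coding: never both groups
  expect_false(any(co$irora & co$crora, na.rm = TRUE))
  # loose prevalence check (tight calibration is asserted at n = 20,000)
  expect_lt(abs(mean(co$rpd) - 0.238), 0.03)
  expect_lt(abs(mean(co$crora) - 0.072), 0.02)
  # planted positive AH effect: carriers have higher mean AH score
  ah <- sim$truth$true_scores$arms2_htra1
  expect_gt(mean(ah[co$crora]), mean(ah[!co$crora]))
  expect_gt(mean(ah[co$rpd]), mean(ah[!co$rpd]))
})

test_that("the stage model recovers the planted intermediate-AMD shift", {
  cfg <- sim_config(n_samples = 4000)
  ests <- vapply(1:10, function(s) {
    sim <- simulate_genotypes(cfg, seed = 900 + s)
    ph <- simulate_phenotypes(sim$matrix, sim$weights, cfg, seed = 900 + s,
                              truth = sim$truth)
    qc <- apply_variant_qc(sim$matrix)
    sc <- compute_all_scores(impute_missing_dosage(
      align_effect_alleles(sim$weights, qc$matrix)))
    fit <- fit_stage_model(ph$cohort, sc)
    fit$estimate[fit$term == "stageintermediate"]
  }, 0)
  planted <- sim_config()$stage_shift[["intermediate"]]  # 0.405
  expect_lt(abs(mean(ests) - planted),
            4 * sd(ests) / sqrt(length(ests)) + 0.015)
})

test_that("null stage shifts give stage estimates centred at zero", {
  cfg <- sim_config(n_samples = 600,
                    stage_shift = c(none = 0, early = 0, intermediate = 0,
                                    late = 0),
                    stage_age_shift = c(none = 0, early = 0,
                                        intermediate = 0, late = 0))
  ests <- replicate(25, {
    s <- sample.int(1e6, 1)
    sim <- simulate_genotypes(cfg, seed = s)
    ph <- simulate_phenotypes(sim$matrix, sim$weights, cfg, seed = s,
                              truth = sim$truth)
    qc <- apply_variant_qc(sim$matrix)
    sc <- compute_all_scores(impute_missing_dosage(
      align_effect_alleles(sim$weights, qc$matrix)))
    fit <- fit_stage_model(ph$cohort, sc)
    fit$estimate[fit$term == "stageintermediate"]
  })
  expect_lt(abs(mean(ests)), 4 * sd(ests) / sqrt(length(ests)))
})

test_that("fixtures round-trip through the pipeline readers", {
  cfg <- sim_config(n_samples = 30,
                    snps_per_pathway = c(complement = 2, ecm = 3,
                                         lipid = 2, arms2_htra1 = 2,
                                         untagged = 1),
                    decoy_counts = c(low_r2 = 1, high_missing = 0,
                                     hwe = 0, rare = 0),
                    missing_rate = 0)
  sim <- simulate_genotypes(cfg, seed = 8)
  ph <- simulate_phenotypes(sim$matrix, sim$weights, cfg, seed = 8,
                            truth = sim$truth)
  dir <- tempfile("fixture")
  paths <- write_fixture(sim$matrix, sim$weights, ph$cohort, dir,
                         truth = sim$truth)
  expect_true(all(file.exists(paths)))

  gm <- read_genotypes(paths["vcf"])
  wt <- read_scoring_file(paths["weights"])
  co <- read_phenotypes(paths["phenotypes"])
  expect_setequal(gm$variants$variant_id, sim$matrix$variants$variant_id)
  expect_equal(co$age, ph$cohort$age, tolerance = 1e-6)

  # scores computed from the re-read files equal the in-memory scores
  sc_disk <- compute_all_scores(impute_missing_dosage(
    align_effect_alleles(wt, gm)))
  sc_mem <- compute_all_scores(impute_missing_dosage(
    align_effect_alleles(sim$weights, sim$matrix)))
  sc_disk <- sc_disk[match(sc_mem$sample_id, sc_disk$sample_id), ]
  for (nm in score_names())
    expect_equal(sc_disk[[nm]], sc_mem[[nm]], tolerance = 1e-5)

  # inconsistent ids are rejected
  bad <- ph$cohort; bad$sample_id[1] <- "NOPE"
  expect_error(write_fixture(sim$matrix, sim$weights, bad, dir), "match")
})

test_that("degenerate simulated cohorts surface model errors", {
  cfg <- sim_config(n_samples = 40, p_male = 0)
  sim <- simulate_genotypes(cfg, seed = 3)
  ph <- simulate_phenotypes(sim$matrix, sim$weights, cfg, seed = 3,
                            truth = sim$truth)
  sc <- compute_all_scores(impute_missing_dosage(
    align_effect_alleles(sim$weights, sim$matrix)))
  expect_error(fit_stage_model(ph$cohort, sc), "collinear|reference")
})
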