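# The least-squares core, the model builders, and the EMM stage contrasts.

test_that("fit_ols reproduces closed-form simple regression on 6 points", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 12.2)
  fit <- fit_ols(y, cbind(`(Intercept)` = 1, x = x))
  # hand formulas: slope = Sxy / Sxx, intercept = ybar - slope * xbar
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(fit$estimate[2], sxy / sxx, tolerance = 1e-14)
  expect_equal(fit$estimate[1], mean(y) - sxy / sxx * mean(x),
               tolerance = 1e-12)
  res <- y - fit$estimate[1] - fit$estimate[2] * x
  expect_equal(attr(fit, "sigma2"), sum(res^2) / 4, tolerance = 1e-14)
  expect_equal(fit$se[2], sqrt(attr(fit, "sigma2") / sxx),
               tolerance = 1e-14)
  expect_equal(fit$ci_high - fit$estimate, qt(0.975, 4) * fit$se,
               tolerance = 1e-14)
})

test_that("fit_ols handles perfect fits and is permutation invariant", {
  set.seed(3)
  X <- cbind(1, rnorm(20), rnorm(20))
  colnames(X) <- c("(Intercept)", "a", "b")
  y <- X[, "a"]
  fit <- fit_ols(y, X)
  expect_equal(fit$estimate, c(0, 1, 0), tolerance = 1e-10)
  expect_equal(sum((y - as.vector(X %*% fit$estimate))^2), 0,
               tolerance = 1e-20)

  y2 <- X %*% c(1, 0.5, -0.3) + rnorm(20)
  perm <- sample(20)
  f1 <- fit_ols(y2, X)
  f2 <- fit_ols(y2[perm], X[perm, ])
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-12)
  expect_equal(f1$se, f2$se, tolerance = 1e-12)
})

test_that("fit_ols agrees with lm and rejects degenerate designs", {
  set.seed(13)
  d <- data.frame(y = rnorm(50), x1 = rnorm(50),
                  x2 = factor(sample(letters[1:3], 50, TRUE)))
  X <- model.matrix(~ x1 + x2, d)
  fit <- fit_ols(d$y, X)
  lfit <- summary(lm(y ~ x1 + x2, d))
  expect_equal(fit$estimate, unname(lfit$coefficients[, 1]),
               tolerance = 1e-12)
  expect_equal(fit$se, unname(lfit$coefficients[, 2]), tolerance = 1e-12)
  expect_equal(fit$p, unname(lfit$coefficients[, 4]), tolerance = 1e-12)
  expect_equal(attr(fit, "r2"), lfit$r.squared, tolerance = 1e-12)

  Xbad <- cbind(X, dup = X[, "x1"])
  expect_error(fit_ols(d$y, Xbad), "collinear")
  expect_error(fit_ols(rnorm(3), X[1:3, ]), "more observations")
})

test_that("stage model uses fixed references and reparameterizes exactly", {
  cohort <- toy_cohort()
  scores <- random_scores(cohort)
  fit <- fit_stage_model(cohort, scores)
  expect_setequal(fit$term, c("(Intercept)", "stageearly",
                              "stageintermediate", "stagelate", "age",
                              "sexmale"))
  # negating age negates its coefficient exactly, others untouched
  cohort2 <- cohort; cohort2$age <- -cohort2$age
  fit2 <- fit_stage_model(cohort2, scores)
  expect_equal(fit2$estimate[fit2$term == "age"],
               -fit$estimate[fit$term == "age"], tolerance = 1e-12)
  expect_equal(fit2$estimate[fit2$term == "stagelate"],
               fit$estimate[fit$term == "stagelate"], tolerance = 1e-12)

  no_ref <- cohort[cohort$stage != "none", ]
  expect_error(fit_stage_model(no_ref, scores), "reference")
})

test_that("biomarker models fit 6 scores x 4 models, skipping constants", {
  cohort <- toy_cohort(400)
  scores <- random_scores(cohort)
  fits <- fit_biomarker_models(cohort, scores)
  expect_length(fits, 24)
  # model 4 carries both atrophy dummies in one fit
  expect_true(all(c("irora", "crora") %in%
                    fits[["4_atrophy.global_prs"]]$term))
  expect_equal(attr(fits[["1_rpd.ah_prs"]], "n"),
               sum(cohort$stage == "intermediate"))

  cohort$pa[cohort$stage == "intermediate"] <- TRUE  # constant column
  expect_warning(fit_biomarker_models(cohort, scores,
                                      score_set = "global_prs"),
                 "constant")
  fits2 <- suppressWarnings(fit_biomarker_models(cohort, scores))
  expect_length(fits2, 18)  # the other models still run
})

test_that("extended models add atrophy terms and fail on constant ones", {
  cohort <- toy_cohort(400)
  scores <- random_scores(cohort)
  fa <- fit_extended_models(cohort, scores)
  expect_setequal(fa$term, c("(Intercept)", "rpd", "pa", "hrf", "age",
                             "sexmale"))
  fb <- fit_extended_models(cohort, scores, include_atrophy = TRUE)
  expect_true(all(c("irora", "crora") %in% fb$term))

  cohort$irora[cohort$stage == "intermediate"] <- FALSE
  cohort$crora[cohort$stage == "intermediate"] <- FALSE
  expect_error(fit_extended_models(cohort, scores, include_atrophy = TRUE),
               "constant")
  fa2 <- fit_extended_models(cohort, scores)  # variant A unaffected
  expect_equal(fa2$estimate, fa$estimate, tolerance = 1e-12)
})

test_that("EMM contrasts reduce to coefficient differences and telescope", {
  cohort <- toy_cohort(500)
  scores <- random_scores(cohort)
  fit <- fit_stage_model(cohort, scores)
  con <- emm_pairwise_contrasts(fit)
  expect_equal(nrow(con), 6)
  est <- function(a, b) con$estimate[con$stage_a == a & con$stage_b == b]
  coefs <- setNames(fit$estimate, fit$term)
  # contrast(early, none) equals the early coefficient exactly
  expect_equal(est("early", "none"), unname(coefs["stageearly"]),
               tolerance = 1e-14)
  expect_equal(est("late", "intermediate"),
               unname(coefs["stagelate"] - coefs["stageintermediate"]),
               tolerance = 1e-14)
  # telescoping: (b-a) + (c-b) - (c-a) = 0
  expect_equal(est("early", "none") + est("intermediate", "early") -
                 est("intermediate", "none"), 0, tolerance = 1e-12)
})

test_that("EMM contrasts match emmeans on the equivalent lm fit", {
  skip_if_not_installed("emmeans")
  cohort <- toy_cohort(300)
  scores <- random_scores(cohort)
  fit <- fit_stage_model(cohort, scores)
  con <- emm_pairwise_contrasts(fit)

  dat <- cohort
  dat$score <- scores$global_prs[match(dat$sample_id, scores$sample_id)]
  lfit <- lm(score ~ stage + age + sex, dat)
  em <- as.data.frame(pairs(emmeans::emmeans(lfit, "stage"),
                            adjust = "none"))
  # emmeans reports first-minus-second; ours is later-minus-earlier stage
  for (i in seq_len(nrow(em))) {
    lv <- strsplit(as.character(em$contrast[i]), " - ")[[1]]
    mine <- con[con$stage_a == lv[2] & con$stage_b == lv[1], ]
    expect_equal(mine$estimate, -em$estimate[i], tolerance = 1e-10)
    expect_equal(mine$se, em$SE[i], tolerance = 1e-10)
    expect_equal(mine$p, em$p.value[i], tolerance = 1e-10)
  }
})

test_that("re-referencing the stage factor leaves contrasts unchanged", {
  cohort <- toy_cohort(300)
  scores <- random_scores(cohort)
  con <- emm_pairwise_contrasts(fit_stage_model(cohort, scores))

  dat <- cohort
  dat$score <- scores$global_prs[match(dat$sample_id, scores$sample_id)]
  dat$stage <- relevel(dat$stage, "late")
  X <- model.matrix(~ stage + age + sex, dat)
  refit <- fit_ols(dat$score, X)
  # late-vs-intermediate from the re-referenced fit: -stageintermediate
  coefs <- setNames(refit$estimate, refit$term)
  expect_equal(con$estimate[con$stage_a == "late" &
                              con$stage_b == "intermediate"],
               unname(-coefs["stageintermediate"]), tolerance = 1e-10)
  vc <- attr(refit, "vcov")
  expect_equal(con$se[con$stage_a == "late" &
                        con$stage_b == "intermediate"],
               sqrt(vc["stageintermediate", "stageintermediate"]),
               tolerance = 1e-10)
})

test_that("stage box plot writes a file and rejects empty cohorts", {
  cohort <- toy_cohort(60)
  scores <- random_scores(cohort)
  path <- tempfile(fileext = ".png")
  plot_scores_by_stage(scores, cohort, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  expect_error(plot_scores_by_stage(scores, cohort[0, ], tempfile()),
               "empty")
})
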