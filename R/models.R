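# Multivariable linear models relating PRS (dependent variable) to AMD
# stage or structural biomarkers (independent variables), adjusted for age
# and sex, on a self-written least-squares core. Reference categories are
# fixed throughout: stage "none" (control group) and female sex. P values
# come from the t distribution with residual degrees of freedom and are
# never adjusted for multiplicity.

#' Ordinary least squares with t-based inference
#'
#' Fits `y ~ X` by QR-based least squares. Standard errors come from
#' `sigma2 * (X'X)^-1` with `sigma2 = RSS / (n - p)`; per-coefficient
#' two-sided P values and 95% confidence intervals use the t distribution
#' with `n - p` degrees of freedom.
#'
#' @param y Numeric response vector.
#' @param X Numeric design matrix (include the intercept column yourself or
#'   via `model.matrix`).
#' @param model_id Optional label carried into result tables.
#' @return A `model_result`: a `data.frame` with columns `term`,
#'   `estimate`, `se`, `statistic`, `p`, `ci_low`, `ci_high`, and
#'   attributes `n`, `df`, `r2`, `sigma2`, `vcov`, `model_id`.
#' @export
fit_ols <- function(y, X, model_id = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(y) || anyNA(X)) stop("NA values in response or design")
  if (n <= p) stop("need more observations than parameters (n = ", n,
                   ", p = ", p, ")")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qd <- qr(X)
  if (qd$rank < p) {
    dropped <- colnames(X)[qd$pivot[seq(qd$rank + 1, p)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qd, y)
  fitted <- as.vector(X %*% beta)
  res <- y - fitted
  df <- n - p
  rss <- sum(res^2)
  sigma2 <- rss / df
  # (X'X)^-1 from the R factor, undoing any column pivoting
  Rmat <- qr.R(qd)
  xtx_inv <- chol2inv(Rmat)
  unpiv <- order(qd$pivot)
  xtx_inv <- xtx_inv[unpiv, unpiv, drop = FALSE]
  vc <- sigma2 * xtx_inv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  tcrit <- qt(0.975, df)
  has_intercept <- any(apply(X, 2, function(col) all(col == col[1]) &&
                               col[1] != 0))
  tss <- if (has_intercept) sum((y - mean(y))^2) else sum(y^2)
  out <- data.frame(term = colnames(X), estimate = unname(beta),
                    se = unname(se), statistic = unname(tstat),
                    p = unname(pval),
                    ci_low = unname(beta - tcrit * se),
                    ci_high = unname(beta + tcrit * se),
                    stringsAsFactors = FALSE)
  structure(out, class = c("model_result", "data.frame"),
            n = n, df = df, r2 = if (tss > 0) 1 - rss / tss else NA_real_,
            sigma2 = sigma2, vcov = vc, model_id = model_id)
}

#' @method print model_result
#' @export
print.model_result <- function(x, ...) {
  id <- attr(x, "model_id")
  if (!is.null(id)) cat("model:", id, "\n")
  cat("n =", attr(x, "n"), " residual df =", attr(x, "df"),
      " R2 =", signif(attr(x, "r2"), 3), "\n")
  df <- as.data.frame(x)
  for (col in c("estimate", "se", "statistic", "ci_low", "ci_high"))
    df[[col]] <- signif(df[[col]], 4)
  df$p <- format.pval(df$p, digits = 3)
  print(df, row.names = FALSE)
  invisible(x)
}

merge_scores <- function(cohort, scores, score_name) {
  if (!score_name %in% score_names())
    stop("unknown score: ", score_name)
  idx <- match(cohort$sample_id, scores$sample_id)
  if (anyNA(idx)) stop("scores missing for some cohort samples")
  cohort$.score <- scores[[score_name]][idx]
  cohort
}

#' Stage model: PRS explained by AMD stage, age and sex
#'
#' Regresses the chosen score on stage dummies (early, intermediate, late
#' versus the "none" control reference), age, and sex (male versus the
#' female reference).
#'
#' @param cohort A cohort table ([read_phenotypes()] or
#'   [simulate_phenotypes()]).
#' @param scores A `score_matrix`.
#' @param score_name One of [score_names()]; default the global score.
#' @return A `model_result` with EMM metadata attached (used by
#'   [emm_pairwise_contrasts()]).
#' @export
fit_stage_model <- function(cohort, scores, score_name = "global_prs") {
  dat <- merge_scores(cohort, scores, score_name)
  dat$stage <- droplevels(factor(dat$stage, levels = STAGE_LEVELS))
  if (!"none" %in% levels(dat$stage) || nlevels(dat$stage) < 2)
    stop("stage model needs the 'none' reference group and at least one ",
         "other stage")
  X <- stats::model.matrix(~ stage + age + sex, data = dat)
  fit <- fit_ols(dat$.score, X,
                 model_id = paste0("stage_", score_name))
  attr(fit, "emm_info") <- list(
    stage_levels = levels(dat$stage),
    covariate_means = c(age = mean(dat$age),
                        sexmale = mean(dat$sex == "male")))
  fit
}

biomarker_model_specs <- function() {
  list("1_rpd" = "rpd", "2_pa" = "pa", "3_hrf" = "hrf",
       "4_atrophy" = c("irora", "crora"))
}

build_biomarker_design <- function(dat, biomarkers) {
  cols <- lapply(biomarkers, function(b) {
    v <- as.numeric(dat[[b]])
    if (anyNA(v)) stop("missing ", b, " flags in the model cohort")
    if (var(v) == 0) stop("biomarker column '", b, "' is constant")
    v
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, setNames(cols, biomarkers)),
             age = dat$age, sexmale = as.numeric(dat$sex == "male"))
  X
}

#' Per-biomarker models across all six scores
#'
#' On the intermediate-AMD subset, fits for every score (global and the
#' five pathway scores) the four biomarker models: (1) RPD, (2) pigmentary
#' abnormalities, (3) hyper-reflective foci, and (4) iRORA and cRORA
#' jointly in one fit (reference: neither atrophy lesion), each adjusted
#' for age and sex. A model whose biomarker column is constant in the
#' cohort is skipped with a warning; the remaining models still run.
#'
#' @param cohort A cohort table; it is filtered to intermediate stage here.
#' @param scores A `score_matrix`.
#' @param score_set Scores to fit; default all six.
#' @return Named list of `model_result`s, names `<model>.<score>` (e.g.
#'   `1_rpd.ah_prs`).
#' @export
fit_biomarker_models <- function(cohort, scores, score_set = score_names()) {
  dat <- cohort[cohort$stage == "intermediate", , drop = FALSE]
  if (nrow(dat) == 0) stop("no intermediate-stage samples in cohort")
  specs <- biomarker_model_specs()
  out <- list()
  for (sc in score_set) {
    d <- merge_scores(dat, scores, sc)
    for (m in names(specs)) {
      id <- paste0(m, ".", sc)
      fit <- tryCatch({
        X <- build_biomarker_design(d, specs[[m]])
        fit_ols(d$.score, X, model_id = id)
      }, error = function(e) {
        warning("skipping model ", id, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(fit)) out[[id]] <- fit
    }
  }
  if (length(out) == 0) stop("no biomarker model could be fitted")
  out
}

#' Extended multi-biomarker models
#'
#' Variant A regresses the chosen score on RPD + PA + HRF + age + sex in a
#' single fit; variant B (`include_atrophy = TRUE`) additionally includes
#' the iRORA and cRORA dummies. Fitted on the intermediate-AMD subset.
#'
#' @inheritParams fit_biomarker_models
#' @param score_name One of [score_names()].
#' @param include_atrophy Add the iRORA/cRORA dummies (variant B).
#' @return A `model_result`.
#' @export
fit_extended_models <- function(cohort, scores, score_name = "global_prs",
                                include_atrophy = FALSE) {
  dat <- cohort[cohort$stage == "intermediate", , drop = FALSE]
  if (nrow(dat) == 0) stop("no intermediate-stage samples in cohort")
  d <- merge_scores(dat, scores, score_name)
  biomarkers <- c("rpd", "pa", "hrf",
                  if (include_atrophy) c("irora", "crora"))
  X <- build_biomarker_design(d, biomarkers)
  fit_ols(d$.score, X,
          model_id = paste0("extended_", if (include_atrophy) "B" else "A",
                            "_", score_name))
}

#' Pairwise stage contrasts of estimated marginal means
#'
#' Computes the model-adjusted mean score per stage — the fitted value at
#' that stage with age fixed at the cohort mean and sex at its observed
#' male proportion — and all pairwise differences as linear contrasts
#' `L b` with variance `L V L'`. Because the covariate terms cancel in a
#' difference of two stages, each contrast reduces to a difference of stage
#' coefficients; its standard error still uses the full coefficient
#' covariance. P values are unadjusted for multiple comparisons.
#'
#' @param fit A stage-model `model_result` from [fit_stage_model()].
#' @param cohort Optional cohort to recompute covariate means from;
#'   defaults to the means stored at fit time.
#' @return A `data.frame` (class `contrast_result`) with one row per stage
#'   pair: `stage_a`, `stage_b`, `emm_a`, `emm_b`, `estimate`
#'   (emm_a - emm_b), `se`, `statistic`, `p`.
#' @export
emm_pairwise_contrasts <- function(fit, cohort = NULL) {
  info <- attr(fit, "emm_info")
  if (is.null(info)) stop("fit carries no EMM metadata; ",
                          "use fit_stage_model()")
  if (!is.null(cohort))
    info$covariate_means <- c(age = mean(cohort$age),
                              sexmale = mean(cohort$sex == "male"))
  vc <- attr(fit, "vcov")
  terms <- fit$term
  beta <- fit$estimate
  df <- attr(fit, "df")
  # design row for the adjusted mean of one stage
  grid_row <- function(stage) {
    x <- setNames(numeric(length(terms)), terms)
    x["(Intercept)"] <- 1
    dummy <- paste0("stage", stage)
    if (dummy %in% terms) x[dummy] <- 1
    else if (stage != info$stage_levels[1])
      return(NULL)   # stage absent from the fit
    x["age"] <- info$covariate_means["age"]
    x["sexmale"] <- info$covariate_means["sexmale"]
    x
  }
  lv <- info$stage_levels
  rows <- lapply(lv, grid_row)
  names(rows) <- lv
  absent <- lv[vapply(rows, is.null, TRUE)]
  if (length(absent) > 0) {
    warning("stage(s) absent from the fit, contrasts skipped: ",
            paste(absent, collapse = ", "))
    lv <- setdiff(lv, absent)
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    xa <- rows[[pr[1]]]; xb <- rows[[pr[2]]]
    L <- xb - xa   # second level minus first, e.g. early - none
    est <- sum(L * beta)
    se <- sqrt(as.numeric(t(L) %*% vc %*% L))
    tstat <- est / se
    data.frame(stage_a = pr[2], stage_b = pr[1],
               emm_a = sum(xb * beta), emm_b = sum(xa * beta),
               estimate = est, se = se, statistic = tstat,
               p = 2 * pt(-abs(tstat), df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Box plot of a score by AMD stage
#'
#' One box per stage with every participant overlaid as a point.
#'
#' @param scores A `score_matrix`.
#' @param cohort A cohort table.
#' @param path Output image path (extension selects the device, e.g.
#'   `.png` or `.svg`).
#' @param score_name One of [score_names()].
#' @param seed Seed for the horizontal point jitter (plot determinism).
#' @return The ggplot object, invisibly (also written to `path`).
#' @export
plot_scores_by_stage <- function(scores, cohort, path,
                                 score_name = "global_prs", seed = 1L) {
  if (nrow(cohort) == 0) stop("empty cohort")
  dat <- merge_scores(cohort, scores, score_name)
  dat$stage <- droplevels(factor(dat$stage, levels = STAGE_LEVELS))
  set.seed(seed)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$stage, y = .data$.score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "AMD stage", y = score_name) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
  invisible(p)
}
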