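# PRS engine: effect-allele alignment against the VCF REF/ALT encoding,
# mean-dosage imputation of missing cells, and the non-averaged weighted
# dosage sums for the global and pathway-specific scores.

COMPLEMENT_BASE <- c(A = "T", C = "G", G = "C", T = "A")

strand_complement <- function(allele) {
  unname(COMPLEMENT_BASE[allele])
}

is_strand_ambiguous <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & strand_complement(a1) == a2
}

#' Align scoring-file effect alleles to the genotype encoding
#'
#' For each variant shared between the weight table and the genotype
#' matrix, converts the stored ALT-allele dosage into an effect-allele
#' dosage. If the effect allele is the ALT allele the dosage is used as is;
#' if it is the REF allele the dosage is flipped (`d <- 2 - d`); if the
#' alleles only match after strand complementation the record is
#' complemented first and the same logic applied. Strand-ambiguous SNPs
#' (A/T or C/G pairs), which cannot be disambiguated without external
#' frequencies, are excluded under the default policy. Variants whose
#' alleles never match are flagged `unmatched` with a warning; excluded and
#' unmatched variants contribute to no score.
#'
#' @param weights A weight table ([read_scoring_file()]).
#' @param gm A [genotype_matrix()].
#' @param ambiguity_policy `"exclude"` (default) or `"keep"` for
#'   strand-ambiguous SNPs (kept SNPs are aligned assuming same-strand
#'   reporting).
#' @return A list of class `aligned_dosage`: `dosages` (samples x aligned
#'   variants, effect-allele scale), `weights` (rows for aligned variants,
#'   in matrix order), `actions` (named character vector over all shared
#'   variants: `as_is`, `flipped`, `strand_complemented`,
#'   `excluded_ambiguous`, `unmatched`), `samples`.
#' @export
align_effect_alleles <- function(weights, gm,
                                 ambiguity_policy = c("exclude", "keep")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  shared <- intersect(weights$variant_id, gm$variants$variant_id)
  if (length(shared) == 0)
    stop("no overlap between scoring file and genotype matrix; ",
         "scores are undefined")
  vmeta <- gm$variants[match(shared, gm$variants$variant_id), ]
  wrow <- weights[match(shared, weights$variant_id), ]
  actions <- setNames(rep("unmatched", length(shared)), shared)
  flip <- setNames(rep(FALSE, length(shared)), shared)
  for (i in seq_along(shared)) {
    eff <- wrow$effect_allele[i]
    oth <- wrow$other_allele[i]
    ref <- vmeta$ref_allele[i]
    alt <- vmeta$alt_allele[i]
    ambiguous <- !is.na(oth) && is_strand_ambiguous(eff, oth)
    if (ambiguous && ambiguity_policy == "exclude") {
      actions[i] <- "excluded_ambiguous"
      next
    }
    other_ok <- function(o, against) is.na(o) || o == against
    if (eff == alt && other_ok(oth, ref)) {
      actions[i] <- "as_is"
    } else if (eff == ref && other_ok(oth, alt)) {
      actions[i] <- "flipped"; flip[i] <- TRUE
    } else {
      ceff <- strand_complement(eff)
      coth <- if (is.na(oth)) NA_character_ else strand_complement(oth)
      if (!is.na(ceff) && ceff == alt && other_ok(coth, ref)) {
        actions[i] <- "strand_complemented"
      } else if (!is.na(ceff) && ceff == ref && other_ok(coth, alt)) {
        actions[i] <- "strand_complemented"; flip[i] <- TRUE
      }
    }
  }
  if (any(actions == "unmatched"))
    warning("allele mismatch, variant(s) left unscored: ",
            paste(shared[actions == "unmatched"], collapse = ", "))
  usable <- shared[actions %in% c("as_is", "flipped", "strand_complemented")]
  if (length(usable) == 0)
    stop("no variant could be aligned; scores are undefined")
  dos <- gm$dosages[, usable, drop = FALSE]
  fl <- flip[usable]
  dos[, fl] <- 2 - dos[, fl, drop = FALSE]
  structure(list(dosages = dos,
                 weights = weights[match(usable, weights$variant_id), ],
                 actions = actions, samples = gm$samples),
            class = "aligned_dosage")
}

#' Impute missing aligned dosages with the per-variant mean
#'
#' Replaces each missing cell by twice the effect-allele frequency
#' estimated from the non-missing dosages of that variant (i.e. the
#' per-variant mean dosage), the standard scoring-tool default. A variant
#' with no non-missing dosage is dropped with a warning.
#'
#' @param aligned An `aligned_dosage` from [align_effect_alleles()].
#' @return The `aligned_dosage` with no missing cells.
#' @export
impute_missing_dosage <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_dosage"))
  dos <- aligned$dosages
  all_missing <- apply(dos, 2, function(x) all(is.na(x)))
  if (any(all_missing)) {
    warning("dropping all-missing variant(s): ",
            paste(colnames(dos)[all_missing], collapse = ", "))
    keep <- !all_missing
    dos <- dos[, keep, drop = FALSE]
    aligned$weights <- aligned$weights[keep, , drop = FALSE]
  }
  for (j in seq_len(ncol(dos))) {
    miss <- is.na(dos[, j])
    if (any(miss)) dos[miss, j] <- mean(dos[!miss, j])
  }
  aligned$dosages <- dos
  aligned
}

#' Weighted dosage sum for one variant subset
#'
#' The score of sample s is `sum_i beta_i * d_si` over the subset — a raw,
#' non-averaged score sum: no division by the variant count and no
#' standardization, so reported scores live on the scale of the published
#' effect sizes.
#'
#' @param aligned An imputed `aligned_dosage`.
#' @param variant_subset Character vector of variant ids to sum over.
#' @param score_name Label used in error messages.
#' @return Named numeric vector of per-sample scores (matrix sample order).
#' @export
compute_score <- function(aligned, variant_subset,
                          score_name = "score") {
  stopifnot(inherits(aligned, "aligned_dosage"))
  idx <- match(variant_subset, colnames(aligned$dosages))
  if (length(variant_subset) == 0 || anyNA(idx))
    stop("score '", score_name, "' is undefined: ",
         if (length(variant_subset) == 0) "empty variant subset"
         else "subset contains unaligned variants")
  beta <- aligned$weights$beta[match(variant_subset,
                                     aligned$weights$variant_id)]
  setNames(as.vector(aligned$dosages[, idx, drop = FALSE] %*% beta),
           aligned$samples)
}

#' Compute the global and all pathway-specific scores
#'
#' The global score sums every aligned weight; each pathway score is
#' restricted to variants whose gene label belongs to that pathway's gene
#' set in the registry. The combined complement + ARMS2/HTRA1 score uses
#' the union of the two sets, so it equals their sum whenever the sets are
#' disjoint.
#'
#' @param aligned An imputed `aligned_dosage`.
#' @param registry Pathway registry, default [pathway_registry()].
#' @return A `data.frame` (class `score_matrix`) with columns `sample_id`,
#'   `global_prs`, `ah_prs`, `c_prs`, `c_ah_prs`, `e_prs`, `l_prs`.
#' @export
compute_all_scores <- function(aligned, registry = pathway_registry()) {
  stopifnot(inherits(aligned, "aligned_dosage"))
  wt <- aligned$weights
  sets <- lapply(registry, function(genes)
    wt$variant_id[wt$gene_label %in% genes])
  subsets <- list(
    global_prs = wt$variant_id,
    ah_prs = sets$arms2_htra1,
    c_prs = sets$complement,
    c_ah_prs = c(sets$complement, sets$arms2_htra1),
    e_prs = sets$ecm,
    l_prs = sets$lipid
  )
  empty <- names(subsets)[vapply(subsets, length, 1L) == 0]
  if (length(empty) > 0)
    stop("no surviving variants for score(s): ",
         paste(empty, collapse = ", "))
  out <- data.frame(sample_id = aligned$samples)
  for (nm in names(subsets))
    out[[nm]] <- unname(compute_score(aligned, subsets[[nm]], nm))
  class(out) <- c("score_matrix", "data.frame")
  out
}

#' Write a score matrix as CSV
#'
#' @param scores A `score_matrix` from [compute_all_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  for (nm in score_names())
    out[[nm]] <- formatC(scores[[nm]], digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
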