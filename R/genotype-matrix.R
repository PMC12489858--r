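#' Construct a genotype dosage matrix
#'
#' Container for imputed genotypes: a samples-by-variants matrix of
#' effect-less ALT-allele dosages in \[0, 2\] (NA = missing) plus per-variant
#' metadata (alleles, position, imputation R2).
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns.
#' @param variants `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `imputation_r2` (NA when unannotated).
#' @param samples Character vector of sample ids (row order of `dosages`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(variants))
  need <- c("variant_id", "chrom", "pos", "ref_allele", "alt_allele",
            "imputation_r2")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0)
    stop("variant metadata missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("dosage matrix has ", ncol(dosages), " columns but ",
         nrow(variants), " variant records")
  if (length(samples) != nrow(dosages))
    stop("dosage matrix has ", nrow(dosages), " rows but ",
         length(samples), " sample ids")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id in metadata")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (any(variants$pos < 1)) stop("variant pos must be >= 1")
  same <- variants$ref_allele == variants$alt_allele
  if (any(same))
    stop("ref_allele == alt_allele for: ",
         paste(variants$variant_id[same], collapse = ", "))
  bad <- !is.na(dosages) & (dosages < 0 | dosages > 2)
  if (any(bad)) stop("dosages must lie in [0, 2] or be NA")
  rownames(dosages) <- samples
  colnames(dosages) <- variants$variant_id
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  nr2 <- sum(!is.na(x$variants$imputation_r2))
  cat("  imputation R2 annotated for", nr2, "variant(s);",
      sum(is.na(x$dosages)), "missing dosage cell(s)\n")
  invisible(x)
}

#' @method dim genotype_matrix
#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset variants by index/logical/id, preserving order.
subset_variants <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, gm$variants$variant_id)
  genotype_matrix(gm$dosages[, keep, drop = FALSE],
                  gm$variants[keep, , drop = FALSE], gm$samples)
}
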