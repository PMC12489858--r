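# Readers and writers for the pipeline's external formats:
# scoring file (tab-separated, PGS-Catalog-style + gene/pathway columns),
# genotype VCF, phenotype CSV, and model-result tables.

SCORING_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                  "other_allele", "effect_weight", "gene_label", "pathway")
PHENO_COLS <- c("sample_id", "age", "sex", "stage",
                "rpd", "pa", "hrf", "irora", "crora")
STAGE_LEVELS <- c("none", "early", "intermediate", "late")
BIOMARKERS <- c("rpd", "pa", "hrf", "irora", "crora")

#' Read a PRS scoring file
#'
#' Parses a tab-separated scoring file with header columns `variant_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `effect_weight`,
#' `gene_label`, `pathway`. The mandatory columns are the variant id, the
#' effect allele and the effect weight; the rest may be absent or empty.
#' Pathway tags come from the controlled vocabulary
#' (`complement`, `ecm`, `lipid`, `arms2_htra1`, `other`); an empty pathway
#' cell is resolved from `gene_label` through [pathway_registry()], and an
#' unknown pathway string is kept as `"other"` with a warning.
#'
#' @param path Path to the tab-separated scoring file.
#' @return A `data.frame` (class `weight_table`) with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `gene_label`, `pathway` plus
#'   `chrom`/`pos` when present.
#' @export
read_scoring_file <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    strip.white = TRUE)
  mandatory <- c("variant_id", "effect_allele", "effect_weight")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0)
    stop("scoring file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  beta <- suppressWarnings(as.numeric(raw$effect_weight))
  bad <- which(is.na(beta) & !(raw$effect_weight %in% c("", "NA")))
  if (length(bad) > 0)
    stop("non-numeric effect_weight at data line(s) ",
         paste(bad, collapse = ", "), " (value(s): ",
         paste(raw$effect_weight[bad], collapse = ", "), ")")
  if (anyNA(beta)) stop("missing effect_weight is not allowed")
  if (anyDuplicated(raw$variant_id))
    stop("duplicate variant_id in scoring file")
  wt <- data.frame(variant_id = raw$variant_id,
                   effect_allele = toupper(raw$effect_allele),
                   other_allele = if ("other_allele" %in% names(raw))
                     toupper(raw$other_allele) else NA_character_,
                   beta = beta,
                   gene_label = if ("gene_label" %in% names(raw))
                     raw$gene_label else "",
                   pathway = if ("pathway" %in% names(raw))
                     raw$pathway else "",
                   stringsAsFactors = FALSE)
  if ("chrom" %in% names(raw)) wt$chrom <- raw$chrom
  if ("pos" %in% names(raw)) wt$pos <- suppressWarnings(as.integer(raw$pos))
  same <- !is.na(wt$other_allele) & wt$effect_allele == wt$other_allele
  if (any(same))
    stop("effect_allele equals other_allele for: ",
         paste(wt$variant_id[same], collapse = ", "))
  # empty pathway cells fall back to the gene-label registry lookup
  empty <- is.na(wt$pathway) | wt$pathway == ""
  wt$pathway[empty] <- gene_to_pathway(wt$gene_label[empty])
  known <- c(pathway_tags(), "")
  unknown <- !(wt$pathway %in% known)
  if (any(unknown)) {
    warning("unknown pathway tag(s) ",
            paste(unique(wt$pathway[unknown]), collapse = ", "),
            " mapped to 'other'")
    wt$pathway[unknown] <- "other"
  }
  class(wt) <- c("weight_table", "data.frame")
  wt
}

#' Write a scoring file
#'
#' Inverse of [read_scoring_file()]; weights are written with 17 significant
#' digits so a write/read round trip reproduces them bit-for-bit.
#'
#' @param weights A weight table as returned by [read_scoring_file()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(weights, path) {
  out <- data.frame(variant_id = weights$variant_id,
                    chrom = if ("chrom" %in% names(weights))
                      weights$chrom else ".",
                    pos = if ("pos" %in% names(weights)) weights$pos else 0L,
                    effect_allele = weights$effect_allele,
                    other_allele = weights$other_allele,
                    effect_weight = formatC(weights$beta, digits = 17,
                                            format = "g"),
                    gene_label = weights$gene_label,
                    pathway = weights$pathway)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Builds a [genotype_matrix()] from a VCF. Dosages are taken from the
#' per-sample dosage field (`DS`) when present, otherwise derived from hard
#' calls (`GT`: 0/1/2 copies of the ALT allele, missing stays missing); the
#' preference order is configurable. Per-variant imputation quality is read
#' from the INFO `R2` (or `DR2`) key and left missing when unannotated.
#'
#' @param path Path to a VCF (v4.2+) file.
#' @param field_preference Character vector ordering the FORMAT fields to
#'   use; default `c("DS", "GT")` (imputed data are dosage-natured).
#' @param multiallelic Policy for records with more than one ALT allele:
#'   `"reject"` (default; error listing the records — the score expects
#'   biallelic loci) or `"drop"` (remove them with a warning).
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, field_preference = c("DS", "GT"),
                           multiallelic = c("reject", "drop")) {
  multiallelic <- match.arg(multiallelic)
  field_preference <- match.arg(field_preference, c("DS", "GT"),
                                several.ok = TRUE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, ":", fix$POS), fix$ID)[multi]
    if (multiallelic == "reject")
      stop("multi-allelic record(s) not supported under policy 'reject': ",
           paste(ids, collapse = ", "))
    warning("dropping ", sum(multi), " multi-allelic record(s)")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("VCF contains no usable biallelic records")
  vid <- fix$ID
  synth <- is.na(vid) | vid == "."
  vid[synth] <- paste0(fix$CHROM[synth], ":", fix$POS[synth], ":",
                       fix$REF[synth], ":", fix$ALT[synth])
  r2 <- suppressWarnings(vcfR::extract.info(vcf, element = "R2",
                                            as.numeric = TRUE))
  if (all(is.na(r2)))
    r2 <- suppressWarnings(vcfR::extract.info(vcf, element = "DR2",
                                              as.numeric = TRUE))
  get_field <- function(el) {
    m <- tryCatch(vcfR::extract.gt(vcf, element = el,
                                   as.numeric = (el == "DS")),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    if (el == "GT") m <- apply(m, c(1, 2), gt_to_count)
    m
  }
  dos <- NULL
  for (el in field_preference) {
    m <- get_field(el)
    if (is.null(m)) next
    if (is.null(dos)) dos <- m else {
      fill <- is.na(dos) & !is.na(m)   # fall back per cell
      dos[fill] <- m[fill]
    }
  }
  if (is.null(dos))
    stop("none of the requested FORMAT fields (",
         paste(field_preference, collapse = ", "), ") found in VCF")
  samples <- colnames(dos)
  dos <- t(dos)   # vcfR returns variants x samples
  genotype_matrix(dos,
                  data.frame(variant_id = vid, chrom = fix$CHROM,
                             pos = as.integer(fix$POS),
                             ref_allele = fix$REF, alt_allele = fix$ALT,
                             imputation_r2 = as.numeric(r2)),
                  samples)
}

# "0/1", "0|1", "./." etc. -> ALT allele count or NA
gt_to_count <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

#' Read a phenotype table
#'
#' Parses the cohort CSV (`sample_id,age,sex,stage,rpd,pa,hrf,irora,crora`).
#' `sex` and `stage` are matched case-insensitively against their controlled
#' vocabularies. Biomarker flags may be missing (typically outside the
#' intermediate stage). A row claiming both iRORA and cRORA violates the
#' combined atrophy coding used by the models (the iRORA group is "at least
#' one iRORA lesion but not one cRORA lesion"); it is repaired to
#' `irora = FALSE, crora = TRUE` with a warning, since cRORA presence
#' defines the cRORA group.
#'
#' @param path Path to the phenotype CSV.
#' @return A `data.frame` (class `cohort_table`) with typed columns;
#'   `stage` is a factor with levels none < early < intermediate < late.
#' @export
read_phenotypes <- function(path) {
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  miss <- setdiff(PHENO_COLS, names(raw))
  if (length(miss) > 0)
    stop("phenotype CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(raw$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
               collapse = ", "))
  age <- as.numeric(raw$age)
  if (anyNA(age) || any(age <= 0)) stop("age must be a positive number")
  sex <- tolower(raw$sex)
  bad <- !(sex %in% c("female", "male"))
  if (any(bad))
    stop("unknown sex label(s): ", paste(unique(raw$sex[bad]), collapse = ", "))
  stage <- tolower(raw$stage)
  bad <- !(stage %in% STAGE_LEVELS)
  if (any(bad))
    stop("unknown stage label(s): ",
         paste(unique(raw$stage[bad]), collapse = ", "))
  parse_flag <- function(x) {
    x <- tolower(x)
    out <- rep(NA, length(x))
    out[x %in% c("1", "true", "t", "yes")] <- TRUE
    out[x %in% c("0", "false", "f", "no")] <- FALSE
    bad <- !is.na(x) & !(x %in% c("", "na", "1", "true", "t", "yes",
                                  "0", "false", "f", "no"))
    if (any(bad)) stop("unparseable biomarker flag value(s): ",
                       paste(unique(x[bad]), collapse = ", "))
    out
  }
  cohort <- data.frame(sample_id = raw$sample_id, age = age,
                       sex = factor(sex, levels = c("female", "male")),
                       stage = factor(stage, levels = STAGE_LEVELS),
                       stringsAsFactors = FALSE)
  for (b in BIOMARKERS) cohort[[b]] <- parse_flag(raw[[b]])
  both <- !is.na(cohort$irora) & !is.na(cohort$crora) &
    cohort$irora & cohort$crora
  if (any(both)) {
    warning(sum(both), " sample(s) flagged both iRORA and cRORA; ",
            "recoded to the cRORA group (irora = FALSE, crora = TRUE)")
    cohort$irora[both] <- FALSE
  }
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotypes()]; biomarker flags are written as 0/1 and
#' missing flags as empty cells.
#'
#' @param cohort A cohort table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  out <- data.frame(sample_id = cohort$sample_id, age = cohort$age,
                    sex = as.character(cohort$sex),
                    stage = as.character(cohort$stage))
  for (b in BIOMARKERS) out[[b]] <- ifelse(is.na(cohort[[b]]), "",
                                           as.integer(cohort[[b]]))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fitted model results to disk
#'
#' Renders one or more fitted models in a deterministic layout: columns
#' `model`, `predictor`, `estimate`, `ci_low`, `ci_high`, `p`. The CSV
#' rendering keeps full precision (17 significant digits); the text
#' rendering aligns columns and separates models into labelled blocks.
#'
#' @param model_results A single model result from [fit_ols()] (or the
#'   higher-level fitters) or a list of them; list names override model ids.
#' @param path Output path.
#' @param format `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(model_results, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (inherits(model_results, "model_result"))
    model_results <- list(model_results)
  if (length(model_results) == 0)
    stop("no model results to write")
  ids <- names(model_results)
  if (is.null(ids)) ids <- rep("", length(model_results))
  rows <- lapply(seq_along(model_results), function(i) {
    mr <- model_results[[i]]
    if (!inherits(mr, "model_result"))
      stop("element ", i, " is not a model_result")
    id <- if (nzchar(ids[i])) ids[i] else
      attr(mr, "model_id") %||% paste0("model_", i)
    data.frame(model = id, predictor = mr$term, estimate = mr$estimate,
               ci_low = mr$ci_low, ci_high = mr$ci_high, p = mr$p)
  })
  tab <- do.call(rbind, rows)
  if (format == "csv") {
    out <- tab
    for (col in c("estimate", "ci_low", "ci_high", "p"))
      out[[col]] <- formatC(tab[[col]], digits = 17, format = "g")
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (id in unique(tab$model)) {
      block <- tab[tab$model == id, c("predictor", "estimate",
                                      "ci_low", "ci_high", "p")]
      writeLines(paste0("== ", id, " =="), con)
      fmt <- block
      for (col in c("estimate", "ci_low", "ci_high", "p"))
        fmt[[col]] <- formatC(block[[col]], digits = 3, format = "e")
      writeLines(capture_table(fmt), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

capture_table <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
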