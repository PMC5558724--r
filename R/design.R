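#' Fixed-effect design matrix
#'
#' Builds X with a leading intercept (overall mean), treatment-coded breed
#' and sex indicators, and optionally raw dosage columns for named variants
#' fitted as fixed effects (e.g. known causal mutations in major genes).
#' Factors with a single level contribute no column; collinear columns are
#' pruned with a warning. Variants fitted as fixed effects must be removed
#' from the random-SNP set by the caller (the returned
#' \code{fixed_variant_idx} gives their column indices in the genotype
#' matrix).
#'
#' @param pheno data frame with at least \code{animal_id}; optional
#'   \code{breed} and \code{sex} columns become indicator contrasts.
#' @param fixed_variants character vector of variant ids to fit as fixed
#'   dosage covariates (default none).
#' @param geno \code{geno_matrix} supplying those dosages; required when
#'   \code{fixed_variants} is non-empty. Rows are matched by animal id.
#' @return list with \code{X} (n x b, full column rank),
#'   \code{fixed_variant_idx} (positions of the fixed variants in
#'   \code{geno}), and \code{colnames}.
#' @export
build_fixed_design <- function(pheno, fixed_variants = character(0),
                               geno = NULL) {
  pheno <- as.data.frame(pheno)
  n <- nrow(pheno)
  X <- matrix(1, n, 1, dimnames = list(NULL, "mean"))
  for (fac in c("breed", "sex")) {
    if (!is.null(pheno[[fac]])) {
      f <- factor(pheno[[fac]])
      if (nlevels(f) > 1) {
        C <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(C) <- paste0(fac, levels(f)[-1])
        X <- cbind(X, C)
      }
    }
  }
  fixed_idx <- integer(0)
  if (length(fixed_variants)) {
    if (is.null(geno)) stop("geno required when fixed_variants are given")
    fixed_idx <- match(fixed_variants, geno$variant_ids)
    if (anyNA(fixed_idx))
      stop("fixed variant(s) not in genotypes: ",
           paste(fixed_variants[is.na(fixed_idx)], collapse = ", "))
    rows <- match(as.character(pheno$animal_id), geno$animal_ids)
    if (anyNA(rows)) stop("phenotyped animal(s) missing from genotypes")
    D <- geno$dosages[rows, fixed_idx, drop = FALSE]
    if (anyNA(D)) {  # mean-impute fixed-covariate dosages
      for (j in seq_len(ncol(D)))
        D[is.na(D[, j]), j] <- 2 * geno$freq[fixed_idx[j]]
    }
    colnames(D) <- fixed_variants
    X <- cbind(X, D)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- qr_x$pivot[-seq_len(qr_x$rank)]
    warning("pruning collinear design column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  list(X = X, fixed_variant_idx = fixed_idx, colnames = colnames(X))
}

#' Read a phenotype table
#'
#' Tab-delimited with header; recognized columns: \code{animal_id},
#' \code{trait_value}, \code{sex} (bull/cow), \code{breed}, \code{d}
#' (daughter count), \code{r} (record count), optional precomputed
#' \code{weight}.
#'
#' @param path file path.
#' @return data frame, one row per animal.
#' @export
read_pheno_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"animal_id" %in% names(tab)) names(tab)[1] <- "animal_id"
  tab$animal_id <- as.character(tab$animal_id)
  if (anyDuplicated(tab$animal_id)) stop("one row per animal required")
  tab
}

#' Read a pedigree table
#'
#' Tab-delimited with header columns animal/sire/dam (names flexible; the
#' first three columns are used). Unknown parents may be blank, 0 or NA.
#'
#' @param path file path.
#' @return data frame with \code{animal_id}, \code{sire_id}, \code{dam_id}.
#' @export
read_pedigree_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  names(tab)[1:3] <- c("animal_id", "sire_id", "dam_id")
  tab
}
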