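#' Genotype matrix container
#'
#' Bundles an n x m allele-dosage matrix (animals x variants, dosages coded
#' 0/1/2 with \code{NA} for missing calls) together with per-variant map
#' information and allele frequencies. Monomorphic variants (frequency 0 or 1)
#' are flagged so that standardization and model fitting can exclude them.
#'
#' @param dosages numeric matrix of 0/1/2 dosages, animals in rows. Row names
#'   are used as animal ids and column names as variant ids when present.
#' @param variant_ids character vector of variant labels (default from column
#'   names, else \code{snp1..snpm}).
#' @param chrom chromosome label per variant (default \code{"1"}).
#' @param pos_bp 1-based base-pair position per variant (default \code{1:m}).
#' @param animal_ids animal labels (default from row names, else
#'   \code{id1..idn}).
#' @return An object of class \code{"geno_matrix"}: a list with elements
#'   \code{dosages}, \code{variant_ids}, \code{chrom}, \code{pos_bp},
#'   \code{animal_ids}, \code{freq} (allele frequency per variant),
#'   \code{call_rate} and \code{monomorphic} (logical).
#' @examples
#' g <- geno_matrix(matrix(c(0, 1, 2, 1, 0, 0), nrow = 3))
#' g$freq
#' @export
geno_matrix <- function(dosages, variant_ids = NULL, chrom = NULL,
                        pos_bp = NULL, animal_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[bad])[1:min(3, sum(bad))], collapse = ", "))
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(variant_ids))
    variant_ids <- colnames(dosages) %||% paste0("snp", seq_len(m))
  if (is.null(animal_ids))
    animal_ids <- rownames(dosages) %||% paste0("id", seq_len(n))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos_bp)) pos_bp <- seq_len(m)
  stopifnot(length(variant_ids) == m, length(chrom) == m,
            length(pos_bp) == m, length(animal_ids) == n)
  dimnames(dosages) <- list(animal_ids, variant_ids)
  fr <- compute_allele_freqs(dosages)
  structure(list(dosages = dosages,
                 variant_ids = as.character(variant_ids),
                 chrom = as.character(chrom),
                 pos_bp = as.integer(pos_bp),
                 animal_ids = as.character(animal_ids),
                 freq = fr$freq,
                 call_rate = fr$call_rate,
                 monomorphic = fr$monomorphic),
            class = "geno_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$animal_ids), "animals x",
      length(x$variant_ids), "variants\n")
  cat("  monomorphic:", sum(x$monomorphic),
      " mean call rate:", signif(mean(x$call_rate), 4), "\n")
  invisible(x)
}

as_dosage_matrix <- function(geno) {
  if (inherits(geno, "geno_matrix")) geno$dosages else {
    g <- as.matrix(geno); storage.mode(g) <- "double"; g
  }
}

#' Allele frequencies from dosages
#'
#' Computes per-variant allele frequencies p_i = mean(dosage)/2 over
#' non-missing calls, the per-variant call rate, and a monomorphic flag
#' (p_i of 0 or 1, or no calls at all).
#'
#' @param geno a \code{geno_matrix} or a dosage matrix.
#' @return list with \code{freq}, \code{call_rate}, \code{monomorphic}.
#' @examples
#' compute_allele_freqs(matrix(c(0, 1, 2, 1), ncol = 1))$freq  # 0.5
#' @export
compute_allele_freqs <- function(geno) {
  d <- as_dosage_matrix(geno)
  nonmiss <- colSums(!is.na(d))
  freq <- ifelse(nonmiss > 0, colMeans(d, na.rm = TRUE) / 2, NA_real_)
  call_rate <- nonmiss / nrow(d)
  mono <- nonmiss == 0 | (!is.na(freq) & (freq <= 0 | freq >= 1))
  list(freq = freq, call_rate = call_rate, monomorphic = mono)
}

#' Standardize a genotype matrix
#'
#' Centres and scales dosages column-wise to Zs_ij = (Z_ij - 2 p_i) /
#' sqrt(2 p_i (1 - p_i)), the usual unit-variance coding under
#' Hardy-Weinberg equilibrium. Missing dosages are mean-imputed to 2 p_i
#' (contributing exactly 0 after centring). Monomorphic variants cannot be
#' scaled; they are dropped when \code{drop_monomorphic} is TRUE (default)
#' and are an error otherwise.
#'
#' @param geno a \code{geno_matrix} or dosage matrix.
#' @param freq optional externally supplied allele frequencies (e.g. the
#'   reference-set frequencies when standardizing validation animals).
#' @param drop_monomorphic drop unscalable variants instead of erroring.
#' @return numeric matrix Zs with attribute \code{"freq"} (frequencies used)
#'   and \code{"kept"} (indices of retained variants).
#' @examples
#' standardize_genotypes(matrix(c(0, 1, 2, 1), ncol = 1))
#' @export
standardize_genotypes <- function(geno, freq = NULL, drop_monomorphic = TRUE) {
  d <- as_dosage_matrix(geno)
  if (is.null(freq)) {
    fr <- compute_allele_freqs(d)
    freq <- fr$freq
    mono <- fr$monomorphic
  } else {
    stopifnot(length(freq) == ncol(d))
    mono <- is.na(freq) | freq <= 0 | freq >= 1
  }
  if (any(mono)) {
    if (!drop_monomorphic)
      stop(sum(mono), " monomorphic variant(s); filter before standardizing")
    d <- d[, !mono, drop = FALSE]
    freq <- freq[!mono]
  }
  kept <- which(!mono)
  sds <- sqrt(2 * freq * (1 - freq))
  Zs <- sweep(d, 2, 2 * freq, "-")
  Zs[is.na(Zs)] <- 0  # mean imputation after centring
  Zs <- sweep(Zs, 2, sds, "/")
  attr(Zs, "freq") <- freq
  attr(Zs, "kept") <- kept
  Zs
}

#' Read a TSV dosage matrix
#'
#' Expects a header line \code{animal_id<TAB>variant ids...}; one row per
#' animal; dosages 0/1/2 with \code{NA} or \code{.} for missing. Optional
#' companion columns are not supported -- use \code{read_plink} for mapped
#' variants or pass map info to \code{\link{geno_matrix}}.
#'
#' @param path file path.
#' @param chrom,pos_bp optional per-variant map vectors.
#' @return a \code{geno_matrix}.
#' @export
read_dosage_tsv <- function(path, chrom = NULL, pos_bp = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = c("NA", "."),
                           colClasses = "character")
  ids <- tab[[1]]
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- ids
  geno_matrix(d, chrom = chrom, pos_bp = pos_bp)
}

#' Read PLINK .bed/.bim/.fam genotypes
#'
#' Minimal reader for the PLINK 1 binary format (SNP-major, magic bytes
#' 0x6c 0x1b 0x01). Dosages count ALT (.bim allele 1) copies; heterozygote
#' 0x02 codes are returned as 1 and the 0x01 code as missing, per the format.
#'
#' @param prefix path prefix; \code{<prefix>.bed/.bim/.fam} must exist.
#' @return a \code{geno_matrix}.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  fam_tab <- utils::read.table(fam, colClasses = "character")
  bim_tab <- utils::read.table(bim, colClasses = "character")
  n <- nrow(fam_tab); m <- nrow(bim_tab)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)  # bytes per variant
  body <- raw[-(1:3)]
  if (length(body) < bpv * m) stop("truncated .bed file")
  # unpack 2-bit codes: 00=hom A1 (2 copies), 10=het, 11=hom A2, 01=missing
  codes <- matrix(NA_integer_, nrow = 4 * bpv, ncol = m)
  bytes <- matrix(as.integer(body[seq_len(bpv * m)]), nrow = bpv)
  for (shift in 0:3) {
    codes[seq(shift + 1, 4 * bpv, by = 4), ] <- bitwAnd(bytes %/% 4L^shift, 3L)
    # column-within-byte order: first sample in lowest 2 bits
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2, NA, 1, 0)  # code 0,1,2,3 -> A1 dosage
  d <- matrix(lookup[codes + 1L], nrow = n, ncol = m)
  rownames(d) <- fam_tab[[2]]
  colnames(d) <- bim_tab[[2]]
  geno_matrix(d, chrom = bim_tab[[1]], pos_bp = as.integer(bim_tab[[4]]))
}

#' Read dosages from a VCF
#'
#' Extracts biallelic GT fields via the vcfR package and converts them to ALT
#' allele dosages. Multi-allelic records are dropped with a warning.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a \code{geno_matrix}.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF genotypes")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  d <- t(apply(gt, 1, count_alt))  # variants x samples
  d <- t(d)                        # samples x variants
  rownames(d) <- colnames(gt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  colnames(d) <- ids
  geno_matrix(d, chrom = fix[, "CHROM"], pos_bp = as.integer(fix[, "POS"]))
}
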