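#' Simulate genotype dosages with controllable LD
#'
#' Each chromosome's haplotypes follow a latent Gaussian first-order Markov
#' chain: z_j = rho z_(j-1) + sqrt(1-rho^2) eps, and the haplotype carries
#' the allele when z_j < qnorm(p_j). This preserves the per-variant allele
#' frequency exactly while giving geometric LD decay with adjacent-variant
#' latent correlation \code{ld_rho}. Dosages are the sum of two independent
#' haplotypes. The chain restarts at chromosome boundaries.
#'
#' @param n animals. @param m variants.
#' @param freq_spec either a numeric vector of m allele frequencies or a
#'   function \code{function(m)} drawing them (default uniform on
#'   [maf, 1-maf]).
#' @param ld_rho adjacent-variant latent correlation in [0,1).
#' @param maf minimum allele frequency for the default frequency draw.
#' @param n_chrom number of equally sized chromosomes.
#' @param bp_spacing base pairs between adjacent variants.
#' @param seed RNG seed (NULL = leave RNG state alone).
#' @return a \code{\link{geno_matrix}}.
#' @export
simulate_genotypes <- function(n, m, freq_spec = NULL, ld_rho = 0,
                               maf = 0.05, n_chrom = 1, bp_spacing = 1000,
                               seed = NULL) {
  if (maf <= 0) stop("maf must be positive")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0,1)")
  if (!is.null(seed)) set.seed(seed)
  p <- if (is.null(freq_spec)) stats::runif(m, maf, 1 - maf)
       else if (is.function(freq_spec)) freq_spec(m)
       else rep_len(freq_spec, m)
  stopifnot(all(p > 0 & p < 1))
  chrom <- sort(rep_len(seq_len(n_chrom), m))
  thr <- stats::qnorm(p)
  hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (ld_rho > 0) {
      sc <- sqrt(1 - ld_rho^2)
      for (j in 2:m) {
        if (chrom[j] == chrom[j - 1])
          z[, j] <- ld_rho * z[, j - 1] + sc * z[, j]
      }
    }
    sweep(z, 2, thr, "<") * 1L
  }
  d <- hap() + hap()
  pos_in_chrom <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  geno_matrix(d, chrom = as.character(chrom),
              pos_bp = as.integer(pos_in_chrom * bp_spacing))
}

#' Simulate SNP effects from the four-component mixture
#'
#' Classes are multinomial with probabilities \code{pr_true}; effects are
#' N(0, gamma_k sigma_g2) given the class (the spike gives exactly 0).
#' Effects are on the standardized-genotype scale. Optionally a set of
#' planted QTL is forced into the largest-variance class, and the effect
#' vector is rescaled so the planted QTL carry \code{qtl_var_frac} of a
#' total genic variance of \code{scale_to} (scaling preserves classes; with
#' \code{scale_to = NULL} the raw mixture draws are returned).
#'
#' @param m number of variants. @param pr_true mixture proportions.
#' @param sigma_g2 additive genetic variance. @param gamma class scalings.
#' @param n_qtl planted large-effect QTL count.
#' @param qtl_var_frac fraction of genic variance carried by planted QTL.
#' @param scale_to total genic variance (sum of squared standardized
#'   effects) to rescale to; \code{NULL} for no rescaling.
#' @param seed RNG seed.
#' @return list of class \code{"sim_truth"}: \code{g_true},
#'   \code{class_true}, \code{qtl_ids} (indices), \code{pr_true},
#'   \code{sigma_g2}.
#' @export
simulate_effects <- function(m, pr_true = c(0.99, 0.007, 0.002, 0.001),
                             sigma_g2 = 1, gamma = c(0, 1e-4, 1e-3, 1e-2),
                             n_qtl = 0, qtl_var_frac = 0, scale_to = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(pr_true) == 4, all(pr_true >= 0), n_qtl >= 0,
            qtl_var_frac >= 0, qtl_var_frac <= 1)
  pr_true <- pr_true / sum(pr_true)
  cls <- sample.int(4, m, replace = TRUE, prob = pr_true)
  g <- numeric(m)
  slab <- cls > 1
  g[slab] <- stats::rnorm(sum(slab), 0, sqrt(gamma[cls[slab]] * sigma_g2))
  qtl_ids <- integer(0)
  if (n_qtl > 0) {
    qtl_ids <- sample.int(m, n_qtl)
    cls[qtl_ids] <- 4L
    g[qtl_ids] <- stats::rnorm(n_qtl, 0, sqrt(gamma[4] * sigma_g2))
  }
  if (!is.null(scale_to)) {
    if (n_qtl > 0 && qtl_var_frac > 0) {
      vq <- sum(g[qtl_ids]^2)
      rest <- setdiff(which(g != 0), qtl_ids)
      vr <- sum(g[rest]^2)
      if (vq > 0) g[qtl_ids] <- g[qtl_ids] * sqrt(qtl_var_frac * scale_to / vq)
      if (vr > 0) g[rest] <- g[rest] * sqrt((1 - qtl_var_frac) * scale_to / vr)
    } else {
      vt <- sum(g^2)
      if (vt > 0) g <- g * sqrt(scale_to / vt)
    }
  }
  structure(list(g_true = g, class_true = cls, qtl_ids = qtl_ids,
                 pr_true = pr_true, sigma_g2 = sigma_g2, gamma = gamma),
            class = "sim_truth")
}

#' Simulate bull/cow phenotypes under the marker model
#'
#' y = X beta + Zs g_true + v + e, with v ~ N(0, A sigma_a2) and
#' e_i ~ N(0, sigma_e2 / w_i) where the record weight w_i follows the bull /
#' cow information formulas (\code{\link{garrick_weight}}) from simulated
#' daughter counts d (bulls) and record counts r (cows). Animals are bulls
#' with probability \code{sex_mix}; bull daughter counts are 1 + Poisson(49)
#' (mean 50) and cow record counts 1 + Poisson(2) (mean 3 lactations).
#'
#' @param geno a \code{geno_matrix} (or a pre-standardized matrix with
#'   attribute-free columns, taken as Zs directly).
#' @param truth a \code{\link{simulate_effects}} result.
#' @param vc \code{\link{variance_components}} (supplies sigma_a2, sigma_e2,
#'   repeatability t and c_frac; h2 for the weights is computed from vc).
#' @param pedigree optional pedigree data frame for A (default unrelated:
#'   A = I).
#' @param sex_mix proportion of bulls. @param beta_true fixed effects for
#'   the mean and (if present) sex contrast.
#' @param breeds number of equally likely breeds (adds breed fixed effects).
#' @param h2_weights heritability plugged into the weight formulas (default
#'   \code{vc$h2}); exposed so a study can weight records by a nominal
#'   target while the generating variances are calibrated separately.
#' @param seed RNG seed.
#' @return data frame of class \code{"sim_pheno"} with columns
#'   \code{animal_id, trait_value, sex, breed, d, r, weight}; attributes
#'   \code{X}, \code{beta_true}, \code{v_true}, \code{E_diag},
#'   \code{h2_realized} and \code{components} (realized variance parts).
#' @export
simulate_phenotypes <- function(geno, truth, vc, pedigree = NULL,
                                sex_mix = 0.5, beta_true = NULL,
                                breeds = 1, h2_weights = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Zs <- if (inherits(geno, "geno_matrix")) standardize_genotypes(geno)
        else as.matrix(geno)
  n <- nrow(Zs)
  h2 <- h2_weights %||% vc$h2
  sex <- ifelse(stats::runif(n) < sex_mix, "bull", "cow")
  d <- ifelse(sex == "bull", 1 + stats::rpois(n, 49), NA)
  r <- ifelse(sex == "cow", 1 + stats::rpois(n, 2), NA)
  w <- numeric(n)
  is_b <- sex == "bull"
  if (any(is_b))
    w[is_b] <- garrick_weight("bull", h2, vc$c_frac, d = d[is_b])
  if (any(!is_b))
    w[!is_b] <- garrick_weight("cow", h2, vc$c_frac, r = r[!is_b], t = vc$t)
  breed <- if (breeds > 1)
    paste0("breed", sample.int(breeds, n, replace = TRUE)) else "breed1"
  pheno <- data.frame(animal_id = rownames(Zs) %||% paste0("id", seq_len(n)),
                      sex = sex, breed = breed, d = d, r = r, weight = w,
                      stringsAsFactors = FALSE)
  des <- build_fixed_design(pheno)
  X <- des$X
  if (is.null(beta_true)) {
    beta_true <- c(1, rep(0.5, ncol(X) - 1))
  }
  beta_true <- rep_len(beta_true, ncol(X))
  v <- numeric(n)
  if (vc$sigma_a2 > 0) {
    if (!is.null(pedigree)) {
      A <- build_nrm(pedigree)
      A <- A[pheno$animal_id, pheno$animal_id]
      v <- drop(crossprod(chol(A), stats::rnorm(n))) * sqrt(vc$sigma_a2)
    } else {
      v <- stats::rnorm(n, 0, sqrt(vc$sigma_a2))
    }
  }
  zg <- drop(Zs %*% truth$g_true)
  e <- stats::rnorm(n, 0, sqrt(vc$sigma_e2 / w))
  y <- drop(X %*% beta_true) + zg + v + e
  pheno$trait_value <- y
  var_g <- stats::var(zg)
  comp <- c(genic = var_g, polygenic = stats::var(v), error = stats::var(e))
  attr(pheno, "X") <- X
  attr(pheno, "beta_true") <- beta_true
  attr(pheno, "v_true") <- v
  attr(pheno, "E_diag") <- build_error_matrix(w)
  attr(pheno, "h2_realized") <- var_g / sum(comp)
  attr(pheno, "components") <- comp
  class(pheno) <- c("sim_pheno", class(pheno))
  pheno
}

#' Simulate a complete reference/validation study
#'
#' The one-call generator behind the package's validation studies: a
#' multi-breed-style reference population with heterogeneous bull/cow
#' record precision, a four-class SNP-effect architecture, and an optional
#' set of planted QTL. Effects are rescaled so the genic variance equals
#' sigma_g2 exactly, and the error variance is calibrated against the
#' realized genic variance and the mean error multiplier so the expected
#' heritability matches \code{h2}.
#'
#' @param n animals (reference + validation). @param m variants.
#' @param h2 target heritability.
#' @param pr_true true mixture proportions.
#' @param sigma_g2 genic variance (scale of the trait).
#' @param polygenic_frac fraction of total variance that is pedigree
#'   polygenic (default 0).
#' @param n_qtl,qtl_var_frac planted QTL and their genic-variance share.
#' @param ld_rho,maf,n_chrom,sex_mix,breeds passed to the generators.
#' @param n_val validation-set size (last animals; 0 for none).
#' @param seed RNG seed controlling the whole pipeline.
#' @return list with \code{geno}, \code{Zs}, \code{truth}, \code{pheno},
#'   \code{y}, \code{X}, \code{E_diag}, \code{vc}, index vectors
#'   \code{ref}/\code{val}, and the validation-standardized genotypes.
#' @export
sim_dataset <- function(n = 2000, m = 5000, h2 = 0.4,
                        pr_true = c(0.99, 0.007, 0.002, 0.001),
                        sigma_g2 = 1, polygenic_frac = 0,
                        n_qtl = 0, qtl_var_frac = 0,
                        ld_rho = 0, maf = 0.05, n_chrom = 1,
                        sex_mix = 0.5, breeds = 1, n_val = 0, seed = 1) {
  set.seed(seed)
  geno <- simulate_genotypes(n, m, ld_rho = ld_rho, maf = maf,
                             n_chrom = n_chrom)
  truth <- simulate_effects(m, pr_true = pr_true, sigma_g2 = sigma_g2,
                            n_qtl = n_qtl, qtl_var_frac = qtl_var_frac,
                            scale_to = sigma_g2)
  Zs <- standardize_genotypes(geno)
  if (length(attr(Zs, "kept")) < m) {
    keep <- attr(Zs, "kept")
    truth$g_true <- truth$g_true[keep]
    truth$class_true <- truth$class_true[keep]
    truth$qtl_ids <- match(intersect(truth$qtl_ids, keep), keep)
  }
  # calibrate variances against the realized genic variance and the mean
  # error multiplier so the expected heritability hits the target:
  # h2 = var_g / (var_g + sa2 + mean_i Var(e_i)), Var(e_i) = sigma_e2 / w_i
  var_g <- stats::var(drop(Zs %*% truth$g_true))
  if (var_g == 0)
    stop("simulated architecture drew no nonzero effects; ",
         "increase m or the slab proportions")
  tot <- var_g / h2
  sigma_a2 <- polygenic_frac * tot
  mean_err_target <- tot - var_g - sigma_a2
  if (mean_err_target <= 0) stop("h2 + polygenic_frac too close to 1")
  set.seed(seed + 1L)
  tmp_sex <- ifelse(stats::runif(n) < sex_mix, "bull", "cow")
  tmp_d <- 1 + stats::rpois(n, 49); tmp_r <- 1 + stats::rpois(n, 2)
  wtmp <- ifelse(tmp_sex == "bull",
                 garrick_weight("bull", h2, 0.1, d = tmp_d),
                 garrick_weight("cow", h2, 0.1, r = tmp_r, t = 0.5))
  sigma_e2 <- mean_err_target / mean(1 / wtmp)
  vc <- variance_components(sigma_g2 = var_g, sigma_a2 = sigma_a2,
                            sigma_e2 = sigma_e2, t = 0.5)
  set.seed(seed + 1L)  # same sex/d/r stream as the weight calibration
  pheno <- simulate_phenotypes(Zs, truth, vc, sex_mix = sex_mix,
                               breeds = breeds, h2_weights = h2)
  idx_val <- if (n_val > 0) seq.int(n - n_val + 1, n) else integer(0)
  idx_ref <- setdiff(seq_len(n), idx_val)
  list(geno = geno, Zs = Zs, truth = truth, pheno = pheno,
       y = pheno$trait_value, X = attr(pheno, "X"),
       E_diag = attr(pheno, "E_diag"), vc = vc,
       h2_realized = attr(pheno, "h2_realized"),
       ref = idx_ref, val = idx_val, seed = seed)
}
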