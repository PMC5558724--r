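#' Solve the GBLUP mixed-model equations
#'
#' Fits y = X beta + u + v + e with u ~ N(0, G sigma_g^2),
#' v ~ N(0, A sigma_a^2) and e ~ N(0, E sigma_e^2) (E diagonal) by direct
#' solution of Henderson's mixed-model equations. Each phenotyped animal
#' carries one record, so the genetic and polygenic incidence matrices are
#' identities. The inverse coefficient matrix is retained so prediction
#' error variances are available. Blocks whose variance is 0 are dropped
#' (their effects are identically 0).
#'
#' @param y numeric phenotype vector (length n).
#' @param X fixed-effect design (n x b) or NULL for no fixed effects.
#' @param G genomic relationship matrix (n x n), invertible (ridged).
#' @param A pedigree relationship matrix (n x n) or NULL when
#'   \code{sigma_a2 = 0}.
#' @param E_diag diagonal of the error matrix (default 1: homogeneous).
#' @param vc a \code{\link{variance_components}} object or list with
#'   \code{sigma_g2}, \code{sigma_a2}, \code{sigma_e2}.
#' @return object of class \code{"mme_solution"}: list with \code{beta},
#'   \code{u}, \code{v}, \code{PEV_u} (matrix), \code{fitted},
#'   \code{residuals}, plus inputs needed downstream (\code{G}, \code{vc}).
#' @examples
#' G <- diag(3); y <- c(1, 2, 3)
#' s <- solve_mme(y, matrix(1, 3, 1), G, vc = list(sigma_g2 = 1,
#'                sigma_a2 = 0, sigma_e2 = 1))
#' @export
solve_mme <- function(y, X, G, A = NULL, E_diag = 1, vc) {
  n <- length(y)
  Ei <- rep_len(1 / E_diag, n)
  sg2 <- vc$sigma_g2; sa2 <- vc$sigma_a2; se2 <- vc$sigma_e2
  if (se2 <= 0) stop("sigma_e2 must be positive")
  use_u <- sg2 > 0
  use_v <- sa2 > 0
  if (use_v && is.null(A)) A <- diag(n)
  b <- if (is.null(X)) 0L else ncol(X)
  if (b > 0) stopifnot(nrow(X) == n)
  if (use_u) stopifnot(nrow(G) == n)

  blocks <- c(if (b > 0) "beta", if (use_u) "u", if (use_v) "v")
  sizes <- c(beta = b, u = if (use_u) n else 0, v = if (use_v) n else 0)
  p <- sum(sizes[blocks])
  if (p == 0) stop("nothing to estimate: no fixed effects and zero variances")
  M <- matrix(0, p, p)
  rhs <- numeric(p)
  off <- stats::setNames(cumsum(c(0, sizes[blocks]))[seq_along(blocks)], blocks)
  ix <- function(blk) off[[blk]] + seq_len(sizes[[blk]])

  EiX <- if (b > 0) X * Ei else NULL
  if (b > 0) {
    M[ix("beta"), ix("beta")] <- crossprod(X, EiX)
    rhs[ix("beta")] <- crossprod(EiX, y)
  }
  inv_or_fail <- function(S, name) {
    out <- tryCatch(solve(S), error = function(e)
      stop("singular ", name, " block in the mixed-model equations: ",
           conditionMessage(e)))
    out
  }
  if (use_u) {
    Ginv <- inv_or_fail(G, "G")
    M[ix("u"), ix("u")] <- Ginv * (se2 / sg2)
    idx <- ix("u")
    M[cbind(idx, idx)] <- M[cbind(idx, idx)] + Ei
    rhs[idx] <- Ei * y
    if (b > 0) {
      M[ix("beta"), idx] <- t(EiX)
      M[idx, ix("beta")] <- EiX
    }
  }
  if (use_v) {
    Ainv <- inv_or_fail(A, "A")
    M[ix("v"), ix("v")] <- Ainv * (se2 / sa2)
    idx <- ix("v")
    M[cbind(idx, idx)] <- M[cbind(idx, idx)] + Ei
    rhs[idx] <- Ei * y
    if (b > 0) {
      M[ix("beta"), idx] <- t(EiX)
      M[idx, ix("beta")] <- EiX
    }
    if (use_u) {
      iu <- ix("u")
      M[cbind(iu, idx)] <- Ei
      M[cbind(idx, iu)] <- Ei
    }
  }
  Cinv <- tryCatch(solve(M), error = function(e)
    stop("singular mixed-model coefficient matrix: ", conditionMessage(e)))
  sol <- Cinv %*% rhs
  beta <- if (b > 0) stats::setNames(drop(sol[ix("beta")]), colnames(X))
          else numeric(0)
  u <- if (use_u) unname(drop(sol[ix("u")])) else numeric(n)
  v <- if (use_v) unname(drop(sol[ix("v")])) else numeric(n)
  PEV_u <- if (use_u) se2 * Cinv[ix("u"), ix("u"), drop = FALSE] else
    matrix(0, n, n)
  if (use_u) dimnames(PEV_u) <- dimnames(G)
  fitted <- unname((if (b > 0) drop(X %*% beta) else 0) + u + v)
  structure(list(beta = beta, u = u, v = v, PEV_u = PEV_u,
                 fitted = fitted, residuals = y - fitted,
                 G = if (use_u) G else NULL, vc = vc, E_diag = 1 / Ei,
                 n = n),
            class = "mme_solution")
}

#' Prediction error variance of the genetic values
#'
#' Var(u - u_hat), read off the u-block of the inverted mixed-model
#' coefficient matrix scaled by sigma_e^2. With no data it equals the prior
#' variance sigma_g^2 G; with infinitely precise records it goes to 0.
#'
#' @param sol an \code{mme_solution}.
#' @param diag_only return just the diagonal.
#' @return matrix (or vector) of prediction error variances.
#' @export
compute_pev_u <- function(sol, diag_only = FALSE) {
  stopifnot(inherits(sol, "mme_solution"))
  if (diag_only) diag(sol$PEV_u) else sol$PEV_u
}

#' GEBV for animals without phenotypes
#'
#' Conditional-mean prediction GEBV_val = G_val_ref G_ref_ref^-1 u_hat,
#' the BLUP of the validation animals' genetic values given the reference
#' solutions. Both relationship blocks must come from the same variant set.
#'
#' @param sol an \code{mme_solution} fitted on the reference animals.
#' @param G_val_ref n_val x n_ref relationship block between validation and
#'   reference animals.
#' @return numeric GEBV vector for the validation animals.
#' @export
predict_gebv <- function(sol, G_val_ref) {
  stopifnot(inherits(sol, "mme_solution"))
  if (is.null(sol$G)) return(rep(0, nrow(G_val_ref)))
  if (ncol(G_val_ref) != sol$n)
    stop("G_val_ref has ", ncol(G_val_ref), " reference columns; expected ",
         sol$n, " (variant/animal set mismatch?)")
  unname(drop(G_val_ref %*% solve(sol$G, sol$u)))
}
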