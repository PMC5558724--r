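#' Genomic relationship matrix
#'
#' G = Zs Zs' / m from a standardized genotype matrix, m being the number of
#' retained variants. Dividing by the variant count gives an expected diagonal
#' near 1 in an outbred sample. A small ridge (default 1e-6) is added to the
#' diagonal so that G is safely invertible in the mixed-model equations.
#'
#' @param Zs standardized genotype matrix (see
#'   \code{\link{standardize_genotypes}}), animals in rows.
#' @param ridge diagonal ridge added for numerical invertibility; set 0 to
#'   disable.
#' @return symmetric n x n matrix with animal dimnames.
#' @export
build_grm <- function(Zs, ridge = 1e-6) {
  Zs <- as.matrix(Zs)
  m <- ncol(Zs)
  if (m == 0L) stop("cannot build G from 0 variants")
  G <- tcrossprod(Zs) / m
  if (ridge > 0) {
    diag(G) <- diag(G) + ridge
  }
  dimnames(G) <- list(rownames(Zs), rownames(Zs))
  G
}

#' Pedigree numerator relationship matrix
#'
#' Builds A by Henderson's tabular method: after a topological sort,
#' A_ii = 1 + 0.5 A_{sire,dam} and A_ij = 0.5 (A_{j,sire(i)} + A_{j,dam(i)}).
#' Unknown parents (NA, "", "0") are treated as unrelated founders. Pedigree
#' cycles are an error.
#'
#' @param ped data frame with columns \code{animal_id}, \code{sire_id},
#'   \code{dam_id} (extra columns ignored). Parents that never appear as
#'   animals are added as founders.
#' @return symmetric q x q matrix with animal ids as dimnames, ordered
#'   parents-before-offspring.
#' @examples
#' ped <- data.frame(animal_id = c("s", "d", "o"),
#'                   sire_id = c(NA, NA, "s"), dam_id = c(NA, NA, "d"))
#' build_nrm(ped)["s", "o"]  # 0.5
#' @export
build_nrm <- function(ped) {
  ped <- as.data.frame(ped)
  cn <- c("animal_id", "sire_id", "dam_id")
  if (!all(cn %in% names(ped))) names(ped)[1:3] <- cn
  norm_id <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", ".", "NA")] <- NA_character_
    x
  }
  anm <- norm_id(ped$animal_id); sire <- norm_id(ped$sire_id)
  dam <- norm_id(ped$dam_id)
  if (anyDuplicated(anm)) stop("duplicate animal ids in pedigree")
  extra <- setdiff(stats::na.omit(c(sire, dam)), anm)
  anm <- c(extra, anm)
  sire <- c(rep(NA_character_, length(extra)), sire)
  dam <- c(rep(NA_character_, length(extra)), dam)
  q <- length(anm)
  idx <- stats::setNames(seq_len(q), anm)
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  # Kahn topological sort; a leftover node means a cycle
  order_out <- integer(0)
  placed <- logical(q)
  repeat {
    ready <- which(!placed &
                   (si == 0L | placed[pmax(si, 1L)] | si == 0L) &
                   (di == 0L | placed[pmax(di, 1L)]))
    ready <- ready[ (si[ready] == 0L | placed[pmax(si[ready], 1L)]) &
                    (di[ready] == 0L | placed[pmax(di[ready], 1L)]) ]
    if (!length(ready)) break
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
  }
  if (length(order_out) < q) stop("pedigree contains a cycle")
  A <- matrix(0, q, q)
  pos <- integer(q)          # original index -> position in A
  for (step in seq_len(q)) {
    i <- order_out[step]
    pos[i] <- step
    s <- if (si[i] > 0L) pos[si[i]] else 0L
    d <- if (di[i] > 0L) pos[di[i]] else 0L
    if (step > 1L) {
      prev <- seq_len(step - 1L)
      row_i <- numeric(step - 1L)
      if (s > 0L) row_i <- row_i + 0.5 * A[prev, s]
      if (d > 0L) row_i <- row_i + 0.5 * A[prev, d]
      A[prev, step] <- row_i
      A[step, prev] <- row_i
    }
    A[step, step] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  ids_sorted <- anm[order_out]
  dimnames(A) <- list(ids_sorted, ids_sorted)
  A
}
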