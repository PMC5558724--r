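#' Posterior probability of the largest-variance class
#'
#' Returns P(i,4) per variant -- the posterior probability that variant i
#' belongs to the mixture component with variance 0.01 sigma_g^2 -- with map
#' coordinates attached for Manhattan-style plotting. This is the QTL-mapping
#' signal used to rank variants.
#'
#' @param summary a \code{"bayesr_posterior"} (or any object with an m x 4
#'   \code{P} element).
#' @param map optional data frame with \code{variant_id}, \code{chrom},
#'   \code{pos_bp} (one row per variant).
#' @return data frame with \code{variant_id}, \code{chrom}, \code{pos_bp},
#'   \code{q4} and \code{g_mean}.
#' @export
top_class_probability <- function(summary, map = NULL) {
  P <- summary$P
  m <- nrow(P)
  if (is.null(map))
    map <- data.frame(variant_id = paste0("snp", seq_len(m)),
                      chrom = "1", pos_bp = seq_len(m))
  stopifnot(nrow(map) == m)
  data.frame(variant_id = map$variant_id, chrom = map$chrom,
             pos_bp = map$pos_bp, q4 = P[, 4],
             g_mean = summary$g_mean %||% rep(NA_real_, m))
}

#' Posterior-probability threshold for QTL reporting
#'
#' The threshold is chosen so that the number of variants at or above it
#' equals the expected number of variants in the largest-variance class,
#' N4 = round(Pr4 * m): i.e. the N4-th largest value of q4. With N4 = 0 the
#' threshold is the maximum (empty report); with N4 >= m it is the minimum.
#'
#' @param q4 vector of largest-class posterior probabilities.
#' @param pr_mean posterior-mean mixture proportions (length 4).
#' @param m number of variants (default \code{length(q4)}).
#' @return scalar threshold with attribute \code{"n4"}.
#' @export
qtl_threshold <- function(q4, pr_mean, m = length(q4)) {
  n4 <- round(pr_mean[4] * m)
  thr <- if (n4 <= 0) {
    message("expected largest-class count is 0; report will be empty")
    max(q4)
  } else if (n4 >= length(q4)) {
    min(q4)
  } else {
    sort(q4, decreasing = TRUE)[n4]
  }
  attr(thr, "n4") <- n4
  thr
}

#' Top-variant QTL report
#'
#' Variants with q4 >= threshold, sorted by q4 descending with ties broken
#' by (chrom, pos). When the expected largest-class count is zero an empty
#' table (with header columns) is returned.
#'
#' @param q4_table output of \code{\link{top_class_probability}}.
#' @param threshold from \code{\link{qtl_threshold}} (or a fixed value).
#' @param empty force an empty report (used when N4 = 0).
#' @return data frame \code{variant_id, chrom, pos_bp, q4, g_mean}.
#' @export
top_variants_report <- function(q4_table, threshold, empty = FALSE) {
  n4 <- attr(threshold, "n4")
  if (isTRUE(empty) || (!is.null(n4) && n4 == 0))
    return(q4_table[0, , drop = FALSE])
  keep <- q4_table$q4 >= as.numeric(threshold)
  out <- q4_table[keep, , drop = FALSE]
  out[order(-out$q4, out$chrom, out$pos_bp), , drop = FALSE]
}

#' Window-level aggregation of QTL signal
#'
#' Optional summary over fixed-width genomic windows: per window, the max
#' and sum of q4 and the variant attaining the max. Off the main path;
#' useful when single-variant signal is spread over LD neighbours.
#'
#' @param q4_table output of \code{\link{top_class_probability}}.
#' @param window_kb window width in kilobases (default 250).
#' @return data frame, one row per non-empty window.
#' @export
qtl_windows <- function(q4_table, window_kb = 250) {
  w <- window_kb * 1000
  win <- floor((q4_table$pos_bp - 1) / w)
  key <- paste(q4_table$chrom, win, sep = ":")
  parts <- split(q4_table, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    top <- which.max(d$q4)
    data.frame(chrom = d$chrom[1],
               start_bp = min(d$pos_bp), end_bp = max(d$pos_bp),
               n_variants = nrow(d), q4_max = d$q4[top],
               q4_sum = sum(d$q4), top_variant = d$variant_id[top])
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}
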