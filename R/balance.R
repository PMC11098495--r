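#' Iterative correction (matrix balancing) weights
#'
#' Computes per-bin multiplicative weights so that the balanced matrix
#' `count * w_i * w_j` has (approximately) equal marginals over surviving
#' bins. This is fixture-grade plumbing: analyses in this package consume
#' weights, they do not produce them, and files balanced by other software are
#' used as-is.
#'
#' Bins whose raw marginal falls below the `filter_quantile` quantile of the
#' nonzero marginals (or is zero) are dropped and receive a missing weight.
#' After convergence, weights are rescaled so the mean nonzero balanced pixel
#' value is 1 (documented convention; wild-type cooler files differ).
#'
#' @param store A `ContactStore`.
#' @param max_iter Maximum iterations (default 300).
#' @param tol Convergence: max relative deviation of surviving marginals from
#'   their mean (default 1e-6).
#' @param filter_quantile Marginal-count quantile below which bins are dropped
#'   (default 0.02).
#' @return Numeric weight vector, `NA` for dropped bins.
#' @export
iterative_correction <- function(store, max_iter = 300L, tol = 1e-6,
                                 filter_quantile = 0.02) {
  M <- store_sparse(store)
  marg <- Matrix::rowSums(M)
  nz <- marg[marg > 0]
  cut <- if (length(nz)) stats::quantile(nz, filter_quantile, names = FALSE) else Inf
  good <- marg > 0 & marg >= cut

  v <- as.numeric(good)
  for (it in seq_len(max_iter)) {
    m <- v * as.vector(M %*% v)
    mg <- m[good]
    mbar <- mean(mg)
    if (mbar == 0) break
    if (max(abs(mg / mbar - 1)) < tol) break
    adj <- rep(1, length(v))
    adj[good] <- mg / mbar
    v <- v / sqrt(adj)
  }
  v[!good] <- NA_real_

  # scale: mean nonzero balanced pixel value = 1
  px <- read_pixels(store)
  bw <- v[px$bin1_id + 1L] * v[px$bin2_id + 1L] * px$count
  s <- mean(bw[!is.na(bw) & bw > 0])
  if (is.finite(s) && s > 0) v <- v / sqrt(s)
  v
}
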