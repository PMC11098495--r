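#' Average contact frequency by distance (cis expected)
#'
#' Computes, per view region, the average contact frequency at every genomic
#' separation `d` (in bins), iterating over chunks of the sparse pixel table
#' and accounting exactly for masked (bad) bins: `n_valid(d)` counts the bin
#' pairs `(i, i+d)` inside the region with both bins valid, and averages
#' divide by it, so filtered rows never dilute the curve. Pairs of distinct
#' regions on the same chromosome (e.g. p and q arms) are reported as
#' rectangle records without a distance index.
#'
#' @param store A balanced `ContactStore`.
#' @param view A genomic view from [make_view()] (default: whole chromosomes).
#' @param use_weights Use balancing weights (see [store_weights()]); `FALSE`
#'   computes raw-count expected only.
#' @param smooth Fill `balanced_avg_smoothed` via [smooth_expected()].
#' @param sigma_log10,aggregate,min_dist Smoothing parameters, see
#'   [smooth_expected()].
#' @param chunk_size Pixels per chunk.
#' @return data.frame with columns `region1`, `region2`, `dist` (bins; `NA`
#'   for rectangle records), `n_valid`, `count_sum`, `balanced_sum`,
#'   `count_avg`, `balanced_avg`, `balanced_avg_smoothed`.
#' @export
expected_cis <- function(store, view = make_view(store), use_weights = TRUE,
                         smooth = TRUE, sigma_log10 = 0.1, aggregate = TRUE,
                         min_dist = 2L, chunk_size = 1e7) {
  validate_view(view, store$chroms)
  vb <- view_bins(store, view)
  nreg <- nrow(view)
  reg_of_bin <- rep(NA_integer_, store$nbins)
  for (k in seq_len(nreg)) reg_of_bin[vb[[k]] + 1L] <- k
  w <- store_weights(store, use_weights)
  lens <- lengths(vb)
  ndmax <- max(lens)

  # per-(region, distance) accumulators, flattened
  acc_cnt <- numeric(nreg * ndmax)
  acc_bal <- numeric(nreg * ndmax)
  # same-chromosome inter-region rectangles
  pair_key <- character(0)
  pair_cnt <- pair_bal <- numeric(0)

  first_bin <- vapply(vb, function(b) if (length(b)) b[1L] else NA_integer_, 0L)
  pixel_chunks(store, chunk_size = chunk_size, fun = function(px) {
    r1 <- reg_of_bin[px$bin1_id + 1L]
    r2 <- reg_of_bin[px$bin2_id + 1L]
    keep <- !is.na(r1) & !is.na(r2)
    if (!any(keep)) return(NULL)
    px <- px[keep, ]; r1 <- r1[keep]; r2 <- r2[keep]
    bal <- px$count * w[px$bin1_id + 1L] * w[px$bin2_id + 1L]
    intra <- r1 == r2
    if (any(intra)) {
      d <- px$bin2_id[intra] - px$bin1_id[intra]
      key <- (r1[intra] - 1L) * ndmax + d + 1L
      acc_cnt <<- acc_cnt + rowsum_fill(px$count[intra], key, nreg * ndmax)
      bi <- bal[intra]
      ok <- !is.na(bi)
      acc_bal <<- acc_bal + rowsum_fill(bi[ok], key[ok], nreg * ndmax)
    }
    inter <- !intra & view$chrom[r1] == view$chrom[r2]
    if (any(inter)) {
      pk <- paste(pmin(r1[inter], r2[inter]), pmax(r1[inter], r2[inter]))
      cs <- rowsum(px$count[inter], pk)
      bi <- bal[inter]
      bs <- rowsum(ifelse(is.na(bi), 0, bi), pk)
      for (u in rownames(cs)) {
        j <- match(u, pair_key)
        if (is.na(j)) {
          pair_key <<- c(pair_key, u)
          pair_cnt <<- c(pair_cnt, cs[u, 1L])
          pair_bal <<- c(pair_bal, bs[u, 1L])
        } else {
          pair_cnt[j] <<- pair_cnt[j] + cs[u, 1L]
          pair_bal[j] <<- pair_bal[j] + bs[u, 1L]
        }
      }
    }
    NULL
  })

  rows <- vector("list", nreg)
  for (k in seq_len(nreg)) {
    n <- lens[k]
    val <- !is.na(w[vb[[k]] + 1L])
    nv <- vapply(0:(n - 1L), function(d) sum(val[seq_len(n - d)] & val[seq_len(n - d) + d]), 0)
    idx <- (k - 1L) * ndmax + seq_len(n)
    rows[[k]] <- data.frame(
      region1 = view$name[k], region2 = view$name[k], dist = 0:(n - 1L),
      n_valid = nv, count_sum = acc_cnt[idx], balanced_sum = acc_bal[idx],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)

  if (length(pair_key)) {
    ij <- do.call(rbind, lapply(strsplit(pair_key, " "), as.integer))
    nv1 <- vapply(ij[, 1L], function(k) sum(!is.na(w[vb[[k]] + 1L])), 0)
    nv2 <- vapply(ij[, 2L], function(k) sum(!is.na(w[vb[[k]] + 1L])), 0)
    rect <- data.frame(
      region1 = view$name[ij[, 1L]], region2 = view$name[ij[, 2L]],
      dist = NA_integer_, n_valid = nv1 * nv2,
      count_sum = pair_cnt, balanced_sum = pair_bal, stringsAsFactors = FALSE)
    rect <- rect[order(match(rect$region1, view$name), match(rect$region2, view$name)), ]
    out <- rbind(out, rect)
  }
  out$count_avg <- ifelse(out$n_valid > 0, out$count_sum / out$n_valid, NA_real_)
  out$balanced_avg <- ifelse(out$n_valid > 0, out$balanced_sum / out$n_valid, NA_real_)
  out$balanced_avg_smoothed <- NA_real_
  rownames(out) <- NULL
  if (smooth)
    out <- smooth_expected(out, sigma_log10 = sigma_log10,
                           aggregate = aggregate, min_dist = min_dist)
  out
}

rowsum_fill <- function(x, key, n) {
  out <- numeric(n)
  if (length(x)) {
    rs <- rowsum(x, key)
    out[as.integer(rownames(rs))] <- rs[, 1L]
  }
  out
}

#' Average contact frequency between chromosomes (trans expected)
#'
#' One record per unordered pair of view regions on different chromosomes;
#' the average is the total (balanced) sum over the region1 x region2
#' rectangle divided by the number of pairs with both bins valid.
#'
#' @inheritParams expected_cis
#' @return data.frame with `region1`, `region2`, `n_valid`, `count_sum`,
#'   `balanced_sum`, `count_avg`, `balanced_avg`.
#' @export
expected_trans <- function(store, view = make_view(store), use_weights = TRUE,
                           chunk_size = 1e7) {
  validate_view(view, store$chroms)
  vb <- view_bins(store, view)
  nreg <- nrow(view)
  reg_of_bin <- rep(NA_integer_, store$nbins)
  for (k in seq_len(nreg)) reg_of_bin[vb[[k]] + 1L] <- k
  w <- store_weights(store, use_weights)

  cnt <- bal <- matrix(0, nreg, nreg)
  pixel_chunks(store, chunk_size = chunk_size, fun = function(px) {
    r1 <- reg_of_bin[px$bin1_id + 1L]
    r2 <- reg_of_bin[px$bin2_id + 1L]
    keep <- !is.na(r1) & !is.na(r2) &
      view$chrom[pmax(r1, 1L)] != view$chrom[pmax(r2, 1L)]
    if (!any(keep)) return(NULL)
    i <- pmin(r1[keep], r2[keep]); j <- pmax(r1[keep], r2[keep])
    b <- px$count[keep] * w[px$bin1_id[keep] + 1L] * w[px$bin2_id[keep] + 1L]
    for (u in seq_along(i)) {
      cnt[i[u], j[u]] <<- cnt[i[u], j[u]] + px$count[keep][u]
      if (!is.na(b[u])) bal[i[u], j[u]] <<- bal[i[u], j[u]] + b[u]
    }
    NULL
  })

  nvalid_reg <- vapply(vb, function(b) sum(!is.na(w[b + 1L])), 0)
  rows <- list()
  for (i in seq_len(nreg)) for (j in seq_len(nreg)) {
    if (j <= i || view$chrom[i] == view$chrom[j]) next
    nv <- nvalid_reg[i] * nvalid_reg[j]
    rows[[length(rows) + 1L]] <- data.frame(
      region1 = view$name[i], region2 = view$name[j], n_valid = nv,
      count_sum = cnt[i, j], balanced_sum = bal[i, j],
      count_avg = if (nv > 0) cnt[i, j] / nv else NA_real_,
      balanced_avg = if (nv > 0) bal[i, j] / nv else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Smooth P(s) curves in log space
#'
#' Replaces the per-distance average with a Gaussian-kernel weighted mean in
#' `log10(d)`, with kernel weights multiplied by `n_valid` so that sparsely
#' sampled distances borrow strength from their neighbours
#' (`smoothed(d) = sum K * balanced_sum / sum K * n_valid`). Distances below
#' `min_dist` (and `d = 0`) pass through unsmoothed: the first diagonals are
#' dominated by ligation artifacts and are excluded from the kernel support.
#'
#' @param tbl An expected table from [expected_cis()].
#' @param sigma_log10 Kernel width in decades of distance (default 0.1),
#'   truncated at 3 sigma.
#' @param aggregate Pool `balanced_sum` and `n_valid` across regions before
#'   smoothing, yielding one genome-wide curve written back to every region's
#'   rows (default TRUE); `FALSE` smooths each region separately.
#' @param min_dist Smallest distance (bins) entering the kernel (default 2).
#' @return `tbl` with `balanced_avg_smoothed` filled for cis records.
#' @export
smooth_expected <- function(tbl, sigma_log10 = 0.1, aggregate = TRUE,
                            min_dist = 2L) {
  cis <- !is.na(tbl$dist) & tbl$region1 == tbl$region2
  tbl$balanced_avg_smoothed <- NA_real_
  smooth_one <- function(d, bs, nv) {
    ok <- d >= min_dist & nv > 0
    ld <- log10(d[ok])
    sm <- rep(NA_real_, length(d))
    if (any(ok)) {
      for (u in which(d >= min_dist)) {
        kd <- abs(log10(d[u]) - ld)
        kk <- kd <= 3 * sigma_log10
        if (!any(kk)) next
        kw <- exp(-0.5 * (kd[kk] / sigma_log10)^2) * nv[ok][kk]
        den <- sum(kw)
        if (den > 0) sm[u] <- sum(exp(-0.5 * (kd[kk] / sigma_log10)^2) * bs[ok][kk]) / den
      }
    }
    passthru <- d < min_dist
    sm[passthru] <- ifelse(nv[passthru] > 0, bs[passthru] / nv[passthru], NA_real_)
    sm
  }
  if (aggregate) {
    sub <- tbl[cis, ]
    agg_bs <- rowsum(sub$balanced_sum, sub$dist)
    agg_nv <- rowsum(sub$n_valid, sub$dist)
    d <- as.numeric(rownames(agg_bs))
    sm <- smooth_one(d, agg_bs[, 1L], agg_nv[, 1L])
    tbl$balanced_avg_smoothed[cis] <- sm[match(tbl$dist[cis], d)]
  } else {
    for (r in unique(tbl$region1[cis])) {
      sel <- cis & tbl$region1 == r
      tbl$balanced_avg_smoothed[sel] <-
        smooth_one(tbl$dist[sel], tbl$balanced_sum[sel], tbl$n_valid[sel])
    }
  }
  tbl
}

#' Log-log derivative of P(s)
#'
#' Central finite differences of `log10 P` against `log10 s` on the smoothed
#' expected curve; one-sided at the endpoints, `NA` where P is missing or
#' non-positive.
#'
#' @param tbl Expected table with a smoothed column, or any data.frame with
#'   `dist` plus the value column.
#' @param value_col Column to differentiate (default `balanced_avg_smoothed`).
#' @param min_dist Smallest distance used (default 1; `d = 0` has no log).
#' @return data.frame with `region1`, `dist`, `slope`.
#' @export
logderiv_expected <- function(tbl, value_col = "balanced_avg_smoothed",
                              min_dist = 1L) {
  if (is.null(tbl$region1)) tbl$region1 <- "all"
  cis <- if (!is.null(tbl$region2)) tbl$region1 == tbl$region2 & !is.na(tbl$dist)
         else !is.na(tbl$dist)
  out <- list()
  for (r in unique(tbl$region1[cis])) {
    sub <- tbl[cis & tbl$region1 == r, ]
    sub <- sub[sub$dist >= min_dist & is.finite(sub[[value_col]]) &
                 sub[[value_col]] > 0, ]
    if (nrow(sub) < 2L) next
    lx <- log10(sub$dist)
    ly <- log10(sub[[value_col]])
    n <- length(lx)
    sl <- rep(NA_real_, n)
    if (n >= 2L) {
      sl[1L] <- (ly[2L] - ly[1L]) / (lx[2L] - lx[1L])
      sl[n] <- (ly[n] - ly[n - 1L]) / (lx[n] - lx[n - 1L])
      if (n > 2L) {
        i <- 2:(n - 1L)
        sl[i] <- (ly[i + 1L] - ly[i - 1L]) / (lx[i + 1L] - lx[i - 1L])
      }
    }
    out[[length(out) + 1L]] <- data.frame(region1 = r, dist = sub$dist,
                                          slope = sl, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(region1 = character(), dist = numeric(),
                                      slope = numeric()))
  do.call(rbind, out)
}
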