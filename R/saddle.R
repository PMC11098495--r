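#' Digitize a track into quantile classes
#'
#' Assigns each valid bin to one of `n_classes` classes delimited by
#' quantiles of the valid track values linearly spaced between `lo_q` and
#' `hi_q`. Values below the lowest edge get the outlier class 0, values above
#' the highest edge get class `n_classes + 1`; invalid bins stay NA.
#'
#' @param track Bin-aligned data.frame with a `value` column.
#' @param n_classes Number of classes (default 5).
#' @param lo_q,hi_q Quantile range delimiting the classes (defaults 0.025 and
#'   0.975, trimming outlier bins into classes 0 and n+1).
#' @param mode `"quantile"` (default) or `"value"` for equal-width-by-value
#'   edges between the `lo_q`/`hi_q` quantiles.
#' @return The track with a `class` integer column plus attribute `edges`.
#' @export
digitize_track <- function(track, n_classes = 5L, lo_q = 0.025, hi_q = 0.975,
                           mode = c("quantile", "value")) {
  mode <- match.arg(mode)
  x <- track$value
  ok <- !is.na(x)
  if (!any(ok)) stop("track has no valid values")
  qs <- seq(lo_q, hi_q, length.out = n_classes + 1L)
  edges <- if (mode == "quantile") stats::quantile(x[ok], qs, names = FALSE)
           else seq(stats::quantile(x[ok], lo_q), stats::quantile(x[ok], hi_q),
                    length.out = n_classes + 1L)
  if (any(diff(edges) <= 0))
    stop("degenerate class edges (track too discrete or constant)")
  cls <- rep(NA_integer_, length(x))
  cls[ok] <- findInterval(x[ok], edges, rightmost.closed = TRUE)
  track$class <- cls
  attr(track, "edges") <- edges
  attr(track, "n_classes") <- as.integer(n_classes)
  track
}

#' Saddle aggregation: mean O/E per pair of track classes
#'
#' For every usable bin pair (both bins valid and in an in-range class) the
#' observed/expected value is accumulated into the class pair of its two
#' bins, in both orders, and class-pair means are returned. Sums come from a
#' chunked scan of the sparse pixel table; the pair counts `C` are computed
#' combinatorially over all valid bin pairs, so unstored (zero) pixels
#' correctly enter the denominator. In `cis` scale, O/E uses the
#' distance-indexed expected of the pixel's region and only intra-region
#' pairs at distance `>= min_dist` contribute; in `trans` scale, region-pair
#' average expected is used and only inter-chromosome pairs contribute.
#'
#' @param store A balanced `ContactStore`.
#' @param expected Expected table from [expected_cis()] (`scale = "cis"`) or
#'   [expected_trans()] (`scale = "trans"`).
#' @param digitized Output of [digitize_track()].
#' @param view The same view the expected table was computed over.
#' @param scale `"cis"` or `"trans"`.
#' @param min_dist Minimum separation (bins) of cis pixels (default 2,
#'   consistent with the expected module's smoothing floor).
#' @param include_outliers Also report outlier classes 0 and n+1
#'   (default FALSE: S is n x n over in-range classes).
#' @param use_weights See [store_weights()].
#' @param chunk_size Pixels per chunk.
#' @return List of class `hic_saddle`: `S` (mean O/E), `C` (pixel counts),
#'   both symmetric matrices, and `scale`.
#' @export
saddle_aggregate <- function(store, expected, digitized,
                             view = make_view(store),
                             scale = c("cis", "trans"), min_dist = 2L,
                             include_outliers = FALSE, use_weights = TRUE,
                             chunk_size = 1e7) {
  scale <- match.arg(scale)
  validate_view(view, store$chroms)
  n <- attr(digitized, "n_classes")
  if (is.null(n)) stop("digitized track must come from digitize_track()")
  cls <- digitized$class
  stopifnot(length(cls) == store$nbins)
  vb <- view_bins(store, view)
  reg_of_bin <- rep(NA_integer_, store$nbins)
  for (k in seq_len(nrow(view))) reg_of_bin[vb[[k]] + 1L] <- k
  w <- store_weights(store, use_weights)

  # expected lookup
  if (scale == "cis") {
    ekey <- split(expected[!is.na(expected$dist) &
                             expected$region1 == expected$region2, ],
                  expected$region1[!is.na(expected$dist) &
                                     expected$region1 == expected$region2])
    elook <- lapply(ekey, function(df) {
      v <- rep(NA_real_, max(df$dist) + 1L)
      v[df$dist + 1L] <- df$balanced_avg
      v
    })
  } else {
    pk <- paste(expected$region1, expected$region2)
    etrans <- stats::setNames(expected$balanced_avg, pk)
  }

  nc <- n + 2L  # classes 0..n+1
  Ssum <- matrix(0, nc, nc)
  Cnt <- matrix(0, nc, nc)
  pixel_chunks(store, chunk_size = chunk_size, fun = function(px) {
    b1 <- px$bin1_id + 1L; b2 <- px$bin2_id + 1L
    r1 <- reg_of_bin[b1]; r2 <- reg_of_bin[b2]
    c1 <- cls[b1]; c2 <- cls[b2]
    bal <- px$count * w[b1] * w[b2]
    keep <- !is.na(r1) & !is.na(r2) & !is.na(c1) & !is.na(c2) & !is.na(bal)
    if (scale == "cis") {
      keep <- keep & r1 == r2 & (px$bin2_id - px$bin1_id) >= min_dist
      if (!any(keep)) return(NULL)
      d <- px$bin2_id[keep] - px$bin1_id[keep]
      rname <- view$name[r1[keep]]
      e <- rep(NA_real_, length(d))
      for (rn in unique(rname)) {
        sel <- rname == rn
        v <- elook[[rn]]
        idx <- d[sel] + 1L
        e[sel] <- ifelse(idx <= length(v), v[pmin(idx, length(v))], NA_real_)
      }
    } else {
      keep <- keep & view$chrom[pmax(r1, 1L)] != view$chrom[pmax(r2, 1L)]
      keep[is.na(keep)] <- FALSE
      if (!any(keep)) return(NULL)
      rn <- paste(view$name[pmin(r1, r2)[keep]], view$name[pmax(r1, r2)[keep]])
      e <- etrans[rn]
    }
    oe <- bal[keep] / e
    ok <- !is.na(oe) & is.finite(oe)
    i <- c1[keep][ok] + 1L; j <- c2[keep][ok] + 1L
    v <- oe[ok]
    off <- i != j  # both-orders accumulation; same-class-pair once
    lin <- c((j - 1L) * nc + i, (i[off] - 1L) * nc + j[off])
    vals <- c(v, v[off])
    Ssum <<- Ssum + matrix(rowsum_fill(vals, lin, nc * nc), nc, nc)
    NULL
  })

  # denominators: all valid bin pairs (stored or not), per class pair
  cls_ok <- cls
  cls_ok[is.na(w) | is.na(reg_of_bin)] <- NA
  if (scale == "cis") {
    for (k in seq_len(nrow(view))) {
      ck <- cls_ok[vb[[k]] + 1L]
      nn <- length(ck)
      for (d in seq.int(min_dist, max(nn - 1L, min_dist))) {
        if (d > nn - 1L) break
        a <- ck[seq_len(nn - d)]; b <- ck[seq_len(nn - d) + d]
        good <- !is.na(a) & !is.na(b)
        if (!any(good)) next
        lin <- c((b[good]) * nc + a[good] + 1L, (a[good]) * nc + b[good] + 1L)
        lin <- c(lin[seq_len(sum(good))],
                 lin[sum(good) + which(a[good] != b[good])])
        Cnt <- Cnt + matrix(rowsum_fill(rep(1, length(lin)), lin, nc * nc), nc, nc)
      }
    }
  } else {
    for (k1 in seq_len(nrow(view))) for (k2 in seq_len(nrow(view))) {
      if (k2 <= k1 || view$chrom[k1] == view$chrom[k2]) next
      t1 <- tabulate(cls_ok[vb[[k1]] + 1L] + 1L, nc)
      t2 <- tabulate(cls_ok[vb[[k2]] + 1L] + 1L, nc)
      o <- outer(t1, t2)
      Cnt <- Cnt + o + t(o) - diag(diag(o))
    }
  }
  S <- ifelse(Cnt > 0, Ssum / Cnt, NA_real_)
  labs <- as.character(0:(n + 1L))
  dimnames(S) <- dimnames(Cnt) <- list(labs, labs)
  if (!include_outliers) {
    keep <- 2:(n + 1L)
    S <- S[keep, keep]; Cnt <- Cnt[keep, keep]
  }
  structure(list(S = S, C = Cnt, scale = scale), class = "hic_saddle")
}

#' @export
print.hic_saddle <- function(x, ...) {
  cat("hic_saddle (", x$scale, "): ", nrow(x$S), "x", ncol(x$S),
      " classes, ", sum(x$C) / 2, " pixel assignments\n", sep = "")
  print(round(x$S, 3))
  invisible(x)
}

#' Compartment strength from a saddle matrix
#'
#' Ratio of within-class to between-class preference over the matrix
#' corners: `(mean(top-left e x e) + mean(bottom-right e x e)) /
#' (2 * mean of the two anti-diagonal corners pooled)`. Values above 1
#' indicate compartmentalization.
#'
#' @param saddle A `hic_saddle` object (or plain matrix).
#' @param extent Corner size `e` in classes (default 1).
#' @return A single number; NA entries are ignored.
#' @export
saddle_strength <- function(saddle, extent = 1L) {
  S <- if (inherits(saddle, "hic_saddle")) saddle$S else saddle
  n <- nrow(S)
  if (extent > n) stop("extent exceeds saddle dimension")
  e <- extent
  tl <- S[seq_len(e), seq_len(e)]
  br <- S[n - e + seq_len(e) - 0L, n - e + seq_len(e)]
  tr <- S[seq_len(e), n - e + seq_len(e)]
  bl <- S[n - e + seq_len(e), seq_len(e)]
  (mean(tl, na.rm = TRUE) + mean(br, na.rm = TRUE)) /
    (2 * mean(c(tr, bl), na.rm = TRUE))
}
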