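#' Diamond-window insulation profile
#'
#' For each bin `i` of each view region and each window size `w` (bp,
#' converted to bins), the raw insulation is the mean balanced value over the
#' diamond of pixels `(a, b)` with `i - w <= a <= i < b <= i + w`, counting
#' only pairs of valid bins in the denominator. The reported score is
#' `log2(raw_i / mean(raw))` with the mean taken over the region's scored
#' bins. Scores are missing within `w` of region edges and where the valid
#' pair fraction `n_valid_pixels / w^2` falls below `min_valid_frac`.
#' Computed by a single pass over sparse pixel chunks (differences +
#' cumulative sums), chunk-size independent.
#'
#' @param store A balanced `ContactStore`.
#' @param view A genomic view (default whole chromosomes).
#' @param window_bp One or more window sizes in bp (multiples of the bin
#'   size).
#' @param min_valid_frac Minimum valid-pair fraction (default 0.66).
#' @param use_weights See [store_weights()].
#' @param chunk_size Pixels per chunk.
#' @return data.frame with one row per bin and window: `chrom`, `start`,
#'   `end`, `region`, `window`, `score`, `n_valid_pixels`, `raw`.
#' @export
insulation_profile <- function(store, view = make_view(store), window_bp,
                               min_valid_frac = 0.66, use_weights = TRUE,
                               chunk_size = 1e7) {
  validate_view(view, store$chroms)
  bs <- store$binsize
  if (any(window_bp %% bs != 0)) stop("window_bp must be a multiple of binsize")
  wins <- as.integer(window_bp / bs)
  if (any(wins < 2L)) stop("window must span at least 2 bins")
  vb <- view_bins(store, view)
  wvec <- store_weights(store, use_weights)
  nreg <- nrow(view)
  reg_of_bin <- rep(NA_integer_, store$nbins)
  for (k in seq_len(nreg)) reg_of_bin[vb[[k]] + 1L] <- k
  first_bin <- vapply(vb, function(b) b[1L], 0L)

  # per (window, region): accumulated diamond balanced-sum per bin, via
  # range-add: pixel (a,b) contributes to bins i in [max(a, b-w), min(b-1, a+w)]
  acc <- lapply(wins, function(w) lapply(lengths(vb), function(n) numeric(n)))
  pixel_chunks(store, chunk_size = chunk_size, fun = function(px) {
    r1 <- reg_of_bin[px$bin1_id + 1L]
    r2 <- reg_of_bin[px$bin2_id + 1L]
    keep <- !is.na(r1) & !is.na(r2) & r1 == r2 & px$bin1_id < px$bin2_id
    bal <- px$count * wvec[px$bin1_id + 1L] * wvec[px$bin2_id + 1L]
    keep <- keep & !is.na(bal)
    if (!any(keep)) return(NULL)
    a <- px$bin1_id[keep]; b <- px$bin2_id[keep]
    v <- bal[keep]; r <- r1[keep]
    for (wi in seq_along(wins)) {
      w <- wins[wi]
      lo <- pmax(a, b - w); hi <- pmin(b - 1L, a + w)
      ok <- lo <= hi & (b - a) <= 2L * w
      if (!any(ok)) next
      for (k in unique(r[ok])) {
        sel <- ok & r == k
        n <- length(acc[[wi]][[k]])
        o <- first_bin[k]
        d <- numeric(n + 1L)
        li <- lo[sel] - o + 1L; hi2 <- hi[sel] - o + 1L
        ad <- rowsum_fill(v[sel], li, n + 1L)
        sb <- rowsum_fill(v[sel], pmin(hi2 + 1L, n + 1L), n + 1L)
        acc[[wi]][[k]] <<- acc[[wi]][[k]] + cumsum(ad - sb)[seq_len(n)]
      }
    }
    NULL
  })

  out <- list()
  for (wi in seq_along(wins)) {
    w <- wins[wi]
    for (k in seq_len(nreg)) {
      ids <- vb[[k]]
      n <- length(ids)
      val <- !is.na(wvec[ids + 1L])
      cumval <- c(0, cumsum(val))
      # n_valid over a in [i-w, i], b in (i, i+w], inside the region
      pos <- seq_len(n)
      nv_left <- cumval[pmin(pos, n) + 1L] - cumval[pmax(pos - w, 1L) - 0L]
      nv_right <- cumval[pmin(pos + w, n) + 1L] - cumval[pos + 1L]
      nvalid <- nv_left * nv_right
      interior <- pos - 1L >= w & pos + w <= n
      raw <- ifelse(interior & nvalid > 0, acc[[wi]][[k]] / nvalid, NA_real_)
      raw[interior & nvalid / w^2 < min_valid_frac] <- NA_real_
      raw[!interior] <- NA_real_
      m <- mean(raw, na.rm = TRUE)
      score <- if (is.finite(m) && m > 0) log2(raw / m) else rep(NA_real_, n)
      out[[length(out) + 1L]] <- data.frame(
        chrom = view$chrom[k],
        start = store$bins$start[ids + 1L], end = store$bins$end[ids + 1L],
        region = view$name[k], window = w * bs,
        score = score, n_valid_pixels = nvalid, raw = raw,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find insulation minima and score their prominence
#'
#' Local minima of the insulation score (strictly lower than both finite
#' neighbours; for plateaus the leftmost bin is reported and flagged) are
#' boundary candidates. The prominence ("boundary strength") of a minimum is
#' the smaller, over the two genomic directions, of the highest score
#' encountered walking away from the minimum until reaching a deeper minimum
#' or the region end, minus the minimum's score. Prominence is invariant to
#' adding a constant to the profile.
#'
#' @param table Output of [insulation_profile()].
#' @return `table` with logical `is_min`, numeric `prominence` (NA off
#'   minima) and logical `plateau_tie` columns added.
#' @export
find_boundaries <- function(table) {
  table$is_min <- FALSE
  table$prominence <- NA_real_
  table$plateau_tie <- FALSE
  for (grp in split(seq_len(nrow(table)),
                    list(table$region, table$window), drop = TRUE)) {
    s <- table$score[grp]
    idx <- which(!is.na(s))
    x <- s[idx]
    n <- length(x)
    if (n < 3L) next
    mins <- integer(0)
    ties <- logical(0)
    i <- 2L
    while (i <= n - 1L) {
      if (x[i] < x[i - 1L]) {
        j <- i
        while (j < n && x[j + 1L] == x[i]) j <- j + 1L
        if (j <= n - 1L && x[j + 1L] > x[i]) {
          mins <- c(mins, i)   # leftmost bin of the plateau
          ties <- c(ties, j > i)
        }
        i <- j + 1L
      } else i <- i + 1L
    }
    if (!length(mins)) next
    prom <- vapply(seq_along(mins), function(mi) {
      m <- mins[mi]
      walk <- function(dir) {
        hi <- -Inf
        p <- m + dir
        while (p >= 1L && p <= n) {
          if (x[p] > hi) hi <- x[p]
          if (x[p] < x[m]) break  # reached a deeper point
          p <- p + dir
        }
        hi
      }
      min(walk(-1L), walk(1L)) - x[m]
    }, 0)
    table$is_min[grp[idx[mins]]] <- TRUE
    table$prominence[grp[idx[mins]]] <- prom
    table$plateau_tie[grp[idx[mins]]] <- ties
  }
  table
}

#' Threshold boundary prominences into strong boundaries
#'
#' Computes, per window size, a threshold on the distribution of prominences
#' of all minima and flags minima at or above it as strong. Automated
#' criteria from image thresholding are available: `"Otsu"` (maximize
#' between-class variance over candidate thresholds) and `"Li"` (iterative
#' minimum cross entropy); a fixed numeric value can be given instead.
#'
#' @param table Output of [find_boundaries()].
#' @param method `"Li"`, `"Otsu"`, or a numeric threshold.
#' @return `table` with a logical `is_strong` column and attribute
#'   `thresholds` (named by window).
#' @export
threshold_boundaries <- function(table, method = "Li") {
  table$is_strong <- FALSE
  thr_out <- c()
  for (w in unique(table$window)) {
    sel <- table$window == w & table$is_min
    p <- table$prominence[sel]
    p <- p[!is.na(p)]
    if (!length(p)) next
    if (is.numeric(method)) thr <- method
    else if (length(unique(p)) < 2L) {
      warning("fewer than two distinct prominences; all minima flagged strong")
      thr <- min(p)
    } else {
      thr <- switch(match.arg(method, c("Li", "Otsu")),
                    Otsu = threshold_otsu(p),
                    Li = threshold_li(p))
    }
    table$is_strong[sel] <- !is.na(table$prominence[sel]) &
      table$prominence[sel] >= thr
    thr_out[as.character(w)] <- thr
  }
  attr(table, "thresholds") <- thr_out
  table
}

#' Otsu and Li automatic thresholds for a numeric sample
#'
#' `threshold_otsu` maximizes the between-class variance over all candidate
#' cuts (evaluated exhaustively at the sorted unique values); `threshold_li`
#' iterates the minimum-cross-entropy fixed point. Both operate on the raw
#' values (no histogram binning).
#'
#' @param x Numeric vector (e.g. boundary prominences).
#' @return Threshold value; classify as strong via `x >= threshold`.
#' @export
threshold_otsu <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  cand <- unique(x)[-1L]  # cut below each unique value
  best <- -Inf
  thr <- cand[1L]
  csum <- cumsum(x)
  for (t in cand) {
    k <- sum(x < t)
    w0 <- k / n; w1 <- 1 - w0
    m0 <- csum[k] / k
    m1 <- (csum[n] - csum[k]) / (n - k)
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- t }
  }
  thr
}

#' @rdname threshold_otsu
#' @param max_iter,tol Iteration controls for the Li fixed point.
#' @export
threshold_li <- function(x, max_iter = 100L, tol = 1e-8) {
  x <- x[!is.na(x)]
  shift <- 0
  if (min(x) <= 0) { shift <- -min(x) + 1e-12; x <- x + shift }
  t_new <- mean(x)
  for (it in seq_len(max_iter)) {
    t_old <- t_new
    lo <- x[x <= t_old]; hi <- x[x > t_old]
    if (!length(lo) || !length(hi)) break
    m0 <- mean(lo); m1 <- mean(hi)
    t_new <- (m1 - m0) / (log(m1) - log(m0))
    if (abs(t_new - t_old) < tol) break
  }
  t_new - shift
}
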