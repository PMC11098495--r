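#' Extract snippets around anchors or anchor pairs
#'
#' Cuts fixed-size windows of `(2f+1) x (2f+1)` bins from the (balanced or
#' observed/expected) map, centered on the bin containing each anchor
#' interval's midpoint (on-diagonal pileups) or on the bin pair of two
#' anchors (off-diagonal pileups, oriented so anchor1 precedes anchor2).
#' Cells falling outside the anchor's view region are missing, never
#' truncated, so every snippet has the same shape. Anchors outside the view
#' (or pairs spanning two regions) are dropped and counted.
#'
#' @param store A `ContactStore`.
#' @param features data.frame of anchors (`chrom`, `start`, `end`) or anchor
#'   pairs (`chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`).
#' @param view A genomic view.
#' @param flank_bp Flank on each side of the center, in bp (multiple of the
#'   bin size).
#' @param mode `"observed"` (balanced values) or `"oe"` (each cell divided by
#'   the expected at its separation within the anchor's region).
#' @param expected Cis expected table, required for `mode = "oe"`.
#' @param use_weights See [store_weights()]; `FALSE` snips raw counts.
#' @param nproc Number of worker processes for snippet retrieval; snippets
#'   may be fetched in any partition, and the result is bit-identical to
#'   serial execution.
#' @return Object of class `snippet_stack`: list with `stack` (3D array:
#'   snippet x row x col), `features` (retained anchors with region),
#'   `n_dropped`, `flank` (bins).
#' @export
snip <- function(store, features, view = make_view(store), flank_bp,
                 mode = c("observed", "oe"), expected = NULL,
                 use_weights = TRUE, nproc = 1L) {
  mode <- match.arg(mode)
  if (mode == "oe" && is.null(expected))
    stop("mode 'oe' requires an expected table")
  validate_view(view, store$chroms)
  bs <- store$binsize
  f <- as.integer(flank_bp / bs)
  paired <- all(c("chrom1", "start1", "chrom2", "start2") %in% names(features))
  vb <- view_bins(store, view)
  reg_of_bin <- rep(NA_integer_, store$nbins)
  for (k in seq_len(nrow(view))) reg_of_bin[vb[[k]] + 1L] <- k
  first_bin <- vapply(vb, function(b) b[1L], 0L)
  lens <- lengths(vb)

  anchor_bin <- function(chrom, start, end) {
    mid <- (start + end) / 2
    hit <- which(store$bins$chrom == chrom & store$bins$start <= mid &
                   store$bins$end > mid)
    if (length(hit)) hit[1L] - 1L else NA_integer_
  }
  if (paired) {
    b1 <- mapply(anchor_bin, features$chrom1, features$start1, features$end1)
    b2 <- mapply(anchor_bin, features$chrom2, features$start2, features$end2)
    swap <- !is.na(b1) & !is.na(b2) & b1 > b2
    tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
  } else {
    b1 <- b2 <- mapply(anchor_bin, features$chrom, features$start, features$end)
  }
  r1 <- ifelse(is.na(b1), NA, reg_of_bin[b1 + 1L])
  r2 <- ifelse(is.na(b2), NA, reg_of_bin[b2 + 1L])
  keep <- !is.na(r1) & !is.na(r2) & r1 == r2
  n_dropped <- sum(!keep)
  b1 <- b1[keep]; b2 <- b2[keep]; reg <- r1[keep]
  feats <- features[keep, , drop = FALSE]
  feats$region <- view$name[reg]

  if (mode == "oe") {
    ecis <- expected[!is.na(expected$dist) & expected$region1 == expected$region2, ]
    elook <- lapply(stats::setNames(view$name, view$name), function(rn) {
      df <- ecis[ecis$region1 == rn, ]
      v <- rep(NA_real_, if (nrow(df)) max(df$dist) + 1L else 0L)
      if (nrow(df)) {
        sm <- df$balanced_avg_smoothed
        v[df$dist + 1L] <- ifelse(is.finite(sm) & sm > 0, sm, df$balanced_avg)
      }
      v
    })
  }

  m <- 2L * f + 1L
  store_sparse(store)  # materialize cache before forking
  snip_one <- function(s) {
    k <- reg[s]
    o <- first_bin[k]; n <- lens[k]
    win <- matrix(NA_real_, m, m)
    p1 <- b1[s] - o + 1L; p2 <- b2[s] - o + 1L  # 1-based within region
    ii <- (p1 - f):(p1 + f); jj <- (p2 - f):(p2 + f)
    ok_i <- ii >= 1L & ii <= n; ok_j <- jj >= 1L & jj <= n
    if (!any(ok_i) || !any(ok_j)) return(win)
    M <- fetch_dense(store, o + ii[ok_i] - 1L, o + jj[ok_j] - 1L,
                     use_weights = use_weights)
    if (mode == "oe") {
      ev <- elook[[view$name[k]]]
      D <- abs(outer(ii[ok_i], jj[ok_j], "-"))
      Ed <- matrix(ev[pmin(D + 1L, length(ev))], nrow(D), ncol(D))
      Ed[D + 1L > length(ev)] <- NA
      M <- M / Ed
    }
    win[which(ok_i), which(ok_j)] <- M
    win
  }
  wins <- if (nproc > 1L)
    parallel::mclapply(seq_along(b1), snip_one, mc.cores = nproc)
  else lapply(seq_along(b1), snip_one)
  stack <- array(NA_real_, c(length(b1), m, m))
  for (s in seq_along(wins)) stack[s, , ] <- wins[[s]]
  structure(list(stack = stack, features = feats, n_dropped = n_dropped,
                 flank = f), class = "snippet_stack")
}

#' @export
print.snippet_stack <- function(x, ...) {
  cat("snippet_stack:", dim(x$stack)[1L], "snippets of",
      dim(x$stack)[2L], "x", dim(x$stack)[3L], "bins;",
      x$n_dropped, "anchors dropped\n")
  invisible(x)
}

#' Average a snippet stack into a pileup
#'
#' Element-wise mean or median across snippets, ignoring missing cells.
#'
#' @param stack A `snippet_stack` from [snip()] (or a plain 3D array).
#' @param stat `"mean"` (default) or `"median"`.
#' @return List with `pileup` (2D matrix) and `n` (contributing snippets per
#'   cell).
#' @export
pileup <- function(stack, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  a <- if (inherits(stack, "snippet_stack")) stack$stack else stack
  fun <- if (stat == "mean") function(v) mean(v, na.rm = TRUE)
         else function(v) stats::median(v, na.rm = TRUE)
  p <- apply(a, c(2L, 3L), fun)
  p[!is.finite(p)] <- NA_real_
  n <- apply(a, c(2L, 3L), function(v) sum(!is.na(v)))
  list(pileup = p, n = n)
}
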