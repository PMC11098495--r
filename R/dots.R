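#' Convolution kernels for dot scoring
#'
#' Builds the stock local-background kernels used for focal-peak (dot)
#' detection as 0/1 masks of size `(2w+1) x (2w+1)`; 1 marks a background
#' pixel. Rows index offsets along the first (upstream) bin axis, columns
#' along the second. With inner half-width `p` and outer half-width `w`:
#'
#' * `donut`: ring with `|di| > p` or `|dj| > p`, excluding the center row
#'   and column (`di = 0` or `dj = 0`).
#' * `vertical` (alias `top`): column band `|dj| <= p`, `p < |di| <= w`.
#' * `horizontal` (alias `bottom`): row band `|di| <= p`, `p < |dj| <= w`.
#' * `lowerleft`: quadrant toward the diagonal, `1 <= di <= w`,
#'   `-w <= dj <= -1`, minus the inner `p x p` corner.
#'
#' The exact masks are pinned by printed matrices in the package test suite.
#' User-supplied masks (odd-sized 0/1 matrices with the center excluded) are
#' accepted anywhere a kernel list is taken.
#'
#' @param w Outer half-width in bins (default 5).
#' @param p Inner (excluded) half-width in bins (default 2).
#' @param names Which kernels to build.
#' @return Named list of integer matrices.
#' @export
dot_kernels <- function(w = 5L, p = 2L,
                        names = c("donut", "vertical", "horizontal", "lowerleft")) {
  stopifnot(w > p, p >= 0)
  di <- matrix(rep(-w:w, 2L * w + 1L), 2L * w + 1L)
  dj <- t(di)
  build <- function(mask) { storage.mode(mask) <- "integer"; mask }
  kernels <- list(
    donut = build((abs(di) > p | abs(dj) > p) & di != 0L & dj != 0L &
                    abs(di) <= w & abs(dj) <= w),
    vertical = build(abs(dj) <= p & abs(di) > p),
    horizontal = build(abs(di) <= p & abs(dj) > p),
    lowerleft = build(di >= 1L & dj <= -1L & !(di <= p & -dj <= p))
  )
  alias <- c(top = "vertical", bottom = "horizontal")
  names <- ifelse(names %in% names(alias), alias[names], names)
  kernels[unique(names)]
}

# out[i,j] = sum over mask cells of M[i+di, j+dj]; cells outside M count 0
conv_mask <- function(M, mask) {
  w <- (nrow(mask) - 1L) %/% 2L
  n1 <- nrow(M); n2 <- ncol(M)
  P <- matrix(0, n1 + 2L * w, n2 + 2L * w)
  P[w + seq_len(n1), w + seq_len(n2)] <- M
  out <- matrix(0, n1, n2)
  off <- which(mask != 0L, arr.ind = TRUE) - (w + 1L)
  for (u in seq_len(nrow(off))) {
    out <- out + P[w + seq_len(n1) + off[u, 1L], w + seq_len(n2) + off[u, 2L]]
  }
  out
}

#' Score pixels for local dot enrichment
#'
#' Sweeps convolution kernels across in-memory tiles of the balanced map to
#' score every in-range cis pixel against its local background. For pixel
#' `(i, j)` and kernel `k`, the local enrichment factor is
#' `f_k = sum_kernel(balanced obs) / sum_kernel(balanced expected)` over
#' valid kernel cells, and `lambda_k = f_k * E(|i-j|) / (w_i w_j)` is the
#' locally adjusted expected raw count. Tiles overlap by the kernel
#' half-width so every pixel is scored exactly once with full context;
#' results are independent of tile size.
#'
#' @param store A balanced `ContactStore`.
#' @param expected Cis expected table from [expected_cis()] over `view`.
#' @param view A genomic view.
#' @param kernels Kernel list from [dot_kernels()] (or user masks).
#' @param max_dist_bp Maximum anchor separation scored (default 2 Mb).
#' @param min_dist Minimum separation in bins (default 2).
#' @param tile_size_bp Tile edge in bp (default 3 Mb).
#' @param min_kernel_frac Minimum fraction of kernel cells that must be valid
#'   for a pixel to be scored (default 0.5); pixels failing for any kernel
#'   are dropped. The background factor is a ratio estimator, stable from
#'   half of even the smallest stock kernel's cells.
#' @param use_weights See [store_weights()].
#' @return data.frame of all scored pixels (zero counts included): `region`,
#'   `bin1_id`, `bin2_id`, `dist`, `count`, `exp_raw`, and per kernel
#'   `la_<kernel>` and `enr_<kernel>` (= count / lambda).
#' @export
score_pixels <- function(store, expected, view = make_view(store),
                         kernels = dot_kernels(), max_dist_bp = 2e6,
                         min_dist = 2L, tile_size_bp = 3e6,
                         min_kernel_frac = 0.5, use_weights = TRUE) {
  validate_view(view, store$chroms)
  bs <- store$binsize
  kw <- (nrow(kernels[[1L]]) - 1L) %/% 2L
  for (k in kernels) {
    if (nrow(k) != ncol(k) || nrow(k) %% 2L == 0L || sum(k) < 1L)
      stop("kernels must be odd square masks with at least one background cell")
  }
  tile <- max(as.integer(tile_size_bp / bs), 2L * kw + 2L)
  maxd <- as.integer(max_dist_bp / bs)
  if (tile <= 2L * kw) stop("kernel larger than tile")
  vb <- view_bins(store, view)
  wvec <- store_weights(store, use_weights)
  out <- list()

  ecis <- expected[!is.na(expected$dist) & expected$region1 == expected$region2, ]
  for (rk in seq_len(nrow(view))) {
    ids <- vb[[rk]]
    n <- length(ids)
    if (n < 2L) next
    er <- ecis[ecis$region1 == view$name[rk], ]
    ev <- rep(NA_real_, n)
    sm <- er$balanced_avg_smoothed
    ev[er$dist + 1L] <- ifelse(is.finite(sm) & sm > 0, sm, er$balanced_avg)
    w_r <- wvec[ids + 1L]
    val <- !is.na(w_r)
    Obal <- fetch_dense(store, ids, use_weights = use_weights)
    Oraw <- fetch_dense(store, ids, use_weights = FALSE)
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    E <- matrix(ev[D + 1L], n, n)
    V <- outer(val, val) & is.finite(E)
    Of <- ifelse(V & !is.na(Obal), Obal, 0)
    Ef <- ifelse(V, E, 0)
    Vn <- V * 1

    tiles <- seq(1L, n, by = tile)
    for (ti in tiles) for (tj in tiles) {
      i_hi <- min(ti + tile - 1L, n)
      j_hi <- min(tj + tile - 1L, n)
      if (tj + tile - 1L < ti || (tj - i_hi) > maxd) next  # off band
      ri <- max(1L, ti - kw):min(n, i_hi + kw)
      rj <- max(1L, tj - kw):min(n, j_hi + kw)
      core_i <- ti:i_hi; core_j <- tj:j_hi
      ci <- match(core_i, ri); cj <- match(core_j, rj)
      kos <- lapply(kernels, function(kk) conv_mask(Of[ri, rj, drop = FALSE], kk)[ci, cj, drop = FALSE])
      kes <- lapply(kernels, function(kk) conv_mask(Ef[ri, rj, drop = FALSE], kk)[ci, cj, drop = FALSE])
      kcn <- lapply(kernels, function(kk) conv_mask(Vn[ri, rj, drop = FALSE], kk)[ci, cj, drop = FALSE])

      dmat <- outer(core_i, core_j, function(a, b) b - a)
      inband <- dmat >= min_dist & dmat <= maxd &
        V[core_i, core_j, drop = FALSE]
      keep <- inband
      for (u in seq_along(kernels))
        keep <- keep & (kcn[[u]] >= min_kernel_frac * sum(kernels[[u]])) &
          (kes[[u]] > 0)
      if (!any(keep)) next
      idx <- which(keep, arr.ind = TRUE)
      i0 <- core_i[idx[, 1L]]; j0 <- core_j[idx[, 2L]]
      exp_raw <- E[cbind(i0, j0)] / (w_r[i0] * w_r[j0])
      rec <- data.frame(region = view$name[rk],
                        bin1_id = ids[i0], bin2_id = ids[j0],
                        dist = j0 - i0,
                        count = Oraw[cbind(i0, j0)],
                        exp_raw = exp_raw, stringsAsFactors = FALSE)
      for (u in seq_along(kernels)) {
        f <- kos[[u]][idx] / kes[[u]][idx]
        rec[[paste0("la_", names(kernels)[u])]] <- f * exp_raw
        rec[[paste0("enr_", names(kernels)[u])]] <- rec$count / (f * exp_raw)
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out))
    return(data.frame(region = character(), bin1_id = integer(),
                      bin2_id = integer(), dist = integer(), count = numeric(),
                      exp_raw = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(match(res$region, view$name), res$bin1_id, res$bin2_id), ]
  rownames(res) <- NULL
  res
}

#' Lambda-chunked Benjamini-Hochberg significance
#'
#' Per kernel, scored pixels are partitioned into geometric lambda chunks
#' with edges `chunk_base^m`; within each chunk, the p-value is the
#' upper-tail Poisson probability `P(X >= count)` evaluated at the chunk's
#' upper edge (conservative), and BH correction is applied across the
#' chunk's pixels. A pixel is retained when significant at `fdr_q` for every
#' kernel.
#'
#' @param scored Output of [score_pixels()].
#' @param fdr_q Nominal FDR level (default 0.1).
#' @param chunk_base Geometric chunk base (default `2^(1/3)`).
#' @return `scored` with per-kernel `q_<kernel>` columns and a logical
#'   `significant` column.
#' @export
lambda_bh <- function(scored, fdr_q = 0.1, chunk_base = 2^(1 / 3)) {
  kcols <- grep("^la_", names(scored), value = TRUE)
  if (!nrow(scored)) {
    for (k in kcols) scored[[sub("^la_", "q_", k)]] <- numeric(0)
    scored$significant <- logical(0)
    return(scored)
  }
  sig <- rep(TRUE, nrow(scored))
  for (k in kcols) {
    la <- scored[[k]]
    m <- ceiling(log(pmax(la, 1e-12)) / log(chunk_base))
    edge <- chunk_base^m
    p <- stats::ppois(scored$count - 1, edge, lower.tail = FALSE)
    q <- rep(NA_real_, length(p))
    for (chunk in unique(m)) {
      s <- m == chunk
      q[s] <- stats::p.adjust(p[s], method = "BH")
    }
    scored[[sub("^la_", "q_", k)]] <- q
    sig <- sig & q <= fdr_q
  }
  scored$significant <- sig
  scored
}

#' Cluster significant pixels and filter dot calls
#'
#' Single-linkage clustering of significant pixels (centroid distance in bp
#' `<= radius_bp`, per region), keeping the most significant pixel of each
#' cluster as its centroid, followed by enrichment filtering (by default the
#' donut and lowerleft enrichments must reach `enrichment_min`). Both steps
#' can be skipped.
#'
#' @param sig Rows of a [lambda_bh()] table (typically
#'   `subset(tbl, significant)`).
#' @param store The `ContactStore` (for bin coordinates).
#' @param radius_bp Clustering radius (default 39000, i.e. touching/adjacent
#'   pixels at typical resolutions).
#' @param cluster Perform clustering (default TRUE; when FALSE every pixel is
#'   its own centroid).
#' @param enrichment_min Minimum `enr_donut` and `enr_lowerleft` for a
#'   reported call (default 1.75); `NULL` skips the filter.
#' @return data.frame of dot calls with interval-pair coordinates
#'   (`chrom1,start1,end1,chrom2,start2,end2`), the score columns, `cluster`,
#'   `cluster_size` and `is_centroid`.
#' @export
cluster_filter <- function(sig, store, radius_bp = 39000, cluster = TRUE,
                           enrichment_min = 1.75) {
  if (!nrow(sig)) {
    out <- cbind(data.frame(chrom1 = character(), start1 = numeric(),
                            end1 = numeric(), chrom2 = character(),
                            start2 = numeric(), end2 = numeric()),
                 sig, data.frame(cluster = integer(), cluster_size = integer(),
                                 is_centroid = logical()))
    return(out)
  }
  bs <- store$binsize
  qcols <- grep("^q_", names(sig), value = TRUE)
  worst_q <- do.call(pmax, sig[qcols])
  sig$cluster <- NA_integer_
  sig$cluster_size <- 1L
  sig$is_centroid <- TRUE
  cl_off <- 0L
  for (reg in unique(sig$region)) {
    rows <- which(sig$region == reg)
    x <- sig$bin1_id[rows] * bs + bs / 2
    y <- sig$bin2_id[rows] * bs + bs / 2
    m <- length(rows)
    parent <- seq_len(m)
    find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
    if (cluster && m > 1L) {
      r2 <- radius_bp^2
      ord <- order(x)
      for (ii in seq_len(m - 1L)) {
        a <- ord[ii]
        for (jj in (ii + 1L):m) {
          b <- ord[jj]
          dx <- x[b] - x[a]
          if (dx > radius_bp) break
          if (dx * dx + (y[b] - y[a])^2 <= r2) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[ra] <- rb
          }
        }
      }
    }
    comp <- vapply(seq_len(m), find, 0L)
    comp <- match(comp, unique(comp)) + cl_off
    cl_off <- max(comp)
    sig$cluster[rows] <- comp
    for (cc in unique(comp)) {
      mem <- rows[comp == cc]
      sig$cluster_size[mem] <- length(mem)
      best <- mem[order(worst_q[mem], -sig$count[mem])][1L]
      sig$is_centroid[mem] <- FALSE
      sig$is_centroid[best] <- TRUE
    }
  }
  calls <- sig[sig$is_centroid, , drop = FALSE]
  if (!is.null(enrichment_min)) {
    ok <- rep(TRUE, nrow(calls))
    if (!is.null(calls$enr_donut)) ok <- ok & calls$enr_donut >= enrichment_min
    if (!is.null(calls$enr_lowerleft)) ok <- ok & calls$enr_lowerleft >= enrichment_min
    calls <- calls[ok, , drop = FALSE]
  }
  b <- store$bins
  out <- cbind(data.frame(
    chrom1 = b$chrom[calls$bin1_id + 1L], start1 = b$start[calls$bin1_id + 1L],
    end1 = b$end[calls$bin1_id + 1L],
    chrom2 = b$chrom[calls$bin2_id + 1L], start2 = b$start[calls$bin2_id + 1L],
    end2 = b$end[calls$bin2_id + 1L], stringsAsFactors = FALSE), calls)
  rownames(out) <- NULL
  out
}

#' Call dots on a balanced map
#'
#' Convenience pipeline: [score_pixels()] then [lambda_bh()] then
#' [cluster_filter()].
#'
#' @inheritParams score_pixels
#' @inheritParams lambda_bh
#' @inheritParams cluster_filter
#' @return data.frame of dot calls (cluster centroids passing filters).
#' @export
call_dots <- function(store, expected, view = make_view(store),
                      kernels = dot_kernels(), fdr_q = 0.1,
                      max_dist_bp = 2e6, min_dist = 2L, tile_size_bp = 3e6,
                      radius_bp = 39000, cluster = TRUE,
                      enrichment_min = 1.75, chunk_base = 2^(1 / 3),
                      use_weights = TRUE) {
  scored <- score_pixels(store, expected, view, kernels = kernels,
                         max_dist_bp = max_dist_bp, min_dist = min_dist,
                         tile_size_bp = tile_size_bp, use_weights = use_weights)
  scored <- lambda_bh(scored, fdr_q = fdr_q, chunk_base = chunk_base)
  cluster_filter(scored[scored$significant, , drop = FALSE], store,
                 radius_bp = radius_bp, cluster = cluster,
                 enrichment_min = enrichment_min)
}
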