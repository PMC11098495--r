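#' Distance-adjusted, centered observed/expected matrix of a region
#'
#' Dense balanced matrix of one view region, divided diagonal-by-diagonal by
#' the within-region mean (observed/expected), symmetric-clipped at extreme
#' percentiles, centered by subtracting 1, with bad bins as NA rows/columns.
#' This is the matrix whose eigendecomposition yields cis compartment
#' profiles.
#'
#' @param store A balanced `ContactStore`.
#' @param bins 0-based bin ids of one contiguous region.
#' @param clip_percentile Two percentiles (of the O/E values over valid bins)
#'   at which to clip, default `c(0.1, 99.9)`.
#' @param use_weights See [store_weights()].
#' @return Dense symmetric matrix with NA at bad bins.
#' @export
oe_centered_matrix <- function(store, bins, clip_percentile = c(0.1, 99.9),
                               use_weights = TRUE) {
  O <- fetch_dense(store, bins, use_weights = use_weights)
  n <- length(bins)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  ed <- vapply(0:(n - 1L), function(d) {
    v <- O[D == d]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  OE <- O / ed[D + 1L]
  valid <- !is.na(OE) & is.finite(OE)
  if (any(valid)) {
    q <- stats::quantile(OE[valid], clip_percentile / 100, names = FALSE)
    OE[valid] <- pmin(pmax(OE[valid], q[1L]), q[2L])
  }
  # diagonals with zero/undefined expected carry no signal
  OE[is.na(O) | !is.finite(OE)] <- NA
  OE[is.na(OE) & !is.na(O)] <- 1
  C <- OE - 1
  (C + t(C)) / 2
}

decompose_centered <- function(C, n_eigs) {
  ok <- which(colSums(!is.na(C)) > 0 & !is.na(diag(C)))
  k <- min(n_eigs, length(ok))
  n <- ncol(C)
  vals <- rep(NA_real_, n_eigs)
  vecs <- matrix(NA_real_, n, n_eigs)
  if (length(ok) < 2L || k < 1L) return(list(values = vals, vectors = vecs))
  Cs <- C[ok, ok]
  Cs[is.na(Cs)] <- 0
  e <- eigen((Cs + t(Cs)) / 2, symmetric = TRUE)
  vals[seq_len(k)] <- e$values[seq_len(k)]
  for (j in seq_len(k)) vecs[ok, j] <- e$vectors[, j]
  list(values = vals, vectors = vecs)
}

#' Cis compartment eigenvectors
#'
#' Per view region: the balanced matrix is adjusted for distance dependence
#' (observed/expected), clipped, centered (see [oe_centered_matrix()]),
#' bad rows/columns are dropped, and the symmetric eigendecomposition is
#' taken. The top `n_eigs` eigenvectors by descending (signed) eigenvalue are
#' reported, unit-norm over valid bins, with NA at bad bins. When a phasing
#' track is supplied the vectors are oriented (and optionally sorted) by
#' their correlation with it, see [phase_eigs()].
#'
#' @param store A balanced `ContactStore`.
#' @param view A genomic view (default whole chromosomes).
#' @param n_eigs Number of eigenvectors (default 3).
#' @param phasing_track Optional bin-aligned track data.frame (`chrom`,
#'   `start`, `end`, `value`), e.g. GC content.
#' @param clip_percentile See [oe_centered_matrix()].
#' @param sort Passed to [phase_eigs()] when a track is given.
#' @param use_weights See [store_weights()].
#' @return Object of class `hic_eigs`: list with `eigenvalues` (data.frame
#'   `region`, `eig`, `eigenvalue`, `phasing_cor`) and `vectors` (bin table
#'   with one column per eigenvector `E1..Ek` and a `region` column).
#' @export
eigs_cis <- function(store, view = make_view(store), n_eigs = 3L,
                     phasing_track = NULL, clip_percentile = c(0.1, 99.9),
                     sort = c("eigenvalue", "correlation"),
                     use_weights = TRUE) {
  sort <- match.arg(sort)
  validate_view(view, store$chroms)
  vb <- view_bins(store, view)
  vecs <- matrix(NA_real_, store$nbins, n_eigs,
                 dimnames = list(NULL, paste0("E", seq_len(n_eigs))))
  region_col <- rep(NA_character_, store$nbins)
  evals <- list()
  for (k in seq_len(nrow(view))) {
    ids <- vb[[k]]
    region_col[ids + 1L] <- view$name[k]
    w <- store_weights(store, use_weights)[ids + 1L]
    if (sum(!is.na(w)) < n_eigs + 1L) {
      warning("region ", view$name[k], " has too few valid bins; all-missing result")
      evals[[k]] <- data.frame(region = view$name[k],
                               eig = paste0("E", seq_len(n_eigs)),
                               eigenvalue = NA_real_, stringsAsFactors = FALSE)
      next
    }
    C <- oe_centered_matrix(store, ids, clip_percentile, use_weights)
    dec <- decompose_centered(C, n_eigs)
    vecs[ids + 1L, ] <- dec$vectors
    evals[[k]] <- data.frame(region = view$name[k],
                             eig = paste0("E", seq_len(n_eigs)),
                             eigenvalue = dec$values, stringsAsFactors = FALSE)
  }
  res <- structure(list(
    eigenvalues = do.call(rbind, evals),
    vectors = cbind(store$bins[c("chrom", "start", "end")],
                    data.frame(region = region_col, stringsAsFactors = FALSE),
                    as.data.frame(vecs))
  ), class = "hic_eigs")
  res$eigenvalues$phasing_cor <- NA_real_
  if (!is.null(phasing_track)) res <- phase_eigs(res, phasing_track, sort = sort)
  res
}

#' @export
print.hic_eigs <- function(x, ...) {
  cat("hic_eigs:", length(unique(x$eigenvalues$region)), "region(s),",
      sum(grepl("^E\\d+$", names(x$vectors))), "eigenvector(s)\n")
  print(utils::head(x$eigenvalues, 12L))
  invisible(x)
}

#' Trans compartment eigenvectors
#'
#' Genome-wide decomposition in which every cis block of the balanced matrix
#' is masked with values sampled (seeded, uniformly with replacement) from
#' the valid trans pixels involving that chromosome, the matrix is scaled by
#' the global trans mean (observed/expected), centered by subtracting 1, and
#' decomposed as in [eigs_cis()]. Trans pixels are left untouched.
#'
#' @inheritParams eigs_cis
#' @param seed Seed for the cis-filling sampler (default 1).
#' @return A `hic_eigs` object (single region `"genome"`).
#' @export
eigs_trans <- function(store, n_eigs = 3L, phasing_track = NULL, seed = 1L,
                       clip_percentile = c(0.1, 99.9),
                       sort = c("eigenvalue", "correlation"),
                       use_weights = TRUE) {
  sort <- match.arg(sort)
  if (nrow(store$chroms) < 2L)
    stop("trans eigenvectors require at least two chromosomes")
  nb <- store$nbins
  allb <- seq_len(nb) - 1L
  F <- fetch_dense(store, allb, use_weights = use_weights)
  chrom_of <- store$bins$chrom
  same <- outer(chrom_of, chrom_of, "==")
  valid <- !is.na(store_weights(store, use_weights))
  vv <- outer(valid, valid, "&")
  trans_vals <- F[!same & vv]
  gmean <- mean(trans_vals, na.rm = TRUE)
  if (!is.finite(gmean) || gmean <= 0) stop("no usable trans signal")

  with_seed(seed, {
    for (ch in store$chroms$name) {
      sel <- which(chrom_of == ch & valid)
      if (!length(sel)) next
      pool <- F[chrom_of == ch & valid, chrom_of != ch & valid]
      pool <- pool[!is.na(pool)]
      m <- length(sel)
      ut <- upper.tri(matrix(0, m, m), diag = TRUE)
      draw <- matrix(NA_real_, m, m)
      draw[ut] <- sample(pool, sum(ut), replace = TRUE)
      draw[lower.tri(draw)] <- t(draw)[lower.tri(draw)]
      F[sel, sel] <- draw
    }
  })
  OE <- F / gmean
  OE[!vv] <- NA
  C <- OE - 1
  C <- (C + t(C)) / 2
  dec <- decompose_centered(C, n_eigs)
  res <- structure(list(
    eigenvalues = data.frame(region = "genome", eig = paste0("E", seq_len(n_eigs)),
                             eigenvalue = dec$values, phasing_cor = NA_real_,
                             stringsAsFactors = FALSE),
    vectors = cbind(store$bins[c("chrom", "start", "end")],
                    data.frame(region = "genome", stringsAsFactors = FALSE),
                    as.data.frame(dec$vectors,
                                  col.names = paste0("E", seq_len(n_eigs))))
  ), class = "hic_eigs")
  names(res$vectors)[-(1:4)] <- paste0("E", seq_len(n_eigs))
  if (!is.null(phasing_track)) res <- phase_eigs(res, phasing_track, sort = sort)
  res
}

#' Orient (and sort) eigenvectors by a phasing track
#'
#' Each eigenvector is multiplied by the sign of its correlation with the
#' track over jointly valid bins, so that every reported vector correlates
#' non-negatively with the track (by convention, positive values then mark
#' the active A compartment when the track is GC content). With
#' `sort = "correlation"` vectors are reordered per region by descending
#' absolute correlation and relabelled `E1..Ek`, since the compartment signal
#' is not always the leading eigenvector.
#'
#' @param result A `hic_eigs` object.
#' @param phasing_track Bin-aligned data.frame with a `value` column.
#' @param sort `"eigenvalue"` (keep order) or `"correlation"`.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return The modified `hic_eigs` object.
#' @export
phase_eigs <- function(result, phasing_track,
                       sort = c("eigenvalue", "correlation"),
                       method = c("pearson", "spearman")) {
  sort <- match.arg(sort)
  method <- match.arg(method)
  track <- phasing_track$value
  stopifnot(length(track) == nrow(result$vectors))
  ecols <- grep("^E\\d+$", names(result$vectors), value = TRUE)
  ev <- result$eigenvalues
  for (reg in unique(ev$region)) {
    sel <- which(!is.na(result$vectors$region) & result$vectors$region == reg)
    cors <- rep(NA_real_, length(ecols))
    for (j in seq_along(ecols)) {
      v <- result$vectors[[ecols[j]]][sel]
      ok <- !is.na(v) & !is.na(track[sel])
      if (sum(ok) > 2L && stats::sd(v[ok]) > 0 && stats::sd(track[sel][ok]) > 0) {
        r <- stats::cor(v[ok], track[sel][ok], method = method)
        if (!is.na(r) && r < 0) {
          result$vectors[[ecols[j]]][sel] <- -v
          r <- -r
        }
        cors[j] <- r
      }
    }
    ord <- if (sort == "correlation") order(-abs(ifelse(is.na(cors), -Inf, cors)))
           else seq_along(ecols)
    block <- as.matrix(result$vectors[sel, ecols, drop = FALSE])[, ord, drop = FALSE]
    result$vectors[sel, ecols] <- block
    ri <- which(ev$region == reg)
    ev$eigenvalue[ri] <- ev$eigenvalue[ri][ord]
    ev$phasing_cor[ri] <- cors[ord]
  }
  result$eigenvalues <- ev
  result
}
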