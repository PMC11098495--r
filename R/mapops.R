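#' Per-bin cis and total coverage
#'
#' Sums pixel counts per bin by iterating over chunks of the pixel table:
#' each off-diagonal pixel adds its count to both bins, a diagonal
#' (self-contact) pixel adds once to its bin (set `double_diagonal = TRUE`
#' to add it twice, matching the marginals used in balancing); cis coverage
#' is restricted to pixels with both bins on one chromosome.
#'
#' @param store A `ContactStore`.
#' @param use_weights Additionally report balanced coverage (requires
#'   weights; default TRUE when a weight column is present).
#' @param double_diagonal Count diagonal pixels twice (default FALSE).
#' @param chunk_size Pixels per chunk.
#' @return data.frame per bin: `chrom`, `start`, `end`, `cis_raw`,
#'   `total_raw`, `cis_balanced`, `total_balanced` (NA at bad bins, absent
#'   without weights), `cis_ratio`.
#' @export
coverage <- function(store, use_weights = !is.null(store$bins$weight),
                     double_diagonal = FALSE, chunk_size = 1e7) {
  nb <- store$nbins
  chrom_of <- store$bins$chrom
  cis_raw <- tot_raw <- numeric(nb)
  cis_bal <- tot_bal <- numeric(nb)
  w <- if (isFALSE(use_weights)) NULL else store_weights(store, use_weights)
  dmul <- if (double_diagonal) 2 else 1
  pixel_chunks(store, chunk_size = chunk_size, fun = function(px) {
    b1 <- px$bin1_id + 1L; b2 <- px$bin2_id + 1L
    diagp <- b1 == b2
    cnt <- px$count
    add1 <- rowsum_fill(ifelse(diagp, dmul * cnt, cnt), b1, nb)
    add2 <- rowsum_fill(cnt[!diagp], b2[!diagp], nb)
    tot_raw <<- tot_raw + add1 + add2
    cis <- chrom_of[b1] == chrom_of[b2]
    c1 <- cis & !diagp
    cis_raw <<- cis_raw + rowsum_fill(ifelse(diagp[cis], dmul * cnt[cis], cnt[cis]),
                                      b1[cis], nb) +
      rowsum_fill(cnt[c1], b2[c1], nb)
    if (!is.null(w)) {
      bal <- cnt * w[b1] * w[b2]
      ok <- !is.na(bal)
      tot_bal <<- tot_bal +
        rowsum_fill(ifelse(diagp[ok], dmul * bal[ok], bal[ok]), b1[ok], nb) +
        rowsum_fill(bal[ok & !diagp], b2[ok & !diagp], nb)
      oc <- ok & cis
      cis_bal <<- cis_bal +
        rowsum_fill(ifelse(diagp[oc], dmul * bal[oc], bal[oc]), b1[oc], nb) +
        rowsum_fill(bal[oc & !diagp], b2[oc & !diagp], nb)
    }
    NULL
  })
  out <- data.frame(chrom = store$bins$chrom, start = store$bins$start,
                    end = store$bins$end, cis_raw = cis_raw,
                    total_raw = tot_raw, stringsAsFactors = FALSE)
  if (!is.null(w)) {
    bad <- is.na(w)
    cis_bal[bad] <- NA; tot_bal[bad] <- NA
    out$cis_balanced <- cis_bal
    out$total_balanced <- tot_bal
  }
  out$cis_ratio <- ifelse(tot_raw > 0, cis_raw / tot_raw, NA_real_)
  out
}

#' Randomly downsample a contact store
#'
#' Replaces each pixel's count by an independent binomial draw with success
#' probability `fraction` (or `target_count / sum(counts)`), drops zero
#' pixels, and writes a valid cooler-schema file. Seeded and reproducible;
#' per-pixel binomial sampling approximates without-replacement sampling at
#' Hi-C scales.
#'
#' @param store A `ContactStore`.
#' @param path Output `.cool` path.
#' @param fraction Sampling fraction in (0, 1].
#' @param target_count Alternative to `fraction`: desired expected total.
#' @param seed Integer seed (required for reproducibility; default 1).
#' @return The new store, opened.
#' @export
downsample <- function(store, path = tempfile(fileext = ".cool"),
                       fraction = NULL, target_count = NULL, seed = 1L) {
  px <- read_pixels(store)
  total <- sum(px$count)
  if (is.null(fraction)) {
    if (is.null(target_count)) stop("give fraction or target_count")
    fraction <- target_count / total
  }
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  with_seed(seed, {
    newc <- if (fraction == 1) px$count
            else stats::rbinom(nrow(px), px$count, fraction)
    px$count <- newc
    px <- px[px$count > 0, , drop = FALSE]
    write_cool(path, store$chroms, store$bins, px, store$binsize)
  })
  open_store(path)
}

#' Adaptive multi-scale smoothing of a balanced region matrix
#'
#' Builds a pyramid of 2x-coarsened raw-count and balanced matrices (raw
#' counts summed, balanced values averaged over valid cells, odd edges
#' padded with missing). Each output cell takes the balanced value from the
#' finest level whose co-located aggregated raw count reaches
#' `cutoff_counts`; the coarse value is spread uniformly back to the fine
#' cells, so total balanced mass is redistributed, not created. Cells
#' failing at every level take the coarsest value. Deterministic.
#'
#' @param store A balanced `ContactStore`.
#' @param region List or one-row data.frame with `chrom`, `start`, `end`.
#' @param cutoff_counts Raw-count threshold (default 10).
#' @param max_levels Maximum coarsenings (default 8).
#' @param use_weights See [store_weights()].
#' @return Dense smoothed balanced matrix (NA where no data at any level).
#' @export
adaptive_smooth <- function(store, region, cutoff_counts = 10L,
                            max_levels = 8L, use_weights = TRUE) {
  ids <- region_bins(store, region$chrom, region$start, region$end)
  raw <- fetch_dense(store, ids, use_weights = FALSE)
  bal <- fetch_dense(store, ids, use_weights = use_weights)
  n <- length(ids)
  coarsen <- function(M, how) {
    m <- ncol(M)
    m2 <- ceiling(m / 2)
    if (m %% 2L == 1L) {
      M <- rbind(cbind(M, NA), NA)
    }
    out <- matrix(NA_real_, m2, m2)
    for (a in seq_len(m2)) for (b in seq_len(m2)) {
      blk <- M[2 * a - 1:0, 2 * b - 1:0]
      out[a, b] <- if (how == "sum") {
        if (all(is.na(blk))) NA_real_ else sum(blk, na.rm = TRUE)
      } else {
        if (all(is.na(blk))) NA_real_ else mean(blk, na.rm = TRUE)
      }
    }
    out
  }
  raws <- list(raw); bals <- list(bal)
  lev <- 1L
  while (lev < max_levels && ncol(raws[[lev]]) > 1L) {
    raws[[lev + 1L]] <- coarsen(raws[[lev]], "sum")
    bals[[lev + 1L]] <- coarsen(bals[[lev]], "mean")
    lev <- lev + 1L
  }
  out <- matrix(NA_real_, n, n)
  done <- matrix(FALSE, n, n)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  for (l in seq_len(lev)) {
    ci <- (ij$i - 1L) %/% (2^(l - 1L)) + 1L
    cj <- (ij$j - 1L) %/% (2^(l - 1L)) + 1L
    rc <- raws[[l]][cbind(ci, cj)]
    hit <- !done & !is.na(rc) & rc >= cutoff_counts
    out[cbind(ij$i, ij$j)[hit, , drop = FALSE]] <-
      bals[[l]][cbind(ci, cj)[hit, , drop = FALSE]]
    done <- done | matrix(hit, n, n)
    if (all(done)) break
  }
  if (!all(done)) {
    ci <- (ij$i - 1L) %/% (2^(lev - 1L)) + 1L
    cj <- (ij$j - 1L) %/% (2^(lev - 1L)) + 1L
    rest <- !done
    vals <- bals[[lev]][cbind(ci, cj)]
    rc <- raws[[lev]][cbind(ci, cj)]
    vals[is.na(rc) | rc == 0] <- NA_real_
    out[cbind(ij$i, ij$j)[rest, , drop = FALSE]] <- vals[rest]
  }
  out
}
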