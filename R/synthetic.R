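#' Recipe for a synthetic contact map
#'
#' Encodes the generative model for a balanced-like Hi-C map with known
#' ground truth: power-law distance decay within chromosomes, a flat
#' inter-chromosomal level, checkerboard compartments, insulating domains,
#' focal dot enrichments, masked (unmappable) bins and Poisson sampling
#' noise. Every analysis module has a parameter-recovery test against maps
#' generated from such recipes.
#'
#' The expected intensity of a bin pair (i, j) is
#' `base * decay * (1 + A v_i v_j) * domain_factor * dot_factor`, where in cis
#' `decay = max(d, 1)^alpha` for separation `d` bins and
#' `domain_factor = depletion^-(boundaries crossed)`; in trans the base is
#' `trans_level` and decay/domain factors are 1. Counts are Poisson with
#' total depth `depth`; bad bins are zeroed and get missing weights.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp
#'   (default two chromosomes of 300 bins at 10 kb).
#' @param binsize Bin size in bp (default 10000).
#' @param alpha Distance-decay exponent (default -1).
#' @param trans_level Trans intensity relative to the cis intensity at
#'   distance 1 bin (default 0.05).
#' @param comp_strength Compartment checkerboard strength `A` in `[0, 1)`
#'   (default 0: no compartments).
#' @param comp_block_bins Block length of the alternating +1/-1 compartment
#'   vector (default 25 bins); ignored when `comp_vector` is given.
#' @param comp_vector Optional explicit per-bin vector of +1/-1.
#' @param boundaries Named list (by chromosome) of boundary positions in bins
#'   from the chromosome start, or NULL.
#' @param domain_depletion Factor (>= 1) by which contacts crossing a domain
#'   boundary are depleted (default 4).
#' @param dots data.frame with `bin1`, `bin2` (genome-wide 0-based bin ids),
#'   `enrichment`, or NULL.
#' @param dot_halfwidth Half-width of the Gaussian dot spot in bins
#'   (default 1; the spot spans `(2h+1)^2` pixels).
#' @param bad_frac Fraction of bins masked at random (default 0.05).
#' @param depth Expected total contact count (default 1e6).
#' @param seed Integer seed; the map is reproducible from (recipe, seed).
#' @return A list of class `map_recipe`.
#' @export
map_recipe <- function(chrom_lengths = c(chr1 = 3e6, chr2 = 3e6),
                       binsize = 1e4, alpha = -1, trans_level = 0.05,
                       comp_strength = 0, comp_block_bins = 25L,
                       comp_vector = NULL, boundaries = NULL,
                       domain_depletion = 4, dots = NULL, dot_halfwidth = 1L,
                       bad_frac = 0.05, depth = 1e6, seed = 42L) {
  stopifnot(trans_level > 0, domain_depletion > 0, comp_strength >= 0,
            comp_strength < 1, bad_frac >= 0, bad_frac < 1, depth >= 0)
  structure(list(chrom_lengths = chrom_lengths, binsize = binsize,
                 alpha = alpha, trans_level = trans_level,
                 comp_strength = comp_strength,
                 comp_block_bins = as.integer(comp_block_bins),
                 comp_vector = comp_vector, boundaries = boundaries,
                 domain_depletion = domain_depletion, dots = dots,
                 dot_halfwidth = as.integer(dot_halfwidth),
                 bad_frac = bad_frac, depth = depth, seed = as.integer(seed)),
            class = "map_recipe")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Expected (noise-free) intensity matrix of a recipe
#'
#' Dense symmetric matrix of relative expected intensities before Poisson
#' sampling and bad-bin masking; used internally by [generate_map()] and by
#' validation against analytic ground truth.
#'
#' @param recipe A [map_recipe()].
#' @return List with `M` (matrix), `bins`, `chroms`, `v` (compartment
#'   vector), `bnd_bins` (genome-wide 0-based boundary bin ids per chrom).
#' @export
recipe_intensity <- function(recipe) {
  bs <- recipe$binsize
  chroms <- data.frame(name = names(recipe$chrom_lengths),
                       length = as.numeric(recipe$chrom_lengths),
                       stringsAsFactors = FALSE)
  bins <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(k) {
    n <- ceiling(chroms$length[k] / bs)
    data.frame(chrom = chroms$name[k], start = (seq_len(n) - 1) * bs,
               end = pmin(seq_len(n) * bs, chroms$length[k]),
               stringsAsFactors = FALSE)
  }))
  nb <- nrow(bins)
  chrom_of <- bins$chrom
  pos <- unlist(lapply(table(factor(chrom_of, levels = chroms$name)),
                       seq_len), use.names = FALSE) - 1L  # bin index within chrom

  v <- recipe$comp_vector
  if (is.null(v)) {
    blk <- recipe$comp_block_bins
    v <- ifelse((pos %/% blk) %% 2L == 0L, 1, -1)
  }
  stopifnot(length(v) == nb)

  same <- outer(chrom_of, chrom_of, "==")
  d <- abs(outer(pos, pos, "-"))
  M <- matrix(recipe$trans_level, nb, nb)
  decay <- pmax(d, 1)^recipe$alpha
  M[same] <- decay[same]
  if (recipe$comp_strength > 0)
    M <- M * (1 + recipe$comp_strength * outer(v, v))

  bnd_global <- list()
  if (!is.null(recipe$boundaries)) {
    # domain depletion: cis pairs crossing k boundaries are divided by depletion^k
    for (ch in names(recipe$boundaries)) {
      b <- sort(recipe$boundaries[[ch]])
      sel <- chrom_of == ch
      p <- pos[sel]
      dom <- findInterval(p, b)  # domain index within chromosome
      ncross <- abs(outer(dom, dom, "-"))
      M[sel, sel] <- M[sel, sel] * recipe$domain_depletion^(-ncross)
      bnd_global[[ch]] <- which(sel)[p %in% b] - 1L
    }
  }
  if (!is.null(recipe$dots) && nrow(recipe$dots)) {
    h <- recipe$dot_halfwidth
    sig <- max(h, 1) / 2
    for (r in seq_len(nrow(recipe$dots))) {
      i0 <- recipe$dots$bin1[r]; j0 <- recipe$dots$bin2[r]
      enr <- recipe$dots$enrichment[r]
      ii <- (i0 - h):(i0 + h); jj <- (j0 - h):(j0 + h)
      ok_i <- ii >= 0 & ii < nb; ok_j <- jj >= 0 & jj < nb
      spot <- outer(exp(-((-h:h)^2) / (2 * sig^2)),
                    exp(-((-h:h)^2) / (2 * sig^2)))
      fac <- 1 + (enr - 1) * spot[ok_i, ok_j, drop = FALSE]
      M[ii[ok_i] + 1L, jj[ok_j] + 1L] <- M[ii[ok_i] + 1L, jj[ok_j] + 1L] * fac
      M[jj[ok_j] + 1L, ii[ok_i] + 1L] <- M[jj[ok_j] + 1L, ii[ok_i] + 1L] * t(fac)
    }
  }
  if (any(M <= 0) || any(!is.finite(M)) || min(M) < 1e-300)
    stop("recipe intensity underflows or is non-positive")
  list(M = M, bins = bins, chroms = chroms, v = v, bnd_bins = bnd_global)
}

#' Generate a synthetic cooler-schema map with ground truth
#'
#' Samples Poisson counts from the recipe's intensity matrix, masks bad bins,
#' balances the map with [iterative_correction()], writes a `.cool` file, and
#' returns the opened store together with the truth tables (compartment
#' vector, boundary list, dot list, decay exponent, bad bins).
#'
#' @param recipe A [map_recipe()].
#' @param path Output `.cool` path (default: tempfile).
#' @param balance Compute and store balancing weights (default TRUE).
#' @return List with `store` (an open `ContactStore`), `path`, and `truth`
#'   (list: `v`, `boundaries`, `dots`, `alpha`, `bad_bins`, `recipe`).
#' @export
generate_map <- function(recipe, path = tempfile(fileext = ".cool"),
                         balance = TRUE) {
  ri <- recipe_intensity(recipe)
  nb <- nrow(ri$bins)
  with_seed(recipe$seed, {
    up <- upper.tri(ri$M, diag = TRUE)
    p <- ri$M[up] / sum(ri$M[up])
    counts <- if (recipe$depth > 0) stats::rpois(length(p), recipe$depth * p)
              else integer(length(p))
    bad <- if (recipe$bad_frac > 0)
      sort(sample.int(nb, round(recipe$bad_frac * nb))) else integer()

    ij <- which(up, arr.ind = TRUE)
    keep <- counts > 0 & !(ij[, 1L] %in% bad) & !(ij[, 2L] %in% bad)
    px <- data.frame(bin1_id = ij[keep, 1L] - 1L, bin2_id = ij[keep, 2L] - 1L,
                     count = counts[keep])
    px <- px[order(px$bin1_id, px$bin2_id), ]
    bins <- ri$bins
    write_cool(path, ri$chroms, bins, px, recipe$binsize)
    store <- open_store(path)
    if (balance) {
      w <- iterative_correction(store)
      w[bad] <- NA_real_
      wh <- w; wh[is.na(wh)] <- NaN
      rhdf5::h5write(wh, path, "bins/weight")
      store <- open_store(path)
    }
    list(store = store, path = path,
         truth = list(v = ri$v, boundaries = ri$bnd_bins,
                      dots = recipe$dots, alpha = recipe$alpha,
                      bad_bins = bad - 1L, recipe = recipe))
  })
}
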