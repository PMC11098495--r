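# Builders for small deterministic fixtures and dense oracles.
# Oracles work from plain dense matrices and never call the chunked/sparse
# code paths they are used to check.

# Store from an explicit dense symmetric count matrix (one or two chroms).
# weights: numeric vector (NA = bad bin) or NULL for an unweighted store.
toy_store <- function(M, binsize = 1000, nchrom = 1L, weights = NULL,
                      path = tempfile(fileext = ".cool")) {
  stopifnot(isSymmetric(unname(M)))
  nb <- nrow(M)
  per <- nb %/% nchrom
  chroms <- data.frame(name = paste0("chr", seq_len(nchrom)),
                       length = c(rep(per * binsize, nchrom - 1),
                                  (nb - per * (nchrom - 1)) * binsize))
  bins <- do.call(rbind, lapply(seq_len(nchrom), function(k) {
    n <- if (k < nchrom) per else nb - per * (nchrom - 1)
    data.frame(chrom = chroms$name[k], start = (seq_len(n) - 1) * binsize,
               end = seq_len(n) * binsize)
  }))
  if (!is.null(weights)) bins$weight <- weights
  up <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  px <- data.frame(bin1_id = up[, 1] - 1L, bin2_id = up[, 2] - 1L,
                   count = M[up])
  px <- px[order(px$bin1_id, px$bin2_id), ]
  write_cool(path, chroms, bins, px, binsize)
  open_store(path)
}

# Dense symmetric (optionally balanced) matrix straight from the pixel table.
dense_oracle <- function(store, use_weights = FALSE) {
  px <- read_pixels(store)
  nb <- store$nbins
  M <- matrix(0, nb, nb)
  for (r in seq_len(nrow(px))) {
    i <- px$bin1_id[r] + 1L; j <- px$bin2_id[r] + 1L
    M[i, j] <- M[i, j] + px$count[r]
    if (i != j) M[j, i] <- M[j, i] + px$count[r]
  }
  if (!isFALSE(use_weights)) {
    w <- store$bins$weight
    M <- M * outer(w, w)
  }
  M
}

# Brute-force per-diagonal expected over one region's dense balanced matrix.
expected_oracle <- function(M, valid) {
  n <- nrow(M)
  do.call(rbind, lapply(0:(n - 1L), function(d) {
    i <- seq_len(n - d); j <- i + d
    ok <- valid[i] & valid[j]
    v <- M[cbind(i[ok], j[ok])]
    data.frame(dist = d, n_valid = sum(ok),
               balanced_sum = sum(v, na.rm = TRUE),
               balanced_avg = if (sum(ok)) sum(v, na.rm = TRUE) / sum(ok) else NA_real_)
  }))
}

# Dense diamond-window insulation oracle (raw mean over valid pairs).
insulation_oracle <- function(M, valid, w) {
  n <- nrow(M)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - 1 < w || i + w > n) next
    a <- (i - w):i
    b <- (i + 1):(i + w)
    pairs <- expand.grid(a = a, b = b)
    ok <- valid[pairs$a] & valid[pairs$b]
    if (!sum(ok)) next
    raw[i] <- mean(M[cbind(pairs$a[ok], pairs$b[ok])])
  }
  raw
}

# Shared synthetic fixtures, built once per test run.
fx_env <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!is.null(fx_env[[name]])) return(fx_env[[name]])
  fx_env[[name]] <- switch(name,
    decay = generate_map(map_recipe(depth = 1e6, seed = 101)),
    comp = generate_map(map_recipe(comp_strength = 0.3, depth = 1e6, seed = 102)),
    bnd = generate_map(map_recipe(
      boundaries = list(chr1 = c(75, 150, 225), chr2 = c(60, 120, 180, 240)),
      depth = 1e6, seed = 103)),
    dots = {
      d <- plant_dots(104)
      list(gen = generate_map(map_recipe(dots = d, depth = 1e6, seed = 104)),
           dots = d)
    },
    stop("unknown fixture ", name))
  fx_env[[name]]
}

# 50 focal dots at loop-scale separations (50-250 kb at 10 kb bins),
# enrichment 3-5x, kept >= 6 bins apart.
plant_dots <- function(seed, nper = 25L, dmin = 5L, dmax = 25L) {
  set.seed(seed)
  d <- data.frame()
  for (ch in 0:1) {
    got <- 0L
    while (got < nper) {
      i <- sample(10:260, 1L)
      j <- i + sample(dmin:dmax, 1L)
      if (nrow(d) && any(abs(d$bin1 - (ch * 300L + i)) <= 5 &
                           abs(d$bin2 - (ch * 300L + j)) <= 5)) next
      d <- rbind(d, data.frame(bin1 = ch * 300L + i, bin2 = ch * 300L + j,
                               enrichment = stats::runif(1, 3, 5)))
      got <- got + 1L
    }
  }
  d
}

bin_track <- function(store, values) {
  cbind(store$bins[c("chrom", "start", "end")], data.frame(value = values))
}
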