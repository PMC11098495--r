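test_that("uniform maps give zero log2 insulation at interior bins", {
  n <- 30
  st <- toy_store(matrix(1, n, n), weights = rep(1, n))
  ins <- insulation_profile(st, window_bp = 5000)  # w = 5 bins
  interior <- !is.na(ins$score)
  expect_equal(which(interior), 6:25)
  expect_equal(ins$raw[interior], rep(1, 20))
  expect_equal(ins$score[interior], rep(0, 20))
})

test_that("a two-block diagonal map has its unique minimum at the junction", {
  n <- 40
  M <- matrix(0, n, n)
  M[1:20, 1:20] <- 1; M[21:40, 21:40] <- 1
  st <- toy_store(M, weights = rep(1, n))
  ins <- find_boundaries(insulation_profile(st, window_bp = 5000))
  expect_equal(which(ins$is_min), 20L)
})

test_that("sparse-chunked profile equals the dense diamond oracle", {
  set.seed(13)
  n <- 80
  M <- matrix(rpois(n * n, 0.7), n, n); M <- M + t(M)
  w <- runif(n, 0.7, 1.4); w[c(11, 12, 40)] <- NA
  st <- toy_store(M, weights = w)
  wbins <- 7L
  ins <- insulation_profile(st, window_bp = 7000, min_valid_frac = 0)
  raw_oracle <- insulation_oracle(dense_oracle(st, use_weights = TRUE),
                                  !is.na(w), wbins)
  expect_equal(ins$raw, raw_oracle, tolerance = 1e-10)
  sc_oracle <- log2(raw_oracle / mean(raw_oracle, na.rm = TRUE))
  expect_equal(ins$score, sc_oracle, tolerance = 1e-10)
})

test_that("prominence follows the topographic walk definition", {
  mk <- function(scores) {
    data.frame(chrom = "chr1", start = seq_along(scores), end = seq_along(scores) + 1,
               region = "chr1", window = 1000, score = scores,
               n_valid_pixels = 1, raw = 1)
  }
  # V shape: one minimum, prominence 2
  b <- find_boundaries(mk(c(3, 1, 3)))
  expect_equal(which(b$is_min), 2L)
  expect_equal(b$prominence[2], 2)
  # monotone profile: no minima
  expect_false(any(find_boundaries(mk(1:6))$is_min))
  # plateau: leftmost bin reported, tie flagged
  p <- find_boundaries(mk(c(5, 2, 2, 2, 5)))
  expect_equal(which(p$is_min), 2L)
  expect_true(p$plateau_tie[2])

  # two minima: the shallower one is limited by the saddle toward the deeper
  prof <- c(5, 1, 4, 2, 6)
  b2 <- find_boundaries(mk(prof))
  expect_equal(which(b2$is_min), c(2L, 4L))
  # exhaustive path-walk oracle
  walk_prom <- function(x, m) {
    best <- c(-Inf, -Inf)
    for (dir in 1:2) {
      hi <- -Inf
      ps <- if (dir == 1) (m - 1):1 else (m + 1):length(x)
      for (p in ps) {
        hi <- max(hi, x[p])
        if (x[p] < x[m]) break
      }
      best[dir] <- hi
    }
    min(best) - x[m]
  }
  expect_equal(b2$prominence[2], walk_prom(prof, 2))
  expect_equal(b2$prominence[4], walk_prom(prof, 4))
  expect_equal(b2$prominence[4], 2)  # saddle at 4 toward the deeper minimum

  # prominence is invariant to adding a constant
  b3 <- find_boundaries(mk(prof + 7))
  expect_equal(b3$prominence[b3$is_min], b2$prominence[b2$is_min])
})

test_that("Otsu and Li thresholds separate a bimodal prominence set", {
  set.seed(21)
  proms <- c(rep(0.01, 100) + runif(100, 0, 0.005), rep(1, 20) + runif(20, 0, 0.1))
  thr <- threshold_otsu(proms)
  expect_true(thr > 0.02 && thr <= 1.2)
  # exhaustive-threshold oracle: maximize between-class variance
  cands <- sort(unique(proms))[-1]
  bcv <- vapply(cands, function(t) {
    lo <- proms[proms < t]; hi <- proms[proms >= t]
    length(lo) / length(proms) * length(hi) / length(proms) *
      (mean(lo) - mean(hi))^2
  }, 0)
  expect_equal(thr, cands[which.max(bcv)])
  thr_li <- threshold_li(proms)
  expect_true(thr_li > 0.02 && thr_li <= 1.2)

  tab <- data.frame(chrom = "c", start = seq_along(proms),
                    end = seq_along(proms) + 1, region = "c", window = 1000,
                    score = 0, n_valid_pixels = 1, raw = 1,
                    is_min = TRUE, prominence = proms, plateau_tie = FALSE)
  got <- threshold_boundaries(tab, "Otsu")
  expect_equal(got$is_strong, proms >= thr)
  # fixed threshold flags by direct comparison
  got2 <- threshold_boundaries(tab, 0.5)
  expect_equal(got2$is_strong, proms >= 0.5)
  # degenerate: single distinct prominence flagged strong with warning
  tab1 <- tab[1:3, ]; tab1$prominence <- 0.2
  expect_warning(got3 <- threshold_boundaries(tab1, "Otsu"), "strong")
  expect_true(all(got3$is_strong))
})

test_that("planted boundaries are recovered within one bin and flagged strong", {
  # a planted boundary is the edge between bins b-1 and b: recovery means a
  # strong minimum within one bin of either junction-flanking bin
  g <- fx("bnd")
  st <- g$store
  ins <- threshold_boundaries(find_boundaries(
    insulation_profile(st, window_bp = 2e5)), "Otsu")
  found <- 0L; total <- 0L
  for (ch in names(g$truth$boundaries)) {
    chrom_start_bin <- min(which(st$bins$chrom == ch)) - 1L
    strong <- ins$start[ins$is_strong & ins$region == ch] / st$binsize
    for (b in g$truth$boundaries[[ch]] - chrom_start_bin) {
      total <- total + 1L
      if (length(strong) &&
          min(pmin(abs(strong - b), abs(strong - (b - 1)))) <= 1)
        found <- found + 1L
    }
  }
  expect_gte(found / total, 0.9)
})

test_that("window arguments are validated", {
  st <- toy_store(matrix(1, 10, 10), weights = rep(1, 10))
  expect_error(insulation_profile(st, window_bp = 1500), "multiple")
  expect_error(insulation_profile(st, window_bp = 1000), "2 bins")
})
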