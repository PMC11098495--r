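test_that("stock kernel masks match their printed definitions", {
  k <- dot_kernels(w = 2L, p = 1L)
  expect_equal(unname(k$donut), matrix(as.integer(c(
    1, 1, 0, 1, 1,
    1, 0, 0, 0, 1,
    0, 0, 0, 0, 0,
    1, 0, 0, 0, 1,
    1, 1, 0, 1, 1)), 5, 5, byrow = TRUE))
  expect_equal(unname(k$vertical), matrix(as.integer(c(
    0, 1, 1, 1, 0,
    0, 0, 0, 0, 0,
    0, 0, 0, 0, 0,
    0, 0, 0, 0, 0,
    0, 1, 1, 1, 0)), 5, 5, byrow = TRUE))
  expect_equal(unname(k$horizontal), t(k$vertical))
  expect_equal(unname(k$lowerleft), matrix(as.integer(c(
    0, 0, 0, 0, 0,
    0, 0, 0, 0, 0,
    0, 0, 0, 0, 0,
    1, 0, 0, 0, 0,
    1, 1, 0, 0, 0)), 5, 5, byrow = TRUE))
  # aliases
  k2 <- dot_kernels(w = 2L, p = 1L, names = c("top", "bottom"))
  expect_equal(k2$vertical, k$vertical)
  expect_equal(k2$horizontal, k$horizontal)
  # center always excluded
  for (m in dot_kernels()) expect_equal(m[6, 6], 0L)
})

test_that("pixel scores equal a dense brute-force convolution oracle", {
  set.seed(17)
  n <- 40
  M <- matrix(rpois(n * n, 4), n, n); M <- M + t(M)
  w <- runif(n, 0.8, 1.2); w[c(9, 24)] <- NA
  st <- toy_store(M, weights = w)
  ex <- expected_cis(st, smooth = FALSE)
  kernels <- dot_kernels(w = 3L, p = 1L)
  sc <- score_pixels(st, ex, kernels = kernels, max_dist_bp = 30 * st$binsize,
                     min_dist = 2L, tile_size_bp = n * st$binsize,
                     min_kernel_frac = 0.5)

  D <- dense_oracle(st, use_weights = TRUE)
  Draw <- dense_oracle(st, use_weights = FALSE)
  ev <- ex$balanced_avg
  for (r in sample(nrow(sc), 25)) {
    i <- sc$bin1_id[r] + 1L; j <- sc$bin2_id[r] + 1L
    for (kn in names(kernels)) {
      kk <- kernels[[kn]]
      num <- den <- 0
      for (di in -3:3) for (dj in -3:3) {
        if (kk[di + 4, dj + 4] == 0) next
        a <- i + di; b <- j + dj
        if (a < 1 || b < 1 || a > n || b > n) next
        if (is.na(w[a]) || is.na(w[b])) next
        num <- num + D[a, b]
        den <- den + ev[abs(a - b) + 1]
      }
      lam <- (num / den) * ev[j - i + 1] / (w[i] * w[j])
      expect_equal(sc[[paste0("la_", kn)]][r], lam, tolerance = 1e-10)
    }
    expect_equal(sc$count[r], Draw[i, j])
  }
})

test_that("tile size does not change scores and runs are deterministic", {
  fxd <- fx("dots")
  st <- fxd$gen$store
  ex <- expected_cis(st)
  sc1 <- score_pixels(st, ex, tile_size_bp = 3e6)
  sc2 <- score_pixels(st, ex, tile_size_bp = 64 * st$binsize)
  sc3 <- score_pixels(st, ex, tile_size_bp = 97 * st$binsize)
  expect_equal(sc2, sc1, tolerance = 1e-12)
  expect_equal(sc3, sc1, tolerance = 1e-12)
  expect_identical(lambda_bh(sc1), lambda_bh(sc1))
})

test_that("a single injected dot on a uniform background scores its enrichment", {
  # n large enough that the dot barely contaminates its diagonal's expected
  n <- 200
  M <- matrix(20, n, n)
  i0 <- 80; j0 <- 95
  M[i0, j0] <- M[j0, i0] <- 200  # 10x
  st <- toy_store(M, weights = rep(1, n))
  ex <- expected_cis(st, smooth = FALSE)
  sc <- score_pixels(st, ex, max_dist_bp = 50 * st$binsize,
                     tile_size_bp = n * st$binsize)
  r <- sc[sc$bin1_id == i0 - 1 & sc$bin2_id == j0 - 1, ]
  expect_equal(r$enr_donut, 10, tolerance = 0.06)
  expect_equal(r$enr_lowerleft, 10, tolerance = 0.06)
})

test_that("lambda-chunked BH reduces to textbook BH within one chunk", {
  set.seed(23)
  base <- 2^(1 / 3)
  sc <- data.frame(region = "r", bin1_id = 1:200, bin2_id = 51:250,
                   dist = 50L, count = rpois(200, 4), exp_raw = 4)
  sc$la_donut <- runif(200, base^3 * 1.001, base^4 * 0.999)  # one chunk
  out <- lambda_bh(sc, fdr_q = 0.1)
  p <- ppois(sc$count - 1, base^4, lower.tail = FALSE)
  expect_equal(out$q_donut, p.adjust(p, "BH"), tolerance = 1e-12)
  # observation below lambda is never significant
  low <- data.frame(region = "r", bin1_id = 1L, bin2_id = 9L, dist = 8L,
                    count = 3, exp_raw = 10, la_donut = 10)
  expect_false(lambda_bh(low, fdr_q = 0.1)$significant)
})

test_that("clustering matches connected components and respects the radius", {
  st <- toy_store(matrix(1, 50, 50), weights = rep(1, 50))
  mk_sig <- function(b1, b2) {
    data.frame(region = "chr1", bin1_id = b1, bin2_id = b2,
               dist = b2 - b1, count = 10, exp_raw = 1,
               la_donut = 1, enr_donut = 10, q_donut = 1e-5,
               la_lowerleft = 1, enr_lowerleft = 10, q_lowerleft = 1e-5,
               significant = TRUE)
  }
  # adjacent pixels cluster; the centroid is one call
  two <- mk_sig(c(10L, 11L), c(20L, 20L))
  got <- cluster_filter(two, st, radius_bp = 2000)
  expect_equal(nrow(got), 1L)
  expect_equal(got$cluster_size, 2L)
  # pixels beyond the radius stay separate
  far <- mk_sig(c(10L, 30L), c(20L, 45L))
  expect_equal(nrow(cluster_filter(far, st, radius_bp = 2000)), 2L)

  # 30-pixel set vs a BFS connected-components oracle
  set.seed(19)
  b1 <- sample(5:45, 30, replace = TRUE)
  b2 <- b1 + sample(5:20, 30, replace = TRUE)
  sig <- mk_sig(as.integer(b1), as.integer(b2))
  radius <- 3000
  got2 <- cluster_filter(sig, st, radius_bp = radius)
  x <- b1 * 1000 + 500; y <- b2 * 1000 + 500
  adj <- outer(x, x, "-")^2 + outer(y, y, "-")^2 <= radius^2
  comp <- rep(NA_integer_, 30); cid <- 0L
  for (s in 1:30) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  expect_equal(nrow(got2), cid)
  expect_equal(sort(got2$cluster_size), as.vector(sort(table(comp))))
})

test_that("planted dots are recovered with high precision and recall", {
  fxd <- fx("dots")
  st <- fxd$gen$store
  dots <- fxd$dots
  ex <- expected_cis(st)
  calls <- call_dots(st, ex, fdr_q = 0.1)
  bad <- fxd$gen$truth$bad_bins
  detectable <- !(dots$bin1 %in% bad | dots$bin2 %in% bad)
  tp <- mapply(function(ci, cj) any(abs(dots$bin1 - ci) <= 1 &
                                      abs(dots$bin2 - cj) <= 1),
               calls$bin1_id, calls$bin2_id)
  recd <- vapply(seq_len(nrow(dots)), function(k)
    any(abs(calls$bin1_id - dots$bin1[k]) <= 1 &
          abs(calls$bin2_id - dots$bin2[k]) <= 1), TRUE)
  expect_gte(mean(tp), 0.8)                 # precision
  expect_gte(mean(recd[detectable]), 0.8)   # recall over unmasked dots
})
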