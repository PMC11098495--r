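test_that("coverage matches dense marginals and conserves the pixel sum", {
  set.seed(41)
  n <- 30
  M <- matrix(rpois(n * n, 3), n, n); M <- M + t(M)
  diag(M) <- rpois(n, 5)
  w <- runif(n, 0.5, 2); w[4] <- NA
  st <- toy_store(M, nchrom = 2L, weights = w)
  cv <- coverage(st)

  chrom_of <- st$bins$chrom
  same <- outer(chrom_of, chrom_of, "==")
  # oracle marginals: off-diagonal counted from both sides, diagonal once
  Mo <- M; diag(Mo) <- 0
  tot_oracle <- rowSums(Mo) + diag(M)
  cis_oracle <- rowSums(Mo * same) + diag(M)
  expect_equal(cv$total_raw, tot_oracle)
  expect_equal(cv$cis_raw, cis_oracle)
  expect_true(all(cv$cis_raw <= cv$total_raw))
  expect_equal(cv$cis_ratio, cis_oracle / tot_oracle)
  expect_true(is.na(cv$total_balanced[4]))

  px <- read_pixels(st)
  offd <- px$bin1_id != px$bin2_id
  expect_equal(sum(cv$total_raw),
               2 * sum(px$count[offd]) + sum(px$count[!offd]))

  # single-chromosome store: cis ratio one wherever covered
  st1 <- toy_store(M, weights = w)
  cv1 <- coverage(st1)
  expect_true(all(cv1$cis_ratio[cv1$total_raw > 0] == 1))

  # an empty bin has zero coverage
  B <- matrix(4, 5, 5); B[3, ] <- 0; B[, 3] <- 0
  cvB <- coverage(toy_store(B))
  expect_equal(cvB$total_raw[3], 0)
})

test_that("binomial downsampling is seeded, bounded, and exact at fraction one", {
  g <- fx("decay")
  st <- g$store
  px <- read_pixels(st)
  N <- sum(px$count)

  same1 <- downsample(st, fraction = 1, seed = 5)
  expect_identical(read_pixels(same1), px)

  d1 <- downsample(st, fraction = 0.5, seed = 7)
  d2 <- downsample(st, fraction = 0.5, seed = 7)
  expect_identical(read_pixels(d1), read_pixels(d2))  # same seed, same file
  d3 <- downsample(st, fraction = 0.5, seed = 8)
  expect_false(identical(read_pixels(d1), read_pixels(d3)))

  tot <- sum(read_pixels(d1)$count)
  expect_lt(abs(tot - 0.5 * N), 3 * sqrt(N * 0.25))
  # target_count interface
  d4 <- downsample(st, target_count = round(N / 4), seed = 9)
  expect_lt(abs(sum(read_pixels(d4)$count) - N / 4), 4 * sqrt(N * 3 / 16))
  expect_error(downsample(st, fraction = 1.5), "fraction")
})

test_that("adaptive smoothing selects the finest sufficiently-sequenced level", {
  # deeply sequenced everywhere: output equals the balanced input
  n <- 32
  M <- matrix(50, n, n)
  st <- toy_store(M, weights = rep(1, n))
  reg <- list(chrom = "chr1", start = 0, end = n * 1000)
  out <- adaptive_smooth(st, reg, cutoff_counts = 10)
  expect_equal(out, fetch_dense(st, 0:(n - 1)), tolerance = 1e-12)

  # all-zero matrix (every bin filtered out): all missing
  z <- toy_store(matrix(0, 8, 8), weights = rep(NA_real_, 8))
  outz <- adaptive_smooth(z, list(chrom = "chr1", start = 0, end = 8000),
                          cutoff_counts = 5)
  expect_true(all(is.na(outz)))

  # 64-bin sparse toy vs an explicit per-cell pyramid-search oracle
  set.seed(43)
  n <- 64
  S <- matrix(rpois(n * n, 0.8) * 4, n, n); S <- pmax(S, t(S))
  st2 <- toy_store(S, weights = rep(1, n))
  cutoff <- 30
  got <- adaptive_smooth(st2, list(chrom = "chr1", start = 0, end = n * 1000),
                         cutoff_counts = cutoff, max_levels = 5)
  raw <- fetch_dense(st2, 0:(n - 1), use_weights = FALSE)
  bal <- fetch_dense(st2, 0:(n - 1))
  raws <- list(raw); bals <- list(bal)
  for (l in 2:5) {
    m <- ncol(raws[[l - 1]]); m2 <- m / 2
    r2 <- matrix(0, m2, m2); b2 <- matrix(0, m2, m2)
    for (a in 1:m2) for (b in 1:m2) {
      r2[a, b] <- sum(raws[[l - 1]][2 * a - 1:0, 2 * b - 1:0])
      b2[a, b] <- mean(bals[[l - 1]][2 * a - 1:0, 2 * b - 1:0])
    }
    raws[[l]] <- r2; bals[[l]] <- b2
  }
  want <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    for (l in 1:5) {
      ci <- (i - 1) %/% 2^(l - 1) + 1; cj <- (j - 1) %/% 2^(l - 1) + 1
      if (raws[[l]][ci, cj] >= cutoff || l == 5) {
        v <- bals[[l]][ci, cj]
        want[i, j] <- if (l == 5 && raws[[l]][ci, cj] == 0) NA_real_ else v
        break
      }
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
  # redistributed, not created: total balanced mass conserved
  expect_equal(sum(got, na.rm = TRUE), sum(bal), tolerance = 0.01 * sum(bal))
})

test_that("downsampling preserves per-pixel expectation across seeds", {
  g <- fx("decay")
  st <- g$store
  px <- read_pixels(st)
  set.seed(45)
  probes <- sample(which(px$count >= 5), 20)
  frac <- 0.3
  sums <- matrix(0, 50, 20)
  for (s in 1:50) {
    d <- downsample(st, fraction = frac, seed = 1000 + s)
    pd <- read_pixels(d)
    key <- paste(pd$bin1_id, pd$bin2_id)
    hit <- match(paste(px$bin1_id[probes], px$bin2_id[probes]), key)
    sums[s, ] <- ifelse(is.na(hit), 0, pd$count[hit])
    unlink(d$path)
  }
  m <- colMeans(sums)
  se <- sqrt(px$count[probes] * frac * (1 - frac) / 50)
  expect_true(all(abs(m - frac * px$count[probes]) <= 3.5 * se + 1e-9))
})
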