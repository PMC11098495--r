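test_that("snippets match a direct dense-slicing oracle", {
  set.seed(31)
  n <- 50
  M <- matrix(rpois(n * n, 5), n, n); M <- M + t(M)
  w <- runif(n, 0.8, 1.2); w[20] <- NA
  st <- toy_store(M, weights = w)
  view <- make_view(st)
  ex <- expected_cis(st, smooth = FALSE)
  f <- 3L
  anchors <- data.frame(chrom1 = "chr1", start1 = c(10, 25, 33) * 1000,
                        end1 = c(11, 26, 34) * 1000,
                        chrom2 = "chr1", start2 = c(18, 30, 45) * 1000,
                        end2 = c(19, 31, 46) * 1000)
  stk <- snip(st, anchors, view, flank_bp = f * 1000, mode = "oe",
              expected = ex)
  D <- dense_oracle(st, use_weights = TRUE)
  ev <- ex$balanced_avg
  for (s in 1:3) {
    i0 <- anchors$start1[s] / 1000 + 1; j0 <- anchors$start2[s] / 1000 + 1
    want <- matrix(NA_real_, 2 * f + 1, 2 * f + 1)
    for (a in -f:f) for (b in -f:f) {
      i <- i0 + a; j <- j0 + b
      if (i < 1 || j < 1 || i > n || j > n) next
      want[a + f + 1, b + f + 1] <- D[i, j] / ev[abs(i - j) + 1]
    }
    expect_equal(stk$stack[s, , ], want, tolerance = 1e-12)
  }
})

test_that("snippets at region edges are missing-padded, never truncated", {
  n <- 30
  st <- toy_store(matrix(2, n, n), weights = rep(1, n))
  a <- data.frame(chrom = "chr1", start = 1000, end = 2000)  # bin 1
  stk <- snip(st, a, flank_bp = 4000, mode = "observed")
  expect_equal(dim(stk$stack), c(1L, 9L, 9L))
  expect_true(all(is.na(stk$stack[1, 1:3, 1:3])))
  expect_true(all(!is.na(stk$stack[1, 4:9, 4:9])))
})

test_that("uniform map in oe mode yields all-ones snippets", {
  n <- 40
  st <- toy_store(matrix(3, n, n), weights = rep(1, n))
  ex <- expected_cis(st, smooth = FALSE)
  a <- data.frame(chrom = "chr1", start = c(10, 20) * 1000,
                  end = c(11, 21) * 1000)
  stk <- snip(st, a, flank_bp = 3000, mode = "oe", expected = ex)
  expect_equal(stk$stack[1, , ], matrix(1, 7, 7))
})

test_that("anchors outside the view are dropped and counted", {
  n <- 30
  st <- toy_store(matrix(1, n, n), nchrom = 2L, weights = rep(1, n))
  view <- make_view(st, regions = data.frame(chrom = "chr1", start = 0,
                                             end = 15000, name = "r1"))
  a <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(5000, 20000, 3000), end = c(6000, 21000, 4000))
  stk <- snip(st, a, view, flank_bp = 2000, mode = "observed")
  expect_equal(dim(stk$stack)[1], 1L)
  expect_equal(stk$n_dropped, 2L)
  # an anchor pair spanning two regions is dropped
  view2 <- make_view(st)
  ap <- data.frame(chrom1 = "chr1", start1 = 5000, end1 = 6000,
                   chrom2 = "chr2", start2 = 5000, end2 = 6000)
  stk2 <- snip(st, ap, view2, flank_bp = 2000, mode = "observed")
  expect_equal(dim(stk2$stack)[1], 0L)
  expect_equal(stk2$n_dropped, 1L)
})

test_that("pileups average element-wise, ignore missing, and are order-invariant", {
  set.seed(33)
  a <- array(rnorm(5 * 7 * 7), c(5, 7, 7))
  a[2, 3, ] <- NA
  a[4, , ] <- NA  # one all-missing snippet
  p <- pileup(a)
  want <- apply(a, c(2, 3), function(v) mean(v, na.rm = TRUE))
  expect_equal(p$pileup, want)
  expect_equal(p$n[1, 1], 4)
  expect_equal(p$n[3, 2], 3)
  pm <- pileup(a, stat = "median")
  expect_equal(pm$pileup, apply(a, c(2, 3), function(v) median(v, na.rm = TRUE)))
  # permutation invariance
  perm <- c(3, 5, 1, 4, 2)
  expect_equal(pileup(a[perm, , ])$pileup, p$pileup)
  # stack of identical snippets averages to that snippet
  b <- array(rep(a[1, , ], each = 3), c(3, 7, 7))
  expect_equal(pileup(b)$pileup, a[1, , ])
})

test_that("snippet retrieval is identical under parallel execution", {
  g <- fx("decay")
  st <- g$store
  ex <- expected_cis(st)
  set.seed(35)
  bins <- sample(20:270, 8)
  a <- data.frame(chrom = "chr1", start = bins * 1e4, end = (bins + 1) * 1e4)
  s1 <- snip(st, a, flank_bp = 1e5, mode = "oe", expected = ex, nproc = 1)
  s2 <- snip(st, a, flank_bp = 1e5, mode = "oe", expected = ex, nproc = 2)
  expect_identical(s1$stack, s2$stack)
})

test_that("dot pileups are center-enriched and boundary pileups are insulated", {
  fxd <- fx("dots")
  st <- fxd$gen$store
  ex <- expected_cis(st)
  b <- st$bins
  d <- fxd$dots
  feats <- data.frame(chrom1 = b$chrom[d$bin1 + 1], start1 = b$start[d$bin1 + 1],
                      end1 = b$end[d$bin1 + 1],
                      chrom2 = b$chrom[d$bin2 + 1], start2 = b$start[d$bin2 + 1],
                      end2 = b$end[d$bin2 + 1])
  p <- pileup(snip(st, feats, flank_bp = 5e4, mode = "oe", expected = ex))$pileup
  f <- 6L  # center index for flank 5 bins
  corners <- p[c(1, 11), c(1, 11)]
  expect_gt(p[f, f], 2 * mean(corners))

  # on-diagonal pileup at planted insulation boundaries: the two
  # cross-boundary quadrants are depleted relative to within-domain quadrants
  gb <- fx("bnd")
  stb <- gb$store
  exb <- expected_cis(stb)
  bb <- stb$bins
  bnd <- unlist(gb$truth$boundaries)
  featsb <- data.frame(chrom = bb$chrom[bnd + 1], start = bb$start[bnd + 1],
                       end = bb$end[bnd + 1])
  pb <- pileup(snip(stb, featsb, flank_bp = 1e5, mode = "oe",
                    expected = exb))$pileup
  cross <- mean(pb[1:8, 14:21], na.rm = TRUE)
  within <- mean(c(pb[1:8, 1:8], pb[14:21, 14:21]), na.rm = TRUE)
  expect_lt(cross, 0.6 * within)
})
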