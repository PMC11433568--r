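test_that("circular sampling has 8r ordered samples with exact affine interpolation", {
  const <- matrix(5, 9, 9)
  for (r in 1:3) {
    nb <- sample_circle(const, 5, 5, r)
    expect_length(nb$samples, 8 * r)
    expect_true(all(nb$samples == 5))
  }

  # bilinear interpolation reproduces affine images exactly
  ramp <- matrix(rep(1:11, each = 11), 11, 11) # f(row, col) = col
  nb <- sample_circle(ramp, 6, 6, 2)
  th <- 2 * pi * (0:15) / 16
  expect_equal(nb$samples, 6 + 2 * cos(th), tolerance = 1e-9)

  # sample 0 is due east; index runs counter-clockwise (row decreases first)
  img <- matrix(0, 5, 5); img[3, 4] <- 1 # east of center
  expect_equal(sample_circle(img, 3, 3, 1)$samples[1], 1)
  img2 <- matrix(0, 5, 5); img2[2, 3] <- 1 # north of center
  expect_equal(sample_circle(img2, 3, 3, 1)$samples[3], 1)

  expect_error(sample_circle(const, 1, 5, 2), "valid region")
})

test_that("median quantization collapses arcs to 8 values and rejects outliers", {
  mk_nb <- function(samples, r, center = 0) {
    structure(list(samples = samples, center = center, r = r),
              class = "circular_neighborhood")
  }
  # r = 1: identity
  s <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(median_quantize(mk_nb(s, 1)), s)
  # r = 2: pair-wise mean-of-two median
  expect_equal(median_quantize(mk_nb(rep(c(10, 20), 8), 2)), rep(15, 8))
  # r = 3: middle order statistic rejects an outlier
  expect_equal(median_quantize(mk_nb(rep(c(5, 100, 7), 8), 3)), rep(7, 8))
})

test_that("mean local difference quantization averages |sample - center| per arc", {
  mk_nb <- function(samples, r, center) {
    structure(list(samples = samples, center = center, r = r),
              class = "circular_neighborhood")
  }
  expect_equal(mean_local_difference_quantize(mk_nb(rep(4, 8), 1, 4)),
               rep(0, 8))
  d <- c(1, -2, 3, -4, 5, -6, 7, -8)
  expect_equal(mean_local_difference_quantize(mk_nb(10 + d, 1, 10)), abs(d))
  expect_equal(mean_local_difference_quantize(mk_nb(rep(c(12, 6), 8), 2, 10)),
               rep(3, 8))
})

test_that("uniformity counts circular transitions and riu2 labels follow it", {
  expect_equal(uniformity(rep(0, 8)), 0)
  expect_equal(uniformity(c(0, 0, 0, 0, 1, 1, 1, 1)), 2)
  expect_equal(uniformity(rep(c(0, 1), 4)), 8)
  expect_equal(riu2_label(rep(1, 8)), 8)
  expect_equal(riu2_label(c(0, 0, 0, 0, 1, 1, 1, 1)), 4)
  expect_equal(riu2_label(rep(c(0, 1), 4)), 9)
  expect_error(uniformity(c(0, 2, 0, 0, 1, 1, 1, 1)), "0, 1")
  expect_error(riu2_label(c(1, 1)), "8 values")
})

test_that("riu2 labeling agrees with brute-force enumeration over all 256 patterns", {
  pats <- all_bit_patterns()
  mine <- apply(pats, 1, riu2_label)
  ref <- apply(pats, 1, oracle_riu2)
  expect_equal(mine, ref)
  expect_equal(length(unique(mine)), 10)
  uniform <- apply(pats, 1, uniformity) <= 2
  expect_equal(length(unique(mine[uniform])), 9)
  expect_equal(sort(unique(mine[uniform])), 0:8)
  # riu2 labels are invariant to circular shifts of the bits
  set.seed(4)
  for (v in sample(0:255, 40)) {
    bits <- as.integer(intToBits(v))[1:8]
    for (sh in 1:7) {
      expect_equal(riu2_label(bits), riu2_label(c(bits[-(1:sh)], bits[1:sh])))
    }
  }
})

test_that("pattern maps match the independent per-pixel oracle", {
  set.seed(21)
  for (case in 1:3) {
    r <- case
    n <- 7 + 2 * r
    img <- matrix(round(runif(n * n, 0, 255)), n, n)
    got <- pattern_maps(img, r)
    want <- oracle_pattern_maps(img, r)
    expect_equal(got$mstrp, want$mstrp, info = paste("mstrp r =", r))
    expect_equal(got$nrtxp, want$nrtxp, info = paste("nrtxp r =", r))
    expect_equal(got$ritxp, want$ritxp, info = paste("ritxp r =", r))
  }
})

test_that("constant and impulse images give the predicted labels", {
  const <- matrix(9, 9, 9)
  for (r in 1:2) {
    maps <- pattern_maps(const, r)
    valid <- maps$mstrp >= 0
    expect_true(all(maps$mstrp[valid] == 8)) # s(0) = 1 on every arc
    expect_true(all(maps$nrtxp[valid] == 8))
    expect_true(all(maps$ritxp[valid] == 1))
    expect_true(all(maps$mstrp[!valid] == -1))
  }
  # bright impulse on a flat field: its own mldqp is uniformly positive and
  # beats the ring threshold, so the impulse pixel keeps label 8
  imp <- matrix(10, 5, 5); imp[3, 3] <- 200
  expect_equal(pattern_maps(imp, 1)$nrtxp[3, 3], 8L)
  # dark center under a brighter ring thresholds to 0
  dark <- matrix(200, 5, 5); dark[3, 3] <- 10
  expect_equal(pattern_maps(dark, 1)$ritxp[3, 3], 0L)
})

test_that("label alphabets and neighborhood sizes match the design constants", {
  for (r in 1:9) {
    n <- 8 * r
    th <- 2 * pi * (0:(n - 1)) / n
    expect_length(th, 8 * r)
  }
  img <- matrix(runif(21 * 21, 0, 255), 21, 21)
  nb <- sample_circle(img, 11, 11, 9)
  expect_length(nb$samples, 72)
  expect_length(median_quantize(nb), 8)
  expect_length(mean_local_difference_quantize(nb), 8)
  maps <- pattern_maps(img, 2)
  expect_true(all(maps$mstrp %in% c(-1L, 0:9)))
  expect_true(all(maps$nrtxp %in% c(-1L, 0:9)))
  expect_true(all(maps$ritxp %in% c(-1L, 0L, 1L)))
})

test_that("rotating the image by 90 degrees rotates the label maps", {
  set.seed(31)
  img <- matrix(round(runif(16 * 16, 0, 255)), 16, 16)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE] # quarter turn
  for (r in c(1, 2)) {
    a <- pattern_maps(img, r)
    b <- pattern_maps(rot90(img), r)
    for (k in c("mstrp", "nrtxp", "ritxp")) {
      expect_equal(b[[k]], rot90(a[[k]]), info = paste(k, "r =", r))
    }
  }
})

test_that("pattern maps are deterministic and scale limits are enforced", {
  img <- matrix(runif(10 * 10, 0, 255), 10, 10)
  expect_identical(pattern_maps(img, 2), pattern_maps(img, 2))
  expect_error(pattern_maps(img, 5), "too small")
  expect_error(pattern_maps(img, 0), "positive")
})
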