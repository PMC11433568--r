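test_that("joint histogram counts label co-occurrences into 20 bins", {
  p <- matrix(-1L, 4, 4); q <- matrix(-1L, 4, 4)
  p[2, 2] <- 3L; q[2, 2] <- 1L
  h <- joint_histogram(p, q)
  expect_length(h, 20)
  expect_equal(as.numeric(h), replace(numeric(20), 8, 1)) # bin 3*2+1 (0-based 7)
  expect_equal(attr(h, "pixel_count"), 1L)

  p2 <- matrix(-1L, 4, 4); q2 <- matrix(-1L, 4, 4)
  p2[2:3, 2:3] <- rbind(c(0L, 0L), c(9L, 9L))
  q2[2:3, 2:3] <- rbind(c(0L, 1L), c(0L, 1L))
  h2 <- as.numeric(joint_histogram(p2, q2))
  want <- numeric(20); want[c(1, 2, 19, 20)] <- 1
  expect_equal(h2, want)

  expect_error(joint_histogram(p, matrix(-1L, 3, 3)), "shapes")
})

test_that("joint histogram agrees with naive counting on random label maps", {
  set.seed(41)
  for (case in 1:5) {
    p <- matrix(sample(c(-1L, 0:9), 256, replace = TRUE), 16, 16)
    q <- matrix(-1L, 16, 16)
    q[p >= 0] <- sample(0:1, sum(p >= 0), replace = TRUE)
    expect_equal(as.numeric(joint_histogram(p, q)), oracle_joint_hist(p, q))
  }
})

test_that("single-scale descriptor has 40 bins with conserved block mass", {
  set.seed(42)
  img <- matrix(runif(20 * 18, 0, 255), 20, 18)
  for (r in c(1, 3)) {
    raw <- scale_descriptor(img, r, normalize = FALSE)
    expect_length(raw, 40)
    valid <- (20 - 2 * r) * (18 - 2 * r)
    expect_equal(sum(raw[1:20]), valid)
    expect_equal(sum(raw[21:40]), valid)
    norm <- scale_descriptor(img, r, normalize = TRUE)
    expect_equal(sum(norm[1:20]), 1, tolerance = 1e-9)
    expect_equal(sum(norm[21:40]), 1, tolerance = 1e-9)
    expect_equal(norm, raw / valid)
  }
})

test_that("constant images put all mass in the (8, 1) bins of both blocks", {
  d <- suppressWarnings(scale_descriptor(matrix(3, 8, 8), 1))
  expect_equal(which(d != 0), c(18, 38)) # 0-based bins 17 and 20+17
  expect_equal(unname(d[c(18, 38)]), c(1, 1))
})

test_that("full descriptor concatenates scales and channels to length 120 S", {
  set.seed(43)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  d5 <- extract_descriptor(img, scales = 1:5)
  expect_length(d5, 600)
  expect_identical(attr(d5, "scales"), 1:5)
  # scale-major, then T, I, F: the first 40 bins are scale 1 on T
  ns <- to_neutrosophic(img, 3)
  expect_equal(unname(d5[1:40]), scale_descriptor(ns$T, 1))
  expect_equal(unname(d5[41:80]), scale_descriptor(ns$I, 1))
  expect_equal(unname(d5[81:120]), scale_descriptor(ns$F, 1))
  expect_equal(unname(d5[121:160]), scale_descriptor(ns$T, 2))
  expect_match(names(d5)[1], "^s1_T_ms_0_0$")
  # determinism
  expect_identical(extract_descriptor(img, scales = 1:2),
                   extract_descriptor(img, scales = 1:2))
  expect_error(extract_descriptor(matrix(1:100 / 1, 10, 10), scales = 1:5),
               "r = 5")
})

test_that("default scale set follows the image-size rule", {
  expect_equal(default_scales(c(64, 64)), 1:9)
  expect_equal(default_scales(c(61, 61)), 1:5)
  expect_equal(default_scales(c(128, 63)), 1:5)
})

test_that("descriptor is invariant to affine intensity rescaling on T and I blocks", {
  set.seed(44)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  a <- extract_descriptor(img, scales = 1:2)
  b <- extract_descriptor(1.7 * img + 11, scales = 1:2)
  tich <- grepl("_T_|_I_", names(a))
  expect_equal(a[tich], b[tich], tolerance = 1e-12)
})

test_that("90-degree rotation leaves the descriptor essentially unchanged", {
  set.seed(45)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  img <- matrix(round(runif(64 * 64, 0, 255)), 64, 64)
  a <- extract_descriptor(img, scales = c(1, 3))
  b <- extract_descriptor(rot90(img), scales = c(1, 3))
  rel_l1 <- sum(abs(a - b)) / sum(abs(a))
  border_fraction <- 1 - (64 - 2 * 3)^2 / 64^2
  expect_lt(rel_l1, 0.02 * border_fraction)
})

test_that("feature store round-trips byte-identically with its sidecar", {
  set.seed(46)
  imgs <- list(a = matrix(runif(144, 0, 255), 12, 12),
               b = matrix(runif(144, 0, 255), 12, 12))
  feats <- lapply(imgs, extract_descriptor, scales = 1:2)
  p1 <- tempfile(fileext = ".csv")
  write_feature_store(feats, p1)
  back <- read_feature_store(p1)
  expect_equal(rownames(back), c("a", "b"))
  expect_equal(unname(back["a", ]), unname(as.numeric(feats$a)))
  meta <- attr(back, "meta")
  expect_equal(meta$w, 3)
  expect_equal(meta$scales, 1:2)
  expect_true(meta$normalize)
  p2 <- tempfile(fileext = ".csv")
  write_feature_store(back, p2, w = meta$w, scales = meta$scales,
                      normalize = meta$normalize)
  expect_identical(readLines(p1), readLines(p2))
})
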