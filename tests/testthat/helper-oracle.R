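# Independent brute-force oracles, written directly from the defining
# formulas and kept free of the package's own code paths.

oracle_bilinear <- function(img, y, x) {
  M <- nrow(img); N <- ncol(img)
  y <- min(max(y, 1), M); x <- min(max(x, 1), N)
  if (abs(y - round(y)) < 1e-6) y <- round(y)
  if (abs(x - round(x)) < 1e-6) x <- round(x)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- min(y0 + 1, M); x1 <- min(x0 + 1, N)
  fy <- y - y0; fx <- x - x0
  img[y0, x0] * (1 - fy) * (1 - fx) + img[y0, x1] * (1 - fy) * fx +
    img[y1, x0] * fy * (1 - fx) + img[y1, x1] * fy * fx
}

# 8r circular samples around 1-based (i, j); n = 0 due east, counter-clockwise.
oracle_samples <- function(img, i, j, r) {
  n <- 0:(8 * r - 1)
  th <- 2 * pi * n / (8 * r)
  vapply(seq_along(n), function(k) {
    oracle_bilinear(img, i - r * sin(th[k]), j + r * cos(th[k]))
  }, numeric(1))
}

oracle_riu2 <- function(bits) {
  U <- abs(bits[8] - bits[1]) + sum(abs(diff(bits)))
  if (U <= 2) sum(bits) else 9L
}

# Full per-pixel label maps from the defining equations, all in plain R.
oracle_pattern_maps <- function(img, r) {
  M <- nrow(img); N <- ncol(img)
  muld <- matrix(0, M, N)
  for (i in 1:M) for (j in 1:N) {
    muld[i, j] <- mean(abs(oracle_samples(img, i, j, r) - img[i, j]))
  }
  mstrp <- nrtxp <- ritxp <- matrix(-1L, M, N)
  for (i in (1 + r):(M - r)) for (j in (1 + r):(N - r)) {
    pc <- img[i, j]
    smp <- oracle_samples(img, i, j, r)
    mqp <- vapply(0:7, function(k) median(smp[(r * k + 1):(r * k + r)]),
                  numeric(1))
    mstrp[i, j] <- oracle_riu2(as.integer(mqp - pc >= 0))
    mldqp <- vapply(0:7, function(k) mean(abs(smp[(r * k + 1):(r * k + r)] - pc)),
                    numeric(1))
    ring_r <- c(rep(i - r, 2 * r + 1), rep(i + r, 2 * r + 1),
                if (r > 0) (i - r + 1):(i + r - 1), if (r > 0) (i - r + 1):(i + r - 1))
    ring_c <- c((j - r):(j + r), (j - r):(j + r),
                rep(j - r, 2 * r - 1), rep(j + r, 2 * r - 1))
    nu <- mean(muld[cbind(ring_r, ring_c)])
    nrtxp[i, j] <- oracle_riu2(as.integer(mldqp - nu >= 0))
    mu <- mean(img[cbind(ring_r, ring_c)])
    ritxp[i, j] <- as.integer(pc - mu >= 0)
  }
  list(mstrp = mstrp, nrtxp = nrtxp, ritxp = ritxp)
}

# Naive per-pixel joint-histogram counter.
oracle_joint_hist <- function(primary, ri) {
  counts <- numeric(20)
  for (i in seq_len(nrow(primary))) for (j in seq_len(ncol(primary))) {
    if (primary[i, j] >= 0 && ri[i, j] >= 0) {
      b <- primary[i, j] * 2 + ri[i, j] + 1
      counts[b] <- counts[b] + 1
    }
  }
  counts
}

# Term-by-term extended Canberra distance.
oracle_canberra <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  s <- 0
  for (t in seq_along(a)) {
    den <- a[t] + ma + b[t] + mb
    if (den > 0) s <- s + abs(a[t] - b[t]) / den
  }
  s
}

# Average precision by explicit rank enumeration over the top-eta list.
oracle_average_precision <- function(relevant, g) {
  hits <- 0; s <- 0
  for (k in seq_along(relevant)) {
    if (relevant[k]) {
      hits <- hits + 1
      s <- s + hits / k
    }
  }
  s / g
}

# Plain single-scale LBP baseline: 8-neighbor riu2 histogram of the raw
# grayscale image, used as the comparison fixture in the noise benchmark.
lbp_baseline_hist <- function(img) {
  M <- nrow(img); N <- ncol(img)
  ii <- 2:(M - 1); jj <- 2:(N - 1)
  ctr <- img[ii, jj]
  off <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
              c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  bits <- lapply(off, function(o) (img[ii + o[1], jj + o[2]] >= ctr) + 0L)
  U <- abs(bits[[8]] - bits[[1]])
  for (n in 2:8) U <- U + abs(bits[[n]] - bits[[n - 1]])
  ones <- Reduce(`+`, bits)
  lab <- ifelse(U <= 2, ones, 9L)
  counts <- tabulate(lab + 1L, nbins = 10L)
  counts / sum(counts)
}

# All 256 8-bit patterns as rows, bit 0 first.
all_bit_patterns <- function() {
  t(vapply(0:255, function(v) as.integer(intToBits(v))[1:8], integer(8)))
}
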