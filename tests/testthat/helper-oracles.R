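# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# Exhaustive Otsu: for every split t in 0..254 with both classes non-empty,
# compute the weighted sum of class variances directly; smallest argmin wins.
naive_otsu <- function(counts) {
  lev <- 0:255
  total <- sum(counts)
  within <- rep(Inf, 255)
  for (t in 0:254) {
    lo <- counts[lev <= t]; hi <- counts[lev > t]
    n1 <- sum(lo); n2 <- sum(hi)
    if (n1 == 0 || n2 == 0) next
    l1 <- lev[lev <= t]; l2 <- lev[lev > t]
    m1 <- sum(lo * l1) / n1; m2 <- sum(hi * l2) / n2
    v1 <- sum(lo * (l1 - m1)^2) / n1
    v2 <- sum(hi * (l2 - m2)^2) / n2
    within[t + 1L] <- (n1 / total) * v1 + (n2 / total) * v2
  }
  m <- min(within)
  as.integer(which(within <= m + 1e-9 * (1 + abs(m)))[1L] - 1L)
}

# Class-variance decomposition at a given threshold: list(within, between, total).
variance_decomposition <- function(counts, t) {
  lev <- 0:255
  total <- sum(counts)
  mu <- sum(counts * lev) / total
  vt <- sum(counts * (lev - mu)^2) / total
  lo <- lev <= t
  n1 <- sum(counts[lo]); n2 <- total - n1
  if (n1 == 0 || n2 == 0) return(list(within = vt, between = 0, total = vt))
  m1 <- sum(counts[lo] * lev[lo]) / n1
  m2 <- sum(counts[!lo] * lev[!lo]) / n2
  v1 <- sum(counts[lo] * (lev[lo] - m1)^2) / n1
  v2 <- sum(counts[!lo] * (lev[!lo] - m2)^2) / n2
  w1 <- n1 / total; w2 <- n2 / total
  list(within = w1 * v1 + w2 * v2,
       between = w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2,
       total = vt)
}

# Brute-force 2D Gaussian convolution with mirror-reflected borders,
# kernel radius ceiling(3*sigma); O(H*W*K^2).
brute_gauss2d <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  H <- nrow(m); W <- ncol(m)
  refl <- function(n) c(rev(seq_len(r)) + 1L, seq_len(n), n - seq_len(r))
  mp <- m[refl(H), refl(W)]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- sum(K * mp[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

# Random plausibly-bimodal or arbitrary 256-bin histogram.
random_histogram <- function() {
  kind <- sample(3, 1)
  if (kind == 1) {                       # bimodal Gaussian mixture
    n <- sample(500:5000, 1)
    c1 <- sample(30:110, 1); c2 <- sample(140:230, 1)
    v <- c(round(rnorm(n, c1, sample(5:25, 1))), round(rnorm(n, c2, sample(5:25, 1))))
    tabulate(pmin(pmax(v, 0), 255) + 1L, 256L)
  } else if (kind == 2) {                # sparse spikes
    counts <- integer(256)
    idx <- sample(256, sample(2:12, 1))
    counts[idx] <- sample(1:100, length(idx), replace = TRUE)
    counts
  } else {                               # uniform-ish noise
    rpois(256, lambda = runif(1, 0.5, 20))
  }
}

# Vectors of length n with exact sample correlation r (via orthonormalization).
construct_exact_r <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); z <- rnorm(n)
  x <- scale(x)[, 1]
  z <- stats::residuals(stats::lm(z ~ x))
  z <- scale(z)[, 1]
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}
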