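test_that("grayscale conversion uses the fixed BT.601 luma weights", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(as.numeric(to_grayscale(px(255, 255, 255))), 255)
  expect_equal(as.numeric(to_grayscale(px(0, 0, 0))), 0)
  expect_equal(as.numeric(to_grayscale(px(255, 0, 0))), 76)  # round(0.299*255)
  set.seed(42)
  img <- array(sample(0:255, 20 * 15 * 3, replace = TRUE), dim = c(20, 15, 3))
  expect_equal(to_grayscale(img),
               round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]))
  expect_identical(to_grayscale(img[, , 1]), img[, , 1])  # gray passes through
})

test_that("gaussian smoothing preserves constants and total intensity, and matches brute-force convolution", {
  const <- matrix(128, 12, 17)
  expect_equal(gaussian_smooth(const, sigma = 1.5), const)

  impulse <- matrix(0, 21, 21); impulse[11, 11] <- 255
  sm <- gaussian_smooth(impulse, sigma = 1)
  r <- ceiling(3 * 1)
  expect_lt(abs(sum(sm) - 255), 0.5 * (2 * r + 1)^2)  # conserved within rounding

  # vertical step edge: monotone ramp, equal to the direct 2D convolution
  step <- matrix(0, 16, 16); step[, 9:16] <- 255
  sm2 <- gaussian_smooth(step, sigma = 2)
  expect_true(all(apply(sm2, 1, function(row) all(diff(row) >= 0))))
  oracle <- pmin(pmax(round(brute_gauss2d(step, 2)), 0), 255)
  expect_equal(sm2, oracle)

  set.seed(7)
  rnd <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
  expect_equal(gaussian_smooth(rnd, sigma = 1.2),
               pmin(pmax(round(brute_gauss2d(rnd, 1.2)), 0), 255))

  expect_error(gaussian_smooth(const, sigma = 0), "positive")
  expect_error(gaussian_smooth(const, sigma = -1), "positive")
  expect_error(gaussian_smooth(matrix(numeric(0), 0, 0)), "empty|matrix")
})

test_that("gray histogram tallies every pixel exactly", {
  img <- matrix(10, 2, 2)
  h <- gray_histogram(img)
  expect_equal(h$counts[11], 4L)
  expect_equal(sum(h$counts), 4L)

  half <- matrix(c(0, 255), 10, 10)
  h2 <- gray_histogram(half)
  expect_equal(h2$counts[c(1, 256)], c(50L, 50L))

  set.seed(11)
  rnd <- matrix(sample(0:255, 100 * 100, replace = TRUE), 100, 100)
  h3 <- gray_histogram(rnd)
  tally <- integer(256)
  for (v in as.integer(rnd)) tally[v + 1L] <- tally[v + 1L] + 1L
  expect_identical(h3$counts, tally)
  expect_equal(h3$total, 10000L)
  expect_error(gray_histogram(matrix(numeric(0), 0, 0)), "empty|matrix")
})

test_that("otsu threshold minimizes intra-class variance with smallest-t tie-breaking", {
  two_spike <- integer(256); two_spike[c(51, 201)] <- 100L
  expect_identical(otsu_threshold(two_spike), 50L)  # ties over [50,199]; smallest wins

  extremes <- integer(256); extremes[c(1, 256)] <- 10L
  expect_identical(otsu_threshold(extremes), 0L)

  set.seed(3)
  v <- c(round(rnorm(3000, 60, 12)), round(rnorm(3000, 190, 18)))
  clumps <- tabulate(pmin(pmax(v, 0), 255) + 1L, 256L)
  t <- otsu_threshold(clumps)
  expect_identical(t, naive_otsu(clumps))
  expect_gt(t, 80); expect_lt(t, 170)  # between the clumps

  single <- integer(256); single[100] <- 50L
  expect_error(otsu_threshold(single), "degenerate")
})

test_that("otsu equals exhaustive search and respects the variance decomposition", {
  set.seed(101)
  for (i in 1:200) {
    h <- random_histogram()
    if (sum(h > 0) < 2) next
    expect_identical(otsu_threshold(h), naive_otsu(h))
  }
  # within-class + between-class variance = total variance at every threshold
  set.seed(5)
  h <- random_histogram()
  for (t in seq(0, 254, by = 17)) {
    d <- variance_decomposition(h, t)
    expect_equal(d$within + d$between, d$total, tolerance = 1e-10)
  }
})

test_that("otsu agrees with an independent implementation on bimodal images", {
  set.seed(2)
  v <- c(round(rnorm(4000, 70, 15)), round(rnorm(4000, 190, 20)))
  g <- matrix(pmin(pmax(v, 0), 255), 80, 100)
  t_pic <- otsu_threshold(gray_histogram(g))
  t_ref <- EBImage::otsu(EBImage::Image(g / 255), range = c(0, 1), levels = 256) * 255
  expect_lt(abs(t_pic - t_ref), 3.5)  # bin-edge conventions differ by a few levels
})

test_that("binarization is a monotone threshold split with recorded polarity", {
  all_light <- matrix(255, 5, 5)
  expect_true(all(binarize(all_light, 100)))
  all_dark <- matrix(0, 5, 5)
  expect_false(any(binarize(all_dark, 100)))

  board <- matrix(c(0, 255), 8, 8)
  m <- binarize(board, 127)
  expect_equal(mean(m), 0.5)
  expect_equal(unname(m), unname(board == 255), ignore_attr = TRUE)
  expect_identical(attr(m, "threshold"), 127L)

  # raising t never converts wall -> void
  set.seed(9)
  g <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  prev <- binarize(g, 0)
  for (t in c(50, 120, 200, 254)) {
    cur <- binarize(g, t)
    expect_true(all(prev | !cur))  # void set shrinks as t rises
    prev <- cur
  }
  # inverted polarity flips the classes
  expect_identical(unname(binarize(g, 100, invert = TRUE)), unname(!binarize(g, 100)))
  expect_error(binarize(g, 255), "\\[0, 254\\]")
  expect_error(binarize(g, -1), "\\[0, 254\\]")
})

test_that("the full preprocessing chain recovers known area fractions", {
  # dark disks (walls) on a light background with mild noise
  set.seed(21)
  H <- 300; W <- 300
  tone <- matrix(210, H, W)
  centers <- expand.grid(r = seq(25, 275, by = 50), c = seq(25, 275, by = 50))
  rad <- 12
  for (k in seq_len(nrow(centers))) {
    rr <- pmax(1, centers$r[k] - rad):pmin(H, centers$r[k] + rad)
    cc <- pmax(1, centers$c[k] - rad):pmin(W, centers$c[k] + rad)
    d2 <- outer((rr - centers$r[k])^2, (cc - centers$c[k])^2, `+`)
    tone[rr, cc][d2 <= rad^2] <- 40
  }
  light_fraction <- mean(tone == 210)
  noisy <- pmin(pmax(round(tone + rnorm(H * W, sd = 8)), 0), 255)
  mask <- preprocess(noisy, sigma = 2, quiet = TRUE)
  expect_lt(abs(mean(mask) - light_fraction), 0.02)
})

test_that("smoothing leaves a noiseless two-tone image's mask unchanged", {
  img <- matrix(60, 200, 240)
  for (s in seq(1, 240, by = 80)) img[, s:(s + 39)] <- 220
  m0 <- preprocess(img, sigma = 0, quiet = TRUE)
  m2 <- preprocess(img, sigma = 2, quiet = TRUE)
  expect_identical(unname(m0 == TRUE), unname(m2 == TRUE))
})

test_that("smoothing removes isolated single-pixel speckle before binarization", {
  arch <- wood_archetype("diffuse_porous", noise_sd = 40)
  ring <- render_ring(arch, width_px = 300, height = 600, seed = 3, rgb = FALSE)
  raw_mask <- binarize(ring$image, otsu_threshold(gray_histogram(ring$image)))
  smooth_mask <- preprocess(ring$image, sigma = 2, quiet = TRUE)
  specks <- function(m) {
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
    sum(sizes == 1)
  }
  expect_lt(specks(smooth_mask), specks(raw_mask))
})

test_that("preprocess reports its threshold", {
  img <- matrix(40, 50, 60); img[, 31:60] <- 210
  expect_message(preprocess(img), "Otsu threshold")
})
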