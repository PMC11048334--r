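make_ann <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("ring annotations are validated against their invariants", {
  ok <- make_ann(specimen_id = "A", year = 2018:2020, image = "a.png",
                 start_px = c(0L, 100L, 250L), end_px = c(100L, 250L, 300L))
  expect_silent(validate_ring_annotations(ok))

  bad_interval <- ok; bad_interval$end_px[2] <- 100L
  expect_error(validate_ring_annotations(bad_interval), "end_px <= start_px")

  overlapping <- ok; overlapping$start_px[2] <- 50L
  expect_error(validate_ring_annotations(overlapping), "overlapping.*2018.*2019")

  dup <- ok; dup$year[2] <- 2018L
  expect_error(validate_ring_annotations(dup), "duplicate year")

  disordered <- ok; disordered$year <- c(2020L, 2019L, 2018L)
  expect_error(validate_ring_annotations(disordered), "increase with radial position")

  expect_error(validate_ring_annotations(ok[, -1]), "lacks columns")
})

test_that("ring statistics summarize the averaged profile over the ring interval", {
  const <- rep(0.3, 100)  # flat profile, as in wood with near-constant porosity
  rs <- ring_stats(const, list(specimen_id = "A", year = 2020, start_px = 0, end_px = 100))
  expect_equal(rs$por_max, 0.3); expect_equal(rs$por_mean, 0.3)
  expect_equal(rs$por_min, 0.3); expect_equal(rs$ring_width_px, 100L)

  ramp <- seq(1, 0, length.out = 100)
  rs2 <- ring_stats(ramp, list(start_px = 0, end_px = 100))
  expect_equal(rs2$por_mean, 0.5, tolerance = 0.01)  # half-pixel discretization

  spike <- rep(0.2, 50); spike[25] <- 0.9
  rs3 <- ring_stats(spike, list(start_px = 0, end_px = 50))
  expect_equal(rs3$por_max, 0.9); expect_equal(rs3$por_min, 0.2)

  rs4 <- ring_stats(const, list(start_px = 10, end_px = 60), scale_um_per_px = 2.5)
  expect_equal(rs4$ring_width_um, 125)

  expect_error(ring_stats(const, list(start_px = 50, end_px = 150)), "outside")
  expect_error(ring_stats(const, list(start_px = 20, end_px = 20)), "empty")
  # profiles carry an origin: interval is in absolute radial pixels
  off <- structure(rep(0.4, 50), origin = 100L)
  expect_equal(ring_stats(off, list(start_px = 120, end_px = 140))$por_mean, 0.4)
  expect_error(ring_stats(off, list(start_px = 0, end_px = 20)), "outside")
})

test_that("series assembly matches annotations to profiles and sorts by year", {
  ann <- make_ann(specimen_id = "A", year = 2018:2020, image = "a.png",
                  start_px = c(0L, 100L, 250L), end_px = c(100L, 250L, 300L))
  set.seed(6)
  profs <- list(a.png = runif(300, 0.2, 0.6))
  bs <- build_series(ann, profs)
  expect_equal(nrow(bs$records), 3L)
  expect_equal(bs$records$year, 2018:2020)
  expect_true(all(bs$records$por_min <= bs$records$por_mean))
  expect_true(all(bs$records$por_mean <= bs$records$por_max))
  expect_named(bs$ring_profiles, c("A.2018", "A.2019", "A.2020"))
  expect_equal(length(bs$ring_profiles[["A.2019"]]), 150L)

  expect_error(build_series(ann, list(b.png = runif(300))), "no profile supplied")

  # a full simulated site: 12 specimens x 30 years -> 360 records
  sim <- simulate_annual_stats(n_specimens = 12, n_years = 30, seed = 2)
  anns <- do.call(rbind, lapply(names(sim$specimens), function(id) {
    w <- sim$specimens[[id]]$ring_width_px
    ends <- cumsum(w)
    make_ann(specimen_id = id, year = as.integer(names(w)),
             image = paste0(id, ".png"),
             start_px = c(0L, ends[-length(ends)]), end_px = ends)
  }))
  set.seed(8)
  profs12 <- lapply(split(anns, anns$image), function(d) runif(max(d$end_px), 0.1, 0.9))
  bs12 <- build_series(anns, profs12)
  expect_equal(nrow(bs12$records), 360L)
  expect_equal(length(unique(bs12$records$specimen_id)), 12L)
})

test_that("profile compression is linear interpolation on relative position", {
  v <- c(0.2, 0.5, 0.9, 0.4)
  expect_identical(compress_profile(v, 4), v)                 # identity at equal length
  expect_equal(compress_profile(rep(0.3, 10), 5), rep(0.3, 5))  # constants stay constant

  ramp <- seq(0, 1, length.out = 11)
  for (m in c(3, 5, 21)) {
    expect_equal(compress_profile(ramp, m), seq(0, 1, length.out = m))
  }
  # endpoints preserved exactly
  set.seed(10)
  w <- runif(17)
  cw <- compress_profile(w, 7)
  expect_identical(cw[c(1, 7)], w[c(1, 17)])
  # idempotent at equal length; commutes with constant shifts
  expect_equal(compress_profile(cw, 7), cw)
  expect_equal(compress_profile(w + 0.1, 7), cw + 0.1)

  expect_error(compress_profile(w, 1), "target_length")
  expect_error(compress_profile(0.5, 5), "length >= 2")
})

test_that("mean annual profiles compress to the shortest ring and average", {
  ramp20 <- seq(0.8, 0.2, length.out = 20)
  expect_equal(as.numeric(mean_annual_profile(list(ramp20))), ramp20)

  # two identical shapes of different lengths collapse to the shorter one
  ramp35 <- seq(0.8, 0.2, length.out = 35)
  m <- mean_annual_profile(list(ramp20, ramp35))
  expect_equal(as.numeric(m), ramp20)
  expect_equal(attr(m, "n"), 2L)

  # averaging pulls the mean profile toward the common signal
  set.seed(13)
  signal <- 0.5 + 0.25 * sin(seq(0, 2 * pi, length.out = 60))
  noisy <- lapply(1:10, function(i) signal + rnorm(60, sd = 0.08))
  mp <- mean_annual_profile(noisy)
  mad_mean <- mean(abs(as.numeric(mp) - signal))
  mad_each <- vapply(noisy, function(p) mean(abs(p - signal)), numeric(1))
  expect_lt(mad_mean, min(mad_each))
})

test_that("per-parameter series extraction and CSV export are consistent", {
  recs <- data.frame(specimen_id = rep(c("A", "B"), each = 3),
                     year = rep(2018:2020, 2),
                     ring_width_px = c(90L, 110L, 100L, 95L, 105L, 102L),
                     por_max = runif(6, 0.5, 0.6), por_mean = runif(6, 0.3, 0.4),
                     por_min = runif(6, 0.1, 0.2))
  s <- series_from_records(recs, "MEAN_Por")
  expect_named(s, c("A", "B"))
  expect_equal(as.numeric(s$A), recs$por_mean[1:3])
  expect_equal(names(s$B), c("2018", "2019", "2020"))

  f <- tempfile(fileext = ".csv")
  write_series_csv(recs, f)
  back <- read.csv(f)
  expect_equal(back$por_mean, recs$por_mean)
  unlink(f)
})
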