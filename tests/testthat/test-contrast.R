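# Contrast engine: histograms, percentile clip bounds, linear stretching,
# and policy application over montage groups.

test_that("histogram equals a brute-force per-value tally", {
  p <- make_plane(rep(0L, 4), 2, 2, 8L)
  h <- compute_histogram(p)
  expect_identical(h[1L], 4L)
  expect_identical(sum(h), 4L)
  expect_length(h, 256L)

  set.seed(31)
  p <- rand_plane(32, 32, 8L)
  h <- compute_histogram(p)
  tally <- vapply(0:255, function(v) sum(p$pixels == v), integer(1))
  expect_identical(h, tally)
  expect_identical(sum(h), 1024L)

  p16 <- rand_plane(16, 16, 16L)
  expect_length(compute_histogram(p16), 65536L)
})

test_that("clip bounds: saturation 0 gives pooled min/max; constant planes degenerate", {
  p <- make_plane(c(10, 50, 120, 200), 2, 2, 8L)
  b <- compute_clip_bounds(compute_histogram(p), 0)
  expect_identical(b, list(low = 10L, high = 200L))

  const <- make_plane(rep(7L, 9), 3, 3, 8L)
  for (f in c(0, 0.004, 0.01)) {
    b <- compute_clip_bounds(compute_histogram(const), f)
    expect_identical(b, list(low = 7L, high = 7L))
    expect_identical(apply_linear_stretch(const, b)$pixels, const$pixels)
  }
  expect_error(compute_clip_bounds(integer(256)), "empty histogram")
})

test_that("clip bounds match the sort-based oracle (worked case + randomized)", {
  # 100 pixels 0..99, 4% saturation: 2 discarded per tail
  p <- make_plane(0:99, 10, 10, 8L)
  b <- compute_clip_bounds(compute_histogram(p), 0.04 / 1)  # 4% total
  oracle <- sort_bounds_oracle(p$pixels, 0.04)
  expect_identical(b$low, oracle$low)
  expect_identical(b$high, oracle$high)
  expect_identical(b, list(low = 2L, high = 97L))

  set.seed(32)
  for (rep in 1:20) {
    n_px <- sample(50:10000, 1)
    w <- sample(5:100, 1)
    h <- max(1L, n_px %/% w)
    bd <- sample(c(8L, 16L), 1)
    # mix smooth and tie-heavy distributions
    vals <- if (rep %% 2 == 0) {
      sample(0:bit_depth_max_(bd), w * h, replace = TRUE)
    } else {
      sample(round(seq(0, bit_depth_max_(bd), length.out = 7)), w * h,
             replace = TRUE)
    }
    p <- make_plane(vals, w, h, bd)
    f <- sample(c(0, 0.0001, 0.001, 0.004, 0.01), 1)
    b <- compute_clip_bounds(compute_histogram(p), f)
    o <- sort_bounds_oracle(p$pixels, f)
    expect_identical(b$low, as.integer(o$low))
    expect_identical(b$high, as.integer(o$high))
  }
})

test_that("linear stretch maps the bounds to the full scale with clamping", {
  p <- make_plane(c(5, 10, 105, 200, 250, 0), 3, 2, 8L)
  s <- apply_linear_stretch(p, list(low = 10L, high = 200L))
  v <- as.vector(t(s$pixels))
  expect_identical(v[2L], 0L)        # at low
  expect_identical(v[4L], 255L)      # at high
  expect_identical(v[3L], 128L)      # round((105-10)*255/190) = round(127.5)
  expect_identical(v[1L], 0L)        # below low clamps
  expect_identical(v[5L], 255L)      # above high clamps

  # full-range bounds are the identity
  q <- make_plane(c(0, 3, 99, 255), 2, 2, 8L)
  expect_identical(apply_linear_stretch(q, list(low = 0L, high = 255L))$pixels,
                   q$pixels)
})

test_that("stretch is monotone; saturation-0 stretch spans the full range; autoscale is idempotent", {
  set.seed(33)
  for (bd in c(8L, 16L)) {
    p <- rand_plane(24, 24, bd)
    b <- compute_clip_bounds(compute_histogram(p), 0)
    s <- apply_linear_stretch(p, b)
    expect_identical(min(s$pixels), 0L)
    expect_identical(max(s$pixels), bit_depth_max_(bd))
    # monotone in the input
    ordv <- order(as.vector(p$pixels))
    expect_true(all(diff(as.vector(s$pixels)[ordv]) >= 0L))
    # idempotence up to 1 intensity unit
    b2 <- compute_clip_bounds(compute_histogram(s), 0)
    s2 <- apply_linear_stretch(s, b2)
    expect_lte(max(abs(s2$pixels - s$pixels)), 1L)
  }
})

test_that("saturation accounting: clipped pixels stay within budget plus bin ties", {
  set.seed(34)
  for (rep in 1:10) {
    p <- rand_plane(40, 40, 8L)
    f <- sample(c(0.001, 0.004, 0.01), 1)
    n <- length(p$pixels)
    b0 <- compute_clip_bounds(compute_histogram(p), 0)
    b <- compute_clip_bounds(compute_histogram(p), f)
    s <- apply_linear_stretch(p, b)
    extremes <- sum(s$pixels == 0L | s$pixels == 255L)
    baseline <- sum(p$pixels == b0$low) + sum(p$pixels == b0$high)
    ties <- sum(p$pixels == b$low) + sum(p$pixels == b$high)
    expect_lte(extremes, baseline + n * f + ties)
  }
})

test_that("enhance_dataset honors mode and scope semantics", {
  set.seed(35)
  mk <- function(vals, base) make_record(list(make_plane(vals, 5, 2, 8L)),
                                         base_name = base)
  a <- mk(c(10, 20, 30, 50, 100, 10, 20, 30, 50, 100), "A")
  b <- mk(c(10, 40, 80, 150, 200, 10, 40, 80, 150, 200), "B")

  # none: identity
  res <- enhance_dataset(list(a, b), contrast_policy("none"), 1L)
  expect_identical(res$records[[1L]]$planes[[1L]]$pixels,
                   a$planes[[1L]]$pixels)

  # joint: pooled bounds (10, 200); A's max lands below full scale
  pol <- contrast_policy("user_defined",
                         channels = list(channel_contrast(scope = "joint")))
  res <- enhance_dataset(list(a, b), pol, 1L)
  expect_identical(res$bounds_report$C1$scope, "joint")
  expect_identical(res$bounds_report$C1$bounds, list(low = 10L, high = 200L))
  expect_lt(max(res$records[[1L]]$planes[[1L]]$pixels), 255L)
  expect_identical(max(res$records[[2L]]$planes[[1L]]$pixels), 255L)

  # individual: each record's own max maps to full scale
  pol <- contrast_policy("user_defined",
                         channels = list(channel_contrast(scope = "individual")))
  res <- enhance_dataset(list(a, b), pol, 1L)
  expect_identical(max(res$records[[1L]]$planes[[1L]]$pixels), 255L)
  expect_identical(max(res$records[[2L]]$planes[[1L]]$pixels), 255L)
  expect_named(res$bounds_report$C1$bounds, c("A", "B"))

  # enhance = FALSE leaves the channel untouched
  pol <- contrast_policy("user_defined",
                         channels = list(channel_contrast(enhance = FALSE)))
  res <- enhance_dataset(list(a, b), pol, 1L)
  expect_identical(res$records[[1L]]$planes[[1L]]$pixels,
                   a$planes[[1L]]$pixels)
  expect_null(res$bounds_report$C1)

  # autoscale stretches every record independently at saturation 0
  res <- enhance_dataset(list(a, b), contrast_policy("autoscale"), 1L)
  expect_identical(max(res$records[[1L]]$planes[[1L]]$pixels), 255L)
  expect_identical(min(res$records[[1L]]$planes[[1L]]$pixels), 0L)

  # mixed bit depths are fatal
  c16 <- make_record(list(rand_plane(5, 2, 16L)), base_name = "C")
  expect_error(enhance_dataset(list(a, c16), contrast_policy("autoscale"), 1L),
               "mixed bit depths")
})

test_that("joint scaling with pooled minimum 0 preserves mean-intensity ratios", {
  set.seed(36)
  base <- matrix(sample(0:500, 400, TRUE), nrow = 20)
  base[1L] <- 0L
  a <- make_record(list(channel_plane(base, 16L)), base_name = "A")
  b <- make_record(list(channel_plane(base * 3L, 16L)), base_name = "B")
  pol <- contrast_policy("user_defined",
                         channels = list(channel_contrast(scope = "joint")))
  res <- enhance_dataset(list(a, b), pol, 1L)
  r_before <- mean(b$planes[[1L]]$pixels) / mean(a$planes[[1L]]$pixels)
  r_after <- mean(res$records[[2L]]$planes[[1L]]$pixels) /
    mean(res$records[[1L]]$planes[[1L]]$pixels)
  expect_lt(abs(r_after - r_before) / r_before, 0.01)
})

test_that("pitfall set: joint scaling preserves the 3-fold ratio, individual destroys it", {
  pit <- generate_pitfall_set()
  sq1_mean <- function(planes, i) region_mean(planes[[i]], pit$masks[[i]][[1L]])
  expect_identical(vapply(1:4, function(i) sq1_mean(pit$planes, i),
                          numeric(1)), c(9000, 3000, 3000, 9000))

  records <- lapply(1:4, function(i) {
    make_record(list(pit$planes[[i]]), base_name = paste0("pic", i))
  })
  joint <- contrast_policy("user_defined",
                           channels = list(channel_contrast(scope = "joint")))
  res <- enhance_dataset(records, joint, 1L)
  m1 <- region_mean(res$records[[1L]]$planes[[1L]], pit$masks[[1L]][[1L]])
  m2 <- region_mean(res$records[[2L]]$planes[[1L]], pit$masks[[2L]][[1L]])
  expect_lt(abs(m1 / m2 - 3), 0.01)

  indiv <- contrast_policy("user_defined",
                           channels = list(channel_contrast(scope = "individual")))
  res_i <- enhance_dataset(records, indiv, 1L)
  n1 <- region_mean(res_i$records[[1L]]$planes[[1L]], pit$masks[[1L]][[1L]])
  n2 <- region_mean(res_i$records[[2L]]$planes[[1L]], pit$masks[[2L]][[1L]])
  expect_gt(abs(n1 / n2 - 3), 0.5)
})
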