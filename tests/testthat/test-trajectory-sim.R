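test_that("line construction validates arguments and is seed-deterministic", {
  expect_error(make_line(0), "positive integer")
  expect_error(make_line(c(2, 3)), "positive integer")

  set.seed(1); a <- make_line(100)
  set.seed(1); b <- make_line(100)
  expect_identical(a, b)
  expect_length(a$p, 100)
  expect_length(a$d, 100)
})

test_that("trajectory evaluation matches hand arithmetic", {
  # linear case: d*t + p
  ln <- make_line(2, p = c(1, 2), d = c(0.01, 0.02))
  tr <- make_trajectory(ln, exponents = c(1L, 1L))
  expect_equal(drop(evaluate_trajectory(tr, 100)), c(2.0, 4.0))

  # squared case: (d*t + p)^2
  tr2 <- make_trajectory(make_line(1, p = 1, d = 1), exponents = 2L)
  expect_equal(drop(evaluate_trajectory(tr2, 3)), 16)

  # zero gradient: constant trajectory equals its intercepts everywhere
  trc <- make_trajectory(make_line(3, p = c(1, -2, 0.5), d = rep(0, 3)),
                         exponents = c(1L, 1L, 1L))
  pts <- evaluate_trajectory(trc, 0:50)
  expect_true(all(pts == matrix(c(1, -2, 0.5), 51, 3, byrow = TRUE)))
})

test_that("square_fraction endpoints force the exponents", {
  set.seed(2)
  ln <- make_line(50)
  expect_true(all(make_trajectory(ln, 0)$exponents == 1L))
  tr_all <- make_trajectory(ln, 1)
  expect_true(all(tr_all$exponents == 2L))
  t0 <- 7
  expect_equal(drop(evaluate_trajectory(tr_all, t0)), (ln$d * t0 + ln$p)^2)
})

test_that("composition identities and interpolation hold exactly", {
  set.seed(3)
  T1 <- make_trajectory(make_line(20), 0.5)
  T2 <- make_trajectory(make_line(20), 0.5)
  tt <- c(0, 17, 250, 499)

  sec1 <- compose_secondary(T1, T2, 1)
  expect_equal(evaluate_trajectory(sec1$T3, tt), evaluate_trajectory(T1, tt))
  expect_equal(evaluate_trajectory(sec1$T4, tt), evaluate_trajectory(T2, tt))

  sec0 <- compose_secondary(T1, T2, 0)
  expect_equal(evaluate_trajectory(sec0$T3, tt), evaluate_trajectory(T2, tt))
  expect_equal(evaluate_trajectory(sec0$T4, tt), evaluate_trajectory(T1, tt))

  half <- compose_secondary(T1, T2, 0.5)
  expect_equal(evaluate_trajectory(half$T3, tt), evaluate_trajectory(half$T4, tt),
               tolerance = 1e-12)

  # interpolation property: T3(t) sits at fraction alpha on the segment
  # between T1(t) and T2(t), checked against direct arithmetic
  for (alpha in c(0.25, 0.6, 0.9)) {
    sec <- compose_secondary(T1, T2, alpha)
    expected <- alpha * evaluate_trajectory(T1, tt) +
      (1 - alpha) * evaluate_trajectory(T2, tt)
    expect_equal(evaluate_trajectory(sec$T3, tt), expected, tolerance = 1e-14)
  }

  expect_error(compose_secondary(T1, make_trajectory(make_line(19), 0.5), 0.5),
               "share D")
  expect_error(compose_secondary(T1, T2, 1.2), "alpha")
})

test_that("alpha = 0.8 secondary is closer to its principal in input space", {
  set.seed(4)
  T1 <- make_trajectory(make_line(100), 0.5)
  T2 <- make_trajectory(make_line(100), 0.5)
  sec <- compose_secondary(T1, T2, 0.8)
  tt <- 0:499
  p1 <- evaluate_trajectory(T1, tt); p2 <- evaluate_trajectory(T2, tt)
  p3 <- evaluate_trajectory(sec$T3, tt)
  d31 <- mean(sqrt(rowSums((p3 - p1)^2)))
  d32 <- mean(sqrt(rowSums((p3 - p2)^2)))
  expect_lt(d31, d32)
})

test_that("increment formation obeys the point-count and disjointness laws", {
  tr <- fixture_trajectory(D = 5, seed = 5)
  # exact point-count law across the full range of sampling gaps
  for (delta in c(0:5, 25, 50, 73, 98)) {
    incs <- form_increments(tr, n = 3, delta = delta)
    expect_true(all(vapply(incs$increments,
                           function(e) nrow(e$points), 1L) == 100L - delta))
  }
  expect_equal(vapply(form_increments(tr, 4, 99)$increments,
                      function(e) nrow(e$points), 1L), rep(1L, 4))

  # documented pseudo-time windows
  i0 <- form_increments(tr, 5, 0)
  expect_equal(i0$increments[[1]]$t, 0:99)
  expect_equal(i0$increments[[2]]$t, 100:199)
  i25 <- form_increments(tr, 5, 25)
  expect_equal(i25$increments[[1]]$t, 0:74)
  expect_equal(i25$increments[[2]]$t, 100:174)

  # disjoint, strictly increasing t ranges
  all_t <- unlist(lapply(i25$increments, `[[`, "t"))
  expect_false(anyDuplicated(all_t) > 0)
  expect_true(all(diff(all_t) > 0))

  expect_error(form_increments(tr, 5, 100), "delta")
  expect_error(form_increments(tr, 0, 0), "positive integer")
})

test_that("noise addition scales with lambda and expands single points", {
  tr <- fixture_trajectory(D = 30, seed = 6)
  incs <- form_increments(tr, 5, 0)

  set.seed(10)
  expect_identical(add_noise(incs, 0)$increments, incs$increments)

  # empirical SD of the injected noise matches lambda * per-dimension SD
  set.seed(11)
  noisy <- add_noise(incs, 0.2)
  sd_dim <- apply(evaluate_trajectory(tr, 0:499), 2, sd)
  resid <- do.call(rbind, lapply(seq_len(5), function(i)
    noisy$increments[[i]]$points - incs$increments[[i]]$points))
  ratio <- apply(resid, 2, sd) / (0.2 * sd_dim)
  expect_lt(abs(median(ratio) - 1), 0.1)

  # delta = 99: one point per increment replicated into 100 jittered copies
  i99 <- form_increments(tr, 5, 99)
  set.seed(12)
  e99 <- add_noise(i99, 0)
  sizes <- vapply(e99$increments, function(e) nrow(e$points), 1L)
  expect_true(all(sizes == 100L))
  spread <- sapply(e99$increments, function(e) max(abs(sweep(e$points, 2,
    colMeans(e$points)))))
  expect_true(all(spread < 0.01))  # 0.001 SD jitter stays tiny

  expect_error(add_noise(incs, -0.1), "lambda")
})

test_that("noiseless positive-gradient trajectories drift monotonically", {
  set.seed(8)
  tr <- make_trajectory(make_line(100), 0.5)
  incs <- form_increments(tr, 5, 0)
  cents <- t(sapply(incs$increments, function(e) colMeans(e$points)))
  d <- sqrt(rowSums(sweep(cents, 2, cents[1, ])^2))
  expect_true(all(diff(d) > 0))
})

test_that("increment generation is bit-identical under a repeated seed", {
  gen <- function() {
    set.seed(99)
    tr <- make_trajectory(make_line(40), 0.5)
    add_noise(form_increments(tr, 4, 10), 0.2)
  }
  expect_identical(gen(), gen())
})

test_that("increments flatten to a long data frame and survive CSV round-trip", {
  tr <- fixture_trajectory(D = 4, seed = 13)
  incs <- form_increments(tr, 3, 50, label = "trajA")
  df <- as.data.frame(incs)
  expect_equal(nrow(df), 3 * 50)
  expect_named(df, c("trajectory_label", "increment", "t",
                     paste0("x_", 1:4)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_increments_csv(incs, f)
  back <- read_increments_csv(f)[["trajA"]]
  expect_equal(back$n, 3)
  expect_equal(back$increments[[2]]$points, incs$increments[[2]]$points,
               ignore_attr = TRUE)
})
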