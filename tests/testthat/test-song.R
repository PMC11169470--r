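test_that("model initialization is deterministic and typed", {
  m <- song_init(100)
  expect_s3_class(m, "song_model")
  expect_false(m$fitted)
  expect_error(song_transform(m, matrix(0, 2, 100)), "not been fitted")

  set.seed(1); m1 <- partial_fit(song_init(100), fixture_blobs(D = 100)$X)
  set.seed(1); m2 <- partial_fit(song_init(100), fixture_blobs(D = 100)$X)
  expect_identical(m1, m2)
  expect_equal(ncol(m1$C), 100)
})

test_that("codebook and layout stay in bijection with a valid graph", {
  b <- fixture_blobs()
  set.seed(2)
  m <- partial_fit(song_init(10), b$X)
  set.seed(3)
  m <- partial_fit(m, b$X + 1)
  expect_equal(nrow(m$C), nrow(m$Y))
  expect_equal(m$E, t(m$E))
  expect_true(all(diag(m$E) == 0))
  expect_true(all(m$E >= 0))
})

test_that("input validation catches mismatches and empty batches", {
  b <- fixture_blobs()
  set.seed(4)
  m <- partial_fit(song_init(10), b$X)
  expect_error(partial_fit(m, matrix(0, 5, 9)), "expects")
  expect_error(song_transform(m, matrix(0, 5, 9)), "expects")
  expect_identical(partial_fit(m, matrix(numeric(0), 0, 10)), m)
})

test_that("well-separated blobs separate in the embedding", {
  b <- fixture_blobs()
  set.seed(5)
  m <- partial_fit(song_init(10), b$X)
  Y <- song_transform(m, b$X)
  dmat <- as.matrix(dist(Y))
  w11 <- dmat[b$group == 1, b$group == 1]
  w22 <- dmat[b$group == 2, b$group == 2]
  within <- c(w11[upper.tri(w11)], w22[upper.tri(w22)])
  between <- dmat[b$group == 1, b$group == 2]
  expect_gte(mean(between > median(within)), 0.95)
})

test_that("a 1D curve in 100 dimensions embeds in its pseudo-time order", {
  set.seed(6)
  tr <- make_trajectory(make_line(100), 0.5)
  X <- evaluate_trajectory(tr, 0:499)
  set.seed(7)
  m <- partial_fit(song_init(100), X)
  Y <- song_transform(m, X)
  tt <- 0:499
  Dh <- abs(outer(tt, tt, "-"))   # geodesic order along the curve
  Dl <- as.matrix(dist(Y))
  rho <- cor(Dh[upper.tri(Dh)], Dl[upper.tri(Dl)], method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("the layout cross-entropy objective decreases over epochs", {
  b <- fixture_blobs()
  set.seed(8)
  m <- partial_fit(song_init(10), b$X)
  obj <- m$objective
  k <- max(1, round(length(obj) * 0.1))
  expect_lt(median(tail(obj, k)), median(head(obj, k)))
})

test_that("fine-tuning with new data keeps previous embeddings stable", {
  set.seed(9)
  tr <- make_trajectory(make_line(100), 0.5)
  incs <- form_increments(tr, 5, 0)
  X_old <- do.call(rbind, lapply(incs$increments[1:4], `[[`, "points"))
  set.seed(10)
  m <- song_init(100)
  for (i in 1:4) m <- partial_fit(m, do.call(rbind,
    lapply(incs$increments[1:i], `[[`, "points")))
  Y_before <- song_transform(m, X_old)
  m <- partial_fit(m, do.call(rbind, lapply(incs$increments, `[[`, "points")))
  Y_after <- song_transform(m, X_old)
  bbox <- sqrt(sum((apply(Y_after, 2, max) - apply(Y_after, 2, min))^2))
  displacement <- mean(sqrt(rowSums((Y_after - Y_before)^2)))
  expect_lt(displacement, 0.2 * bbox)
})

test_that("quantization error shrinks as the growth threshold shrinks", {
  set.seed(11)
  tr <- make_trajectory(make_line(50), 0.5)
  X <- evaluate_trajectory(tr, 0:299)
  qe <- vapply(c(0.4, 0.2, 0.1, 0.05), function(gc) {
    set.seed(12)
    m <- partial_fit(song_init(50, song_config(grow_coef = gc)), X)
    quantization_error(m, X)
  }, numeric(1))
  expect_true(all(diff(qe) < 0))
})

test_that("coding vectors map exactly to their layout positions", {
  b <- fixture_blobs()
  set.seed(13)
  m <- partial_fit(song_init(10), b$X)
  expect_equal(song_transform(m, m$C), m$Y)
})

test_that("inputs sharing a cell stay within the cell's layout radius", {
  b <- fixture_blobs()
  set.seed(14)
  m <- partial_fit(song_init(10), b$X)
  Y <- song_transform(m, b$X)
  nearest <- apply(b$X, 1, function(x)
    which.min(colSums((t(m$C) - x)^2)))
  for (j in unique(nearest)) {
    nbrs <- which(m$E[j, ] > 0)
    if (length(nbrs) == 0) next
    radius <- max(sqrt(rowSums((m$Y[nbrs, , drop = FALSE] -
                                  matrix(m$Y[j, ], length(nbrs), 2,
                                         byrow = TRUE))^2)))
    pts <- Y[nearest == j, , drop = FALSE]
    if (nrow(pts) < 2) next
    expect_lte(max(dist(pts)), 2 * radius + 1e-9)
  }
})

test_that("checkpoints restore exactly and resumed runs match unbroken ones", {
  b <- fixture_blobs()
  set.seed(15)
  m <- partial_fit(song_init(10), b$X)

  f_rds <- withr::local_tempfile(fileext = ".rds")
  song_save(m, f_rds)
  expect_identical(song_load(f_rds), m)

  f_json <- withr::local_tempfile(fileext = ".json")
  song_save(m, f_json, format = "json")
  mj <- song_load(f_json, format = "json")
  expect_equal(mj$C, m$C, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mj$Y, m$Y, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mj$E, m$E, tolerance = 1e-12, ignore_attr = TRUE)

  X2 <- b$X + 2
  set.seed(16); cont <- partial_fit(m, X2)
  set.seed(16); resumed <- partial_fit(song_load(f_rds), X2)
  expect_identical(cont, resumed)
})
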