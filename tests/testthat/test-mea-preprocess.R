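test_that("high-pass filter kills DC, keeps 1 kHz, rejects 10 Hz", {
  fs <- 25000
  tt <- seq_len(fs) / fs
  rec <- mea_recording(rbind(rep(1, fs),
                             sin(2 * pi * 1000 * tt),
                             sin(2 * pi * 10 * tt)), fs)
  f <- highpass(rec)
  core <- 2000:23000  # avoid filter edge transients
  expect_lt(max(abs(f$signals[1, core])), 1e-6)
  expect_lt(abs(max(abs(f$signals[2, core])) - 1), 0.05)
  atten_db <- 20 * log10(max(abs(f$signals[3, core])))
  expect_lt(atten_db, -40)
  expect_error(highpass(rec, cutoff_hz = 13000), "Nyquist")
})

test_that("segmentation yields floor(duration / window) full windows", {
  fs <- 2500
  rec <- mea_recording(matrix(rnorm(3 * fs * 120), 3), fs)
  segs <- segment_recording(rec, 4)
  expect_length(segs, 30)
  expect_true(all(vapply(segs, ncol, 1L) == fs * 4))

  # the documented sample count at the hardware rate
  rec25 <- mea_recording(matrix(0, 1, 100000 + 5000), 25000)
  segs25 <- segment_recording(rec25, 4)
  expect_length(segs25, 1)
  expect_equal(ncol(segs25[[1]]), 100000)

  # partial trailing window discarded; sub-window recording yields none
  short <- mea_recording(matrix(0, 2, round(3.9 * fs)), fs)
  expect_warning(none <- segment_recording(short, 4), "shorter")
  expect_length(none, 0)
})

test_that("FFT features have fixed length, non-negative amplitudes", {
  blk <- matrix(rnorm(9 * 20000), 9)
  fv <- fft_features(blk, k = 1000)
  expect_length(fv, 1000)
  expect_true(all(fv >= 0))
  expect_true(all(is.finite(fv)))

  expect_true(all(fft_features(matrix(0, 9, 20000)) == 0))
  expect_error(fft_features(matrix(0, 1, 10), k = 1000), "exceeds")
})

test_that("a pure sine concentrates energy in its reduced bin", {
  fs <- 5000
  n <- fs * 4
  freq <- 750
  blk <- matrix(sin(2 * pi * freq * seq_len(n) / fs), 1)
  fv <- fft_features(blk, k = 1000)
  # single channel: n/2 = 10000 bins averaged 10-into-1; the sine's bin
  # (index freq * 4 + 1) lands in reduced bin ceiling((freq*4 + 1)/10)
  expect_equal(which.max(fv), ceiling((freq * 4 + 1) / 10))
  expect_gt(max(fv), 10 * sort(fv, decreasing = TRUE)[2])
})

test_that("kept half-spectrum energy is bounded by total signal energy", {
  set.seed(20)
  blk <- matrix(rnorm(4 * 8000), 4)
  half <- ncol(blk) %/% 2
  spec <- unlist(lapply(seq_len(nrow(blk)), function(ch)
    Mod(stats::fft(blk[ch, ]))[seq_len(half)]))
  # Parseval: sum |X_k|^2 == n * sum x^2; the kept half is at most all of it
  expect_lte(sum(spec^2), ncol(blk) * sum(blk^2))
  expect_gt(sum(spec^2), 0.3 * ncol(blk) * sum(blk^2))
})

test_that("reduction variants keep length and ordering semantics", {
  set.seed(21)
  blk <- matrix(rnorm(2 * 4000), 2)
  for (rd in c("mean", "truncate", "max")) {
    expect_length(fft_features(blk, k = 500, reduce = rd), 500)
  }
  # truncation keeps the lowest bins verbatim
  full <- Mod(stats::fft(blk[1, ]))[1:100]
  expect_equal(fft_features(blk, k = 100, reduce = "truncate"), full[1:100])
})

test_that("featurization is deterministic for identical input bytes", {
  set.seed(22)
  sig <- matrix(rnorm(3 * 40000), 3)
  r1 <- mea_recording(sig, 2500)
  r2 <- mea_recording(sig, 2500)
  expect_identical(mea_features(r1, k = 200), mea_features(r2, k = 200))
})

test_that("increments assemble per timepoint with renumbering over gaps", {
  set.seed(23)
  fs <- 1000
  mk <- function(tp, lab) mea_recording(matrix(rnorm(2 * fs * 12), 2), fs,
                                        timepoint = tp, label = lab)
  # six timepoints -> six increments with equal segment counts
  recs <- lapply(1:6, mk, lab = "org1")
  incs <- build_increments(recs, k = 50, cutoff_hz = 300)
  expect_named(incs, "org1")
  expect_equal(incs$org1$n, 6)
  expect_true(all(vapply(incs$org1$increments,
                         function(e) nrow(e$points), 1L) == 3))
  expect_equal(incs$org1$D, 50)

  # a missing timepoint renumbers increments consecutively
  gappy <- lapply(c(1, 2, 4, 6), mk, lab = "org2")
  incs2 <- build_increments(gappy, k = 50)
  expect_equal(vapply(incs2$org2$increments, `[[`, 1L, "i"), 1:4)

  expect_error(build_increments(c(recs, list(mk(3, "org1"))), k = 50),
               "duplicate")
  expect_identical(build_increments(list()), list())
})
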