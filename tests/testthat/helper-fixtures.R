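# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files are read.

# A nonlinear trajectory with the simulator's default coefficient ranges.
fixture_trajectory <- function(D = 100, seed = 1, square_fraction = 0.5) {
  set.seed(seed)
  make_trajectory(make_line(D), square_fraction)
}

# Two principal + two secondary trajectories for the similarity experiments.
fixture_alpha_streams <- function(alpha, seed, D = 100, n = 5) {
  set.seed(seed)
  T1 <- make_trajectory(make_line(D), 0.5)
  T2 <- make_trajectory(make_line(D), 0.5)
  sec <- compose_secondary(T1, T2, alpha)
  list(T1 = form_increments(T1, n, 0, "T1"),
       T2 = form_increments(T2, n, 0, "T2"),
       T3 = form_increments(sec$T3, n, 0, "T3"),
       T4 = form_increments(sec$T4, n, 0, "T4"))
}

# A tiny two-blob dataset for separability checks.
fixture_blobs <- function(n_per = 200, D = 10, sep = 6, seed = 7) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * D), n_per, D),
             matrix(stats::rnorm(n_per * D, mean = sep), n_per, D))
  list(X = X, group = rep(1:2, each = n_per))
}

# Mean displacement QC across consecutive sessions of a seeded single-stream
# run; used by the orientation / ablation tests.
fixture_run_qc <- function(seed, reset, n = 5, D = 100) {
  set.seed(seed)
  tr <- make_trajectory(make_line(D), 0.5)
  incs <- form_increments(tr, n, 0, "T1")
  st <- session_state(D)
  qc <- numeric(0)
  for (i in seq_len(n)) {
    st <- run_session(st, list(T1 = incs$increments[[i]]$points),
                      reset_params = reset)
    if (i > 1) {
      qc <- c(qc, orientation_qc(st$history[[i - 1]],
                                 st$history[[i]])$displacement)
    }
  }
  mean(qc)
}

# A projection object built directly from a median matrix (bypasses the
# embedding; used by the metric tests).
fixture_projection <- function(medians, label = "P") {
  structure(list(label = label, increments = seq_len(nrow(medians)),
                 medians = medians, points = NULL),
            class = "ilvis_projection")
}
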