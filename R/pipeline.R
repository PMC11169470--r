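#' Create a fresh incremental-training state
#'
#' A session state bundles the parametric embedding model with all data
#' increments seen so far. At each session the model is fine-tuned on the
#' full accumulated dataset (full replay), which is the pipeline's defense
#' against catastrophic forgetting, and a partial visualization of everything
#' seen so far is produced.
#'
#' @param D Feature dimensionality.
#' @param config A [song_config()].
#' @return An object of class `ilvis_state`.
#' @export
session_state <- function(D, config = song_config()) {
  structure(list(model = song_init(D, config),
                 D = as.integer(D),
                 config = config,
                 data = NULL,
                 meta = data.frame(label = character(0),
                                   increment = integer(0)),
                 i = 0L,
                 history = list()),
            class = "ilvis_state")
}

#' Run one incremental training session
#'
#' Appends the new increments (one matrix per trajectory/organoid label) to
#' the accumulated data, fine-tunes the embedding model on the union of all
#' increments so far, and produces the partial visualization `V_i` by
#' projecting the accumulated data.
#'
#' @param state An `ilvis_state`.
#' @param new_increments Named list mapping a label to an `M x D` matrix of
#'   new points. Labels absent from the list simply skip this session
#'   (their increments are renumbered consecutively).
#' @param reset_params If `TRUE`, the model parameters are reinitialized
#'   before training instead of being carried over. This ablation mode breaks
#'   the orientation continuity of consecutive visualizations and exists for
#'   quality-control comparisons only.
#' @return The updated state. `state$history[[i]]` holds `V_i` as a data
#'   frame with columns `x`, `y`, `label`, `increment`.
#' @export
run_session <- function(state, new_increments, reset_params = FALSE) {
  stopifnot(inherits(state, "ilvis_state"), is.list(new_increments))
  if (is.null(names(new_increments)) || any(names(new_increments) == "")) {
    stop("`new_increments` must be a named list (label -> points matrix)",
         call. = FALSE)
  }
  for (lab in names(new_increments)) {
    pts <- as.matrix(new_increments[[lab]])
    if (ncol(pts) != state$D) {
      stop(sprintf("increment for '%s' has %d columns, expected %d",
                   lab, ncol(pts), state$D), call. = FALSE)
    }
    prev <- length(unique(state$meta$increment[state$meta$label == lab]))
    inc_id <- prev + 1L
    state$data <- rbind(state$data, pts)
    state$meta <- rbind(state$meta,
                        data.frame(label = rep(lab, nrow(pts)),
                                   increment = rep(inc_id, nrow(pts))))
  }
  if (reset_params) state$model <- song_init(state$D, state$config)
  state$model <- partial_fit(state$model, state$data)
  V <- song_transform(state$model, state$data)
  state$i <- state$i + 1L
  state$history[[state$i]] <- data.frame(x = V[, 1], y = V[, 2],
                                         label = state$meta$label,
                                         increment = state$meta$increment)
  state
}

#' Trace increment medians into a 2D progression trajectory
#'
#' Computes the coordinate-wise 2D median of each increment's points in a
#' partial visualization and orders them chronologically. The median is used
#' rather than the mean because it is robust to outlying segments.
#'
#' @param V A visualization data frame (`x`, `y`, `label`, `increment`), as
#'   stored in `ilvis_state$history`.
#' @param labels Labels to trace (default: all present in `V`).
#' @return A named list of `ilvis_projection` objects, each with fields
#'   `label`, `increments` and `medians` (an `n x 2` matrix).
#' @export
trace_medians <- function(V, labels = NULL) {
  stopifnot(is.data.frame(V), all(c("x", "y", "label", "increment") %in% names(V)))
  if (is.null(labels)) labels <- unique(V$label)
  out <- lapply(labels, function(lab) {
    sub <- V[V$label == lab, , drop = FALSE]
    ids <- sort(unique(sub$increment))
    med <- t(vapply(ids, function(i) {
      pts <- sub[sub$increment == i, c("x", "y"), drop = FALSE]
      if (nrow(pts) == 0L) {
        warning(sprintf("empty increment %d for label '%s'; skipped", i, lab))
        return(c(NA_real_, NA_real_))
      }
      c(stats::median(pts$x), stats::median(pts$y))
    }, numeric(2)))
    keep <- stats::complete.cases(med)
    structure(list(label = lab, increments = ids[keep],
                   medians = med[keep, , drop = FALSE],
                   points = sub),
              class = "ilvis_projection")
  })
  names(out) <- labels
  out
}

#' @export
print.ilvis_projection <- function(x, ...) {
  cat(sprintf("<ilvis_projection> label=%s  increments=%d\n",
              x$label, length(x$increments)))
  print(round(x$medians, 3))
  invisible(x)
}

#' Jointly model several trajectories in one shared embedding
#'
#' Runs one incremental training session per increment index: at session `i`,
#' the `i`-th increment of every stream that has one is introduced, the shared
#' model is fine-tuned on all accumulated data, and the visualization is
#' refreshed. Because all streams share one model, the directions and
#' distances of the traced trajectories are directly comparable.
#'
#' @param streams Named list of `ilvis_increments` objects (one per
#'   trajectory/organoid). All must share the feature dimensionality.
#' @param config A [song_config()].
#' @param reset_params Ablation flag forwarded to [run_session()].
#' @return A list with elements `state` (the final `ilvis_state`) and
#'   `projections` (per-label `ilvis_projection` traced from the final
#'   visualization).
#' @export
joint_model <- function(streams, config = song_config(), reset_params = FALSE) {
  stopifnot(is.list(streams), length(streams) >= 1)
  if (is.null(names(streams)) || any(names(streams) == "")) {
    names(streams) <- vapply(streams, function(s) s$label, character(1))
  }
  Ds <- vapply(streams, function(s) s$D, 1L)
  if (length(unique(Ds)) != 1L) {
    stop("all streams must share the feature dimensionality", call. = FALSE)
  }
  n_sessions <- max(vapply(streams, function(s) s$n, 1L))
  state <- session_state(Ds[1], config)
  for (i in seq_len(n_sessions)) {
    batch <- list()
    for (lab in names(streams)) {
      s <- streams[[lab]]
      if (s$n >= i) batch[[lab]] <- s$increments[[i]]$points
    }
    state <- run_session(state, batch, reset_params = reset_params)
  }
  V <- state$history[[state$i]]
  list(state = state, projections = trace_medians(V))
}

#' Orientation stability between consecutive visualizations
#'
#' Quantifies how much the points shared by two consecutive partial
#' visualizations moved, normalized by the bounding-box diagonal of the newer
#' one. Points are matched by row order (the accumulated data keeps a stable
#' order across sessions). A small score means the newer visualization kept
#' the structure and orientation of the previous one; parameter carry-over is
#' what keeps this score low. The optimal rigid-alignment (rotation +
#' translation) residual is also reported: a low residual with a high
#' displacement score indicates a rigid motion such as a global rotation.
#'
#' @param V_prev,V_curr Visualization data frames from consecutive sessions.
#' @return A list with `displacement` (mean shared-point displacement over
#'   the bounding-box diagonal of `V_curr`), `rigid_residual` (RMS residual
#'   after optimal rigid alignment, same normalization), and `n_shared`.
#' @export
orientation_qc <- function(V_prev, V_curr) {
  stopifnot(is.data.frame(V_prev), is.data.frame(V_curr))
  n <- nrow(V_prev)
  if (n == 0L || nrow(V_curr) < n) {
    stop("no shared points between the two visualizations", call. = FALSE)
  }
  A <- as.matrix(V_prev[seq_len(n), c("x", "y")])
  B <- as.matrix(V_curr[seq_len(n), c("x", "y")])
  diag_len <- sqrt(sum((apply(V_curr[, c("x", "y")], 2, max) -
                          apply(V_curr[, c("x", "y")], 2, min))^2))
  if (diag_len <= 0) diag_len <- .Machine$double.eps
  disp <- mean(sqrt(rowSums((A - B)^2))) / diag_len
  # optimal rigid alignment (Kabsch): rotate/translate B onto A
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  sv <- svd(crossprod(Ac, Bc))
  R <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  resid <- sqrt(mean(rowSums((Ac - Bc %*% R)^2))) / diag_len
  list(displacement = disp, rigid_residual = resid, n_shared = n)
}

#' Monotone-trend score of a traced trajectory
#'
#' For a progression expected to drift steadily away from its origin, counts
#' the increments whose median moves strictly farther from the first
#' increment's median than the previous one did. A trajectory with `n`
#' increments scores at most `n` (the first increment counts by convention);
#' a score of at least `n - 1` is the usual pass mark for a captured trend.
#'
#' @param proj An `ilvis_projection`.
#' @return Integer score between 1 and `length(proj$increments)`.
#' @export
trend_score <- function(proj) {
  stopifnot(inherits(proj, "ilvis_projection"))
  m <- proj$medians
  d <- sqrt(rowSums(sweep(m, 2, m[1, ])^2))
  sum(d > c(-Inf, d[-length(d)]))
}
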