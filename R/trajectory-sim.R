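#' Define a high-dimensional line
#'
#' A trajectory starts from a straight line in `D`-dimensional space,
#' parameterized by a pseudo-time `t`: component `i` of the line at time `t`
#' is `d[i] * t + p[i]`. Intercepts `p` and gradients `d` are either supplied
#' explicitly or drawn uniformly from `p_range` and `d_range`.
#'
#' The default coefficient ranges (`p` in \[-1, 1\], `d` in \[0, 0.01\]) keep
#' component magnitudes of order 1--100 over the default pseudo-time span
#' (t up to 499) even after squaring selected dimensions, which keeps the
#' simulated trajectories on a visualizable scale. Gradients are non-negative
#' by default so the simulated process drifts steadily away from its origin,
#' emulating the gradual increase in electrical activity seen in maturing
#' neural cultures.
#'
#' @param D Dimensionality (positive integer).
#' @param p,d Optional explicit intercept / gradient vectors of length `D`.
#' @param p_range,d_range Uniform sampling ranges used when `p`/`d` are not
#'   supplied.
#' @return An object of class `ilvis_line` with fields `p`, `d`, `D`.
#' @examples
#' set.seed(1)
#' ln <- make_line(10)
#' str(ln)
#' @export
make_line <- function(D, p = NULL, d = NULL,
                      p_range = c(-1, 1), d_range = c(0, 0.01)) {
  if (length(D) != 1L || !is.finite(D) || D < 1 || D != round(D)) {
    stop("`D` must be a positive integer", call. = FALSE)
  }
  D <- as.integer(D)
  if (is.null(p)) p <- stats::runif(D, p_range[1], p_range[2])
  if (is.null(d)) d <- stats::runif(D, d_range[1], d_range[2])
  stopifnot(length(p) == D, length(d) == D, all(is.finite(p)), all(is.finite(d)))
  structure(list(p = as.numeric(p), d = as.numeric(d), D = D),
            class = "ilvis_line")
}

#' Bend a line into a nonlinear trajectory
#'
#' Component `i` of the trajectory at pseudo-time `t` is
#' `(d[i] * t + p[i])^a[i]` where each exponent `a[i]` is 1 or 2. A random
#' subset of dimensions (expected fraction `square_fraction`) is squared,
#' which introduces the nonlinearity the embedding is later asked to recover.
#'
#' @param line An `ilvis_line`.
#' @param square_fraction Probability that a dimension is squared (in \[0, 1\]).
#' @param exponents Optional explicit exponent vector (entries in {1, 2});
#'   overrides `square_fraction`.
#' @return An object of class `ilvis_trajectory`.
#' @export
make_trajectory <- function(line, square_fraction = 0.5, exponents = NULL) {
  stopifnot(inherits(line, "ilvis_line"))
  if (is.null(exponents)) {
    if (square_fraction < 0 || square_fraction > 1) {
      stop("`square_fraction` must lie in [0, 1]", call. = FALSE)
    }
    exponents <- ifelse(stats::runif(line$D) < square_fraction, 2L, 1L)
  }
  exponents <- as.integer(exponents)
  if (length(exponents) != line$D || !all(exponents %in% c(1L, 2L))) {
    stop("`exponents` must be a D-vector with entries in {1, 2}", call. = FALSE)
  }
  structure(list(line = line, exponents = exponents, composition = NULL,
                 D = line$D),
            class = "ilvis_trajectory")
}

#' Compose two secondary trajectories from two principal ones
#'
#' Given principal trajectories `T1`, `T2` and a similarity factor `alpha`,
#' the secondaries are the convex combinations
#' `T3 = alpha * T1 + (1 - alpha) * T2` and
#' `T4 = (1 - alpha) * T1 + alpha * T2`, applied component-wise to the
#' already-exponentiated parents. With `alpha = 1` the secondaries coincide
#' with their principals; with `alpha > 0.5`, `T3` resembles `T1` more than
#' `T2` (and symmetrically for `T4`).
#'
#' @param T1,T2 `ilvis_trajectory` objects sharing the same dimensionality.
#' @param alpha Similarity factor in \[0, 1\].
#' @return A list with elements `T3` and `T4` (both `ilvis_trajectory`).
#' @export
compose_secondary <- function(T1, T2, alpha) {
  stopifnot(inherits(T1, "ilvis_trajectory"), inherits(T2, "ilvis_trajectory"))
  if (T1$D != T2$D) stop("parent trajectories must share D", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  mk <- function(a) {
    structure(list(line = NULL, exponents = NULL,
                   composition = list(parent1 = T1, parent2 = T2, alpha = a),
                   D = T1$D),
              class = "ilvis_trajectory")
  }
  list(T3 = mk(alpha), T4 = mk(1 - alpha))
}

#' Evaluate a trajectory at integer pseudo-times
#'
#' @param traj An `ilvis_trajectory`.
#' @param t Vector of pseudo-time values (t >= 0).
#' @return A `length(t) x D` numeric matrix.
#' @export
evaluate_trajectory <- function(traj, t) {
  stopifnot(inherits(traj, "ilvis_trajectory"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (!is.null(traj$composition)) {
    cmp <- traj$composition
    return(cmp$alpha * evaluate_trajectory(cmp$parent1, t) +
             (1 - cmp$alpha) * evaluate_trajectory(cmp$parent2, t))
  }
  ln <- traj$line
  base <- outer(t, ln$d) + matrix(ln$p, nrow = length(t), ncol = ln$D,
                                  byrow = TRUE)
  sq <- traj$exponents == 2L
  if (any(sq)) base[, sq] <- base[, sq, drop = FALSE]^2
  base
}

#' Form data increments along a trajectory
#'
#' Increment `i` contains one point per integer pseudo-time `t` with
#' `100 * (i - 1) <= t < 100 * i - delta`, i.e. `100 - delta` points. The
#' sampling gap `delta` models the time between consecutive recordings of a
#' longitudinal experiment: `delta = 0` yields a seamless stream, larger
#' values leave unobserved stretches of the underlying process between
#' increments.
#'
#' @param traj An `ilvis_trajectory`.
#' @param n Number of increments (>= 1).
#' @param delta Sampling gap in \[0, 99\].
#' @param label Trajectory identifier carried through the pipeline.
#' @return An object of class `ilvis_increments`: a list with fields `label`,
#'   `delta`, `D`, and `increments` -- an ordered list of
#'   `list(i, t, points)` entries where `points` is an `M x D` matrix.
#' @export
form_increments <- function(traj, n, delta = 0, label = "T1") {
  stopifnot(inherits(traj, "ilvis_trajectory"))
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer", call. = FALSE)
  if (delta < 0 || delta > 99) stop("`delta` must lie in [0, 99]", call. = FALSE)
  incs <- lapply(seq_len(n), function(i) {
    tt <- seq.int(100L * (i - 1L), 100L * i - delta - 1L)
    list(i = i, t = tt, points = evaluate_trajectory(traj, tt))
  })
  structure(list(label = label, delta = delta, D = traj$D, traj = traj,
                 n = length(incs), increments = incs),
            class = "ilvis_increments")
}

#' Add observation noise to increments
#'
#' Each point receives independent per-dimension Gaussian noise
#' `lambda * phi` with `phi ~ N(0, SD_dim^2)`. By default `SD_dim` is the
#' per-dimension standard deviation of the noiseless trajectory over the full
#' pseudo-time span, so `lambda` acts as a scale-free "percentage of noise"
#' (e.g. `lambda = 0.2` injects 20% noise in every dimension regardless of its
#' magnitude).
#'
#' When increments contain a single point each (sampling gap `delta = 99`),
#' that point is additionally replicated into `expand_points` points by
#' adding N(0, `expand_sd`^2) jitter, so that downstream density-based model
#' fitting has more than one observation per increment. The replication is
#' deliberately not an interpolation between sampled pseudo-times.
#'
#' @param incs An `ilvis_increments` object.
#' @param lambda Noise scale (fraction; 0 returns the input unchanged apart
#'   from the single-point expansion).
#' @param per_dim_sd Optional explicit D-vector of per-dimension SDs.
#' @param expand_points,expand_sd Replication count and jitter SD used when
#'   increments hold a single point.
#' @return A new `ilvis_increments` object.
#' @export
add_noise <- function(incs, lambda, per_dim_sd = NULL,
                      expand_points = 100L, expand_sd = 0.001) {
  stopifnot(inherits(incs, "ilvis_increments"))
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  n <- incs$n
  D <- incs$D
  if (is.null(per_dim_sd)) {
    full_t <- seq.int(0L, 100L * n - 1L)
    per_dim_sd <- apply(evaluate_trajectory(incs$traj, full_t), 2, stats::sd)
  }
  stopifnot(length(per_dim_sd) == D, all(per_dim_sd >= 0))
  single_point <- all(vapply(incs$increments, function(e) nrow(e$points), 1L) == 1L)
  out <- incs
  out$increments <- lapply(incs$increments, function(e) {
    pts <- e$points
    if (lambda > 0) {
      noise <- matrix(stats::rnorm(length(pts)), nrow(pts), D) *
        matrix(per_dim_sd, nrow(pts), D, byrow = TRUE)
      pts <- pts + lambda * noise
    }
    if (single_point) {
      pts <- matrix(pts[1L, ], expand_points, D, byrow = TRUE) +
        matrix(stats::rnorm(expand_points * D, sd = expand_sd), expand_points, D)
      e$t <- rep(e$t[1L], expand_points)
    }
    e$points <- pts
    e
  })
  out
}

#' Two independent trajectories sharing an origin
#'
#' Convenience constructor for the diverging-pair experiment: both
#' trajectories start at the same point `p` but have independently drawn
#' gradients and exponents, so their paths coincide at `t = 0` and separate
#' as pseudo-time grows.
#'
#' @inheritParams make_line
#' @param square_fraction Passed to [make_trajectory()].
#' @return A list with elements `T1` and `T2`.
#' @export
make_diverging_pair <- function(D, square_fraction = 0.5,
                                p_range = c(-1, 1), d_range = c(0, 0.01)) {
  p <- stats::runif(D, p_range[1], p_range[2])
  l1 <- make_line(D, p = p, d_range = d_range)
  l2 <- make_line(D, p = p, d_range = d_range)
  list(T1 = make_trajectory(l1, square_fraction),
       T2 = make_trajectory(l2, square_fraction))
}

#' @export
print.ilvis_increments <- function(x, ...) {
  sizes <- vapply(x$increments, function(e) nrow(e$points), 1L)
  cat(sprintf("<ilvis_increments> label=%s  n=%d  D=%d  delta=%s\n",
              x$label, x$n, x$D,
              if (is.null(x$delta)) "NA" else as.character(x$delta)))
  cat("points per increment:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten increments to a data frame
#'
#' @param x An `ilvis_increments` object.
#' @param row.names,optional Unused, kept for generic compatibility.
#' @param ... Unused.
#' @return A data frame with columns `trajectory_label`, `increment`, `t`
#'   and `x_1 .. x_D`.
#' @export
as.data.frame.ilvis_increments <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  blocks <- lapply(x$increments, function(e) {
    df <- as.data.frame(e$points)
    names(df) <- paste0("x_", seq_len(ncol(df)))
    tt <- if (is.null(e$t)) rep(NA_integer_, nrow(df)) else e$t
    cbind(data.frame(trajectory_label = x$label, increment = e$i, t = tt),
          df)
  })
  do.call(rbind, blocks)
}

# Internal: stack an increments object into (matrix, increment ids)
incs_matrix <- function(incs, upto = NULL) {
  keep <- incs$increments
  if (!is.null(upto)) keep <- keep[vapply(keep, `[[`, 1L, "i") <= upto]
  X <- do.call(rbind, lapply(keep, `[[`, "points"))
  inc <- rep(vapply(keep, `[[`, 1L, "i"),
             vapply(keep, function(e) nrow(e$points), 1L))
  list(X = X, increment = inc)
}
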