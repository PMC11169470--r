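#' Mean Euclidean distance between two traced trajectories
#'
#' For trajectories A and B with matching increment counts `n`, the
#' dissimilarity is the average over increments of the Euclidean distance
#' between their 2D medians:
#' `D(A, B) = (1/n) * sum_i sqrt((a_i^x - b_i^x)^2 + (a_i^y - b_i^y)^2)`.
#' Both trajectories must live in the same embedding (jointly modeled) for
#' the value to be meaningful; it is reported in embedding units.
#'
#' @param A,B `ilvis_projection` objects with equal increment counts.
#' @param truncate If `TRUE`, compare only the first `min(n_A, n_B)`
#'   increments instead of refusing unequal lengths.
#' @return A single non-negative number.
#' @export
trajectory_distance <- function(A, B, truncate = FALSE) {
  stopifnot(inherits(A, "ilvis_projection"), inherits(B, "ilvis_projection"))
  na <- nrow(A$medians); nb <- nrow(B$medians)
  if (na != nb && !truncate) {
    stop(sprintf("trajectories have %d and %d increments; set truncate = TRUE to compare the first min(n) increments",
                 na, nb), call. = FALSE)
  }
  n <- min(na, nb)
  ma <- A$medians[seq_len(n), , drop = FALSE]
  mb <- B$medians[seq_len(n), , drop = FALSE]
  mean(sqrt(rowSums((ma - mb)^2)))
}

#' Rank trajectories by distance to a reference
#'
#' Computes the mean median-to-median Euclidean distance from each candidate
#' trajectory to the reference and ranks them in increasing order (rank 1 =
#' most similar progression). Ties are broken by the order the candidates
#' were supplied in.
#'
#' @param reference An `ilvis_projection` used as the reference trajectory.
#' @param others Named list of `ilvis_projection` candidates.
#' @param truncate Passed to [trajectory_distance()].
#' @return A data frame with columns `label`, `distance`, `rank`, ordered by
#'   rank; the reference itself appears first with distance 0.
#' @export
rank_distances <- function(reference, others, truncate = FALSE) {
  stopifnot(inherits(reference, "ilvis_projection"))
  if (!is.list(others) || length(others) == 0) {
    stop("`others` must be a non-empty list of projections", call. = FALSE)
  }
  labs <- names(others)
  if (is.null(labs)) labs <- vapply(others, function(p) p$label, character(1))
  d <- vapply(others, function(p) trajectory_distance(reference, p, truncate),
              numeric(1))
  rk <- rank(d, ties.method = "first")
  out <- data.frame(label = c(reference$label, labs),
                    distance = c(0, unname(d)),
                    rank = c(NA_integer_, as.integer(rk)))
  out[order(c(-Inf, d)), , drop = FALSE]
}

#' Manifold-preservation diagnostics between input and embedded increments
#'
#' Compares the geometry of the per-increment medians in the high-dimensional
#' input space with the geometry of the corresponding 2D medians: returns the
#' two pairwise inter-increment distance matrices and the Spearman correlation
#' of their upper triangles. A correlation near 1 means the embedding
#' preserved the relative spacing of the increments.
#'
#' @param incs An `ilvis_increments` object (input-space increments).
#' @param proj The matching `ilvis_projection` (embedded increments).
#' @return A list with `high` and `low` (`n x n` symmetric distance matrices)
#'   and `spearman` (NA when fewer than 3 increments are available).
#' @export
preservation_diagnostics <- function(incs, proj) {
  stopifnot(inherits(incs, "ilvis_increments"), inherits(proj, "ilvis_projection"))
  med_high <- t(vapply(incs$increments,
                       function(e) apply(e$points, 2, stats::median),
                       numeric(incs$D)))
  n <- nrow(proj$medians)
  if (nrow(med_high) != n) {
    stop("increment counts differ between the two spaces", call. = FALSE)
  }
  Dh <- as.matrix(stats::dist(med_high))
  Dl <- as.matrix(stats::dist(proj$medians))
  rho <- if (n >= 3) {
    stats::cor(Dh[upper.tri(Dh)], Dl[upper.tri(Dl)], method = "spearman")
  } else {
    NA_real_
  }
  list(high = Dh, low = Dl, spearman = rho)
}
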