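#' Configuration of the self-organizing embedding
#'
#' Collects the tunable hyperparameters of the incremental embedding. The
#' algorithm iterates three steps per training session: (1) vector
#' quantization -- inputs are assigned to their nearest coding vector, winners
#' move toward the input, and a new coding vector is spawned at an input whose
#' distance to the nearest coding vector exceeds a growth threshold; (2)
#' self-organization -- the edge between the winner and the runner-up is
#' reinforced while the winner's other edges decay, so edges spanning dense
#' input regions carry high weight; (3) layout -- the 2D node positions are
#' optimized by stochastic gradient descent on the cross-entropy between the
#' graph's edge weights and a `1/(1 + d^2)` low-dimensional kernel, with
#' negative sampling for repulsion.
#'
#' @param init_nodes Number of coding vectors created from the first batch.
#' @param grow_coef Growth threshold as a fraction of the session data's RMS
#'   distance to its centroid; smaller values give a denser codebook.
#' @param nn_mult Floor of the growth threshold as a multiple of the median
#'   nearest-neighbor distance of the session data; keeps the codebook from
#'   memorizing every observation when noise dominates the geometry.
#' @param max_nodes Hard cap on codebook size.
#' @param org_epochs Passes over the session data for the organization steps.
#' @param lr_start,lr_final Linearly decayed vector-quantization learning rate.
#' @param neighbor_lr_frac Fraction of the learning rate applied to the
#'   winner's graph neighbors (winner-take-most).
#' @param edge_decay Multiplicative decay applied to the winner's edges at
#'   each Hebbian reinforcement.
#' @param prune_rel Edges lighter than this fraction of the maximum weight are
#'   removed at the end of each session.
#' @param layout_epochs SGD epochs of the 2D layout per session.
#' @param layout_lr Initial layout learning rate (linearly decayed to 0).
#' @param neg_samples Negative samples per edge endpoint per epoch.
#' @param repulsion_eps Softening constant in the repulsive gradient.
#' @param grad_clip Per-coordinate clamp on SGD updates.
#' @param spawn_jitter SD of the 2D jitter placing a new node near its
#'   parent's layout position.
#' @param edge_ratio Hebbian gate: the winner/runner-up edge is reinforced
#'   only when the runner-up is at most this factor farther from the input
#'   than the winner, i.e. when the input lies between the two neighborhoods.
#' @param placement_metric Distance matrix used for the per-session MDS
#'   placement of the layout: `"euclidean"` (classical MDS of the coding
#'   vectors; metric-faithful at the global scale, the default) or
#'   `"geodesic"` (shortest paths over the topology graph plus
#'   `placement_knn` nearest-neighbor shortcuts; unfolds strongly curved
#'   manifolds at the cost of stretching global distances).
#' @param placement_knn Number of nearest-neighbor shortcut edges per coding
#'   vector added to the topology graph when computing geodesic placement
#'   distances (the model's own graph is not modified).
#' @param transform_knn Number of nearest coding vectors combined when
#'   projecting an input to 2D.
#' @return A list of class `song_config`.
#' @export
song_config <- function(init_nodes = 4L,
                        grow_coef = 0.15,
                        nn_mult = 1.5,
                        max_nodes = 1000L,
                        org_epochs = 3L,
                        lr_start = 0.6,
                        lr_final = 0.05,
                        neighbor_lr_frac = 0.1,
                        edge_decay = 0.99,
                        prune_rel = 1e-3,
                        layout_epochs = 150L,
                        layout_lr = 0.05,
                        neg_samples = 5L,
                        repulsion_eps = 1e-3,
                        grad_clip = 4,
                        spawn_jitter = 0.05,
                        edge_ratio = 3,
                        placement_metric = c("euclidean", "geodesic"),
                        placement_knn = 3L,
                        transform_knn = 3L) {
  cfg <- list(init_nodes = as.integer(init_nodes), grow_coef = grow_coef,
              nn_mult = nn_mult,
              max_nodes = as.integer(max_nodes),
              org_epochs = as.integer(org_epochs),
              lr_start = lr_start, lr_final = lr_final,
              neighbor_lr_frac = neighbor_lr_frac, edge_decay = edge_decay,
              prune_rel = prune_rel,
              layout_epochs = as.integer(layout_epochs),
              layout_lr = layout_lr, neg_samples = as.integer(neg_samples),
              repulsion_eps = repulsion_eps, grad_clip = grad_clip,
              spawn_jitter = spawn_jitter, edge_ratio = edge_ratio,
              placement_metric = match.arg(placement_metric),
              placement_knn = as.integer(placement_knn),
              transform_knn = as.integer(transform_knn))
  stopifnot(cfg$init_nodes >= 1, cfg$grow_coef > 0, cfg$max_nodes >= 4,
            cfg$org_epochs >= 1, cfg$layout_epochs >= 1, cfg$neg_samples >= 0)
  class(cfg) <- "song_config"
  cfg
}

#' Initialize a parametric embedding model
#'
#' Creates an empty model of dimensionality `D`. The coding vectors are
#' placed at randomly chosen data points when the first batch arrives (see
#' [partial_fit()]); until then the model is unfitted. The model state
#' `theta = {C, E, Y}` (coding vectors, weighted topology graph, 2D layout)
#' is retained across sessions and fine-tuned, never reinitialized.
#'
#' @param D Input dimensionality.
#' @param config A [song_config()].
#' @return An object of class `song_model`.
#' @export
song_init <- function(D, config = song_config()) {
  stopifnot(length(D) == 1L, D >= 1, D == round(D))
  if (!inherits(config, "song_config")) config <- do.call(song_config, config)
  structure(list(D = as.integer(D),
                 C = matrix(numeric(0), 0L, D),
                 E = matrix(numeric(0), 0L, 0L),
                 Y = matrix(numeric(0), 0L, 2L),
                 config = config,
                 fitted = FALSE,
                 sessions = 0L,
                 objective = numeric(0)),
            class = "song_model")
}

#' @export
print.song_model <- function(x, ...) {
  cat(sprintf("<song_model> D=%d  nodes=%d  edges=%d  sessions=%d%s\n",
              x$D, nrow(x$C), sum(x$E > 0) / 2, x$sessions,
              if (x$fitted) "" else "  (unfitted)"))
  invisible(x)
}

#' Fine-tune the embedding model on a data batch
#'
#' Runs one training session on `X`: codebook growth and vector quantization,
#' Hebbian graph reinforcement, and the cross-entropy 2D layout. Existing
#' parameters are updated in place -- this is what keeps consecutive
#' visualizations of a growing longitudinal dataset mutually comparable.
#'
#' @param model A `song_model`.
#' @param X Numeric matrix (rows = observations, columns = `model$D`).
#' @return The updated `song_model`. Field `objective` holds the layout
#'   cross-entropy trace of this session.
#' @export
partial_fit <- function(model, X) {
  stopifnot(inherits(model, "song_model"))
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(model)
  if (ncol(X) != model$D) {
    stop(sprintf("data has %d columns but model expects %d", ncol(X), model$D),
         call. = FALSE)
  }
  if (!all(is.finite(X))) stop("`X` must be finite", call. = FALSE)
  cfg <- model$config

  first_session <- !model$fitted
  if (first_session) {
    k0 <- min(cfg$init_nodes, nrow(X))
    pick <- sample.int(nrow(X), k0)
    model$C <- X[pick, , drop = FALSE]
    model$E <- matrix(0, k0, k0)
    model$Y <- matrix(stats::rnorm(k0 * 2L, sd = 0.1), k0, 2L)
    model$fitted <- TRUE
  }

  # Growth threshold: fraction of the RMS distance to the batch centroid,
  # floored at a multiple of the typical nearest-neighbor spacing. The floor
  # matters for noisy high-dimensional data, where pairwise distances
  # concentrate and a purely scale-based threshold would spawn one coding
  # vector per observation instead of letting winners average out the noise.
  ctr <- colMeans(X)
  rms <- sqrt(mean(rowSums(sweep(X, 2L, ctr)^2)))
  med_nn <- 0
  if (nrow(X) > 2) {
    sub <- X[sample.int(nrow(X), min(nrow(X), 400L)), , drop = FALSE]
    dm <- as.matrix(stats::dist(sub))
    diag(dm) <- Inf
    med_nn <- stats::median(apply(dm, 1, min))
  }
  theta <- max(cfg$grow_coef * rms, cfg$nn_mult * med_nn,
               .Machine$double.eps)

  K_old <- nrow(model$C)

  # organization phase: vector quantization, growth, Hebbian graph updates
  res <- .song_session_cpp(model$C, model$E, model$Y, X,
                           theta, cfg$org_epochs,
                           cfg$lr_start, cfg$lr_final,
                           cfg$neighbor_lr_frac, cfg$edge_decay,
                           cfg$prune_rel, cfg$max_nodes,
                           0L, cfg$layout_lr, cfg$neg_samples,
                           cfg$repulsion_eps, cfg$grad_clip, cfg$spawn_jitter,
                           cfg$edge_ratio)
  model$C <- res$C
  model$E <- res$E
  model$Y <- res$Y
  K <- nrow(model$C)

  # placement of newly grown nodes: a spawned node starts collapsed onto its
  # parent's layout position, which folds badly once whole new regions of the
  # input space arrive. Seed new node positions from classical MDS on the
  # graph geodesics (input-space edge lengths), rigidly aligned to the
  # carried-over layout of the pre-existing nodes, which are left untouched.
  # At the very first session there is no previous layout, so the MDS
  # solution seeds all nodes.
  if (K > K_old && K >= 3) {
    G <- if (cfg$placement_metric == "geodesic") {
      .song_geodesics_cpp(model$C, model$E, cfg$placement_knn)
    } else {
      as.matrix(stats::dist(model$C))
    }
    Y0 <- try(suppressWarnings(stats::cmdscale(G, k = 2)), silent = TRUE)
    if (!inherits(Y0, "try-error") && is.matrix(Y0) && ncol(Y0) == 2 &&
        all(is.finite(Y0))) {
      Y0 <- Y0 + matrix(stats::rnorm(length(Y0), sd = 1e-4), nrow(Y0), 2L)
      if (first_session || K_old < 3) {
        gs <- max(G)
        if (gs > 0) Y0 <- Y0 / gs * 10  # initial layout scale
        model$Y <- Y0
      } else {
        anchors_old <- model$Y[seq_len(K_old), , drop = FALSE]
        fit <- procrustes_map(anchors_old, Y0[seq_len(K_old), , drop = FALSE])
        model$Y <- fit(Y0)
      }
    }
  }

  # layout phase: stochastic-gradient cross-entropy fine-tuning of Y
  res2 <- .song_session_cpp(model$C, model$E, model$Y, X,
                            theta, 0L,
                            cfg$lr_start, cfg$lr_final,
                            cfg$neighbor_lr_frac, cfg$edge_decay,
                            cfg$prune_rel, cfg$max_nodes,
                            cfg$layout_epochs, cfg$layout_lr, cfg$neg_samples,
                            cfg$repulsion_eps, cfg$grad_clip,
                            cfg$spawn_jitter, cfg$edge_ratio)
  model$E <- res2$E
  model$Y <- res2$Y
  model$objective <- as.numeric(res2$objective)
  model$sessions <- model$sessions + 1L
  model
}

# Similarity transform (rotation/reflection + isotropic scale + translation)
# mapping point set B onto A; returns a function applying the fit to new rows.
procrustes_map <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(crossprod(Bc, Ac))  # t(Bc) %*% Ac
  R <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / max(sum(Bc^2), .Machine$double.eps)
  function(M) {
    sweep(s * (sweep(M, 2, cb) %*% R), 2, ca, `+`)
  }
}

#' Project data through a fitted embedding model
#'
#' Each input is mapped to a convex combination of the 2D positions of its
#' nearest coding vectors (inverse-squared-distance weights). An input that
#' coincides with a coding vector maps exactly to that vector's position, so
#' the codebook and its layout stay in bijection.
#'
#' @param model A fitted `song_model`.
#' @param X Numeric matrix with `model$D` columns.
#' @return An `nrow(X) x 2` matrix of embedding coordinates.
#' @export
song_transform <- function(model, X) {
  stopifnot(inherits(model, "song_model"))
  if (!model$fitted) stop("model has not been fitted yet", call. = FALSE)
  X <- as.matrix(X)
  if (ncol(X) != model$D) {
    stop(sprintf("data has %d columns but model expects %d", ncol(X), model$D),
         call. = FALSE)
  }
  .song_transform_cpp(model$C, model$Y, X, model$config$transform_knn)
}

#' Mean quantization error of a model on data
#'
#' Average Euclidean distance from each row of `X` to its nearest coding
#' vector; a codebook-resolution diagnostic.
#'
#' @inheritParams song_transform
#' @return A single number.
#' @export
quantization_error <- function(model, X) {
  stopifnot(inherits(model, "song_model"), model$fitted)
  .song_quant_error_cpp(model$C, as.matrix(X))
}

#' Save / load a model checkpoint
#'
#' `song_save()` writes the complete model state to `path`; `song_load()`
#' restores it exactly, so a run resumed from a checkpoint is identical to an
#' unbroken run under the same RNG state. The default format is RDS; with
#' `format = "json"` a portable JSON checkpoint (full numeric precision) is
#' written instead.
#'
#' @param model A `song_model`.
#' @param path File path.
#' @param format `"rds"` (exact binary round-trip) or `"json"`.
#' @return `song_load()` returns the restored `song_model`.
#' @export
song_save <- function(model, path, format = c("rds", "json")) {
  stopifnot(inherits(model, "song_model"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(model, path)
  } else {
    idx <- which(upper.tri(model$E) & model$E > 0, arr.ind = TRUE)
    payload <- list(
      D = model$D,
      C = model$C,
      edges = data.frame(i = idx[, 1], j = idx[, 2],
                         w = model$E[idx]),
      Y = model$Y,
      config = unclass(model$config),
      fitted = model$fitted,
      sessions = model$sessions,
      objective = model$objective
    )
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname song_save
#' @export
song_load <- function(path, format = c("rds", "json")) {
  format <- match.arg(format)
  if (format == "rds") {
    model <- readRDS(path)
    stopifnot(inherits(model, "song_model"))
    return(model)
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- nrow(payload$C)
  E <- matrix(0, K, K)
  if (length(payload$edges) && nrow(payload$edges) > 0) {
    for (r in seq_len(nrow(payload$edges))) {
      i <- payload$edges$i[r]; j <- payload$edges$j[r]
      E[i, j] <- E[j, i] <- payload$edges$w[r]
    }
  }
  cfg <- do.call(song_config, payload$config)
  structure(list(D = as.integer(payload$D),
                 C = matrix(as.numeric(payload$C), K, payload$D),
                 E = E,
                 Y = matrix(as.numeric(payload$Y), K, 2L),
                 config = cfg,
                 fitted = isTRUE(payload$fitted),
                 sessions = as.integer(payload$sessions),
                 objective = as.numeric(payload$objective)),
            class = "song_model")
}
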