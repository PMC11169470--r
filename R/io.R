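#' Write / read increments as long-format CSV
#'
#' Columns: `trajectory_label`, `increment`, `t`, `x_1 .. x_D`.
#'
#' @param incs An `ilvis_increments` object (or named list of them).
#' @param path Output CSV path.
#' @return `read_increments_csv()` returns a named list of
#'   `ilvis_increments` objects.
#' @export
write_increments_csv <- function(incs, path) {
  if (inherits(incs, "ilvis_increments")) incs <- list(incs)
  df <- do.call(rbind, lapply(incs, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_increments_csv
#' @export
read_increments_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  xcols <- grep("^x_", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x_", "", xcols)))]
  out <- lapply(split(df, df$trajectory_label), function(sub) {
    ids <- sort(unique(sub$increment))
    incs <- lapply(seq_along(ids), function(q) {
      blk <- sub[sub$increment == ids[q], , drop = FALSE]
      list(i = q, t = blk$t,
           points = as.matrix(blk[, xcols, drop = FALSE]))
    })
    structure(list(label = sub$trajectory_label[1], delta = NULL,
                   D = length(xcols), traj = NULL, n = length(incs),
                   increments = incs),
              class = "ilvis_increments")
  })
  out
}

#' Write a visualization (and its medians) to CSV
#'
#' @param V A visualization data frame (`x`, `y`, `label`, `increment`).
#' @param path Output CSV path for the points.
#' @param medians_path Optional CSV path for the per-increment medians.
#' @export
write_visualization_csv <- function(V, path, medians_path = NULL) {
  utils::write.csv(V, path, row.names = FALSE)
  if (!is.null(medians_path)) {
    projs <- trace_medians(V)
    med <- do.call(rbind, lapply(projs, function(p) {
      data.frame(label = p$label, increment = p$increments,
                 x = p$medians[, 1], y = p$medians[, 2])
    }))
    utils::write.csv(med, medians_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration, seed and package version of a run as JSON, so
#' the run can be replayed exactly.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration values.
#' @param seed The RNG seed used.
#' @export
write_run_manifest <- function(path, config, seed) {
  payload <- list(
    package = "ilvis",
    version = as.character(utils::packageVersion("ilvis")),
    r_version = as.character(getRversion()),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
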