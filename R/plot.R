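#' Plot a partial visualization with traced medians
#'
#' Scatter plot of one partial visualization in the pipeline's house style:
#' one color per trajectory label, newer increments drawn with stronger
#' intensity, and arrows connecting the increment medians in chronological
#' order.
#'
#' @param V A visualization data frame (`x`, `y`, `label`, `increment`).
#' @param medians Draw the chronological median arrows.
#' @param cex Point size.
#' @return Invisibly, the per-label `ilvis_projection` list.
#' @export
plot_visualization <- function(V, medians = TRUE, cex = 0.5) {
  stopifnot(is.data.frame(V))
  labs <- unique(V$label)
  base_cols <- grDevices::hcl.colors(max(3L, length(labs)), "Dark 3")
  plot(V$x, V$y, type = "n", xlab = "dim 1", ylab = "dim 2", asp = 1)
  for (q in seq_along(labs)) {
    sub <- V[V$label == labs[q], ]
    imax <- max(sub$increment)
    alpha <- 0.25 + 0.75 * sub$increment / imax
    cols <- grDevices::adjustcolor(base_cols[q], alpha.f = 1)
    cols <- vapply(alpha, function(a)
      grDevices::adjustcolor(base_cols[q], alpha.f = a), character(1))
    graphics::points(sub$x, sub$y, col = cols, pch = 16, cex = cex)
  }
  projs <- trace_medians(V)
  if (medians) {
    for (q in seq_along(labs)) {
      m <- projs[[labs[q]]]$medians
      if (nrow(m) > 1) {
        graphics::arrows(m[-nrow(m), 1], m[-nrow(m), 2],
                         m[-1, 1], m[-1, 2],
                         length = 0.08, lwd = 2, col = base_cols[q])
      }
      graphics::points(m[, 1], m[, 2], pch = 21, bg = "white",
                       col = base_cols[q], cex = 1.2)
    }
  }
  if (length(labs) > 1) {
    graphics::legend("topleft", legend = labs, col = base_cols[seq_along(labs)],
                     pch = 16, bty = "n", cex = 0.8)
  }
  invisible(projs)
}
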