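#' Plot probe traces of a run
#'
#' Potassium and recovery traces for every probe, faceted by variable --
#' the simulated analogue of the paper-style probe figures.
#'
#' @param object A `csd_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csd_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$probes, c("K", "R"),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(K = "extracellular potassium K",
                            R = "recovery variable R"))) +
    ggplot2::labs(x = "time", y = NULL, colour = "probe") +
    ggplot2::theme_minimal()
}

#' Plot a potassium field snapshot
#'
#' @param run A `csd_run` with snapshots (or a bare matrix).
#' @param which Snapshot index (ignored for a bare matrix).
#' @return A ggplot object.
#' @export
plot_field <- function(run, which = 1L) {
  if (inherits(run, "csd_run")) {
    if (is.null(run$snapshots)) {
      stop("run has no snapshots; set snapshot_stride > 0", call. = FALSE)
    }
    m <- run$snapshots$K[, , which]
    t <- run$snapshots$times[which]
  } else {
    m <- run
    t <- NA_real_
  }
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    K = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$K)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(1, max(m)))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = if (is.finite(t)) sprintf("t = %g", t) else NULL,
                  x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Plot an F-sweep regime map
#'
#' @param object A `csd_sweep` from [sweep_F].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csd_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$F, y = 1, fill = .data$regime)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "recovery-modulation factor F", y = NULL,
                  fill = "wave-2 regime") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
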