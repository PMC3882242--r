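#' Detect wave events in probe traces
#'
#' A wave event is one contiguous suprathreshold excursion of the potassium
#' trace: onset at the first upward crossing of the threshold, offset at the
#' following downward crossing (crossing times linearly interpolated), with
#' the peak in between.  The threshold defaults to the model's `K_theta`,
#' the operational definition of "CSD evoked".
#'
#' @param x A `csd_run` (events for every probe) or a probe trace tibble
#'   with columns `time` and `K` (see [probe_trace]).
#' @param threshold Crossing threshold; defaults to the run's `K_theta`
#'   (0.2 for a bare trace).
#' @return A tibble with columns `probe` (for runs), `wave`, `onset_time`,
#'   `peak_time`, `peak_value`, `offset_time` (`NA` if the trace ends while
#'   still suprathreshold).
#' @examples
#' tr <- tibble::tibble(time = 0:200,
#'                      K = 0.03 + 0.97 * exp(-(0:200 - 100)^2 / 50))
#' detect_wave_events(tr)
#' @export
detect_wave_events <- function(x, threshold = NULL) {
  if (inherits(x, "csd_run")) {
    thr <- threshold %||% x$scenario$params$K_theta
    return(dplyr::bind_rows(lapply(unique(x$probes$probe), function(nm) {
      dplyr::mutate(trace_events(probe_trace(x, nm), thr),
                    probe = nm, .before = 1)
    })))
  }
  trace_events(x, threshold %||% 0.2)
}

trace_events <- function(trace, threshold) {
  t <- trace$time
  v <- trace$K
  stopifnot(length(t) == length(v), length(t) > 0)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  empty <- tibble::tibble(wave = integer(), onset_time = numeric(),
                          peak_time = numeric(), peak_value = numeric(),
                          offset_time = numeric())
  above <- v > threshold
  if (!any(above)) return(empty)
  d <- diff(above)
  ups <- which(d == 1L)        # crossing between index i and i+1
  downs <- which(d == -1L)
  starts <- ups
  if (above[1]) starts <- c(0L, starts)    # starts suprathreshold
  cross <- function(i) {
    # linear interpolation of the threshold crossing in (t[i], t[i+1])
    t[i] + (threshold - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  out <- lapply(seq_along(starts), function(w) {
    i0 <- starts[w]
    onset <- if (i0 == 0L) t[1] else cross(i0)
    j <- downs[downs > i0]
    if (length(j)) {
      j <- j[1]
      offset <- cross(j)
      seg <- (i0 + 1L):j
    } else {
      offset <- NA_real_
      seg <- (i0 + 1L):length(v)
    }
    pk <- seg[which.max(v[seg])]
    tibble::tibble(wave = w, onset_time = onset, peak_time = t[pk],
                   peak_value = v[pk], offset_time = offset)
  })
  dplyr::bind_rows(out)
}

#' Classify the propagation regime of each wave
#'
#' Pairs the wave events recorded at the control and modulated probes (by
#' order, within a matching window) and labels each delivered wave:
#' `"blocked"` when the control probe records the wave but the modulated
#' probe does not (the wave bypassed the modulated area), `"slowed"` when
#' both record it and the modulated onset lags the control onset by more
#' than `delta`, and `"homogeneous"` otherwise.
#'
#' @param x A `csd_run` with standard `"control"` and `"modulated"` probes,
#'   or a control-probe trace (then `modulated` must be given).
#' @param modulated Modulated-probe trace when `x` is a trace.
#' @param n_waves Number of delivered waves to classify; defaults to the
#'   run's stimulus count.
#' @param delta Slowdown margin (time units): onset delays beyond numerical
#'   jitter.  Default 1 (ten recording intervals at the default stride).
#' @param window Matching window; defaults to the inter-stimulus interval
#'   (or `Inf` for a single wave).
#' @param threshold Crossing threshold; defaults as in
#'   [detect_wave_events].
#' @return A tibble with columns `wave`, `control_onset`, `modulated_onset`,
#'   `delay`, `regime`.
#' @examples
#' run <- csd_simulate(make_scenario("homogeneous", t_end = 50))
#' classify_regime(run, n_waves = 1)
#' @export
classify_regime <- function(x, modulated = NULL, n_waves = NULL, delta = 1,
                            window = NULL, threshold = NULL) {
  if (inherits(x, "csd_run")) {
    thr <- threshold %||% x$scenario$params$K_theta
    ctl <- trace_events(probe_trace(x, "control"), thr)
    mod <- trace_events(probe_trace(x, "modulated"), thr)
    n_waves <- n_waves %||% length(x$scenario$stimuli)
    if (is.null(window)) {
      st <- vapply(x$scenario$stimuli, `[[`, numeric(1), "t_on")
      window <- if (length(st) > 1) min(diff(sort(st))) else Inf
    }
  } else {
    if (is.null(modulated)) {
      stop("supply a csd_run, or both a control and a modulated trace",
           call. = FALSE)
    }
    thr <- threshold %||% 0.2
    ctl <- trace_events(x, thr)
    mod <- trace_events(modulated, thr)
    n_waves <- n_waves %||% nrow(ctl)
    window <- window %||% Inf
  }
  out <- vector("list", n_waves)
  jm <- 1L
  for (i in seq_len(n_waves)) {
    c_on <- if (i <= nrow(ctl)) ctl$onset_time[i] else NA_real_
    m_on <- NA_real_
    if (!is.na(c_on)) {
      # next unconsumed modulated event within the matching window
      while (jm <= nrow(mod) && mod$onset_time[jm] < c_on - window / 2) {
        jm <- jm + 1L
      }
      if (jm <= nrow(mod) && mod$onset_time[jm] <= c_on + window) {
        m_on <- mod$onset_time[jm]
        jm <- jm + 1L
      }
    }
    regime <- if (is.na(c_on)) {
      NA_character_
    } else if (is.na(m_on)) {
      "blocked"
    } else if (m_on - c_on > delta) {
      "slowed"
    } else {
      "homogeneous"
    }
    out[[i]] <- tibble::tibble(wave = i, control_onset = c_on,
                               modulated_onset = m_on,
                               delay = m_on - c_on, regime = regime)
  }
  dplyr::bind_rows(out)
}

#' Propagation speed of the wavefront along a ray
#'
#' Tracks the front position -- the farthest suprathreshold cell along a
#' ray from `origin` in `direction` -- across field snapshots, and returns
#' the least-squares slope of position (length units) against time.
#'
#' @param snapshots Snapshot list from a `csd_run` (`run$snapshots`), or a
#'   `csd_run` with snapshots.
#' @param origin Numeric `(row, col)` of the ray origin (cells).
#' @param direction Numeric `(drow, dcol)`; need not be normalised.
#' @param threshold Suprathreshold level (default 0.2).
#' @param dx Grid spacing; taken from the run when available.
#' @param time_range Optional `c(t0, t1)` restricting the fit (e.g. to one
#'   wave's transit).
#' @param position_range Optional `c(r0, r1)` in length units restricting
#'   which front positions enter the fit (e.g. to the modulated area).
#' @return The fitted speed (length units per time), with the per-snapshot
#'   front positions attached as attribute `"front"`.
#' @export
propagation_speed <- function(snapshots, origin, direction, threshold = 0.2,
                              dx = NULL, time_range = NULL,
                              position_range = NULL) {
  if (inherits(snapshots, "csd_run")) {
    dx <- dx %||% snapshots$scenario$params$dx
    threshold <- threshold %||% snapshots$scenario$params$K_theta
    snapshots <- snapshots$snapshots
  }
  dx <- dx %||% 1
  if (is.null(snapshots)) {
    stop("no snapshots recorded; set snapshot_stride > 0", call. = FALSE)
  }
  dims <- dim(snapshots$K)
  dir <- direction / sqrt(sum(direction^2))
  # sample the ray at one-cell steps until it leaves the grid
  rmax_cells <- 2 * max(dims[1:2])
  steps <- 0:rmax_cells
  rows <- round(origin[1] + steps * dir[1])
  cols <- round(origin[2] + steps * dir[2])
  ok <- rows >= 1 & rows <= dims[1] & cols >= 1 & cols <= dims[2]
  rows <- rows[ok]
  cols <- cols[ok]
  steps <- steps[ok]
  idx <- cbind(rows, cols)
  front <- vapply(seq_along(snapshots$times), function(s) {
    v <- snapshots$K[, , s][idx]
    sup <- which(v > threshold)
    if (length(sup)) steps[max(sup)] * dx else NA_real_
  }, numeric(1))
  keep <- !is.na(front) & front < max(steps) * dx  # drop saturated frames
  tt <- snapshots$times
  if (!is.null(time_range)) {
    keep <- keep & tt >= time_range[1] & tt <= time_range[2]
  }
  if (!is.null(position_range)) {
    keep <- keep & front >= position_range[1] & front <= position_range[2]
  }
  if (sum(keep) < 2) {
    stop("front never appears on the ray (or in the requested window); ",
         "speed undefined", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, tt[keep]), front[keep])
  structure(unname(fit$coefficients[2]),
            front = tibble::tibble(time = tt[keep], position = front[keep]))
}

#' Detect re-entrant (self-sustained) activity
#'
#' A run shows re-entry when a probe records strictly more wave events than
#' stimuli were delivered: the extra waves are self-sustained (spiral)
#' activity rather than direct responses.
#'
#' @param run A `csd_run`.
#' @param probe Probe name, or `NULL` to consider every probe.
#' @param n_stimuli Number of delivered stimuli; defaults to the scenario's.
#' @param threshold Crossing threshold; defaults to the run's `K_theta`.
#' @return A list with `reentry` (logical) and `extra_waves` (maximal
#'   excess event count over the probes considered).
#' @examples
#' run <- csd_simulate(make_scenario("homogeneous", t_end = 50))
#' detect_reentry(run)
#' @export
detect_reentry <- function(run, probe = NULL, n_stimuli = NULL,
                           threshold = NULL) {
  stopifnot(inherits(run, "csd_run"))
  n_stimuli <- n_stimuli %||% length(run$scenario$stimuli)
  thr <- threshold %||% run$scenario$params$K_theta
  nms <- probe %||% unique(run$probes$probe)
  counts <- vapply(nms, function(nm) {
    nrow(trace_events(probe_trace(run, nm), thr))
  }, numeric(1))
  extra <- max(counts) - n_stimuli
  list(reentry = extra > 0, extra_waves = max(extra, 0))
}

#' Map the propagation regime of the second wave across F
#'
#' Runs the two-wave scenario of `preset` for every value in `F_grid`,
#' classifies the second wave at the modulated probe, and reports the
#' regime table together with the blocked/slowed boundary: the largest `F`
#' labelled `"blocked"` and the smallest labelled `"slowed"`.  As `F`
#' increases the regimes must appear in the order blocked, slowed,
#' homogeneous; a non-monotone sequence triggers a warning (the full table
#' is still returned for diagnosis).
#'
#' @param preset Two-stimulus preset name (`"bypass"` or `"slowdown"`;
#'   both share the protocol and differ only in their default `F`).
#' @param F_grid Sorted vector of `F` values in `(0, 1]`.
#' @param delta Slowdown margin passed to [classify_regime].
#' @param ... Passed to [make_scenario] (e.g. `nrow`, `ncol`, `interval`).
#' @return A `csd_sweep`: the regime tibble (`F`, `regime`,
#'   `control_onset`, `modulated_onset`, `delay`) with attributes
#'   `largest_blocked` and `smallest_slowed`.
#' @export
sweep_F <- function(preset = "bypass", F_grid, delta = 1, ...) {
  stopifnot(all(F_grid > 0 & F_grid <= 1), !is.unsorted(F_grid))
  rows <- lapply(F_grid, function(f) {
    run <- csd_simulate(make_scenario(preset, F = f, ...))
    cls <- classify_regime(run, delta = delta)
    dplyr::mutate(cls[cls$wave == 2L, ], F = f, .before = 1)
  })
  tbl <- dplyr::bind_rows(rows)
  blocked <- tbl$F[tbl$regime %in% "blocked"]
  slowed <- tbl$F[tbl$regime %in% "slowed"]
  ord <- factor(tbl$regime, levels = c("blocked", "slowed", "homogeneous"))
  if (any(diff(as.integer(ord)) < 0)) {
    warning("regime sequence is not monotone in F (possible dt/interval ",
            "sensitivity); inspect the returned table", call. = FALSE)
  }
  structure(tbl, class = c("csd_sweep", class(tbl)),
            largest_blocked = if (length(blocked)) max(blocked) else NA_real_,
            smallest_slowed = if (length(slowed)) min(slowed) else NA_real_)
}

#' @rdname sweep_F
#' @param sweep A `csd_sweep`.
#' @export
sweep_boundaries <- function(sweep) {
  c(largest_blocked = attr(sweep, "largest_blocked"),
    smallest_slowed = attr(sweep, "smallest_slowed"))
}

#' @export
print.csd_sweep <- function(x, ...) {
  b <- sweep_boundaries(x)
  NextMethod()
  cat("largest blocked F: ", b[1], "; smallest slowed F: ", b[2], "\n",
      sep = "")
  invisible(x)
}
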