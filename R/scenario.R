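#' Region specifications and masks
#'
#' Regions of the grid (modulated area, stimulus site, block segment) are
#' described by small geometric specs and realised as logical masks on a
#' given grid.  Row/column indices are 1-based and inclusive; fractional
#' centres are allowed for disks (the default stimulus is centred between
#' cells at the grid centre).
#'
#' @param row_min,row_max,col_min,col_max Rectangle bounds (cells,
#'   inclusive).
#' @param center_row,center_col Disk centre in cell coordinates.
#' @param radius Disk radius in cells; a cell belongs to the disk when its
#'   centre lies within `radius` of the disk centre.
#' @return A region spec (class `csd_region`), or for [region_mask] a
#'   logical matrix with a `label` attribute.
#' @examples
#' r <- region_rect(2, 3, 2, 4)
#' sum(region_mask(r, 5, 5))   # 6 cells
#' @export
region_rect <- function(row_min, row_max, col_min, col_max) {
  stopifnot(row_min <= row_max, col_min <= col_max)
  structure(list(shape = "rect", row_min = row_min, row_max = row_max,
                 col_min = col_min, col_max = col_max),
            class = "csd_region")
}

#' @rdname region_rect
#' @export
region_disk <- function(center_row, center_col, radius) {
  stopifnot(radius > 0)
  structure(list(shape = "disk", center_row = center_row,
                 center_col = center_col, radius = radius),
            class = "csd_region")
}

#' @rdname region_rect
#' @param region A region spec.
#' @param nrow,ncol Grid shape.
#' @param label Label attached to the mask.
#' @export
region_mask <- function(region, nrow, ncol, label = "region") {
  m <- matrix(FALSE, nrow, ncol)
  if (region$shape == "rect") {
    if (region$row_min < 1 || region$row_max > nrow ||
        region$col_min < 1 || region$col_max > ncol) {
      stop("region outside the ", nrow, "x", ncol, " grid", call. = FALSE)
    }
    m[region$row_min:region$row_max, region$col_min:region$col_max] <- TRUE
  } else if (region$shape == "disk") {
    rows <- matrix(seq_len(nrow), nrow, ncol)
    cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
    m <- (rows - region$center_row)^2 + (cols - region$center_col)^2 <=
      region$radius^2
    if (!any(m)) stop("disk region contains no cells", call. = FALSE)
  } else {
    stop("unknown region shape: ", region$shape, call. = FALSE)
  }
  attr(m, "label") <- label
  m
}

#' Stimulus and block events
#'
#' A stimulus clamps potassium inside its region to `amplitude` while
#' active (`t_on <= t < t_on + duration`); the recovery field is untouched.
#' The amplitude must exceed `K_theta`, otherwise no wave can be evoked.  A
#' block freezes both fields inside its region while active
#' (`t_on <= t < t_off`) -- an externally imposed absolute refractory state
#' whose release can seed free wave ends (the spiral protocol).
#'
#' @param t_on Activation time (>= 0).
#' @param duration Stimulus duration (> 0).
#' @param region A region spec; stimuli default to a central disk when the
#'   scenario is assembled by [make_scenario].
#' @param amplitude Potassium level imposed.
#' @param t_off Block release time (> `t_on`).
#' @param mode Block mode.  `"freeze"` (the default) holds the blocked
#'   cells at their current values while leaving them diffusively coupled
#'   to their neighbours; `"insulate"` additionally seals the block's faces
#'   with internal zero-flux walls, so no potassium current crosses into or
#'   out of the blocked tissue -- a fully sealed anodal block.  The spiral
#'   preset uses insulated blocks.
#' @return An event object (`csd_stimulus` / `csd_block`).
#' @examples
#' stimulus_event(0, 10, region_disk(40.5, 40.5, 3))
#' block_event(400, 500, region_rect(20, 22, 1, 60))
#' @export
stimulus_event <- function(t_on, duration, region, amplitude = 1) {
  stopifnot(t_on >= 0, duration > 0)
  structure(list(t_on = t_on, duration = duration, region = region,
                 amplitude = amplitude),
            class = "csd_stimulus")
}

#' @rdname stimulus_event
#' @export
block_event <- function(t_on, t_off, region, mode = c("freeze", "insulate")) {
  if (!(t_on < t_off)) stop("block_event: need t_on < t_off", call. = FALSE)
  mode <- match.arg(mode)
  structure(list(t_on = t_on, t_off = t_off, region = region, mode = mode),
            class = "csd_block")
}

#' Apply a stimulus event to a simulation state
#'
#' If the event is active at time `t` (`t_on <= t < t_on + duration`),
#' potassium inside the event's region is set (clamped, not incremented) to
#' the event's amplitude; the recovery field is untouched.  An inactive
#' event returns the state unchanged.  [csd_simulate] applies the same rule
#' after every Euler step.
#'
#' @param state A [csd_state].
#' @param event A [stimulus_event].
#' @param t Current time.
#' @return The (possibly updated) `csd_state`.
#' @examples
#' p <- csd_params()
#' st <- csd_state(matrix(p$K_rest, 20, 20), matrix(p$R_rest, 20, 20))
#' ev <- stimulus_event(0, 10, region_disk(10.5, 10.5, 3))
#' max(apply_stimulus(st, ev, t = 5)$K)    # 1 inside the disk
#' @export
apply_stimulus <- function(state, event, t) {
  stopifnot(inherits(state, "csd_state"), inherits(event, "csd_stimulus"))
  if (t < event$t_on || t >= event$t_on + event$duration) return(state)
  mask <- region_mask(event$region, nrow(state$K), ncol(state$K))
  state$K[mask] <- event$amplitude
  state
}

#' Assemble and validate a simulation scenario
#'
#' A scenario is one in-silico experiment: model parameters, grid shape,
#' the modulated area, a stimulus/block schedule, probe locations and the
#' total simulated time.  Validation checks that regions and probes lie on
#' the grid, that every stimulus is suprathreshold, and that probes named
#' `"modulated"` and `"control"` sit at equal (integer-rounded) distance
#' from the first stimulus centre, as the two standard probes must.
#'
#' @param params A [csd_params].
#' @param nrow,ncol Grid shape in cells.
#' @param modulated_region Region spec for the modulated area (or `NULL`).
#' @param stimuli List of [stimulus_event]s.
#' @param blocks List of [block_event]s.
#' @param probes Data frame with columns `name`, `row`, `col`.
#' @param t_end Total simulated time.
#' @param kinetics Kinetics form name.
#' @param probe_stride Probe recording stride in steps.
#' @param snapshot_stride Field snapshot stride in steps (0 = none).
#' @param snapshot_R Also keep recovery-field snapshots?
#' @return An object of class `csd_scenario`.
#' @seealso [make_scenario] for the shipped presets.
#' @export
csd_scenario <- function(params = csd_params(), nrow = 80, ncol = 80,
                         modulated_region = NULL, stimuli = list(),
                         blocks = list(), probes = NULL, t_end = 1000,
                         kinetics = "default_cubic", probe_stride = 4L,
                         snapshot_stride = 0L, snapshot_R = FALSE) {
  validate_csd_params(params)
  stopifnot(nrow >= 3, ncol >= 3, t_end > 0)
  kinetics_form(kinetics)  # errors on unknown form
  if (is.null(probes)) {
    probes <- tibble::tibble(name = character(), row = integer(),
                             col = integer())
  }
  probes <- tibble::as_tibble(probes)
  stopifnot(all(c("name", "row", "col") %in% names(probes)))
  if (nrow(probes) > 0 &&
      (any(probes$row < 1 | probes$row > nrow) ||
       any(probes$col < 1 | probes$col > ncol))) {
    stop("csd_scenario: probe coordinates outside the grid", call. = FALSE)
  }
  if (!is.null(modulated_region)) {
    region_mask(modulated_region, nrow, ncol)  # errors if off-grid
  }
  for (st in stimuli) {
    stopifnot(inherits(st, "csd_stimulus"))
    region_mask(st$region, nrow, ncol)
    if (st$amplitude <= params$K_theta) {
      stop("csd_scenario: stimulus amplitude ", st$amplitude,
           " does not exceed K_theta = ", params$K_theta,
           "; no wave can be evoked", call. = FALSE)
    }
  }
  for (b in blocks) {
    stopifnot(inherits(b, "csd_block"))
    region_mask(b$region, nrow, ncol)
  }
  sc <- structure(
    list(params = params, nrow = as.integer(nrow), ncol = as.integer(ncol),
         modulated_region = modulated_region, stimuli = stimuli,
         blocks = blocks, probes = probes, t_end = t_end,
         kinetics = kinetics, probe_stride = as.integer(probe_stride),
         snapshot_stride = as.integer(snapshot_stride),
         snapshot_R = isTRUE(snapshot_R)),
    class = "csd_scenario")
  check_probe_equidistance(sc)
  sc
}

check_probe_equidistance <- function(sc) {
  std <- c("modulated", "control")
  if (!all(std %in% sc$probes$name) || length(sc$stimuli) == 0) {
    return(invisible(TRUE))
  }
  ctr <- stimulus_center(sc$stimuli[[1]]$region)
  d <- vapply(std, function(nm) {
    p <- sc$probes[sc$probes$name == nm, ][1, ]
    round(sqrt((p$row - ctr[1])^2 + (p$col - ctr[2])^2))
  }, numeric(1))
  if (d[1] != d[2]) {
    stop("csd_scenario: standard probes are not equidistant from the ",
         "stimulus site (rounded distances ", d[1], " vs ", d[2], ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

stimulus_center <- function(region) {
  if (region$shape == "disk") {
    c(region$center_row, region$center_col)
  } else {
    c((region$row_min + region$row_max) / 2,
      (region$col_min + region$col_max) / 2)
  }
}

#' @export
print.csd_scenario <- function(x, ...) {
  cat("<csd_scenario> ", x$nrow, "x", x$ncol, " grid, t_end = ", x$t_end,
      ", kinetics = ", x$kinetics, "\n", sep = "")
  cat("  F = ", x$params$F, "; ", length(x$stimuli), " stimulus(es), ",
      length(x$blocks), " block(s), ", nrow(x$probes), " probe(s)\n",
      sep = "")
  invisible(x)
}

# Protocol constants shared by the presets.  The paper's figures fix the
# qualitative layout (central stimulus, rectangular modulated area in the
# upper-right quadrant, two equidistant probes); sizes and times are this
# package's documented reconstruction (see the methods vignette).  All
# cell coordinates are stated for the reference 80x80 grid and scaled
# proportionally for other shapes; the control probe is the point
# reflection of the modulated probe through the grid centre, so the two
# probes are exactly equidistant from the stimulus site on any grid.
preset_constants <- function(nrow = 80, ncol = 80) {
  ctr <- c((nrow + 1) / 2, (ncol + 1) / 2)
  sr <- nrow / 80
  sc <- ncol / 80
  pm <- c(max(1, round(21 * sr)), min(ncol, round(61 * sc)))
  list(
    center = ctr,
    stim_radius = 3,
    stim_duration = 10,
    modulated = region_rect(max(1, round(15 * sr)), round(26 * sr),
                            round(55 * sc), min(ncol, round(66 * sc))),
    probe_modulated = pm,
    probe_control = c(nrow + 1 - pm[1], ncol + 1 - pm[2]),
    interval = 1000,            # inter-stimulus interval (time units)
    interval_third = 1500,      # extra interval before the third wave
    wave_time = 700,            # stimulus-to-classification allowance
    # spiral (re-entry) protocol: a sealed central block turns the cortex
    # into an annular corridor; a transient side gate makes the evoked wave
    # unidirectional, so it circulates and re-excites each site every lap
    spiral_obstacle = region_disk(ctr[1], ctr[2], round(13 * sr)),
    spiral_obstacle_window = c(0, 4000),
    spiral_gate = region_rect(round(48 * sr), nrow, round(30 * sc),
                              round(33 * sc)),
    spiral_gate_window = c(0, 500),
    spiral_stim = c(round(66 * sr), ctr[2]),
    spiral_probes = list(corridor_a = c(max(1, round(21 * sr)),
                                        round(61 * sc)),
                         corridor_b = c(round(60 * sr), round(20 * sc))),
    spiral_t_end = 4500
  )
}

#' Scenario presets for the four in-silico experiments
#'
#' Builds a fully validated [csd_scenario] for one of the shipped presets:
#'
#' * `"homogeneous"`: one central stimulus with `F = 1`; the wave crosses
#'   the whole cortex and both probes record identical traces.
#' * `"bypass"`: two successive stimuli with strongly slowed recovery in the
#'   modulated area (default `F = 0.05`); the second wave never crosses
#'   threshold inside the modulated area.
#' * `"slowdown"`: two stimuli with moderately slowed recovery (default
#'   `F = 0.25`); the second wave enters the modulated area with delayed
#'   onset.
#' * `"three_waves"`: three stimuli (the third after a longer interval);
#'   the waves are homogeneous, blocked and slowed in that order.
#' * `"spiral"`: one stimulus plus a transient block of a long segment of
#'   the wavefront's path; release of the block leaves free wave ends that
#'   curl into re-entrant spiral waves.
#'
#' @param preset Preset name.
#' @param F Recovery-modulation factor; defaults depend on the preset.
#' @param params Base parameters (the preset overrides `F`).
#' @param nrow,ncol Grid shape.
#' @param interval Inter-stimulus interval; default is the preset's.
#' @param t_end Total simulated time; default is the preset's.
#' @param probe_stride,snapshot_stride,snapshot_R Recording settings.
#' @return A `csd_scenario`.
#' @examples
#' sc <- make_scenario("homogeneous")
#' length(sc$stimuli)
#' make_scenario("bypass", F = 0.05)$params$F
#' @export
make_scenario <- function(preset = c("homogeneous", "bypass", "slowdown",
                                     "three_waves", "spiral"),
                          F = NULL, params = csd_params(), nrow = 80,
                          ncol = 80, interval = NULL, t_end = NULL,
                          probe_stride = 4L, snapshot_stride = 0L,
                          snapshot_R = FALSE) {
  preset <- match.arg(preset)
  k <- preset_constants(nrow, ncol)
  defF <- switch(preset, homogeneous = 1, bypass = 0.05, slowdown = 0.25,
                 three_waves = 0.05, spiral = 1)
  p <- params
  p$F <- if (is.null(F)) defF else F
  p <- do.call(csd_params, unclass(p))
  if (is.null(interval)) interval <- k$interval
  stim_region <- if (preset == "spiral") {
    region_disk(k$spiral_stim[1], k$spiral_stim[2], k$stim_radius)
  } else {
    region_disk(k$center[1], k$center[2], k$stim_radius)
  }
  stim_at <- function(t0) {
    stimulus_event(t0, k$stim_duration, stim_region, amplitude = p$K_max)
  }
  stim_times <- switch(preset,
    homogeneous = 0,
    bypass = c(0, interval),
    slowdown = c(0, interval),
    three_waves = c(0, interval, interval + k$interval_third),
    spiral = 0)
  if (is.null(t_end)) {
    t_end <- max(stim_times) + k$wave_time
    if (preset == "homogeneous") t_end <- k$wave_time + 700  # full recovery
    if (preset == "spiral") t_end <- k$spiral_t_end
  }
  blocks <- list()
  if (preset == "spiral") {
    blocks <- list(
      block_event(k$spiral_obstacle_window[1],
                  min(k$spiral_obstacle_window[2], t_end),
                  k$spiral_obstacle, mode = "insulate"),
      block_event(k$spiral_gate_window[1], k$spiral_gate_window[2],
                  k$spiral_gate, mode = "insulate"))
  }
  probes <- if (preset == "spiral") {
    tibble::tibble(
      name = names(k$spiral_probes),
      row = unname(vapply(k$spiral_probes, `[`, numeric(1), 1)),
      col = unname(vapply(k$spiral_probes, `[`, numeric(1), 2)))
  } else {
    tibble::tibble(
      name = c("modulated", "control"),
      row = c(k$probe_modulated[1], k$probe_control[1]),
      col = c(k$probe_modulated[2], k$probe_control[2]))
  }
  csd_scenario(params = p, nrow = nrow, ncol = ncol,
               modulated_region = if (preset == "spiral") NULL else k$modulated,
               stimuli = lapply(stim_times, stim_at), blocks = blocks,
               probes = probes, t_end = t_end,
               probe_stride = probe_stride,
               snapshot_stride = snapshot_stride, snapshot_R = snapshot_R)
}

#' @rdname make_scenario
#' @export
scenario_presets <- function() {
  c("homogeneous", "bypass", "slowdown", "three_waves", "spiral")
}
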