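#' Run a CSD scenario
#'
#' Integrates the coupled potassium/recovery fields over the scenario's
#' schedule with the explicit forward-Euler scheme and records probe traces
#' (and optionally field snapshots).  The model is fully deterministic:
#' identical scenarios produce bit-identical results.
#'
#' Shipped kinetics forms run in compiled code; user-registered forms fall
#' back to the plain-R reference stepper [csd_step] (identical scheme,
#' considerably slower).
#'
#' @param scenario A [csd_scenario].
#' @param engine `"auto"` (compiled when the kinetics form is shipped),
#'   `"compiled"`, or `"reference"`.
#' @return An object of class `csd_run` with components
#'   `probes` (tibble: `time`, `probe`, `K`, `R`), `snapshots` (list with
#'   `times`, `K` and optionally `R` arrays; `NULL` unless requested),
#'   `K`, `R` (final fields), and the echoed `scenario`.
#' @examples
#' sc <- make_scenario("homogeneous", t_end = 50)
#' run <- csd_simulate(sc)
#' head(tidy(run))
#' @export
csd_simulate <- function(scenario, engine = c("auto", "compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(scenario, "csd_scenario"))
  sc <- scenario
  p <- sc$params
  n_steps <- as.integer(round(sc$t_end / p$dt))
  compiled_ok <- sc$kinetics %in% builtin_forms
  if (engine == "compiled" && !compiled_ok) {
    stop("kinetics form \"", sc$kinetics, "\" has no compiled implementation;",
         " use engine = \"reference\"", call. = FALSE)
  }
  use_compiled <- engine == "compiled" || (engine == "auto" && compiled_ok)

  modulated <- if (is.null(sc$modulated_region)) {
    matrix(FALSE, sc$nrow, sc$ncol)
  } else {
    region_mask(sc$modulated_region, sc$nrow, sc$ncol, label = "modulated")
  }
  ev_list <- function(events, with_amp) {
    lapply(events, function(e) {
      mask <- region_mask(e$region, sc$nrow, sc$ncol)
      out <- list(idx = which(mask) - 1L, t_on = e$t_on,
                  t_off = if (with_amp) e$t_on + e$duration else e$t_off)
      if (with_amp) {
        out$amplitude <- e$amplitude
      } else {
        out$insulate <- as.integer(identical(e$mode, "insulate"))
      }
      out
    })
  }
  stimuli <- ev_list(sc$stimuli, TRUE)
  blocks <- ev_list(sc$blocks, FALSE)
  K0 <- matrix(p$K_rest, sc$nrow, sc$ncol)
  R0 <- matrix(p$R_rest, sc$nrow, sc$ncol)
  probes <- cbind(sc$probes$row - 1L, sc$probes$col - 1L)
  storage.mode(probes) <- "integer"

  if (use_compiled) {
    res <- .sim_core(K0, R0, unclass(p),
                     form = match(sc$kinetics, builtin_forms) - 1L,
                     modulated = modulated, stimuli = stimuli,
                     blocks = blocks, probes = probes, n_steps = n_steps,
                     probe_stride = sc$probe_stride,
                     snap_stride = sc$snapshot_stride,
                     snap_R = sc$snapshot_R)
  } else {
    res <- sim_reference(K0, R0, p, sc, modulated, stimuli, blocks, probes,
                         n_steps)
  }

  probe_tbl <- tibble::tibble(
    time = rep(res$times, times = nrow(sc$probes)),
    probe = rep(sc$probes$name, each = length(res$times)),
    K = as.vector(res$probe_K),
    R = as.vector(res$probe_R))
  snapshots <- NULL
  if (sc$snapshot_stride > 0) {
    snapshots <- list(times = res$snap_times, K = res$snap_K)
    if (sc$snapshot_R) snapshots$R <- res$snap_R
  }
  structure(list(probes = probe_tbl, snapshots = snapshots,
                 K = res$K, R = res$R, step_index = res$step_index,
                 scenario = sc),
            class = "csd_run")
}

# Plain-R engine: same stepping, clamping and recording semantics as the
# compiled core (integer step windows for events).
sim_reference <- function(K0, R0, p, sc, modulated, stimuli, blocks, probes,
                          n_steps) {
  step_of <- function(t) as.integer(ceiling(t / p$dt - 1e-9))
  for (i in seq_along(stimuli)) {
    stimuli[[i]]$s_on <- step_of(stimuli[[i]]$t_on)
    stimuli[[i]]$s_off <- step_of(stimuli[[i]]$t_off)
  }
  for (i in seq_along(blocks)) {
    blocks[[i]]$s_on <- step_of(blocks[[i]]$t_on)
    blocks[[i]]$s_off <- step_of(blocks[[i]]$t_off)
  }
  np <- nrow(probes)
  pidx <- probes[, 1] + 1L + probes[, 2] * nrow(K0)
  n_rec <- 1L + if (sc$probe_stride > 0) n_steps %/% sc$probe_stride else 0L
  times <- numeric(n_rec)
  probe_K <- matrix(NA_real_, n_rec, np)
  probe_R <- matrix(NA_real_, n_rec, np)
  n_snap <- if (sc$snapshot_stride > 0) 1L + n_steps %/% sc$snapshot_stride else 0L
  snap_times <- numeric(n_snap)
  snap_K <- if (n_snap > 0) array(NA_real_, c(nrow(K0), ncol(K0), n_snap))
  snap_R <- if (n_snap > 0 && sc$snapshot_R) {
    array(NA_real_, c(nrow(K0), ncol(K0), n_snap))
  }
  state <- csd_state(K0, R0)
  times[1] <- 0
  probe_K[1, ] <- state$K[pidx]
  probe_R[1, ] <- state$R[pidx]
  irec <- 1L
  isnap <- 0L
  if (n_snap > 0) {
    snap_times[1] <- 0
    snap_K[, , 1] <- state$K
    if (sc$snapshot_R) snap_R[, , 1] <- state$R
    isnap <- 1L
  }
  for (s in seq_len(n_steps)) {
    block_mask <- NULL
    ins_mask <- NULL
    for (b in blocks) {
      if (s >= b$s_on && s < b$s_off) {
        if (b$insulate) {
          if (is.null(ins_mask)) ins_mask <- matrix(FALSE, nrow(K0), ncol(K0))
          ins_mask[b$idx + 1L] <- TRUE
        } else {
          if (is.null(block_mask)) {
            block_mask <- matrix(FALSE, nrow(K0), ncol(K0))
          }
          block_mask[b$idx + 1L] <- TRUE
        }
      }
    }
    state <- csd_step(state, p, modulated = modulated, block = block_mask,
                      insulated = ins_mask, form = sc$kinetics)
    for (e in stimuli) {
      if (s >= e$s_on && s < e$s_off) state$K[e$idx + 1L] <- e$amplitude
    }
    if (sc$probe_stride > 0 && s %% sc$probe_stride == 0L) {
      irec <- irec + 1L
      times[irec] <- s * p$dt
      probe_K[irec, ] <- state$K[pidx]
      probe_R[irec, ] <- state$R[pidx]
    }
    if (n_snap > 0 && s %% sc$snapshot_stride == 0L) {
      isnap <- isnap + 1L
      snap_times[isnap] <- s * p$dt
      snap_K[, , isnap] <- state$K
      if (sc$snapshot_R) snap_R[, , isnap] <- state$R
    }
  }
  list(times = times, probe_K = probe_K, probe_R = probe_R,
       snap_times = snap_times, snap_K = snap_K, snap_R = snap_R,
       K = state$K, R = state$R, step_index = n_steps)
}

#' Extract one probe's trace
#'
#' @param run A `csd_run`.
#' @param name Probe name.
#' @return A tibble with columns `time`, `K`, `R`; the probe's name and
#'   grid location are attached as attributes.
#' @examples
#' run <- csd_simulate(make_scenario("homogeneous", t_end = 50))
#' probe_trace(run, "control")
#' @export
probe_trace <- function(run, name) {
  stopifnot(inherits(run, "csd_run"))
  if (!name %in% run$probes$probe) {
    stop("no probe named \"", name, "\"", call. = FALSE)
  }
  tr <- run$probes[run$probes$probe == name, c("time", "K", "R")]
  loc <- run$scenario$probes[run$scenario$probes$name == name, ][1, ]
  attr(tr, "probe") <- name
  attr(tr, "location") <- c(row = loc$row, col = loc$col)
  tr
}

#' @export
print.csd_run <- function(x, ...) {
  sc <- x$scenario
  cat("<csd_run> ", sc$nrow, "x", sc$ncol, " grid, ", x$step_index,
      " steps to t = ", sc$t_end, "\n", sep = "")
  cat("  probes: ", paste(unique(x$probes$probe), collapse = ", "),
      if (!is.null(x$snapshots)) {
        paste0("; ", length(x$snapshots$times), " snapshots")
      } else "", "\n", sep = "")
  invisible(x)
}

#' Tidy and summary methods for simulation runs
#'
#' `tidy()` returns the probe traces in long form (`time`, `probe`, `K`,
#' `R`).  `glance()` returns a one-row summary: number of steps, probes,
#' wave events per probe, and the final fields' maximal deviation from
#' rest.
#'
#' @param x A `csd_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.csd_run <- function(x, ...) x$probes

#' @rdname tidy.csd_run
#' @export
glance.csd_run <- function(x, ...) {
  p <- x$scenario$params
  ev <- detect_wave_events(x)
  tibble::tibble(
    n_steps = x$step_index,
    t_end = x$scenario$t_end,
    n_probes = nrow(x$scenario$probes),
    n_stimuli = length(x$scenario$stimuli),
    total_wave_events = nrow(ev),
    max_K_deviation = max(abs(x$K - p$K_rest)),
    max_R_deviation = max(abs(x$R - p$R_rest)))
}
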