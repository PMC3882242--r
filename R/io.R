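#' Serialize scenarios to and from configuration files
#'
#' A scenario round-trips losslessly through a plain configuration list
#' (JSON or YAML): `read_scenario(write_scenario(sc, path))` reproduces the
#' scenario, and rerunning it reproduces every output bit-identically --
#' the pipeline contains no randomness.
#'
#' @param scenario A [csd_scenario].
#' @param path Output file; format chosen by extension (`.json` or
#'   `.yaml`/`.yml`).
#' @return `write_scenario` returns `path` invisibly; `read_scenario` and
#'   `config_to_scenario` return a validated `csd_scenario`;
#'   `scenario_to_config` returns a plain list.
#' @examples
#' sc <- make_scenario("homogeneous", t_end = 50)
#' cfg <- scenario_to_config(sc)
#' identical(config_to_scenario(cfg), sc)
#' @export
scenario_to_config <- function(scenario) {
  stopifnot(inherits(scenario, "csd_scenario"))
  sc <- scenario
  reg <- function(r) if (is.null(r)) NULL else unclass(r)
  list(
    params = unclass(sc$params),
    grid = list(nrow = sc$nrow, ncol = sc$ncol),
    kinetics = sc$kinetics,
    modulated_region = reg(sc$modulated_region),
    stimuli = lapply(sc$stimuli, function(e) {
      list(t_on = e$t_on, duration = e$duration, amplitude = e$amplitude,
           region = reg(e$region))
    }),
    blocks = lapply(sc$blocks, function(e) {
      list(t_on = e$t_on, t_off = e$t_off, mode = e$mode %||% "freeze",
           region = reg(e$region))
    }),
    probes = lapply(seq_len(nrow(sc$probes)), function(i) {
      as.list(sc$probes[i, ])
    }),
    t_end = sc$t_end,
    probe_stride = sc$probe_stride,
    snapshot_stride = sc$snapshot_stride,
    snapshot_R = sc$snapshot_R)
}

#' @rdname scenario_to_config
#' @param config A configuration list as produced by [scenario_to_config]
#'   (or read from file).
#' @export
config_to_scenario <- function(config) {
  cfg <- config
  need <- c("params", "grid", "t_end")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("configuration is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- as.numeric  # JSON readers return integers for whole numbers
  region <- function(r) {
    if (is.null(r)) return(NULL)
    if (identical(r$shape, "rect")) {
      region_rect(num(r$row_min), num(r$row_max), num(r$col_min),
                  num(r$col_max))
    } else if (identical(r$shape, "disk")) {
      region_disk(num(r$center_row), num(r$center_col), num(r$radius))
    } else {
      stop("configuration: unknown region shape \"", r$shape, "\"",
           call. = FALSE)
    }
  }
  params <- do.call(csd_params, lapply(cfg$params, num))
  probes <- if (length(cfg$probes)) {
    dplyr::bind_rows(lapply(cfg$probes, function(p) {
      tibble::tibble(name = p$name, row = num(p$row), col = num(p$col))
    }))
  } else {
    NULL
  }
  csd_scenario(
    params = params, nrow = cfg$grid$nrow, ncol = cfg$grid$ncol,
    modulated_region = region(cfg$modulated_region),
    stimuli = lapply(cfg$stimuli, function(e) {
      stimulus_event(num(e$t_on), num(e$duration), region(e$region),
                     num(e$amplitude))
    }),
    blocks = lapply(cfg$blocks, function(e) {
      block_event(num(e$t_on), num(e$t_off), region(e$region),
                  mode = e$mode %||% "freeze")
    }),
    probes = probes, t_end = num(cfg$t_end),
    kinetics = cfg$kinetics %||% "default_cubic",
    probe_stride = cfg$probe_stride %||% 4L,
    snapshot_stride = cfg$snapshot_stride %||% 0L,
    snapshot_R = cfg$snapshot_R %||% FALSE)
}

#' @rdname scenario_to_config
#' @export
write_scenario <- function(scenario, path) {
  cfg <- scenario_to_config(scenario)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cfg, path, precision = 15L)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname scenario_to_config
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  config_to_scenario(cfg)
}

#' Export probe traces and field snapshots
#'
#' `export_probes()` writes the tidy probe table (`time`, `probe`, `K`,
#' `R`) as CSV.  `export_snapshots()` writes the recorded potassium
#' snapshots either as one CSV matrix per snapshot or as a single
#' multi-page 16-bit TIFF stack (potassium scaled linearly from
#' `[0, K_max]`), plus a JSON sidecar with the snapshot times, step
#' indices, scaling and parameters.
#'
#' @param run A `csd_run`.
#' @param path Output CSV file (probes) .
#' @param dir Output directory (snapshots).
#' @param format `"csv"` or `"tiff"`.
#' @param prefix Filename prefix for snapshot files.
#' @return The written path(s), invisibly.
#' @export
export_probes <- function(run, path) {
  stopifnot(inherits(run, "csd_run"))
  utils::write.csv(run$probes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_probes
#' @export
export_snapshots <- function(run, dir, format = c("csv", "tiff"),
                             prefix = "snapshot") {
  format <- match.arg(format)
  stopifnot(inherits(run, "csd_run"))
  if (is.null(run$snapshots)) {
    stop("run has no snapshots; set snapshot_stride > 0 in the scenario",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sn <- run$snapshots
  p <- run$scenario$params
  n <- length(sn$times)
  files <- character(0)
  if (format == "csv") {
    files <- vapply(seq_len(n), function(i) {
      f <- file.path(dir, sprintf("%s_%05d.csv", prefix, i))
      utils::write.table(sn$K[, , i], f, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      f
    }, character(1))
  } else {
    f <- file.path(dir, paste0(prefix, "_K.tif"))
    pages <- lapply(seq_len(n), function(i) {
      pmin(pmax(sn$K[, , i] / p$K_max, 0), 1)
    })
    tiff::writeTIFF(pages, f, bits.per.sample = 16L)
    files <- f
  }
  sidecar <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(
    list(times = sn$times,
         step_index = as.integer(round(sn$times / p$dt)),
         scaling = list(K_range = c(0, p$K_max),
                        tiff_bits = if (format == "tiff") 16L else NULL),
         params = unclass(p)),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, sidecar))
}
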