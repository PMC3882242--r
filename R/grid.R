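#' Five-point Laplacian with zero-flux boundaries
#'
#' Discrete Laplacian of a 2D field using the 5-point stencil and mirror
#' ghost cells (ghost value equals the adjacent boundary value), divided by
#' `dx^2`.  Mirror ghosts implement the zero-flux (Neumann) boundary: no
#' potassium leaves the grid, so the stencil conserves mass exactly --
#' `sum(laplacian_zero_flux(x)) == 0` to rounding for any field.
#'
#' @param field Numeric matrix of finite values.
#' @param dx Grid spacing.
#' @return A matrix of the same shape.
#' @examples
#' laplacian_zero_flux(matrix(1, 4, 5))        # all zero
#' m <- matrix(0, 3, 3); m[2, 2] <- 1
#' laplacian_zero_flux(m)                      # -4 centre, +1 neighbours
#' @export
laplacian_zero_flux <- function(field, dx = 1) {
  stopifnot(is.matrix(field), dx > 0)
  if (!all(is.finite(field))) {
    stop("laplacian_zero_flux: non-finite values in field", call. = FALSE)
  }
  nr <- nrow(field)
  nc <- ncol(field)
  up    <- field[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- field[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  left  <- field[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- field[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  (up + down + left + right - 4 * field) / dx^2
}

# 5-point Laplacian where cells in `walls` are sealed: any stencil arm that
# would reach a wall cell is mirrored (as at the outer boundary), and wall
# cells themselves exchange nothing.
laplacian_with_walls <- function(field, dx, walls) {
  nr <- nrow(field)
  nc <- ncol(field)
  pick <- function(shifted, wall_shifted) {
    ifelse(wall_shifted, field, shifted)
  }
  iu <- c(1L, seq_len(nr - 1L))
  id <- c(seq_len(nr)[-1L], nr)
  jl <- c(1L, seq_len(nc - 1L))
  jr <- c(seq_len(nc)[-1L], nc)
  up    <- pick(field[iu, , drop = FALSE], walls[iu, , drop = FALSE])
  down  <- pick(field[id, , drop = FALSE], walls[id, , drop = FALSE])
  left  <- pick(field[, jl, drop = FALSE], walls[, jl, drop = FALSE])
  right <- pick(field[, jr, drop = FALSE], walls[, jr, drop = FALSE])
  out <- (up + down + left + right - 4 * field) / dx^2
  out[walls] <- 0
  out
}

#' Simulation state
#'
#' A minimal container for the coupled fields: potassium `K`, recovery `R`,
#' the current time `t` and the Euler `step_index` (`t = step_index * dt`).
#'
#' @param K,R Numeric matrices of equal shape.
#' @param t Current time.
#' @param step_index Integer step counter.
#' @return An object of class `csd_state`.
#' @examples
#' p <- csd_params()
#' st <- csd_state(matrix(p$K_rest, 8, 8), matrix(p$R_rest, 8, 8))
#' @export
csd_state <- function(K, R, t = 0, step_index = 0L) {
  stopifnot(is.matrix(K), is.matrix(R), all(dim(K) == dim(R)))
  structure(list(K = K, R = R, t = t, step_index = as.integer(step_index)),
            class = "csd_state")
}

#' One forward-Euler step of the coupled fields (reference stepper)
#'
#' Advances the state by one time step `dt`:
#' `K <- K + dt * (D * laplacian(K) + f(K, R))` and
#' `R <- R + dt * modulated_recovery_rate(K, R)`, with cells inside an
#' active block mask held frozen at their current values (the
#' absolute-refractory clamp used by the spiral protocol).  This is the
#' plain-R reference implementation; [csd_simulate] drives the identical
#' scheme in compiled code for shipped kinetics forms and falls back to this
#' stepper for user-registered forms.
#'
#' @param state A [csd_state].
#' @param params A [csd_params].
#' @param modulated Logical matrix marking the modulated area (or `NULL`).
#' @param block Logical matrix of frozen cells (or `NULL` for none).
#' @param insulated Logical matrix of frozen cells that are additionally
#'   sealed by internal zero-flux walls (see [block_event]'s
#'   `mode = "insulate"`), or `NULL`.
#' @param form Kinetics form name.
#' @return The advanced `csd_state`.
#' @examples
#' p <- csd_params()
#' st <- csd_state(matrix(p$K_rest, 8, 8), matrix(p$R_rest, 8, 8))
#' st2 <- csd_step(st, p)      # resting state is a fixed point
#' identical(st2$K, st$K)
#' @export
csd_step <- function(state, params, modulated = NULL, block = NULL,
                     insulated = NULL, form = "default_cubic") {
  K <- state$K
  R <- state$R
  if (is.null(modulated)) modulated <- matrix(FALSE, nrow(K), ncol(K))
  lap <- if (!is.null(insulated) && any(insulated)) {
    laplacian_with_walls(K, params$dx, insulated)
  } else {
    laplacian_zero_flux(K, params$dx)
  }
  Kn <- K + params$dt * (params$D * lap + reaction_rate(K, R, params, form))
  Rn <- R + params$dt *
    modulated_recovery_rate(K, R, params, in_modulated_area = modulated,
                            form = form)
  frozen <- block
  if (!is.null(insulated)) {
    frozen <- if (is.null(frozen)) insulated else (frozen | insulated)
  }
  if (!is.null(frozen) && any(frozen)) {
    Kn[frozen] <- K[frozen]
    Rn[frozen] <- R[frozen]
  }
  if (!all(is.finite(Kn)) || !all(is.finite(Rn))) {
    stop("numerical blow-up at step ", state$step_index + 1L,
         " (t = ", state$t + params$dt, "); check dt against ",
         "check_stability() and the reaction stiffness", call. = FALSE)
  }
  csd_state(Kn, Rn, t = state$t + params$dt,
            step_index = state$step_index + 1L)
}
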