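#' Model parameters for the CSD reaction-diffusion model
#'
#' Bundles every scalar constant of the two-variable CSD model together with
#' the numerical settings of the explicit scheme.  All quantities are
#' dimensionless; potassium levels are expressed on a relative scale where
#' `K_max = 1` is the ceiling reached during a CSD wave.
#'
#' The local kinetics are
#' \deqn{\partial K/\partial t = D \Delta K + f(K, R)}
#' \deqn{dR/dt = E (K - K_{rest}) - C (R - R_{rest})}
#' with the bistable reaction term (form `"default_cubic"`)
#' \deqn{f = (K - K_{rest})\,[A (K - K_\theta)(K - K_{max}) - B (R - R_{rest})].}
#' `E` couples potassium elevation into growth of the recovery variable and
#' `C` sets its relaxation back to `R_rest`; both are printed rate constants
#' of the model (0.03 and 0.018).  Inside the modulated area, `dR/dt` is
#' multiplied by `F` whenever it is negative, so recovery is slowed but its
#' fastest (growth) rate is unchanged.
#'
#' @param A Reaction coefficient of the bistable cubic (negative so that the
#'   cubic is positive between `K_theta` and `K_max`).
#' @param B Coupling strength of the recovery variable into the potassium
#'   reaction term.
#' @param C Relaxation rate of the recovery variable (1/time).
#' @param D Diffusion constant of extracellular potassium
#'   (length units squared per time).
#' @param E Growth rate coupling potassium elevation into the recovery
#'   variable (1/time).
#' @param F Recovery-modulation factor in `(0, 1]`; applied inside the
#'   modulated area only while `dR/dt < 0`.  `F = 1` reproduces the control
#'   dynamics exactly.
#' @param K_rest Resting extracellular potassium level.
#' @param K_theta Threshold potassium level beyond which CSD is evoked.
#' @param K_max Maximal potassium level during CSD.
#' @param R_rest Resting value of the recovery variable.
#' @param dt Time step of the explicit Euler scheme.
#' @param dx Grid spacing (length units per grid cell).
#'
#' @return An object of class `csd_params`: a named list of validated scalars.
#' @examples
#' p <- csd_params()
#' p$K_theta
#' csd_params(F = 0.05)$F
#' @export
csd_params <- function(A = -0.54, B = 0.12, C = 0.018, D = 0.005, E = 0.03,
                       F = 1, K_rest = 0.03, K_theta = 0.2, K_max = 1,
                       R_rest = 0.5, dt = 0.05, dx = 0.25) {
  p <- list(A = A, B = B, C = C, D = D, E = E, F = F,
            K_rest = K_rest, K_theta = K_theta, K_max = K_max,
            R_rest = R_rest, dt = dt, dx = dx)
  validate_csd_params(p)
  structure(p, class = "csd_params")
}

validate_csd_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("A", "B", "C", "D", "E", "F", "K_rest", "K_theta", "K_max",
               "R_rest", "dt", "dx")) {
    if (!num1(p[[nm]])) {
      stop("csd_params: `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (p$F <= 0 || p$F > 1) {
    stop("csd_params: `F` must lie in (0, 1]; got ", p$F, call. = FALSE)
  }
  if (!(p$K_rest < p$K_theta && p$K_theta < p$K_max)) {
    stop("csd_params: need K_rest < K_theta < K_max", call. = FALSE)
  }
  if (p$D <= 0) stop("csd_params: `D` must be positive", call. = FALSE)
  if (p$dt <= 0) stop("csd_params: `dt` must be positive", call. = FALSE)
  if (p$dx <= 0) stop("csd_params: `dx` must be positive", call. = FALSE)
  if (p$C < 0 || p$E < 0) {
    stop("csd_params: recovery rates `C` and `E` must be non-negative",
         call. = FALSE)
  }
  st <- check_stability(p)
  if (!st$pass) {
    stop("csd_params: explicit scheme unstable: dt = ", p$dt,
         " exceeds the diffusion bound dx^2/(4 D) = ", st$bound, call. = FALSE)
  }
  invisible(p)
}

#' Explicit-scheme stability guard
#'
#' The forward-Euler/5-point scheme for the diffusion part is stable only
#' when `dt <= dx^2 / (4 D)`.  The reaction term usually demands a much
#' smaller `dt` for accuracy; this guard catches outright instability.
#'
#' @param params A [csd_params] object (or plain named list with `D`, `dt`,
#'   `dx`).
#' @return A list with elements `pass` (logical), `bound` (the maximal
#'   stable `dt`), and `margin` (`bound - dt`; zero margin is still a pass).
#' @examples
#' check_stability(csd_params())           # pass
#' check_stability(csd_params(dx = 1))$bound
#' @export
check_stability <- function(params) {
  bound <- params$dx^2 / (4 * params$D)
  list(pass = params$dt <= bound, bound = bound, margin = bound - params$dt)
}

#' @export
print.csd_params <- function(x, ...) {
  cat("<csd_params>\n")
  cat(sprintf("  kinetics: A=%g B=%g C=%g E=%g  (F=%g)\n", x$A, x$B, x$C, x$E, x$F))
  cat(sprintf("  levels:   K_rest=%g K_theta=%g K_max=%g R_rest=%g\n",
              x$K_rest, x$K_theta, x$K_max, x$R_rest))
  st <- check_stability(x)
  cat(sprintf("  numerics: D=%g dt=%g dx=%g (diffusion bound dt <= %g)\n",
              x$D, x$dt, x$dx, st$bound))
  invisible(x)
}
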