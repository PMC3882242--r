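#' Pointwise CSD kinetics
#'
#' The local (space-free) dynamics of the model: the potassium reaction term
#' `f(K, R)` and the recovery-variable rate `dR/dt`.  Both accept vectors or
#' matrices and recycle `params` scalars, so they can be applied to whole
#' fields.
#'
#' `reaction_rate()` evaluates the bistable reaction term of the selected
#' kinetics form.  For the shipped `"default_cubic"` form,
#' `f = (K - K_rest) * (A * (K - K_theta) * (K - K_max) - B * (R - R_rest))`:
#' a cubic with stable rest and excited states separated by the threshold
#' `K_theta`, and a recovery coupling that vanishes at `K_rest` so the
#' resting state is a fixed point for any `R`.
#'
#' `recovery_rate()` evaluates `dR/dt = E * (K - K_rest) - C * (R - R_rest)`:
#' the recovery variable grows while potassium is elevated and relaxes back
#' to `R_rest` afterwards.
#'
#' @param K Potassium level(s); finite numeric.
#' @param R Recovery level(s); finite numeric.
#' @param params A [csd_params] object.
#' @param form Name of a registered kinetics form (see [kinetics_form]).
#' @return Numeric rate(s), same shape as the broadcast of `K` and `R`.
#' @examples
#' p <- csd_params()
#' reaction_rate(p$K_rest, p$R_rest, p)   # 0: resting fixed point
#' reaction_rate(0.5, 0.5, p) > 0         # suprathreshold -> excitation
#' recovery_rate(1, 0.5, p)               # K high -> R grows
#' @export
reaction_rate <- function(K, R, params, form = "default_cubic") {
  check_finite_KR(K, R)
  kinetics_form(form)$reaction(K, R, params)
}

#' @rdname reaction_rate
#' @export
recovery_rate <- function(K, R, params, form = "default_cubic") {
  check_finite_KR(K, R)
  kinetics_form(form)$recovery(K, R, params)
}

#' Regionally modulated recovery rate
#'
#' Inside the modulated area the recovery rate is multiplied by the factor
#' `F` in `(0, 1]` whenever `dR/dt < 0`.  Positive (growth) rates are never
#' modulated, so the fastest recovery rate equals the control area's;
#' outside the modulated area the rate is returned bit-identically.
#'
#' @inheritParams reaction_rate
#' @param in_modulated_area Logical (scalar or same shape as `K`): is the
#'   point inside the modulated area?
#' @return Numeric rate(s) of `R` change.
#' @examples
#' p <- csd_params(F = 0.1)
#' modulated_recovery_rate(0.03, 0.8, p, in_modulated_area = TRUE)
#' modulated_recovery_rate(0.03, 0.8, p, in_modulated_area = FALSE)
#' @export
modulated_recovery_rate <- function(K, R, params, in_modulated_area,
                                    form = "default_cubic") {
  rate <- recovery_rate(K, R, params, form = form)
  if (params$F <= 0 || params$F > 1) {
    stop("modulated_recovery_rate: `F` must lie in (0, 1]", call. = FALSE)
  }
  slow <- in_modulated_area & (rate < 0)
  rate[slow] <- params$F * rate[slow]
  rate
}

check_finite_KR <- function(K, R) {
  if (!all(is.finite(K)) || !all(is.finite(R))) {
    stop("kinetics: non-finite K or R", call. = FALSE)
  }
  invisible(TRUE)
}

# --- kinetics form registry ------------------------------------------------

the <- new.env(parent = emptyenv())
the$kinetics <- list()

#' Pluggable kinetics forms
#'
#' The algebra of the reaction and recovery terms is pluggable: a kinetics
#' form is a pair of functions `reaction(K, R, params)` and
#' `recovery(K, R, params)` registered under a name.  Registered forms must
#' satisfy the structural contracts of the model: `(K_rest, R_rest)` is a
#' fixed point of both rates; with `R` frozen at `R_rest` the reaction term
#' is negative on `(K_rest, K_theta)` and positive on `(K_theta, K_max)`
#' (bistable excitation); and the recovery rate is increasing in `K` and
#' decreasing in `R`.
#'
#' Two forms ship with the package.  `"default_cubic"` couples recovery into
#' the reaction term through a factor `(K - K_rest)`, so the resting state
#' is a fixed point for any recovery level and potassium never undershoots
#' its baseline.  `"additive_cubic"` uses the additive FitzHugh-Nagumo-style
#' coupling `- B (R - R_rest)` instead.  Simulations driven by a shipped
#' form run in compiled code; user-registered forms run through the
#' reference R stepper.
#'
#' @param name Name of the form.
#' @param reaction,recovery Vectorized functions `(K, R, params) -> rate`.
#' @return `kinetics_form()` returns the registered form (a list with
#'   `name`, `reaction`, `recovery`); `register_kinetics_form()` returns it
#'   invisibly; `kinetics_forms()` returns the registered names.
#' @examples
#' names(kinetics_form("default_cubic"))
#' kinetics_forms()
#' @export
kinetics_form <- function(name) {
  f <- the$kinetics[[name]]
  if (is.null(f)) {
    stop("unknown kinetics form \"", name, "\"; registered: ",
         paste(kinetics_forms(), collapse = ", "), call. = FALSE)
  }
  f
}

#' @rdname kinetics_form
#' @export
register_kinetics_form <- function(name, reaction, recovery) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(reaction), is.function(recovery))
  the$kinetics[[name]] <- list(name = name, reaction = reaction,
                               recovery = recovery)
  invisible(the$kinetics[[name]])
}

#' @rdname kinetics_form
#' @export
kinetics_forms <- function() names(the$kinetics)

builtin_forms <- c("default_cubic", "additive_cubic")

register_builtin_forms <- function() {
  register_kinetics_form(
    "default_cubic",
    reaction = function(K, R, params) {
      (K - params$K_rest) *
        (params$A * (K - params$K_theta) * (K - params$K_max) -
           params$B * (R - params$R_rest))
    },
    recovery = function(K, R, params) {
      params$E * (K - params$K_rest) - params$C * (R - params$R_rest)
    }
  )
  register_kinetics_form(
    "additive_cubic",
    reaction = function(K, R, params) {
      params$A * (K - params$K_rest) * (K - params$K_theta) * (K - params$K_max) -
        params$B * (R - params$R_rest)
    },
    recovery = function(K, R, params) {
      params$E * (K - params$K_rest) - params$C * (R - params$R_rest)
    }
  )
}
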