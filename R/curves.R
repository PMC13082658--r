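#' Hill-curve evaluators
#'
#' Smoothed Hill-type muscle curves: active force-length, parallel passive
#' force-length, and force-velocity. All three are dimensionless
#' (normalised to `Fmax`), smooth everywhere (former cusps are blended with
#' a tanh/softplus construction of gain `s_smooth`), and vectorised over
#' their first argument.
#'
#' Conventions: length is expressed per resting length `l0`; strain rate is
#' expressed per `vmax` with *positive = lengthening*, so the eccentric
#' branch is the positive half-axis and active force vanishes at
#' `v_norm = -1` (shortening at the maximum strain rate).
#'
#' @param l_norm Muscle length per `l0` (> 0).
#' @param v_norm Strain rate per `vmax` (positive = lengthening).
#' @param p A [muscle_params()] object.
#' @return A numeric vector of normalised forces.
#' @name hill_curves
NULL

#' @rdname hill_curves
#' @export
#' @examples
#' active_force_length(c(0.9, 1, 1.1))
active_force_length <- function(l_norm, p = muscle_params()) {
  if (any(l_norm <= 0)) stop("`l_norm` must be positive")
  cpp_active_fl(as.numeric(l_norm), params_pack(p))
}

#' @rdname hill_curves
#' @export
passive_force_length <- function(l_norm, p = muscle_params()) {
  if (any(l_norm <= 0)) stop("`l_norm` must be positive")
  if (p$c1 < 0) stop("`c1` must be non-negative")
  cpp_passive_fl(as.numeric(l_norm), params_pack(p))
}

#' @rdname hill_curves
#' @export
force_velocity <- function(v_norm, p = muscle_params()) {
  cpp_force_velocity(as.numeric(v_norm), params_pack(p))
}

#' Total muscle force
#'
#' Standard Hill composition: active force (activation x force-length x
#' force-velocity) plus the parallel passive force, both scaled by `Fmax`.
#' The result is a tensile (non-negative) force in newtons.
#'
#' @param a Activation in `[0, 1]`.
#' @param l_norm Muscle length per `l0`.
#' @param v_norm Strain rate per `vmax` (positive = lengthening).
#' @param p A [muscle_params()] object.
#' @return Force (N), vectorised over the inputs.
#' @export
#' @examples
#' muscle_force(1, 1, 0)  # = Fmax at optimum length, isometric
muscle_force <- function(a, l_norm, v_norm, p = muscle_params()) {
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  p$Fmax * (a * active_force_length(l_norm, p) * force_velocity(v_norm, p) +
              passive_force_length(l_norm, p))
}

#' Tabulate the Hill curves
#'
#' Convenience evaluation grid for plotting or export.
#'
#' @param p A [muscle_params()] object.
#' @param l_norm,v_norm Grids to evaluate on.
#' @return A long tibble with columns `curve`, `x`, `value`.
#' @export
hill_curve_table <- function(p = muscle_params(),
                             l_norm = seq(0.6, 1.4, by = 0.005),
                             v_norm = seq(-1.5, 1.5, by = 0.005)) {
  dplyr::bind_rows(
    tibble::tibble(curve = "active_force_length", x = l_norm,
                   value = active_force_length(l_norm, p)),
    tibble::tibble(curve = "passive_force_length", x = l_norm,
                   value = passive_force_length(l_norm, p)),
    tibble::tibble(curve = "force_velocity", x = v_norm,
                   value = force_velocity(v_norm, p))
  )
}
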