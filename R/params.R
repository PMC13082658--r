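#' Muscle parameter set
#'
#' Bundles every Hill-curve, activation and strength parameter for one
#' muscle. Both muscles of the antagonistic pair share a single parameter
#' set (the model is symmetric). Defaults are the baseline values of the
#' human-forearm elbow model: a 1300 N peak isometric force, a maximum
#' strain rate of 1.6 resting lengths per second, activation/deactivation
#' time constants of 94.5/65 ms, and a parallel passive stiffness scale of
#' 0.05 with slack at resting length.
#'
#' @param Fmax Peak active isometric force (N).
#' @param vmax Maximum strain rate (resting lengths per second) at which
#'   concentric active force vanishes.
#' @param alpha_a Activation time constant (s).
#' @param alpha_d Deactivation time constant (s).
#' @param c1 Parallel passive stiffness scale (dimensionless); 0 disables
#'   the passive element.
#' @param l0 Resting (optimal) muscle length (m).
#' @param b Active force-length shape triple `c(b1, b2, b3)`. `b1 = 2`
#'   keeps the curve (and its Hessian) smooth everywhere.
#' @param c2,c3 Passive-curve exponential rate and slack length (per `l0`).
#' @param d Force-velocity shape triple `c(d1, d2, d3)`: concentric
#'   curvature, eccentric plateau (multiple of `Fmax`), eccentric shape.
#' @param s_smooth Smoothing gain used at every former cusp/discontinuity.
#' @param d2_scaling How the eccentric plateau reacts to changes in `Fmax`:
#'   `"absolute_eccentric"` keeps `d2_eff * Fmax` at its baseline product
#'   (eccentric strength is preserved when isometric strength drops),
#'   `"literal"` sets `d2_eff = 1300 / Fmax`, `"none"` leaves `d2_eff = d[2]`.
#' @param activation_scaling `"thelen"` (default) scales the time
#'   constants with the activation level (`alpha_a * (0.5 + 1.5 a)` when
#'   activating, `alpha_d / (0.5 + 1.5 a)` when deactivating), as in the
#'   first-order activation model this component follows; `"constant"`
#'   uses the raw constants throughout.
#'
#' @return An object of class `muscle_params` (a named list, including the
#'   derived eccentric plateau `d2_eff`).
#' @export
#' @examples
#' p <- muscle_params()
#' p$d2_eff
#' muscle_params(Fmax = 650)$d2_eff  # eccentric plateau rescaled
muscle_params <- function(Fmax = 1300, vmax = 1.6,
                          alpha_a = 0.0945, alpha_d = 0.065,
                          c1 = 0.05, l0 = 0.32,
                          b = c(2, -1.3, 0.53), c2 = 5, c3 = 1,
                          d = c(4, 1.4, 30.24), s_smooth = 500,
                          d2_scaling = c("absolute_eccentric", "literal", "none"),
                          activation_scaling = c("thelen", "constant")) {
  d2_scaling <- match.arg(d2_scaling)
  activation_scaling <- match.arg(activation_scaling)
  stopifnot(Fmax > 0, vmax > 0, alpha_a > 0, alpha_d > 0, l0 > 0,
            length(b) == 3, length(d) == 3)
  if (c1 < 0) stop("`c1` must be non-negative")
  p <- list(
    Fmax = Fmax, vmax = vmax, alpha_a = alpha_a, alpha_d = alpha_d,
    c1 = c1, l0 = l0, b = b, c2 = c2, c3 = c3, d = d,
    s_smooth = s_smooth, d2_scaling = d2_scaling,
    activation_scaling = activation_scaling,
    d2_eff = scale_eccentric_plateau(Fmax, d2 = d[2], rule = d2_scaling)
  )
  structure(p, class = "muscle_params")
}

#' Eccentric plateau after peak-force scaling
#'
#' Ageing reduces isometric strength faster than eccentric strength, so when
#' `Fmax` is swept the normalised eccentric plateau is rescaled to keep the
#' absolute eccentric force ceiling constant at its baseline value
#' (1.4 x 1300 N).
#'
#' @param Fmax Peak isometric force (N).
#' @param d2 Baseline plateau (multiple of baseline `Fmax`).
#' @param rule `"absolute_eccentric"` (default), `"literal"`
#'   (`1300 / Fmax`), or `"none"`.
#' @return The effective plateau `d2_eff` (dimensionless).
#' @export
#' @examples
#' scale_eccentric_plateau(1300)  # 1.4
#' scale_eccentric_plateau(650)   # 2.8
scale_eccentric_plateau <- function(Fmax, d2 = 1.4,
                                    rule = c("absolute_eccentric", "literal",
                                             "none")) {
  rule <- match.arg(rule)
  stopifnot(Fmax > 0)
  switch(rule,
         absolute_eccentric = d2 * 1300 / Fmax,
         literal = 1300 / Fmax,
         none = d2)
}

#' Arm geometry and inertia
#'
#' Constant-moment-arm elbow: at the resting angle `theta0` both muscles are
#' at their resting length, and flexion shortens the flexor by
#' `r * (theta - theta0)` while stretching the extensor by the same amount.
#' The forearm-plus-hand load is a lumped inertia; motion is in a
#' horizontal plane so no gravity enters.
#'
#' @param r Muscle moment arm (m).
#' @param I Moment of inertia about the elbow (kg m^2).
#' @param theta0 Resting elbow flexion angle (rad).
#' @param l0 Muscle resting length (m).
#' @return An object of class `arm_geometry`.
#' @export
arm_geometry <- function(r = 0.04, I = 6.88e-2, theta0 = pi / 2, l0 = 0.32) {
  stopifnot(r > 0, I > 0, l0 > 0)
  structure(list(r = r, I = I, theta0 = theta0, l0 = l0),
            class = "arm_geometry")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat("<muscle_params>\n")
  cat(sprintf("  Fmax    %8.1f N      vmax %5.2f l0/s\n", x$Fmax, x$vmax))
  cat(sprintf("  alpha_a %8.1f ms     alpha_d %5.1f ms\n",
              1000 * x$alpha_a, 1000 * x$alpha_d))
  cat(sprintf("  c1      %8.3f        d2_eff  %5.3f (%s)\n",
              x$c1, x$d2_eff, x$d2_scaling))
  invisible(x)
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat(sprintf("<arm_geometry> r = %.3f m, I = %.4f kg m^2, theta0 = %.1f deg\n",
              x$r, x$I, 180 / pi * x$theta0))
  invisible(x)
}

#' Parameter multipliers of the factorial sweep
#'
#' The five ageing-related parameters and the multiplier grids applied to
#' their baseline values in the full factorial sweep (4 x 4 x 7 x 7 x 5 =
#' 3920 combinations).
#'
#' @return A tibble with columns `parameter`, `baseline`, `multiplier` and
#'   the absolute `value`.
#' @export
#' @examples
#' sweep_ranges()
sweep_ranges <- function() {
  base <- c(Fmax = 1300, vmax = 1.6, alpha_a = 0.0945, alpha_d = 0.065,
            c1 = 0.05)
  mult <- list(
    Fmax = c(0.5, 0.8, 1.0, 1.5),
    vmax = c(0.75, 1.0, 1.5, 2.0),
    alpha_a = c(0.15, 0.25, 0.5, 0.75, 1.0, 1.5, 2.0),
    alpha_d = c(0.15, 0.25, 0.5, 0.75, 1.0, 1.5, 2.0),
    c1 = c(0, 0.6, 1.0, 1.4, 1.8)
  )
  tibble::tibble(
    parameter = rep(names(mult), lengths(mult)),
    baseline = base[rep(names(mult), lengths(mult))],
    multiplier = unlist(mult, use.names = FALSE)
  ) |>
    dplyr::mutate(value = .data$baseline * .data$multiplier)
}

# pack parameters + geometry into the flat double vector the C++ core reads
params_pack <- function(p, g = arm_geometry(l0 = p$l0)) {
  c(p$Fmax, p$vmax, p$alpha_a, p$alpha_d, p$c1, p$l0,
    p$b[1], p$b[2], p$b[3], p$c2, p$c3,
    p$d[1], p$d2_eff, p$d[3], p$s_smooth,
    g$r, g$I, g$theta0,
    if (identical(p$activation_scaling, "thelen")) 0 else 1)
}
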