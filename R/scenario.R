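#' Corner parameter sets of the sweep
#'
#' The three named reference parameter sets: `"baseline"` (the
#' human-forearm defaults), `"youngest"` (highest force and strain rate,
#' fastest activation/deactivation, no passive stiffness) and `"oldest"`
#' (the opposite extreme of the sweep ranges).
#'
#' @param which One of `"baseline"`, `"youngest"`, `"oldest"`.
#' @param ... Passed on to [muscle_params()] (e.g. `activation_scaling`).
#' @return A [muscle_params()] object.
#' @export
#' @examples
#' make_corner_params("youngest")
make_corner_params <- function(which = c("baseline", "youngest", "oldest"),
                               ...) {
  which <- match.arg(which)
  m <- switch(which,
    baseline = c(Fmax = 1, vmax = 1, alpha_a = 1, alpha_d = 1, c1 = 1),
    youngest = c(Fmax = 1.5, vmax = 2, alpha_a = 0.15, alpha_d = 0.15,
                 c1 = 0),
    oldest = c(Fmax = 0.5, vmax = 0.75, alpha_a = 2, alpha_d = 2, c1 = 1.8))
  muscle_params(Fmax = 1300 * m[["Fmax"]], vmax = 1.6 * m[["vmax"]],
                alpha_a = 0.0945 * m[["alpha_a"]],
                alpha_d = 0.065 * m[["alpha_d"]],
                c1 = 0.05 * m[["c1"]], ...)
}

#' Archetypal excitation schedules
#'
#' Deterministic (per seed) piecewise-constant excitation schedules used
#' as forward-simulation inputs in tests: all-zero, a flexor step, a
#' bang-bang pair (agonist then antagonist at full drive, the agonist
#' being the extensor), and a triphasic agonist-antagonist-agonist
#' pattern. Switch times of the latter two are randomised under `seed`.
#'
#' @param kind `"zero"`, `"step"`, `"bang_bang"`, or `"triphasic"`.
#' @param N Number of steps.
#' @param seed Integer seed for the randomised switch times.
#' @return A tibble with `N` rows and columns `u_flex`, `u_ext`.
#' @export
make_excitation <- function(kind = c("zero", "step", "bang_bang",
                                     "triphasic"),
                            N = 80, seed = 1) {
  kind <- match.arg(kind)
  uf <- ue <- rep(0, N)
  if (kind == "step") {
    uf[] <- 1
  } else if (kind == "bang_bang") {
    t1 <- withr::with_seed(seed, sample(seq(5, N - 5), 1))
    ue[seq_len(t1)] <- 1                 # agonist (extensor) burst
    uf[seq(t1 + 1, N)] <- 1              # antagonist braking
  } else if (kind == "triphasic") {
    ts <- withr::with_seed(seed, sort(sample(seq(5, N - 5), 3)))
    ue[seq_len(ts[1])] <- 1
    uf[seq(ts[1] + 1, ts[2])] <- 1
    ue[seq(ts[2] + 1, ts[3])] <- 1
  }
  tibble::tibble(u_flex = uf, u_ext = ue)
}

#' Static-equilibrium activations at a posture
#'
#' Finds the activations that keep the joint at rest at angle `theta`: the
#' stretched muscle contributes passive force, its active drive is zero,
#' and the opposing muscle's activation is solved (by root finding on the
#' net joint torque) so the torques cancel. With no passive stiffness both
#' activations are zero.
#'
#' @param c1 Passive stiffness scale.
#' @param theta Posture (rad).
#' @param p A [muscle_params()]; its `c1` is overridden by `c1`.
#' @param g An [arm_geometry()].
#' @return A list `a_flex`, `a_ext` in `[0, 1]`.
#' @export
#' @examples
#' make_equilibrium_case(c1 = 0.09, theta = 135 * pi / 180)
make_equilibrium_case <- function(c1, theta, p = muscle_params(),
                                  g = arm_geometry(l0 = p$l0)) {
  p$c1 <- c1
  len <- muscle_lengths(theta, g)
  lf <- len$l_flex / g$l0; le <- len$l_ext / g$l0
  net0 <- muscle_force(0, lf, 0, p) - muscle_force(0, le, 0, p)
  if (abs(net0) < 1e-12) return(list(a_flex = 0, a_ext = 0))
  # activate the side whose activation raises torque against the imbalance
  side <- if (net0 < 0) "flex" else "ext"
  torq <- function(a) {
    af <- if (side == "flex") a else 0
    ae <- if (side == "ext") a else 0
    muscle_force(af, lf, 0, p) - muscle_force(ae, le, 0, p)
  }
  if (sign(torq(0)) == sign(torq(1)))
    stop("static equilibrium infeasible: required activation exceeds 1")
  a <- uniroot(torq, c(0, 1), tol = 1e-12)$root
  list(a_flex = if (side == "flex") a else 0,
       a_ext = if (side == "ext") a else 0)
}

#' Synthetic sweep table with planted linear structure
#'
#' Builds a sweep-shaped table whose response is an exact linear
#' combination of the 16-term normalised importance basis plus optional
#' Gaussian noise — the ground-truth fixture for validating the importance
#' regression.
#'
#' @param coeffs Named coefficient vector over (a subset of) the terms
#'   `"(Intercept)"`, the five main effects and the ten pairwise
#'   interactions; missing terms are zero.
#' @param grid Parameter grid (default the full factorial).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed for the noise.
#' @param response Name of the generated response column.
#' @return The grid with the planted response appended.
#' @export
#' @examples
#' tab <- make_regression_table(c(`(Intercept)` = 0.5, alpha_a = 0.3))
make_regression_table <- function(coeffs, grid = build_full_factorial(),
                                  noise_sd = 0, seed = 1,
                                  response = "J_RMSE") {
  X <- cbind(`(Intercept)` = 1, importance_design(grid))
  unknown <- setdiff(names(coeffs), colnames(X))
  if (length(unknown)) stop("unknown terms: ", paste(unknown, collapse = ", "))
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta[names(coeffs)] <- coeffs
  y <- drop(X %*% beta)
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, rnorm(length(y), sd = noise_sd))
  grid[[response]] <- y
  grid
}
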