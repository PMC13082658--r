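#' Muscle lengths at a joint angle
#'
#' Symmetric constant-moment-arm kinematics: flexion past the resting angle
#' shortens the flexor and stretches the extensor by the same amount, so
#' `l_flex + l_ext == 2 * l0` identically.
#'
#' @param theta Elbow flexion angle (rad), in `[0, pi]`.
#' @param g An [arm_geometry()] object.
#' @return A tibble with columns `theta`, `l_flex`, `l_ext` (m).
#' @export
#' @examples
#' muscle_lengths(pi / 2)          # both at resting length
#' muscle_lengths(135 * pi / 180)  # flexor shortened, extensor stretched
muscle_lengths <- function(theta, g = arm_geometry()) {
  tibble::tibble(
    theta = theta,
    l_flex = g$l0 - g$r * (theta - g$theta0),
    l_ext = g$l0 + g$r * (theta - g$theta0)
  )
}

#' Excitation-to-activation rate
#'
#' First-order approach of activation `a` toward the neural excitation `u`,
#' with distinct activation (`alpha_a`) and deactivation (`alpha_d`) time
#' constants blended through a smooth tanh switch on the sign of `u - a`.
#' With `activation_scaling = "thelen"` the effective time constants also
#' depend on the activation level (`alpha_a * (0.5 + 1.5 a)` rising,
#' `alpha_d / (0.5 + 1.5 a)` falling).
#'
#' @param a Activation in `[0, 1]`.
#' @param u Excitation in `[0, 1]`.
#' @param p A [muscle_params()] object.
#' @return `da/dt` (1/s), vectorised.
#' @export
activation_rate <- function(a, u, p = muscle_params()) {
  cpp_act_rate(as.numeric(a), as.numeric(u), params_pack(p))
}

# initial arm state: at rest at `theta`, activations at static equilibrium
initial_state <- function(theta, p, g = arm_geometry(l0 = p$l0)) {
  eq <- make_equilibrium_case(c1 = p$c1, theta = theta, p = p, g = g)
  c(theta = theta, omega = 0, a_flex = eq$a_flex, a_ext = eq$a_ext)
}

#' Time derivative of the arm state
#'
#' Equations of motion of the frictionless, gravity-free elbow:
#' `dtheta/dt = omega`, `domega/dt = r (F_flex - F_ext) / I` with forces
#' from [muscle_force()] at the state's muscle lengths and velocities, and
#' activation rates from [activation_rate()]. This R composition exists as
#' a readable reference; the optimiser uses an equivalent compiled path.
#'
#' @param state Named numeric `c(theta, omega, a_flex, a_ext)`.
#' @param u_flex,u_ext Excitations in `[0, 1]`.
#' @param p A [muscle_params()] object.
#' @param g An [arm_geometry()] object.
#' @return Named numeric derivative of the four states.
#' @export
state_derivative <- function(state, u_flex, u_ext, p = muscle_params(),
                             g = arm_geometry(l0 = p$l0)) {
  stopifnot(u_flex >= 0, u_flex <= 1, u_ext >= 0, u_ext <= 1)
  theta <- state[[1]]; omega <- state[[2]]
  a_f <- state[[3]]; a_e <- state[[4]]
  len <- muscle_lengths(theta, g)
  vf <- -(g$r / g$l0) * omega / p$vmax   # strain rate per vmax
  ve <- (g$r / g$l0) * omega / p$vmax
  Ff <- muscle_force(a_f, len$l_flex / g$l0, vf, p)
  Fe <- muscle_force(a_e, len$l_ext / g$l0, ve, p)
  c(theta = omega,
    omega = g$r * (Ff - Fe) / g$I,
    a_flex = activation_rate(a_f, u_flex, p),
    a_ext = activation_rate(a_e, u_ext, p))
}

#' One classical Runge-Kutta step
#'
#' Fourth-order step of the arm dynamics with controls held constant.
#'
#' @param state Named numeric `c(theta, omega, a_flex, a_ext)`.
#' @param u_flex,u_ext Excitations, constant over the step.
#' @param dt Step length (s), > 0.
#' @inheritParams state_derivative
#' @return The state after `dt`.
#' @export
rk4_step <- function(state, u_flex, u_ext, dt, p = muscle_params(),
                     g = arm_geometry(l0 = p$l0)) {
  stopifnot(dt > 0)
  k1 <- state_derivative(state, u_flex, u_ext, p, g)
  k2 <- state_derivative(state + dt / 2 * k1, u_flex, u_ext, p, g)
  k3 <- state_derivative(state + dt / 2 * k2, u_flex, u_ext, p, g)
  k4 <- state_derivative(state + dt * k3, u_flex, u_ext, p, g)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Forward-simulate an excitation schedule
#'
#' Integrates the arm dynamics through a piecewise-constant excitation
#' schedule by repeated RK4 steps. Used as the independent oracle against
#' which optimal-control solutions are replayed.
#'
#' @param x0 Initial state, or `NULL` to start at rest at `theta_start` of
#'   `task` with static-equilibrium activations.
#' @param schedule A tibble with columns `u_flex`, `u_ext` (one row per
#'   step), e.g. from [make_excitation()].
#' @param p A [muscle_params()] object.
#' @param g An [arm_geometry()] object.
#' @param task A [task_config()] supplying `dt` (and the start posture when
#'   `x0` is `NULL`).
#' @return A trajectory tibble (one row per node, `N + 1` rows) with
#'   columns `time`, `theta`, `omega`, `a_flex`, `a_ext`, `u_flex`,
#'   `u_ext`, `l_flex`, `l_ext`, `F_flex`, `F_ext`.
#' @export
forward_simulate <- function(x0 = NULL, schedule, p = muscle_params(),
                             g = arm_geometry(l0 = p$l0),
                             task = task_config()) {
  if (is.null(x0)) x0 <- initial_state(task$theta_start, p, g)
  N <- nrow(schedule)
  X <- matrix(NA_real_, N + 1, 4)
  X[1, ] <- x0
  state <- x0
  for (k in seq_len(N)) {
    state <- rk4_step(state, schedule$u_flex[k], schedule$u_ext[k],
                      task$dt, p, g)
    X[k + 1, ] <- state
  }
  assemble_trajectory(X, schedule, task$dt, p, g)
}

# decorate a node matrix (theta, omega, a_flex, a_ext) into the trajectory
# tibble schema shared by forward_simulate() and solve_ocp()
assemble_trajectory <- function(X, schedule, dt, p, g) {
  n <- nrow(X)
  theta <- X[, 1]; omega <- X[, 2]
  len <- muscle_lengths(theta, g)
  vf <- -(g$r / g$l0) * omega / p$vmax
  ve <- (g$r / g$l0) * omega / p$vmax
  tibble::tibble(
    time = dt * (seq_len(n) - 1),
    theta = theta, omega = omega,
    a_flex = X[, 3], a_ext = X[, 4],
    u_flex = c(schedule$u_flex, NA_real_),
    u_ext = c(schedule$u_ext, NA_real_),
    l_flex = len$l_flex, l_ext = len$l_ext,
    F_flex = muscle_force(pmin(pmax(X[, 3], 0), 1), len$l_flex / g$l0, vf, p),
    F_ext = muscle_force(pmin(pmax(X[, 4], 0), 1), len$l_ext / g$l0, ve, p)
  )
}
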