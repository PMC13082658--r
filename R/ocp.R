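#' Point-to-point task definition
#'
#' Defines the reaching task: start and target elbow angles, horizon,
#' control discretisation and objective weights. The objective is the sum
#' of squared muscle-length errors to the target over all nodes (the
#' running cost), plus a small terminal-position penalty of weight `w`;
#' optionally augmented with squared-excitation and smoothed mechanical
#' work penalties.
#'
#' @param theta_start_deg,theta_target_deg Start/target elbow flexion
#'   (degrees). Defaults are the sweep task 135 -> 45; the comparison task
#'   against empirical reaching uses 120 -> 60.
#' @param T Horizon (s).
#' @param dt Control/integration step (s); `T/dt` must be an integer.
#' @param w Terminal-position penalty weight.
#' @param objective `"plain"` (positional error only) or `"augmented"`
#'   (adds excitation and work penalties).
#' @param W_exc Weight on summed squared excitations (m).
#' @param W_work Weight on the smoothed-absolute mechanical work rate
#'   (m/J).
#' @param s_w Smoothing gain of the smooth absolute value
#'   `smab(x) = x * tanh(s_w * x)` used in the work term.
#' @param include_node0 Whether the (fixed) initial node enters the running
#'   cost. It contributes only a constant, so the optimum is unchanged;
#'   the default excludes it.
#' @return A `task_config` object.
#' @export
task_config <- function(theta_start_deg = 135, theta_target_deg = 45,
                        T = 0.4, dt = 0.005, w = 0.01,
                        objective = c("plain", "augmented"),
                        W_exc = 1e-5, W_work = 1e-4, s_w = 100,
                        include_node0 = FALSE) {
  objective <- match.arg(objective)
  N <- T / dt
  if (abs(N - round(N)) > 1e-9) stop("`T/dt` must be an integer")
  structure(list(
    theta_start = theta_start_deg * pi / 180,
    theta_target = theta_target_deg * pi / 180,
    T = T, dt = dt, N = as.integer(round(N)), w = w,
    objective = objective, W_exc = W_exc, W_work = W_work, s_w = s_w,
    include_node0 = include_node0
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "<task_config> %g -> %g deg over %g s (dt = %g ms, N = %d, w = %g, %s)\n",
    180 / pi * x$theta_start, 180 / pi * x$theta_target, x$T,
    1000 * x$dt, x$N, x$w, x$objective))
  invisible(x)
}

#' Objective terms on a trajectory
#'
#' `objective_sse()` is the running cost: the sum over nodes of squared
#' muscle-length error to the target posture, for both muscles (m^2).
#' `objective_end()` is the terminal-position penalty `w * error_N` (m^2).
#' `objective_augmented()` adds the squared-excitation and smoothed-work
#' penalties to `J = J_SSE + J_end`.
#'
#' @param trajectory A trajectory tibble (see [forward_simulate()]).
#' @param task A [task_config()].
#' @param g An [arm_geometry()].
#' @return A single numeric (m^2).
#' @export
objective_sse <- function(trajectory, task = task_config(),
                          g = arm_geometry()) {
  tgt <- muscle_lengths(task$theta_target, g)
  idx <- if (task$include_node0) seq_len(nrow(trajectory)) else -1L
  sum((trajectory$l_flex[idx] - tgt$l_flex)^2 +
        (trajectory$l_ext[idx] - tgt$l_ext)^2)
}

#' @rdname objective_sse
#' @export
objective_end <- function(trajectory, task = task_config(),
                          g = arm_geometry()) {
  tgt <- muscle_lengths(task$theta_target, g)
  n <- nrow(trajectory)
  task$w * ((trajectory$l_flex[n] - tgt$l_flex)^2 +
              (trajectory$l_ext[n] - tgt$l_ext)^2)
}

#' @rdname objective_sse
#' @param p A [muscle_params()] object (the work term needs muscle forces).
#' @export
objective_augmented <- function(trajectory, task = task_config(),
                                p = muscle_params(),
                                g = arm_geometry(l0 = p$l0)) {
  J <- objective_sse(trajectory, task, g) + objective_end(trajectory, task, g)
  u <- c(trajectory$u_flex, trajectory$u_ext)
  J_exc <- task$W_exc * sum(u^2, na.rm = TRUE)
  smab <- function(x) x * tanh(task$s_w * x)
  ldf <- -g$r * trajectory$omega
  lde <- g$r * trajectory$omega
  wk <- smab(ldf * trajectory$F_flex) + smab(lde * trajectory$F_ext)
  J_work <- task$W_work * task$dt * sum(wk[-1])
  J + J_exc + J_work
}

#' Initial guess for the reaching problem
#'
#' Linear interpolation of the muscle lengths from the start to the target
#' posture over the horizon, with all other states and all controls zero.
#'
#' @param task A [task_config()].
#' @param g An [arm_geometry()].
#' @return A list with `states` (tibble: `time`, `l_flex`, `l_ext`) and
#'   `controls` (tibble: `u_flex`, `u_ext`, all zero).
#' @export
initial_guess <- function(task = task_config(), g = arm_geometry()) {
  s <- muscle_lengths(task$theta_start, g)
  t <- muscle_lengths(task$theta_target, g)
  frac <- seq(0, 1, length.out = task$N + 1)
  list(
    states = tibble::tibble(
      time = frac * task$T,
      l_flex = s$l_flex + frac * (t$l_flex - s$l_flex),
      l_ext = s$l_ext + frac * (t$l_ext - s$l_ext)
    ),
    controls = tibble::tibble(u_flex = rep(0, task$N),
                              u_ext = rep(0, task$N))
  )
}

#' Solver settings
#'
#' Settings of the shooting solver: an L-BFGS-B inner solve over the
#' box-bounded excitations with exact adjoint gradients, wrapped in an
#' augmented-Lagrangian outer loop that enforces the terminal-rest
#' constraint `omega(T) = 0`.
#'
#' @param maxit Inner L-BFGS-B iteration cap.
#' @param factr,pgtol Inner convergence tolerances (see [stats::optim()]).
#' @param lmm L-BFGS-B memory depth (stored correction pairs).
#' @param max_outer Maximum augmented-Lagrangian updates.
#' @param omega_tol Terminal-velocity feasibility tolerance (rad/s).
#' @param mu0,mu_growth Initial penalty weight and growth factor.
#' @return A list of class `ocp_control`.
#' @export
ocp_control <- function(maxit = 20000, factr = 10, pgtol = 1e-9, lmm = 20,
                        max_outer = 12, omega_tol = 1e-6,
                        mu0 = 0.1, mu_growth = 10) {
  structure(list(maxit = maxit, factr = factr, pgtol = pgtol, lmm = lmm,
                 max_outer = max_outer, omega_tol = omega_tol,
                 mu0 = mu0, mu_growth = mu_growth),
            class = "ocp_control")
}

#' Solve the point-to-point optimal-control problem
#'
#' Finds piecewise-constant excitations in `[0, 1]` minimising the
#' positional-error objective subject to the arm dynamics (RK4, 5 ms
#' steps), a fixed initial state at rest (with activations at the static
#' equilibrium of the start posture), and terminal rest `omega(T) = 0`.
#' The problem is transcribed by direct shooting: states are generated
#' from the controls by the same RK4 integrator used for simulation, so
#' the dynamics are satisfied exactly at every node, and the gradient of
#' the objective with respect to every control is computed by a discrete
#' adjoint sweep (machine-precision complex-step stage Jacobians).
#'
#' Extension and flexion tasks are mapped to a single canonical frame
#' internally (the model is exactly mirror-symmetric), so a mirrored task
#' returns the exactly mirrored solution.
#'
#' @param p A [muscle_params()] object.
#' @param g An [arm_geometry()]; its `l0` is taken from `p`.
#' @param task A [task_config()].
#' @param guess `NULL` for the cold start (linear-length guess: zero
#'   controls), an `ocp_solution` to warm start from, or a list with a
#'   `controls` tibble.
#' @param control An [ocp_control()].
#' @return An `ocp_solution`: trajectory and control tibbles, objective
#'   decomposition (`J_SSE`, `J_end`, `J`, and the augmented terms when
#'   requested), solver status and terminal feasibility.
#' @export
#' @examples
#' \donttest{
#' sol <- solve_ocp(muscle_params(), task = task_config())
#' glance(sol)
#' }
solve_ocp <- function(p, g = arm_geometry(l0 = p$l0), task = task_config(),
                      guess = NULL, control = ocp_control()) {
  mirrored <- task$theta_start < task$theta_target
  ctask <- task
  if (mirrored) {
    ctask$theta_start <- 2 * g$theta0 - task$theta_start
    ctask$theta_target <- 2 * g$theta0 - task$theta_target
  }
  u0 <- guess_controls(guess, ctask$N, mirrored)
  fit <- solve_ocp_canonical(p, g, ctask, u0, control)
  if (mirrored) {
    fit$U <- fit$U[, 2:1]
    fit$X <- cbind(2 * g$theta0 - fit$X[, 1], -fit$X[, 2],
                   fit$X[, 4], fit$X[, 3])
  }
  controls <- tibble::tibble(u_flex = fit$U[, 1], u_ext = fit$U[, 2])
  trajectory <- assemble_trajectory(fit$X, controls, task$dt, p, g)
  structure(list(
    trajectory = trajectory, controls = controls,
    J_SSE = fit$J_SSE, J_end = fit$J_end, J = fit$J,
    J_exc = fit$J_exc, J_work = fit$J_work,
    omega_T = fit$omega_N, feasibility = fit$feasibility,
    solver_status = fit$status,
    params = p, geometry = g, task = task
  ), class = "ocp_solution")
}

# accepts NULL / ocp_solution / list(controls = ...) / matrix
guess_controls <- function(guess, N, mirrored) {
  if (is.null(guess)) return(matrix(0, N, 2))
  U <- if (inherits(guess, "ocp_solution")) {
    as.matrix(guess$controls)
  } else if (is.list(guess) && !is.null(guess$controls)) {
    as.matrix(guess$controls[, c("u_flex", "u_ext")])
  } else {
    as.matrix(guess)
  }
  if (nrow(U) != N) stop("guess controls have wrong length")
  if (mirrored) U <- U[, 2:1]
  U
}

solve_ocp_canonical <- function(p, g, task, U0, control) {
  par <- params_pack(p, g)
  x0 <- initial_state(task$theta_start, p, g)
  N <- task$N
  aug <- identical(task$objective, "augmented")
  uv <- c(U0[, 1], U0[, 2])
  lambda <- 0; mu <- control$mu0
  cache <- new.env(parent = emptyenv())
  evalf <- function(u) {
    if (is.null(cache$u) || !identical(u, cache$u)) {
      cache$res <- cpp_cost_grad(x0, u, task$dt, par, task$theta_target,
                                 task$w, task$include_node0, lambda, mu,
                                 aug, task$W_exc, task$W_work, task$s_w)
      cache$u <- u
    }
    cache$res
  }
  iters <- 0L; conv <- TRUE; omega_prev <- Inf; outer_used <- 0L
  for (outer in seq_len(control$max_outer)) {
    outer_used <- outer
    cache$u <- NULL
    opt <- optim(uv, fn = function(u) evalf(u)$J_total,
                 gr = function(u) evalf(u)$grad,
                 method = "L-BFGS-B", lower = 0, upper = 1,
                 control = list(maxit = control$maxit,
                                factr = control$factr,
                                pgtol = control$pgtol,
                                lmm = control$lmm))
    uv <- opt$par
    iters <- iters + opt$counts[[1]]
    conv <- opt$convergence %in% c(0L, 52L) # 52: line-search stall at optimum
    res <- evalf(uv)
    om <- res$omega_N
    if (abs(om) <= control$omega_tol) break
    lambda <- lambda + mu * om
    if (abs(om) > 0.25 * abs(omega_prev)) mu <- mu * control$mu_growth
    omega_prev <- om
  }
  res <- evalf(uv)
  U <- cbind(uv[seq_len(N)], uv[N + seq_len(N)])
  X <- cpp_rollout(x0, U, task$dt, par)
  list(U = U, X = X,
       J_SSE = res$J_SSE, J_end = res$J_end, J = res$J,
       J_exc = if (aug) res$J_exc else NA_real_,
       J_work = if (aug) res$J_work else NA_real_,
       omega_N = res$omega_N,
       feasibility = 0,  # shooting: dynamics hold exactly at every node
       status = list(converged = conv && abs(res$omega_N) <= control$omega_tol,
                     iterations = iters, outer_iterations = outer_used,
                     message = opt$message))
}

#' @export
print.ocp_solution <- function(x, ...) {
  cat("<ocp_solution>\n")
  cat(sprintf("  task %g -> %g deg, N = %d\n",
              180 / pi * x$task$theta_start, 180 / pi * x$task$theta_target,
              x$task$N))
  cat(sprintf("  J = %.6g m^2 (J_SSE %.6g + J_end %.3g), omega(T) = %.2e rad/s\n",
              x$J, x$J_SSE, x$J_end, x$omega_T))
  cat(sprintf("  converged: %s (%d gradient evals, %d outer)\n",
              x$solver_status$converged, x$solver_status$iterations,
              x$solver_status$outer_iterations))
  invisible(x)
}

#' @export
tidy.ocp_solution <- function(x, ...) x$trajectory

#' @export
glance.ocp_solution <- function(x, ...) {
  tibble::tibble(
    J = x$J, J_SSE = x$J_SSE, J_end = x$J_end,
    J_RMSE = rmse_metric(x$J_SSE, x$task$N, x$params$l0),
    omega_T = x$omega_T, feasibility = x$feasibility,
    converged = x$solver_status$converged,
    iterations = x$solver_status$iterations
  )
}
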