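# objective terms, initial guess, and the shooting solver's contracts

test_that("running-cost and terminal objectives match hand arithmetic", {
  task <- task_config()
  g <- arm_geometry()
  N <- task$N
  # trajectory parked at the target: zero error
  at_target <- tibble::tibble(
    time = task$dt * 0:N,
    l_flex = muscle_lengths(task$theta_target, g)$l_flex,
    l_ext = muscle_lengths(task$theta_target, g)$l_ext)
  expect_equal(objective_sse(at_target, task, g), 0)
  expect_equal(objective_end(at_target, task, g), 0)
  # parked at the start: per-node error 2 (r pi/2)^2, summed over N nodes
  at_start <- tibble::tibble(
    time = task$dt * 0:N,
    l_flex = muscle_lengths(task$theta_start, g)$l_flex,
    l_ext = muscle_lengths(task$theta_start, g)$l_ext)
  per_node <- 2 * (0.04 * pi / 2)^2
  expect_equal(objective_sse(at_start, task, g), N * per_node,
               tolerance = 1e-12)
  expect_equal(N * per_node, 0.6317, tolerance = 1e-3)
  expect_equal(objective_end(at_start, task, g), 0.01 * per_node,
               tolerance = 1e-12)
  # one muscle displaced by delta contributes delta^2 per node
  delta <- 0.004
  off <- dplyr::mutate(at_target, l_flex = .data$l_flex + delta)
  expect_equal(objective_sse(off, task, g), N * delta^2, tolerance = 1e-12)
  # terminal penalty scales linearly in w
  task2 <- task_config(w = 0.02)
  expect_equal(objective_end(at_start, task2, g),
               2 * objective_end(at_start, task, g))
})

test_that("augmented objective reduces to J for idle trajectories and smab is even/saturating", {
  task <- task_config(objective = "augmented")
  p <- muscle_params(c1 = 0)
  tr <- forward_simulate(schedule = make_excitation("zero", N = task$N),
                         p = p, task = task)
  expect_equal(objective_augmented(tr, task, p),
               objective_sse(tr, task) + objective_end(tr, task),
               tolerance = 1e-12)
  smab <- function(x, s = 100) x * tanh(s * x)
  expect_equal(smab(0.5), 0.5, tolerance = 1e-12)
  expect_equal(smab(-0.3), smab(0.3))
  expect_lt(smab(1e-4), 1e-4)
})

test_that("initial guess interpolates lengths linearly with zero controls", {
  task <- task_config()
  g <- arm_geometry()
  gs <- initial_guess(task, g)
  s <- muscle_lengths(task$theta_start, g)
  t <- muscle_lengths(task$theta_target, g)
  n <- nrow(gs$states)
  expect_equal(gs$states$l_flex[1], s$l_flex)
  expect_equal(gs$states$l_ext[n], t$l_ext)
  mid <- (n + 1) / 2
  expect_equal(gs$states$l_flex[mid], (s$l_flex + t$l_flex) / 2)
  expect_true(all(gs$controls == 0))
  expect_equal(nrow(gs$controls), task$N)
})

test_that("adjoint gradient of the shooting objective matches finite differences", {
  p <- muscle_params(c1 = 0.07)
  g <- arm_geometry()
  task <- small_task()
  par <- reachopt:::params_pack(p, g)
  x0 <- reachopt:::initial_state(task$theta_start, p, g)
  set.seed(3)
  u <- runif(2 * task$N)
  f <- function(u) reachopt:::cpp_cost_grad(
    x0, u, task$dt, par, task$theta_target, task$w, FALSE,
    0.2, 1.5, TRUE, 1e-5, 1e-4, 100)
  r0 <- f(u)
  h <- 1e-6
  for (j in sample(2 * task$N, 6)) {
    up <- u; up[j] <- up[j] + h
    um <- u; um[j] <- um[j] - h
    gn <- (f(up)$J_total - f(um)$J_total) / (2 * h)
    expect_equal(r0$grad[j], gn, tolerance = 1e-5)
  }
})

test_that("solved trajectories satisfy the solver's contracts", {
  sol <- cached_solve()  # baseline, sweep task
  task <- ro_task()
  expect_true(sol$solver_status$converged)
  expect_true(all(sol$controls >= 0 & sol$controls <= 1))
  expect_lt(abs(sol$omega_T), 1e-6)
  expect_equal(sol$J, sol$J_SSE + sol$J_end, tolerance = 1e-12)
  # objective recomputed from the returned trajectory matches the solver's
  expect_equal(objective_sse(sol$trajectory, task), sol$J_SSE,
               tolerance = 1e-10)
  # replay through the independent R-level integrator: multiple-shooting
  # consistency well under the 1e-6 feasibility tolerance
  replay <- forward_simulate(x0 = unlist(sol$trajectory[1, c(
    "theta", "omega", "a_flex", "a_ext")]),
    schedule = sol$controls, p = sol$params, task = task)
  expect_lt(max(abs(replay$theta - sol$trajectory$theta)), 1e-6)
  expect_lt(max(abs(replay$a_flex - sol$trajectory$a_flex)), 1e-6)
  # initial node: rest + static equilibrium (antagonist balances the
  # stretched agonist's passive pull)
  expect_equal(sol$trajectory$omega[1], 0)
  eq <- make_equilibrium_case(0.05, task$theta_start, sol$params)
  expect_equal(sol$trajectory$a_flex[1], eq$a_flex)
})

test_that("warm-started re-solve is stationary and the mirror task is exactly symmetric", {
  sol <- cached_solve()
  re <- solve_ocp(sol$params, task = ro_task(), guess = sol,
                  control = ro_ctrl())
  expect_lt(abs(re$J - sol$J), 1e-8)
  # mirrored task (45 -> 135): same objective, roles swapped exactly
  mtask <- task_config(theta_start_deg = 45, theta_target_deg = 135)
  msol <- solve_ocp(sol$params, task = mtask, control = ro_ctrl())
  expect_identical(msol$J, sol$J)
  expect_identical(msol$controls$u_flex, sol$controls$u_ext)
  expect_equal(msol$trajectory$theta, pi - sol$trajectory$theta,
               tolerance = 1e-12)
})

test_that("the augmented objective is solvable and decomposes additively", {
  task <- task_config(T = 0.1, objective = "augmented")
  p <- muscle_params()
  sol <- solve_ocp(p, task = task, control = ro_ctrl())
  expect_true(is.finite(sol$J_exc) && sol$J_exc >= 0)
  expect_true(is.finite(sol$J_work))
  # solver-side terms agree with the trajectory-level evaluation
  expect_equal(objective_augmented(sol$trajectory, task, p),
               sol$J + sol$J_exc + sol$J_work, tolerance = 1e-8)
})

test_that("tidy and glance expose the trajectory and the objective decomposition", {
  sol <- cached_solve()
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), ro_task()$N + 1)
  gl <- glance(sol)
  expect_equal(gl$J, sol$J)
  expect_true(gl$converged)
  expect_equal(gl$J_RMSE, rmse_metric(sol$J_SSE, ro_task()$N, 0.32))
})
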