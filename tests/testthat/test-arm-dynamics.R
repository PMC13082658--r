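# kinematics, activation dynamics, equations of motion, RK4 and the
# forward-simulation oracle

test_that("muscle lengths follow the symmetric constant-moment-arm map", {
  g <- arm_geometry()
  expect_equal(unlist(muscle_lengths(pi / 2, g)[, c("l_flex", "l_ext")]),
               c(l_flex = 0.32, l_ext = 0.32))
  l135 <- muscle_lengths(135 * pi / 180, g)
  expect_equal(l135$l_flex, 0.32 - 0.04 * pi / 4, tolerance = 1e-12)
  expect_equal(l135$l_ext, 0.32 + 0.04 * pi / 4, tolerance = 1e-12)
  l45 <- muscle_lengths(45 * pi / 180, g)
  expect_equal(l45$l_flex, l135$l_ext)
  # sum identity at arbitrary angles
  th <- seq(0.1, 3, length.out = 11)
  ll <- muscle_lengths(th, g)
  expect_equal(ll$l_flex + ll$l_ext, rep(2 * 0.32, 11))
})

test_that("activation rate is first-order with distinct rise and fall time scales", {
  p <- muscle_params()
  expect_equal(activation_rate(0.5, 0.5, p), 0)
  # activating: positive, order 1/alpha_a (Thelen scaling at a = 0 gives
  # time constant alpha_a/2)
  r_up <- activation_rate(0, 1, p)
  expect_gt(r_up, 0)
  expect_equal(r_up, 1 / (0.0945 * 0.5), tolerance = 1e-3)
  # deactivating: negative, magnitude from the adopted law
  # (tau = alpha_d / (0.5 + 1.5 a) at a = 1 -> rate = -2/alpha_d)
  r_dn <- activation_rate(1, 0, p)
  expect_lt(r_dn, 0)
  expect_equal(r_dn, -(0.5 + 1.5) / 0.065, tolerance = 1e-3)
  # constant-time-constant variant
  pc <- muscle_params(activation_scaling = "constant")
  expect_equal(activation_rate(0, 1, pc), 1 / 0.0945, tolerance = 1e-3)
  expect_equal(activation_rate(1, 0, pc), -1 / 0.065, tolerance = 1e-3)
})

test_that("state derivative matches torque arithmetic and symmetry", {
  p <- muscle_params()
  g <- arm_geometry()
  # symmetric state: no net torque
  d <- state_derivative(c(pi / 2, 0, 0.3, 0.3), 0.3, 0.3, p, g)
  expect_equal(unname(d[2]), 0, tolerance = 1e-12)
  # imbalance of 100 N -> domega/dt = r * 100 / I
  x <- c(pi / 2, 0, 0, 0)
  d0 <- state_derivative(x, 0, 0, p, g)
  # engineered: known active flexor force (passive parts cancel)
  Ff <- muscle_force(0.4, 1, 0, p) - muscle_force(0, 1, 0, p)
  dd <- state_derivative(c(pi / 2, 0, 0.4, 0), 0.4, 0, p, g)
  expect_equal(unname(dd[2] - d0[2]), 0.04 * Ff / 0.0688, tolerance = 1e-9)
  expect_equal(0.04 * 100 / 0.0688, 58.14, tolerance = 1e-4)
  # stretched extensor's passive force extends the arm when both muscles idle
  pc <- muscle_params(c1 = 0.09)
  de <- state_derivative(c(135 * pi / 180, 0, 0, 0), 0, 0, pc, g)
  expect_lt(de[2], 0)
})

test_that("RK4 stepping has 4th-order accuracy and preserves the length identity", {
  p <- muscle_params(c1 = 0.09)
  g <- arm_geometry()
  # fixed point: equilibrium activations, zero excitation equal to a, no motion
  eq <- make_equilibrium_case(0, pi / 2, muscle_params(c1 = 0))
  x <- c(pi / 2, 0, eq$a_flex, eq$a_ext)
  xn <- rk4_step(x, 0, 0, 0.005, muscle_params(c1 = 0), g)
  expect_equal(unname(xn), unname(x), tolerance = 1e-14)
  # convergence order: error vs a fine-step reference scales ~ dt^4
  x0 <- c(135 * pi / 180, 0, 0.1, 0.05)
  roll <- function(dt, Ttot = 0.02) {
    s <- x0
    for (i in seq_len(round(Ttot / dt))) s <- rk4_step(s, 1, 0.2, dt, p, g)
    s
  }
  ref <- roll(3.125e-4)
  errs <- sapply(c(5e-3, 2.5e-3, 1.25e-3), function(dt)
    max(abs(roll(dt) - ref)))
  order <- log2(errs[1] / errs[2])
  expect_gt(order, 3.5)
  order2 <- log2(errs[2] / errs[3])
  expect_gt(order2, 3.5)
  # kinematic identity holds at every step by construction
  tr <- forward_simulate(schedule = make_excitation("bang_bang", N = 20),
                         p = p, task = task_config())
  expect_equal(tr$l_flex + tr$l_ext, rep(2 * 0.32, nrow(tr)))
})

test_that("forward simulation honours trivial schedules", {
  g <- arm_geometry()
  task <- task_config()
  # zero excitation, no stiffness, start at rest: nothing moves
  p0 <- muscle_params(c1 = 0)
  tr <- forward_simulate(schedule = make_excitation("zero", N = 40),
                         p = p0, task = task)
  expect_equal(tr$theta, rep(task$theta_start, 41))
  expect_equal(tr$omega, rep(0, 41))
  # flexor step from 90 degrees: initial monotone flexion
  tr2 <- forward_simulate(x0 = c(pi / 2, 0, 0, 0),
                          schedule = make_excitation("step", N = 20),
                          p = p0, task = task)
  expect_true(all(diff(tr2$theta[1:10]) > 0))
})

test_that("activations stay in [0,1] under random excitation schedules", {
  p <- muscle_params(alpha_d = 0.065 * 0.15)  # fastest deactivation
  task <- task_config()
  set.seed(42)
  for (i in 1:100) {
    N <- 16
    sched <- tibble::tibble(u_flex = runif(N), u_ext = runif(N))
    x0 <- c(135 * pi / 180, 0, runif(1), runif(1))
    tr <- forward_simulate(x0 = x0, schedule = sched, p = p, task = task)
    expect_true(all(tr$a_flex >= -1e-12 & tr$a_flex <= 1 + 1e-12))
    expect_true(all(tr$a_ext >= -1e-12 & tr$a_ext <= 1 + 1e-12))
  }
})

test_that("mirror symmetry: swapped muscles and reflected angle give the reflected trajectory", {
  p <- muscle_params(c1 = 0.09)
  task <- task_config()
  g <- arm_geometry()
  sched <- make_excitation("triphasic", N = 40, seed = 7)
  x0 <- c(135 * pi / 180, 0, 0.1, 0.3)
  tr <- forward_simulate(x0 = x0, schedule = sched, p = p, task = task)
  x0m <- c(2 * g$theta0 - x0[1], 0, x0[4], x0[3])
  schedm <- tibble::tibble(u_flex = sched$u_ext, u_ext = sched$u_flex)
  trm <- forward_simulate(x0 = x0m, schedule = schedm, p = p, task = task)
  expect_equal(trm$theta, 2 * g$theta0 - tr$theta, tolerance = 1e-12)
  expect_equal(trm$a_flex, tr$a_ext, tolerance = 1e-12)
  expect_equal(trm$F_ext, tr$F_flex, tolerance = 1e-9)
})

test_that("angular momentum change equals the time integral of net torque", {
  p <- muscle_params(c1 = 0.09)
  g <- arm_geometry()
  # fine steps so the trapezoid quadrature resolves the RK4 integral
  task <- task_config(T = 0.05, dt = 5e-5)
  N <- task$N
  sched <- tibble::tibble(u_flex = rep(0.2, N), u_ext = rep(1, N))
  tr <- forward_simulate(x0 = c(135 * pi / 180, 0, 0, 0), schedule = sched,
                         p = p, task = task)
  torque <- g$r * (tr$F_flex - tr$F_ext)
  impulse <- sum(task$dt * (torque[-1] + torque[-(N + 1)]) / 2)
  dL <- g$I * (tr$omega[N + 1] - tr$omega[1])
  expect_equal(impulse, dL, tolerance = 1e-6)
})
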