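#' Full factorial parameter grid
#'
#' Cartesian product of the multiplier grids of the five ageing-related
#' parameters (4 x 4 x 7 x 7 x 5 = 3920 combinations), in deterministic
#' order: parameters nested alphabetically (`Fmax`, `alpha_a`, `alpha_d`,
#' `c1`, `vmax`), last varying fastest, values ascending.
#'
#' @param multipliers Named list of multiplier vectors; defaults to the
#'   study ranges (see [sweep_ranges()]).
#' @return A tibble with one row per combination: `trial`, multiplier
#'   columns (`*_mult`) and absolute parameter values.
#' @export
#' @examples
#' nrow(build_full_factorial())  # 3920
build_full_factorial <- function(multipliers = NULL) {
  if (is.null(multipliers)) {
    rng <- sweep_ranges()
    multipliers <- split(rng$multiplier, rng$parameter)
  }
  base <- c(Fmax = 1300, vmax = 1.6, alpha_a = 0.0945, alpha_d = 0.065,
            c1 = 0.05)
  nm <- sort(names(multipliers))
  grid <- tidyr::expand_grid(!!!setNames(
    lapply(nm, function(n) sort(multipliers[[n]])), paste0(nm, "_mult")))
  for (n in nm) grid[[n]] <- base[[n]] * grid[[paste0(n, "_mult")]]
  dplyr::mutate(grid, trial = dplyr::row_number(), .before = 1)
}

#' Fine grid over the deactivation-time x stiffness plane
#'
#' Grid varying only the deactivation time constant and the passive
#' stiffness scale over their sweep ranges (0.6 ms and 0.005-unit
#' increments by default), all other parameters at baseline. The grid
#' composition is explicit configuration: pass coarser steps for a quick
#' look at the plane.
#'
#' @param step_alpha_d Deactivation-time increment (s).
#' @param step_c1 Stiffness increment.
#' @param alpha_d_range,c1_range Inclusive ranges (s, unitless).
#' @return A tibble in the same shape as [build_full_factorial()].
#' @export
#' @examples
#' nrow(build_finer_grid(step_alpha_d = 0.030, step_c1 = 0.045))
build_finer_grid <- function(step_alpha_d = 0.0006, step_c1 = 0.005,
                             alpha_d_range = c(0.00975, 0.130),
                             c1_range = c(0, 0.09)) {
  stopifnot(step_alpha_d > 0, step_c1 > 0)
  ad <- seq(alpha_d_range[1], alpha_d_range[2], by = step_alpha_d)
  c1 <- seq(c1_range[1], c1_range[2], by = step_c1)
  grid <- tidyr::expand_grid(alpha_d = ad, c1 = c1)
  tibble::tibble(
    trial = seq_len(nrow(grid)),
    Fmax_mult = 1, alpha_a_mult = 1,
    alpha_d_mult = grid$alpha_d / 0.065,
    c1_mult = grid$c1 / 0.05, vmax_mult = 1,
    Fmax = 1300, alpha_a = 0.0945, alpha_d = grid$alpha_d,
    c1 = grid$c1, vmax = 1.6
  )
}

#' Solve every combination of a parameter grid
#'
#' Runs the point-to-point optimisation for each row of a parameter grid
#' and collects one metrics record per combination. The full factorial
#' uses the cold linear-length initial guess for every trial; the finer
#' grid is warm-started from the baseline-case solution
#' (`warm_start = "baseline"`). Non-convergent solves are retried once
#' from the baseline warm start, then flagged (never dropped). Output
#' depends only on the grid, so row order and chunking cannot change it.
#'
#' @param grid A tibble from [build_full_factorial()] or
#'   [build_finer_grid()] (columns `Fmax`, `vmax`, `alpha_a`, `alpha_d`,
#'   `c1`).
#' @param task A [task_config()].
#' @param g An [arm_geometry()].
#' @param control An [ocp_control()].
#' @param warm_start `"none"` (cold linear guess) or `"baseline"`.
#' @param tol_frac Band for the temporal metrics.
#' @param progress Print a line every `progress` trials (0 = quiet).
#' @param ... Extra arguments passed to [muscle_params()] (e.g.
#'   `activation_scaling`).
#' @return The grid with the [solution_metrics()] columns appended.
#' @export
run_sweep <- function(grid, task = task_config(), g = arm_geometry(),
                      control = ocp_control(),
                      warm_start = c("none", "baseline"),
                      tol_frac = 0.01, progress = 0, ...) {
  warm_start <- match.arg(warm_start)
  base_sol <- NULL
  get_base <- function() {
    if (is.null(base_sol))
      base_sol <<- solve_ocp(muscle_params(...), g = g, task = task,
                             control = control)
    base_sol
  }
  if (warm_start == "baseline") get_base()
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    p <- muscle_params(Fmax = grid$Fmax[i], vmax = grid$vmax[i],
                       alpha_a = grid$alpha_a[i], alpha_d = grid$alpha_d[i],
                       c1 = grid$c1[i], ...)
    guess <- if (warm_start == "baseline") get_base() else NULL
    sol <- solve_ocp(p, g = g, task = task, guess = guess, control = control)
    if (!sol$solver_status$converged) {
      sol2 <- solve_ocp(p, g = g, task = task, guess = get_base(),
                        control = control)
      if (sol2$J <= sol$J || sol2$solver_status$converged) sol <- sol2
    }
    if (progress > 0 && i %% progress == 0)
      message(sprintf("trial %d / %d", i, nrow(grid)))
    solution_metrics(sol, tol_frac = tol_frac)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}

#' Stiffness-neutral deactivation time
#'
#' Locates the deactivation time constant at which a small change in
#' passive stiffness leaves performance unchanged, by bisecting the sign
#' of `J_RMSE(c1_hi) - J_RMSE(c1_lo)` over a bracket of `alpha_d` (all
#' other parameters at baseline). Below the root, added stiffness helps
#' (fast deactivation releases the antagonist latch); above it, added
#' stiffness hurts.
#'
#' @param c1_pair The stiffness probe pair `c(lo, hi)` (default a
#'   0.01-unit change, 0.04 -> 0.05).
#' @param bracket `alpha_d` bracket (s).
#' @param tol Bisection tolerance on `alpha_d` (s).
#' @param task,g,control As in [run_sweep()].
#' @param rmse_fun Optional evaluator `function(alpha_d, c1) -> J_RMSE`
#'   replacing the optimal-control solves (used to validate the bisection
#'   against planted landscapes).
#' @param ... Passed to [muscle_params()].
#' @return A list: `alpha_d_star` (s), `evaluations` (tibble of probe
#'   solves), `iterations`.
#' @export
find_neutral_deactivation <- function(c1_pair = c(0.04, 0.05),
                                      bracket = c(0.00975, 0.130),
                                      tol = 5e-4,
                                      task = task_config(),
                                      g = arm_geometry(),
                                      control = ocp_control(),
                                      rmse_fun = NULL, ...) {
  if (is.null(rmse_fun)) {
    base <- solve_ocp(muscle_params(...), g = g, task = task,
                      control = control)
    rmse_fun <- function(ad, c1) {
      sol <- solve_ocp(muscle_params(alpha_d = ad, c1 = c1, ...),
                       g = g, task = task, guess = base, control = control)
      rmse_metric(sol$J_SSE, task$N, sol$params$l0)
    }
  }
  evals <- list()
  gfun <- function(ad) {
    js <- vapply(c1_pair, function(c1) {
      j <- rmse_fun(ad, c1)
      evals[[length(evals) + 1]] <<- tibble::tibble(
        alpha_d = ad, c1 = c1, J_RMSE = j)
      j
    }, numeric(1))
    js[2] - js[1]
  }
  lo <- bracket[1]; hi <- bracket[2]
  glo <- gfun(lo); ghi <- gfun(hi)
  if (sign(glo) == sign(ghi))
    stop("no sign change of the stiffness effect over the bracket")
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- gfun(mid)
    it <- it + 1L
    if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else { hi <- mid }
  }
  list(alpha_d_star = (lo + hi) / 2,
       evaluations = dplyr::bind_rows(evals), iterations = it)
}
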