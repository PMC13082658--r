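#' Normalised root-mean-square error of a solution
#'
#' Converts the summed squared muscle-length error `J_SSE` into the
#' root-mean-square positional error in units of the resting length:
#' `J_RMSE = sqrt(J_SSE / N) / (2 l0)`. The division by two makes the
#' metric read as the normalised error of one muscle (both muscles are
#' symmetric and contribute equally to `J_SSE`). The alternate reading
#' that instead halves `J_SSE` inside the root,
#' `sqrt(J_SSE / (2 N)) / l0`, is available via `reading`.
#'
#' @param J_SSE Summed squared error (m^2), >= 0.
#' @param N Number of nodes in the running cost.
#' @param l0 Resting length (m).
#' @param reading `"half_total"` (default) or `"per_muscle"`.
#' @return `J_RMSE` in units of `l0`.
#' @export
#' @examples
#' rmse_metric(0, 80, 0.32)
rmse_metric <- function(J_SSE, N, l0 = 0.32,
                        reading = c("half_total", "per_muscle")) {
  reading <- match.arg(reading)
  stopifnot(all(J_SSE >= 0), N > 0)
  switch(reading,
         per_muscle = sqrt(J_SSE / (2 * N)) / l0,
         half_total = sqrt(J_SSE / N) / (2 * l0))
}

#' Coactivation time series and mean
#'
#' Coactivation at each instant is the smaller of the two activations,
#' `a_c(t) = min(a_flex(t), a_ext(t))`; its mean is the time average over
#' the horizon (trapezoid rule over the nodes).
#'
#' @param a_flex,a_ext Activation samples at the nodes.
#' @param time Node times (s), equally or unequally spaced.
#' @return A list with `series` (tibble: `time`, `a_c`) and `mean`.
#' @export
#' @examples
#' coactivation(c(0.2, 0.2, 0.8), c(0.6, 0.6, 0.6), c(0, 0.1, 0.2))$mean
coactivation <- function(a_flex, a_ext, time) {
  a_c <- pmin(a_flex, a_ext)
  n <- length(time)
  mean_ac <- sum(diff(time) * (a_c[-1] + a_c[-n]) / 2) / (time[n] - time[1])
  list(series = tibble::tibble(time = time, a_c = a_c), mean = mean_ac)
}

# first crossing of |theta - target| into `band`, linearly interpolated
first_entry <- function(time, dev, band) {
  inside <- dev <= band
  if (inside[1]) return(time[1])
  k <- which(inside)[1]
  if (is.na(k)) return(NA_real_)
  # interpolate between k-1 (outside) and k (inside)
  f <- (dev[k - 1] - band) / (dev[k - 1] - dev[k])
  time[k - 1] + f * (time[k] - time[k - 1])
}

#' Time to target
#'
#' First time the joint angle enters a tolerance band around the target,
#' linearly interpolated between nodes. The band is a fraction `tol_frac`
#' of the total excursion (default 1%, i.e. 0.9 degrees for the 90-degree
#' task). Returns the horizon `T` if the band is never reached.
#'
#' @param time Node times (s).
#' @param theta Joint angle at the nodes (rad).
#' @param task A [task_config()].
#' @param tol_frac Band half-width as a fraction of the excursion.
#' @return `T_T` (s).
#' @export
time_to_target <- function(time, theta, task = task_config(),
                           tol_frac = 0.01) {
  band <- tol_frac * abs(task$theta_start - task$theta_target)
  dev <- abs(theta - task$theta_target)
  tt <- first_entry(time, dev, band)
  if (is.na(tt)) task$T else tt
}

#' Time to stable point
#'
#' Earliest time after which the joint angle stays inside the tolerance
#' band for the rest of the horizon (so overshoots that leave the band
#' push it later). Same band as [time_to_target()]; returns `T` if the
#' trajectory ends outside the band.
#'
#' @inheritParams time_to_target
#' @return `T_S` (s), with `T_S >= T_T`.
#' @export
time_to_stable <- function(time, theta, task = task_config(),
                           tol_frac = 0.01) {
  band <- tol_frac * abs(task$theta_start - task$theta_target)
  dev <- abs(theta - task$theta_target)
  n <- length(time)
  if (dev[n] > band) return(task$T)
  outside <- which(dev > band)
  if (length(outside) == 0) return(time[1])
  k <- max(outside)  # last node outside; entry is between k and k+1
  f <- (dev[k] - band) / (dev[k] - dev[k + 1])
  time[k] + f * (time[k + 1] - time[k])
}

#' Ballistic-phase fraction of the error
#'
#' Fraction of the summed squared positional error accrued at nodes up to
#' the time-to-target — i.e. how much of the performance metric is decided
#' during the ballistic approach rather than during stabilisation.
#'
#' @param trajectory A trajectory tibble.
#' @param task A [task_config()].
#' @param T_T Time to target (s), e.g. from [time_to_target()].
#' @param g An [arm_geometry()].
#' @return A fraction in `[0, 1]`.
#' @export
ballistic_fraction <- function(trajectory, task = task_config(), T_T,
                               g = arm_geometry()) {
  tgt <- muscle_lengths(task$theta_target, g)
  err <- (trajectory$l_flex - tgt$l_flex)^2 + (trajectory$l_ext - tgt$l_ext)^2
  keep <- if (task$include_node0) rep(TRUE, nrow(trajectory)) else
    seq_len(nrow(trajectory)) > 1
  tot <- sum(err[keep])
  if (tot == 0) return(1)
  sum(err[keep & trajectory$time <= T_T + 1e-12]) / tot
}

#' All scalar outcomes of one solution
#'
#' Computes the full per-solution metrics record: normalised RMSE, mean
#' coactivation, time to target, time to stable point, and the
#' ballistic-phase fraction of the error.
#'
#' @param sol An `ocp_solution`.
#' @param tol_frac Tolerance band for the temporal metrics.
#' @param reading RMSE reading, see [rmse_metric()].
#' @return A one-row tibble: `J_RMSE` (units of `l0`), `a_c_mean`, `T_T`,
#'   `T_S`, `J_RMSE_rel`, plus `J_SSE`, `J` and `converged`.
#' @export
solution_metrics <- function(sol, tol_frac = 0.01,
                             reading = c("half_total", "per_muscle")) {
  reading <- match.arg(reading)
  tr <- sol$trajectory
  co <- coactivation(tr$a_flex, tr$a_ext, tr$time)
  tt <- time_to_target(tr$time, tr$theta, sol$task, tol_frac)
  ts <- time_to_stable(tr$time, tr$theta, sol$task, tol_frac)
  tibble::tibble(
    J_RMSE = rmse_metric(sol$J_SSE, sol$task$N, sol$params$l0, reading),
    a_c_mean = co$mean,
    T_T = tt, T_S = ts,
    J_RMSE_rel = ballistic_fraction(tr, sol$task, tt, sol$geometry),
    J_SSE = sol$J_SSE, J = sol$J,
    converged = sol$solver_status$converged
  )
}
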