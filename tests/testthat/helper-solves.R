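# shared solve cache: expensive optimal-control solutions reused across
# test files (helpers are sourced once per test run)
ro_cache <- new.env(parent = emptyenv())

ro_task <- function() task_config()
ro_ctrl <- function() ocp_control()

# solve (or fetch) the sweep task for a multiplier combination
cached_solve <- function(Fmax_mult = 1, vmax_mult = 1, alpha_a_mult = 1,
                         alpha_d_mult = 1, c1_mult = 1, guess = NULL, ...) {
  key <- paste(Fmax_mult, vmax_mult, alpha_a_mult, alpha_d_mult, c1_mult,
               is.null(guess), sep = "|")
  if (is.null(ro_cache[[key]])) {
    p <- muscle_params(Fmax = 1300 * Fmax_mult, vmax = 1.6 * vmax_mult,
                       alpha_a = 0.0945 * alpha_a_mult,
                       alpha_d = 0.065 * alpha_d_mult,
                       c1 = 0.05 * c1_mult, ...)
    ro_cache[[key]] <- solve_ocp(p, task = ro_task(), guess = guess,
                                 control = ro_ctrl())
  }
  ro_cache[[key]]
}

# short-horizon task for plumbing tests where the physics does not matter
small_task <- function() task_config(T = 0.1)

# Table 2 multiplier grids
table2_mult <- list(
  Fmax = c(0.5, 0.8, 1.0, 1.5),
  vmax = c(0.75, 1.0, 1.5, 2.0),
  alpha_a = c(0.15, 0.25, 0.5, 0.75, 1.0, 1.5, 2.0),
  alpha_d = c(0.15, 0.25, 0.5, 0.75, 1.0, 1.5, 2.0),
  c1 = c(0, 0.6, 1.0, 1.4, 1.8)
)
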