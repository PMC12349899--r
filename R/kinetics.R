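# Motor mechanochemistry: rate laws and desk assays.
#
# Arm-level rates (an arm lumps N_h myosin heads):
#   binding   k_bind = 40 * N_h per second (given an admissible free site)
#   walking   k_w(F) = (v0 / step) * max(0, 1 - F / (F_st * N_h))
#   unbinding k_u(F) = k_u0 * exp(-F / F_cat), floored at 0.01 * k_u0
# F is the load opposing the walking direction, floored at zero. The linear
# force-velocity law reproduces the unloaded velocity v0 and the arm stall
# force F_st * N_h exactly; the exponential decrease of k_u with load gives
# catch-bond behavior. The walking step equals the binding-site spacing.

#' Motor kinetics strategy
#'
#' Bundles the walking and unbinding rate functions with their calibration
#' constants. The default strategy is a linear force-velocity relation with
#' catch-bond unbinding, calibrated to the unloaded velocity `v0`, the
#' per-head stall force `F_st` (arm stall `F_st * N_h`) and a
#' load-softened unbinding rate.
#'
#' @param params an `actomyo_params` object.
#' @return An object of class `motor_kinetics`: list with `k_w(F)`,
#'   `k_u(F)` (both vectorized over load F in pN), `k_bind_arm` (1/s),
#'   `step_size` (nm), `F_stall_arm` (pN).
#' @examples
#' kin <- motor_kinetics(default_params())
#' kin$k_w(0) * kin$step_size   # unloaded velocity, nm/s
#' kin$k_w(kin$F_stall_arm)     # 0 at stall
#' @export
motor_kinetics <- function(params = default_params()) {
  step <- params$site_spacing
  Fs <- params$F_st * params$N_h
  kw0 <- params$v0 / step
  ku0 <- params$k_u0
  Fc <- params$F_cat
  structure(list(
    k_w = function(F) kw0 * pmax(0, 1 - pmax(F, 0) / Fs),
    k_u = function(F) pmax(ku0 * exp(-pmax(F, 0) / Fc), 0.01 * ku0),
    k_bind_arm = params$k_bind_per_head * params$N_h,
    step_size = step,
    F_stall_arm = Fs
  ), class = "motor_kinetics")
}

#' Stall load of a motor arm
#'
#' Ramps a static opposing load on a bound arm and reports the smallest
#' load at which the walking rate reaches zero.
#'
#' @param params an `actomyo_params` object.
#' @param dF load increment of the ramp (pN).
#' @return The stall load (pN). Divide by `params$N_h` for the per-head
#'   stall force.
#' @examples
#' stall_load(default_params()) / 8  # per-head stall, pN
#' @export
stall_load <- function(params = default_params(), dF = 0.01) {
  kin <- motor_kinetics(params)
  F <- seq(0, 4 * kin$F_stall_arm, by = dF)
  k <- kin$k_w(F)
  i <- which(k <= 0)[1]
  if (is.na(i)) stop("walking rate never reached zero on the ramp")
  F[i]
}

#' Unloaded gliding assay
#'
#' Simulates a single bound arm walking along a long straight filament
#' with the load clamped to zero and unbinding disabled, using the same
#' per-tick stepping probability `1 - exp(-k_w(0) dt)` as the full engine,
#' and returns the mean velocity.
#'
#' @param params an `actomyo_params` object.
#' @param nsteps number of time ticks (use >= 1e6 for ~5% precision;
#'   the default gives ~3 nm/s standard error).
#' @param load static opposing load (pN) held on the arm.
#' @return list with `velocity` (nm/s), `distance` (nm), `time` (s),
#'   `n_steps_taken`.
#' @export
gliding_assay <- function(params = default_params(), nsteps = 5e6, load = 0) {
  kin <- motor_kinetics(params)
  p <- 1 - exp(-kin$k_w(load) * params$dt)
  # per-tick Bernoulli stepping, drawn in chunks from R's RNG
  taken <- 0
  left <- nsteps
  while (left > 0) {
    m <- min(left, 1e6)
    taken <- taken + sum(stats::runif(m) < p)
    left <- left - m
  }
  tt <- nsteps * params$dt
  d <- taken * kin$step_size
  list(velocity = d / tt, distance = d, time = tt, n_steps_taken = taken)
}

#' Per-step event probability
#'
#' Probability that an event with rate `rate` fires within one kinetics
#' tick: `1 - exp(-rate * dt_eff)`.
#'
#' @param rate event rate (1/s).
#' @param params an `actomyo_params` object.
#' @param ticks number of integration steps per kinetics evaluation.
#' @return probability in `[0, 1]`.
#' @export
event_probability <- function(rate, params = default_params(), ticks = 1) {
  1 - exp(-rate * params$dt * ticks)
}

#' Sample stochastic event waiting times
#'
#' Draws waiting times from the discrete per-tick Bernoulli process used by
#' the engine (geometric number of ticks times `dt`). At the default time
#' step every per-tick probability is far below 1, so the waiting times are
#' exponential to high accuracy; tests verify this against the continuous
#' law with a Kolmogorov-Smirnov check.
#'
#' @param rate event rate (1/s).
#' @param params an `actomyo_params` object.
#' @param n number of events.
#' @return numeric vector of waiting times (s).
#' @export
sample_event_times <- function(rate, params = default_params(), n = 1e4) {
  p <- 1 - exp(-rate * params$dt)
  (stats::rgeom(n, p) + 1) * params$dt
}
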