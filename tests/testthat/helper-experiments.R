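# Experiment drivers shared by the acceptance-level tests.

# One two-filament run: classify the initial motor/ACP arrangement
# (the placement determines which force limit the pair approaches),
# then simulate and measure.
run_two_filament_seed <- function(seed, t_production = 10) {
  set.seed(seed)
  st <- build_system(preset("two_filament_desk"))
  sp <- motor_spans(st)
  lo <- sp$center - sp$half_length
  hi <- sp$center + sp$half_length
  acp_z <- acp_tensions(st)$z
  separated <- max(lo) > min(hi)
  gap <- c(min(hi), max(lo))
  n_between <- if (separated) sum(acp_z > gap[1] & acp_z < gap[2]) else 0L
  union_reg <- c(min(lo), max(hi))
  n_inside <- sum(acp_z > union_reg[1] & acp_z < union_reg[2])
  cls <- if (separated && n_between > 0) "decoupled"
         else if (n_inside == 0) "cooperative"
         else "intermediate"
  st <- advance(st, 1e4, freeze_actin = TRUE, walk = FALSE,
                unbind = FALSE)$state
  run <- advance(st, ceiling(t_production / st$params$dt),
                 record_every = 5000)
  m <- measure_run(run$state, run$snapshots)
  at <- acp_tensions(run$state)
  between <- separated & at$z > gap[1] & at$z < gap[2]
  list(eta = m$eta, class = cls, n_between = n_between,
       tension_between = at$tension[between],
       tension_other = at$tension[!between])
}

run_bundle_seed <- function(seed, t_production = 9) {
  set.seed(seed)
  r <- simulate_system("bundle_desk", t_production = t_production)
  r$measurement$eta
}
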