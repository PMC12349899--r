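# Motor mechanochemistry: rate laws, binding rules, walking and unbinding.

test_that("kinetics strategy reproduces its calibration observables", {
  kin <- motor_kinetics(default_params())
  # unloaded velocity: k_w(0) * step = v0
  expect_equal(kin$k_w(0) * kin$step_size, 140)
  # arm stall force F_st * N_h, zero walking at and beyond stall
  expect_equal(kin$F_stall_arm, 45.6)
  expect_equal(kin$k_w(kin$F_stall_arm), 0)
  expect_equal(kin$k_w(2 * kin$F_stall_arm), 0)
  # linear force-velocity: half load, half speed
  expect_equal(kin$k_w(kin$F_stall_arm / 2) * kin$step_size, 70)
  # both rates non-increasing in load (catch-bond unbinding)
  F <- seq(0, 2 * kin$F_stall_arm, by = 0.1)
  expect_true(all(diff(kin$k_w(F)) <= 1e-12))
  expect_true(all(diff(kin$k_u(F)) <= 1e-12))
  expect_equal(kin$k_u(0), 20)
  # floored, never exactly zero
  expect_gte(min(kin$k_u(F)), 0.2)
})

test_that("stall load ramp gives the per-head stall force", {
  expect_equal(stall_load(default_params()) / 8, 5.7, tolerance = 1e-3)
})

test_that("per-step binding probability matches the stated rate", {
  p <- default_params()
  # 8 heads at 40/s each -> 320/s -> 1 - exp(-320 dt)
  expect_equal(event_probability(320, p), 3.673e-3, tolerance = 1e-3)
})

test_that("unloaded gliding reproduces the walking velocity", {
  set.seed(8)
  g <- gliding_assay(nsteps = 1e6)
  expect_equal(g$velocity, 140, tolerance = 0.15)
  # at stall the arm does not move
  g0 <- gliding_assay(nsteps = 1e4, load = 45.6)
  expect_equal(g0$velocity, 0)
})

test_that("event waiting times are exponential", {
  set.seed(31)
  p <- default_params()
  for (rate in c(20, 320)) {
    tt <- sample_event_times(rate, p, n = 1e4)
    ks <- suppressWarnings(stats::ks.test(tt, stats::pexp, rate = rate))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("arms only bind filaments matching their walking polarity", {
  # one filament with its barbed end at low z: only arms walking toward -z
  # (left side of a +z-oriented backbone) may bind
  set.seed(4)
  p <- default_params()
  st <- new_state(p, box_um = c(2, 2, 4), boundary = rep("open", 3))
  st <- add_filament(st, build_filament(2800, c(1000, 1000, 500),
                                        c(0, 0, 1), p))
  st <- add_motor(st, build_motor(24, 42, 42), c(1013.5, 1000, 1900),
                  c(0, 0, 1))
  r <- advance(st, 5000, freeze_actin = TRUE, walk = FALSE, unbind = FALSE)
  arms <- r$state$arms
  expect_gt(sum(arms$bound), 0)
  expect_true(all(arms$side[arms$bound] == "L"))
})

test_that("two arms sharing an anchor never bind the same filament", {
  set.seed(12)
  st <- build_two_filament_system(
    system_spec("two_filament", box_um = c(5, 5, 8), filament_um = 6,
                N_M = 2, N_ACP = 0))
  r <- advance(st, 8000, freeze_actin = TRUE, walk = FALSE, unbind = FALSE)
  arms <- r$state$arms
  fil_of <- r$state$seg$fil
  for (anchor in unique(arms$anchor)) {
    q <- which(arms$anchor == anchor & arms$bound)
    if (length(q) == 2)
      expect_false(fil_of[arms$seg[q[1]]] == fil_of[arms$seg[q[2]]])
  }
  # with two antiparallel filaments at most half the arms can engage
  expect_lte(sum(arms$bound), nrow(arms) / 2)
})

test_that("site occupancy is exclusive and consistent with arm state", {
  set.seed(13)
  st <- build_two_filament_system(
    system_spec("two_filament", box_um = c(5, 5, 8), filament_um = 6,
                N_M = 2, N_ACP = 6))
  r <- advance(st, 20000, record_every = 0)
  st1 <- r$state
  # every bound arm's site is marked with its own code
  b <- which(st1$arms$bound)
  keys <- paste(st1$arms$seg[b], st1$arms$site[b])
  expect_false(any(duplicated(keys)))
  for (q in b)
    expect_equal(st1$occ[st1$arms$seg[q], st1$arms$site[q]], q + 1L)
  # cross-linker sites stay marked
  for (q in seq_len(nrow(st1$acps))) {
    expect_equal(st1$occ[st1$acps$seg1[q], st1$acps$site1[q]], 1L)
    expect_equal(st1$occ[st1$acps$seg2[q], st1$acps$site2[q]], 1L)
  }
})

test_that("bound arms walk monotonically toward the barbed end", {
  set.seed(21)
  p <- default_params()
  st <- new_state(p, box_um = c(2, 2, 4), boundary = rep("open", 3))
  st <- add_filament(st, build_filament(2800, c(1000, 1000, 500),
                                        c(0, 0, 1), p))
  st <- add_motor(st, build_motor(8, 42, 42), c(1013.5, 1000, 1900),
                  c(0, 0, 1))
  st <- advance(st, 5000, freeze_actin = TRUE, walk = FALSE,
                unbind = FALSE)$state
  expect_gt(sum(st$arms$bound), 0)
  # freeze actin and walk without unbinding: the axial coordinate
  # (segment, site) must never increase
  r <- advance(st, 30000, record_every = 1000, freeze_actin = TRUE,
               bind = FALSE, unbind = FALSE)
  for (arm in which(st$arms$bound)) {
    coord <- vapply(r$snapshots, function(sn)
      (sn$arms$seg[arm] - 1) * 20 + sn$arms$site[arm], 0)
    expect_true(all(diff(coord) <= 0))
  }
  # and walking stops at the barbed-end terminal site
  expect_true(all(vapply(r$snapshots, function(sn)
    all(sn$arms$seg[sn$arms$bound] >= 1), TRUE)))
})
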