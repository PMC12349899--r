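test_that("default parameters satisfy the model invariants", {
  p <- default_params()
  expect_gt(p$dt, 0)
  expect_equal(p$r0_A, 140)
  expect_equal(p$r0_ACP, 23.5)
  expect_equal(p$L_MB, 42)
  expect_equal(p$r0_M2, 13.5)
  expect_identical(p$r0_M3, 0)
  expect_equal(p$site_spacing, 7)
  expect_equal(p$N_h, 8)
  expect_equal(p$F_st, 5.7)
  expect_equal(p$v0, 140)
  expect_equal(p$Lp_A, 9)
  # bending stiffness is derived from the persistence length, not free
  expect_equal(p$kappa_b_A, p$Lp_A * 1e-6 * p$kBT / (p$r0_A * 1e-9))
  expect_true(all(c(p$theta0_A, p$theta0_ACP, p$theta0_M) == 0))
  expect_error(default_params(no_such_knob = 1), "unknown parameter")
  # overriding the persistence length re-derives kappa_b_A
  p2 <- default_params(Lp_A = 18)
  expect_equal(p2$kappa_b_A, 2 * p$kappa_b_A)
})

test_that("parameter validation rejects broken sets", {
  p <- default_params()
  p$dt <- -1
  expect_error(validate_params(p), "dt")
  p <- default_params()
  p$r0_M3 <- 5
  expect_error(validate_params(p), "r0_M3")
  p <- default_params()
  p$kappa_b_A <- p$kappa_b_A * 2
  expect_error(validate_params(p), "kappa_b_A")
})

test_that("parameter sets round-trip through YAML and JSON configs", {
  p <- default_params(N_h = 4, mu = 0.5)
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("cfg.", ext))
    write_params(p, path)
    q <- read_params(path)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  }
  # unknown keys are rejected
  path <- file.path(tempdir(), "bad.json")
  x <- unclass(p)
  x$typo_key <- 1
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  expect_error(read_params(path), "typo_key")
})

test_that("motor construction reproduces the reference architectures", {
  m <- build_motor(24, 42, 42)
  expect_equal(m$n_seg, 11)
  expect_equal(m$L_M, 462)
  expect_equal(nrow(m$arm_table), 24)
  m4 <- build_motor(4, 42, 42)
  expect_equal(m4$n_seg, 1)
  expect_equal(m4$L_M, 42)
  # the single bare-zone segment's endpoints carry the arms
  expect_setequal(unique(m4$arm_table$vertex), c(1, 2))
  m16 <- build_motor(16, 714, 42)
  expect_equal(m16$L_M, 2 * 42 * 3 + 714)
  expect_equal(m16$L_M, 966)
  expect_error(build_motor(10, 42, 42), "divisible by 4")
  expect_error(build_motor(24, -42, 42), "positive")
})

test_that("motor length law and arm budget hold across architectures", {
  cases <- expand.grid(N_a = c(4, 8, 16, 24, 48),
                       L_sp = c(42, 84, 138))
  for (q in seq_len(nrow(cases))) {
    N_a <- cases$N_a[q]; L_sp <- cases$L_sp[q]
    for (L_bz in c(L_sp, 3 * L_sp)) {
      m <- build_motor(N_a, L_bz, L_sp)
      expect_equal(m$L_M, 2 * L_sp * (N_a / 4 - 1) + L_bz)
      expect_equal(nrow(m$arm_table), N_a)
      expect_equal(sum(m$arm_table$side == "L"), N_a / 2)
      # mirror symmetry about the bare-zone center
      v <- m$arm_table$vertex
      expect_setequal(v, m$n_vert + 1L - v)
      # every arm-bearing vertex carries exactly two arms
      expect_true(all(table(v) == 2))
    }
  }
})

test_that("filament construction rounds to the nearest whole segment", {
  expect_equal(build_filament(140)$n_seg, 1)
  expect_equal(build_filament(9000)$n_seg, 64)   # round(64.29)
  expect_equal(build_filament(19000)$n_seg, 136) # round(135.7)
  expect_error(build_filament(100), "at least one segment")
  f <- build_filament(1400, c(1, 2, 3), c(1, 0, 0))
  expect_equal(nrow(f$coords), 11)
  # colinear along the direction, barbed end at the origin
  expect_equal(f$coords[1, ], c(1, 2, 3))
  expect_equal(unname(diff(f$coords[, 1])), rep(140, 10))
  expect_equal(sd(f$coords[, 2]), 0)
})

test_that("each segment carries floor(r0_A / site_spacing) binding sites", {
  st <- fixture_filament_state(n_seg = 3)
  expect_equal(ncol(st$occ), 20)
  expect_equal(nrow(st$occ), 3)
  expect_true(all(st$occ == 0))
})

test_that("cylinder drag follows the approximate form", {
  mu <- 1e-3
  # sphere-like limit r0 = rc: factor (3 + 2)/5 = 1
  expect_equal(drag_coefficient(7, 7, mu), 3 * pi * mu * 7e-9)
  z <- drag_coefficient(140, 7, mu)
  expect_equal(z, 3 * pi * mu * 7e-9 * 43 / 5, tolerance = 1e-12)
  expect_equal(z, 5.67e-10, tolerance = 2e-3)
  expect_equal(drag_coefficient(140, 7, 2 * mu), 2 * z)
  expect_error(drag_coefficient(-1, 7, mu), "> 0")
})

test_that("point forces distribute linearly onto segment endpoints", {
  F <- c(3, -1, 2)
  d <- distribute_to_endpoints(F, 0.5)
  expect_equal(d$barbed, F / 2)
  expect_equal(d$pointed, F / 2)
  d0 <- distribute_to_endpoints(F, 0)
  expect_equal(d0$barbed, F)
  expect_equal(d0$pointed, c(0, 0, 0))
  for (s in c(0.1, 0.37, 0.93)) {
    d <- distribute_to_endpoints(F, s)
    expect_equal(d$barbed + d$pointed, F)
  }
  expect_error(distribute_to_endpoints(F, 1.2), "\\[0, 1\\]")
})
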