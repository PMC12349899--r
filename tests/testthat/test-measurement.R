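# Cross-section tension measurement and steady-state detection.

test_that("plane layout follows the measurement protocol", {
  p <- default_params()
  st <- new_state(p, box_um = c(5, 5, 20))
  # 20-um domain at 200-nm spacing -> 100 planes
  cs <- cross_section_forces(st, "z", spacing = 200)
  expect_equal(nrow(cs), 100)
  # network protocol: 20 planes per axis
  stn <- new_state(p, box_um = c(20, 20, 0.1))
  expect_equal(nrow(cross_section_forces(stn, "x", n_planes = 20)), 20)
  expect_equal(nrow(cross_section_forces(stn, "y", n_planes = 20)), 20)
  expect_error(cross_section_forces(st, "z", spacing = -5), "spacing")
})

test_that("a stretched spring crossing a plane registers its tension", {
  p <- default_params(kappa_s_A = 1e-3)
  st <- new_state(p, box_um = c(2, 2, 2), boundary = rep("open", 3))
  st <- add_filament(st, build_filament(140, c(1000, 1000, 850),
                                        c(0, 0, 1), p))
  st$pos[2, 3] <- st$pos[2, 3] + 30   # 30 nm extension -> 30 pN tension
  cs <- cross_section_forces(st, "z", spacing = 200)
  crossing <- cs$plane > 850 & cs$plane < 1020
  expect_equal(sum(crossing), 1)
  expect_true(all(abs(cs$actin[crossing] - 30) < 1e-9))
  expect_true(all(cs$total[!crossing] == 0))
  # compression counts negative
  st$pos[2, 3] <- st$pos[2, 3] - 60   # 30 nm compression
  cs <- cross_section_forces(st, "z", spacing = 200)
  expect_true(all(abs(cs$actin[cs$plane > 850 & cs$plane < 960] + 30) < 1e-9))
  # an oblique spring contributes its axial component only
  st2 <- new_state(p, box_um = c(2, 2, 2), boundary = rep("open", 3))
  d <- c(3, 0, 4) / 5
  st2 <- add_filament(st2, build_filament(140, c(1000, 1000, 850), d, p))
  v <- st2$fils[[1]]
  st2$pos[v[2], ] <- st2$pos[v[1], ] + (140 + 25) * d
  cs2 <- cross_section_forces(st2, "z", spacing = 200)
  expect_equal(max(cs2$actin), 25 * abs(d[3]), tolerance = 1e-9)
})

test_that("a freshly built system carries no tension", {
  set.seed(25)
  st <- build_two_filament_system(
    system_spec("two_filament", box_um = c(5, 5, 8), filament_um = 6,
                N_M = 2, N_ACP = 6))
  cs <- cross_section_forces(st, "z", spacing = 200)
  expect_lt(max(abs(cs$total)), 1)   # pN; below any motor force scale
})

test_that("minimum-image crossing is honored on periodic axes", {
  p <- default_params(kappa_s_A = 1e-3)
  st <- new_state(p, box_um = c(2, 2, 2), boundary = rep("periodic", 3))
  # a bond spanning the z boundary: from z = 1950 wrapping to z = 160
  # (rest 140 nm stretched to 210 -> 70 pN)
  av <- actomyosim:::.add_vertices(st, rbind(c(1000, 1000, 1950),
                                             c(1000, 1000, 160)), 0L)
  st <- av$state
  st$bonds <- rbind(st$bonds, data.frame(i = 1L, j = 2L, r0 = 140,
                                         ks = 1e-3, cat = 1L))
  cs <- cross_section_forces(st, "z", spacing = 200)
  hit <- cs$plane > 1950 | cs$plane < 160
  expect_true(all(abs(cs$actin[hit] - 70) < 1e-9))
  expect_true(all(cs$actin[!hit] == 0))
})

test_that("steady-state detection finds plateaus and flags failures", {
  t <- seq(0, 10, length.out = 120)
  # constant series: the whole series qualifies
  w <- steady_state_window(t, rep(5, 120))
  expect_true(w$qualified)
  expect_equal(w$t_start, 0)
  # ramp then plateau: the window starts at the plateau onset (+- 2 frames)
  v <- c(seq(0, 100, length.out = 60), rep(100, 60))
  w2 <- steady_state_window(t, v)
  expect_true(w2$qualified)
  expect_lt(abs(w2$idx[1] - 60), 4)
  expect_equal(w2$t_end, t[120])
  # pure noise about a mean qualifies
  set.seed(30)
  w3 <- steady_state_window(t, 50 + rnorm(120, 0, 2))
  expect_true(w3$qualified)
  # a relentless ramp does not; the tail fallback is flagged
  w4 <- steady_state_window(t, seq(1, 100, length.out = 120))
  expect_false(w4$qualified)
  expect_error(steady_state_window(t[1:20], rep(1, 20)), "too short")
})

test_that("total force and efficiency follow their definitions", {
  mk <- function(v) data.frame(plane = 1:5, total = v)
  frames <- replicate(12, mk(rep(7, 5)), simplify = FALSE)
  expect_equal(total_force(frames), 7)
  expect_error(total_force(frames[1:5]), "shorter than 10")
  expect_equal(efficiency(273.6, 547.2), 0.5)
  expect_equal(efficiency(1, 1), 1)
  expect_error(efficiency(1, 0), "F_M_max")
})

test_that("motor force accounting splits by mode and motor", {
  st <- fixture_full_state()
  # displace the anchor to put a known force on the bound arm
  arm <- which(st$arms$bound)[1]
  av <- st$arms$anchor[arm]
  f <- compute_forces(st)
  fs <- actomyosim:::.arm_site_forces(st)
  expect_equal(fs$f_site[arm, ], f$arm[av, ] * -1, tolerance = 1e-9)
  mm <- motor_max_force(st, "bundle")
  expect_equal(mm$F_M_max, sum(abs(fs$f_site[arm, 3])) / 2)
  mn <- motor_max_force(st, "network")
  expect_equal(mn$F_M_max,
               (abs(fs$f_site[arm, 1]) + abs(fs$f_site[arm, 2])) / 4)
  st$arms$bound[arm] <- FALSE
  st$motors <- list()
  expect_error(motor_max_force(st), "no motors")
})
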