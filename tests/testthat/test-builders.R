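# System builders: counts, geometry, placement distributions and
# reproducibility.

test_that("the two-filament system matches the reference construction", {
  set.seed(2)
  st <- build_two_filament_system()
  expect_equal(length(st$fils), 2)
  # 19 um -> 136 segments per filament
  expect_equal(as.integer(table(st$seg$fil)), c(136L, 136L))
  expect_equal(length(st$motors), 2)
  expect_equal(nrow(st$arms), 48)
  expect_equal(nrow(st$acps), 16)
  # barbed ends clamped to opposite z boundaries
  barbed <- vapply(st$fils, function(v) v[1], 1L)
  expect_true(all(st$clamped[barbed]))
  expect_equal(sort(st$pos[barbed, 3]), c(0, 20000))
  # antiparallel polarity
  tz <- vapply(seq_along(st$fils), function(q) {
    v <- st$fils[[q]]; sign(st$pos[v[2], 3] - st$pos[v[1], 3])
  }, 0)
  expect_equal(sort(tz), c(-1, 1))
  # motors-only control is valid
  st0 <- build_two_filament_system(
    system_spec("two_filament", N_ACP = 0))
  expect_equal(nrow(st0$acps), 0)
  # a filament longer than the domain is rejected
  expect_error(build_two_filament_system(
    system_spec("two_filament", box_um = c(5, 5, 10), filament_um = 19)),
    "longer than the domain")
})

test_that("random placements differ across seeds but not within a seed", {
  mk <- function(seed) {
    set.seed(seed)
    build_two_filament_system(system_spec("two_filament",
                                          box_um = c(5, 5, 8),
                                          filament_um = 6, N_ACP = 4))
  }
  a <- mk(1); b <- mk(1); c <- mk(2)
  expect_identical(a$pos, b$pos)
  expect_identical(a$acps, b$acps)
  expect_false(identical(a$pos, c$pos))
})

test_that("bundles hold 2 N_F^2 filaments on a 27-nm lane grid", {
  set.seed(6)
  st2 <- build_bundle(system_spec("bundle", N_F = 2, N_M = 0, N_ACP = 0,
                                  filament_um = 6, box_um = c(5, 5, 14)))
  expect_equal(length(st2$fils), 8)
  st7 <- build_bundle(system_spec("bundle", N_F = 7, N_M = 0, N_ACP = 0,
                                  filament_um = 6, box_um = c(5, 5, 14)))
  expect_equal(length(st7$fils), 98)
  expect_equal(length(st7$fils) / length(st2$fils), 12.25)
  # lane pitch 27 nm
  xs <- sort(unique(round(st7$pos[st7$vtype == 0L, 1], 6)))
  expect_equal(unique(round(diff(xs), 6)), 27)
  expect_equal(length(xs), 7)
})

test_that("bundle polarities are balanced across seeds", {
  set.seed(9)
  ups <- 0; tot <- 0
  for (rep in 1:6) {
    st <- build_bundle(system_spec("bundle", N_F = 4, N_M = 0, N_ACP = 0,
                                   filament_um = 6, box_um = c(5, 5, 14)))
    tz <- vapply(seq_along(st$fils), function(q) {
      v <- st$fils[[q]]
      d <- st$pos[v[2], 3] - st$pos[v[1], 3]
      d <- d - 14000 * round(d / 14000)
      sign(d)
    }, 0)
    ups <- ups + sum(tz > 0); tot <- tot + length(tz)
  }
  # 192 draws at p = 0.5: allow 4 binomial sigmas
  expect_lt(abs(ups / tot - 0.5), 4 * sqrt(0.25 / tot))
})

test_that("motor localization respects the f-interval", {
  set.seed(14)
  p <- default_params()
  base <- build_bundle(system_spec("bundle", N_F = 2, N_M = 0, N_ACP = 0,
                                   filament_um = 9, box_um = c(5, 5, 20)))
  # f = 0.06 on a 20-um box: centers within [9.4, 10.6] um
  st <- place_binders(base, N_M = 30, N_ACP = 0, f = 0.06)
  sp <- motor_spans(st)
  expect_true(all(sp$center > 9400 - 231 & sp$center < 10600 + 231))
  # f = 1: centers uniform over the box (KS against uniform)
  set.seed(15)
  st1 <- place_binders(base, N_M = 60, N_ACP = 0, f = 1)
  ctr <- vapply(seq_along(st1$motors), function(m) {
    v <- st1$motors[[m]]$vertices
    z <- st1$pos[v, 3]
    if (diff(range(z)) > 10000) z <- (z + 10000) %% 20000  # unwrap
    mean(range(z)) %% 20000
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ctr, "punif", 0, 20000))
  expect_gt(ks$p.value, 0.01)
  expect_error(place_binders(base, 1, 0, f = 0), "f must")
})

test_that("network growth calibrates to ~10 um mean filament length", {
  set.seed(19)
  p <- default_params()
  mean_seg <- 10000 / p$r0_A
  target <- round(250 * mean_seg)   # enough mass for >= 200 filaments
  k_p <- calibrate_polymerization(p$k_n_A, target, mean_seg)
  lens <- grow_filament_lengths(p$k_n_A, k_p, target)
  expect_gte(length(lens), 200)
  mean_um <- mean(lens) * p$r0_A / 1000
  expect_gt(mean_um, 9); expect_lt(mean_um, 11)
})

test_that("network filaments and motors lie in the plane", {
  set.seed(20)
  spec <- system_spec("network", box_um = c(6, 6, 0.1), N_M = 3,
                      N_ACP = 0, target_length_um = 1.5,
                      total_actin_um = 20)
  st <- build_network(spec)
  # all filament tangents perpendicular to z
  for (v in st$fils) {
    d <- diff(st$pos[v, 3])
    d <- d - 100 * round(d / 100)
    expect_lt(max(abs(d)), 1e-6)
  }
  expect_equal(length(st$motors), 3)
  # in-plane motor axes
  for (m in st$motors) {
    dz <- diff(st$pos[m$vertices, 3])
    expect_lt(max(abs(dz)), 1e-6)
  }
})

test_that("cross-linkers always join two distinct filaments at free sites", {
  set.seed(22)
  st <- build_bundle(system_spec("bundle", N_F = 2, N_M = 0, N_ACP = 40,
                                 filament_um = 6, box_um = c(5, 5, 14)))
  expect_equal(nrow(st$acps), 40)
  f1 <- st$seg$fil[st$acps$seg1]
  f2 <- st$seg$fil[st$acps$seg2]
  expect_true(all(f1 != f2))
  # both arms near their rest length by construction
  p <- st$params
  for (q in seq_len(nrow(st$acps))) {
    ctr <- st$pos[st$acps$center[q], ]
    for (arm in 1:2) {
      sp <- actomyosim:::.site_pos_m(
        st, st$pos, st$acps[[paste0("seg", arm)]][q],
        st$acps[[paste0("site", arm)]][q])
      r <- sqrt(sum(actomyosim:::.mi_vec(sp - ctr, st)^2))
      expect_equal(r, p$r0_ACP, tolerance = 0.05)
    }
  }
  # zero linkers is a valid control
  st0 <- init_crosslinks(st, 0)
  expect_identical(nrow(st0$acps), nrow(st$acps))
})
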