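# Deterministic force field: every term must equal minus the gradient of
# its potential, pairwise terms must obey Newton's third law, and the
# repulsion must vanish identically beyond its cutoff.

test_that("forces equal minus the finite-difference energy gradient", {
  set.seed(42)
  for (rep in 1:3) {
    st <- fixture_filament_state(n_seg = 4, jitter = 15)
    f <- compute_forces(st)$total
    g <- numerical_gradient(st)
    scale <- max(abs(f))
    expect_gt(scale, 0)
    expect_lt(max(abs(f + g)) / scale, 1e-5)
  }
})

test_that("gradient oracle holds with cross-linkers and bound motor arms", {
  set.seed(7)
  for (rep in 1:3) {
    st <- fixture_full_state(jitter = 6)
    f <- compute_forces(st)$total
    g <- numerical_gradient(st)
    scale <- max(abs(f))
    expect_gt(scale, 0)
    expect_lt(max(abs(f + g)) / scale, 1e-5)
  }
})

test_that("internal forces sum to zero (Newton's third law)", {
  set.seed(11)
  st <- fixture_full_state(jitter = 8)
  f <- compute_forces(st)
  # no walls in an open box, so the total must vanish
  expect_equal(max(abs(f$wall)), 0)
  tot <- colSums(f$total)
  expect_lt(sqrt(sum(tot^2)), 1e-9 * sum(sqrt(rowSums(f$total^2))) + 1e-12)
  # each category is internally balanced too
  for (cat in c("stretch", "bend", "acp", "arm", "repulsion"))
    expect_lt(max(abs(colSums(f[[cat]]))), 1e-9)
})

test_that("stretching restores the rest length with the right magnitude", {
  p <- default_params(kappa_s_A = 1e-3)
  st <- fixture_filament_state(n_seg = 1, params = p)
  st$pos[2, 3] <- st$pos[1, 3] + p$r0_A + 10   # stretch by 10 nm
  f <- compute_forces(st)
  # kappa_s = 1e-3 N/m over 10 nm -> 10 pN restoring, equal and opposite
  expect_equal(f$stretch[2, 3], -10, tolerance = 1e-10)
  expect_equal(f$stretch[1, 3], 10, tolerance = 1e-10)
  st$pos[2, 3] <- st$pos[1, 3] + p$r0_A        # at rest: zero force
  expect_equal(max(abs(compute_forces(st)$total)), 0)
})

test_that("bending is zero when straight and restoring when perturbed", {
  st <- fixture_filament_state(n_seg = 2)
  expect_equal(max(abs(compute_forces(st)$bend)), 0)
  # small lateral displacement of the middle vertex
  st$pos[2, 1] <- st$pos[2, 1] + 2
  f <- compute_forces(st)$bend
  expect_lt(f[2, 1], 0)               # pushes back toward straight
  expect_equal(sum(f[, 1]), 0, tolerance = 1e-12)
  # restoring torque ~ kappa_b * theta for small angles
  theta <- 2 * (2 / 140)
  kb <- default_params()$kappa_b_A * 1e21  # pN nm
  expect_equal(-f[2, 1] * 140 / 2, kb * theta, tolerance = 0.01)
})

test_that("energy decreases monotonically under noise-free relaxation", {
  set.seed(3)
  st <- fixture_filament_state(n_seg = 5, jitter = 20)
  e0 <- potential_energy(st)
  e <- e0
  for (it in 1:8) {
    st <- advance(st, 200, thermal = FALSE, bind = FALSE,
                  walk = FALSE, unbind = FALSE)$state
    e2 <- potential_energy(st)
    expect_lte(e2, e + 1e-9)
    e <- e2
  }
  expect_lt(e, 0.05 * e0)
})

test_that("actin repulsion is harmonic inside the cutoff and exactly zero beyond", {
  p <- default_params()
  st <- new_state(p, box_um = c(5, 5, 5), boundary = rep("open", 3))
  st <- add_filament(st, build_filament(140, c(2000, 2000, 2000), c(0, 0, 1), p))
  gap <- p$rc_A / 2
  st <- add_filament(st, build_filament(140, c(2000 + gap, 2000, 2000),
                                        c(0, 0, 1), p))
  f <- compute_forces(st)
  # parallel overlapping segments at rc/2: magnitude kappa_r * rc/2,
  # pushed apart symmetrically
  mag <- p$kappa_r_A * 1e3 * (p$rc_A - gap)
  expect_equal(sum(f$repulsion[1:2, 1]), -mag, tolerance = 1e-9)
  expect_equal(sum(f$repulsion[3:4, 1]), mag, tolerance = 1e-9)
  expect_equal(f$repulsion[1:2, 1], f$repulsion[3:4, 1] * -1,
               tolerance = 1e-9)
  # beyond the cutoff: identically zero, no smooth tail
  st$pos[3:4, 1] <- 2000 + p$rc_A + 1e-6
  expect_identical(max(abs(compute_forces(st)$repulsion)), 0)
})

test_that("motor arm two-spring force vanishes at its equilibrium", {
  st <- fixture_full_state()
  arm <- which(st$arms$bound)[1]
  # place the anchor exactly r0_M2 away, perpendicular to the filament,
  # from the bound site (zero axial offset)
  seg <- st$arms$seg[arm]
  sfrac <- (st$arms$site[arm] - 1) / ncol(st$occ)
  a <- st$seg$a[seg]; b <- st$seg$b[seg]
  site <- st$pos[a, ] + sfrac * (st$pos[b, ] - st$pos[a, ])
  anchor_v <- st$arms$anchor[arm]
  st$pos[anchor_v, ] <- site + c(default_params()$r0_M2, 0, 0)
  f <- compute_forces(st)
  expect_equal(max(abs(f$arm[anchor_v, ])), 0, tolerance = 1e-9)
  # pure axial offset: move the anchor on the sphere of radius r0_M2 so
  # the transverse spring stays at rest while the binding site sits 10 nm
  # from the perpendicular foot; only the longitudinal spring acts
  r2 <- default_params()$r0_M2
  st$pos[anchor_v, ] <- site + c(sqrt(r2^2 - 10^2), 0, -10)
  f <- compute_forces(st)
  # kappa_s_M3 = 1e-3 N/m over 10 nm -> 10 pN restoring, purely axial
  expect_equal(f$arm[anchor_v, ], c(0, 0, 10), tolerance = 1e-9)
  # action-reaction: forces on the filament balance the anchor force
  expect_lt(max(abs(colSums(f$arm))), 1e-9)
})
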