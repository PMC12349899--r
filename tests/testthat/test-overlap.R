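# Contractile-unit overlap theory: critical length, pairwise
# cooperativity, the cooperative motor number Xi and the force estimate.

test_that("critical length follows L_c = 2 L_sp (N_a/4 - 1)", {
  expect_equal(critical_length(24, 42), 420)
  expect_equal(critical_length(16, 42), 252)
  # a 4-arm motor cooperates on any contact
  expect_equal(critical_length(4, 42), 0)
  expect_error(critical_length(10, 42), "divisible")
})

test_that("pairwise cooperativity has the three branches", {
  Lc <- 420
  expect_equal(pairwise_xi(0, Lc), 0)
  expect_equal(pairwise_xi(Lc / 2, Lc), 0.5)
  expect_equal(pairwise_xi(Lc, Lc), 1)
  expect_equal(pairwise_xi(460, Lc, L_M = 462), 1)
  expect_error(pairwise_xi(-1, Lc), "negative")
})

test_that("force estimate is linear in Xi with the printed constant", {
  expect_equal(estimate_force(1, 24, 8, 5.7), 547.2)
  expect_equal(estimate_force(2, 24, 8, 5.7), 1094.4)
  expect_equal(estimate_force(3), 3 * estimate_force(1))
  expect_error(estimate_force(0.5), "Xi")
})

test_that("Xi spans its limits: isolated motors and a full stack", {
  m1 <- data.frame(center = 0, L_M = 462, N_a = 24, L_sp = 42)
  expect_equal(xi_max(m1)$Xi, 1)
  n <- 7
  stack <- data.frame(center = rep(0, n), L_M = 462, N_a = 24, L_sp = 42)
  expect_equal(xi_max(stack)$Xi, n)
  # three motors: full overlap with one neighbor, half-critical with another
  tri <- data.frame(center = c(0, 0, NA), L_M = 462, N_a = 24, L_sp = 42)
  tri$center[3] <- -(462 - 420 / 2)   # overlap exactly L_c / 2, on the left
  expect_equal(xi_max(tri)$Xi, 2.5)
})

test_that("Xi matches an exhaustive brute-force evaluation", {
  # independent oracle: literal loops over motors, sides and neighbors
  oracle <- function(centers, L_M, L_c, wrap = NULL) {
    n <- length(centers)
    best <- 1
    for (i in seq_len(n)) for (side in c("L", "R")) {
      s <- 1
      for (k in seq_len(n)) {
        if (k == i) next
        dc <- centers[k] - centers[i]
        if (!is.null(wrap)) dc <- dc - wrap * round(dc / wrap)
        ov <- max(0, L_M - abs(dc))
        if (ov == 0) next
        member <- if (abs(dc) < L_M / 2) TRUE
                  else if (side == "L") dc < 0 else dc > 0
        if (!member) next
        s <- s + if (ov >= L_c) 1 else ov / L_c
      }
      best <- max(best, s)
    }
    best
  }
  set.seed(77)
  for (rep in 1:500) {
    n <- sample(1:30, 1)
    wrap <- if (stats::runif(1) < 0.5) 20000 else NULL
    centers <- stats::runif(n, 0, 20000)
    m <- data.frame(center = centers, L_M = 462, N_a = 24, L_sp = 42)
    expect_equal(xi_max(m, wrap = wrap)$Xi,
                 oracle(centers, 462, 420, wrap))
  }
})

test_that("confining motors (smaller f) never lowers the expected Xi", {
  set.seed(41)
  L <- 20000; N_M <- 52
  fs <- c(1, 0.5, 0.2, 0.06)
  means <- vapply(fs, function(f) {
    mean(vapply(1:200, function(q) {
      ctr <- L / 2 + stats::runif(N_M, -f * L / 2, f * L / 2)
      m <- data.frame(center = ctr, L_M = 462, N_a = 24, L_sp = 42)
      xi_max(m, wrap = L)$Xi
    }, 0))
  }, 0)
  # smaller f -> larger E[Xi]
  expect_true(all(diff(means) >= 0))
  expect_gt(means[length(means)], means[1])
})

test_that("at fixed length and arm budget the bare-zone variant overlaps more easily", {
  # N_a = 16, L_M = 966 nm two ways: long bare zone (L_sp = 42) vs wide
  # arm spacing (L_sp = L_bz = 138); the former has the smaller L_c
  expect_equal(build_motor(16, 714, 42)$L_M, build_motor(16, 138, 138)$L_M)
  expect_lt(critical_length(16, 42), critical_length(16, 138))
  set.seed(55)
  L <- 20000; N_M <- 20
  exi <- function(L_sp, L_bz) {
    mean(vapply(1:200, function(q) {
      ctr <- stats::runif(N_M, 0, L)
      m <- data.frame(center = ctr, L_M = 966, N_a = 16, L_sp = L_sp)
      xi_max(m, wrap = L)$Xi
    }, 0))
  }
  expect_gte(exi(42, 714), exi(138, 138))
})

test_that("E[Xi] is non-decreasing in the number of motors", {
  set.seed(61)
  L <- 20000
  means <- vapply(c(4, 13, 52, 150), function(N_M) {
    mean(vapply(1:150, function(q) {
      m <- data.frame(center = stats::runif(N_M, 0, L), L_M = 462,
                      N_a = 24, L_sp = 42)
      xi_max(m, wrap = L)$Xi
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("network-mode Xi respects the 30-degree axis gate", {
  # two stacked motors with aligned axes cooperate fully
  m <- data.frame(x = c(0, 0), y = c(0, 0), angle = c(0, 0.1),
                  L_M = 462, N_a = 24, L_sp = 42)
  expect_equal(xi_max(m, mode = "network")$Xi, 2)
  # perpendicular axes are not comparable
  m$angle <- c(0, pi / 2)
  expect_equal(xi_max(m, mode = "network")$Xi, 1)
  # nearly-antiparallel axes are the same undirected orientation
  m$angle <- c(0, pi - 0.05)
  expect_equal(xi_max(m, mode = "network")$Xi, 2)
})

test_that("overlap reports combine Xi with the force estimate", {
  m <- data.frame(center = c(0, 100, 5000), L_M = 462, N_a = 24, L_sp = 42)
  rep <- overlap_report(m)
  expect_equal(rep$F_est, 547.2 * rep$Xi, tolerance = 1e-12)
  expect_true(all(rep$xi$xi >= 0 & rep$xi$xi <= 1))
  expect_gte(rep$Xi, 1)
  expect_lte(rep$Xi, 3)
})
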