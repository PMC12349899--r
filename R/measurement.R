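# Cross-section tension measurement.
#
# Tension transmitted across a plane is the sum, over every spring-like
# element crossing it, of the axis component of the force the element
# exerts on its lower endpoint: positive when the element is stretched
# (tension), negative when compressed. Only extensional (spring) terms are
# summed; bending contributions are excluded by construction. Elements are
# bucketed into four categories: actin segments, cross-linker arms, motor
# arms and motor backbones.

# site position from an arbitrary position matrix (min-image unwrapped
# relative to the segment's barbed-side vertex)
.site_pos_m <- function(state, pos, seg, site) {
  a <- state$seg$a[seg]; b <- state$seg$b[seg]
  pa <- pos[a, ]
  d <- .mi_vec(pos[b, ] - pa, state)
  pa + (site - 1) / ncol(state$occ) * d
}

# per-arm spring force on the filament site (pN), rows = arms
.arm_site_forces <- function(state, pos = state$pos, arms = state$arms) {
  p <- state$params
  km2 <- p$kappa_s_M2 * 1e3; km3 <- p$kappa_s_M3 * 1e3
  n <- nrow(arms)
  out <- matrix(0, n, 3)
  anchor_xyz <- matrix(0, n, 3)
  site_xyz <- matrix(0, n, 3)
  for (m in seq_len(n)) {
    if (!isTRUE(arms$bound[m])) next
    av <- state$arms$anchor[m]
    a <- pos[av, ]
    sgm <- arms$seg[m]
    pa <- a + .mi_vec(pos[state$seg$a[sgm], ] - a, state)
    d <- .mi_vec(pos[state$seg$b[sgm], ] - pos[state$seg$a[sgm], ], state)
    b <- pa + (arms$site[m] - 1) / ncol(state$occ) * d
    th <- d / sqrt(sum(d^2))
    dv <- b - a
    r <- sqrt(sum(dv^2))
    g <- c(0, 0, 0)
    if (r > 1e-9) g <- g - km2 * (r - p$r0_M2) * dv / r
    o <- sum(dv * th)
    g <- g - km3 * o * th
    out[m, ] <- g
    anchor_xyz[m, ] <- a
    site_xyz[m, ] <- b
  }
  list(f_site = out, anchor = anchor_xyz, site = site_xyz)
}

# table of spring elements: endpoints along `ax`, force-on-lower-endpoint
# axis component (pN), category
.element_table <- function(state, pos, arms, ax) {
  p <- state$params
  rows <- list()
  if (nrow(state$bonds)) {
    i <- state$bonds$i; j <- state$bonds$j
    d <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
    for (q in 1:3) d[, q] <- d[, q] - (state$bkind[q] == 1L) *
        state$box[q] * round(d[, q] / state$box[q])
    r <- sqrt(rowSums(d^2))
    tension <- state$bonds$ks * 1e3 * (r - state$bonds$r0)
    flow <- tension * abs(d[, ax]) / r
    rows[[1]] <- data.frame(
      c1 = pos[i, ax], c2 = pos[i, ax] + d[, ax], flow = flow,
      cat = ifelse(state$bonds$cat == 1L, "actin", "motor_backbone"))
  }
  if (nrow(state$acps)) {
    ac <- state$acps
    ks <- p$kappa_s_ACP * 1e3
    sub <- list()
    for (arm12 in 1:2) {
      seg <- if (arm12 == 1) ac$seg1 else ac$seg2
      site <- if (arm12 == 1) ac$site1 else ac$site2
      n <- nrow(ac)
      c1 <- numeric(n); c2 <- numeric(n); fl <- numeric(n)
      for (q in seq_len(n)) {
        ctr <- pos[ac$center[q], ]
        s <- ctr + .mi_vec(.site_pos_m(state, pos, seg[q], site[q]) - ctr,
                           state)
        d <- s - ctr
        r <- sqrt(sum(d^2))
        tension <- ks * (r - p$r0_ACP)
        c1[q] <- ctr[ax]; c2[q] <- s[ax]
        fl[q] <- tension * abs(d[ax]) / r
      }
      sub[[arm12]] <- data.frame(c1 = c1, c2 = c2, flow = fl, cat = "acp")
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, sub)
  }
  if (nrow(arms) && any(arms$bound)) {
    af <- .arm_site_forces(state, pos, arms)
    bnd <- which(arms$bound)
    c1 <- af$anchor[bnd, ax]; c2 <- af$site[bnd, ax]
    # force on the lower endpoint: -f_site on the anchor when the anchor is
    # lower, +f_site on the site when the site is lower
    fl <- ifelse(c2 >= c1, -af$f_site[bnd, ax], af$f_site[bnd, ax])
    rows[[length(rows) + 1L]] <-
      data.frame(c1 = c1, c2 = c2, flow = fl, cat = "motor_arm")
  }
  do.call(rbind, rows)
}

#' Cross-section force profile
#'
#' Sums the axis component of the extensional (spring) forces of every
#' element crossing each measurement plane, bucketed by element category
#' (actin, cross-linker, motor arm, motor backbone), with tension counted
#' positive. Planes are minimum-image aware on periodic axes.
#'
#' @param state an `actomyo_state`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param spacing plane spacing (nm); mutually exclusive with `n_planes`.
#' @param n_planes number of evenly spaced planes.
#' @param pos optional position matrix (e.g. from a snapshot); defaults to
#'   the state's current positions.
#' @param arms optional arm table matching `pos`.
#' @return data frame: one row per plane with columns `plane` (nm),
#'   `actin`, `acp`, `motor_arm`, `motor_backbone`, `total` (pN).
#' @export
cross_section_forces <- function(state, axis = "z", spacing = 200,
                                 n_planes = NULL, pos = state$pos,
                                 arms = state$arms) {
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be x, y or z")
  L <- state$box[ax]
  if (!is.null(n_planes)) spacing <- L / n_planes
  if (spacing <= 0) stop("spacing must be > 0")
  np <- floor(L / spacing)
  planes <- spacing * (seq_len(np) - 0.5)
  el <- .element_table(state, pos, arms, ax)
  cats <- c("actin", "acp", "motor_arm", "motor_backbone")
  out <- data.frame(plane = planes)
  for (cc in cats) out[[cc]] <- 0
  if (!is.null(el) && nrow(el)) {
    lo <- pmin(el$c1, el$c2)
    hi <- pmax(el$c1, el$c2)
    shifts <- if (state$bkind[ax] == 1L) c(-L, 0, L) else 0
    for (cc in cats) {
      sel <- el$cat == cc
      if (!any(sel)) next
      acc <- numeric(np)
      for (sh in shifts) {
        cross <- outer(planes + sh, lo[sel], ">") &
          outer(planes + sh, hi[sel], "<")
        acc <- acc + as.vector(cross %*% el$flow[sel])
      }
      out[[cc]] <- acc
    }
  }
  out$total <- out$actin + out$acp + out$motor_arm + out$motor_backbone
  out
}

#' Steady-state window of a force time series
#'
#' Finds the earliest suffix window of at least 20 frames whose linear
#' trend, normalized by the window mean, drifts by less than 1% over the
#' window; the window always extends to the end of the series. If no
#' suffix qualifies, the last half of the series is returned with a
#' warning flag.
#'
#' @param time frame times (s).
#' @param value frame values.
#' @param min_frames minimum window length in frames.
#' @param tol relative drift tolerance per window.
#' @return list with `t_start`, `t_end`, `idx` (frame indices) and
#'   `qualified` (logical).
#' @export
steady_state_window <- function(time, value, min_frames = 20, tol = 1e-2) {
  n <- length(value)
  if (n < 50) stop("series too short for steady-state detection (need >= 50)")
  for (i in seq_len(n - min_frames + 1L)) {
    idx <- i:n
    tt <- time[idx]; vv <- value[idx]
    mu <- mean(vv)
    if (abs(mu) < 1e-12) mu <- 1e-12
    sl <- stats::cov(tt, vv) / stats::var(tt)
    drift <- abs(sl * (tt[length(tt)] - tt[1]) / mu)
    if (drift < tol)
      return(list(t_start = tt[1], t_end = tt[length(tt)], idx = idx,
                  qualified = TRUE))
  }
  idx <- (floor(n / 2)):n
  list(t_start = time[idx[1]], t_end = time[n], idx = idx, qualified = FALSE)
}

#' Total force from cross-section records over a steady window
#'
#' The total force acting on the system is the mean over planes and
#' steady-state frames of the per-plane totals.
#'
#' @param frames list of cross-section data frames (one per frame in the
#'   steady window), as returned by [cross_section_forces()].
#' @return `F_tot` (pN).
#' @export
total_force <- function(frames) {
  if (length(frames) < 10)
    stop("steady window shorter than 10 frames")
  mean(vapply(frames, function(s) mean(s$total), 0))
}

#' Maximal motor force
#'
#' For bundles and the filament pair: half the sum over motors of the
#' summed magnitudes of the z components of each motor's arm spring
#' forces. For networks: a quarter of the summed x-force magnitudes plus
#' the summed y-force magnitudes.
#'
#' @param state an `actomyo_state`.
#' @param mode `"bundle"` or `"network"`.
#' @param pos,arms optional snapshot positions/arm table.
#' @return list with `F_M_max` (pN) and `per_motor` (vector of
#'   per-motor summed arm-force magnitudes along the measurement axes).
#' @export
motor_max_force <- function(state, mode = c("bundle", "network"),
                            pos = state$pos, arms = state$arms) {
  mode <- match.arg(mode)
  if (!length(state$motors)) stop("no motors: F_M^max undefined")
  af <- .arm_site_forces(state, pos, arms)
  mot <- state$arms$motor
  nm <- length(state$motors)
  if (mode == "bundle") {
    fz <- abs(af$f_site[, 3]) * arms$bound
    per <- vapply(seq_len(nm), function(m) sum(fz[mot == m]), 0)
    list(F_M_max = sum(per) / 2, per_motor = per)
  } else {
    fx <- abs(af$f_site[, 1]) * arms$bound
    fy <- abs(af$f_site[, 2]) * arms$bound
    perx <- vapply(seq_len(nm), function(m) sum(fx[mot == m]), 0)
    pery <- vapply(seq_len(nm), function(m) sum(fy[mot == m]), 0)
    list(F_M_max = (sum(perx) + sum(pery)) / 4, per_motor = perx + pery)
  }
}

#' Force-generation efficiency
#'
#' `eta = F_tot / F_M^max`: the realized structure-level tension divided by
#' the maximal force the motors exert.
#'
#' @param F_tot total force (pN).
#' @param F_M_max maximal motor force (pN), must be > 0.
#' @return eta (dimensionless).
#' @export
efficiency <- function(F_tot, F_M_max) {
  if (F_M_max <= 0) stop("F_M_max must be > 0 for eta")
  F_tot / F_M_max
}

#' Per-cross-linker mean arm tension
#'
#' @param state an `actomyo_state`.
#' @param pos optional snapshot positions.
#' @return data frame with `acp`, `z` (center height, nm), `tension`
#'   (mean of the two arm spring tensions, pN; positive = stretched).
#' @export
acp_tensions <- function(state, pos = state$pos) {
  ac <- state$acps
  if (!nrow(ac)) return(data.frame(acp = integer(0), z = numeric(0),
                                   tension = numeric(0)))
  ks <- state$params$kappa_s_ACP * 1e3
  r0 <- state$params$r0_ACP
  tn <- numeric(nrow(ac)); zz <- numeric(nrow(ac))
  for (q in seq_len(nrow(ac))) {
    ctr <- pos[ac$center[q], ]
    t1 <- ks * (sqrt(sum(.mi_vec(
      .site_pos_m(state, pos, ac$seg1[q], ac$site1[q]) - ctr, state)^2)) - r0)
    t2 <- ks * (sqrt(sum(.mi_vec(
      .site_pos_m(state, pos, ac$seg2[q], ac$site2[q]) - ctr, state)^2)) - r0)
    tn[q] <- (t1 + t2) / 2
    zz[q] <- ctr[3]
  }
  data.frame(acp = seq_len(nrow(ac)), z = zz, tension = tn)
}

#' Measure a production run
#'
#' Computes the cross-section force time series from recorded snapshots,
#' detects the steady-state window, and evaluates `F_tot`, `F_M^max`
#' (averaged over steady frames) and the efficiency `eta`.
#'
#' @param state the final `actomyo_state` of the run.
#' @param snapshots snapshot list from [advance()].
#' @param mode `"bundle"` (z sections; also used for the filament pair) or
#'   `"network"` (x and y sections).
#' @param spacing plane spacing (nm) for bundle mode.
#' @param n_planes planes per axis for network mode.
#' @param keep_profiles retain the full per-frame plane profiles (long
#'   data frame with one row per time and plane).
#' @return A `measurement_result`: list with `F_tot`, `F_M_max`, `eta`,
#'   `series` (data frame time/force), `window` (steady window),
#'   `sections` (profile of the final frame) and, when requested,
#'   `profiles`.
#' @export
measure_run <- function(state, snapshots, mode = c("bundle", "network"),
                        spacing = 200, n_planes = 20,
                        keep_profiles = FALSE) {
  mode <- match.arg(mode)
  if (length(snapshots) < 50)
    stop("need >= 50 snapshots for steady-state measurement")
  profiles <- if (keep_profiles) vector("list", length(snapshots)) else NULL
  frame_force <- function(q) {
    sn <- snapshots[[q]]
    if (mode == "bundle") {
      cs <- cross_section_forces(state, "z", spacing = spacing,
                                 pos = sn$pos, arms = sn$arms)
      cs$axis <- "z"
    } else {
      cx <- cross_section_forces(state, "x", n_planes = n_planes,
                                 pos = sn$pos, arms = sn$arms)
      cy <- cross_section_forces(state, "y", n_planes = n_planes,
                                 pos = sn$pos, arms = sn$arms)
      cx$axis <- "x"; cy$axis <- "y"
      cs <- rbind(cx, cy)
    }
    if (keep_profiles) {
      cs$time <- sn$time
      profiles[[q]] <<- cs
    }
    mean(cs$total)
  }
  ft <- vapply(seq_along(snapshots), frame_force, 0)
  tt <- vapply(snapshots, function(s) s$time, 0)
  win <- steady_state_window(tt, ft)
  F_tot <- mean(ft[win$idx])
  fm <- vapply(win$idx, function(q) {
    sn <- snapshots[[q]]
    motor_max_force(state, mode, pos = sn$pos, arms = sn$arms)$F_M_max
  }, 0)
  F_M_max <- mean(fm)
  last <- snapshots[[length(snapshots)]]
  sections <- if (mode == "bundle") {
    cross_section_forces(state, "z", spacing = spacing,
                         pos = last$pos, arms = last$arms)
  } else {
    cross_section_forces(state, "x", n_planes = n_planes,
                         pos = last$pos, arms = last$arms)
  }
  structure(list(F_tot = F_tot, F_M_max = F_M_max,
                 eta = efficiency(F_tot, F_M_max),
                 series = data.frame(time = tt, force = ft),
                 window = win, sections = sections,
                 profiles = if (keep_profiles) do.call(rbind, profiles)),
            class = "measurement_result")
}

#' @export
print.measurement_result <- function(x, ...) {
  cat(sprintf(
    "<measurement_result> F_tot = %.1f pN, F_M_max = %.1f pN, eta = %.3f (steady %.3g-%.3g s%s)\n",
    x$F_tot, x$F_M_max, x$eta, x$window$t_start, x$window$t_end,
    if (x$window$qualified) "" else ", tail fallback"))
  invisible(x)
}
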