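# SimulationState: one mutable-by-copy record holding every vertex, spring,
# binding-site occupancy and binder of a simulated system, plus the domain
# and parameter set. Builders assemble it; advance() evolves it.
#
# Coordinates are in nm. Stiffnesses are kept in the user-facing SI units of
# the parameter set (N/m, N m) and converted once per engine call.
#
# Occupancy codes: 0 free, 1 cross-linker, k+1 = motor arm k (1-based).

#' Create an empty simulation state
#'
#' @param params an `actomyo_params` object.
#' @param box_um domain dimensions (um) per axis.
#' @param boundary character 3-vector, per-axis boundary kind:
#'   `"periodic"`, `"wall"` (repulsive) or `"open"`.
#' @return An `actomyo_state` object.
#' @export
new_state <- function(params = default_params(),
                      box_um = c(5, 5, 20),
                      boundary = c("periodic", "periodic", "wall")) {
  bk <- match(boundary, c("open", "periodic", "wall")) - 1L
  if (any(is.na(bk))) stop("boundary kinds must be open/periodic/wall")
  structure(list(
    params = params,
    box = box_um * 1000,    # nm
    bkind = bk,
    pos = matrix(numeric(0), 0, 3),
    vtype = integer(0),     # 0 actin, 1 motor backbone, 2 ACP center
    clamped = logical(0),
    bonds = data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                       ks = numeric(0), cat = integer(0)),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        kb = numeric(0)),
    fils = list(),          # integer vertex vectors, barbed end first
    seg = data.frame(a = integer(0), b = integer(0), fil = integer(0),
                     local = integer(0)),
    occ = matrix(integer(0), 0, floor(params$r0_A / params$site_spacing)),
    arms = data.frame(motor = integer(0), anchor = integer(0),
                      side = character(0), wfrom = integer(0),
                      wto = integer(0), bound = logical(0),
                      seg = integer(0), site = integer(0)),
    motors = list(),        # per-motor: spec + vertex ids
    acps = data.frame(center = integer(0), seg1 = integer(0),
                      site1 = integer(0), seg2 = integer(0),
                      site2 = integer(0)),
    time = 0,
    warnings = character(0)
  ), class = "actomyo_state")
}

#' @export
print.actomyo_state <- function(x, ...) {
  cat(sprintf(
    "<actomyo_state> %d vertices | %d filaments (%d segments) | %d motors (%d arms, %d bound) | %d ACPs | t = %.4g s\n",
    nrow(x$pos), length(x$fils), nrow(x$seg), length(x$motors),
    nrow(x$arms), sum(x$arms$bound), nrow(x$acps), x$time))
  invisible(x)
}

# append vertices; returns list(state, ids)
.add_vertices <- function(state, coords, vtype, clamped = FALSE) {
  n0 <- nrow(state$pos)
  n <- nrow(coords)
  state$pos <- rbind(state$pos, coords)
  state$vtype <- c(state$vtype, rep.int(vtype, n))
  state$clamped <- c(state$clamped, rep(clamped, length.out = n))
  list(state = state, ids = n0 + seq_len(n))
}

#' Add an actin filament to a state
#'
#' Appends the filament's vertices (barbed end first), its extensional and
#' bending springs, its segments and their free binding sites.
#'
#' @param state an `actomyo_state`.
#' @param fil a `filament_spec` from [build_filament()].
#' @param clamp_barbed clamp the barbed-end vertex in place.
#' @return The updated state.
#' @export
add_filament <- function(state, fil, clamp_barbed = FALSE) {
  p <- state$params
  clamp <- c(clamp_barbed, rep(FALSE, nrow(fil$coords) - 1L))
  av <- .add_vertices(state, fil$coords, 0L, clamp)
  state <- av$state
  ids <- av$ids
  n_seg <- fil$n_seg
  state$bonds <- rbind(state$bonds, data.frame(
    i = ids[seq_len(n_seg)], j = ids[seq_len(n_seg) + 1L],
    r0 = p$r0_A, ks = p$kappa_s_A, cat = 1L))
  if (n_seg >= 2) {
    m <- seq_len(n_seg - 1L)
    state$angles <- rbind(state$angles, data.frame(
      i = ids[m], j = ids[m + 1L], k = ids[m + 2L], kb = p$kappa_b_A))
  }
  fid <- length(state$fils) + 1L
  state$fils[[fid]] <- ids
  state$seg <- rbind(state$seg, data.frame(
    a = ids[seq_len(n_seg)], b = ids[seq_len(n_seg) + 1L],
    fil = fid, local = seq_len(n_seg)))
  state$occ <- rbind(state$occ,
                     matrix(0L, n_seg, ncol(state$occ)))
  state
}

#' Add a motor filament to a state
#'
#' Places the backbone as a straight chain along `axis` centered at
#' `center`, appends backbone springs and bending triples, and registers
#' the motor's arms (all initially unbound).
#'
#' @param state an `actomyo_state`.
#' @param motor a `motor_spec` from [build_motor()].
#' @param center 3-vector (nm), backbone midpoint.
#' @param axis 3-vector, backbone direction (normalized internally).
#' @return The updated state.
#' @export
add_motor <- function(state, motor, center, axis = c(0, 0, 1)) {
  p <- state$params
  u <- axis / sqrt(sum(axis^2))
  s <- motor$seg_len * (0:motor$n_seg) - motor$L_M / 2
  coords <- cbind(center[1] + s * u[1], center[2] + s * u[2],
                  center[3] + s * u[3])
  av <- .add_vertices(state, coords, 1L)
  state <- av$state
  ids <- av$ids
  n_seg <- motor$n_seg
  state$bonds <- rbind(state$bonds, data.frame(
    i = ids[seq_len(n_seg)], j = ids[seq_len(n_seg) + 1L],
    r0 = motor$seg_len, ks = p$kappa_s_M1, cat = 2L))
  if (n_seg >= 2) {
    m <- seq_len(n_seg - 1L)
    state$angles <- rbind(state$angles, data.frame(
      i = ids[m], j = ids[m + 1L], k = ids[m + 2L], kb = p$kappa_b_M))
  }
  mid <- length(state$motors) + 1L
  state$motors[[mid]] <- list(spec = motor, vertices = ids)
  at <- motor$arm_table
  state$arms <- rbind(state$arms, data.frame(
    motor = mid, anchor = ids[at$vertex], side = at$side,
    wfrom = ids[at$wfrom], wto = ids[at$wto],
    bound = FALSE, seg = NA_integer_, site = NA_integer_))
  state
}

#' Nominal z-interval (or axial interval) spanned by each motor backbone
#'
#' @param state an `actomyo_state`.
#' @return data.frame with columns `motor`, `center`, `half_length` (nm),
#'   using current vertex positions projected on the z axis.
#' @export
motor_spans <- function(state) {
  if (!length(state$motors))
    return(data.frame(motor = integer(0), center = numeric(0),
                      half_length = numeric(0)))
  do.call(rbind, lapply(seq_along(state$motors), function(m) {
    v <- state$motors[[m]]$vertices
    z <- state$pos[v, 3]
    data.frame(motor = m, center = mean(range(z)),
               half_length = diff(range(z)) / 2)
  }))
}

# position of binding site `site` (1-based) on global segment `seg`,
# minimum-image unwrapped relative to the segment's barbed-side vertex
site_position <- function(state, seg, site) {
  a <- state$seg$a[seg]; b <- state$seg$b[seg]
  pa <- state$pos[a, ]
  d <- .mi_vec(state$pos[b, ] - pa, state)
  frac <- (site - 1) / ncol(state$occ)
  pa + frac * d
}

.mi_vec <- function(d, state) {
  per <- state$bkind == 1L
  d[per] <- d[per] - state$box[per] * round(d[per] / state$box[per])
  d
}

#' Place permanent cross-linkers
#'
#' Samples `N_ACP` admissible pairs of free binding sites on two distinct
#' filaments whose separation is within geometric reach of a two-armed
#' cross-linker, marks the sites occupied and places the linker's center
#' on the perpendicular bisector of the pair so both arms start at their
#' rest length (the hinge, not the arms, carries any initial strain).
#' Links are permanent: they are never released during a run.
#'
#' This reproduces, distributionally, an initialization phase in which
#' cross-linkers bind while the actin scaffold is held stationary.
#'
#' @param state an `actomyo_state` with filaments already added.
#' @param N_ACP number of cross-linkers to place.
#' @param z_range optional z-interval (nm) restricting placement.
#' @param max_tries sampling attempts per linker before giving up.
#' @return The updated state; if fewer than `N_ACP` admissible pairs are
#'   found a warning is emitted and recorded in `state$warnings`.
#' @export
init_crosslinks <- function(state, N_ACP, z_range = NULL, max_tries = 200) {
  if (N_ACP == 0) return(state)
  if (length(state$fils) < 2)
    stop("cross-linkers need at least two filaments")
  p <- state$params
  # both arms at rest length requires site separation < 2 r0_ACP
  reach_lo <- 0.5 * p$r0_ACP
  reach_hi <- 1.96 * p$r0_ACP
  placed <- 0L
  nseg <- nrow(state$seg)
  nsites <- ncol(state$occ)
  for (q in seq_len(N_ACP)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s1 <- sample.int(nseg, 1L)
      k1 <- sample.int(nsites, 1L)
      if (state$occ[s1, k1] != 0L) next
      if (!is.null(z_range)) {
        z1 <- site_position(state, s1, k1)[3]
        if (z1 < z_range[1] || z1 > z_range[2]) next
      }
      f1 <- state$seg$fil[s1]
      # candidate partner sites on other filaments within reach
      pos1 <- site_position(state, s1, k1)
      cand_seg <- which(state$seg$fil != f1)
      found <- FALSE
      for (s2 in sample(cand_seg, length(cand_seg))) {
        a2 <- state$seg$a[s2]
        dmid <- .mi_vec(state$pos[a2, ] + 0.5 *
                          .mi_vec(state$pos[state$seg$b[s2], ] -
                                    state$pos[a2, ], state) - pos1, state)
        if (sqrt(sum(dmid^2)) > reach_hi + p$r0_A) next
        free <- which(state$occ[s2, ] == 0L)
        if (!length(free)) next
        for (k2 in sample(free, length(free))) {
          d <- .mi_vec(site_position(state, s2, k2) - pos1, state)
          r <- sqrt(sum(d^2))
          if (r >= reach_lo && r <= reach_hi) {
            # center on the perpendicular bisector at arm rest length
            h2 <- p$r0_ACP^2 - (r / 2)^2
            mid <- pos1 + d / 2
            if (h2 > 1e-9) {
              e <- .perp_unit(d)
              phi <- stats::runif(1, 0, 2 * pi)
              e2 <- .rotate_about(e, d / r, phi)
              ctr <- mid + sqrt(h2) * e2
            } else ctr <- mid
            av <- .add_vertices(state, matrix(ctr, 1, 3), 2L)
            state <- av$state
            state$occ[s1, k1] <- 1L
            state$occ[s2, k2] <- 1L
            state$acps <- rbind(state$acps, data.frame(
              center = av$ids, seg1 = s1, site1 = k1, seg2 = s2, site2 = k2))
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) { ok <- TRUE; placed <- placed + 1L; break }
    }
    if (!ok) break
  }
  if (placed < N_ACP) {
    msg <- sprintf("placed only %d of %d cross-linkers (admissible site pairs exhausted)",
                   placed, N_ACP)
    warning(msg)
    state$warnings <- c(state$warnings, msg)
  }
  state
}

.perp_unit <- function(d) {
  u <- d / sqrt(sum(d^2))
  e <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- e - sum(e * u) * u
  v / sqrt(sum(v^2))
}

.rotate_about <- function(v, axis, phi) {
  # Rodrigues rotation of v about unit axis
  v * cos(phi) + .cross(axis, v) * sin(phi) +
    axis * sum(axis * v) * (1 - cos(phi))
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- engine marshalling ------------------------------------------------

# convert the state to the 0-based engine list (nm / pN / s units)
.state_sys <- function(state) {
  p <- state$params
  KS <- 1e3    # N/m -> pN/nm
  KB <- 1e21   # N m -> pN nm
  zeta_v <- numeric(nrow(state$pos))
  z_act <- drag_coefficient(p$r0_A, p$d_A, p$mu) * 1e3
  z_mot <- drag_coefficient(p$L_MB, p$d_M, p$mu) * 1e3
  z_acp <- drag_coefficient(p$r0_ACP, p$d_ACP, p$mu) * 1e3
  zeta_v[state$vtype == 0L] <- z_act
  zeta_v[state$vtype == 1L] <- z_mot
  zeta_v[state$vtype == 2L] <- z_acp
  nsites <- ncol(state$occ)
  list(
    pos = state$pos,
    zeta = zeta_v,
    vtype = as.integer(state$vtype),
    clamped = as.integer(state$clamped),
    bond_i = as.integer(state$bonds$i - 1L),
    bond_j = as.integer(state$bonds$j - 1L),
    bond_cat = as.integer(state$bonds$cat),
    bond_r0 = state$bonds$r0,
    bond_ks = state$bonds$ks * KS,
    ang_i = as.integer(state$angles$i - 1L),
    ang_j = as.integer(state$angles$j - 1L),
    ang_k = as.integer(state$angles$k - 1L),
    ang_kb = state$angles$kb * KB,
    seg_a = as.integer(state$seg$a - 1L),
    seg_b = as.integer(state$seg$b - 1L),
    seg_fil = as.integer(state$seg$fil),
    seg_local = as.integer(state$seg$local - 1L),
    fil_nseg = as.integer(vapply(state$fils, function(v) length(v) - 1L, 1L)),
    occ = as.integer(t(state$occ)),
    arm_anchor = as.integer(state$arms$anchor - 1L),
    arm_wfrom = as.integer(state$arms$wfrom - 1L),
    arm_wto = as.integer(state$arms$wto - 1L),
    arm_sib = as.integer(.arm_siblings(state) - 1L),
    arm_bound = as.integer(state$arms$bound),
    arm_seg = as.integer(ifelse(state$arms$bound, state$arms$seg - 1L, -1L)),
    arm_site = as.integer(ifelse(state$arms$bound, state$arms$site - 1L, -1L)),
    acp_center = as.integer(state$acps$center - 1L),
    acp_seg1 = as.integer(state$acps$seg1 - 1L),
    acp_site1 = as.integer(state$acps$site1 - 1L),
    acp_seg2 = as.integer(state$acps$seg2 - 1L),
    acp_site2 = as.integer(state$acps$site2 - 1L),
    box = state$box,
    bkind = as.integer(state$bkind),
    epar = list(
      dt = p$dt, kBT = p$kBT * 1e21,
      ks_acp = p$kappa_s_ACP * KS, r0_acp = p$r0_ACP,
      kb_acp = p$kappa_b_ACP * KB,
      km2 = p$kappa_s_M2 * KS, km3 = p$kappa_s_M3 * KS, r0m2 = p$r0_M2,
      kr = p$kappa_r_A * KS, rc = p$rc_A, wallk = p$kappa_r_A * KS,
      site_sp = p$site_spacing, seg_r0 = p$r0_A, nsites = as.integer(nsites),
      kbind = p$k_bind_per_head * p$N_h,
      kw0 = p$v0 / p$site_spacing,
      Fstall = p$F_st * p$N_h,
      ku0 = p$k_u0, kumin_frac = 0.01, Fcat = p$F_cat,
      capture = p$r0_M2 + 2 * p$site_spacing,
      kin_every = 5L,
      nlist_every = as.integer(getOption("actomyosim.nlist_every", 12L)),
      skin = getOption("actomyosim.skin", 25),
      max_disp = 70
    )
  )
}

# sibling arm index (the other arm sharing the anchor), or 0 when none
.arm_siblings <- function(state) {
  n <- nrow(state$arms)
  sib <- integer(n)
  if (n == 0) return(sib)
  for (q in seq_len(n)) {
    s <- which(state$arms$anchor == state$arms$anchor[q])
    s <- s[s != q]
    sib[q] <- if (length(s)) s[1] else 0L
  }
  sib
}

#' Advance a simulation state in time
#'
#' Runs the overdamped Langevin integrator: deterministic forces
#' (stretching, bending, actin-actin repulsion, motor-arm two-spring
#' forces, cross-linker springs, wall penalties), thermal kicks satisfying
#' the fluctuation-dissipation relation, and the forward Euler update.
#' Motor-arm kinetics (binding with polarity alignment and same-anchor
#' exclusion, load-dependent walking toward the barbed end, catch-bond
#' unbinding) run on top of the mechanics.
#'
#' Reproducibility: all randomness is drawn from R's RNG stream, so
#' `set.seed()` before the call makes trajectories bit-identical.
#'
#' @param state an `actomyo_state`.
#' @param nsteps number of time steps of `params$dt` seconds.
#' @param record_every snapshot interval in steps (0 = no snapshots).
#' @param freeze_actin hold all actin vertices fixed (initialization phase).
#' @param thermal include thermal forces.
#' @param bind,walk,unbind enable the corresponding kinetic events.
#' @return list with `state` (advanced), and `snapshots` (list of
#'   `list(time, pos, arms)` records).
#' @export
advance <- function(state, nsteps, record_every = 0, freeze_actin = FALSE,
                    thermal = TRUE, bind = TRUE, walk = TRUE, unbind = TRUE) {
  sys <- .state_sys(state)
  res <- .am_run(sys, as.integer(nsteps), as.integer(record_every),
                 freeze_actin, thermal, bind, walk, unbind)
  if (res$aborted) {
    stop("integration aborted at step ", res$steps_done, ": ",
         res$abort_reason,
         " (check stiffness/dt combination)")
  }
  t0 <- state$time
  state$pos <- res$pos
  state$occ <- matrix(res$occ, nrow = nrow(state$occ), byrow = TRUE)
  state$arms$bound <- res$arm_bound == 1L
  state$arms$seg <- ifelse(res$arm_bound == 1L, res$arm_seg + 1L, NA_integer_)
  state$arms$site <- ifelse(res$arm_bound == 1L, res$arm_site + 1L, NA_integer_)
  state$time <- t0 + nsteps * state$params$dt
  snaps <- lapply(res$snapshots, function(sn) {
    list(time = t0 + sn$step * state$params$dt,
         pos = sn$pos,
         arms = data.frame(
           bound = sn$arm_bound == 1L,
           seg = ifelse(sn$arm_bound == 1L, sn$arm_seg + 1L, NA_integer_),
           site = ifelse(sn$arm_bound == 1L, sn$arm_site + 1L, NA_integer_)))
  })
  list(state = state, snapshots = snaps)
}

#' Deterministic forces of the current configuration
#'
#' Evaluates every force category once, with exact all-pairs repulsion, and
#' returns the per-vertex decomposition together with per-arm loads and the
#' force each bound arm exerts on its filament site.
#'
#' @param state an `actomyo_state`.
#' @return list of N x 3 matrices (`total`, `stretch`, `bend`, `acp`,
#'   `arm`, `repulsion`, `wall`, all pN) plus `arm_load` (pN) and
#'   `arm_fsite` (pN, per arm).
#' @export
compute_forces <- function(state) {
  .am_forces(.state_sys(state))
}

#' Total potential energy of the current configuration
#'
#' Sum of stretching, bending, repulsion, motor-arm, cross-linker and wall
#' potentials, in pN nm.
#'
#' @param state an `actomyo_state`.
#' @return scalar energy (pN nm).
#' @export
potential_energy <- function(state) {
  .am_energy(.state_sys(state))
}

#' Thermal force sample
#'
#' Draws stochastic forces satisfying the fluctuation-dissipation relation:
#' each Cartesian component has mean zero and variance `2 kBT zeta / dt`.
#'
#' @param zeta drag coefficient (N s/m).
#' @param params an `actomyo_params` (uses `kBT`, `dt`).
#' @param n number of 3-vector samples.
#' @return n x 3 matrix of forces (N).
#' @export
thermal_force <- function(zeta, params = default_params(), n = 1) {
  if (zeta <= 0) stop("zeta must be > 0")
  sd <- sqrt(2 * params$kBT * zeta / params$dt)
  matrix(stats::rnorm(3 * n, 0, sd), n, 3)
}
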