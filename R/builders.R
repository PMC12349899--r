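# Builders for the three simulated systems: an anti-parallel filament pair
# clamped between rigid walls, a disorganized bundle on an N_F x N_F lane
# grid, and a quasi-2D random network grown by nucleation/polymerization.

#' System specification
#'
#' Collects everything a builder needs: system kind, domain, counts and
#' motor architecture. Defaults reproduce the reference conditions
#' (24-arm motors, 2 motors + 16 cross-linkers for the filament pair).
#'
#' @param kind `"two_filament"`, `"bundle"` or `"network"`.
#' @param box_um domain dimensions (um).
#' @param filament_um actin filament length (um).
#' @param N_F bundle lane-grid parameter (filament count is `2 N_F^2`).
#' @param N_M motor count.
#' @param N_ACP cross-linker count.
#' @param f motor-localization fraction in (0, 1]: motors centers are drawn
#'   from a region of length `f * L_z` centered at mid-height.
#' @param N_a,L_bz,L_sp motor architecture (see [build_motor()]).
#' @param target_length_um (networks) mean filament length to calibrate the
#'   polymerization/nucleation ratio to.
#' @param total_actin_um (networks) total actin length to grow.
#' @return A `system_spec` list.
#' @export
system_spec <- function(kind = c("two_filament", "bundle", "network"),
                        box_um = NULL, filament_um = NULL,
                        N_F = 2, N_M = NULL, N_ACP = NULL, f = 1,
                        N_a = 24, L_bz = 42, L_sp = 42,
                        target_length_um = 10, total_actin_um = NULL) {
  kind <- match.arg(kind)
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]")
  if (is.null(box_um))
    box_um <- switch(kind, two_filament = c(5, 5, 20), bundle = c(5, 5, 20),
                     network = c(20, 20, 0.1))
  if (is.null(filament_um))
    filament_um <- switch(kind, two_filament = 19, bundle = 9, network = NA)
  if (is.null(N_M)) N_M <- switch(kind, two_filament = 2, bundle = 4,
                                  network = 8)
  if (is.null(N_ACP)) N_ACP <- switch(kind, two_filament = 16, bundle = 120,
                                      network = 60)
  if (is.null(total_actin_um) && kind == "network")
    total_actin_um <- 400
  structure(list(kind = kind, box_um = box_um, filament_um = filament_um,
                 N_F = N_F, N_M = N_M, N_ACP = N_ACP, f = f,
                 N_a = N_a, L_bz = L_bz, L_sp = L_sp,
                 target_length_um = target_length_um,
                 total_actin_um = total_actin_um),
            class = "system_spec")
}

#' Documented density-to-count calibration pairs
#'
#' The bundle studies fix motor and cross-linker densities rather than
#' counts; the printed calibration points are `R_M = 0.005` corresponding
#' to `N_M = 4` at `N_F = 2` and `N_M = 52` at `N_F = 7`, with
#' `R_ACP = 0.04`. Counts are the primary interface of the builders; this
#' helper documents the printed pairings.
#'
#' @param N_F bundle size parameter.
#' @param R_M motor density parameter.
#' @return data frame with the known calibration rows matching the inputs.
#' @export
binder_density_table <- function(N_F = NULL, R_M = NULL) {
  tab <- data.frame(N_F = c(2, 7), R_M = c(0.005, 0.005),
                    N_M = c(4, 52), R_ACP = c(0.04, 0.04))
  if (!is.null(N_F)) tab <- tab[tab$N_F %in% N_F, ]
  if (!is.null(R_M)) tab <- tab[tab$R_M %in% R_M, ]
  tab
}

#' Build the clamped anti-parallel filament pair
#'
#' Two anti-parallel filaments run along z, laterally separated by
#' `2 r0_M2` so that a motor centered between them sits at its transverse
#' spring equilibrium from both. Each barbed end is clamped to the wall it
#' points at (filament 1: barbed at z = 0; filament 2: barbed at z = L_z).
#' `N_M` motors are placed at uniform-random z inside the overlap region
#' (backbone fully inside), and `N_ACP` permanent cross-linkers link the
#' two filaments at uniform-random admissible sites within the overlap.
#'
#' @param spec a `system_spec` of kind `"two_filament"`.
#' @param params an `actomyo_params` object.
#' @return An `actomyo_state`.
#' @export
build_two_filament_system <- function(spec = system_spec("two_filament"),
                                      params = default_params()) {
  stopifnot(spec$kind == "two_filament")
  box <- spec$box_um * 1000
  Lf <- spec$filament_um * 1000
  if (Lf > box[3]) stop("filament longer than the domain")
  st <- new_state(params, spec$box_um, c("periodic", "periodic", "wall"))
  xc <- box[1] / 2; yc <- box[2] / 2
  dx <- params$r0_M2
  f1 <- build_filament(Lf, c(xc - dx, yc, 0), c(0, 0, 1), params)
  f2 <- build_filament(Lf, c(xc + dx, yc, box[3]), c(0, 0, -1), params)
  st <- add_filament(st, f1, clamp_barbed = TRUE)
  st <- add_filament(st, f2, clamp_barbed = TRUE)
  z_lo <- box[3] - f1$length   # overlap region
  z_hi <- f1$length
  motor <- build_motor(spec$N_a, spec$L_bz, spec$L_sp)
  if (z_hi - z_lo < motor$L_M) stop("overlap shorter than the motor")
  for (m in seq_len(spec$N_M)) {
    zc <- stats::runif(1, z_lo + motor$L_M / 2, z_hi - motor$L_M / 2)
    st <- add_motor(st, motor, c(xc, yc, zc), c(0, 0, 1))
  }
  st <- init_crosslinks(st, spec$N_ACP, z_range = c(z_lo, z_hi))
  st
}

#' Build a disorganized bundle
#'
#' `N_F^2` lanes on a square grid with 27-nm pitch, centered in the
#' cross-section; two filaments per lane (total `2 N_F^2`), each placed at
#' a uniform-random z offset (wrapping through the periodic z boundary)
#' with random polarity. Motors and cross-linkers are then placed by
#' [place_binders()].
#'
#' @param spec a `system_spec` of kind `"bundle"`.
#' @param params an `actomyo_params` object.
#' @return An `actomyo_state` (all axes periodic).
#' @export
build_bundle <- function(spec = system_spec("bundle"),
                         params = default_params()) {
  stopifnot(spec$kind == "bundle")
  if (spec$N_F < 1) stop("N_F must be >= 1")
  box <- spec$box_um * 1000
  Lf <- spec$filament_um * 1000
  st <- new_state(params, spec$box_um, c("periodic", "periodic", "periodic"))
  pitch <- 27
  lane <- (seq_len(spec$N_F) - (spec$N_F + 1) / 2) * pitch
  n_fil <- 2L * spec$N_F^2
  # draw all z offsets and polarities; a bundle severed by a z-interval
  # holding no filament cannot bear ring tension, so redraw until the
  # pooled arcs cover the ring (with a 100-nm junction-overlap margin)
  for (try in 1:200) {
    z0 <- stats::runif(n_fil, 0, box[3])
    up <- stats::runif(n_fil) < 0.5
    if (.arcs_cover_ring(z0, Lf, box[3], margin = 100)) break
    if (try == 200) {
      msg <- "bundle ring coverage not achieved; filaments leave a gap"
      warning(msg)
      st$warnings <- c(st$warnings, msg)
    }
  }
  q <- 0L
  for (ix in seq_len(spec$N_F)) {
    for (iy in seq_len(spec$N_F)) {
      for (w in 1:2) {
        q <- q + 1L
        org <- c(box[1] / 2 + lane[ix], box[2] / 2 + lane[iy],
                 if (up[q]) z0[q] else (z0[q] + Lf) %% box[3])
        fl <- build_filament(Lf, org, c(0, 0, if (up[q]) 1 else -1), params)
        fl$coords[, 3] <- fl$coords[, 3] %% box[3]
        st <- add_filament(st, fl)
      }
    }
  }
  place_binders(st, spec$N_M, spec$N_ACP, spec$f,
                motor = build_motor(spec$N_a, spec$L_bz, spec$L_sp))
}

#' Place motors and cross-linkers in a built bundle
#'
#' Motor centers are drawn uniformly from the z-interval of length
#' `f * L_z` centered at mid-height (`f = 1`: anywhere); backbones are
#' oriented along z and positioned at a uniform-random point of the lane
#' grid's cross-section, from which every neighboring lane is within the
#' arms' capture radius. Cross-linkers are placed over the whole bundle by
#' [init_crosslinks()]. Arms bind during the subsequent settling phase of
#' [simulate_system()].
#'
#' @param state a bundle `actomyo_state` with filaments only.
#' @param N_M motor count.
#' @param N_ACP cross-linker count.
#' @param f localization fraction in (0, 1].
#' @param motor a `motor_spec`.
#' @return The updated state.
#' @export
place_binders <- function(state, N_M, N_ACP, f = 1,
                          motor = build_motor(24, 42, 42)) {
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]")
  box <- state$box
  zc0 <- box[3] / 2
  half <- f * box[3] / 2
  if (2 * half < motor$L_M && f < 1) {
    msg <- "motor allocation region shorter than the motor backbone"
    warning(msg)
    state$warnings <- c(state$warnings, msg)
  }
  xy <- .lane_extent(state)
  for (m in seq_len(N_M)) {
    zc <- (zc0 + stats::runif(1, -half, half)) %% box[3]
    xc <- stats::runif(1, xy$x[1], xy$x[2])
    yc <- stats::runif(1, xy$y[1], xy$y[2])
    state <- add_motor(state, motor, c(xc, yc, zc), c(0, 0, 1))
  }
  if (N_ACP > 0) state <- init_crosslinks(state, N_ACP)
  state
}

# do arcs of length `len` starting at z0 (mod L) cover the whole ring,
# with each arc shrunk by `margin` at both ends so junctions overlap?
.arcs_cover_ring <- function(z0, len, L, margin = 0, grid = 10) {
  pts <- seq(0, L - grid, by = grid)
  covered <- rep(FALSE, length(pts))
  a <- (z0 + margin) %% L
  l2 <- len - 2 * margin
  for (q in seq_along(a)) {
    d <- (pts - a[q]) %% L
    covered <- covered | (d <= l2)
  }
  all(covered)
}

# bounding box of actin positions in the cross-section
.lane_extent <- function(state) {
  act <- state$vtype == 0L
  list(x = range(state$pos[act, 1]), y = range(state$pos[act, 2]))
}

#' Grow network filament lengths by nucleation and polymerization
#'
#' Stochastic growth: nucleation creates a one-segment seed at rate
#' `k_n_A`; every barbed end elongates by one segment at rate `k_p_A`;
#' growth stops when the target total segment count is reached.
#'
#' @param k_n nucleation rate (1/s).
#' @param k_p polymerization rate per barbed end (1/s).
#' @param target_segments total segment budget.
#' @return integer vector of per-filament segment counts.
#' @export
grow_filament_lengths <- function(k_n, k_p, target_segments) {
  lens <- integer(0)
  total <- 0L
  while (total < target_segments) {
    n <- length(lens)
    rate_tot <- k_n + k_p * n
    ev <- stats::runif(1) * rate_tot
    if (ev < k_n) { lens <- c(lens, 1L) }
    else { i <- 1L + as.integer((ev - k_n) %/% k_p); lens[i] <- lens[i] + 1L }
    total <- total + 1L
  }
  lens
}

#' Calibrate the polymerization rate for a target mean filament length
#'
#' With constant-rate nucleation and constant-speed elongation stopped at a
#' total mass `M` (segments), filament ages are ~uniform, so the mean
#' length is `k_p T / 2` with `M = k_n k_p T^2 / 2`. Eliminating the stop
#' time gives `k_p = 2 k_n mean^2 / M`.
#'
#' @param k_n nucleation rate (1/s).
#' @param target_segments total segment budget.
#' @param mean_segments desired mean filament length in segments.
#' @return polymerization rate `k_p` (1/s).
#' @export
calibrate_polymerization <- function(k_n, target_segments, mean_segments) {
  2 * k_n * mean_segments^2 / target_segments
}

#' Build a quasi-2D random network
#'
#' Filaments are grown by the nucleation/polymerization process, then laid
#' down at uniform-random xy positions and in-plane orientations in a thin
#' slab (periodic in x and y, repulsive walls in z); all filament axes are
#' perpendicular to z. Motors are placed at random in-plane positions and
#' orientations; cross-linkers at admissible site pairs.
#'
#' @param spec a `system_spec` of kind `"network"`.
#' @param params an `actomyo_params` object.
#' @return An `actomyo_state`.
#' @export
build_network <- function(spec = system_spec("network"),
                          params = default_params()) {
  stopifnot(spec$kind == "network")
  box <- spec$box_um * 1000
  target_seg <- round(spec$total_actin_um * 1000 / params$r0_A)
  mean_seg <- spec$target_length_um * 1000 / params$r0_A
  k_p <- calibrate_polymerization(params$k_n_A, target_seg, mean_seg)
  lens <- grow_filament_lengths(params$k_n_A, k_p, target_seg)
  st <- new_state(params, spec$box_um, c("periodic", "periodic", "wall"))
  zmid <- box[3] / 2
  for (L in lens) {
    th <- stats::runif(1, 0, 2 * pi)
    org <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]), zmid)
    fl <- build_filament(L * params$r0_A, org, c(cos(th), sin(th), 0), params)
    fl$coords[, 1] <- fl$coords[, 1] %% box[1]
    fl$coords[, 2] <- fl$coords[, 2] %% box[2]
    st <- add_filament(st, fl)
  }
  motor <- build_motor(spec$N_a, spec$L_bz, spec$L_sp)
  for (m in seq_len(spec$N_M)) {
    th <- stats::runif(1, 0, 2 * pi)
    ctr <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]), zmid)
    st <- add_motor(st, motor, ctr, c(cos(th), sin(th), 0))
  }
  if (spec$N_ACP > 0) st <- init_crosslinks(st, spec$N_ACP)
  st
}

#' Build any system from its specification
#'
#' @param spec a `system_spec`.
#' @param params an `actomyo_params` object.
#' @return An `actomyo_state`.
#' @export
build_system <- function(spec, params = default_params()) {
  switch(spec$kind,
         two_filament = build_two_filament_system(spec, params),
         bundle = build_bundle(spec, params),
         network = build_network(spec, params),
         stop("unknown system kind"))
}
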