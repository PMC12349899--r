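# Physical validation assays: worm-like-chain statistics of free filaments.

#' Sample an equilibrium worm-like-chain filament configuration
#'
#' Draws the joint angles of a discrete worm-like chain from the Boltzmann
#' distribution of the bending Hamiltonian (`p(theta) ~ sin(theta)
#' exp(-kappa_b theta^2 / 2 kBT)`, azimuths uniform) and assembles vertex
#' positions with all segments at rest length. Used to start thermal runs
#' in equilibrium so finite-length relaxation of the slowest bending modes
#' does not bias time-averaged statistics.
#'
#' @param n_seg number of segments.
#' @param params an `actomyo_params` object.
#' @param origin barbed-end position (nm).
#' @return n_seg+1 x 3 coordinate matrix.
#' @export
wlc_sample_filament <- function(n_seg, params = default_params(),
                                origin = c(0, 0, 0)) {
  beta_k <- (params$kappa_b_A * 1e21) / (params$kBT * 1e21)  # 1/rad^2
  t <- c(0, 0, 1)
  pos <- matrix(0, n_seg + 1, 3)
  pos[1, ] <- origin
  for (s in seq_len(n_seg)) {
    if (s > 1) {
      # Rayleigh proposal with sin(theta)/theta rejection
      repeat {
        th <- sqrt(-2 * log(stats::runif(1)) / beta_k)
        if (th < pi && stats::runif(1) < sin(th) / th) break
      }
      phi <- stats::runif(1, 0, 2 * pi)
      e1 <- .perp_unit(t)
      e2 <- .cross(t, e1)
      t <- cos(th) * t + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
      t <- t / sqrt(sum(t^2))
    }
    pos[s + 1, ] <- pos[s, ] + params$r0_A * t
  }
  pos
}

#' Tangent-tangent correlation of filament snapshots
#'
#' Ensemble average of `t(s0 + s) . t(s0)` over all tangent pairs of all
#' filaments and snapshots, as a function of the arc separation `s`.
#'
#' @param snapshots list of position matrices (or snapshot lists with a
#'   `pos` element).
#' @param fils list of vertex-index vectors, one per filament.
#' @param max_sep_segments largest separation (in segments).
#' @return data frame with `s_nm` and `corr`.
#' @export
tangent_correlation <- function(snapshots, fils, max_sep_segments = 14) {
  r0 <- NULL
  acc <- matrix(0, max_sep_segments, 2)  # sum, count
  for (sn in snapshots) {
    pos <- if (is.list(sn) && !is.null(sn$pos)) sn$pos else sn
    for (v in fils) {
      tg <- diff(pos[v, , drop = FALSE])
      tg <- tg / sqrt(rowSums(tg^2))
      if (is.null(r0)) r0 <- mean(sqrt(rowSums(diff(pos[v, ])^2)))
      n <- nrow(tg)
      for (s in seq_len(min(max_sep_segments, n - 1))) {
        d <- rowSums(tg[1:(n - s), , drop = FALSE] *
                       tg[(1 + s):n, , drop = FALSE])
        acc[s, 1] <- acc[s, 1] + sum(d)
        acc[s, 2] <- acc[s, 2] + length(d)
      }
    }
  }
  data.frame(s_nm = r0 * seq_len(max_sep_segments),
             corr = acc[, 1] / acc[, 2])
}

#' Persistence length from a thermal simulation of free filaments
#'
#' Simulates free 9-um filaments (64 segments each, worm-like-chain
#' initial draw) under thermal forces only, accumulates the
#' tangent-tangent correlation over snapshots after a discard fraction,
#' and fits `exp(-s / Lp)` over separations up to ~2 um by a
#' through-origin regression of `log C` on `s` with inverse-variance
#' weights. Fluctuations of `log C(s)` grow roughly linearly with
#' separation - they are dominated by slowly relaxing long-wavelength
#' bending modes - so the regression weights are `1/s^2` on `log C`
#' (equivalently `1/s^4` on the per-separation slope estimates), which
#' keeps the noisy large-separation points from dominating the fit.
#'
#' @param n_steps integration steps.
#' @param n_fil number of independent filaments simulated together
#'   (placed far apart in an open domain).
#' @param params an `actomyo_params` object.
#' @param sample_every snapshot interval (steps).
#' @param discard fraction of initial snapshots discarded.
#' @param filament_um filament length (um).
#' @return list with `Lp_um` (fitted persistence length) and `corr`
#'   (the correlation table).
#' @export
persistence_length_run <- function(n_steps = 2e6, n_fil = 2,
                                   params = default_params(),
                                   sample_every = 5e3, discard = 0.25,
                                   filament_um = 9) {
  n_seg <- round(filament_um * 1000 / params$r0_A)
  st <- new_state(params, box_um = c(100, 100, 100), rep("open", 3))
  for (q in seq_len(n_fil)) {
    coords <- wlc_sample_filament(n_seg, params,
                                  origin = c(2e4 * q, 5e4, 3e4))
    f <- build_filament(n_seg * params$r0_A, coords[1, ], c(0, 0, 1), params)
    f$coords <- coords
    st <- add_filament(st, f)
  }
  run <- advance(st, n_steps, record_every = sample_every,
                 bind = FALSE, walk = FALSE, unbind = FALSE)
  snaps <- run$snapshots
  keep <- snaps[seq_along(snaps) > discard * length(snaps)]
  max_sep <- max(2L, floor(2000 / params$r0_A))
  ct <- tangent_correlation(keep, st$fils, max_sep_segments = max_sep)
  ok <- ct$corr > 0
  # weighted through-origin fit of log C = -s/Lp: GLS slope with
  # Var(log C) ~ s^2 gives weights 1/s^4 on the per-s slopes
  w <- 1 / ct$s_nm[ok]^4
  slope <- sum(w * ct$s_nm[ok] * log(ct$corr[ok])) / sum(w * ct$s_nm[ok]^2)
  Lp_nm <- -1 / slope
  list(Lp_um = Lp_nm / 1000, corr = ct)
}
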