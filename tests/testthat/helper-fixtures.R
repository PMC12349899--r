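# In-code fixtures for unit tests. Everything is generated, nothing stored.

# a short free filament, optionally bent by thermal-scale noise
fixture_filament_state <- function(n_seg = 4, jitter = 0,
                                   params = default_params(),
                                   boundary = rep("open", 3)) {
  st <- new_state(params, box_um = c(5, 5, 5), boundary = boundary)
  st <- add_filament(st, build_filament(n_seg * params$r0_A,
                                        c(500, 500, 500), c(0, 0, 1),
                                        params))
  if (jitter > 0)
    st$pos <- st$pos + matrix(stats::rnorm(length(st$pos), 0, jitter),
                              nrow(st$pos), 3)
  st
}

# two parallel filaments bridged by one cross-linker, plus one motor with a
# manually bound arm: exercises every force term
fixture_full_state <- function(jitter = 0, params = default_params()) {
  st <- new_state(params, box_um = c(5, 5, 5), boundary = rep("open", 3))
  st <- add_filament(st, build_filament(3 * params$r0_A,
                                        c(2000, 2000, 2000), c(0, 0, 1),
                                        params))
  st <- add_filament(st, build_filament(3 * params$r0_A,
                                        c(2030, 2000, 2420), c(0, 0, -1),
                                        params))
  st <- init_crosslinks(st, 1)
  st <- add_motor(st, build_motor(8, 42, 42), c(2015, 2014, 2210), c(0, 0, 1))
  # bind one right-side arm to filament 2 (its barbed end sits at high z,
  # so an arm walking toward +z is properly aligned)
  arm <- which(st$arms$side == "R")[1]
  seg <- which(st$seg$fil == 2)[2]
  st$arms$bound[arm] <- TRUE
  st$arms$seg[arm] <- seg
  st$arms$site[arm] <- 7L
  st$occ[seg, 7L] <- arm + 1L
  if (jitter > 0)
    st$pos <- st$pos + matrix(stats::rnorm(length(st$pos), 0, jitter),
                              nrow(st$pos), 3)
  st
}

# central-difference gradient of the potential energy
numerical_gradient <- function(state, h = 1e-4) {
  g <- matrix(0, nrow(state$pos), 3)
  for (i in seq_len(nrow(state$pos))) {
    for (d in 1:3) {
      sp <- state; sp$pos[i, d] <- sp$pos[i, d] + h
      sm <- state; sm$pos[i, d] <- sm$pos[i, d] - h
      g[i, d] <- (potential_energy(sp) - potential_energy(sm)) / (2 * h)
    }
  }
  g
}

# a state of n independent beads (no bonds), for diffusion checks
fixture_beads_state <- function(n, params = default_params()) {
  st <- new_state(params, box_um = c(50, 50, 50), boundary = rep("open", 3))
  coords <- matrix(stats::runif(3 * n, 2e4, 3e4), n, 3)
  av <- actomyosim:::.add_vertices(st, coords, 0L)
  av$state
}
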