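#' Construct a semiflexible actin filament
#'
#' An actin filament is a chain of cylindrical segments of rest length
#' `r0_A` (140 nm by default). The number of segments is the nearest
#' integer to `length / r0_A` (minimum 1), and each segment keeps the exact
#' rest length, so a requested 9000 nm gives 64 segments of 140 nm.
#' Vertex 0 is the barbed end; motor arms walk toward it. Each segment
#' carries discrete binding sites every `site_spacing` nm (20 per segment
#' with defaults), shared by cross-linkers and motor arms.
#'
#' @param length filament length (nm); must be at least one segment.
#' @param origin 3-vector, position of the barbed end (nm).
#' @param direction 3-vector pointing from barbed to pointed end
#'   (normalized internally).
#' @param params an `actomyo_params` object.
#' @return A `filament_spec`: list with `coords` (vertex matrix, barbed end
#'   first), `n_seg`, `length` (realized, nm) and `polarity` (unit vector
#'   barbed to pointed).
#' @examples
#' f <- build_filament(9000, c(0, 0, 0), c(0, 0, 1))
#' f$n_seg  # 64
#' @export
build_filament <- function(length, origin = c(0, 0, 0),
                           direction = c(0, 0, 1),
                           params = default_params()) {
  if (length < params$r0_A)
    stop("filament length must be at least one segment (", params$r0_A, " nm)")
  dirn <- direction / sqrt(sum(direction^2))
  n_seg <- max(1L, as.integer(round(length / params$r0_A)))
  s <- params$r0_A * (0:n_seg)
  coords <- cbind(origin[1] + s * dirn[1],
                  origin[2] + s * dirn[2],
                  origin[3] + s * dirn[3])
  structure(list(coords = coords, n_seg = n_seg,
                 length = n_seg * params$r0_A, polarity = dirn),
            class = "filament_spec")
}

#' Construct a bipolar motor (thick) filament
#'
#' A motor filament has a straight backbone of serially connected segments
#' with a central arm-free bare zone, flanked symmetrically by arm-bearing
#' segments of length `L_sp`. Every endpoint of an arm-bearing segment
#' carries two arms; each arm lumps `N_h` myosin heads. Arms on the left
#' half of the backbone walk (and pull) toward the left backbone end, arms
#' on the right half toward the right end, mimicking the bipolar polarity
#' of myosin II thick filaments.
#'
#' The three structural variation modes are all expressed through the
#' arguments: more arms (`N_a` up, `L_bz = L_sp = L_MB`), a longer bare
#' zone (`L_bz` a larger multiple of `L_sp`), or wider arm spacing
#' (`L_sp = L_bz` both enlarged). The bare zone is realized as
#' `L_bz / L_sp` segments of length `L_sp`.
#'
#' Total backbone length: `L_M = 2 * L_sp * (N_a/4 - 1) + L_bz`. With the
#' reference architecture (`N_a = 24`, `L_bz = L_sp = 42`) this gives 11
#' segments and `L_M = 462` nm. In the degenerate `N_a = 4` case the single
#' bare-zone segment's two endpoints carry the arms.
#'
#' @param N_a number of arms; must be >= 4 and divisible by 4.
#' @param L_bz bare-zone length (nm), positive multiple of `L_sp`.
#' @param L_sp arm spacing / backbone segment length (nm), positive.
#' @return A `motor_spec`: list with `N_a`, `L_bz`, `L_sp`, `L_M`,
#'   `n_seg`, `seg_len`, `arm_table` (data frame: vertex index 1-based
#'   along the backbone, side "L"/"R", walk-direction vertex pair) and
#'   `bare_zone` (segment index range).
#' @examples
#' m <- build_motor(24, 42, 42)
#' m$L_M    # 462
#' m$n_seg  # 11
#' @export
build_motor <- function(N_a, L_bz = 42, L_sp = 42) {
  if (N_a < 4 || N_a %% 4 != 0)
    stop("N_a must be >= 4 and divisible by 4 (bipolar geometry undefined)")
  if (L_bz <= 0 || L_sp <= 0) stop("L_bz and L_sp must be positive")
  n_bz <- L_bz / L_sp
  if (abs(n_bz - round(n_bz)) > 1e-9)
    stop("L_bz must be a positive multiple of the segment length L_sp")
  n_bz <- as.integer(round(n_bz))
  n_arm_side <- N_a / 4 - 1          # arm-bearing segments per side
  n_seg <- 2L * n_arm_side + n_bz
  L_M <- 2 * L_sp * n_arm_side + L_bz
  n_vert <- n_seg + 1L
  # arm-bearing vertices: endpoints of the non-bare segments; in the
  # degenerate N_a = 4 case, the bare segment's two endpoints
  n_side_vert <- N_a / 4             # arm-bearing vertices per side
  left_v <- seq_len(n_side_vert)
  right_v <- n_vert - seq_len(n_side_vert) + 1L
  arm_vert <- c(left_v, rev(right_v))
  side <- rep(c("L", "R"), each = n_side_vert)
  # walking direction along the backbone: toward the arm's own end
  wfrom <- integer(length(arm_vert))
  wto <- integer(length(arm_vert))
  for (q in seq_along(arm_vert)) {
    v <- arm_vert[q]
    if (side[q] == "L") {
      if (v == 1L) { wfrom[q] <- 2L; wto[q] <- 1L }
      else { wfrom[q] <- v; wto[q] <- v - 1L }
    } else {
      if (v == n_vert) { wfrom[q] <- n_vert - 1L; wto[q] <- n_vert }
      else { wfrom[q] <- v; wto[q] <- v + 1L }
    }
  }
  arm_table <- data.frame(
    vertex = rep(arm_vert, each = 2L),
    side = rep(side, each = 2L),
    wfrom = rep(wfrom, each = 2L),
    wto = rep(wto, each = 2L)
  )
  stopifnot(nrow(arm_table) == N_a)
  structure(list(N_a = N_a, L_bz = L_bz, L_sp = L_sp, L_M = L_M,
                 n_seg = n_seg, seg_len = L_sp, n_vert = n_vert,
                 bare_zone = c(n_arm_side + 1L, n_arm_side + n_bz),
                 arm_table = arm_table),
            class = "motor_spec")
}

#' @export
print.motor_spec <- function(x, ...) {
  cat(sprintf(
    "<motor_spec> N_a = %d arms, L_bz = %g nm, L_sp = %g nm, L_M = %g nm (%d segments)\n",
    x$N_a, x$L_bz, x$L_sp, x$L_M, x$n_seg))
  invisible(x)
}

#' Distribute a point force applied along a segment onto its endpoints
#'
#' A force applied at axial fraction `s` of a segment (0 = barbed-side
#' endpoint) is shared linearly: the barbed-side vertex receives
#' `(1 - s) * F`, the pointed-side vertex `s * F`. The sum is conserved
#' exactly.
#'
#' @param point_force numeric 3-vector (pN).
#' @param s axial fraction in `[0, 1]`.
#' @return list with `barbed` and `pointed` force 3-vectors.
#' @export
distribute_to_endpoints <- function(point_force, s) {
  if (s < 0 || s > 1) stop("axial fraction s must lie in [0, 1]")
  list(barbed = (1 - s) * point_force, pointed = s * point_force)
}
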