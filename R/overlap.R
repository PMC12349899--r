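# Contractile-unit overlap theory.
#
# Motors in a cross-linked bundle partition it into serially connected
# contractile units; forces of motors within one unit add, units in series
# do not. Two motors cooperate when their backbones overlap by at least the
# critical length L_c = 2 L_sp (N_a/4 - 1): with that much overlap, no
# cross-linker can sit between the two arm-bearing halves and counteract
# one motor against the other. The effective number of cooperating motors
#   Xi = max over motors i and sides j of ( 1 + sum_k xi_ik^j ),
# with xi = 1 for full cooperative overlap, L_ov/L_c for partial overlap
# and 0 for none, predicts the bundle force F_est = F_st N_h N_a Xi / 2.

#' Critical overlap length for cooperative motor pairs
#'
#' `L_c = 2 L_sp (N_a / 4 - 1)`: twice the backbone length occupied by the
#' arms on one side of a motor. For the degenerate 4-arm motor any contact
#' is fully cooperative (`L_c = 0`).
#'
#' @param N_a arms per motor (>= 4, divisible by 4).
#' @param L_sp arm spacing (nm).
#' @return critical length (nm).
#' @examples
#' critical_length(24, 42)  # 420
#' @export
critical_length <- function(N_a, L_sp) {
  if (any(N_a < 4) || any(N_a %% 4 != 0))
    stop("N_a must be >= 4 and divisible by 4")
  2 * L_sp * (N_a / 4 - 1)
}

#' Pairwise cooperativity of two overlapping motors
#'
#' @param L_ov overlap length between two motor backbones (nm, >= 0).
#' @param L_c critical overlap length (nm).
#' @param L_M motor backbone length (nm); overlaps are capped at `L_M`.
#' @return xi in `[0, 1]`: 1 if `L_c <= L_ov <= L_M`, `L_ov / L_c` if
#'   `0 < L_ov < L_c`, 0 if `L_ov = 0`.
#' @export
pairwise_xi <- function(L_ov, L_c, L_M = Inf) {
  if (any(L_ov < 0)) stop("negative overlap length")
  L_ov <- pmin(L_ov, L_M)
  ifelse(L_ov >= L_c, 1, ifelse(L_ov > 0, L_ov / L_c, 0))
}

# overlap length of two intervals centered at c1, c2 with half-lengths
# h1, h2, optionally on a ring of circumference `wrap`
.interval_overlap <- function(dc, h1, h2, wrap = NULL) {
  if (!is.null(wrap)) dc <- dc - wrap * round(dc / wrap)
  pmax(0, pmin(h1 + h2 - abs(dc), 2 * pmin(h1, h2)))
}

#' Maximum number of cooperatively overlapping motors
#'
#' Evaluates `Xi` for a motor configuration. Each motor contributes a left
#' and a right evaluation window: a neighbor is counted on side L (R) when
#' its backbone center lies at or left (right) of the reference motor's
#' center; a neighbor whose backbone spans the reference center counts on
#' both sides. `Xi` ranges from 1 (no overlaps) to the number of motors
#' (all stacked).
#'
#' For 2D networks (`mode = "network"`), motors are compared pairwise only
#' when their axis directions differ by less than 30 degrees (axes are
#' directionless), and the overlap is that of their projections onto the
#' pair's mean axis.
#'
#' @param motors data frame with columns `center` (nm; for networks
#'   `x`, `y` in nm and `angle` in radians), `L_M` (nm), and per-motor
#'   `N_a`, `L_sp` (used for each reference motor's own `L_c`).
#' @param wrap ring circumference (nm) for periodic bundles, or `NULL`.
#' @param mode `"bundle"` (1D z-intervals) or `"network"` (2D axes).
#' @return list with `Xi`, `argmax` (motor index), `side` ("L"/"R"),
#'   and `xi` (data frame of nonzero pairwise terms).
#' @export
xi_max <- function(motors, wrap = NULL, mode = c("bundle", "network")) {
  mode <- match.arg(mode)
  n <- nrow(motors)
  if (n < 1) stop("Xi is undefined without motors")
  if (!("L_c" %in% names(motors)))
    motors$L_c <- critical_length(motors$N_a, motors$L_sp)
  if (mode == "bundle") {
    # fully vectorized: dc[i, k] = center_k - center_i (minimum image)
    dc <- outer(motors$center, motors$center, function(a, b) b - a)
    if (!is.null(wrap)) dc <- dc - wrap * round(dc / wrap)
    half <- motors$L_M / 2
    L_ov <- pmax(0, pmin(outer(half, half, "+") - abs(dc),
                         2 * outer(half, half, pmin)))
    comparable <- matrix(TRUE, n, n)
  } else {
    L_ov <- matrix(0, n, n)
    comparable <- matrix(FALSE, n, n)
    dc <- matrix(0, n, n)
    for (i in seq_len(n)) for (k in seq_len(n)) {
      if (k == i) next
      ov <- .pair_geometry(motors, i, k, wrap, mode)
      if (is.null(ov)) next
      comparable[i, k] <- TRUE
      L_ov[i, k] <- ov$L_ov
      dc[i, k] <- ov$dc
    }
  }
  Lc_i <- matrix(motors$L_c, n, n)
  xi <- ifelse(L_ov >= Lc_i, 1, ifelse(L_ov > 0, L_ov / Lc_i, 0))
  xi[!comparable] <- 0
  diag(xi) <- 0
  # side membership: a neighbor spanning the reference center counts on
  # both sides, otherwise on the side its center falls on
  half_k <- matrix(motors$L_M / 2, n, n, byrow = TRUE)
  both <- abs(dc) < half_k
  onL <- both | dc < 0
  onR <- both | dc > 0
  sumL <- 1 + rowSums(xi * onL)
  sumR <- 1 + rowSums(xi * onR)
  if (max(sumL) >= max(sumR)) {
    argmax <- which.max(sumL); side <- "L"; Xi <- sumL[argmax]
  } else {
    argmax <- which.max(sumR); side <- "R"; Xi <- sumR[argmax]
  }
  nz <- which(xi > 0, arr.ind = TRUE)
  xi_df <- data.frame(
    i = as.integer(nz[, 1]), k = as.integer(nz[, 2]),
    L_ov = L_ov[nz], xi = xi[nz],
    sides = paste0(ifelse(onL[nz], "L", ""), ifelse(onR[nz], "R", "")))
  list(Xi = unname(Xi), argmax = unname(argmax), side = side, xi = xi_df)
}

# overlap geometry of a motor pair; returns NULL if not comparable
.pair_geometry <- function(motors, i, k, wrap, mode) {
  if (mode == "bundle") {
    dc <- motors$center[k] - motors$center[i]
    if (!is.null(wrap)) dc <- dc - wrap * round(dc / wrap)
    L_ov <- .interval_overlap(dc, motors$L_M[i] / 2, motors$L_M[k] / 2,
                              wrap = NULL)
  } else {
    da <- (motors$angle[k] - motors$angle[i]) %% pi
    if (min(da, pi - da) >= pi / 6) return(NULL)
    am <- motors$angle[i] + if (da <= pi / 2) da / 2 else (da - pi) / 2
    u <- c(cos(am), sin(am))
    d <- c(motors$x[k] - motors$x[i], motors$y[k] - motors$y[i])
    if (!is.null(wrap)) d <- d - wrap * round(d / wrap)
    dc <- sum(d * u)
    # transverse separation beyond reach means no overlap to speak of;
    # the theory ignores transverse geometry, as for bundles
    L_ov <- .interval_overlap(dc, motors$L_M[i] / 2, motors$L_M[k] / 2,
                              wrap = NULL)
  }
  half_k <- motors$L_M[k] / 2
  sides <- if (abs(dc) < half_k) c("L", "R") else if (dc < 0) "L" else "R"
  list(L_ov = L_ov, sides = sides, dc = dc)
}

#' Force predicted from the cooperative motor number
#'
#' `F_est = F_st N_h N_a Xi / 2`: half of a motor's arms can engage one
#' polarity, so a contractile unit of `Xi` cooperating motors pulls with
#' `Xi` times the single-motor force.
#'
#' @param Xi cooperative motor number (>= 1).
#' @param N_a arms per motor.
#' @param N_h heads per arm.
#' @param F_st per-head stall force (pN).
#' @return estimated force (pN).
#' @examples
#' estimate_force(1)  # 547.2 pN with defaults
#' @export
estimate_force <- function(Xi, N_a = 24, N_h = 8, F_st = 5.7) {
  if (any(Xi < 1)) stop("Xi must be >= 1")
  F_st * N_h * N_a * Xi / 2
}

#' Full overlap report for a motor configuration
#'
#' Computes the critical length, all pairwise cooperativities, `Xi` and the
#' predicted force for a set of motors described by positions and
#' architecture.
#'
#' @inheritParams xi_max
#' @param N_h heads per arm.
#' @param F_st per-head stall force (pN).
#' @return An `overlap_report`: list with `L_c` (per motor), `Xi`,
#'   `argmax`, `side`, `xi` (pair table) and `F_est` (pN, using the
#'   argmax motor's arm count).
#' @export
overlap_report <- function(motors, wrap = NULL,
                           mode = c("bundle", "network"),
                           N_h = 8, F_st = 5.7) {
  mode <- match.arg(mode)
  if (!("L_c" %in% names(motors)))
    motors$L_c <- critical_length(motors$N_a, motors$L_sp)
  xm <- xi_max(motors, wrap = wrap, mode = mode)
  rep <- list(L_c = motors$L_c, Xi = xm$Xi, argmax = xm$argmax,
              side = xm$side, xi = xm$xi,
              F_est = estimate_force(xm$Xi, motors$N_a[xm$argmax],
                                     N_h, F_st))
  class(rep) <- "overlap_report"
  rep
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> Xi = %.3f (motor %d, side %s), F_est = %.1f pN\n",
              x$Xi, x$argmax, x$side, x$F_est))
  invisible(x)
}

#' Motor table of a simulation state
#'
#' Extracts the per-motor architecture and current backbone position in the
#' format consumed by [xi_max()] / [overlap_report()].
#'
#' @param state an `actomyo_state` with motors.
#' @return data frame with `center`, `L_M`, `N_a`, `L_sp`, `L_bz`.
#' @export
state_motor_table <- function(state) {
  sp <- motor_spans(state)
  do.call(rbind, lapply(seq_along(state$motors), function(m) {
    s <- state$motors[[m]]$spec
    data.frame(center = sp$center[m], L_M = s$L_M, N_a = s$N_a,
               L_sp = s$L_sp, L_bz = s$L_bz)
  }))
}
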