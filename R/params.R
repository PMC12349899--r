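#' Default simulation parameters
#'
#' Returns the full set of physical constants, geometric reference lengths,
#' stiffnesses and kinetic rates used by the model, as a validated
#' `actomyo_params` object. All values can be overridden by name.
#'
#' Units follow the conventions of the field's bead-spring models:
#' lengths in nm, time in s, energies in J, stiffnesses in N/m (extensional)
#' or N m (bending, per rad^2), forces in pN, viscosity in Pa s.
#'
#' Key defaults: time step `dt = 1.15e-5` s; actin segment length
#' `r0_A = 140` nm with binding sites every `site_spacing = 7` nm (20 per
#' segment); cross-linker arm length `r0_ACP = 23.5` nm; motor backbone
#' segment `L_MB = 42` nm; motor-arm transverse equilibrium distance
#' `r0_M2 = 13.5` nm and longitudinal equilibrium `r0_M3 = 0`; `N_h = 8`
#' myosin heads per arm binding at `40*N_h` per second; per-head stall force
#' `F_st = 5.7` pN; unloaded walking velocity `v0 = 140` nm/s; actin
#' persistence length `Lp_A = 9` um. The actin bending stiffness is derived,
#' not free: `kappa_b_A = Lp_A * kBT / r0_A`.
#'
#' The default medium viscosity is 0.86 Pa s, a cytoplasm-scale effective
#' viscosity. Together with the default `dt` it keeps the explicit Euler
#' update stable for segment stiffnesses large enough that thermal length
#' fluctuations stay below ~1% of the segment length (see the methods
#' vignette for the stability analysis).
#'
#' @param ... named overrides of any default value.
#' @return An object of class `actomyo_params` (a named list).
#' @examples
#' p <- default_params()
#' p$r0_A
#' p2 <- default_params(N_h = 4, F_st = 6)
#' @export
default_params <- function(...) {
  kBT <- 4.11e-21
  p <- list(
    # integration / thermodynamics
    dt    = 1.15e-5,     # s
    kBT   = kBT,         # J (300 K)
    mu    = 0.86,        # Pa s, effective medium viscosity

    # geometry (nm)
    r0_A     = 140,      # actin segment rest length
    d_A      = 7,        # actin diameter (drag + repulsion cutoff)
    r0_ACP   = 23.5,     # ACP arm rest length
    d_ACP    = 10,       # ACP drag diameter
    L_MB     = 42,       # motor backbone segment reference length
    d_M      = 120,      # motor backbone drag diameter: hydrodynamic
                         # envelope of a backbone segment with its two
                         # 8-head arm bundles
    r0_M2    = 13.5,     # motor arm transverse equilibrium distance
    r0_M3    = 0,        # motor arm longitudinal equilibrium offset
    rc_A     = 7,        # actin-actin repulsion cutoff
    site_spacing = 7,    # binding-site spacing along actin

    # stiffnesses
    kappa_s_A   = 1.0e-2,   # N/m actin extensional
    kappa_s_M1  = 1.0e-2,   # N/m backbone extensional (= kappa_s_A)
    kappa_s_ACP = 2.0e-3,   # N/m ACP arm extensional
    kappa_s_M2  = 1.0e-3,   # N/m motor arm transverse spring
    kappa_s_M3  = 1.0e-3,   # N/m motor arm longitudinal spring
    kappa_b_A   = 9e-6 * kBT / 140e-9,  # N m, from Lp_A (derived)
    kappa_b_M   = 20 * 9e-6 * kBT / 140e-9,  # N m, stiff backbone
    kappa_b_ACP = 5.0e-26,  # N m, ACP inter-arm hinge
    kappa_r_A   = 1.69e-3,  # N/m repulsion / wall stiffness

    # equilibrium angles (rad); all straight
    theta0_A = 0, theta0_ACP = 0, theta0_M = 0,

    # motor mechanochemistry
    N_h            = 8,     # myosin heads lumped per arm
    k_bind_per_head = 40,   # 1/s per head -> arm binds at 40*N_h
    F_st           = 5.7,   # pN stall force per head
    v0             = 140,   # nm/s unloaded walking velocity
    k_u0           = 20,    # 1/s unloaded arm unbinding rate
    F_cat          = 10,    # pN catch-bond force scale

    # network assembly
    k_n_A = 0.2,   # 1/s nucleation rate (domain-level)
    k_p_A = 50,    # 1/s polymerization rate per barbed end

    # actin mechanics reference
    Lp_A = 9       # um persistence length
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(over)] <- over
    # keep the derived bending stiffness consistent unless set explicitly
    if (("Lp_A" %in% names(over) || "kBT" %in% names(over) ||
         "r0_A" %in% names(over)) && !("kappa_b_A" %in% names(over))) {
      p$kappa_b_A <- p$Lp_A * 1e-6 * p$kBT / (p$r0_A * 1e-9)
    }
  }
  class(p) <- "actomyo_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity, zero equilibrium angles, and the derived relation
#' `kappa_b_A = Lp_A * kBT / r0_A`.
#'
#' @param p an `actomyo_params` object (or plain named list).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  need <- names(default_params_skeleton())
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (!(p$dt > 0)) stop("dt must be > 0")
  lens <- c("r0_A", "d_A", "r0_ACP", "d_ACP", "L_MB", "d_M", "r0_M2",
            "rc_A", "site_spacing")
  for (nm in lens) if (!(p[[nm]] > 0)) stop(nm, " must be > 0")
  if (p$r0_M3 != 0) stop("r0_M3 must be 0 (right-angle longitudinal spring)")
  rates <- c("k_bind_per_head", "k_u0", "k_n_A", "k_p_A")
  for (nm in rates) if (p[[nm]] < 0) stop(nm, " must be >= 0")
  if (p$theta0_A != 0 || p$theta0_ACP != 0 || p$theta0_M != 0)
    stop("equilibrium angles must be 0 (straight)")
  kb_expect <- p$Lp_A * 1e-6 * p$kBT / (p$r0_A * 1e-9)
  if (abs(p$kappa_b_A - kb_expect) > 1e-6 * kb_expect)
    stop("kappa_b_A must equal Lp_A*kBT/r0_A (derived, not independent)")
  invisible(p)
}

# internal: names of the canonical parameter set
default_params_skeleton <- function() {
  p <- list(
    dt = 1, kBT = 1, mu = 1, r0_A = 1, d_A = 1, r0_ACP = 1, d_ACP = 1,
    L_MB = 1, d_M = 1, r0_M2 = 1, r0_M3 = 0, rc_A = 1, site_spacing = 1,
    kappa_s_A = 1, kappa_s_M1 = 1, kappa_s_ACP = 1, kappa_s_M2 = 1,
    kappa_s_M3 = 1, kappa_b_A = 1, kappa_b_M = 1, kappa_b_ACP = 1,
    kappa_r_A = 1, theta0_A = 0, theta0_ACP = 0, theta0_M = 0,
    N_h = 1, k_bind_per_head = 1, F_st = 1, v0 = 1, k_u0 = 1, F_cat = 1,
    k_n_A = 1, k_p_A = 1, Lp_A = 1
  )
  p
}

#' Write a parameter set to a YAML or JSON config file
#'
#' @param p an `actomyo_params` object.
#' @param path output path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  x <- unclass(p)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 17)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("config path must end in .yaml, .yml or .json")
  }
  invisible(path)
}

#' Read a parameter set from a YAML or JSON config file
#'
#' Unknown keys are rejected so silent typos in configs cannot pass.
#' Missing keys are an error too: configs written by [write_params()] are
#' always complete.
#'
#' @param path config file path.
#' @return An `actomyo_params` object.
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config path must end in .yaml, .yml or .json")
  }
  known <- names(default_params_skeleton())
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown key(s) in config: ", paste(bad, collapse = ", "))
  p <- x[known]
  class(p) <- "actomyo_params"
  validate_params(p)
  p
}

#' @export
print.actomyo_params <- function(x, ...) {
  cat("<actomyo_params> ", length(unclass(x)), " parameters\n", sep = "")
  cat(sprintf("  dt = %.3g s, kBT = %.3g J, mu = %.3g Pa s\n",
              x$dt, x$kBT, x$mu))
  cat(sprintf("  actin: r0 = %g nm, Lp = %g um, sites every %g nm\n",
              x$r0_A, x$Lp_A, x$site_spacing))
  cat(sprintf("  motor: L_MB = %g nm, N_h = %g, F_st = %g pN, v0 = %g nm/s\n",
              x$L_MB, x$N_h, x$F_st, x$v0))
  invisible(x)
}

#' Drag coefficient of a cylindrical segment
#'
#' Approximate drag of a cylinder of length `r0` and diameter `rc` in a
#' medium of viscosity `mu`:
#' \deqn{\zeta = 3\pi\mu r_c (3 + 2 r_0/r_c)/5.}
#' For `r0 = rc` this reduces to the Stokes-like `3 pi mu rc`.
#'
#' @param r0 segment length (nm).
#' @param rc segment diameter (nm).
#' @param mu medium viscosity (Pa s).
#' @return Drag coefficient in N s/m.
#' @examples
#' drag_coefficient(140, 7, 1e-3)
#' @export
drag_coefficient <- function(r0, rc, mu) {
  if (any(r0 <= 0) || any(rc <= 0) || any(mu <= 0))
    stop("r0, rc and mu must all be > 0")
  3 * pi * mu * (rc * 1e-9) * (3 + 2 * r0 / rc) / 5
}
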