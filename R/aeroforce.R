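#' Glottal area profile along the free surface
#'
#' For the symmetric half model, the local glottal area at a free-surface
#' station at medial position `x` (mm) is `A(s) = 2 (midline_x - x) l_gl`,
#' floored at a small positive `a_floor` so the Bernoulli law stays defined
#' during contact.
#'
#' @param x_mm Medial positions of the free-surface stations, mm (ordered
#'   inferior to superior).
#' @param midline_mm Midline position, mm.
#' @param l_gl_mm Anterior-posterior glottal length, mm.
#' @param a_floor Contact floor, mm^2 (default 0.001).
#' @return Areas per station, mm^2.
#' @export
area_profile <- function(x_mm, midline_mm, l_gl_mm, a_floor = 1e-3) {
  pmax(2 * (midline_mm - x_mm) * l_gl_mm, a_floor)
}

#' Bernoulli pressure with flow separation
#'
#' Quasi-1D Bernoulli pressure at each station:
#' `p = p_sub - (p_sub - p_sup) (A_sep / A)^2` where `A < A_sep`, and
#' `p = p_sub` where `A >= A_sep`, with separation area
#' `A_sep = 1.3 A_min`.
#'
#' @param A Areas per station, mm^2 (positive; already floored).
#' @param p_sub,p_sup Subglottal and supraglottal pressures, Pa.
#' @return List with `p` (Pa per station), `A_min`, `A_sep` (mm^2).
#' @export
bernoulli_pressure <- function(A, p_sub, p_sup = 0) {
  if (any(A <= 0)) stop("areas must be positive (apply the contact floor first)",
                        call. = FALSE)
  if (p_sub < p_sup)
    warning("p_sub < p_sup: reversed pressure drop; flow rate will be zero")
  A_min <- min(A)
  A_sep <- 1.3 * A_min
  list(p = bernoulli_branch(A, A_sep, p_sub, p_sup),
       A_min = A_min, A_sep = A_sep)
}

#' @rdname bernoulli_pressure
#' @description `bernoulli_branch` evaluates the branch rule for a given
#'   separation area (the raw formula, without tying `A_sep` to the profile
#'   minimum).
#' @param A_sep Separation area, mm^2.
#' @export
bernoulli_branch <- function(A, A_sep, p_sub, p_sup = 0) {
  ifelse(A < A_sep, p_sub - (p_sub - p_sup) * (A_sep / A)^2, p_sub)
}

#' Nodal forces from a surface pressure profile
#'
#' Integrates the station pressures edgewise along the free-surface chain.
#' Each edge carries the mean of its end-station pressures, acting along the
#' inward (into the tissue) normal of the deformed edge, unit out-of-plane
#' depth; the edge load splits equally between its two end nodes.
#'
#' @param p Pressures per station, Pa.
#' @param x_mm,z_mm Deformed station coordinates, mm (inferior to superior).
#' @return Matrix `length(p) x 2` of nodal forces `(F_x, F_z)` in N per metre
#'   of anterior-posterior depth.
#' @export
nodal_forces <- function(p, x_mm, z_mm) {
  n <- length(p)
  stopifnot(length(x_mm) == n, length(z_mm) == n)
  F <- matrix(0, n, 2)
  if (n < 2) return(F)
  for (i in seq_len(n - 1)) {
    pe <- (p[i] + p[i + 1]) / 2
    dx <- (x_mm[i + 1] - x_mm[i]) * 1e-3
    dz <- (z_mm[i + 1] - z_mm[i]) * 1e-3
    # inward normal times edge length: (-dz, dx) for an inferior->superior
    # chain with tissue on the lateral side
    fx <- pe * (-dz); fz <- pe * dx
    F[i, ] <- F[i, ] + c(fx, fz) / 2
    F[i + 1, ] <- F[i + 1, ] + c(fx, fz) / 2
  }
  F
}

#' Glottal volumetric flow rate
#'
#' `Q = 1.3 A_min sqrt(2 (p_sub - p_sup) / rho_air)` in mL/s, with air
#' density 1.14 kg/m^3; zero when the glottis is closed or the pressure drop
#' is non-positive.
#'
#' @param A_min Minimum glottal area, mm^2 (0 when closed).
#' @param p_sub,p_sup Pressures, Pa.
#' @param rho_air Air density, kg/m^3 (default 1.14).
#' @return Flow rate, mL/s.
#' @export
flow_rate <- function(A_min, p_sub, p_sup = 0, rho_air = 1.14) {
  dp <- p_sub - p_sup
  ifelse(A_min <= 0 | dp <= 0, 0, 1.3 * A_min * sqrt(2 * pmax(dp, 0) / rho_air))
}
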