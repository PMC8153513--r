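#' Material property set for the layered vocal-fold model
#'
#' The parameter vector of the forward model: density `rho` (kg/m^3),
#' viscosity `eta` (Poise; 1 Poise = 0.1 Pa s, converted at assembly), layer
#' Young's moduli `E_bdy`, `E_cvr`, `E_lig` (Pa), Poisson ratio `nu`
#' (dimensionless, shared by all layers), subglottal and supraglottal
#' pressures `p_sub`, `p_sup` (Pa), and the medial pre-compression offset
#' `x0` (mm; equal to the midline position when there is no compression).
#'
#' Density, viscosity and the Poisson ratio are uniform across layers; only
#' the Young's modulus differs per layer.
#'
#' @param rho Density, kg/m^3.
#' @param eta Viscosity, Poise.
#' @param E_bdy,E_cvr,E_lig Young's moduli of body, cover and ligament, Pa.
#' @param nu Poisson ratio; must satisfy `-1 < nu < 1/2`.
#' @param p_sub,p_sup Driving pressures, Pa.
#' @param x0 Medial-compression offset, mm (default 8.4 = no compression).
#' @return An object of class `vf_props`.
#' @examples
#' vf_props(E_cvr = 600)
#' @export
vf_props <- function(rho = 1049.75, eta = 3, E_bdy = 11800, E_cvr = 600,
                     E_lig = 2000, nu = 0.4995, p_sub = 1000, p_sup = 0,
                     x0 = 8.4) {
  if (any(c(E_bdy, E_cvr, E_lig) <= 0) || rho <= 0 || eta < 0)
    stop("inadmissible material properties: require E > 0, rho > 0, eta >= 0",
         call. = FALSE)
  if (!(nu > -1 && nu < 0.5))
    stop("constitutive-domain error: require -1 < nu < 1/2", call. = FALSE)
  if (x0 < 0)
    stop("inadmissible x0: must be non-negative (mm)", call. = FALSE)
  structure(list(rho = rho, eta = eta, E_bdy = E_bdy, E_cvr = E_cvr,
                 E_lig = E_lig, nu = nu, p_sub = p_sub, p_sup = p_sup,
                 x0 = x0),
            class = "vf_props")
}

#' @export
print.vf_props <- function(x, ...) {
  cat("<vf_props>\n")
  cat(sprintf("  E_bdy %.4g Pa, E_cvr %.4g Pa, E_lig %.4g Pa, nu %.4g\n",
              x$E_bdy, x$E_cvr, x$E_lig, x$nu))
  cat(sprintf("  rho %.4g kg/m^3, eta %.4g Poise, p_sub %.4g Pa, p_sup %.4g Pa, x0 %.4g mm\n",
              x$rho, x$eta, x$p_sub, x$p_sup, x$x0))
  invisible(x)
}

#' Lame parameters from Young's modulus and Poisson ratio
#'
#' `mu = E / (2 (1 + nu))`, `lambda = nu E / ((1 + nu)(1 - 2 nu))`.
#'
#' @param E Young's modulus, Pa (> 0).
#' @param nu Poisson ratio in (-1, 1/2).
#' @return Named list with `mu` and `lambda` in Pa.
#' @export
lame_parameters <- function(E, nu) {
  if (any(E <= 0)) stop("constitutive-domain error: E must be positive", call. = FALSE)
  if (!(nu > -1 && nu < 0.5))
    stop("constitutive-domain error: require -1 < nu < 1/2", call. = FALSE)
  list(mu = E / (2 * (1 + nu)), lambda = nu * E / ((1 + nu) * (1 - 2 * nu)))
}

#' Plane-strain constitutive matrices
#'
#' Elasticity matrix `C` for the in-plane isotropic law (Voigt strain
#' ordering `[e_xx, e_zz, gamma_xz]`) and the viscous shape matrix
#' `S = C / mu`, which realizes stiffness-proportional viscous damping via
#' the substitution `mu -> mu + eta d/dt` in the factored form of `C`.
#'
#' @inheritParams lame_parameters
#' @return List with `C`, `S` (3 x 3), `mu`, `lambda`.
#' @export
constitutive <- function(E, nu) {
  lp <- lame_parameters(E, nu)
  C <- matrix(c(lp$lambda + 2 * lp$mu, lp$lambda, 0,
                lp$lambda, lp$lambda + 2 * lp$mu, 0,
                0, 0, lp$mu), 3, 3)
  list(C = C, S = C / lp$mu, mu = lp$mu, lambda = lp$lambda)
}

# strain-displacement matrix of a linear triangle; nodes mm -> converted to m.
# Local dof order (x1,x2,x3,z1,z2,z3) matching the global [alpha; beta] split.
element_B <- function(coords_mm) {
  p <- coords_mm * 1e-3
  x <- p[, 1]; z <- p[, 2]
  detJ <- (x[2] - x[1]) * (z[3] - z[1]) - (x[3] - x[1]) * (z[2] - z[1])
  A <- detJ / 2
  if (A <= 0) stop("singular-element error: non-positive triangle area", call. = FALSE)
  b <- c(z[2] - z[3], z[3] - z[1], z[1] - z[2]) / detJ   # d(phi)/dx
  cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1]) / detJ  # d(phi)/dz
  B <- rbind(c(b, 0, 0, 0),
             c(0, 0, 0, cc),
             c(cc, b))
  list(B = B, area = A)
}

#' Element mass, damping and stiffness matrices (linear triangle)
#'
#' Consistent mass `Me` (per-coordinate block `rho A / 12 * [[2,1,1],[1,2,1],
#' [1,1,2]]`, unit out-of-plane depth), stiffness `Ke = A B' C B`, damping
#' `De = A B' (eta_SI S) B` with `eta` converted from Poise to Pa s.  All in
#' SI units; element coordinates are taken in mm and converted internally.
#'
#' @param coords_mm 3 x 2 matrix of node coordinates, mm.
#' @param E Young's modulus of the element's layer, Pa.
#' @param nu Poisson ratio.
#' @param rho Density, kg/m^3.
#' @param eta Viscosity, Poise.
#' @return List with 6 x 6 `Me`, `De`, `Ke` (dof order x1,x2,x3,z1,z2,z3) and
#'   the element `area` in m^2.
#' @export
element_matrices <- function(coords_mm, E, nu, rho, eta) {
  eb <- element_B(coords_mm)
  cm <- constitutive(E, nu)
  Ke <- eb$area * t(eb$B) %*% cm$C %*% eb$B
  De <- eb$area * t(eb$B) %*% (0.1 * eta * cm$S) %*% eb$B
  m3 <- rho * eb$area / 12 * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3)
  Me <- matrix(0, 6, 6)
  Me[1:3, 1:3] <- m3
  Me[4:6, 4:6] <- m3
  list(Me = Me, De = De, Ke = Ke, area = eb$area)
}

# Unit-coefficient assembly cache: per-layer stiffness with E = 1 Pa, and the
# mass matrix with rho = 1.  Because lambda and mu are both proportional to E
# at fixed nu, and D = eta_SI * 2 (1 + nu) * sum_layers Khat_layer, the full
# (M, D, K) for any property set is a scalar combination of these blocks.
# This is what makes ensemble runs affordable.
#
# formulation "bbar": the volumetric (lambda) part of the stiffness uses the
# area-weighted mean divergence over each quad patch of the structured mesh
# (mean-dilatation / B-bar), relieving the volumetric locking that fully
# integrated linear triangles exhibit at nu near 1/2.  "full" is the verbatim
# fully integrated element.
assembly_cache <- function(mesh, nu, formulation = c("bbar", "full")) {
  formulation <- match.arg(formulation)
  if (formulation == "bbar" && is.null(mesh$patch)) {
    warning("mesh has no patch structure; falling back to full integration")
    formulation <- "full"
  }
  lp <- lame_parameters(1, nu)
  nN <- nrow(mesh$nodes)
  ndof <- 2L * nN
  nel <- nrow(mesh$triangles)
  lev <- levels(mesh$layer)
  C_mu <- lp$mu * diag(c(2, 2, 1))

  trip <- lapply(setNames(lev, lev),
                 function(l) list(i = integer(0), j = integer(0), x = numeric(0)))
  add <- function(l, gd, mat) {
    trip[[l]]$i <<- c(trip[[l]]$i, rep(gd, times = length(gd)))
    trip[[l]]$j <<- c(trip[[l]]$j, rep(gd, each = length(gd)))
    trip[[l]]$x <<- c(trip[[l]]$x, as.vector(mat))
  }
  mi <- integer(0); mj <- integer(0); mx <- numeric(0)
  div_rows <- vector("list", nel)
  areas <- numeric(nel)
  for (e in seq_len(nel)) {
    nd <- mesh$triangles[e, ]
    gd <- c(nd, nN + nd)   # global dofs [alpha..., beta...]
    eb <- element_B(mesh$nodes[nd, , drop = FALSE])
    areas[e] <- eb$area
    d_row <- eb$B[1, ] + eb$B[2, ]           # divergence operator
    div_rows[[e]] <- d_row
    l <- as.character(mesh$layer[e])
    Ke_mu <- eb$area * t(eb$B) %*% C_mu %*% eb$B
    if (formulation == "full")
      Ke_mu <- Ke_mu + lp$lambda * eb$area * tcrossprod(d_row)
    add(l, gd, Ke_mu)
    m3 <- eb$area / 12 * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3)
    Me <- matrix(0, 6, 6)
    Me[1:3, 1:3] <- m3; Me[4:6, 4:6] <- m3
    mi <- c(mi, rep(gd, times = 6)); mj <- c(mj, rep(gd, each = 6))
    mx <- c(mx, as.vector(Me))
  }
  if (formulation == "bbar") {
    for (p in unique(mesh$patch)) {
      els <- which(mesh$patch == p)
      gd <- sort(unique(as.vector(rbind(mesh$triangles[els, , drop = FALSE],
                                        nN + mesh$triangles[els, , drop = FALSE]))))
      dbar <- numeric(length(gd))
      Atot <- 0
      for (e in els) {
        nd <- mesh$triangles[e, ]
        pos <- match(c(nd, nN + nd), gd)
        dbar[pos] <- dbar[pos] + areas[e] * div_rows[[e]]
        Atot <- Atot + areas[e]
      }
      dbar <- dbar / Atot
      l <- as.character(mesh$layer[els[1]])
      add(l, gd, lp$lambda * Atot * tcrossprod(dbar))
    }
  }
  Khat <- lapply(trip, function(tr)
    Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(ndof, ndof)))
  Mhat <- Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(ndof, ndof))
  list(Khat = Khat, Mhat = Mhat, nu = nu, ndof = ndof,
       formulation = formulation)
}

#' Assemble global system matrices
#'
#' Scatter-adds element matrices into sparse global mass, damping and
#' stiffness operators of dimension `2N x 2N`, dof ordering
#' `[x_1..x_N, z_1..z_N]`.  The Young's modulus is chosen per element layer;
#' density and viscosity are uniform.
#'
#' @param mesh A `vf_mesh`.
#' @param props A [vf_props()].
#' @param cache Optional precomputed unit-coefficient cache (internal reuse).
#' @param formulation `"bbar"` (default; mean-dilatation treatment of the
#'   volumetric stiffness over the mesher's quad patches, which avoids
#'   volumetric locking at `nu` near 1/2) or `"full"` (verbatim fully
#'   integrated linear triangles).
#' @return Object of class `vf_system`: sparse `M`, `D`, `K`, the mesh, the
#'   property set, and `fixed_dofs` (not yet eliminated).
#' @export
vf_assemble <- function(mesh, props, cache = NULL,
                        formulation = c("bbar", "full")) {
  stopifnot(inherits(mesh, "vf_mesh"), inherits(props, "vf_props"))
  if (is.null(cache)) cache <- assembly_cache(mesh, props$nu, formulation)
  if (!isTRUE(all.equal(cache$nu, props$nu)))
    stop("assembly cache was built for a different Poisson ratio", call. = FALSE)
  E <- c(body = props$E_bdy, ligament = props$E_lig, cover = props$E_cvr)
  K <- E[["body"]] * cache$Khat$body + E[["ligament"]] * cache$Khat$ligament +
    E[["cover"]] * cache$Khat$cover
  D <- (0.1 * props$eta) * 2 * (1 + props$nu) *
    (cache$Khat$body + cache$Khat$ligament + cache$Khat$cover)
  M <- props$rho * cache$Mhat
  nN <- nrow(mesh$nodes)
  fixed_dofs <- c(mesh$fixed_nodes, nN + mesh$fixed_nodes)
  structure(list(M = M, D = D, K = K, mesh = mesh, props = props,
                 fixed_dofs = sort(fixed_dofs), constrained = FALSE),
            class = "vf_system")
}

#' Eliminate fixed degrees of freedom
#'
#' Removes both dofs of every fixed node by row/column deletion and records
#' the mapping from retained dofs back to nodes.
#'
#' @param sys A `vf_system` from [vf_assemble()].
#' @param fixed_nodes Node indices to fix; defaults to the mesh's fixed set.
#' @return A constrained `vf_system` with `free_dofs` (original indices) and
#'   `dof_of_node` lookup matrix (`NA` for eliminated dofs).
#' @export
vf_constrain <- function(sys, fixed_nodes = sys$mesh$fixed_nodes) {
  stopifnot(inherits(sys, "vf_system"))
  nN <- nrow(sys$mesh$nodes)
  if (length(fixed_nodes) >= nN)
    stop("degenerate-system error: all nodes fixed", call. = FALSE)
  fixed_dofs <- sort(c(fixed_nodes, nN + fixed_nodes))
  keep <- setdiff(seq_len(2L * nN), fixed_dofs)
  dof_of_node <- matrix(NA_integer_, nN, 2)
  dof_of_node[cbind(match(keep[keep <= nN], seq_len(nN)), 1L)] <-
    seq_along(keep[keep <= nN])
  zin <- keep[keep > nN] - nN
  dof_of_node[cbind(zin, 2L)] <- length(keep[keep <= nN]) + seq_along(zin)
  out <- sys
  out$M <- sys$M[keep, keep, drop = FALSE]
  out$D <- sys$D[keep, keep, drop = FALSE]
  out$K <- sys$K[keep, keep, drop = FALSE]
  out$free_dofs <- keep
  out$dof_of_node <- dof_of_node
  out$fixed_nodes_applied <- fixed_nodes
  out$constrained <- TRUE
  out
}

#' @export
print.vf_system <- function(x, ...) {
  cat(sprintf("<vf_system> %s, %d dofs\n",
              if (x$constrained) "constrained" else "unconstrained", nrow(x$K)))
  invisible(x)
}

#' Export a system matrix in MatrixMarket format (debugging aid)
#' @param sys A `vf_system`.
#' @param which One of "M", "D", "K".
#' @param path Output .mtx file.
#' @return `path`, invisibly.
#' @export
write_mtx <- function(sys, which = c("K", "M", "D"), path) {
  which <- match.arg(which)
  Matrix::writeMM(sys[[which]], path)
  invisible(path)
}
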