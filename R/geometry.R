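#' Three-layer vocal-fold cross-section geometry
#'
#' Builds the M5-style two-dimensional vocal-fold profile used throughout the
#' package: a body layer attached to the lateral (tracheal) wall, a ligament
#' band, and a superficial cover shell along the medial (glottal) surface.
#' Coordinates are in millimetres with the origin at the inferior-lateral
#' corner; `x` increases medially so the glottal midline (the plane of
#' symmetry and of collision) sits at `x = height_ml`.
#'
#' The medial free-surface polyline runs inferior to superior: a flat
#' attachment at the inferior face, an inferior slope converging toward the
#' glottis, a short vertical medial (contact) face flush with the midline, and
#' a chamfered superior edge.  The default polyline is read from the published
#' M5 profile qualitatively and scales affinely with the requested dimensions;
#' a user polyline (in mm, inferior to superior, strictly increasing in `z`)
#' may be supplied instead.
#'
#' Layer boundaries are medial-depth offsets of the free surface: every free
#' surface vertex `(x, z)` maps to `(x - d, z)` at offset depth `d`, so the
#' cover occupies depths `[0, t_cover]`, the ligament `(t_cover,
#' t_cover + t_ligament]`, and the body the remainder down to the lateral
#' wall.  This makes the layer polygons exact sub-polygons of the profile.
#'
#' @param depth_is Inferior-superior extent in mm (default 10.51).
#' @param height_ml Medial-lateral height in mm (default 8.40); the midline is
#'   at this `x`.
#' @param length_ap Anterior-posterior glottal length in mm (default 17.00);
#'   used only when converting the 2D model to areas and forces.
#' @param t_cover,t_ligament Cover and ligament thicknesses in mm, measured as
#'   medial-depth offsets from the free surface.  Defaults 0.8 and 1.2 mm,
#'   scaled with `height_ml`.
#' @param medial_polyline Optional n x 2 matrix of free-surface vertices
#'   `(x, z)` in mm, ordered inferior to superior.  First vertex must lie on
#'   `z = 0`, last on `z = depth_is`.
#' @return An object of class `vf_geometry`.
#' @examples
#' geom <- vf_geometry()
#' geom$midline_x
#' @export
vf_geometry <- function(depth_is = 10.51, height_ml = 8.40, length_ap = 17.00,
                        t_cover = 0.8 * height_ml / 8.40,
                        t_ligament = 1.2 * height_ml / 8.40,
                        medial_polyline = NULL) {
  if (!all(is.finite(c(depth_is, height_ml, length_ap, t_cover, t_ligament))) ||
      any(c(depth_is, height_ml, length_ap, t_cover, t_ligament) <= 0)) {
    stop("invalid geometry: all dimensions must be positive and finite",
         call. = FALSE)
  }
  if (is.null(medial_polyline)) {
    # reference profile at the default 8.40 x 10.51 mm bounding box
    ref <- matrix(c(
      2.80, 0.00,
      8.40, 7.90,
      8.40, 8.90,
      8.00, 10.00,
      7.20, 10.51), ncol = 2, byrow = TRUE)
    sx <- height_ml / 8.40
    sz <- depth_is / 10.51
    medial_polyline <- cbind(ref[, 1] * sx, ref[, 2] * sz)
  } else {
    medial_polyline <- as.matrix(medial_polyline)
    if (ncol(medial_polyline) != 2 || nrow(medial_polyline) < 2)
      stop("invalid geometry: medial_polyline must be an n x 2 matrix", call. = FALSE)
    if (any(diff(medial_polyline[, 2]) <= 0))
      stop("invalid geometry: medial_polyline must be strictly increasing in z",
           call. = FALSE)
    if (abs(medial_polyline[1, 2]) > 1e-9 ||
        abs(medial_polyline[nrow(medial_polyline), 2] - depth_is) > 1e-9)
      stop("invalid geometry: medial_polyline must span z = 0 to z = depth_is",
           call. = FALSE)
  }
  if (max(medial_polyline[, 1]) > height_ml + 1e-9)
    stop("invalid geometry: free surface extends beyond the midline", call. = FALSE)
  min_depth <- min(medial_polyline[, 1])
  if (t_cover + t_ligament >= min_depth)
    stop("invalid geometry: layer shells thicker than the thinnest section",
         call. = FALSE)

  poly_profile <- rbind(c(0, 0), medial_polyline, c(0, depth_is))
  off <- function(d) cbind(medial_polyline[, 1] - d, medial_polyline[, 2])
  c1 <- off(t_cover)                   # cover/ligament interface
  c2 <- off(t_cover + t_ligament)      # ligament/body interface
  rev2 <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  layers <- list(
    cover    = rbind(medial_polyline, rev2(c1)),
    ligament = rbind(c1, rev2(c2)),
    body     = rbind(c(0, 0), c2, c(0, depth_is))
  )

  structure(list(
    depth_is = depth_is, height_ml = height_ml, length_ap = length_ap,
    t_cover = t_cover, t_ligament = t_ligament,
    midline_x = height_ml,
    medial_polyline = medial_polyline,
    profile = poly_profile,
    layer_polylines = layers
  ), class = "vf_geometry")
}

#' @export
print.vf_geometry <- function(x, ...) {
  cat("<vf_geometry>\n")
  cat(sprintf("  bounding box : %.2f mm (ML) x %.2f mm (IS), l_gl = %.2f mm\n",
              x$height_ml, x$depth_is, x$length_ap))
  cat(sprintf("  midline at x = %.2f mm; cover %.2f mm, ligament %.2f mm\n",
              x$midline_x, x$t_cover, x$t_ligament))
  cat(sprintf("  profile area : %.3f mm^2\n", polygon_area(x$profile)))
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' @param poly n x 2 matrix of vertices (closed implicitly).
#' @return Signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; z <- poly[, 2]
  xn <- c(x[-1], x[1]); zn <- c(z[-1], z[1])
  sum(x * zn - xn * z) / 2
}

# piecewise-linear interpolation of the free-surface x at height z
surface_x_at <- function(geom, z) {
  stats::approx(geom$medial_polyline[, 2], geom$medial_polyline[, 1],
                xout = z, rule = 2)$y
}

#' Triangulate a vocal-fold geometry
#'
#' Deterministic structured triangulation.  The domain is sliced by horizontal
#' rays from the free surface to the lateral wall; along each ray, nodes are
#' placed at the layer interface depths (`t_cover`, `t_cover + t_ligament`)
#' and the remaining body depth is divided uniformly.  Stations along the free
#' surface always include the profile vertices, so the triangulated area
#' equals the polygon area exactly and no element straddles a layer boundary.
#'
#' Boundary conventions: the lateral wall and the inferior/superior
#' attachment faces are fixed (tracheal walls and mounting); the medial
#' surface chain, ordered inferior to superior, is the free (aerodynamically
#' loaded) boundary.
#'
#' @param geom A [vf_geometry()].
#' @param target_elements Requested element count (>= 20); the realized count
#'   is within 15 percent of the request.
#' @param fixed_boundary Which boundary is clamped: `"wall"` (default; the
#'   lateral wall only, matching how silicone folds are held in their
#'   mounting bracket, with the inferior and superior faces traction-free)
#'   or `"attachment"` (additionally clamps the inferior and superior faces;
#'   over-anchoring an incompressible fold this way forces the medial
#'   surface to bulge into the midline and suppresses oscillation).
#' @return An object of class `vf_mesh` with fields `nodes` (n x 2, mm),
#'   `triangles` (m x 3 node indices, positively oriented), `layer`
#'   (per-element factor body/ligament/cover), `fixed_nodes`, `free_surface`
#'   (ordered node chain), and bookkeeping for the ray grid.
#' @examples
#' mesh <- vf_triangulate(vf_geometry(), 120)
#' nrow(mesh$triangles)
#' @export
vf_triangulate <- function(geom, target_elements = 205,
                           fixed_boundary = c("wall", "attachment")) {
  fixed_boundary <- match.arg(fixed_boundary)
  stopifnot(inherits(geom, "vf_geometry"))
  if (target_elements < 20)
    stop("target_elements must be at least 20", call. = FALSE)
  pl <- geom$medial_polyline
  seg_len <- sqrt(rowSums(diff(pl)^2))
  L_free <- sum(seg_len)
  L_ray  <- mean(surface_x_at(geom, seq(0, geom$depth_is, length.out = 65)))

  # choose (n_s rays along the surface) x (m element layers through depth)
  n_vert <- nrow(pl)
  best <- NULL
  for (m in 3:24) {
    n_s <- max(n_vert - 1, round(target_elements / (2 * m)))
    count <- 2 * n_s * m
    aspect <- (L_free / n_s) / (L_ray / m)   # element aspect ratio, want ~1
    score <- abs(count - target_elements) + 0.5 * abs(log(aspect))
    if (is.null(best) || score < best$score)
      best <- list(n_s = n_s, m = m, score = score, count = count)
  }
  n_s <- best$n_s; m <- best$m
  if (abs(best$count - target_elements) > 0.15 * target_elements)
    stop("refinement error: cannot meet target element count within 15%",
         call. = FALSE)

  # stations along the free polyline: all vertices, plus interior points per
  # segment allocated by length (largest remainder), deterministic
  extra <- n_s + 1 - n_vert
  quota <- extra * seg_len / L_free
  base <- floor(quota)
  rem <- quota - base
  left <- extra - sum(base)
  if (left > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stations <- pl[1, , drop = FALSE]
  for (k in seq_along(seg_len)) {
    nk <- base[k]
    if (nk > 0) {
      tt <- seq_len(nk) / (nk + 1)
      stations <- rbind(stations,
                        cbind(pl[k, 1] + tt * (pl[k + 1, 1] - pl[k, 1]),
                              pl[k, 2] + tt * (pl[k + 1, 2] - pl[k, 2])))
    }
    stations <- rbind(stations, pl[k + 1, , drop = FALSE])
  }
  stopifnot(nrow(stations) == n_s + 1)

  # nodes: for station i, horizontal ray from the free surface to the wall
  d_lay <- c(0, geom$t_cover, geom$t_cover + geom$t_ligament)
  n_body <- m - 2
  nodes <- matrix(0, (n_s + 1) * (m + 1), 2)
  idx <- function(i, j) as.integer(i * (m + 1) + j + 1)  # i in 0..n_s, j in 0..m
  for (i in 0:n_s) {
    xs <- stations[i + 1, 1]; zs <- stations[i + 1, 2]
    depth_body <- xs - d_lay[3]
    dj <- c(d_lay, d_lay[3] + seq_len(n_body) * depth_body / n_body)
    nodes[idx(i, 0:m), ] <- cbind(xs - dj, rep(zs, m + 1))
  }

  tri <- matrix(0L, 2 * n_s * m, 3)
  lay <- integer(2 * n_s * m)
  e <- 0L
  for (i in 0:(n_s - 1)) for (j in 0:(m - 1)) {
    a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    tri[e + 1L, ] <- c(a, b, cc)
    tri[e + 2L, ] <- c(a, cc, d)
    lab <- if (j == 0) 3L else if (j == 1) 2L else 1L  # 1 body, 2 lig, 3 cover
    lay[e + 1L] <- lab; lay[e + 2L] <- lab
    e <- e + 2L
  }

  wall  <- idx(0:n_s, m)
  inf_r <- idx(0, 0:m)
  sup_r <- idx(n_s, 0:m)
  fixed <- if (fixed_boundary == "wall") sort(wall)
           else sort(unique(c(wall, inf_r, sup_r)))
  free_chain <- idx(1:(n_s - 1), 0)

  structure(list(
    nodes = nodes, triangles = tri,
    layer = factor(c("body", "ligament", "cover")[lay],
                   levels = c("body", "ligament", "cover")),
    fixed_nodes = fixed, free_surface = free_chain,
    patch = rep(seq_len(n_s * m), each = 2),  # quad of origin, for B-bar
    n_s = n_s, m = m, geom = geom
  ), class = "vf_mesh")
}

#' @export
print.vf_mesh <- function(x, ...) {
  cat("<vf_mesh>\n")
  cat(sprintf("  %d nodes, %d triangles (%s)\n", nrow(x$nodes), nrow(x$triangles),
              paste(sprintf("%s: %d", levels(x$layer), table(x$layer)), collapse = ", ")))
  cat(sprintf("  %d fixed nodes, %d free-surface nodes\n",
              length(x$fixed_nodes), length(x$free_surface)))
  invisible(x)
}

#' Per-element signed areas of a triangulation (mm^2)
#' @param mesh A `vf_mesh`.
#' @return Numeric vector of signed triangle areas.
#' @export
triangle_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$triangles[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$triangles[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$triangles[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
   (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

#' Write / read a mesh as a plain-text node/element file
#'
#' Format: a header line, `node id x z` records, then `element id n1 n2 n3
#' layer` records.  Round-trips exactly at 12 significant digits.
#'
#' @param mesh A `vf_mesh`.
#' @param path Output file.
#' @return `write_mesh` returns `path` invisibly; `read_mesh` returns a
#'   `vf_mesh` (without geometry provenance).
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vfbayes mesh: %d nodes %d elements",
                     nrow(mesh$nodes), nrow(mesh$triangles)), con)
  writeLines(sprintf("node %d %.12g %.12g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("element %d %d %d %d %s", seq_len(nrow(mesh$triangles)),
                     mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3], as.character(mesh$layer)), con)
  writeLines(sprintf("fixed %s", paste(mesh$fixed_nodes, collapse = " ")), con)
  writeLines(sprintf("free_surface %s", paste(mesh$free_surface, collapse = " ")), con)
  if (!is.null(mesh$patch))
    writeLines(sprintf("patch %s", paste(mesh$patch, collapse = " ")), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ln <- readLines(path)
  nd <- ln[startsWith(ln, "node ")]
  el <- ln[startsWith(ln, "element ")]
  ndm <- do.call(rbind, lapply(strsplit(nd, " "), function(f) as.numeric(f[3:4])))
  elf <- strsplit(el, " ")
  tri <- do.call(rbind, lapply(elf, function(f) as.integer(f[3:5])))
  lay <- factor(vapply(elf, function(f) f[6], ""),
                levels = c("body", "ligament", "cover"))
  fx <- as.integer(strsplit(sub("^fixed ", "", ln[startsWith(ln, "fixed ")]), " ")[[1]])
  fs <- as.integer(strsplit(sub("^free_surface ", "",
                                ln[startsWith(ln, "free_surface ")]), " ")[[1]])
  pt_ln <- ln[startsWith(ln, "patch ")]
  pt <- if (length(pt_ln))
    as.integer(strsplit(sub("^patch ", "", pt_ln), " ")[[1]]) else NULL
  structure(list(nodes = ndm, triangles = tri, layer = lay,
                 fixed_nodes = fx, free_surface = fs, patch = pt),
            class = "vf_mesh")
}

#' Export a mesh in Gmsh .msh v2 format (for visualization)
#' @param mesh A `vf_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.9g %.9g 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$triangles))), con)
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(nrow(mesh$triangles)),
                     as.integer(mesh$layer), as.integer(mesh$layer),
                     mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3]),
             con)
  writeLines("$EndElements", con)
  invisible(path)
}
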