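#' Geometric configuration of the axisymmetric eye model
#'
#' The globe is assembled from two intersecting spheres: an anterior corneal
#' sphere and a scleral sphere, joined at the chord defined by the corneal
#' diameter, with a limbal transition band straddling the junction. Only the
#' central corneal thickness is printed in the source material-parameter
#' table; the remaining dimensions are package conventions and can be
#' overridden here.
#'
#' @param anterior_corneal_radius radius of the anterior corneal sphere, mm.
#' @param corneal_diameter chord diameter at the corneo-scleral junction, mm.
#' @param CCT central corneal thickness, micrometres. Values outside
#'   \[300, 800\] are rejected unless `allow_extreme_cct = TRUE`.
#' @param limbus_width width of the limbal band, mm.
#' @param scleral_radius radius of the scleral sphere, mm.
#' @param scleral_thickness scleral wall thickness, mm.
#' @param mesh_resolution integer refinement level; 1 is the coarse desk-scale
#'   default, 2 halves the element size.
#' @param allow_extreme_cct explicit override for out-of-range CCT.
#' @return object of class `eye_geometry_config`.
#' @examples
#' eye_geometry_config(CCT = 558)
#' @export
eye_geometry_config <- function(anterior_corneal_radius = 7.7,
                                corneal_diameter = 11.5,
                                CCT = 558,
                                limbus_width = 1,
                                scleral_radius = 12,
                                scleral_thickness = 0.8,
                                mesh_resolution = 1L,
                                allow_extreme_cct = FALSE) {
  lens <- c(anterior_corneal_radius, corneal_diameter, CCT, limbus_width,
            scleral_radius, scleral_thickness)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop_wiop("all geometric dimensions must be positive finite numbers")
  if ((CCT < 300 || CCT > 800) && !allow_extreme_cct)
    stop_wiop("CCT = ", CCT, " um is outside [300, 800] um; ",
              "set allow_extreme_cct = TRUE to override")
  if (corneal_diameter >= 2 * scleral_radius)
    stop_wiop("corneal diameter must be smaller than the scleral diameter")
  if (corneal_diameter / 2 >= anterior_corneal_radius)
    stop_wiop("degenerate geometry: corneal half-diameter (", corneal_diameter / 2,
              " mm) must be smaller than the anterior corneal radius (",
              anterior_corneal_radius, " mm)")
  if (CCT / 1000 >= anterior_corneal_radius)
    stop_wiop("degenerate geometry: CCT exceeds the anterior corneal radius")
  mesh_resolution <- as.integer(mesh_resolution)
  if (mesh_resolution < 1L) stop_wiop("mesh_resolution must be >= 1")
  structure(
    list(anterior_corneal_radius = anterior_corneal_radius,
         corneal_diameter = corneal_diameter,
         CCT = CCT,
         limbus_width = limbus_width,
         scleral_radius = scleral_radius,
         scleral_thickness = scleral_thickness,
         mesh_resolution = mesh_resolution),
    class = "eye_geometry_config")
}

#' @export
print.eye_geometry_config <- function(x, ...) {
  cat(sprintf(paste0("<eye_geometry_config> Ra = %g mm, corneal diameter = %g mm, ",
                     "CCT = %g um,\n  limbus %g mm, scleral R = %g mm, t = %g mm, ",
                     "resolution %d\n"),
              x$anterior_corneal_radius, x$corneal_diameter, x$CCT,
              x$limbus_width, x$scleral_radius, x$scleral_thickness,
              x$mesh_resolution))
  invisible(x)
}

#' Build the axisymmetric eye mesh
#'
#' Discretises the corneo-limbo-scleral meridian into a chain of ring
#' (surface-of-revolution) membrane elements. The meridian runs from the
#' corneal apex (on the symmetry axis, node 1) to the posterior scleral pole.
#' Each element carries a region label, a reference thickness, and its fibre
#' architecture: two mutually orthogonal in-surface families (the smeared
#' axisymmetric equivalent of the nasal-temporal / superior-inferior pair)
#' in the cornea, one circumferential family in the limbus, none in the
#' sclera. Nodes on the posterior cap (polar angle beyond 130 degrees) are
#' clamped, mimicking the support of the orbit.
#'
#' @param config an [eye_geometry_config()].
#' @return object of class `eye_mesh` with fields `nodes` (n x 2 matrix of
#'   `r`, `y` in mm; the symmetry axis is `y`, positive outward through the
#'   apex), `elements` (two-column connectivity), `region` (factor per
#'   element), `thickness` (mm per element), `fibres` (per-element list of
#'   unit direction pairs), `anterior` (anterior corneal node indices),
#'   `apex` (index 1), `fixed` (clamped node mask) and the originating
#'   `config`.
#' @examples
#' mesh <- build_eye_mesh(eye_geometry_config(CCT = 558))
#' mesh
#' @export
build_eye_mesh <- function(config) {
  stopifnot(inherits(config, "eye_geometry_config"))
  Ra <- config$anterior_corneal_radius
  Rs <- config$scleral_radius
  rj <- config$corneal_diameter / 2
  w  <- config$limbus_width
  res <- config$mesh_resolution

  yj <- sqrt(Rs^2 - rj^2)              # junction height on the scleral sphere
  yc <- yj - sqrt(Ra^2 - rj^2)          # corneal sphere centre height
  alpha_j <- asin(rj / Ra)              # corneal polar half-angle
  phi_j <- asin(rj / Rs)                # scleral polar angle at junction

  s_cornea <- Ra * alpha_j              # corneal meridian arc length
  s_sclera <- Rs * (pi - phi_j)         # scleral meridian arc length

  # node spacing: uniform on the cornea, geometrically graded on the sclera
  n_c <- 20L * res
  ds_c <- s_cornea / n_c
  s_nodes_c <- seq(0, s_cornea, length.out = n_c + 1L)

  ds_max <- 2.4 / res
  s_rel <- ds_c
  s_list <- numeric(0)
  pos <- 0
  while (pos < s_sclera - 1e-9) {
    step <- min(ds_max, s_rel, s_sclera - pos)
    pos <- pos + step
    s_list <- c(s_list, pos)
    s_rel <- s_rel * 1.25
  }
  s_list[length(s_list)] <- s_sclera

  # coordinates: corneal arc then scleral arc (junction node shared)
  alpha <- s_nodes_c / Ra
  r_c <- Ra * sin(alpha)
  y_c <- yc + Ra * cos(alpha)
  phi <- phi_j + s_list / Rs
  r_s <- Rs * sin(phi)
  y_s <- Rs * cos(phi)

  r <- c(r_c, r_s)
  y <- c(y_c, y_s)
  n_node <- length(r)
  nodes <- cbind(r = r, y = y)

  # arc coordinate of every node measured from the apex, junction at s_cornea
  s_node <- c(s_nodes_c, s_cornea + s_list)

  elements <- cbind(seq_len(n_node - 1L), 2:n_node)
  s_mid <- (s_node[elements[, 1L]] + s_node[elements[, 2L]]) / 2

  region <- ifelse(s_mid < s_cornea - w / 2, "cornea",
                   ifelse(s_mid <= s_cornea + w / 2, "limbus", "sclera"))
  region <- factor(region, levels = c("cornea", "limbus", "sclera"))

  cct_mm <- config$CCT / 1000
  ts <- config$scleral_thickness
  thickness <- ifelse(region == "cornea", cct_mm,
                      ifelse(region == "sclera", ts,
                             cct_mm + (ts - cct_mm) *
                               (s_mid - (s_cornea - w / 2)) / w))

  # fibre directions at element midpoints on the phi = 0 meridian plane
  # (x = r): meridional tangent and circumferential unit vectors
  dr <- r[elements[, 2L]] - r[elements[, 1L]]
  dy <- y[elements[, 2L]] - y[elements[, 1L]]
  ln <- sqrt(dr^2 + dy^2)
  fibres <- lapply(seq_len(nrow(elements)), function(e) {
    switch(as.character(region[e]),
           cornea = list(meridional = c(dr[e] / ln[e], dy[e] / ln[e], 0),
                         circumferential = c(0, 0, 1)),
           limbus = list(circumferential = c(0, 0, 1)),
           sclera = list())
  })

  # anterior corneal node set: nodes bounding at least one corneal element
  ant_el <- which(region == "cornea")
  anterior <- sort(unique(as.integer(elements[ant_el, ])))

  # clamp the posterior cap (polar angle on the scleral sphere > 130 deg)
  phi_node <- c(rep(0, n_c + 1L), phi)  # corneal nodes never clamped
  fixed <- phi_node > 130 / 180 * pi

  mesh <- structure(
    list(nodes = nodes, elements = elements, region = region,
         thickness = thickness, fibres = fibres,
         anterior = anterior, apex = 1L, fixed = fixed,
         s_node = s_node, s_cornea = s_cornea,
         config = config, n_theta = 48L),
    class = "eye_mesh")
  mesh
}

#' @export
print.eye_mesh <- function(x, ...) {
  cat(sprintf("<eye_mesh> %d nodes, %d ring elements (%d cornea / %d limbus / %d sclera)\n",
              nrow(x$nodes), nrow(x$elements),
              sum(x$region == "cornea"), sum(x$region == "limbus"),
              sum(x$region == "sclera")))
  cat(sprintf("  apex at y = %.3f mm, %d anterior corneal nodes, %d clamped nodes\n",
              x$nodes[x$apex, "y"], length(x$anterior), sum(x$fixed)))
  cat(sprintf("  CCT = %g um, anterior radius = %g mm\n",
              x$config$CCT, x$config$anterior_corneal_radius))
  invisible(x)
}

# lateral (frustum) areas of a subset of ring elements, lumped half-half to
# their end nodes; returns a full-length nodal vector
lumped_ring_areas <- function(r, y, elements, subset = seq_len(nrow(elements))) {
  e1 <- elements[subset, 1L]; e2 <- elements[subset, 2L]
  ln <- sqrt((r[e2] - r[e1])^2 + (y[e2] - y[e1])^2)
  Ae <- pi * (r[e1] + r[e2]) * ln        # exact frustum lateral area
  half <- Ae / 2
  A_acc <- numeric(length(r))
  for (k in seq_along(subset)) {
    A_acc[e1[k]] <- A_acc[e1[k]] + half[k]
    A_acc[e2[k]] <- A_acc[e2[k]] + half[k]
  }
  A_acc
}

# y-projected (signed, outward) nodal areas of a subset of elements:
# each element's lateral surface projects onto the annulus pi*(r2^2 - r1^2),
# split half-half between its end nodes. Ordering is apex -> pole so the
# outward normal has a positive y-projection on the anterior cap.
projected_ring_areas_y <- function(r, elements, subset = seq_len(nrow(elements))) {
  e1 <- elements[subset, 1L]; e2 <- elements[subset, 2L]
  Ay <- pi * (r[e2]^2 - r[e1]^2)
  half <- Ay / 2
  A_acc <- numeric(length(r))
  for (k in seq_along(subset)) {
    A_acc[e1[k]] <- A_acc[e1[k]] + half[k]
    A_acc[e2[k]] <- A_acc[e2[k]] + half[k]
  }
  A_acc
}

#' Per-node areas of the anterior corneal surface
#'
#' Lumps the lateral area of each anterior corneal ring element half-half
#' onto its end nodes, recomputed in an arbitrary (current) configuration.
#' With `projected = TRUE` the signed y-projected areas are returned instead;
#' these are the effective areas through which a spatially uniform pressure
#' does work along the anterior-posterior axis, and they telescope exactly to
#' the disc area of the corneal rim.
#'
#' @param mesh an [build_eye_mesh()] mesh.
#' @param coords optional n x 2 matrix of current nodal coordinates
#'   (defaults to the mesh reference configuration).
#' @param projected logical; return signed y-projected areas.
#' @return named numeric vector of areas (mm^2) over the anterior corneal
#'   node indices.
#' @examples
#' mesh <- build_eye_mesh(eye_geometry_config())
#' sum(anterior_nodal_areas(mesh))
#' @export
anterior_nodal_areas <- function(mesh, coords = NULL, projected = FALSE) {
  stopifnot(inherits(mesh, "eye_mesh"))
  if (is.null(coords)) coords <- mesh$nodes
  r <- coords[, 1L]; y <- coords[, 2L]
  sel <- which(mesh$region == "cornea")
  A <- if (projected) projected_ring_areas_y(r, mesh$elements, sel)
       else lumped_ring_areas(r, y, mesh$elements, sel)
  out <- A[mesh$anterior]
  names(out) <- mesh$anterior
  out
}

# replace nodal coordinates, keeping topology, thickness and labels; used by
# the zero-pressure recovery where the candidate stress-free geometry changes
remesh_nodes <- function(mesh, nodes) {
  mesh$nodes <- nodes
  mesh
}
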