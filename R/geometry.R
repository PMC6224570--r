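#' Nuclear geometry in internal coordinates
#'
#' A geometry holds internal coordinates together with per-coordinate
#' effective inertias. For the two-dimensional photoswitch surrogate the
#' coordinates are the torsion theta (the CNNC-like dihedral driving
#' trans/cis isomerization) and the bend alpha (the NNC-like angle
#' modulating the excited-state gap); both are angular. Angular coordinates
#' are given in degrees at the interface and stored in radians; the torsion
#' is wrapped to (-180, 180] degrees.
#'
#' @param coords numeric vector of coordinates. Angular entries in degrees
#'   unless `degrees = FALSE`; non-angular entries (e.g. the bond-length-like
#'   coordinate of the 1-D models) in bohr.
#' @param inertia strictly positive per-coordinate effective inertias
#'   (atomic units; mass times length squared for angular coordinates).
#' @param angular logical vector flagging which coordinates are angles.
#' @param degrees are angular coordinates supplied in degrees?
#' @return an object of class `polhop_geometry`.
#' @examples
#' geometry(c(180, 115), inertia = c(1.5e5, 1.25e4))
#' @export
geometry <- function(coords, inertia, angular = rep(TRUE, length(coords)),
                     degrees = TRUE) {
  coords <- as.numeric(coords)
  inertia <- as.numeric(inertia)
  if (length(coords) != length(inertia))
    stop("coords and inertia must have equal length")
  if (!all(is.finite(coords))) stop("non-finite coordinate")
  if (!all(is.finite(inertia)) || any(inertia <= 0))
    stop("all inertias must be strictly positive")
  if (length(angular) != length(coords))
    stop("angular flag vector must match coords")
  x <- coords
  if (degrees) x[angular] <- deg_to_rad(x[angular])
  if (angular[1]) x[1] <- wrap_angle(x[1])
  structure(list(coords = x, inertia = inertia, angular = angular),
            class = "polhop_geometry")
}

# wrap to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

#' @export
print.polhop_geometry <- function(x, ...) {
  v <- x$coords
  v[x$angular] <- rad_to_deg(v[x$angular])
  unit <- ifelse(x$angular, "deg", "bohr")
  cat("<polhop_geometry> ",
      paste(sprintf("%.4f %s", v, unit), collapse = ", "), "\n")
  invisible(x)
}

#' Coordinates of a geometry at interface units
#'
#' @param Q a `polhop_geometry`.
#' @return numeric vector, angles in degrees.
#' @export
coords_deg <- function(Q) {
  v <- Q$coords
  v[Q$angular] <- rad_to_deg(v[Q$angular])
  v
}

#' Classify the isomer of a torsional geometry
#'
#' trans if the absolute torsion is at least 90 degrees (the boundary value
#' 90 itself counts as trans, a documented tie-break), cis otherwise.
#'
#' @param Q a `polhop_geometry` whose first coordinate is the torsion.
#' @return `"trans"` or `"cis"`.
#' @examples
#' classify_isomer(geometry(c(180, 115), c(1.5e5, 1.25e4)))
#' @export
classify_isomer <- function(Q) {
  th <- if (inherits(Q, "polhop_geometry")) Q$coords[1] else deg_to_rad(Q[1])
  if (abs(wrap_angle(th)) >= pi / 2 - 1e-15) "trans" else "cis"
}
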