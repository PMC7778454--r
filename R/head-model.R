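#' Layered spherical head phantom
#'
#' Builds a four-shell concentric-sphere head model (brain, CSF, skull, scalp)
#' together with a cortical source space: a quasi-uniform Fibonacci lattice of
#' radially oriented dipole locations on the outer brain surface. The sphere
#' phantom is an analytic stand-in for a tessellated anatomical head: it keeps
#' the two physical features the joint reconstruction method relies on -- the
#' spatial low-pass filtering of scalp potentials by the skull, and the
#' "banana"-shaped optical sensitivity between nearby optodes -- while staying
#' fully deterministic and mesh-free.
#'
#' @param shell_radii numeric(4), outer radii in mm of brain, CSF, skull and
#'   scalp compartments, strictly increasing. Default `c(80, 82, 87, 92)`.
#' @param conductivities numeric(4), relative electrical conductivities of the
#'   four compartments (brain, CSF, skull, scalp). Default `c(1, 5, 1/80, 1)`,
#'   i.e. the skull is 80x more resistive than brain/scalp and CSF is 5x more
#'   conductive.
#' @param optical_props named list, one entry per wavelength (names are
#'   wavelengths in nm) with fields `mua` (absorption coefficient, 1/mm) and
#'   `musp` (reduced scattering coefficient, 1/mm) of the homogeneous optical
#'   medium. Defaults to literature-typical brain-like values at 750/850 nm.
#' @param wavelengths numeric, wavelengths in nm; must match the names of
#'   `optical_props`. Default `c(750, 850)`.
#' @param n_sources integer, number of cortical source voxels to place on the
#'   brain shell (>= 500). Default 2500.
#'
#' @return A list with classes `eegdot_head`:
#'   \describe{
#'     \item{head}{`HeadModel`: shell radii, conductivities, optical
#'       properties, wavelengths.}
#'     \item{sources}{`SourceSpace`: `positions` (V x 3, mm), `normals`
#'       (V x 3 unit radial vectors), `voxel_ids` (1..V), `spacing_mm`
#'       (median nearest-neighbour spacing).}
#'   }
#' @examples
#' hm <- build_spherical_head(n_sources = 600)
#' range(sqrt(rowSums(hm$sources$positions^2)))  # all at the brain radius
#' @export
build_spherical_head <- function(shell_radii = c(80, 82, 87, 92),
                                 conductivities = c(1, 5, 1 / 80, 1),
                                 optical_props = default_optical_props(),
                                 wavelengths = c(750, 850),
                                 n_sources = 2500) {
  if (length(shell_radii) != 4L || any(diff(shell_radii) <= 0)) {
    stop("`shell_radii` must be 4 strictly increasing radii (mm)", call. = FALSE)
  }
  if (length(conductivities) != 4L || any(conductivities <= 0)) {
    stop("`conductivities` must be 4 positive values", call. = FALSE)
  }
  if (n_sources < 500) {
    stop("`n_sources` must be at least 500 for a usable cortical shell", call. = FALSE)
  }
  wl <- as.character(wavelengths)
  if (!all(wl %in% names(optical_props))) {
    stop("`optical_props` must have an entry for every wavelength", call. = FALSE)
  }
  for (w in wl) {
    op <- optical_props[[w]]
    if (op$musp <= 0) stop("reduced scattering coefficient must be > 0", call. = FALSE)
    if (op$mua <= 0) stop("absorption coefficient must be > 0", call. = FALSE)
  }

  head <- structure(
    list(
      shell_radii = stats::setNames(shell_radii, c("brain", "csf", "skull", "scalp")),
      conductivities = stats::setNames(conductivities, c("brain", "csf", "skull", "scalp")),
      optical_props = optical_props[wl],
      wavelengths = wavelengths
    ),
    class = "eegdot_head_model"
  )

  dirs <- fibonacci_sphere(n_sources)
  positions <- dirs * shell_radii[1]
  sources <- structure(
    list(
      positions = positions,
      normals = dirs,
      voxel_ids = seq_len(n_sources),
      radius_mm = shell_radii[1],
      spacing_mm = lattice_spacing(shell_radii[1], n_sources)
    ),
    class = "eegdot_source_space"
  )

  structure(list(head = head, sources = sources), class = "eegdot_head")
}

#' Literature-typical optical properties of a homogeneous brain-like medium
#'
#' Absorption (`mua`) and reduced scattering (`musp`) coefficients in 1/mm at
#' 750 and 850 nm. Override by passing your own list to
#' [build_spherical_head()].
#' @return named list keyed by wavelength (nm as character).
#' @export
default_optical_props <- function() {
  list(
    `750` = list(mua = 0.0178, musp = 1.25),
    `850` = list(mua = 0.0186, musp = 1.10)
  )
}

# Quasi-uniform points on the unit sphere (golden-angle spiral). Deterministic.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)                 # polar angle
  theta <- pi * (1 + sqrt(5)) * i            # golden-angle azimuth
  cbind(
    x = sin(phi) * cos(theta),
    y = sin(phi) * sin(theta),
    z = cos(phi)
  )
}

# Median nearest-neighbour spacing of the lattice: estimated from the
# area-per-point of the sphere (exact enough for linking radii and docs).
lattice_spacing <- function(radius, n) {
  sqrt(4 * pi * radius^2 / n)
}

# Euclidean distance between rows of a and rows of b (na x nb matrix).
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Direction on the unit sphere for a point expressed in the tangent plane of
# `center_dir` (a unit vector): (u, v) are mm offsets along the two tangent
# axes; the point is mapped by normalized addition (gnomonic-like projection),
# which is accurate for patch-scale offsets.
tangent_to_sphere <- function(center_dir, uv, radius) {
  basis <- tangent_basis(center_dir)
  p <- matrix(center_dir, nrow(uv), 3, byrow = TRUE) * radius +
    uv[, 1] %o% basis$e1 + uv[, 2] %o% basis$e2
  p / sqrt(rowSums(p^2)) * radius
}

# Orthonormal tangent basis at a unit direction vector.
tangent_basis <- function(center_dir) {
  ref <- if (abs(center_dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * center_dir) * center_dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    center_dir[2] * e1[3] - center_dir[3] * e1[2],
    center_dir[3] * e1[1] - center_dir[1] * e1[3],
    center_dir[1] * e1[2] - center_dir[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

#' @export
print.eegdot_head <- function(x, ...) {
  cat("Spherical head phantom\n")
  cat("  shells (mm):", paste(x$head$shell_radii, collapse = " / "), "\n")
  cat("  conductivities:", paste(signif(x$head$conductivities, 3), collapse = " / "), "\n")
  cat("  wavelengths (nm):", paste(x$head$wavelengths, collapse = ", "), "\n")
  cat("  cortical sources:", nrow(x$sources$positions),
      sprintf("(spacing ~%.1f mm)\n", x$sources$spacing_mm))
  invisible(x)
}
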