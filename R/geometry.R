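#' Detector geometry
#'
#' Bundles the experimental geometry of a small-angle scattering detector:
#' X-ray wavelength, sample-to-detector distance, pixel size and beam centre.
#' Units follow the conventions of small-angle beamlines: wavelength in
#' angstrom, distance in metres, pixel size in micrometres, scattering vector
#' magnitudes in inverse nanometres.  The azimuth origin is fixed at the +x
#' axis with counter-clockwise positive angles (radians internally).
#'
#' @param wavelength X-ray wavelength in angstrom (> 0).
#' @param distance sample-to-detector distance in metres (> 0).
#' @param pixel_size detector pixel edge in micrometres (> 0).
#' @param beam_centre numeric length-2, fractional pixel coordinates (x, y)
#'   of the direct beam, 1-based like R matrix indices.
#' @param image_shape integer length-2, image dimensions as (nx, ny).
#' @return an object of class `detector_geometry`.
#' @examples
#' geom <- detector_geometry(1.033, 0.694, 75, c(512, 512), c(1024, 1024))
#' @export
detector_geometry <- function(wavelength, distance, pixel_size,
                              beam_centre, image_shape) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1,
            is.numeric(distance), length(distance) == 1,
            is.numeric(pixel_size), length(pixel_size) == 1,
            length(beam_centre) == 2, length(image_shape) == 2)
  if (wavelength <= 0) stop("wavelength must be positive (angstrom)")
  if (distance <= 0) stop("distance must be positive (metres)")
  if (pixel_size <= 0) stop("pixel_size must be positive (micrometres)")
  if (any(beam_centre < 1) || beam_centre[1] > image_shape[1] ||
      beam_centre[2] > image_shape[2])
    stop("beam_centre must lie inside the image bounds")
  structure(list(wavelength = wavelength, distance = distance,
                 pixel_size = pixel_size, beam_centre = as.numeric(beam_centre),
                 image_shape = as.integer(image_shape),
                 azimuth_origin = "+x, counter-clockwise"),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("detector_geometry: lambda =", x$wavelength, "A, L =", x$distance,
      "m, pixel =", x$pixel_size, "um, centre = (",
      x$beam_centre[1], ",", x$beam_centre[2], "), shape = (",
      x$image_shape[1], "x", x$image_shape[2], ")\n")
  invisible(x)
}

#' Scattering-vector magnitude at a detector radius
#'
#' Exact Bragg geometry: `q = (4 pi / lambda) sin(atan(radius / L) / 2)`,
#' with the wavelength converted from angstrom to nanometres so that q is
#' returned in inverse nanometres.
#'
#' @param radius radial distance from the beam centre on the detector, in mm.
#'   Vectorised.
#' @param geom a [detector_geometry()].
#' @return q in nm^-1.
#' @export
q_of_radius <- function(radius, geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  if (any(radius < 0)) stop("radius must be non-negative")
  lambda_nm <- geom$wavelength / 10
  two_theta <- atan(radius / 1000 / geom$distance)
  (4 * pi / lambda_nm) * sin(two_theta / 2)
}

#' Detector radius at a scattering-vector magnitude
#'
#' Inverse of [q_of_radius()].
#'
#' @param q scattering-vector magnitude in nm^-1.  Vectorised.
#' @param geom a [detector_geometry()].
#' @return radius in mm.
#' @export
radius_of_q <- function(q, geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  if (any(q < 0)) stop("q must be non-negative")
  lambda_nm <- geom$wavelength / 10
  s <- q * lambda_nm / (4 * pi)
  if (any(s > 1)) stop("q beyond the back-scattering limit for this wavelength")
  geom$distance * tan(2 * asin(s)) * 1000
}

#' Calibrate the sample-to-detector distance from a reference ring
#'
#' Given the measured radius of a diffraction ring of known d-spacing
#' (canonically the silver behenate (001) ring, d = 58.380 angstrom), solves
#' the exact Bragg geometry for the unique distance that places the ring at
#' that radius.  This inverts [q_of_radius()]: the returned distance L
#' satisfies `q_of_radius(ring_radius, geom(L)) == 2*pi*10/d_spacing`.
#'
#' @param ring_radius measured ring radius in mm (> 0).
#' @param d_spacing lattice spacing of the calibrant in angstrom.
#' @param wavelength X-ray wavelength in angstrom.
#' @return calibrated distance in metres.
#' @export
calibrate_distance <- function(ring_radius, d_spacing, wavelength) {
  if (length(ring_radius) != 1 || ring_radius <= 0)
    stop("ring_radius must be a single positive value (mm)")
  if (d_spacing <= wavelength / 2)
    stop("non-physical calibrant: d_spacing must exceed wavelength/2")
  s <- wavelength / (2 * d_spacing)
  (ring_radius / 1000) / tan(2 * asin(s))
}

#' Ratio of two rectangular beam areas
#'
#' Small utility for comparing illuminated areas (and hence the expected
#' number of domains in the beam) between beamline configurations, e.g. a
#' 25 x 250 um SAXS beam against a 2 x 2 um microfocus beam.
#'
#' @param beam1,beam2 numeric length-2, beam width and height in micrometres.
#' @return `prod(beam1) / prod(beam2)`.
#' @export
beam_area_ratio <- function(beam1, beam2) {
  stopifnot(length(beam1) == 2, length(beam2) == 2,
            all(beam1 > 0), all(beam2 > 0))
  prod(beam1) / prod(beam2)
}

#' Remap a detector image onto a polar (q, phi) grid
#'
#' Samples the image by bilinear interpolation at the detector position of
#' every (q, phi) bin centre.  Masked detector pixels propagate: a polar bin
#' whose interpolation footprint is more than half masked (or which falls
#' outside the detector) is flagged invalid in the output mask.  A constant
#' image maps to the same constant in every valid bin.
#'
#' @param image numeric matrix, indexed `image[ix, iy]` with x along rows
#'   (matching `image_shape = c(nx, ny)`).
#' @param geom a [detector_geometry()].
#' @param grid a [polar_grid()].
#' @param mask optional logical matrix, `TRUE` where the pixel is valid;
#'   defaults to all valid.
#' @return a [polar_pattern()].
#' @export
polar_remap <- function(image, geom, grid, mask = NULL) {
  stopifnot(inherits(geom, "detector_geometry"), inherits(grid, "polar_grid"))
  if (!is.matrix(image) || any(dim(image) != geom$image_shape))
    stop("image shape does not match geometry image_shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (any(dim(mask) != dim(image))) stop("mask shape does not match image")
  if (!any(mask)) stop("empty pattern: image is fully masked")

  r_mm <- radius_of_q(grid$q, geom)
  px <- r_mm * 1000 / geom$pixel_size          # radius in pixels
  x <- geom$beam_centre[1] + outer(px, cos(grid$phi))
  y <- geom$beam_centre[2] + outer(px, sin(grid$phi))

  nx <- nrow(image); ny <- ncol(image)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 1 & (x0 + 1) <= nx & y0 >= 1 & (y0 + 1) <= ny
  x0[!inside] <- 1; y0[!inside] <- 1           # safe dummy indices

  idx <- function(i, j) cbind(as.vector(i), as.vector(j))
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  gather <- function(m) {
    v00 <- m[idx(x0, y0)];     v10 <- m[idx(x0 + 1, y0)]
    v01 <- m[idx(x0, y0 + 1)]; v11 <- m[idx(x0 + 1, y0 + 1)]
    matrix(w00 * v00 + w10 * v10 + w01 * v01 + w11 * v11,
           nrow = length(grid$q))
  }
  val <- gather(image)
  badfrac <- gather(1 - (mask * 1))            # masked fraction of footprint
  ok <- inside & badfrac <= 0.5
  if (!any(ok)) stop("empty pattern: no polar bin has unmasked support")
  val[!ok] <- 0
  polar_pattern(val, grid, mask = ok)
}
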