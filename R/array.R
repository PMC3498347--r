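# Microphone-array geometry, propagation model and image plane.
#
# Coordinate convention: the array lies in the z = 0 plane, x right, y up,
# the image plane at z = distance (all in meters).

#' Construct a microphone-array geometry
#'
#' @param mic_positions Numeric matrix (M x 3) of microphone coordinates in
#'   meters, or a data frame with columns x, y, z.
#' @param weights Non-negative per-microphone shading weights (default unit).
#' @param name Free-text label.
#' @return An `array_geometry` object: list with `mics` (tibble x, y, z,
#'   weight) and `name`.
#' @export
array_geometry <- function(mic_positions, weights = NULL, name = "array") {
  if (is.data.frame(mic_positions)) {
    mic_positions <- as.matrix(mic_positions[, c("x", "y", "z")])
  }
  mic_positions <- matrix(as.numeric(mic_positions), ncol = 3)
  m <- nrow(mic_positions)
  if (m < 1) stop("geometry needs at least one microphone")
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("one weight per microphone required")
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative with at least one positive")
  }
  structure(
    list(
      mics = tibble::tibble(
        x = mic_positions[, 1], y = mic_positions[, 2], z = mic_positions[, 3],
        weight = as.numeric(weights)
      ),
      name = name
    ),
    class = "array_geometry"
  )
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry '%s': %d mics, aperture %.3f m>\n",
              x$name, nrow(x$mics), array_span(x)))
  invisible(x)
}

mic_matrix <- function(geometry) {
  as.matrix(geometry$mics[, c("x", "y", "z")])
}

#' Maximum pairwise microphone distance (aperture) in meters
#' @param geometry An `array_geometry`.
#' @export
array_span <- function(geometry) {
  p <- mic_matrix(geometry)
  if (nrow(p) < 2) return(0)
  max(stats::dist(p))
}

#' Build a star-shaped microphone array
#'
#' Microphones are laid out on `n_arms` equiangular arms with logarithmic
#' radial spacing, then scaled so the maximum pairwise distance equals
#' `span` and translated so the centroid sits at the origin. The default
#' 3 x 16 configuration reproduces the 48-channel, 3.4 m aperture star
#' array used for acoustic-camera recording of elephants at ~8 m. The
#' commercial array's exact arm layout is unpublished; results that depend
#' on sidelobe structure are layout-dependent.
#'
#' @param n_arms Number of arms (default 3).
#' @param mics_per_arm Microphones per arm (default 16).
#' @param span Target maximum pairwise distance in meters (default 3.4).
#' @param name Label for the geometry.
#' @return An `array_geometry` with `n_arms * mics_per_arm` microphones and
#'   unit weights.
#' @export
#' @examples
#' g <- build_star_array()
#' nrow(g$mics)      # 48
#' array_span(g)     # 3.4
build_star_array <- function(n_arms = 3, mics_per_arm = 16, span = 3.4,
                             name = "star-48") {
  if (span <= 0) stop("invalid geometry: span must be positive")
  if (n_arms < 1 || mics_per_arm < 1) stop("invalid geometry: need >= 1 arm and mic")
  # log-spaced radii on (0, 1]; a single mic per arm sits at the tip
  radii <- if (mics_per_arm == 1) 1 else
    (exp(seq_len(mics_per_arm) / mics_per_arm) - 1) / (exp(1) - 1)
  pos <- do.call(rbind, lapply(seq_len(n_arms), function(a) {
    th <- 2 * pi * (a - 1) / n_arms + pi / 2
    cbind(radii * cos(th), radii * sin(th), 0)
  }))
  if (nrow(pos) > 1) {
    cur <- max(stats::dist(pos))
    if (cur > 0) pos <- pos * (span / cur)
  } else {
    pos[] <- 0
  }
  pos <- sweep(pos, 2, colMeans(pos))
  array_geometry(pos, name = name)
}

#' Propagation model for air
#'
#' Speed of sound used for run times and beamforming. The default 343 m/s
#' corresponds to ~20 deg C air; it is deliberately distinct from the
#' 350 m/s used by the vocal-tract tube model (see [tube_model()]) and the
#' two are never shared implicitly.
#'
#' @param speed_of_sound Speed of sound in m/s (> 0).
#' @param attenuation "spherical" (1/r amplitude loss) or "none".
#' @export
propagation_model <- function(speed_of_sound = 343, attenuation = c("spherical", "none")) {
  if (speed_of_sound <= 0) stop("speed_of_sound must be positive")
  structure(
    list(speed_of_sound = speed_of_sound,
         attenuation = match.arg(attenuation)),
    class = "propagation_model"
  )
}

#' Image plane for acoustic maps
#'
#' A rectangular grid parallel to the array at z = `distance`, centered on
#' the array axis.
#'
#' @param distance Distance from the array plane in meters (default 8, the
#'   recording distance to the elephants).
#' @param width,height Plane extent in meters.
#' @param nx,ny Grid resolution in pixels.
#' @export
image_plane <- function(distance = 8, width = 4, height = 3, nx = 64, ny = 48) {
  if (distance <= 0) stop("distance must be positive")
  if (nx < 1 || ny < 1) stop("grid resolution must be >= 1")
  structure(
    list(distance = distance, width = width, height = height,
         nx = as.integer(nx), ny = as.integer(ny)),
    class = "image_plane"
  )
}

#' Pixel-center coordinates of an image plane
#' @param plane An `image_plane`.
#' @return Tibble with columns ix, iy, x, y, z (one row per pixel).
#' @export
plane_grid <- function(plane) {
  xs <- seq(-plane$width / 2, plane$width / 2, length.out = plane$nx)
  ys <- seq(-plane$height / 2, plane$height / 2, length.out = plane$ny)
  g <- tidyr::expand_grid(iy = seq_len(plane$ny), ix = seq_len(plane$nx))
  tibble::tibble(ix = g$ix, iy = g$iy,
                 x = xs[g$ix], y = ys[g$iy], z = plane$distance)
}

#' Absolute propagation run times from each microphone to a point
#'
#' Run time pi_i = |r_i| / v, with r_i the vector from microphone i to the
#' focus point and v the speed of sound.
#'
#' @param geometry An `array_geometry`.
#' @param point Length-3 coordinate in meters.
#' @param model A `propagation_model`.
#' @return Numeric vector of run times in seconds, one per microphone.
#' @export
run_times <- function(geometry, point, model = propagation_model()) {
  p <- mic_matrix(geometry)
  d <- sqrt(rowSums(sweep(p, 2, as.numeric(point))^2))
  if (any(d == 0)) stop("degenerate geometry: focus point coincides with a microphone")
  d / model$speed_of_sound
}

#' Relative inter-microphone delays
#'
#' Delta_i = pi_i - min(pi_i): the extra travel time of each channel
#' relative to the earliest-arriving microphone.
#'
#' @param times Numeric vector of absolute run times in seconds.
#' @return Delays in seconds; the minimum is exactly 0.
#' @export
relative_delays <- function(times) {
  if (length(times) == 0) stop("empty run-time vector")
  times - min(times)
}

#' Serialize an array geometry to JSON
#' @param geometry An `array_geometry`.
#' @param path Output file.
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(
    list(name = geometry$name,
         mic_positions = mic_matrix(geometry),
         weights = geometry$mics$weight),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an array geometry from JSON
#' @param path JSON file written by [write_geometry()].
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  array_geometry(j$mic_positions, weights = j$weights, name = j$name)
}
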