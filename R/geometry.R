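#' Display geometry
#'
#' Describes a participant's display: the physical width of the visible part
#' of the screen, its horizontal resolution, and the viewing distance. These
#' three numbers standardise stimulus size and spatial frequency across
#' heterogeneous displays by fixing the pixels-per-degree conversion.
#'
#' @param screen_width_cm Width of the visible display area, cm.
#' @param horizontal_resolution_px Horizontal resolution, pixels.
#' @param viewing_distance_cm Viewing distance, cm.
#' @return A list of class `"display_geometry"`.
#' @examples
#' geom <- display_geometry(40, 1000, 60)
#' pixels_per_degree(geom)
#' @export
display_geometry <- function(screen_width_cm, horizontal_resolution_px,
                             viewing_distance_cm) {
  vals <- c(screen_width_cm, horizontal_resolution_px, viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all display geometry fields must be strictly positive and finite",
         call. = FALSE)
  }
  structure(
    list(screen_width_cm = screen_width_cm,
         horizontal_resolution_px = horizontal_resolution_px,
         viewing_distance_cm = viewing_distance_cm),
    class = "display_geometry"
  )
}

#' Pixels per degree of visual angle
#'
#' Converts display geometry into the number of pixels subtending one degree
#' of visual angle at the display centre, using the exact relation: one degree
#' spans `2 * d * tan(0.5 deg)` cm at viewing distance `d`, times the pixel
#' density in px/cm. The exact tangent form (rather than the small-angle
#' approximation) keeps the conversion correct at the parafoveal
#' eccentricities the spatial task uses.
#'
#' @param geometry A [display_geometry()].
#' @return Pixels per degree (numeric scalar).
#' @export
pixels_per_degree <- function(geometry) {
  stopifnot(inherits(geometry, "display_geometry"))
  px_per_cm <- geometry$horizontal_resolution_px / geometry$screen_width_cm
  cm_per_deg <- 2 * geometry$viewing_distance_cm * tan(0.5 * pi / 180)
  px_per_cm * cm_per_deg
}

#' Render a Gabor stimulus as a luminance matrix
#'
#' Produces the stimulus the task presents: a sinusoidal luminance grating of
#' `config$grating_sf` cycles/degree at the given orientation, windowed by a
#' Gaussian envelope (space constant `config$envelope_space_constant` deg,
#' hard-truncated at `config$envelope_truncation` deg) and scaled to
#' `config$contrast_fraction` of the available range. The grating is in sine
#' phase with respect to the envelope centre, so the centre pixel always sits
#' at the mean luminance (0.5); `polarity` selects positive or negative sine,
#' mirroring the per-presentation polarity randomisation used to avoid
#' luminance artefacts.
#'
#' @param geometry A [display_geometry()] fixing pixels per degree.
#' @param orientation_deg Grating orientation, degrees anticlockwise from
#'   horizontal.
#' @param polarity `+1` (positive sine) or `-1` (negative sine).
#' @param config A [design_config()] supplying stimulus parameters.
#' @return A square numeric matrix with values in `[0, 1]`, background 0.5,
#'   spanning +/- the truncation radius.
#' @export
render_gabor <- function(geometry, orientation_deg, polarity = 1,
                         config = design_config()) {
  stopifnot(polarity %in% c(-1, 1))
  sigma <- config$envelope_space_constant
  trunc <- config$envelope_truncation
  if (trunc < sigma) {
    warning("envelope truncation (", trunc, " deg) is smaller than the space ",
            "constant (", sigma, " deg); the envelope is clipped well above ",
            "its 1/e point", call. = FALSE)
  }
  ppd <- pixels_per_degree(geometry)
  half_px <- ceiling(trunc * ppd)
  ax <- seq(-half_px, half_px) / ppd            # degrees
  x <- matrix(ax, nrow = length(ax), ncol = length(ax), byrow = TRUE)
  y <- matrix(ax, nrow = length(ax), ncol = length(ax))
  th <- orientation_deg * pi / 180
  # u is the modulation axis (perpendicular to the grating bars); at 0 deg the
  # luminance varies along x, so a 0 deg render is the transpose of a 90 deg one
  u <- x * cos(th) + y * sin(th)
  env <- exp(-(x^2 + y^2) / (2 * sigma^2))
  env[x^2 + y^2 > trunc^2] <- 0
  0.5 * (1 + config$contrast_fraction * polarity *
           sin(2 * pi * config$grating_sf * u) * env)
}
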