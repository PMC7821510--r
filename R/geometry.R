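#' Scene geometry for a lit forest-edge recording site
#'
#' Describes the fixed spatial layout of a sampling site: the four-microphone
#' array, the streetlight, the forest-edge plane and the speed of sound. All
#' coordinates are metres in the array frame: the central microphone sits at
#' the origin (horizontally), the forest edge runs parallel to the x axis at
#' `y = 4` (the central microphone stands 4 m into the open), and the light
#' sits on the edge at `(4, 4, 4)` — a four-metre-tall lamppost.
#'
#' @param mic_positions numeric 4 x 3 matrix of microphone coordinates (m).
#'   Default: an equilateral horizontal triangle of radius 1.2 m plus a
#'   central microphone, all at 0.9 m above ground (the array is deployed
#'   with microphones between roughly 0.8 and 1 m height).
#' @param light_position numeric length-3, position of the light (m);
#'   default `c(4, 4, 4)`.
#' @param edge_normal,edge_offset oriented forest-edge plane: a position `p`
#'   is inside the forest iff `sum(edge_normal * p) > edge_offset`. Default
#'   plane `y = 4`, forest at `y > 4`.
#' @param air_temp_c air temperature in degrees Celsius used to derive the
#'   speed of sound when `speed_of_sound` is `NULL`. Default 16.2 (the
#'   campaign-mean night temperature).
#' @param speed_of_sound optional speed of sound in m/s; overrides
#'   `air_temp_c` when given.
#'
#' @return An object of class `scene_geometry`.
#' @examples
#' geom <- scene_geometry()
#' geom$speed_of_sound
#' @export
scene_geometry <- function(mic_positions = default_mic_positions(),
                           light_position = c(4, 4, 4),
                           edge_normal = c(0, 1, 0),
                           edge_offset = 4,
                           air_temp_c = 16.2,
                           speed_of_sound = NULL) {
  mic_positions <- as.matrix(mic_positions)
  if (ncol(mic_positions) != 3 || nrow(mic_positions) < 4)
    stop("`mic_positions` must be a matrix with >= 4 rows and 3 columns")
  storage.mode(mic_positions) <- "double"
  if (!all(is.finite(mic_positions))) stop("microphone coordinates must be finite")
  # collinearity check: the horizontal footprint must span a plane
  xy <- cbind(mic_positions[, 1:2], 1)
  if (qr(xy)$rank < 3)
    stop("microphones are collinear in the horizontal plane; positions are unlocalizable")
  if (length(light_position) != 3) stop("`light_position` must have length 3")
  if (length(edge_normal) != 3 || all(edge_normal == 0))
    stop("`edge_normal` must be a non-zero length-3 vector")
  nrm <- sqrt(sum(edge_normal^2))
  c_sound <- if (is.null(speed_of_sound)) speed_of_sound_air(air_temp_c) else speed_of_sound
  if (!is.finite(c_sound) || c_sound <= 0) stop("speed of sound must be positive")
  structure(list(
    mic_positions = mic_positions,
    light_position = as.numeric(light_position),
    edge_normal = as.numeric(edge_normal) / nrm,
    edge_offset = as.numeric(edge_offset) / nrm,
    air_temp_c = air_temp_c,
    speed_of_sound = c_sound
  ), class = "scene_geometry")
}

#' Default microphone layout
#'
#' Three microphones at the corners of a horizontal equilateral triangle
#' (circumradius 2 m) plus one at its centre, all at 0.9 m height.
#'
#' @param radius circumradius of the triangle (m).
#' @param height microphone height above ground (m).
#' @return 4 x 3 numeric matrix.
#' @export
default_mic_positions <- function(radius = 2, height = 0.9) {
  ang <- c(90, 210, 330) * pi / 180
  rbind(
    c(0, 0, height),
    cbind(radius * cos(ang), radius * sin(ang), height)
  )
}

#' Speed of sound in dry air
#'
#' `c = 331.3 * sqrt(1 + T / 273.15)` m/s with `T` in degrees Celsius.
#'
#' @param temp_c air temperature (Celsius).
#' @return speed of sound (m/s).
#' @export
speed_of_sound_air <- function(temp_c) {
  331.3 * sqrt(1 + temp_c / 273.15)
}

#' @export
print.scene_geometry <- function(x, ...) {
  cat("<scene_geometry>\n")
  cat("  microphones (m):\n")
  print(round(x$mic_positions, 3))
  cat(sprintf("  light at (%.2f, %.2f, %.2f) m\n",
              x$light_position[1], x$light_position[2], x$light_position[3]))
  cat(sprintf("  forest edge: %.2f x + %.2f y + %.2f z > %.2f is inside\n",
              x$edge_normal[1], x$edge_normal[2], x$edge_normal[3], x$edge_offset))
  cat(sprintf("  speed of sound: %.2f m/s\n", x$speed_of_sound))
  invisible(x)
}

#' Distance from positions to the light
#'
#' Euclidean distance between each 3D position and the light. With the
#' default geometry (light at `(4, 4, 4)`) this is
#' `sqrt((x-4)^2 + (y-4)^2 + (z-4)^2)`: 4 m is subtracted from each axis
#' because the light stands on the forest edge, 4 m from the central
#' microphone, at 4 m height.
#'
#' @param x,y,z numeric vectors of coordinates (m), or `x` may be a data
#'   frame with columns `x`, `y`, `z`.
#' @param geometry a [scene_geometry()].
#' @return numeric vector of distances (m).
#' @examples
#' distance_to_light(7, 8, 4)  # 5
#' @export
distance_to_light <- function(x, y = NULL, z = NULL, geometry = scene_geometry()) {
  if (is.data.frame(x)) {
    y <- x$y; z <- x$z; x <- x$x
  }
  L <- geometry$light_position
  sqrt((x - L[1])^2 + (y - L[2])^2 + (z - L[3])^2)
}

#' Label positions as inside the forest or in the open
#'
#' The binary response of the flight-path models: 1 when the position lies
#' on the forest side of the oriented edge plane, 0 in the open. A position
#' exactly on the plane is labelled open (0); the tie is measure-zero and
#' the rule keeps labelling deterministic.
#'
#' @inheritParams distance_to_light
#' @return integer vector of 0/1 labels.
#' @examples
#' label_pfif(0, 10, 2)  # 1: inside the forest
#' label_pfif(0, 0, 2)   # 0: open habitat
#' @export
label_pfif <- function(x, y = NULL, z = NULL, geometry = scene_geometry()) {
  if (is.data.frame(x)) {
    y <- x$y; z <- x$z; x <- x$x
  }
  n <- geometry$edge_normal
  as.integer(x * n[1] + y * n[2] + z * n[3] > geometry$edge_offset)
}

#' Assign vertical and horizontal zones around the light
#'
#' Stratifies positions relative to the light: vertically `"under"`
#' (`z < 4` m) versus `"above"`, and horizontally `"back"` (`x > 4` m,
#' behind the light as seen from the array) versus `"front"` (`x < 4` m).
#' Boundary ties (`z = 4`, `x = 4`) go to `"above"` and `"front"`.
#'
#' @inheritParams distance_to_light
#' @return data frame with character columns `zone_vertical` and
#'   `zone_horizontal`.
#' @examples
#' assign_zones(2, 5, 3.9)  # under / front
#' @export
assign_zones <- function(x, y = NULL, z = NULL, geometry = scene_geometry()) {
  if (is.data.frame(x)) {
    y <- x$y; z <- x$z; x <- x$x
  }
  L <- geometry$light_position
  tibble::tibble(
    zone_vertical = ifelse(z < L[3], "under", "above"),
    zone_horizontal = ifelse(x > L[1], "back", "front")
  )
}

#' Attach distance, habitat label and zones to localized positions
#'
#' Adds to a position table the distance to the light `D`, the inside-forest
#' label `pfif`, the vertical/horizontal zones, and the precision weight
#' `weight = 1/I^2` when an imprecision column `I` is present.
#'
#' @param positions data frame with columns `x`, `y`, `z` (m) and optionally
#'   `I` (m).
#' @param geometry a [scene_geometry()].
#' @return the input with columns `D`, `pfif`, `zone_vertical`,
#'   `zone_horizontal` (and `weight`) added.
#' @export
label_positions <- function(positions, geometry = scene_geometry()) {
  stopifnot(all(c("x", "y", "z") %in% names(positions)))
  positions$D <- distance_to_light(positions, geometry = geometry)
  positions$pfif <- label_pfif(positions, geometry = geometry)
  zones <- assign_zones(positions, geometry = geometry)
  positions$zone_vertical <- zones$zone_vertical
  positions$zone_horizontal <- zones$zone_horizontal
  if ("I" %in% names(positions)) positions$weight <- precision_weight(positions$I)
  tibble::as_tibble(positions)
}
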