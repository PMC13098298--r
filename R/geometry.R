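# Default tracked skeleton: 13 nodes — nose, both ears, neck, four paws, tail
# base, the catheter implant (locomotion anchor), both levers and the active
# lever's cue light.
pose_nodes <- function() {
  c("nose", "ear_left", "ear_right", "neck",
    "paw_front_left", "paw_front_right", "paw_back_left", "paw_back_right",
    "base", "catheter", "lever_active", "lever_inactive", "cue_light")
}

# Rigid offsets (px) of secondary body nodes relative to the catheter anchor.
body_node_offsets <- function() {
  list(
    ear_left       = c(14, -7),
    ear_right      = c(14, 7),
    neck           = c(10, 0),
    paw_front_left = c(8, -9),
    paw_front_right = c(8, 9),
    paw_back_left  = c(-8, -9),
    paw_back_right = c(-8, 9),
    base           = c(-14, 0)
  )
}

#' Chamber geometry and camera calibration defaults
#'
#' Describes the operant chamber as seen by the overhead camera: pixel extent
#' of the floor area the animal can occupy, the pixel-to-centimeter
#' conversion factor, the camera frame rate, and the fixed pixel positions of
#' the two levers and the cue light. Defaults describe a 30 x 25 cm chamber
#' imaged at about 0.111 cm/px and 10 frames per second, with the levers on
#' one wall 150 px apart.
#'
#' @param chamber_px Chamber extent in pixels, `c(width, height)`.
#' @param cm_per_px Conversion factor (cm per pixel).
#' @param frame_rate Camera frame rate (frames per second).
#' @param lever_active_px,lever_inactive_px,cue_light_px Fixed node positions.
#' @return A list of class `chamber_geometry`.
#' @export
default_geometry <- function(chamber_px = c(width = 270, height = 225),
                             cm_per_px = 0.111,
                             frame_rate = 10,
                             lever_active_px = c(60, 200),
                             lever_inactive_px = c(210, 200),
                             cue_light_px = c(60, 178)) {
  stopifnot(length(chamber_px) == 2L, all(chamber_px > 0),
            cm_per_px > 0, frame_rate > 0)
  structure(
    list(chamber_px = unname(chamber_px), cm_per_px = cm_per_px,
         frame_rate = frame_rate,
         lever_px = list(active = unname(lever_active_px),
                         inactive = unname(lever_inactive_px)),
         cue_light_px = unname(cue_light_px)),
    class = "chamber_geometry"
  )
}

# Fold coordinates into [lower, upper] by repeated reflection at the walls
# (the tent map). Reflection, unlike clamping, preserves a uniform occupancy
# density, which the zone-occupancy calibration of the simulator relies on.
fold_into <- function(x, lower, upper) {
  span <- upper - lower
  y <- (x - lower) %% (2 * span)
  lower + ifelse(y > span, 2 * span - y, y)
}
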