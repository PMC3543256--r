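# shared fixtures: everything is generated in code at test time

default_screen <- screen_geometry()

# a frame built directly from a pixel matrix
raw_frame <- function(px, index = 0L) {
  structure(list(pixels = px, width_px = ncol(px), height_px = nrow(px),
                 index = as.integer(index)), class = "eye_frame")
}

uniform_frame <- function(level, w = 64, h = 48) raw_frame(matrix(level, h, w))

# small, fast scene for image-level tests (pupil radius 12 in a 200x150 frame)
small_scene <- function(pupil_center = c(90, 80), seed = 1L, ...) {
  scene_params(image_width_px = 200, image_height_px = 150,
               pupil_center = pupil_center, pupil_radius_px = 12,
               iris_radius_px = 32,
               glint_centers = rbind(c(78, 88), c(102, 88), c(90, 67.2)),
               seed = seed, ...)
}

small_detector <- function(...) {
  detector_config(r_min = 8, r_max = 20, ...)
}

# glint candidate at a position, for validator tests
cand <- function(x, y) {
  structure(list(centroid = c(x, y), area_px = 9L, mass = 2000),
            class = "glint_candidate")
}

# quick training config for tests that only need a converged small fit
quick_train <- function(...) train_config(epochs = 200, ...)
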