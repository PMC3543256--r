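#' Detector configuration
#'
#' Tuning constants for the image-processing chain. Thresholds are set once
#' per indoor session and left unchanged, so they are plain configuration
#' constants here. The triangle validator accepts a glint triple only when
#' the directions of the three sides match 0, 60 and 120 degrees within
#' `angle_tol_deg` and every side length falls inside `side_range`.
#'
#' @param pupil_threshold Intensity below which a pixel is pupil candidate
#'   (dark-pupil binarisation).
#' @param glint_threshold Intensity above which a pixel is glint candidate.
#' @param r_min,r_max Pupil radius search range (px), `0 < r_min < r_max`.
#' @param hough_accumulator_step Centre grid step of the circle-Hough
#'   accumulator (px).
#' @param roi_scale When a previous pupil detection is available the frame
#'   is processed only inside a rectangle of half-width
#'   `roi_scale * previous radius` centred on the previous centre.
#' @param angle_tol_deg Tolerance on the three side directions, in (0, 30).
#' @param side_range Numeric `(L_min, L_max)` admissible side lengths (px).
#' @param min_blob_area Minimum pixel count of a glint blob.
#' @param min_support_frac Minimum Hough peak support for a pupil
#'   detection, as a fraction of the candidate circle's perimeter.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(pupil_threshold = 60, glint_threshold = 200,
                            r_min = 20, r_max = 60,
                            hough_accumulator_step = 1, roi_scale = 4,
                            angle_tol_deg = 10, side_range = c(8, 60),
                            min_blob_area = 5, min_support_frac = 0.15) {
  stopifnot(r_min > 0, r_min < r_max, angle_tol_deg > 0, angle_tol_deg < 30,
            side_range[1] < side_range[2], hough_accumulator_step > 0,
            roi_scale > 0, min_blob_area >= 1,
            min_support_frac > 0, min_support_frac < 1,
            pupil_threshold >= 0, pupil_threshold <= 255,
            glint_threshold >= 0, glint_threshold <= 255)
  structure(list(pupil_threshold = pupil_threshold,
                 glint_threshold = glint_threshold,
                 r_min = r_min, r_max = r_max,
                 hough_accumulator_step = hough_accumulator_step,
                 roi_scale = roi_scale, angle_tol_deg = angle_tol_deg,
                 side_range = side_range, min_blob_area = min_blob_area,
                 min_support_frac = min_support_frac),
            class = "detector_config")
}

# frame rejection marker carrying the failing stage (pupil|glints|triangle)
rejection <- function(stage) {
  structure(list(stage = stage), class = "frame_rejection")
}

#' Test for a rejected frame
#' @param x Any object.
#' @return `TRUE` if `x` marks a rejected frame.
#' @export
is_rejection <- function(x) inherits(x, "frame_rejection")

#' Threshold a frame into a binary mask
#'
#' Dark polarity marks pixels strictly below the threshold (used for the
#' dark pupil), bright polarity pixels strictly above it (used for the
#' glints).
#'
#' @param frame An `eye_frame`.
#' @param threshold Intensity threshold in `[0, 255]`.
#' @param polarity `"dark"` or `"bright"`.
#' @return Logical matrix with the frame's dimensions.
#' @export
binarize <- function(frame, threshold, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  stopifnot(threshold >= 0, threshold <= 255)
  if (polarity == "dark") frame$pixels < threshold else frame$pixels > threshold
}

# boundary of a binary mask: true pixels with at least one false or
# out-of-image 4-neighbour
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  interior <- matrix(FALSE, h, w)
  if (h > 2 && w > 2) {
    interior[2:(h - 1), 2:(w - 1)] <-
      mask[1:(h - 2), 2:(w - 1)] & mask[3:h, 2:(w - 1)] &
      mask[2:(h - 1), 1:(w - 2)] & mask[2:(h - 1), 3:w]
  }
  mask & !interior
}

# circle-Hough over the boundary pixels of a dark mask; returns the refined
# centre, radius and peak support, or NULL when no sufficient peak exists
hough_circle_detect <- function(mask, cfg) {
  bnd <- which(mask_boundary(mask))
  if (length(bnd) == 0) return(NULL)
  h <- nrow(mask)
  ye <- ((bnd - 1) %% h) + 1
  xe <- ((bnd - 1) %/% h) + 1
  step <- cfg$hough_accumulator_step
  radii <- seq(ceiling(cfg$r_min), floor(cfg$r_max), by = 1)
  # accumulator window: bounding box of possible centres
  gx0 <- floor((min(xe) - cfg$r_max) / step); gx1 <- ceiling((max(xe) + cfg$r_max) / step)
  gy0 <- floor((min(ye) - cfg$r_max) / step); gy1 <- ceiling((max(ye) + cfg$r_max) / step)
  nx <- gx1 - gx0 + 1; ny <- gy1 - gy0 + 1
  best <- list(votes = -Inf)
  peak_by_r <- numeric(length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    nang <- max(60L, ceiling(2 * pi * r))
    th <- seq(0, 2 * pi, length.out = nang + 1)[-(nang + 1)]
    cx <- round((rep(xe, each = nang) - r * cos(th)) / step) - gx0 + 1
    cy <- round((rep(ye, each = nang) - r * sin(th)) / step) - gy0 + 1
    ok <- cx >= 1 & cx <= nx & cy >= 1 & cy <= ny
    idx <- cx[ok] + (cy[ok] - 1) * nx
    acc <- tabulate(idx, nbins = nx * ny)
    # each boundary pixel may vote several times per cell at dense angular
    # sampling; normalise to "distinct pixels" scale
    acc <- acc / (nang / (2 * pi * r / step))
    pk <- which.max(acc)
    peak_by_r[k] <- acc[pk]
    if (acc[pk] > best$votes) {
      best <- list(votes = acc[pk], r = r, acc = acc, peak = pk)
    }
  }
  if (!is.finite(best$votes) ||
      best$votes < cfg$min_support_frac * 2 * pi * best$r / step) return(NULL)
  # subpixel centre: vote-weighted centroid of the supra-threshold
  # neighbourhood around the peak cell at the winning radius
  px <- ((best$peak - 1) %% nx) + 1
  py <- ((best$peak - 1) %/% nx) + 1
  nb <- expand.grid(dx = -2:2, dy = -2:2)
  nbx <- px + nb$dx; nby <- py + nb$dy
  keep <- nbx >= 1 & nbx <= nx & nby >= 1 & nby <= ny
  nbx <- nbx[keep]; nby <- nby[keep]
  v <- best$acc[nbx + (nby - 1) * nx]
  use <- v >= 0.5 * best$votes
  cx <- sum((nbx[use] + gx0 - 1) * v[use]) / sum(v[use]) * step
  cy <- sum((nby[use] + gy0 - 1) * v[use]) / sum(v[use]) * step
  # radius: support-weighted mean over radii with near-peak support
  ruse <- peak_by_r >= 0.75 * best$votes
  rad <- sum(radii[ruse] * peak_by_r[ruse]) / sum(peak_by_r[ruse])
  list(center = c(cx, cy), radius_px = rad, score = best$votes)
}

#' Detect the pupil centre by binary thresholding and a circle Hough transform
#'
#' The frame is thresholded with dark polarity, the boundary pixels of the
#' resulting mask vote in a circle-Hough accumulator over candidate centres
#' and radii in `[r_min, r_max]`, and the global maximum is refined to
#' subpixel precision by a vote-weighted centroid of the accumulator
#' neighbourhood. Only the centre matters downstream, not the true pupil
#' shape. When a previous detection is supplied, processing is restricted
#' to a rectangular region of interest around it (half-width
#' `roi_scale * previous radius`); if nothing is found inside the ROI the
#' full frame is retried before giving up.
#'
#' @param frame An `eye_frame`.
#' @param cfg A [detector_config()].
#' @param prev Optional previous `pupil_detection` for ROI tracking.
#' @return A `pupil_detection` (fields `center`, `radius_px`, `score`) or
#'   `NULL` when no circle with sufficient support exists.
#' @export
detect_pupil <- function(frame, cfg = detector_config(), prev = NULL) {
  stopifnot(inherits(cfg, "detector_config"))
  mask <- binarize(frame, cfg$pupil_threshold, "dark")
  run <- function(m, ox, oy) {
    res <- hough_circle_detect(m, cfg)
    if (is.null(res)) return(NULL)
    res$center <- res$center + c(ox, oy)
    res
  }
  if (!is.null(prev)) {
    half <- cfg$roi_scale * prev$radius_px
    x0 <- max(1L, floor(prev$center[1] - half))
    x1 <- min(frame$width_px, ceiling(prev$center[1] + half))
    y0 <- max(1L, floor(prev$center[2] - half))
    y1 <- min(frame$height_px, ceiling(prev$center[2] + half))
    if (x1 > x0 && y1 > y0) {
      res <- run(mask[y0:y1, x0:x1, drop = FALSE], x0 - 1, y0 - 1)
      if (!is.null(res)) return(as_pupil_detection(res))
    }
  }
  res <- run(mask, 0, 0)
  if (is.null(res)) return(NULL)
  as_pupil_detection(res)
}

as_pupil_detection <- function(x) {
  structure(x, class = "pupil_detection")
}

# sparse 8-connected component labelling of a logical mask; returns a list
# of integer index vectors (matrix indices), one per component
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0) return(list())
  visited <- logical(h * w)
  comps <- list()
  dy <- rep(c(-1L, 0L, 1L), times = 3)[-5]   # 8 neighbour offsets
  dx <- rep(c(-1L, 0L, 1L), each = 3)[-5]
  for (s in fg) {
    if (visited[s]) next
    queue <- s; visited[s] <- TRUE; members <- integer(0)
    while (length(queue) > 0) {
      cur <- queue
      members <- c(members, cur)
      y <- ((cur - 1L) %% h) + 1L
      x <- ((cur - 1L) %/% h) + 1L
      ny <- rep(y, each = 8L) + dy
      nx <- rep(x, each = 8L) + dx
      ok <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
      nbr <- unique(ny[ok] + (nx[ok] - 1L) * h)
      nbr <- nbr[mask[nbr] & !visited[nbr]]
      visited[nbr] <- TRUE
      queue <- nbr
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Intensity-weighted blob centroid
#'
#' Weighted mean position of a set of pixels,
#' `c = sum(p * w(p)) / sum(w(p))` with `w(p) = I(p) - offset`. With
#' `offset = 0` this is the plain centre of mass; subtracting the detection
#' threshold removes the background pedestal and makes the centroid of a
#' thresholded Gaussian spot accurate to a few hundredths of a pixel.
#'
#' @param x,y Pixel coordinates.
#' @param intensity Pixel intensities.
#' @param offset Weight offset, usually the detection threshold.
#' @return Numeric `(x, y)` centroid.
#' @export
blob_centroid <- function(x, y, intensity, offset = 0) {
  w <- intensity - offset
  stopifnot(all(w >= 0), sum(w) > 0)
  c(sum(x * w), sum(y * w)) / sum(w)
}

#' Detect glint candidate blobs
#'
#' Bright-polarity thresholding followed by 8-connected component
#' labelling; components of at least `min_blob_area` pixels are returned
#' with their background-corrected intensity-weighted centroid (subpixel),
#' pixel area and summed intensity.
#'
#' @param frame An `eye_frame`.
#' @param cfg A [detector_config()].
#' @return A list of `glint_candidate` objects (fields `centroid`,
#'   `area_px`, `mass`); possibly empty.
#' @export
detect_glint_candidates <- function(frame, cfg = detector_config()) {
  mask <- binarize(frame, cfg$glint_threshold, "bright")
  comps <- label_components8(mask)
  out <- list()
  h <- frame$height_px
  for (m in comps) {
    if (length(m) < cfg$min_blob_area) next
    ys <- ((m - 1) %% h) + 1
    xs <- ((m - 1) %/% h) + 1
    ints <- frame$pixels[m]
    ctr <- blob_centroid(xs, ys, ints, offset = cfg$glint_threshold)
    out[[length(out) + 1L]] <- structure(
      list(centroid = ctr, area_px = length(m), mass = sum(ints)),
      class = "glint_candidate")
  }
  out
}

# fold a segment direction to [0, 180) degrees
fold_direction <- function(dx, dy) {
  (atan2(dy, dx) * 180 / pi) %% 180
}

# distance between two line directions on the half-circle
line_angle_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Validate a three-glint triangle among candidate blobs
#'
#' Searches all 3-subsets of the candidates for one forming the expected
#' triangular pattern: the directions of the three joining lines must match
#' 0, 60 and 120 degrees each within `angle_tol_deg` (directions are folded
#' to `[0, 180)` since glint pairs are unordered lines), and every side
#' length must lie within `side_range`. Frames without such a subset are
#' discarded; this simple test is very effective at rejecting spurious
#' reflections. When several subsets pass, the one with the smallest total
#' angular deviation wins. The returned glints are canonically ordered: the
#' two endpoints of the near-horizontal side left to right, then the apex.
#'
#' @param candidates List of `glint_candidate` objects.
#' @param cfg A [detector_config()].
#' @return A `glint_triple` (fields `glints` 3x2 matrix, `side_directions`,
#'   `side_lengths`, `deviation_deg`) or a rejection marker; see
#'   [is_rejection()].
#' @export
validate_triangle <- function(candidates, cfg = detector_config()) {
  if (length(candidates) < 3) return(rejection("triangle"))
  pts <- t(vapply(candidates, function(g) g$centroid, numeric(2)))
  subsets <- utils::combn(length(candidates), 3)
  targets <- c(0, 60, 120)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  best <- NULL
  for (j in seq_len(ncol(subsets))) {
    id <- subsets[, j]
    p <- pts[id, , drop = FALSE]
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    dx <- p[pairs[, 2], 1] - p[pairs[, 1], 1]
    dy <- p[pairs[, 2], 2] - p[pairs[, 1], 2]
    len <- sqrt(dx^2 + dy^2)
    if (any(len < cfg$side_range[1]) || any(len > cfg$side_range[2])) next
    ang <- fold_direction(dx, dy)
    dev_best <- Inf; assign_best <- NULL
    for (pp in perms) {
      d <- line_angle_dist(ang, targets[pp])
      if (all(d <= cfg$angle_tol_deg)) {
        if (sum(d) < dev_best) { dev_best <- sum(d); assign_best <- pp }
      }
    }
    if (is.null(assign_best)) next
    if (is.null(best) || dev_best < best$deviation_deg) {
      base_side <- which(targets[assign_best] == 0)
      base_pts <- pairs[base_side, ]
      apex <- setdiff(1:3, base_pts)
      # left endpoint of the near-horizontal side first
      if (p[base_pts[1], 1] > p[base_pts[2], 1] ||
          (p[base_pts[1], 1] == p[base_pts[2], 1] &&
           p[base_pts[1], 2] > p[base_pts[2], 2]))
        base_pts <- rev(base_pts)
      ord <- c(base_pts, apex)
      best <- structure(list(
        glints = p[ord, , drop = FALSE],
        candidate_idx = id[ord],
        side_directions = ang,
        side_lengths = len,
        deviation_deg = dev_best), class = "glint_triple")
    }
  }
  if (is.null(best)) return(rejection("triangle"))
  best
}

#' Extract the eye-feature vector from one frame
#'
#' Composes the full detection chain: pupil detection, glint candidate
#' detection and triangle validation. A failure at any stage rejects the
#' frame with a stage tag (`"pupil"`, `"glints"` or `"triangle"`); rejected
#' frames are skipped downstream, never fatal.
#'
#' @param frame An `eye_frame`.
#' @param cfg A [detector_config()].
#' @param prev Optional previous `pupil_detection` for ROI tracking.
#' @return An `eye_features` object (fields `pupil`, `triple`, `vector`:
#'   the named 8-vector pupil x,y then glints 1-3 x,y in canonical order)
#'   or a rejection marker.
#' @export
extract_features <- function(frame, cfg = detector_config(), prev = NULL) {
  pupil <- detect_pupil(frame, cfg, prev)
  if (is.null(pupil)) return(rejection("pupil"))
  cands <- detect_glint_candidates(frame, cfg)
  if (length(cands) == 0) return(rejection("glints"))
  triple <- validate_triangle(cands, cfg)
  if (is_rejection(triple)) return(triple)
  vec <- c(pupil$center, t(triple$glints))
  names(vec) <- feature_names()
  structure(list(pupil = pupil, triple = triple, vector = vec),
            class = "eye_features")
}
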