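# Stimulus registry, morph timeline, screen/ROI geometry and pixel <-> degree
# conversion. Coordinates are stimulus pixel space: origin top-left, y downward,
# 0-based, polygon boundaries closed.

#' Canonical expression labels
#'
#' The six basic emotion categories, in the column/row order used throughout
#' the package (confusion matrices, registries, report tables).
#'
#' @return Character vector of six labels.
#' @export
expression_labels <- function() {
  c("happiness", "surprise", "anger", "sadness", "disgust", "fear")
}

#' Canonical region-of-interest labels
#'
#' @param with_other If `TRUE`, append `"other"` (face area outside the three
#'   regions, i.e. forehead/chin/background).
#' @return Character vector.
#' @export
roi_labels <- function(with_other = FALSE) {
  out <- c("eyes", "nose", "mouth")
  if (with_other) out <- c(out, "other")
  out
}

#' Screen geometry
#'
#' Physical description of the display used to convert gaze pixel coordinates
#' into visual angle. Horizontal and vertical pixel pitch are derived
#' independently, so non-square pixels are supported.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param width_cm,height_cm Physical display size in cm.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px, height_px, width_cm, height_cm,
                            viewing_distance_cm) {
  vals <- c(width_px = width_px, height_px = height_px, width_cm = width_cm,
            height_cm = height_cm, viewing_distance_cm = viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen geometry parameters must be positive and finite",
         call. = FALSE)
  }
  structure(as.list(vals), class = "screen_geometry")
}

#' Default screen geometry
#'
#' A 22-inch 1680 x 1050 display (47.4 x 29.6 cm) viewed at 80 cm, typical of
#' remote-eyetracker setups for face-viewing experiments.
#'
#' @return A `screen_geometry` object.
#' @export
default_screen_geometry <- function() {
  screen_geometry(1680L, 1050L, 47.4, 29.6, 80)
}

#' Degrees of visual angle per pixel
#'
#' Per-pixel angular subtense via the arctangent of physical pixel size over
#' viewing distance. Horizontal and vertical values may differ when pixels are
#' not square.
#'
#' @param screen A [screen_geometry()] object.
#' @return Named numeric vector `c(horizontal =, vertical =)`, deg/px.
#' @export
degrees_per_pixel <- function(screen) {
  stopifnot(inherits(screen, "screen_geometry"))
  if (screen$viewing_distance_cm <= 0) {
    stop("viewing distance must be positive", call. = FALSE)
  }
  px_w <- screen$width_cm / screen$width_px
  px_h <- screen$height_cm / screen$height_px
  c(horizontal = atan(px_w / screen$viewing_distance_cm) * 180 / pi,
    vertical   = atan(px_h / screen$viewing_distance_cm) * 180 / pi)
}

#' Morph timeline of a dynamic expression clip
#'
#' Frame onsets for a neutral-to-apex morph sequence played at a fixed frame
#' rate. Total clip duration is rounded to the nearest millisecond, so 31
#' frames at 30 fps give a 1,033-ms clip.
#'
#' @param n_frames Number of frames (>= 1).
#' @param fps Frame rate in frames per second.
#' @return A list of class `morph_timeline` with `n_frames`,
#'   `frame_duration_ms`, `onsets_ms` and `total_ms`.
#' @examples
#' morph_timeline(31, 30)$total_ms  # 1033
#' @export
morph_timeline <- function(n_frames = 31L, fps = 30) {
  if (!is.finite(n_frames) || n_frames < 1 || n_frames != round(n_frames)) {
    stop("n_frames must be a positive integer", call. = FALSE)
  }
  if (!is.finite(fps) || fps <= 0) {
    stop("fps must be positive", call. = FALSE)
  }
  frame_ms <- 1000 / fps
  structure(list(
    n_frames = as.integer(n_frames),
    frame_duration_ms = frame_ms,
    onsets_ms = (seq_len(n_frames) - 1) * frame_ms,
    total_ms = round(n_frames * frame_ms)
  ), class = "morph_timeline")
}

#' Stimulus registry
#'
#' One entry per model x expression. With the default 40 models and six basic
#' expressions this yields the full 240-clip stimulus set; models are split
#' evenly into female (first half) and male (second half) posers.
#'
#' @param n_models Number of face models (>= 1).
#' @param expressions Unique expression labels.
#' @param clip_duration_ms Clip duration applied to every entry.
#' @return data.frame with columns `stimulus_id`, `model_id`, `sex`,
#'   `expression`, `clip_duration_ms`.
#' @export
stimulus_registry <- function(n_models = 40L,
                              expressions = expression_labels(),
                              clip_duration_ms = 1033) {
  if (!is.finite(n_models) || n_models < 1) {
    stop("n_models must be >= 1", call. = FALSE)
  }
  if (length(expressions) == 0) {
    stop("expressions must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(expressions)) {
    stop("expression labels must be unique", call. = FALSE)
  }
  n_models <- as.integer(n_models)
  grid <- expand.grid(expression = expressions, model_id = seq_len(n_models),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$model_id), c("model_id", "expression")]
  sex <- ifelse(grid$model_id <= ceiling(n_models / 2), "female", "male")
  out <- data.frame(
    stimulus_id = sprintf("M%02d_%s", grid$model_id, grid$expression),
    model_id = grid$model_id,
    sex = sex,
    expression = grid$expression,
    clip_duration_ms = clip_duration_ms,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Region of interest
#'
#' @param label One of `"eyes"`, `"nose"`, `"mouth"`.
#' @param x,y Polygon vertex coordinates (ordered, >= 3 vertices, simple).
#' @return Object of class `roi`.
#' @export
roi <- function(label, x, y) {
  if (!label %in% roi_labels()) {
    stop("roi label must be one of: ", paste(roi_labels(), collapse = ", "),
         call. = FALSE)
  }
  if (length(x) != length(y) || length(x) < 3) {
    stop("polygon needs >= 3 vertices with matching x/y", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("polygon vertices must be finite", call. = FALSE)
  }
  structure(list(label = label, x = as.numeric(x), y = as.numeric(y)),
            class = "roi")
}

# Shoelace area (absolute).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Default three-region ROI layout
#'
#' Horizontal bands, as fractions of the face bounding box height: an eye/
#' eyebrow band in the upper-middle face, a nose/cheek band in the middle and
#' a mouth band in the lower face. The forehead (above the eye band) and the
#' chin (below the mouth band) are deliberately left uncovered.
#'
#' @return Named list of band fractions used by [build_default_rois()].
#' @export
default_roi_layout <- function() {
  list(eyes  = c(top = 0.20, bottom = 0.42),
       nose  = c(top = 0.44, bottom = 0.66),
       mouth = c(top = 0.68, bottom = 0.88),
       left = 0.10, right = 0.90)
}

#' Build the default rectangular ROI set
#'
#' Constructs three mutually non-overlapping band polygons inside a face
#' bounding box, parameterized by height fractions.
#'
#' @param face_box Named numeric `c(x =, y =, width =, height =)`: the face
#'   bounding box in stimulus pixels (origin top-left).
#' @param layout Band fractions; see [default_roi_layout()].
#' @return List of three `roi` objects named `eyes`, `nose`, `mouth`.
#' @export
build_default_rois <- function(face_box, layout = default_roi_layout()) {
  need <- c("x", "y", "width", "height")
  if (!all(need %in% names(face_box))) {
    stop("face_box needs named elements x, y, width, height", call. = FALSE)
  }
  if (face_box[["width"]] <= 0 || face_box[["height"]] <= 0) {
    stop("face_box must have positive width and height", call. = FALSE)
  }
  fr <- c(layout$eyes, layout$nose, layout$mouth, layout$left, layout$right)
  if (any(fr < 0 | fr > 1)) {
    stop("layout fractions must lie in [0, 1]", call. = FALSE)
  }
  if (layout$left >= layout$right) {
    stop("layout left fraction must be below right fraction", call. = FALSE)
  }
  bands <- list(eyes = layout$eyes, nose = layout$nose, mouth = layout$mouth)
  tops <- vapply(bands, `[[`, numeric(1), "top")
  bottoms <- vapply(bands, `[[`, numeric(1), "bottom")
  if (any(bottoms <= tops)) {
    stop("each band must have bottom fraction > top fraction", call. = FALSE)
  }
  ord <- order(tops)
  if (any(bottoms[ord][-3] > tops[ord][-1])) {
    stop("ROI bands overlap vertically", call. = FALSE)
  }
  x0 <- face_box[["x"]] + layout$left * face_box[["width"]]
  x1 <- face_box[["x"]] + layout$right * face_box[["width"]]
  mk <- function(label, band) {
    y0 <- face_box[["y"]] + band[["top"]] * face_box[["height"]]
    y1 <- face_box[["y"]] + band[["bottom"]] * face_box[["height"]]
    roi(label, x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  list(eyes = mk("eyes", bands$eyes),
       nose = mk("nose", bands$nose),
       mouth = mk("mouth", bands$mouth))
}

#' Face bounding box subtending a given visual angle
#'
#' Centers a box on the screen whose width and height subtend the requested
#' angles at the configured viewing distance.
#'
#' @param screen A [screen_geometry()] object.
#' @param width_deg,height_deg Target angular size of the face.
#' @return Named numeric `c(x =, y =, width =, height =)` in pixels.
#' @export
face_box_for_angle <- function(screen, width_deg = 8.8, height_deg = 11.6) {
  stopifnot(inherits(screen, "screen_geometry"))
  d <- screen$viewing_distance_cm
  w_cm <- 2 * d * tan(width_deg / 2 * pi / 180)
  h_cm <- 2 * d * tan(height_deg / 2 * pi / 180)
  w_px <- w_cm / (screen$width_cm / screen$width_px)
  h_px <- h_cm / (screen$height_cm / screen$height_px)
  c(x = (screen$width_px - w_px) / 2, y = (screen$height_px - h_px) / 2,
    width = w_px, height = h_px)
}

# Point-on-segment test with tolerance eps (pixels).
on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-9) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  seg2 <- (x2 - x1)^2 + (y2 - y1)^2
  if (abs(cross) > eps * max(1, sqrt(seg2))) return(FALSE)
  dot <- (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)
  dot >= -eps && dot <= seg2 + eps
}

#' Point-in-polygon test (closed boundary)
#'
#' Even-odd ray casting; points on the boundary count as inside.
#'
#' @param px,py Point coordinates.
#' @param poly An `roi` object or a list with `x`, `y` vertex vectors.
#' @return Logical.
#' @export
point_in_polygon <- function(px, py, poly) {
  xs <- poly$x; ys <- poly$y
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (on_segment(px, py, xs[i], ys[i], xs[j], ys[j])) return(TRUE)
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Assign a gaze point to a region of interest
#'
#' Points inside no region map to `"other"` (forehead, chin, background).
#' Should overlapping regions both contain the point, the fixed priority
#' eyes > mouth > nose resolves the tie; with the default non-overlapping
#' layout the assignment is unique.
#'
#' @param px,py Point coordinates in stimulus pixels.
#' @param rois List of `roi` objects.
#' @return A single label: `"eyes"`, `"nose"`, `"mouth"` or `"other"`.
#' @export
assign_roi <- function(px, py, rois) {
  if (!is.finite(px) || !is.finite(py)) return("other")
  labels <- vapply(rois, `[[`, character(1), "label")
  for (lab in c("eyes", "mouth", "nose")) {
    k <- which(labels == lab)
    if (length(k) && point_in_polygon(px, py, rois[[k[1]]])) return(lab)
  }
  "other"
}

#' Vectorized ROI assignment
#'
#' @param x,y Coordinate vectors of equal length.
#' @param rois List of `roi` objects.
#' @return Character vector of labels.
#' @export
assign_roi_points <- function(x, y, rois) {
  stopifnot(length(x) == length(y))
  out <- rep("other", length(x))
  labels <- vapply(rois, `[[`, character(1), "label")
  # priority applied by writing lowest-priority regions first
  for (lab in c("nose", "mouth", "eyes")) {
    k <- which(labels == lab)
    if (!length(k)) next
    poly <- rois[[k[1]]]
    hit <- in_polygon_vec(x, y, poly$x, poly$y)
    out[hit] <- lab
  }
  out[!is.finite(x) | !is.finite(y)] <- "other"
  out
}

# Vectorized even-odd test over points; boundary points included via a
# half-open crossing rule plus an explicit edge pass for axis-aligned edges.
in_polygon_vec <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  # boundary: treat points on any edge as inside
  j <- n
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    seg2 <- (xj - xi)^2 + (yj - yi)^2
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    dot <- (px - xi) * (xj - xi) + (py - yi) * (yj - yi)
    on_edge <- on_edge |
      (abs(cross) <= 1e-9 * max(1, sqrt(seg2)) & dot >= -1e-9 & dot <= seg2 + 1e-9)
    j <- i
  }
  inside | on_edge
}

#' Polygon centroid
#'
#' @param poly An `roi` or list with `x`, `y`.
#' @return Numeric `c(x, y)`.
#' @export
polygon_centroid <- function(poly) {
  c(x = mean(poly$x), y = mean(poly$y))
}
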