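#' Marker specification
#'
#' Describes the fiducial square used to calibrate a view: its known physical
#' side length, its measured size in pixels, and a confidence score for the
#' marker detection.
#'
#' @param physical_size_mm Side length of the square marker in millimetres.
#' @param pixel_size_px Measured side length of the marker in pixels.
#' @param confidence Detection confidence in `[0, 1]`.
#' @return An object of class `marker_spec`.
#' @export
marker_spec <- function(physical_size_mm, pixel_size_px, confidence = 1) {
  stopifnot(is.numeric(physical_size_mm), length(physical_size_mm) == 1L,
            is.numeric(pixel_size_px), length(pixel_size_px) == 1L,
            is.numeric(confidence), length(confidence) == 1L)
  if (!is.finite(physical_size_mm) || physical_size_mm <= 0)
    stop("marker physical size must be a positive length (mm)", call. = FALSE)
  if (!is.finite(pixel_size_px) || pixel_size_px <= 0)
    stop("calibration error: marker pixel size must be positive", call. = FALSE)
  if (!is.finite(confidence) || confidence < 0 || confidence > 1)
    stop("marker confidence must lie in [0, 1]", call. = FALSE)
  structure(list(physical_size_mm = physical_size_mm,
                 pixel_size_px = pixel_size_px,
                 confidence = confidence),
            class = "marker_spec")
}

#' Per-frame scale factor from a fiducial marker
#'
#' The marker of known physical size converts pixels into millimetres:
#' `alpha = M_mm / M_px` (mm per pixel). Each view carries its own marker and
#' therefore its own scale factor; factors are never averaged across views.
#'
#' @param marker A [marker_spec()].
#' @return Scale factor in mm per pixel (strictly positive scalar).
#' @export
compute_scale_factor <- function(marker) {
  stopifnot(inherits(marker, "marker_spec"))
  marker$physical_size_mm / marker$pixel_size_px
}

#' Convert a pixel dimension to millimetres
#'
#' `D_mm = alpha * D_px` with `alpha` the per-frame scale factor.
#'
#' @param d_px Dimension in pixels (positive).
#' @param alpha Scale factor in mm per pixel (positive).
#' @return Dimension in millimetres.
#' @export
convert_dimension <- function(d_px, alpha) {
  if (!all(is.finite(d_px)) || any(d_px <= 0))
    stop("calibration error: pixel dimension must be positive", call. = FALSE)
  if (!all(is.finite(alpha)) || any(alpha <= 0))
    stop("calibration error: scale factor must be positive", call. = FALSE)
  alpha * d_px
}

#' Four calibrated fruit dimensions
#'
#' Container for the four orthogonal physical dimensions driving the feature
#' stage: top-view width/height and side-view width/height, all in mm.
#' Invariant checks (positivity, sanity bounds, per-view aspect ratio) can be
#' relaxed with `strict = FALSE`, in which case violations become QC flags on
#' the object instead of errors.
#'
#' @param w_top,h_top,w_side,h_side Dimensions in millimetres.
#' @param fruit_id Opaque identifier.
#' @param sanity_bounds_mm Length-2 numeric, allowed dimension range.
#' @param max_aspect_ratio Per-view max/min bound.
#' @param strict Error on violations (`TRUE`) or record QC flags (`FALSE`).
#' @return An object of class `fruit_dimensions` with a `qc_flags` attribute.
#' @export
fruit_dimensions <- function(w_top, h_top, w_side, h_side, fruit_id = NA_character_,
                             sanity_bounds_mm = c(20, 150),
                             max_aspect_ratio = 2.0,
                             strict = FALSE) {
  d <- c(w_top = w_top, h_top = h_top, w_side = w_side, h_side = h_side)
  if (!all(is.finite(d)) || any(d <= 0))
    stop("fruit dimensions must all be positive and finite", call. = FALSE)
  flags <- character(0)
  if (any(d < sanity_bounds_mm[1]) || any(d > sanity_bounds_mm[2]))
    flags <- c(flags, "sanity_bounds_violation")
  ar_top <- max(w_top, h_top) / min(w_top, h_top)
  ar_side <- max(w_side, h_side) / min(w_side, h_side)
  if (ar_top > max_aspect_ratio || ar_side > max_aspect_ratio)
    flags <- c(flags, "aspect_ratio_violation")
  if (strict && length(flags) > 0)
    stop("fruit dimensions rejected; QC flags: ", paste(flags, collapse = ", "),
         call. = FALSE)
  structure(list(w_top = w_top, h_top = h_top, w_side = w_side, h_side = h_side,
                 fruit_id = fruit_id),
            qc_flags = flags, class = "fruit_dimensions")
}

#' @export
print.fruit_dimensions <- function(x, ...) {
  cat(sprintf("fruit_dimensions [%s]: Wtop=%.2f Htop=%.2f Wside=%.2f Hside=%.2f mm\n",
              x$fruit_id, x$w_top, x$h_top, x$w_side, x$h_side))
  fl <- attr(x, "qc_flags")
  if (length(fl)) cat("  qc_flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Extract fruit and marker bounding boxes from a binary mask
#'
#' Labels connected foreground components (`EBImage::bwlabel`), identifies the
#' marker as the component whose tight bounding box is closest to square
#' (`|w - h| / max(w, h) <= squareness_tol`), and takes the largest remaining
#' component as the fruit. Extents follow the inclusive pixel convention
#' `max index - min index + 1`. If several components satisfy the squareness
#' criterion the smallest-area one is taken as the marker and a
#' `low_marker_confidence` flag is raised (tie-break rationale: fiducials are
#' small relative to produce).
#'
#' @param mask Numeric or logical matrix; foreground is `> 0`.
#' @param marker_physical_size_mm Known side length of the fiducial square.
#' @param squareness_tol Relative width/height mismatch tolerated for the marker.
#' @return List with `fruit_width_px`, `fruit_height_px`, `fruit_bbox`,
#'   `marker` (a [marker_spec()]), `marker_bbox`, and `qc_flags`.
#' @export
extract_dimensions_from_mask <- function(mask, marker_physical_size_mm = 30,
                                         squareness_tol = 0.1) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask > 0)
  lab <- as.matrix(lab)
  n_comp <- max(lab)
  if (n_comp < 2)
    stop("extraction error: expected fruit and marker, found ",
         n_comp, " component(s)", call. = FALSE)
  boxes <- lapply(seq_len(n_comp), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    # rows index image y, cols index image x
    list(w = diff(range(idx[, 2])) + 1L,
         h = diff(range(idx[, 1])) + 1L,
         area = nrow(idx),
         bbox = c(xmin = min(idx[, 2]), ymin = min(idx[, 1]),
                  xmax = max(idx[, 2]), ymax = max(idx[, 1])))
  })
  sq <- vapply(boxes, function(b) abs(b$w - b$h) / max(b$w, b$h), numeric(1))
  areas <- vapply(boxes, `[[`, numeric(1), "area")
  cand <- which(sq <= squareness_tol)
  flags <- character(0)
  if (length(cand) == 0) {
    # no clean square: fall back to most-square component, flag it
    cand <- which.min(sq)
    flags <- c(flags, "low_marker_confidence")
  } else if (length(cand) > 1) {
    cand <- cand[which.min(areas[cand])]
    flags <- c(flags, "low_marker_confidence")
  }
  marker_i <- cand
  rest <- setdiff(seq_len(n_comp), marker_i)
  fruit_i <- rest[which.max(areas[rest])]
  mb <- boxes[[marker_i]]; fb <- boxes[[fruit_i]]
  conf <- if ("low_marker_confidence" %in% flags) 0.25 else 1 - sq[marker_i]
  list(fruit_width_px = fb$w, fruit_height_px = fb$h, fruit_bbox = fb$bbox,
       marker = marker_spec(marker_physical_size_mm, (mb$w + mb$h) / 2, conf),
       marker_bbox = mb$bbox, qc_flags = flags)
}

#' One calibrated view of a fruit
#'
#' @param view_label `"top"` or `"side"`.
#' @param fruit_width_px,fruit_height_px Tight bounding-box extents in pixels.
#' @param marker [marker_spec()] observed in the same frame.
#' @param qc_flags Character vector of flags carried from extraction.
#' @return Object of class `view_measurement`.
#' @export
view_measurement <- function(view_label, fruit_width_px, fruit_height_px, marker,
                             qc_flags = character(0)) {
  view_label <- match.arg(view_label, c("top", "side"))
  if (any(c(fruit_width_px, fruit_height_px) <= 0))
    stop("fruit pixel extents must be positive", call. = FALSE)
  stopifnot(inherits(marker, "marker_spec"))
  structure(list(view_label = view_label,
                 fruit_width_px = fruit_width_px,
                 fruit_height_px = fruit_height_px,
                 marker = marker, qc_flags = qc_flags),
            class = "view_measurement")
}

#' Quality-control flags for a measured fruit
#'
#' Checks the aspect-ratio sanity bound per view, the marker detection
#' confidence, and (when bounding boxes and an image extent are supplied)
#' whether the fruit touches the image border, which suggests occlusion or
#' truncation.
#'
#' @param dims A [fruit_dimensions()].
#' @param marker_confidence Lowest marker confidence across views.
#' @param max_aspect_ratio Per-view max/min bound (default 2).
#' @param confidence_threshold Below this the `low_marker_confidence` flag is set.
#' @param fruit_bbox Optional `c(xmin, ymin, xmax, ymax)` in px.
#' @param image_size Optional `c(width, height)` in px.
#' @return Character vector of flags (possibly empty): subset of
#'   `aspect_ratio_violation`, `low_marker_confidence`, `occlusion_suspect`.
#' @export
quality_check <- function(dims, marker_confidence = 1,
                          max_aspect_ratio = 2.0, confidence_threshold = 0.5,
                          fruit_bbox = NULL, image_size = NULL) {
  stopifnot(inherits(dims, "fruit_dimensions"))
  flags <- character(0)
  ar_top <- max(dims$w_top, dims$h_top) / min(dims$w_top, dims$h_top)
  ar_side <- max(dims$w_side, dims$h_side) / min(dims$w_side, dims$h_side)
  if (ar_top > max_aspect_ratio || ar_side > max_aspect_ratio)
    flags <- c(flags, "aspect_ratio_violation")
  if (marker_confidence < confidence_threshold)
    flags <- c(flags, "low_marker_confidence")
  if (!is.null(fruit_bbox) && !is.null(image_size)) {
    if (fruit_bbox["xmin"] <= 1 || fruit_bbox["ymin"] <= 1 ||
        fruit_bbox["xmax"] >= image_size[1] || fruit_bbox["ymax"] >= image_size[2])
      flags <- c(flags, "occlusion_suspect")
  }
  flags
}

#' Assemble calibrated fruit dimensions from two views
#'
#' Applies each view's own scale factor to its pixel extents (per-frame
#' calibration; factors are never shared or averaged) and composes the four
#' physical dimensions. QC flags from the views, from marker confidence and
#' from the dimension sanity checks are merged; in strict mode any flag is a
#' rejection error.
#'
#' @param top,side [view_measurement()] objects labelled accordingly.
#' @param fruit_id Identifier carried onto the result.
#' @param strict Reject flagged fruit with an error.
#' @inheritParams fruit_dimensions
#' @return A [fruit_dimensions()] with merged `qc_flags` attribute.
#' @export
assemble_fruit_dimensions <- function(top, side, fruit_id = NA_character_,
                                      sanity_bounds_mm = c(20, 150),
                                      max_aspect_ratio = 2.0,
                                      confidence_threshold = 0.5,
                                      strict = FALSE) {
  stopifnot(inherits(top, "view_measurement"), inherits(side, "view_measurement"))
  if (top$view_label != "top" || side$view_label != "side")
    stop("views must be labelled 'top' and 'side'", call. = FALSE)
  a_top <- compute_scale_factor(top$marker)
  a_side <- compute_scale_factor(side$marker)
  dims <- fruit_dimensions(
    w_top = convert_dimension(top$fruit_width_px, a_top),
    h_top = convert_dimension(top$fruit_height_px, a_top),
    w_side = convert_dimension(side$fruit_width_px, a_side),
    h_side = convert_dimension(side$fruit_height_px, a_side),
    fruit_id = fruit_id, sanity_bounds_mm = sanity_bounds_mm,
    max_aspect_ratio = max_aspect_ratio, strict = FALSE)
  conf <- min(top$marker$confidence, side$marker$confidence)
  flags <- unique(c(attr(dims, "qc_flags"), top$qc_flags, side$qc_flags,
                    quality_check(dims, marker_confidence = conf,
                                  max_aspect_ratio = max_aspect_ratio,
                                  confidence_threshold = confidence_threshold)))
  attr(dims, "qc_flags") <- flags
  if (strict && length(flags) > 0)
    stop("fruit rejected; QC flags: ", paste(flags, collapse = ", "),
         call. = FALSE)
  dims
}

#' Measure a rendered two-view scene
#'
#' Convenience wrapper: runs [extract_dimensions_from_mask()] on the top and
#' side masks and assembles calibrated [fruit_dimensions()].
#'
#' @param top_mask,side_mask Binary matrices containing fruit and marker.
#' @param marker_physical_size_mm Fiducial side length (mm).
#' @param fruit_id Identifier.
#' @param strict Passed to [assemble_fruit_dimensions()].
#' @return A [fruit_dimensions()].
#' @export
measure_scene <- function(top_mask, side_mask, marker_physical_size_mm = 30,
                          fruit_id = NA_character_, strict = FALSE) {
  et <- extract_dimensions_from_mask(top_mask, marker_physical_size_mm)
  es <- extract_dimensions_from_mask(side_mask, marker_physical_size_mm)
  assemble_fruit_dimensions(
    view_measurement("top", et$fruit_width_px, et$fruit_height_px, et$marker, et$qc_flags),
    view_measurement("side", es$fruit_width_px, es$fruit_height_px, es$marker, es$qc_flags),
    fruit_id = fruit_id, strict = strict)
}

#' Read / write dimension tables
#'
#' The on-disk schema is a CSV with columns `fruit_id, w_top_mm, h_top_mm,
#' w_side_mm, h_side_mm` and optionally `volume_ml` (ground truth) and
#' `qc_flags` (semicolon-separated).
#'
#' @param path CSV file path.
#' @return `read_dimension_table`: a data.frame in the schema above.
#' @export
read_dimension_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fruit_id", "w_top_mm", "h_top_mm", "w_side_mm", "h_side_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dimension table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_dimension_table
#' @param dims_list List of [fruit_dimensions()] objects (or a data.frame
#'   already in schema).
#' @export
write_dimension_table <- function(dims_list, path) {
  df <- if (is.data.frame(dims_list)) dims_list else dimension_table(dims_list)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_dimension_table
#' @export
dimension_table <- function(dims_list) {
  stopifnot(all(vapply(dims_list, inherits, logical(1), "fruit_dimensions")))
  data.frame(
    fruit_id = vapply(dims_list, function(d) as.character(d$fruit_id), character(1)),
    w_top_mm = vapply(dims_list, `[[`, numeric(1), "w_top"),
    h_top_mm = vapply(dims_list, `[[`, numeric(1), "h_top"),
    w_side_mm = vapply(dims_list, `[[`, numeric(1), "w_side"),
    h_side_mm = vapply(dims_list, `[[`, numeric(1), "h_side"),
    qc_flags = vapply(dims_list, function(d)
      paste(attr(d, "qc_flags"), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Read / write binary mask PNGs
#'
#' Masks are single-channel PNGs with foreground strictly above zero. Colour
#' PNGs are collapsed by their first channel on read.
#'
#' @param path PNG file path.
#' @return `read_mask_png`: an integer 0/1 matrix (rows = image y).
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[img > 0] <- 1L
  mask
}

#' @rdname read_mask_png
#' @param mask Numeric or logical matrix; foreground is `> 0`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}
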