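#' Semi-axes derived from the four calibrated dimensions
#'
#' The measured widths and heights are interpreted as full ellipsoid diameters:
#' `a = Wtop/2`, `b = Htop/2`, `c_sw = Wside/2`, `c_sh = Hside/2`, and the
#' averaged third axis `c_avg = (Wside + Hside)/4` (always the mean of `c_sw`
#' and `c_sh`).
#'
#' @param dims A [fruit_dimensions()].
#' @return List of class `semi_axes` with `a`, `b`, `c_sw`, `c_sh`, `c_avg` (mm).
#' @export
semi_axes <- function(dims) {
  stopifnot(inherits(dims, "fruit_dimensions"))
  structure(list(a = dims$w_top / 2, b = dims$h_top / 2,
                 c_sw = dims$w_side / 2, c_sh = dims$h_side / 2,
                 c_avg = (dims$w_side + dims$h_side) / 4),
            class = "semi_axes")
}

#' Ellipsoid volume proxies
#'
#' Three variants of `V = (4/3) * pi * a * b * c` differing in the third
#' semi-axis (`c_avg`, `c_sw`, `c_sh`), converted from cubic millimetres to
#' millilitres (divide by 1000).
#'
#' @param s A [semi_axes()] object.
#' @return Named numeric: `v_ellip_avg`, `v_ellip_sw`, `v_ellip_sh` (mL).
#' @export
ellipsoid_volume_proxies <- function(s) {
  stopifnot(inherits(s, "semi_axes"))
  base <- (4 / 3) * pi * s$a * s$b
  c(v_ellip_avg = base * s$c_avg, v_ellip_sw = base * s$c_sw,
    v_ellip_sh = base * s$c_sh) / 1000
}

#' Mean diameter and equivalent-sphere volume
#'
#' `D_bar` is the arithmetic mean of the four dimensions; the sphere proxy is
#' `(4/3) * pi * (D_bar/2)^3` in mL.
#'
#' @param dims A [fruit_dimensions()].
#' @return Named numeric: `d_mean` (mm), `v_sphere` (mL).
#' @export
mean_diameter_sphere_volume <- function(dims) {
  stopifnot(inherits(dims, "fruit_dimensions"))
  d_bar <- (dims$w_top + dims$h_top + dims$w_side + dims$h_side) / 4
  c(d_mean = d_bar, v_sphere = (4 / 3) * pi * (d_bar / 2)^3 / 1000)
}

#' Elliptical cross-sectional areas
#'
#' `A_top = pi * a * b`, `A_side = pi * c_sw * c_sh` in square millimetres.
#'
#' @param s A [semi_axes()] object.
#' @return Named numeric: `a_top`, `a_side` (mm^2).
#' @export
cross_sectional_areas <- function(s) {
  stopifnot(inherits(s, "semi_axes"))
  c(a_top = pi * s$a * s$b, a_side = pi * s$c_sw * s$c_sh)
}

#' Ramanujan approximation to the ellipse perimeter
#'
#' Ramanujan's second approximation:
#' `h = (A - B)^2 / (A + B)^2`,
#' `P ~ pi * (A + B) * (1 + 3h / (10 + sqrt(4 - 3h)))`.
#' Relative error is below 1e-5 for axis ratios up to 4 and vanishes for the
#' circle (`h = 0`, giving `2*pi*r` exactly).
#'
#' @param A,B Semi-axes (mm), order-free.
#' @return Perimeter in mm (vectorised over `A`, `B`).
#' @export
ellipse_perimeter <- function(A, B) {
  if (any(!is.finite(A)) || any(!is.finite(B)) || any(A <= 0) || any(B <= 0))
    stop("ellipse semi-axes must be positive", call. = FALSE)
  h <- (A - B)^2 / (A + B)^2
  pi * (A + B) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Knud-Thomsen approximation to the ellipsoid surface area
#'
#' `S ~ 4*pi*((a^p b^p + a^p c^p + b^p c^p)/3)^(1/p)` with exponent
#' `p = 1.6075`. Exact for the sphere; worst-case relative error about 1.06%
#' over all ellipsoids.
#'
#' @param a,b,c Semi-axes (mm), permutation-invariant.
#' @param p Knud-Thomsen exponent (> 1), default 1.6075.
#' @return Surface area in mm^2 (vectorised).
#' @export
ellipsoid_surface_area <- function(a, b, c, p = 1.6075) {
  if (any(c(a, b, c) <= 0)) stop("ellipsoid semi-axes must be positive", call. = FALSE)
  if (p <= 1) stop("Knud-Thomsen exponent must exceed 1", call. = FALSE)
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

#' Sphericity
#'
#' Ratio of the surface area of a sphere of equal volume to the actual
#' surface area: `Psi = pi^(1/3) * (6 V)^(2/3) / S`. Equals 1 for a perfect
#' sphere and is scale-invariant; `V` in mm^3, `S` in mm^2.
#'
#' @param volume_mm3 Volume in cubic millimetres.
#' @param surface_mm2 Surface area in square millimetres.
#' @return Dimensionless sphericity (vectorised).
#' @export
sphericity <- function(volume_mm3, surface_mm2) {
  if (any(volume_mm3 <= 0) || any(surface_mm2 <= 0))
    stop("volume and surface area must be positive", call. = FALSE)
  pi^(1 / 3) * (6 * volume_mm3)^(2 / 3) / surface_mm2
}

#' Shape ratios, eccentricities and interaction terms
#'
#' Aspect ratios per view (`Wtop/Htop`, `Wside/Hside`), cross-view ratios
#' (`Wtop/Wside`, `Htop/Hside`), the area ratio `A_top/A_side`, per-view
#' ellipse eccentricities `e = sqrt(1 - (minor/major)^2)`, and the two
#' interaction terms `A_top * Wside` and `A_side * Htop`.
#'
#' @param dims A [fruit_dimensions()].
#' @param s A [semi_axes()] (defaults to `semi_axes(dims)`).
#' @param areas Output of [cross_sectional_areas()] (recomputed if missing).
#' @return Named numeric vector of 9 features.
#' @export
shape_ratios <- function(dims, s = semi_axes(dims), areas = cross_sectional_areas(s)) {
  ecc <- function(u, v) sqrt(1 - (min(u, v) / max(u, v))^2)
  c(ar_top = dims$w_top / dims$h_top,
    ar_side = dims$w_side / dims$h_side,
    ratio_w = dims$w_top / dims$w_side,
    ratio_h = dims$h_top / dims$h_side,
    area_ratio = unname(areas["a_top"] / areas["a_side"]),
    e_top = ecc(s$a, s$b),
    e_side = ecc(s$c_sw, s$c_sh),
    ix_atop_wside = unname(areas["a_top"] * dims$w_side),
    ix_aside_htop = unname(areas["a_side"] * dims$h_top))
}

#' Canonical feature names
#'
#' The ordered 25-element feature schema produced by [build_feature_vector()].
#' @return Character vector of length 25.
#' @export
feature_names <- function() {
  c("w_top", "h_top", "w_side", "h_side", "d_mean",
    "v_ellip_avg", "v_ellip_sw", "v_ellip_sh", "v_sphere",
    "a_top", "a_side", "p_top", "p_side", "s_avg", "psi_avg", "sa_to_v",
    "ar_top", "ar_side", "ratio_w", "ratio_h", "area_ratio",
    "e_top", "e_side", "ix_atop_wside", "ix_aside_htop")
}

#' Names of the strictly-positive magnitude features
#'
#' The subset of the canonical features that are log-transformed during
#' preprocessing: volumes, areas, perimeters, the surface area and the
#' interaction terms. Ratios, eccentricities, sphericity and the raw linear
#' dimensions stay on their natural scale.
#' @return Character vector.
#' @export
log_feature_names <- function() {
  c("v_ellip_avg", "v_ellip_sw", "v_ellip_sh", "v_sphere",
    "a_top", "a_side", "p_top", "p_side", "s_avg",
    "ix_atop_wside", "ix_aside_htop")
}

#' Build the canonical 25-element feature vector
#'
#' Deterministic, pure function of the four calibrated dimensions. Units:
#' lengths mm, areas mm^2, volumes mL, perimeters mm, surface area mm^2;
#' ratios, eccentricities and sphericity dimensionless. `s_avg` is the
#' Knud-Thomsen surface area on `(a, b, c_avg)`; `psi_avg` pairs it with the
#' averaged ellipsoid volume proxy; `sa_to_v = s_avg / v_ellip_avg`
#' (mm^2 per mL).
#'
#' @param dims A [fruit_dimensions()].
#' @return Named numeric vector of length 25 in [feature_names()] order.
#' @export
build_feature_vector <- function(dims) {
  s <- semi_axes(dims)
  vols <- ellipsoid_volume_proxies(s)
  sph <- mean_diameter_sphere_volume(dims)
  areas <- cross_sectional_areas(s)
  p_top <- ellipse_perimeter(s$a, s$b)
  p_side <- ellipse_perimeter(s$c_sw, s$c_sh)
  s_avg <- ellipsoid_surface_area(s$a, s$b, s$c_avg)
  psi_avg <- sphericity(vols["v_ellip_avg"] * 1000, s_avg)
  out <- c(w_top = dims$w_top, h_top = dims$h_top,
           w_side = dims$w_side, h_side = dims$h_side,
           d_mean = unname(sph["d_mean"]),
           vols,
           v_sphere = unname(sph["v_sphere"]),
           areas,
           p_top = p_top, p_side = p_side,
           s_avg = s_avg,
           psi_avg = unname(psi_avg),
           sa_to_v = unname(s_avg / vols["v_ellip_avg"]),
           shape_ratios(dims, s, areas))
  out <- out[feature_names()]
  if (!all(is.finite(out)))
    stop("non-finite feature value for fruit ", dims$fruit_id, call. = FALSE)
  out
}

#' Feature table for a dimension table
#'
#' Applies [build_feature_vector()] row-wise to a dimension table (the
#' metrology CSV schema) and returns `fruit_id` + 25 feature columns, plus
#' `volume_ml` if ground truth is present.
#'
#' @param dims_df Data.frame with `w_top_mm`, `h_top_mm`, `w_side_mm`,
#'   `h_side_mm` and optionally `fruit_id`, `volume_ml`.
#' @return Data.frame with 25 feature columns in canonical order.
#' @export
build_feature_table <- function(dims_df) {
  stopifnot(is.data.frame(dims_df))
  n <- nrow(dims_df)
  ids <- if ("fruit_id" %in% names(dims_df)) as.character(dims_df$fruit_id)
         else sprintf("fruit_%03d", seq_len(n))
  feats <- t(vapply(seq_len(n), function(i) {
    d <- fruit_dimensions(dims_df$w_top_mm[i], dims_df$h_top_mm[i],
                          dims_df$w_side_mm[i], dims_df$h_side_mm[i],
                          fruit_id = ids[i])
    build_feature_vector(d)
  }, numeric(25)))
  out <- data.frame(fruit_id = ids, feats, stringsAsFactors = FALSE)
  names(out) <- c("fruit_id", feature_names())
  if ("volume_ml" %in% names(dims_df)) out$volume_ml <- dims_df$volume_ml
  out
}
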