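#' Evaluate an expression under a local RNG seed
#'
#' All stochastic generator operations route their draws through this helper:
#' with `seed = NULL` the expression consumes the caller's RNG stream; with an
#' integer seed the global RNG state is saved, the stream is seeded, and the
#' previous state restored afterwards, so the generator never leaks RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulated fruit shape
#'
#' A superellipsoid `|x/ax|^eps + |y/ay|^eps + |z/az|^eps = 1` (eps = 2 gives
#' an ellipsoid; larger eps is blockier, smaller more pointed) with an
#' optional multiplicative low-order radial lobe emulating localised
#' protrusions and asymmetry:
#' `r(theta, phi) = r0(theta, phi) * (1 + A * sin(theta)^2 * cos(m*phi + phase))`.
#' The `sin^2` factor keeps the surface continuous at the poles.
#'
#' @param semi_axes_mm Numeric length-3 `(ax, ay, az)` in mm, each in (10, 80).
#' @param epsilon Superellipsoid exponent in `[1.5, 3.5]`.
#' @param lobe_amplitude Fractional radial perturbation in `[0, 0.1]`.
#' @param lobe_order Integer azimuthal order of the lobe (default 3).
#' @param lobe_phase Azimuthal phase in radians.
#' @return Object of class `fruit_shape`.
#' @export
fruit_shape <- function(semi_axes_mm, epsilon = 2, lobe_amplitude = 0,
                        lobe_order = 3, lobe_phase = 0) {
  stopifnot(length(semi_axes_mm) == 3, all(is.finite(semi_axes_mm)))
  if (any(semi_axes_mm <= 10) || any(semi_axes_mm >= 80))
    stop("semi-axes must lie in (10, 80) mm", call. = FALSE)
  if (epsilon < 1.5 || epsilon > 3.5)
    stop("superellipsoid exponent must lie in [1.5, 3.5]", call. = FALSE)
  if (lobe_amplitude < 0 || lobe_amplitude > 0.1)
    stop("lobe amplitude must lie in [0, 0.1]", call. = FALSE)
  structure(list(semi_axes_mm = as.numeric(semi_axes_mm), epsilon = epsilon,
                 lobe_amplitude = lobe_amplitude,
                 lobe_order = as.integer(lobe_order), lobe_phase = lobe_phase),
            class = "fruit_shape")
}

#' Radial surface function of a shape
#'
#' Distance from the centre to the surface along the direction with polar
#' angle `theta` (from +z) and azimuth `phi`. Vectorised; `theta` and `phi`
#' are recycled to a common length.
#'
#' @param shape A [fruit_shape()].
#' @param theta,phi Spherical angles in radians.
#' @return Numeric vector of radii (mm).
#' @export
shape_radius <- function(shape, theta, phi) {
  ax <- shape$semi_axes_mm[1]; ay <- shape$semi_axes_mm[2]
  az <- shape$semi_axes_mm[3]; e <- shape$epsilon
  st <- sin(theta)
  ux <- st * cos(phi); uy <- st * sin(phi); uz <- cos(theta)
  r0 <- (abs(ux / ax)^e + abs(uy / ay)^e + abs(uz / az)^e)^(-1 / e)
  if (shape$lobe_amplitude > 0) {
    r0 <- r0 * (1 + shape$lobe_amplitude * st^2 *
                  cos(shape$lobe_order * phi + shape$lobe_phase))
  }
  r0
}

#' Generator configuration
#'
#' Defaults describe a supermarket-orange population: n = 150 fruit, full
#' diameters inside 50-88 mm, 1% multiplicative Gaussian measurement noise,
#' a 30 mm fiducial, and per-view scale factors drawn from 0.35-0.5 mm/px.
#'
#' Shape variation follows the way real citrus deviates from an ellipsoid:
#' fruit are oblate to varying degree (the polar axis is `flatten` times the
#' equatorial size) and their cross-sections grow blockier as they flatten —
#' the superellipsoid exponent is coupled to the observable flattening via
#' `epsilon = epsilon_round + epsilon_flatten_slope * (1 - flatten) + jitter`.
#' The coupling makes shape-dependent volume deviation largely *systematic*
#' (recoverable from aspect-ratio/eccentricity descriptors), while the
#' jitter and the lobe perturbation remain irreducible shape noise no
#' two-view measurement can see.
#'
#' @param n Number of fruit.
#' @param size_range_mm Allowed full-diameter range (mm).
#' @param dimension_noise_sd Relative (fractional) s.d. of measurement noise.
#' @param flatten_range Range of the polar-to-equatorial diameter ratio
#'   (uniform; values below 1 are oblate, slightly above 1 prolate).
#' @param epsilon_round Superellipsoid exponent of a perfectly round fruit.
#' @param epsilon_flatten_slope Increase of the exponent per unit flattening.
#' @param epsilon_jitter Half-width of the uniform unobservable exponent
#'   jitter.
#' @param lobe_amplitude_range Lobe amplitude range sampled uniformly.
#' @param axis_spread Maximum relative deviation of the two equatorial axis
#'   diameters from the fruit's base size (in-plane anisotropy; default 6%).
#' @param marker_physical_size_mm Fiducial square side (mm).
#' @param alpha_range_mm_px Per-view scale-factor range (mm per px).
#' @param seed Integer seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n = 150, size_range_mm = c(50, 88),
                             dimension_noise_sd = 0.01,
                             flatten_range = c(0.75, 1.05),
                             epsilon_round = 2.0,
                             epsilon_flatten_slope = 2.5,
                             epsilon_jitter = 0.05,
                             lobe_amplitude_range = c(0, 0.04),
                             axis_spread = 0.06,
                             marker_physical_size_mm = 30,
                             alpha_range_mm_px = c(0.35, 0.5),
                             seed = 1L) {
  stopifnot(n > 0, length(size_range_mm) == 2, size_range_mm[1] < size_range_mm[2],
            dimension_noise_sd >= 0, axis_spread >= 0, axis_spread <= 1,
            epsilon_jitter >= 0)
  if (size_range_mm[1] < 20 || size_range_mm[2] > 150)
    stop("config error: size range outside sanity bounds (20-150 mm)", call. = FALSE)
  if (diff(flatten_range) < 0 || diff(lobe_amplitude_range) < 0)
    stop("config error: invalid perturbation ranges", call. = FALSE)
  structure(list(n = as.integer(n), size_range_mm = size_range_mm,
                 dimension_noise_sd = dimension_noise_sd,
                 flatten_range = flatten_range,
                 epsilon_round = epsilon_round,
                 epsilon_flatten_slope = epsilon_flatten_slope,
                 epsilon_jitter = epsilon_jitter,
                 lobe_amplitude_range = lobe_amplitude_range,
                 axis_spread = axis_spread,
                 marker_physical_size_mm = marker_physical_size_mm,
                 alpha_range_mm_px = alpha_range_mm_px,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw one fruit shape from the configured population
#'
#' An overall fruit size is drawn uniformly in `size_range_mm`; the two
#' equatorial diameters perturb it by independent relative factors
#' `1 + U(-axis_spread, axis_spread)`, the polar diameter is `flatten` times
#' the base size with `flatten ~ U(flatten_range)`, and all three are
#' clamped into the size range. The superellipsoid exponent follows the
#' flattening coupling described in [generator_config()] (clipped to the
#' valid `[1.5, 3.5]` band); the lobe amplitude is uniform over its range
#' with a random order (2 or 3) and phase. The three axis diameters are
#' randomly permuted so the flattened axis is oriented arbitrarily with
#' respect to the two camera views, as fruit on a conveyor are. A degenerate configuration
#' (`flatten_range = c(1, 1)`, zero slope and jitter, `epsilon_round = 2`,
#' zero lobe) yields a pure ellipsoid.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed, or `NULL` to consume the caller's RNG stream.
#' @return A [fruit_shape()].
#' @export
sample_shape <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  with_rng(seed, {
    d0 <- stats::runif(1, config$size_range_mm[1], config$size_range_mm[2])
    flatten <- stats::runif(1, config$flatten_range[1], config$flatten_range[2])
    # the polar diameter may not drop below the population floor, so small
    # fruit are necessarily rounder than large ones
    flatten <- max(flatten, config$size_range_mm[1] / d0)
    d <- d0 * c(1 + stats::runif(2, -config$axis_spread, config$axis_spread),
                flatten)
    d <- pmin(pmax(d, config$size_range_mm[1]), config$size_range_mm[2])
    # fruit land on the stage in arbitrary orientation: the flattened axis is
    # not tied to the camera geometry
    d <- d[sample.int(3)]
    eps <- config$epsilon_round +
      config$epsilon_flatten_slope * (1 - flatten) +
      stats::runif(1, -config$epsilon_jitter, config$epsilon_jitter)
    eps <- min(max(eps, 1.5), 3.5)
    lobe <- stats::runif(1, config$lobe_amplitude_range[1],
                         config$lobe_amplitude_range[2])
    fruit_shape(d / 2, epsilon = eps, lobe_amplitude = lobe,
                lobe_order = sample(2:3, 1),
                lobe_phase = stats::runif(1, 0, 2 * pi))
  })
}

# Quadrature grid for volume / extent computations (package-internal).
.shape_grid <- function(n_theta, n_phi) {
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  list(theta = theta, phi = phi,
       TH = matrix(theta, n_theta, n_phi),
       PH = matrix(phi, n_theta, n_phi, byrow = TRUE))
}

#' Oracle volume of a simulated fruit
#'
#' For a star-shaped surface with radial function `r(theta, phi)` the volume
#' is `(1/3) * int r^3 sin(theta) dOmega`, evaluated by composite Simpson
#' quadrature in the polar angle and a periodic trapezoid rule in azimuth.
#' For `epsilon = 2`, `lobe = 0` this matches the ellipsoid closed form
#' `(4/3) pi ax ay az / 1000` to well below 1e-6 relative; general shapes in
#' the supported exponent range are resolved to better than 1e-5 relative on
#' the default grid (this stands in for a destructive water-displacement
#' ground truth).
#'
#' @param shape A [fruit_shape()].
#' @param n_theta,n_phi Quadrature resolution (n_theta must be odd).
#' @return Volume in mL.
#' @export
true_volume <- function(shape, n_theta = 181, n_phi = 360) {
  stopifnot(inherits(shape, "fruit_shape"), n_theta %% 2 == 1)
  g <- .shape_grid(n_theta, n_phi)
  r <- shape_radius(shape, g$TH, g$PH)
  f <- r^3 * sin(g$TH) / 3
  # Simpson weights over theta, uniform (periodic) over phi
  w_th <- rep(c(2, 4), length.out = n_theta); w_th[c(1, n_theta)] <- 1
  h_th <- pi / (n_theta - 1)
  integ <- sum((w_th * h_th / 3) * f) * (2 * pi / n_phi)
  if (!is.finite(integ) || integ <= 0)
    stop("oracle error: volume quadrature did not converge", call. = FALSE)
  integ / 1000
}

#' Analytic superellipsoid volume
#'
#' Closed form `8 * ax*ay*az * Gamma(1 + 1/e)^3 / Gamma(1 + 3/e)` (mL), valid
#' for lobe-free shapes; used as an independent check of the quadrature
#' oracle.
#'
#' @param shape A [fruit_shape()] with `lobe_amplitude = 0`.
#' @return Volume in mL.
#' @export
superellipsoid_volume_analytic <- function(shape) {
  stopifnot(inherits(shape, "fruit_shape"))
  if (shape$lobe_amplitude != 0)
    stop("analytic volume is only available for lobe-free shapes", call. = FALSE)
  e <- shape$epsilon
  8 * prod(shape$semi_axes_mm) * gamma(1 + 1 / e)^3 / gamma(1 + 3 / e) / 1000
}

# Silhouette extents of the two orthographic projections (mm).
# Top view looks along -z (image plane x-y); side view along -y (plane x-z).
.projection_extents <- function(shape, n_theta = 181, n_phi = 360) {
  g <- .shape_grid(n_theta, n_phi)
  r <- shape_radius(shape, g$TH, g$PH)
  st <- sin(g$TH)
  x <- r * st * cos(g$PH); y <- r * st * sin(g$PH); z <- r * cos(g$TH)
  c(w_top = max(x) - min(x), h_top = max(y) - min(y),
    w_side = max(x) - min(x), h_side = max(z) - min(z))
}

#' Observe the four dimensions of a simulated fruit
#'
#' Computes the noiseless silhouette extents of the top (x-y plane) and side
#' (x-z plane) orthographic projections, applies i.i.d. multiplicative
#' Gaussian noise `(1 + N(0, sd))` per dimension (resampling a bounded number
#' of times if a draw turns a dimension non-positive), and quantises to
#' pixels with a per-view scale factor drawn from `alpha_range_mm_px`.
#'
#' @param shape A [fruit_shape()].
#' @param config A [generator_config()].
#' @param seed Integer seed or `NULL` (caller's stream).
#' @return List with `dims_true`, `dims_observed` (named numeric, mm),
#'   `px` (named integer pixel extents), and `alpha` (per-view mm/px).
#' @export
observe_dimensions <- function(shape, config, seed = NULL) {
  stopifnot(inherits(shape, "fruit_shape"), inherits(config, "generator_config"))
  dims_true <- .projection_extents(shape)
  with_rng(seed, {
    sd <- config$dimension_noise_sd
    obs <- dims_true
    if (sd > 0) {
      for (i in seq_along(obs)) {
        for (try in 1:100) {
          cand <- dims_true[i] * (1 + stats::rnorm(1, 0, sd))
          if (cand > 0) { obs[i] <- cand; break }
          if (try == 100) stop("noise resampling failed to produce positive dims",
                               call. = FALSE)
        }
      }
    }
    alpha <- stats::runif(2, config$alpha_range_mm_px[1], config$alpha_range_mm_px[2])
    names(alpha) <- c("top", "side")
    px <- round(c(obs[c("w_top", "h_top")] / alpha[["top"]],
                  obs[c("w_side", "h_side")] / alpha[["side"]]))
    storage.mode(px) <- "integer"
    list(dims_true = dims_true, dims_observed = obs, px = px, alpha = alpha)
  })
}

# Star-shaped silhouette radial profile of a projection.
# axes: c(1,2) for top view (x-y), c(1,3) for side view (x-z).
.silhouette_profile <- function(shape, axes, n_bins = 720, n_theta = 271, n_phi = 540) {
  g <- .shape_grid(n_theta, n_phi)
  r <- shape_radius(shape, g$TH, g$PH)
  st <- sin(g$TH)
  pts <- cbind(x = as.vector(r * st * cos(g$PH)),
               y = as.vector(r * st * sin(g$PH)),
               z = as.vector(r * cos(g$TH)))
  u <- pts[, axes[1]]; v <- pts[, axes[2]]
  ang <- atan2(v, u) %% (2 * pi)
  rad <- sqrt(u^2 + v^2)
  bin <- pmin(floor(ang / (2 * pi) * n_bins) + 1L, n_bins)
  prof <- rep(0, n_bins)
  agg <- tapply(rad, bin, max)
  prof[as.integer(names(agg))] <- agg
  # guard isolated empty bins by neighbour maximum
  empty <- which(prof == 0)
  for (i in empty) {
    prof[i] <- max(prof[(i %% n_bins) + 1L], prof[((i - 2) %% n_bins) + 1L])
  }
  prof
}

#' Render calibrated two-view masks for a fruit
#'
#' Draws the fruit silhouette (exact star-shaped projection of the radial
#' surface, rasterised from its angular radial profile) and a filled fiducial
#' square of side `round(marker_mm / alpha)` px in the top-left corner of
#' each canvas. Errors if fruit and marker would overlap or the fruit does
#' not fit the canvas.
#'
#' @param shape A [fruit_shape()].
#' @param alpha Named numeric `c(top=, side=)` scale factors in mm/px.
#' @param canvas_px Canvas side length (square canvas).
#' @param marker_physical_size_mm Fiducial side (mm).
#' @return List with binary matrices `top`, `side` (1 = foreground), and the
#'   marker pixel sizes used.
#' @export
render_views <- function(shape, alpha = c(top = 0.4, side = 0.4),
                         canvas_px = 384, marker_physical_size_mm = 30) {
  stopifnot(inherits(shape, "fruit_shape"), all(alpha > 0))
  render_one <- function(axes, a) {
    prof <- .silhouette_profile(shape, axes)
    n_bins <- length(prof)
    marker_px <- round(marker_physical_size_mm / a)
    # fruit centred in the lower-right 2/3 of the canvas
    cx <- canvas_px * 0.62; cy <- canvas_px * 0.62
    xs <- matrix(seq_len(canvas_px), canvas_px, canvas_px, byrow = TRUE)
    ys <- matrix(seq_len(canvas_px), canvas_px, canvas_px)
    dx <- (xs - cx) * a; dy <- (ys - cy) * a
    d <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx) %% (2 * pi)
    bin <- pmin(floor(ang / (2 * pi) * n_bins) + 1L, n_bins)
    mask <- matrix(0L, canvas_px, canvas_px)
    mask[d <= prof[bin]] <- 1L
    fruit_max_px <- max(prof) / a
    if (cx - fruit_max_px < marker_px + 10 && cy - fruit_max_px < marker_px + 10)
      stop("render error: fruit and marker overlap", call. = FALSE)
    if (cx + fruit_max_px > canvas_px || cy + fruit_max_px > canvas_px ||
        cx - fruit_max_px < 1 || cy - fruit_max_px < 1)
      stop("render error: fruit does not fit the canvas", call. = FALSE)
    mask[3:(2 + marker_px), 3:(2 + marker_px)] <- 1L
    list(mask = mask, marker_px = marker_px)
  }
  top <- render_one(c(1, 2), alpha[["top"]])
  side <- render_one(c(1, 3), alpha[["side"]])
  list(top = top$mask, side = side$mask,
       marker_px = c(top = top$marker_px, side = side$marker_px),
       alpha = alpha)
}

#' Generate a synthetic fruit dataset
#'
#' Draws `config$n` fruit, computes their oracle volumes and noisy observed
#' dimensions, and builds the canonical 25-feature table. The result carries
#' the full per-sample records (shapes, true/observed dimensions, pixel
#' measurements) plus a manifest of the seed and configuration.
#'
#' @param config A [generator_config()].
#' @return Object of class `synthetic_dataset`: list with `samples` (list),
#'   `features` (data.frame: fruit_id, 25 features, volume_ml), and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  samples <- with_rng(config$seed, {
    lapply(seq_len(config$n), function(i) {
      shape <- sample_shape(config)
      obs <- observe_dimensions(shape, config)
      list(fruit_id = sprintf("fruit_%03d", i), shape = shape,
           true_volume_ml = true_volume(shape),
           dims_true = obs$dims_true, dims_observed = obs$dims_observed,
           px = obs$px, alpha = obs$alpha)
    })
  })
  dims_df <- data.frame(
    fruit_id = vapply(samples, `[[`, character(1), "fruit_id"),
    w_top_mm = vapply(samples, function(s) s$dims_observed[["w_top"]], numeric(1)),
    h_top_mm = vapply(samples, function(s) s$dims_observed[["h_top"]], numeric(1)),
    w_side_mm = vapply(samples, function(s) s$dims_observed[["w_side"]], numeric(1)),
    h_side_mm = vapply(samples, function(s) s$dims_observed[["h_side"]], numeric(1)),
    volume_ml = vapply(samples, `[[`, numeric(1), "true_volume_ml"),
    stringsAsFactors = FALSE)
  feats <- build_feature_table(dims_df)
  structure(list(samples = samples, dimensions = dims_df, features = feats,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  v <- x$features$volume_ml
  cat(sprintf("synthetic_dataset: n=%d, volume %.1f-%.1f mL (mean %.1f, sd %.1f), seed %d\n",
              nrow(x$features), min(v), max(v), mean(v), stats::sd(v),
              x$config$seed))
  invisible(x)
}
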