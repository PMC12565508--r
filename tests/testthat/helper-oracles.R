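# Independent numerical oracles used to freeze expected values. These stay
# deliberately separate from the package's own code paths: perimeters via the
# complete elliptic integral, surface areas via a brute-force surface
# integral, volumes via Monte-Carlo indicator sampling, bounding boxes via
# per-pixel scans, signed-rank p-values via full 2^n enumeration.

# Ellipse perimeter: P = 4 A int_0^{pi/2} sqrt(1 - m sin^2 t) dt, m = 1-(B/A)^2.
oracle_ellipse_perimeter <- function(A, B) {
  a <- max(A, B); b <- min(A, B)
  m <- 1 - (b / a)^2
  4 * a * stats::integrate(function(t) sqrt(1 - m * sin(t)^2), 0, pi / 2,
                           rel.tol = 1e-12)$value
}

# Ellipsoid surface area by 2-D Simpson quadrature of |r_theta x r_phi|.
oracle_ellipsoid_surface <- function(a, b, c, n_theta = 201, n_phi = 400) {
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  TH <- matrix(theta, n_theta, n_phi)
  PH <- matrix(phi, n_theta, n_phi, byrow = TRUE)
  st <- sin(TH); ct <- cos(TH)
  integrand <- st * sqrt((b * c * st * cos(PH))^2 +
                         (a * c * st * sin(PH))^2 +
                         (a * b * ct)^2)
  w <- rep(c(2, 4), length.out = n_theta); w[c(1, n_theta)] <- 1
  sum((w * (pi / (n_theta - 1)) / 3) * integrand) * (2 * pi / n_phi)
}

# Monte-Carlo volume of a fruit_shape via the radial inside test (mL).
oracle_mc_volume <- function(shape, n = 2e5, seed = 1) {
  a <- max(shape$semi_axes_mm) * 1.12 # bounding half-width incl. lobe
  withr::with_seed(seed, {
    p <- matrix(stats::runif(3 * n, -a, a), ncol = 3)
    r <- sqrt(rowSums(p^2))
    theta <- acos(pmin(pmax(p[, 3] / pmax(r, 1e-12), -1), 1))
    phi <- atan2(p[, 2], p[, 1])
    inside <- r <= fruitvol::shape_radius(shape, theta, phi)
    mean(inside) * (2 * a)^3 / 1000
  })
}

# Per-pixel bounding-box oracle (inclusive extents) for a labelled component.
oracle_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  c(w = diff(range(idx[, 2])) + 1L, h = diff(range(idx[, 1])) + 1L)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force average precision: integrate the precision envelope over recall.
oracle_ap <- function(tp_flags, n_gt) {
  cum_tp <- cumsum(tp_flags); cum_fp <- cumsum(!tp_flags)
  rec <- cum_tp / n_gt; prec <- cum_tp / (cum_tp + cum_fp)
  ap <- 0; prev_r <- 0
  for (i in seq_along(rec)) {
    p_max <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev_r) * p_max
    prev_r <- rec[i]
  }
  ap
}

# Draw a simple scene: filled rectangle marker + filled ellipse fruit.
make_scene <- function(canvas = c(260, 260),
                       marker = list(x = 10, y = 10, w = 30, h = 30),
                       fruit = list(cx = 160, cy = 150, rx = 55, ry = 45)) {
  m <- matrix(0L, canvas[1], canvas[2])
  m[marker$y:(marker$y + marker$h - 1), marker$x:(marker$x + marker$w - 1)] <- 1L
  xs <- matrix(seq_len(canvas[2]), canvas[1], canvas[2], byrow = TRUE)
  ys <- matrix(seq_len(canvas[1]), canvas[1], canvas[2])
  m[((xs - fruit$cx) / fruit$rx)^2 + ((ys - fruit$cy) / fruit$ry)^2 <= 1] <- 1L
  m
}

# Small pure-ellipsoid noiseless config reused across tests.
noiseless_ellipsoid_config <- function(n = 150, seed = 42) {
  generator_config(n = n, seed = seed, dimension_noise_sd = 0,
                   flatten_range = c(1, 1), epsilon_round = 2,
                   epsilon_flatten_slope = 0, epsilon_jitter = 0,
                   lobe_amplitude_range = c(0, 0))
}
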