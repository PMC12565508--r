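test_that("semi-axes halve the dimensions and c_avg is the mean of c_sw, c_sh", {
  s <- semi_axes(fruit_dimensions(60, 50, 58, 54))
  expect_equal(unclass(s)[c("a", "b", "c_sw", "c_sh", "c_avg")],
               list(a = 30, b = 25, c_sw = 29, c_sh = 27, c_avg = 28))
  withr::with_seed(1, {
    for (i in 1:20) {
      d <- fruit_dimensions(runif(1, 40, 90), runif(1, 40, 90),
                            runif(1, 40, 90), runif(1, 40, 90))
      s <- semi_axes(d)
      expect_equal(s$c_avg, (s$c_sw + s$c_sh) / 2, tolerance = 1e-15)
    }
  })
})

test_that("ellipsoid volume proxies match closed forms and are monotone", {
  s <- semi_axes(fruit_dimensions(60, 60, 60, 60))
  expect_equal(unname(ellipsoid_volume_proxies(s)),
               rep(4 / 3 * pi * 27, 3), tolerance = 1e-9)
  s2 <- semi_axes(fruit_dimensions(60, 50, 58, 54))
  v <- ellipsoid_volume_proxies(s2)
  expect_equal(v[["v_ellip_avg"]], 4 / 3 * pi * 30 * 25 * 28 / 1000,
               tolerance = 1e-12)
  # c_sw == c_sh collapses all three proxies
  v3 <- ellipsoid_volume_proxies(semi_axes(fruit_dimensions(60, 50, 56, 56)))
  expect_equal(unname(v3), rep(v3[[1]], 3))
  # strict monotonicity in each dimension
  base <- c(60, 50, 58, 54)
  v0 <- ellipsoid_volume_proxies(semi_axes(do.call(fruit_dimensions, as.list(base))))
  for (i in 1:4) {
    up <- base; up[i] <- up[i] + 2
    vi <- ellipsoid_volume_proxies(semi_axes(do.call(fruit_dimensions, as.list(up))))
    expect_true(all(vi >= v0), info = paste("dim", i))
  }
})

test_that("mean diameter and sphere volume follow the definitions", {
  md <- mean_diameter_sphere_volume(fruit_dimensions(60, 60, 60, 60))
  expect_equal(md[["d_mean"]], 60)
  expect_equal(md[["v_sphere"]], 113.0973355, tolerance = 1e-9)
  expect_equal(mean_diameter_sphere_volume(
    fruit_dimensions(50, 60, 70, 80))[["d_mean"]], 65)
  # sphere of mean diameter lies between the single-axis extremes
  v <- mean_diameter_sphere_volume(fruit_dimensions(50, 60, 70, 80))[["v_sphere"]]
  vol <- function(d) 4 / 3 * pi * (d / 2)^3 / 1000
  expect_gt(v, vol(50)); expect_lt(v, vol(80))
})

test_that("cross-sectional areas are elliptical and symmetric", {
  a <- cross_sectional_areas(semi_axes(fruit_dimensions(60, 60, 60, 60)))
  expect_equal(a[["a_top"]], 900 * pi)
  a2 <- cross_sectional_areas(semi_axes(fruit_dimensions(60, 50, 58, 54)))
  expect_equal(a2[["a_top"]], 750 * pi)
  a3 <- cross_sectional_areas(semi_axes(fruit_dimensions(50, 60, 54, 58)))
  expect_equal(a3[["a_top"]], a2[["a_top"]])
  expect_equal(a3[["a_side"]], a2[["a_side"]])
})

test_that("Ramanujan perimeter matches the elliptic-integral oracle", {
  expect_equal(ellipse_perimeter(5, 5), 10 * pi, tolerance = 1e-14)
  expect_equal(ellipse_perimeter(2, 1), 9.688448, tolerance = 1e-5)
  expect_equal(ellipse_perimeter(2, 1), oracle_ellipse_perimeter(2, 1),
               tolerance = 1e-5)
  expect_equal(ellipse_perimeter(2, 1), ellipse_perimeter(1, 2))
  withr::with_seed(11, {
    for (i in 1:50) {
      A <- runif(1, 5, 60); B <- A / runif(1, 1, 4)
      expect_equal(ellipse_perimeter(A, B), oracle_ellipse_perimeter(A, B),
                   tolerance = 2e-4)
    }
  })
})

test_that("Knud-Thomsen surface area is near the surface-integral oracle", {
  expect_equal(ellipsoid_surface_area(30, 30, 30), 3600 * pi, tolerance = 1e-12)
  s <- ellipsoid_surface_area(3, 2, 1)
  expect_equal(s, oracle_ellipsoid_surface(3, 2, 1), tolerance = 0.012)
  perms <- list(c(3, 2, 1), c(1, 3, 2), c(2, 1, 3))
  for (p in perms)
    expect_equal(ellipsoid_surface_area(p[1], p[2], p[3]), s, tolerance = 1e-12)
})

test_that("sphericity is 1 for spheres, < 1 otherwise, and scale-invariant", {
  r <- 30
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1, tolerance = 1e-12)
  v <- 4 / 3 * pi * 3 * 2 * 1
  expect_lt(sphericity(v, oracle_ellipsoid_surface(3, 2, 1)), 1)
  for (k in c(0.5, 2, 10)) {
    expect_equal(sphericity(v * k^3, oracle_ellipsoid_surface(3, 2, 1) * k^2),
                 sphericity(v, oracle_ellipsoid_surface(3, 2, 1)),
                 tolerance = 1e-12)
  }
})

test_that("shape ratios, eccentricities and interactions evaluate correctly", {
  sp <- shape_ratios(fruit_dimensions(60, 60, 60, 60))
  expect_equal(unname(sp[c("ar_top", "ar_side", "ratio_w", "ratio_h",
                           "area_ratio")]), rep(1, 5))
  expect_equal(unname(sp[c("e_top", "e_side")]), c(0, 0))
  sp2 <- shape_ratios(fruit_dimensions(60, 50, 60, 60))
  expect_equal(sp2[["e_top"]], 0.5527708, tolerance = 1e-6)
  expect_equal(sp2[["ix_atop_wside"]], 750 * pi * 60, tolerance = 1e-9)
})

test_that("the feature vector has 25 canonical entries and is pure", {
  d <- fruit_dimensions(60, 60, 60, 60)
  fv <- build_feature_vector(d)
  expect_identical(names(fv), feature_names())
  expect_length(fv, 25)
  expect_equal(fv[["v_ellip_avg"]], fv[["v_sphere"]], tolerance = 1e-9)
  expect_equal(fv[["v_ellip_avg"]], 113.0973355, tolerance = 1e-6)
  expect_equal(fv[["psi_avg"]], 1, tolerance = 1e-9)
  expect_identical(fv, build_feature_vector(fruit_dimensions(60, 60, 60, 60)))
  # every feature responds to at least one dimension; each dimension moves
  # its governing raw feature
  base <- c(60, 55, 58, 52)
  fv0 <- build_feature_vector(do.call(fruit_dimensions, as.list(base)))
  changed <- rep(FALSE, 25); names(changed) <- feature_names()
  for (i in 1:4) {
    up <- base; up[i] <- up[i] + 1
    fvi <- build_feature_vector(do.call(fruit_dimensions, as.list(up)))
    changed <- changed | (abs(fvi - fv0) > 1e-12)
    expect_equal(fvi[[c("w_top", "h_top", "w_side", "h_side")[i]]], up[i])
  }
  expect_true(all(changed))
})

test_that("volumes convert mm^3 to mL by exactly 1000", {
  withr::with_seed(3, {
    for (i in 1:20) {
      d <- fruit_dimensions(runif(1, 45, 90), runif(1, 45, 90),
                            runif(1, 45, 90), runif(1, 45, 90))
      s <- semi_axes(d)
      v_ml <- ellipsoid_volume_proxies(s)[["v_ellip_avg"]]
      v_mm3 <- 4 / 3 * pi * s$a * s$b * s$c_avg
      expect_equal(v_mm3 / v_ml, 1000, tolerance = 1e-12)
    }
  })
})

test_that("feature tables preserve ids, order and ground truth", {
  df <- data.frame(fruit_id = c("x", "y"),
                   w_top_mm = c(60, 70), h_top_mm = c(58, 68),
                   w_side_mm = c(59, 69), h_side_mm = c(57, 67),
                   volume_ml = c(100, 160))
  ft <- build_feature_table(df)
  expect_identical(names(ft), c("fruit_id", feature_names(), "volume_ml"))
  expect_equal(ft$volume_ml, c(100, 160))
  expect_equal(ft$w_top[1], 60)
})
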