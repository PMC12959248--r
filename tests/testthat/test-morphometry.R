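# Geometry engine: components, contours, hulls, rectangles, records.

test_that("connected components use 8-connectivity with row-major order", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE          # diagonal touch -> one component
  expect_length(connected_components(mask_from_matrix(m)), 1)
  m2 <- matrix(FALSE, 8, 8)
  m2[1:1, 1:5] <- TRUE                      # 5 px
  m2[6:8, 7] <- TRUE                        # 3 px, separated
  comps <- connected_components(mask_from_matrix(m2))
  expect_length(comps, 2)
  expect_equal(sort(vapply(comps, `[[`, numeric(1), "pixel_count")), c(3, 5))
  expect_length(connected_components(mask_from_matrix(matrix(FALSE, 3, 3))), 0)
})

test_that("largest component follows physical area with first-in-scan ties", {
  m <- matrix(FALSE, 20, 20)
  m[2:11, 2:11] <- TRUE                     # 100 px
  m[14:18, 14:18] <- TRUE                   # 25 px
  comps <- connected_components(mask_from_matrix(m))
  big <- largest_component(comps, 10, 10)
  expect_equal(big$pixel_count, 100)
  # single component returns itself
  one <- connected_components(mask_from_matrix(matrix(TRUE, 2, 2)))
  expect_identical(largest_component(one, 10, 10), one[[1]])
  # tie resolves to the first in row-major scan order
  m3 <- matrix(FALSE, 20, 20)
  m3[10:12, 2:4] <- TRUE                    # first encountered at row 10? no:
  m3[2:4, 10:12] <- TRUE                    # row-major scan hits row 2 first
  comps3 <- connected_components(mask_from_matrix(m3))
  win <- largest_component(comps3, 10, 10)
  expect_equal(unname(win$bbox["rmin"]), 2)
  # empty list raises the dedicated no-tumour condition
  expect_error(largest_component(list(), 10, 10), class = "melmorph_no_tumour")
  expect_error(compute_morphometrics(mask_from_matrix(matrix(FALSE, 4, 4))),
               class = "melmorph_no_tumour")
})

test_that("component area is pixel count times pixel footprint", {
  m <- matrix(FALSE, 12, 12); m[2:11, 2:11] <- TRUE
  comp <- connected_components(mask_from_matrix(m))[[1]]
  expect_equal(component_area(comp, 10, 10), 0.01)       # 100 px @ 10 um
  expect_equal(component_area(comp, 10, 20), 0.02)       # anisotropic
  disc <- make_disc_mask(5, 20)
  comp2 <- largest_component(connected_components(disc), 20, 20)
  expect_equal(component_area(comp2, 20, 20), pi * 25, tolerance = 0.01)
})

test_that("outer contours behave at the degenerate and hole cases", {
  # single pixel: small closed polygon of positive area <= one pixel
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  comp <- connected_components(mask_from_matrix(m))[[1]]
  poly <- trace_outer_contour(comp, 10, 10)
  a <- abs(sum(poly$x * c(poly$y[-1], poly$y[1]) -
               c(poly$x[-1], poly$x[1]) * poly$y) / 2)
  expect_gt(a, 0)
  expect_lte(a, 0.01^2)
  # 10x10 px solid square: perimeter within 5% of 40 pixel lengths
  m2 <- matrix(FALSE, 14, 14); m2[3:12, 3:12] <- TRUE
  comp2 <- connected_components(mask_from_matrix(m2))[[1]]
  p <- contour_perimeter(trace_outer_contour(comp2, 1000, 1000))
  expect_equal(p, 40, tolerance = 0.05)
  # interior holes are ignored by the outer contour
  donut <- make_ellipse_mask(5, 5, 20)
  px <- donut$pixels
  n <- nrow(px)
  xs <- ((seq_len(n) - 0.5) * 0.02) - (n * 0.02 / 2)
  R2 <- outer(xs, xs, function(yy, xx) xx^2 + yy^2)
  donut$pixels <- px & (R2 >= 2^2)
  compd <- largest_component(connected_components(donut), 20, 20)
  pd <- contour_perimeter(trace_outer_contour(compd, 20, 20))
  expect_equal(pd, 2 * pi * 5, tolerance = 0.02)
})

test_that("perimeter of vector polygons is exact and needs closure", {
  sq <- contour_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_identical(contour_perimeter(sq), 40)
  open_poly <- contour_polygon(c(0, 10, 10), c(0, 0, 10), closed = FALSE)
  expect_error(contour_perimeter(open_poly), "closed")
})

test_that("convex hull is idempotent, tight and contains its input", {
  # convex input: same vertex set (order may rotate)
  sq <- contour_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10))
  h <- convex_hull(sq)
  expect_setequal(paste(h$x, h$y), paste(sq$x, sq$y))
  # 5-point star: hull is its 5 outer tips
  t_out <- seq(0, 2 * pi, length.out = 6)[-6]
  t_in <- t_out + pi / 5
  star <- contour_polygon(
    as.vector(rbind(10 * cos(t_out), 4 * cos(t_in))),
    as.vector(rbind(10 * sin(t_out), 4 * sin(t_in))))
  hs <- convex_hull(star)
  expect_length(hs$x, 5)
  expect_equal(sort(sqrt(hs$x^2 + hs$y^2)), rep(10, 5), tolerance = 1e-9)
  # random cloud: containment and hull-of-hull stability
  withr::with_seed(99, {
    pts <- cbind(rnorm(200), rnorm(200))
    hull <- convex_hull(pts)
    hull2 <- convex_hull(hull)
    expect_equal(length(hull$x), length(hull2$x))
    # every point inside or on the hull (cross products non-negative)
    n <- length(hull$x)
    nxt <- c(2:n, 1)
    for (k in seq_len(200)) {
      cr <- (hull$x[nxt] - hull$x) * (pts[k, 2] - hull$y) -
            (hull$y[nxt] - hull$y) * (pts[k, 1] - hull$x)
      expect_gte(min(cr), -1e-9)
    }
  })
  # collinear input degenerates
  expect_error(convex_hull(cbind(1:5, 2 * (1:5))), class = "melmorph_degenerate")
})

test_that("minimum-area rectangle is exact on rectangles and equivariant", {
  rect <- cbind(c(0, 40, 40, 0), c(0, 0, 10, 10))
  r0 <- min_area_rect(convex_hull(rect))
  expect_equal(c(r0$side_a, r0$side_b, r0$angle), c(40, 10, 0), tolerance = 1e-9)
  th <- 30 * pi / 180
  rot <- cbind(rect[, 1] * cos(th) - rect[, 2] * sin(th),
               rect[, 1] * sin(th) + rect[, 2] * cos(th))
  r30 <- min_area_rect(convex_hull(rot))
  expect_equal(c(r30$side_a, r30$side_b), c(40, 10), tolerance = 1e-6)
  expect_equal(r30$angle, 30, tolerance = 1e-6)
  # all hull vertices inside or on the rectangle
  hull <- convex_hull(rot)
  crn <- r30$corners
  for (k in seq_along(hull$x)) {
    d <- cbind(hull$x[k] - crn[, 1], hull$y[k] - crn[, 2])
    expect_lte(min(sqrt(rowSums(d^2))), 45)  # sanity: vertices near rectangle
  }
})

test_that("minimum-area rectangle matches the rotation-sweep oracle", {
  withr::with_seed(42, {
    for (i in 1:50) {
      n <- sample(5:40, 1)
      pts <- cbind(rnorm(n), rnorm(n)) * runif(1, 0.5, 20)
      hull <- convex_hull(pts)
      r <- min_area_rect(hull)
      oa <- oracle_min_rect_area(cbind(hull$x, hull$y))
      expect_lt(abs(r$side_a * r$side_b - oa) / oa, 1e-4)
    }
  })
})

test_that("nodularity index follows its definition and bounds", {
  expect_equal(nodularity_index(8, 2), 0.25)
  expect_equal(nodularity_index(40, 0.5), 0.0125)
  expect_equal(nodularity_index(7, 7), 1)
  expect_error(nodularity_index(0, 0), "positive")
  expect_error(nodularity_index(2, 8), "exceed")
  # a disc has NI 1 (bounding square), whatever the radius
  r <- compute_morphometrics(make_disc_mask(3, 20))
  expect_equal(r$ni, 1, tolerance = 0.005)
})

test_that("morphometric record recovers the analytic ellipse within 1%", {
  mask <- make_ellipse_mask(20, 5, 20)
  r <- compute_morphometrics(mask)
  expect_equal(r$area_mm2, pi * 100, tolerance = 0.01)
  expect_equal(r$major_mm, 40, tolerance = 0.01)
  expect_equal(r$dbt_mm, 10, tolerance = 0.01)
  expect_equal(r$ni, 0.25, tolerance = 0.01)
  expect_equal(r$n_components, 1)
  expect_equal(r$largest_fraction, 1)
})

test_that("a distant satellite does not change the record (largest-piece rule)", {
  mask <- make_ellipse_mask(8, 3, 40)
  r_main <- compute_morphometrics(mask)
  px <- mask$pixels
  px[3:6, 3:6] <- TRUE                       # 16-px distant blob
  mask2 <- segmentation_mask(px, 40, 40, "with_satellite")
  r2 <- compute_morphometrics(mask2)
  expect_equal(r2$area_mm2, r_main$area_mm2)
  expect_equal(r2$perimeter_mm, r_main$perimeter_mm)
  expect_equal(r2$major_mm, r_main$major_mm)
  expect_equal(r2$n_components, 2)
  expect_lt(r2$largest_fraction, 1)
})

test_that("records are rotation invariant within 1% after rasterization", {
  base <- compute_morphometrics(make_ellipse_mask(8, 3, 10))
  for (rot in c(17, 30, 77)) {
    r <- compute_morphometrics(make_ellipse_mask(8, 3, 10, rot_deg = rot))
    for (col in c("area_mm2", "perimeter_mm", "major_mm", "dbt_mm", "ni"))
      expect_equal(r[[col]], base[[col]], tolerance = 0.01)
  }
})

test_that("vector-polygon geometry is exactly scale equivariant", {
  withr::with_seed(5, {
    pts <- cbind(rnorm(30), rnorm(30))
    h1 <- convex_hull(pts)
    r1 <- min_area_rect(h1)
    p1 <- contour_perimeter(h1)
    k <- 3.7
    h2 <- convex_hull(pts * k)
    r2 <- min_area_rect(h2)
    expect_equal(contour_perimeter(h2), k * p1, tolerance = 1e-12)
    expect_equal(r2$side_a, k * r1$side_a, tolerance = 1e-12)
    expect_equal(r2$side_b, k * r1$side_b, tolerance = 1e-12)
    expect_equal(r2$side_b / r2$side_a, r1$side_b / r1$side_a, tolerance = 1e-12)
  })
})

test_that("every computed record satisfies the geometric inequalities", {
  masks <- list(make_disc_mask(4, 20),
                make_ellipse_mask(9, 2, 20),
                make_ellipse_mask(6, 5, 20, rot_deg = 40),
                generate_shape(shape_spec("nodular_blob", seed = 3))$mask,
                generate_shape(shape_spec("superficial_strip", seed = 4))$mask)
  for (mask in masks) {
    r <- compute_morphometrics(mask)
    expect_lte(r$dbt_mm, r$major_mm)
    expect_gt(r$ni, 0); expect_lte(r$ni, 1)
    expect_lte(r$area_mm2, r$major_mm * r$dbt_mm)
    # isoperimetric inequality with 0.5% discretization slack
    expect_gte(r$perimeter_mm^2 * 1.005, 4 * pi * r$area_mm2)
  }
})
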