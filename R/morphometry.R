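# Derivation of the five objective morphological tumour parameters from a
# calibrated binary mask: area, perimeter, major axis length, digital
# Breslow thickness (dBT) and Nodularity Index (NI).
#
# All parameters are computed on the largest 8-connected piece of
# segmented tumour only, which makes serially-sliced specimens (several
# tumour profiles in one block) behave like single-profile slides.
# Major/minor axis lengths are the side lengths of the minimum-AREA
# enclosing rectangle of the tumour outline, obtained by rotating
# calipers over the convex hull (the optimal rectangle has one side
# collinear with a hull edge).

# signed polygon area; positive for the orientation convention used for
# outer boundaries (y increases down the image)
.shoelace <- function(x, y) {
  n <- length(x)
  nxt <- c(2:n, 1)
  sum(x * y[nxt] - x[nxt] * y) / 2
}

#' Label 8-connected foreground components of a mask
#'
#' Components are returned in row-major first-encounter order, which fixes
#' the tie-break used by [largest_component()].
#'
#' @param mask a [segmentation_mask()].
#' @return list of `tumour_component` objects (empty for an empty mask),
#'   each with `pixels` (n x 2 row/col indices), `pixel_count` and `bbox`
#'   (`rmin, rmax, cmin, cmax`).
#' @export
connected_components <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  lab <- label_components_8(mask$pixels)
  k <- attr(lab, "n_components")
  if (k == 0L) return(list())
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  lapply(seq_len(k), function(i) {
    px <- idx[labs == i, , drop = FALSE]
    structure(list(pixels = px,
                   pixel_count = nrow(px),
                   bbox = c(rmin = min(px[, 1]), rmax = max(px[, 1]),
                            cmin = min(px[, 2]), cmax = max(px[, 2]))),
              class = "tumour_component")
  })
}

#' Select the largest piece of segmented tumour
#'
#' "Largest" means largest physical area (pixel count weighted by the
#' pixel footprint); with a tie the first component in row-major scan
#' order wins.  An empty component list raises a condition of class
#' `melmorph_no_tumour`, distinct from I/O errors, so callers can count
#' no-tumour slides.
#'
#' @param components list from [connected_components()].
#' @param mpp_x,mpp_y calibration in microns per pixel.
#' @return the selected `tumour_component`.
#' @export
largest_component <- function(components, mpp_x, mpp_y) {
  if (!length(components))
    stop_melmorph("no tumour detected: mask has no foreground component",
                  "melmorph_no_tumour")
  areas <- vapply(components, function(cmp) cmp$pixel_count, numeric(1)) *
    mpp_x * mpp_y
  components[[which.max(areas)]]   # which.max takes the first maximum
}

#' Physical area of a component in mm^2
#'
#' Area is the foreground pixel count times the pixel footprint; enclosed
#' background (holes) is not counted.
#'
#' @param comp a `tumour_component`.
#' @param mpp_x,mpp_y calibration in microns per pixel.
#' @return area in mm^2.
#' @export
component_area <- function(comp, mpp_x, mpp_y) {
  comp$pixel_count * (mpp_x / 1000) * (mpp_y / 1000)
}

# circular moving average; relaxes residual staircase noise on contours
# extracted from raw (unsmoothed) binary fields
.smooth_closed <- function(v, w = 3L) {
  n <- length(v)
  out <- v
  half <- (w - 1L) %/% 2L
  for (k in seq.int(-half, half)) out <- out + v[((seq_len(n) - 1 + k) %% n) + 1]
  (out - v) / w
}

# separable Gaussian smoothing of a zero-padded indicator matrix
.blur_indicator <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  out <- stats::filter(m, k, sides = 2)          # along columns
  out <- t(stats::filter(t(out), k, sides = 2))  # along rows
  out[is.na(out)] <- 0
  out
}

# smoothing scale (pixels) of the iso-contour extraction; field smoothing
# is only worthwhile for components comfortably larger than the kernel --
# smaller components keep the raw iso-contour, whose staircase excess
# (~1%) is negligible at their size
.contour_sigma <- 1.5
.blur_min_bbox_px <- 24L

#' Trace the sub-pixel outer contour of a component
#'
#' The component is rendered alone on a zero-padded grid; the indicator is
#' smoothed with a small Gaussian (sigma 1.5 px) and its 0.5 iso-level
#' extracted by marching squares, giving a closed sub-pixel polygon in mm
#' coordinates.  Smoothing the field rather than the polygon makes the
#' boundary estimate unbiased for straight edges and removes the
#' staircase excess of raw binary iso-contours (which would otherwise
#' inflate perimeters by a resolution-independent ~1%); foreground pixel
#' centres are clamped to stay at or above the iso-level so thin necks
#' cannot split the contour.  Components too small to smooth (under 16
#' pixels or under 4 px across) fall back to the raw binary iso-contour
#' with a light vertex moving average.  Hole boundaries are discarded:
#' only the ring with the largest absolute area is kept.
#'
#' @param comp a `tumour_component`.
#' @param mpp_x,mpp_y calibration in microns per pixel.
#' @return a `contour_polygon`: list with `x`, `y` (mm, first vertex not
#'   repeated) and `closed = TRUE`, oriented so the signed area is
#'   positive.
#' @export
trace_outer_contour <- function(comp, mpp_x, mpp_y) {
  bb <- comp$bbox
  min_bbox_px <- min(bb["rmax"] - bb["rmin"], bb["cmax"] - bb["cmin"]) + 1L
  sigma <- .contour_sigma
  use_blur <- comp$pixel_count >= 16L && min_bbox_px >= .blur_min_bbox_px
  pad <- if (use_blur) ceiling(3 * sigma) + 2L else 2L
  nr <- bb["rmax"] - bb["rmin"] + 2L * pad - 1L
  nc <- bb["cmax"] - bb["cmin"] + 2L * pad - 1L
  m <- matrix(0, nr, nc)
  ij <- cbind(comp$pixels[, 1] - bb["rmin"] + pad,
              comp$pixels[, 2] - bb["cmin"] + pad)
  m[ij] <- 1
  z <- if (use_blur) pmax(.blur_indicator(m, sigma), m * 0.501) else m
  cl <- grDevices::contourLines(x = seq_len(nr), y = seq_len(nc), z = z,
                                levels = 0.5)
  areas <- vapply(cl, function(g) abs(.shoelace(g$x, g$y)), numeric(1))
  ring <- cl[[which.max(areas)]]
  row_f <- ring$x + (bb["rmin"] - pad)   # back to mask pixel coordinates
  col_f <- ring$y + (bb["cmin"] - pad)
  n <- length(row_f)
  if (row_f[1] == row_f[n] && col_f[1] == col_f[n]) {
    row_f <- row_f[-n]; col_f <- col_f[-n]
  }
  x <- (col_f - 0.5) * mpp_x / 1000
  y <- (row_f - 0.5) * mpp_y / 1000
  if (use_blur && length(x) >= 12L) {
    x <- .smooth_closed(x)
    y <- .smooth_closed(y)
  }
  if (.shoelace(x, y) < 0) { x <- rev(x); y <- rev(y) }
  structure(list(x = as.numeric(x), y = as.numeric(y), closed = TRUE),
            class = "contour_polygon")
}

#' Create a contour polygon from vertex coordinates
#' @param x,y vertex coordinates in mm (first vertex not repeated).
#' @param closed whether the polygon is closed.
#' @return a `contour_polygon`.
#' @export
contour_polygon <- function(x, y, closed = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  if (closed && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  structure(list(x = as.numeric(x), y = as.numeric(y), closed = isTRUE(closed)),
            class = "contour_polygon")
}

#' Perimeter of a closed contour polygon (mm)
#' @param poly a `contour_polygon`.
#' @return total Euclidean edge length including the closing edge.
#' @export
contour_perimeter <- function(poly) {
  stopifnot(inherits(poly, "contour_polygon"))
  if (!isTRUE(poly$closed)) stop("perimeter is only defined for closed polygons")
  n <- length(poly$x)
  nxt <- c(2:n, 1)
  sum(sqrt((poly$x[nxt] - poly$x)^2 + (poly$y[nxt] - poly$y)^2))
}

#' Convex hull of a contour polygon
#'
#' @param poly a `contour_polygon`, or an n x 2 matrix of points.
#' @return a `contour_polygon` whose vertices are the hull's extreme
#'   points with positive signed area and no three collinear consecutive
#'   vertices.  All-collinear input raises a `melmorph_degenerate`
#'   condition.
#' @export
convex_hull <- function(poly) {
  pts <- if (inherits(poly, "contour_polygon")) cbind(poly$x, poly$y)
         else as.matrix(poly)
  if (nrow(pts) < 3L)
    stop_melmorph("convex hull needs at least 3 vertices", "melmorph_degenerate")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) >= 3L && .shoelace(hp[, 1], hp[, 2]) < 0)
    hp <- hp[rev(seq_len(nrow(hp))), , drop = FALSE]
  # drop residual collinear triples
  scale2 <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))^2
  repeat {
    n <- nrow(hp)
    if (n < 3L) break
    prv <- c(n, 1:(n - 1)); nxt <- c(2:n, 1)
    cross <- (hp[, 1] - hp[prv, 1]) * (hp[nxt, 2] - hp[, 2]) -
             (hp[, 2] - hp[prv, 2]) * (hp[nxt, 1] - hp[, 1])
    drop <- abs(cross) <= 1e-12 * scale2
    if (!any(drop)) break
    hp <- hp[!drop, , drop = FALSE]
  }
  if (nrow(hp) < 3L)
    stop_melmorph("degenerate hull: input points are collinear",
                  "melmorph_degenerate")
  contour_polygon(hp[, 1], hp[, 2])
}

#' Minimum-area enclosing rectangle by rotating calipers
#'
#' Enumerates hull edges as candidate flush sides (the minimum-area
#' enclosing rectangle of a convex polygon has one side collinear with a
#' polygon edge) and takes the orientation with the smallest area; ties
#' resolve to the smallest angle.
#'
#' @param hull convex `contour_polygon` from [convex_hull()].
#' @param case_id optional identifier used in error messages.
#' @return a `bounding_rect`: list with `centre` (mm), `angle` (degrees in
#'   \[0, 90), rectangle orientation modulo 90), `side_a` (major axis
#'   length, mm), `side_b` (minor axis length = dBT, mm) and `corners`
#'   (4 x 2 matrix, mm).
#' @export
min_area_rect <- function(hull, case_id = NULL) {
  stopifnot(inherits(hull, "contour_polygon"))
  x <- hull$x; y <- hull$y
  n <- length(x)
  if (n < 3L)
    stop_melmorph("degenerate hull passed to min_area_rect", "melmorph_degenerate")
  nxt <- c(2:n, 1)
  ex <- x[nxt] - x; ey <- y[nxt] - y
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  best <- NULL
  for (i in which(keep)) {
    dx <- ex[i] / len[i]; dy <- ey[i] / len[i]
    p1 <- x * dx + y * dy          # projection on edge direction
    p2 <- -x * dy + y * dx         # projection on edge normal
    w <- max(p1) - min(p1)
    h <- max(p2) - min(p2)
    a <- w * h
    ang <- (atan2(dy, dx) * 180 / pi) %% 90
    cand <- list(area = a, w = w, h = h, angle = ang,
                 c1 = (min(p1) + max(p1)) / 2, c2 = (min(p2) + max(p2)) / 2,
                 dx = dx, dy = dy)
    if (is.null(best) || a < best$area * (1 - 1e-12) ||
        (a <= best$area * (1 + 1e-12) && ang < best$angle)) {
      best <- cand
    }
  }
  if (is.null(best) || min(best$w, best$h) <= 1e-12)
    stop_melmorph(sprintf("degenerate (zero-width) geometry%s",
                          if (is.null(case_id)) "" else paste0(" for case ", case_id)),
                  "melmorph_degenerate")
  centre <- c(x = best$c1 * best$dx - best$c2 * best$dy,
              y = best$c1 * best$dy + best$c2 * best$dx)
  hw <- best$w / 2; hh <- best$h / 2
  sgn <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  corners <- cbind(
    centre[1] + sgn[, 1] * hw * best$dx - sgn[, 2] * hh * best$dy,
    centre[2] + sgn[, 1] * hw * best$dy + sgn[, 2] * hh * best$dx)
  structure(list(centre = centre,
                 angle = best$angle,
                 side_a = max(best$w, best$h),
                 side_b = min(best$w, best$h),
                 corners = corners),
            class = "bounding_rect")
}

#' Nodularity Index
#'
#' NI = minor axis length / major axis length of the minimum enclosing
#' rectangle; a size-independent shape metric in (0, 1] measuring tumour
#' depth per unit width (1 = maximally nodular).
#'
#' @param major_axis,minor_axis rectangle side lengths in mm.
#' @return dimensionless NI.
#' @export
nodularity_index <- function(major_axis, minor_axis) {
  if (!is.finite(major_axis) || !is.finite(minor_axis) ||
      minor_axis <= 0 || major_axis <= 0)
    stop("axis lengths must be positive")
  if (minor_axis > major_axis)
    stop("minor axis must not exceed major axis")
  minor_axis / major_axis
}

#' Compute the five morphological biomarkers for one mask
#'
#' Selects the largest 8-connected piece of tumour and derives: area
#' (mm^2, foreground pixels of that piece), perimeter (mm, sub-pixel outer
#' contour, hole boundaries excluded), major axis length and digital
#' Breslow thickness (mm, sides of the minimum-area enclosing rectangle)
#' and the Nodularity Index.  `n_components` and `largest_fraction`
#' (fraction of all foreground pixels belonging to the analysed piece) are
#' reported for QC, together with the rectangle angle for audit.
#'
#' @param mask a [segmentation_mask()] with at least one foreground pixel.
#' @return one-row data frame (a morphometric record).
#' @export
compute_morphometrics <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  comps <- connected_components(mask)
  comp <- largest_component(comps, mask$mpp_x, mask$mpp_y)
  total_px <- sum(vapply(comps, function(cmp) cmp$pixel_count, numeric(1)))
  contour <- trace_outer_contour(comp, mask$mpp_x, mask$mpp_y)
  rect <- min_area_rect(convex_hull(contour), case_id = mask$case_id)
  data.frame(
    case_id = mask$case_id,
    area_mm2 = component_area(comp, mask$mpp_x, mask$mpp_y),
    perimeter_mm = contour_perimeter(contour),
    major_mm = rect$side_a,
    dbt_mm = rect$side_b,
    ni = nodularity_index(rect$side_a, rect$side_b),
    n_components = length(comps),
    largest_fraction = comp$pixel_count / total_px,
    rect_angle_deg = rect$angle,
    stringsAsFactors = FALSE)
}
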