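# Reading calibrated segmentation masks, polygon regions and cohort tables.
#
# Conventions used throughout the package:
#   * pixel calibration (mpp) is in microns per pixel, one value per axis;
#   * pixel (i, j) (1-based row/column) has its physical centre at
#     x = (j - 0.5) * mpp_x / 1000 mm, y = (i - 0.5) * mpp_y / 1000 mm,
#     with y increasing down the image;
#   * any non-zero pixel value is foreground ("invasive melanoma") -- the
#     upstream segmentation is strictly two-class.

check_mpp <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop_melmorph(
      sprintf("calibration error: %s must be a positive micron-per-pixel value (got %s)",
              name, paste(format(value), collapse = ", ")),
      "melmorph_calibration_error")
  }
  as.numeric(value)
}

#' Construct a calibrated binary segmentation mask
#'
#' @param pixels logical (or numeric, thresholded at > 0) matrix; `TRUE`
#'   marks invasive melanoma.
#' @param mpp_x,mpp_y microns per pixel along image columns / rows.
#' @param case_id case identifier carried through to the morphometric record.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(pixels, mpp_x, mpp_y, case_id = "case") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("mask must have at least one row and one column")
  if (is.numeric(pixels)) pixels <- pixels > 0
  if (!is.logical(pixels)) stop("pixels must be logical or numeric")
  if (anyNA(pixels)) stop("mask pixels must not contain missing values")
  structure(
    list(pixels = pixels,
         mpp_x = check_mpp(mpp_x, "mpp_x"),
         mpp_y = check_mpp(mpp_y, "mpp_y"),
         case_id = as.character(case_id)),
    class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %s: %d x %d px @ %.3g x %.3g um/px, %d foreground px\n",
              x$case_id, nrow(x$pixels), ncol(x$pixels), x$mpp_x, x$mpp_y,
              sum(x$pixels)))
  invisible(x)
}

# Resolution tags are trusted only inside the plausible whole-slide range;
# a silently wrong physical unit is the worst possible failure mode here.
.mpp_plausible <- function(mpp) is.finite(mpp) && mpp >= 0.1 && mpp <= 10

.mpp_from_tiff_tags <- function(img) {
  rx <- attr(img, "x.resolution")
  ry <- attr(img, "y.resolution")
  unit <- attr(img, "resolution.unit") %||% "inch"
  if (is.null(rx) || is.null(ry) || !is.numeric(rx) || !is.numeric(ry) ||
      rx <= 0 || ry <= 0) return(NULL)
  per_unit_um <- switch(unit, inch = 25400, cm = 10000, NULL)
  if (is.null(per_unit_um)) return(NULL)
  mpp <- c(per_unit_um / rx, per_unit_um / ry)
  if (.mpp_plausible(mpp[1]) && .mpp_plausible(mpp[2])) mpp else NULL
}

#' Read a segmentation mask from an 8-bit grey PNG or TIFF
#'
#' Any pixel value greater than zero is treated as invasive melanoma.
#' For TIFF input, x/y resolution tags are used as calibration when both
#' are present and within the plausible 0.1-10 um/px range; explicit
#' `mpp_x`/`mpp_y` arguments always override tags, and are mandatory for
#' PNG input (which carries no trusted physical resolution).
#'
#' @param path path to a single-channel PNG or TIFF file.
#' @param mpp_x,mpp_y microns per pixel; may be omitted only for TIFF with
#'   plausible resolution tags.
#' @param case_id defaults to the file name without extension.
#' @return A [segmentation_mask()].
#' @export
read_mask <- function(path, mpp_x = NULL, mpp_y = NULL, case_id = NULL) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  tag_mpp <- NULL
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    tag_mpp <- .mpp_from_tiff_tags(img)
  } else {
    stop(sprintf("unsupported mask format '%s' (PNG or TIFF expected)", ext))
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1]
    } else {
      stop(sprintf("multi-channel image (%d channels): masks must be single-channel grey",
                   dim(img)[3]))
    }
  }
  mpp_x <- mpp_x %||% tag_mpp[1]
  mpp_y <- mpp_y %||% tag_mpp[2]
  if (is.null(mpp_x) || is.null(mpp_y)) {
    stop_melmorph(
      sprintf("calibration error: no mpp supplied for %s and no plausible TIFF resolution tags",
              basename(path)),
      "melmorph_calibration_error")
  }
  segmentation_mask(img > 0, mpp_x, mpp_y,
                    case_id %||% tools::file_path_sans_ext(basename(path)))
}

# Region sets (vector alternative to pixel masks) ---------------------------

#' Construct a polygon region set
#'
#' A region set is a list of polygons in millimetre coordinates; each
#' polygon is a list of rings (closed vertex sequences), the first being
#' the outer boundary and the remainder holes.  Ring closure is implicit:
#' a repeated final vertex is accepted and dropped.
#'
#' @param polygons list of polygons; each polygon a list of n x 2 numeric
#'   matrices (x, y in mm).
#' @param case_id case identifier.
#' @return An object of class `region_set`.
#' @export
region_set <- function(polygons, case_id = "case") {
  if (!length(polygons)) stop("region set must contain at least one polygon")
  polygons <- lapply(polygons, function(poly) {
    if (is.matrix(poly)) poly <- list(poly)
    lapply(poly, function(ring) {
      ring <- as.matrix(ring)
      if (ncol(ring) != 2L) stop("rings must be n x 2 matrices of mm coordinates")
      n <- nrow(ring)
      if (n >= 2L && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
      if (nrow(ring) < 3L) stop("every ring needs at least 3 distinct vertices")
      ring
    })
  })
  structure(list(case_id = as.character(case_id), polygons = polygons),
            class = "region_set")
}

#' Read polygon regions from GeoJSON (coordinates in mm)
#'
#' Supports Polygon and MultiPolygon geometries, bare or wrapped in
#' Feature / FeatureCollection objects.  Inner rings are holes.
#'
#' @param path GeoJSON file.
#' @param case_id defaults to a `case_id` property when present, else the
#'   file name.
#' @return A [region_set()].
#' @export
read_regions_geojson <- function(path, case_id = NULL) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- list()
  props_id <- NULL
  collect <- function(obj) {
    type <- obj$type %||% ""
    if (type == "FeatureCollection") {
      for (f in obj$features) collect(f)
    } else if (type == "Feature") {
      props_id <<- props_id %||% obj$properties$case_id
      collect(obj$geometry)
    } else if (type %in% c("Polygon", "MultiPolygon")) {
      geoms[[length(geoms) + 1L]] <<- obj
    } else {
      stop(sprintf("unsupported GeoJSON geometry '%s'", type))
    }
  }
  collect(js)
  ring_mat <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  polygons <- list()
  for (g in geoms) {
    polys <- if (g$type == "Polygon") list(g$coordinates) else g$coordinates
    for (p in polys)
      polygons[[length(polygons) + 1L]] <- lapply(p, ring_mat)
  }
  region_set(polygons,
             case_id %||% props_id %||% tools::file_path_sans_ext(basename(path)))
}

# Even-odd scanline fill of one polygon (outer ring + holes).
.fill_polygon <- function(rings, xs, ys) {
  x1 <- numeric(0); y1 <- numeric(0); x2 <- numeric(0); y2 <- numeric(0)
  for (ring in rings) {
    n <- nrow(ring)
    nxt <- c(2:n, 1)
    x1 <- c(x1, ring[, 1]); y1 <- c(y1, ring[, 2])
    x2 <- c(x2, ring[nxt, 1]); y2 <- c(y2, ring[nxt, 2])
  }
  inside <- matrix(FALSE, length(ys), length(xs))
  for (i in seq_along(ys)) {
    y0 <- ys[i]
    cross <- (y1 <= y0 & y2 > y0) | (y2 <= y0 & y1 > y0)
    if (!any(cross)) next
    xint <- x1[cross] + (y0 - y1[cross]) / (y2[cross] - y1[cross]) *
      (x2[cross] - x1[cross])
    inside[i, ] <- (findInterval(xs, sort(xint)) %% 2L) == 1L
  }
  inside
}

#' Rasterize a polygon region set to a segmentation mask
#'
#' A pixel is foreground iff its centre lies inside an outer ring and
#' outside that ring's holes (even-odd rule).  The grid covers the
#' regions' bounding box plus a one-pixel background margin.
#'
#' @param regions a [region_set()].
#' @param mpp_x,mpp_y target calibration in microns per pixel.
#' @return A [segmentation_mask()]; its `origin_mm` attribute records the
#'   physical coordinate of the grid origin.
#' @export
rasterize_regions <- function(regions, mpp_x, mpp_y) {
  stopifnot(inherits(regions, "region_set"))
  mpp_x <- check_mpp(mpp_x, "mpp_x")
  mpp_y <- check_mpp(mpp_y, "mpp_y")
  sx <- mpp_x / 1000; sy <- mpp_y / 1000
  all_pts <- do.call(rbind, unlist(regions$polygons, recursive = FALSE))
  xr <- range(all_pts[, 1]); yr <- range(all_pts[, 2])
  area <- sum(vapply(regions$polygons, function(p)
    abs(.shoelace(p[[1]][, 1], p[[1]][, 2])), numeric(1)))
  if (area <= 0) stop("degenerate region set: zero total outer-ring area")
  nc <- ceiling((xr[2] - xr[1]) / sx) + 2L
  nr <- ceiling((yr[2] - yr[1]) / sy) + 2L
  ox <- xr[1] - sx; oy <- yr[1] - sy
  xs <- ox + (seq_len(nc) - 0.5) * sx
  ys <- oy + (seq_len(nr) - 0.5) * sy
  fg <- matrix(FALSE, nr, nc)
  for (poly in regions$polygons) fg <- fg | .fill_polygon(poly, xs, ys)
  if (!any(fg)) stop("degenerate region set: no pixel centre falls inside any region")
  out <- segmentation_mask(fg, mpp_x, mpp_y, regions$case_id)
  attr(out, "origin_mm") <- c(x = ox, y = oy)
  out
}

# Tables --------------------------------------------------------------------

.morph_cols <- c("case_id", "area_mm2", "perimeter_mm", "major_mm", "dbt_mm",
                 "ni", "n_components", "largest_fraction", "rect_angle_deg")

#' Write a per-case morphometrics table as CSV
#'
#' Lengths/areas are serialized at 3 decimal places (mm / mm2) and the
#' Nodularity Index at 4; internal computation is always full precision.
#'
#' @param records data frame of morphometric records as produced by
#'   [compute_morphometrics()] (one row per case).
#' @param path output CSV path.
#' @export
write_morphometrics_table <- function(records, path) {
  records <- as.data.frame(records)
  missing <- setdiff(.morph_cols, names(records))
  if (length(missing))
    stop(sprintf("morphometric records lack column(s): %s",
                 paste(missing, collapse = ", ")))
  records <- records[, .morph_cols]
  for (col in c("area_mm2", "perimeter_mm", "major_mm", "dbt_mm"))
    records[[col]] <- round(records[[col]], 3)
  records$ni <- round(records$ni, 4)
  records$largest_fraction <- round(records$largest_fraction, 4)
  records$rect_angle_deg <- round(records$rect_angle_deg, 2)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a morphometrics table written by [write_morphometrics_table()]
#' @param path CSV path.
#' @return data frame of morphometric records.
#' @export
read_morphometrics_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.morph_cols, names(tab))
  if (length(missing))
    stop(sprintf("schema error: morphometrics table missing column(s): %s",
                 paste(missing, collapse = ", ")))
  tab
}

.cohort_mandatory <- c("case_id", "time_os", "event_os", "time_mss",
                       "event_mss", "age", "sex", "site")
.cohort_numeric <- c("time_os", "event_os", "time_mss", "event_mss", "age",
                     "area_mm2", "perimeter_mm", "major_mm", "dbt_mm", "ni",
                     "breslow_mm")

.parse_numeric_col <- function(x, col) {
  raw <- trimws(as.character(x))
  raw[raw %in% c("", "NA", "Unknown", "unknown")] <- NA
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(out))
  if (length(bad))
    stop(sprintf("parse error: non-numeric value '%s' in column '%s' (row %d)",
                 raw[bad[1]], col, bad[1]))
  out
}

.parse_level_col <- function(x, levels) {
  raw <- tolower(trimws(as.character(x)))
  raw[!(raw %in% levels)] <- NA   # "Unknown" and friends become missing
  raw
}

#' Read a per-case cohort table (CSV or TSV)
#'
#' The mandatory schema is `case_id, time_os, event_os, time_mss,
#' event_mss, age, sex, site`; morphometric columns (`area_mm2`,
#' `perimeter_mm`, `major_mm`, `dbt_mm`, `ni`) and clinical extras
#' (`breslow_mm`, `ajcc_stage`, `subtype`, `ulceration`, ...) are carried
#' through when present.  Unrecognised categorical levels (e.g.
#' `"Unknown"`) become missing values; the row is retained.
#'
#' @param path CSV (`,`) or TSV (tab) file with a header row.
#' @return data frame, one row per case.
#' @export
read_cohort_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  missing <- setdiff(.cohort_mandatory, names(tab))
  if (length(missing))
    stop(sprintf("schema error: cohort table missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  for (col in intersect(.cohort_numeric, names(tab)))
    tab[[col]] <- .parse_numeric_col(tab[[col]], col)
  tab$sex <- .parse_level_col(tab$sex, c("male", "female"))
  tab$site <- .parse_level_col(tab$site, c("central", "peripheral"))
  for (col in c("time_os", "time_mss")) {
    bad <- which(tab[[col]] < 0)
    if (length(bad))
      stop(sprintf("negative survival time in column '%s' (row %d)", col, bad[1]))
  }
  for (col in c("event_os", "event_mss")) {
    if (any(!tab[[col]] %in% c(0, 1), na.rm = TRUE))
      stop(sprintf("column '%s' must be binary 0/1", col))
  }
  tab$case_id <- as.character(tab$case_id)
  tab
}

#' Write a cohort table as CSV
#' @param cohort data frame in the cohort schema.
#' @param path output path.
#' @export
write_cohort_table <- function(cohort, path) {
  missing <- setdiff(.cohort_mandatory, names(cohort))
  if (length(missing))
    stop(sprintf("cohort table missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
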