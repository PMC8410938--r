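# Atlas layouts, vessel masks, rasterisation and region-averaged traces.
#
# Coordinate conventions (recorded here once, used everywhere):
#   * image row 1 is the top of the frame and maps to rostral;
#   * atlas x is millimetres lateral of bregma (positive right),
#     atlas y is millimetres rostro-caudal (positive rostral);
#   * a pixel (r, c) is "inside" a region when its centre lies inside the
#     polygon, with boundary pixels counted as inside (inclusive tie-break).

#' Atlas layout for one imaging window
#'
#' Couples named cortical region polygons (millimetres relative to bregma)
#' with the bregma pixel, midline orientation and pixel size of a specific
#' window, as required to rasterise the atlas onto that window.
#'
#' @param regions Named list of polygons; each a matrix/data frame with
#'   columns `x` (mm lateral) and `y` (mm rostral). Defaults to the packaged
#'   approximate layout for S1FL, S1HL, S1BF, M1 and M2.
#' @param bregma_px Bregma position as c(row, col) in (binned) pixels.
#' @param midline_angle Rotation (degrees, counter-clockwise in image
#'   coordinates) of the midline away from the image vertical.
#' @param pixel_size Pixel size in micrometres per (binned) pixel.
#' @return Object of class `atlas_layout`.
#' @export
atlas_layout <- function(regions = NULL, bregma_px, midline_angle = 0,
                         pixel_size = 14.55) {
  if (is.null(regions)) regions <- read_atlas_regions()
  regions <- lapply(regions, function(p) {
    p <- as.matrix(as.data.frame(p)[, c("x", "y")])
    if (nrow(p) < 3) abort("each region polygon needs at least 3 vertices")
    if (polygon_self_intersects(p)) {
      abort("region polygons must be non-self-intersecting")
    }
    p
  })
  if (anyDuplicated(names(regions))) abort("region names must be unique")
  if (pixel_size <= 0) abort("pixel_size must be > 0")
  structure(list(regions = regions,
                 bregma_px = as.numeric(bregma_px),
                 midline_angle = as.numeric(midline_angle),
                 pixel_size = as.numeric(pixel_size)),
            class = "atlas_layout")
}

#' @export
print.atlas_layout <- function(x, ...) {
  cat(sprintf(
    "<atlas_layout> %d regions (%s); bregma (%.1f, %.1f) px; midline %g deg; %.2f um/px\n",
    length(x$regions), paste(names(x$regions), collapse = ", "),
    x$bregma_px[1], x$bregma_px[2], x$midline_angle, x$pixel_size))
  invisible(x)
}

#' Read region polygons from a layout YAML file
#'
#' @param path YAML file with a `regions:` map of `x_mm`/`y_mm` mm vertex
#'   vectors (a bare `y` key is a YAML 1.1 boolean, hence the suffix);
#'   defaults to the packaged approximate layout.
#' @return Named list of polygon matrices.
#' @export
read_atlas_regions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atlas_regions_mm.yaml",
                        package = "widevolt")
  }
  y <- yaml::read_yaml(path)
  lapply(y$regions, function(r) cbind(x = as.numeric(r$x_mm),
                                      y = as.numeric(r$y_mm)))
}

#' Default layout for a synthetic/standard window
#'
#' Places bregma at mid-height, one tenth of the width from the medial edge,
#' midline vertical — the geometry the synthetic generator renders.
#'
#' @param image_shape c(rows, cols) of the binned image.
#' @param pixel_size um per binned pixel.
#' @return An [atlas_layout()].
#' @export
default_atlas_layout <- function(image_shape, pixel_size = 14.55) {
  atlas_layout(bregma_px = c(round(image_shape[1] / 2),
                             round(image_shape[2] / 10)),
               midline_angle = 0, pixel_size = pixel_size)
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    for (j in seq((i + 2), n)) {
      if (i == 1 && j == n) next  # shared vertex with closing edge
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]
      q1 <- seg[j, 1:2]; q2 <- seg[j, 3:4]
      d1 <- cross(p2[1] - p1[1], p2[2] - p1[2], q1[1] - p1[1], q1[2] - p1[2])
      d2 <- cross(p2[1] - p1[1], p2[2] - p1[2], q2[1] - p1[1], q2[2] - p1[2])
      d3 <- cross(q2[1] - q1[1], q2[2] - q1[2], p1[1] - q1[1], p1[2] - q1[2])
      d4 <- cross(q2[1] - q1[1], q2[2] - q1[2], p2[1] - q1[1], p2[2] - q1[2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

# mm -> pixel coordinates for one polygon under a layout (rotation about
# bregma by midline_angle).
polygon_to_px <- function(poly_mm, layout) {
  s <- 1000 / layout$pixel_size  # px per mm
  col0 <- poly_mm[, "x"] * s
  row0 <- -poly_mm[, "y"] * s   # rostral (positive y) is up (smaller row)
  th <- layout$midline_angle * pi / 180
  cs <- cos(th); sn <- sin(th)
  cbind(row = layout$bregma_px[1] + (row0 * cs - col0 * sn),
        col = layout$bregma_px[2] + (row0 * sn + col0 * cs))
}

# Vectorised even-odd point-in-polygon over pixel centres, inclusive at the
# boundary. `pr`, `pc` numeric vectors of pixel-centre coordinates.
points_in_polygon <- function(pr, pc, poly_px, eps = 1e-9) {
  n <- nrow(poly_px)
  inside <- rep(FALSE, length(pr))
  onedge <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    ri <- poly_px[i, "row"]; ci <- poly_px[i, "col"]
    rj <- poly_px[j, "row"]; cj <- poly_px[j, "col"]
    # edge crossing test on the row axis
    crosses <- ((ri > pr) != (rj > pr))
    if (any(crosses)) {
      xint <- ci + (pr[crosses] - ri) * (cj - ci) / (rj - ri)
      flip <- pc[crosses] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
    # boundary: distance of point to segment <= eps
    vr <- rj - ri; vc <- cj - ci
    len2 <- vr^2 + vc^2
    if (len2 > 0) {
      tt <- pmin(1, pmax(0, ((pr - ri) * vr + (pc - ci) * vc) / len2))
      d2 <- (pr - (ri + tt * vr))^2 + (pc - (ci + tt * vc))^2
      onedge <- onedge | d2 <= eps^2
    }
    j <- i
  }
  inside | onedge
}

#' Rasterise an atlas layout onto an image grid
#'
#' Converts each region polygon from millimetres to pixels (translation to
#' bregma, rotation by the midline angle, scale by pixel size) and labels
#' every pixel whose centre falls inside a polygon. Each pixel receives at
#' most one label; with the packaged disjoint polygons the order of regions is
#' immaterial, with overlapping custom polygons the first region in the layout
#' wins.
#'
#' @param layout An [atlas_layout()].
#' @param image_shape c(rows, cols) of the target grid.
#' @return Integer label matrix (0 = unlabelled) with a `regions` attribute
#'   naming levels 1..K, class `atlas_labels`.
#' @export
rasterize_atlas <- function(layout, image_shape) {
  stopifnot(inherits(layout, "atlas_layout"))
  h <- image_shape[1]; w <- image_shape[2]
  if (layout$bregma_px[1] < 1 || layout$bregma_px[1] > h ||
      layout$bregma_px[2] < 1 || layout$bregma_px[2] > w) {
    abort("bregma_px must lie inside the image")
  }
  pr <- rep(seq_len(h), times = w)
  pc <- rep(seq_len(w), each = h)
  lab <- matrix(0L, h, w)
  for (k in seq_along(layout$regions)) {
    px <- polygon_to_px(layout$regions[[k]], layout)
    inside <- points_in_polygon(pr, pc, px)
    sel <- inside & (lab == 0L)
    if (!any(inside)) {
      warn(sprintf("region '%s' rasterises to zero pixels on this window",
                   names(layout$regions)[k]))
    }
    lab[matrix(c(pr[sel], pc[sel]), ncol = 2)] <- k
  }
  structure(lab, regions = names(layout$regions), class = "atlas_labels")
}

#' Binarise a raw donor frame into a vessel/imperfection exclusion mask
#'
#' Dark, non-fluorescent pixels (superficial blood vessels, window
#' imperfections) are excluded from all further computation. The threshold is
#' either a fixed count value shared across animals (the default workflow) or
#' derived by Otsu's method from the frame histogram.
#'
#' @param raw_donor_frame A lit (non-dark) raw donor frame, counts (matrix).
#' @param method "fixed" or "otsu".
#' @param threshold Count threshold for `method = "fixed"`; pixels strictly
#'   below it are excluded.
#' @param max_count Full-scale camera count (12-bit default), used by Otsu.
#' @return Logical matrix, `TRUE` = excluded.
#' @export
make_vessel_mask <- function(raw_donor_frame, method = c("fixed", "otsu"),
                             threshold = 500, max_count = 4095) {
  method <- match.arg(method)
  if (method == "otsu") {
    img <- EBImage::Image(pmin(pmax(raw_donor_frame / max_count, 0), 1))
    threshold <- EBImage::otsu(img, range = c(0, 1), levels = 256) * max_count
  }
  mask <- raw_donor_frame < threshold
  if (all(mask)) {
    warn("vessel threshold excludes every pixel (threshold above data range)")
  } else if (!any(mask) && method == "fixed" &&
             threshold <= min(raw_donor_frame)) {
    # uniform bright frame with a sub-minimum threshold: nothing excluded
    mask
  }
  mask
}

#' Region-averaged voltage trace
#'
#' Unweighted mean of the %dR/R stack over the valid pixels of one region,
#' frame by frame.
#'
#' @param ratio A `ratio_seq` from [compute_drr()].
#' @param labels Label image from [rasterize_atlas()].
#' @param region Region name.
#' @return Tibble with columns `region`, `frame`, `time_ms` (relative to the
#'   first stimulus), `drr_pct`, `n_pixels`.
#' @export
region_trace <- function(ratio, labels, region) {
  stopifnot(inherits(ratio, "ratio_seq"))
  regions <- attr(labels, "regions")
  k <- match(region, regions)
  if (is.na(k)) abort(sprintf("unknown region '%s'", region))
  sel <- (unclass(labels) == k) & ratio$valid_mask
  n <- sum(sel)
  if (n == 0L) {
    abort(sprintf(
      "region '%s' has no valid pixels (empty intersection with masks)",
      region))
  }
  nt <- dim(ratio$drr)[3]
  m <- matrix(ratio$drr, ncol = nt)
  tr <- colMeans(m[as.vector(sel), , drop = FALSE])
  s1 <- ratio$stim_frames[1] %||% NA_integer_
  tibble::tibble(
    region = region,
    frame = seq_len(nt),
    time_ms = if (is.na(s1)) NA_real_ else
      frame_time_ms(seq_len(nt), s1, ratio$frame_rate),
    drr_pct = tr,
    n_pixels = n
  )
}

#' Region-averaged traces for every region of a label image
#'
#' @inheritParams region_trace
#' @param regions Region names; default all regions present in `labels`.
#' @return Tibble, one row per region x frame (regions with no valid pixels
#'   are skipped with a warning).
#' @export
region_traces <- function(ratio, labels, regions = attr(labels, "regions")) {
  out <- lapply(regions, function(r) {
    tryCatch(region_trace(ratio, labels, r),
             error = function(e) {
               warn(sprintf("skipping region '%s': %s", r, conditionMessage(e)))
               NULL
             })
  })
  dplyr::bind_rows(out)
}
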