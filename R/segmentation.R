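#' Segmentation settings
#'
#' Controls binarization of a slide scan into particle foreground and
#' background. A brightness offset and contrast gain are applied to the
#' intensities before thresholding (mirroring the adjustable binarization of
#' slide-scanning instruments); the threshold is then either chosen
#' automatically from the image histogram (Otsu) or set manually. Foreground
#' is the dark side of the threshold, as particles absorb transmitted light.
#'
#' @param threshold_mode `"automatic"` (histogram-based, Otsu) or `"manual"`.
#' @param manual_threshold Intensity threshold in \[0, 1\], used in manual mode.
#' @param brightness_offset Added to intensities before thresholding.
#' @param contrast_gain Positive multiplier applied about mid-gray before
#'   thresholding.
#' @param min_region_area_px Connected foreground regions smaller than this
#'   many pixels are discarded (noise suppression).
#' @param crop_size_px Side length of the square crop extracted per particle;
#'   the workflow's standard is 280 px.
#' @return Object of class `segmentation_settings`.
#' @export
segmentation_settings <- function(threshold_mode = c("automatic", "manual"),
                                  manual_threshold = 0.5,
                                  brightness_offset = 0,
                                  contrast_gain = 1,
                                  min_region_area_px = 20L,
                                  crop_size_px = 280L) {
  threshold_mode <- match.arg(threshold_mode)
  if (!is.numeric(contrast_gain) || length(contrast_gain) != 1 ||
      is.na(contrast_gain) || contrast_gain <= 0) {
    stop("invalid settings: contrast_gain must be positive")
  }
  if (threshold_mode == "manual" &&
      (!is.numeric(manual_threshold) || manual_threshold < 0 || manual_threshold > 1)) {
    stop("invalid settings: manual_threshold must lie in [0, 1]")
  }
  if (min_region_area_px < 0) stop("invalid settings: min_region_area_px must be >= 0")
  if (crop_size_px < 1) stop("invalid settings: crop_size_px must be >= 1")
  structure(
    list(
      threshold_mode = threshold_mode,
      manual_threshold = as.numeric(manual_threshold),
      brightness_offset = as.numeric(brightness_offset),
      contrast_gain = as.numeric(contrast_gain),
      min_region_area_px = as.integer(min_region_area_px),
      crop_size_px = as.integer(crop_size_px)
    ),
    class = "segmentation_settings"
  )
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that touch
# only diagonally are merged afterwards with a small union-find pass.
label_mask <- function(mask) {
  storage.mode(mask) <- "logical"
  if (!any(mask)) {
    return(matrix(0L, nrow(mask), ncol(mask)))
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  L <- t(EBImage::imageData(lab))
  storage.mode(L) <- "integer"
  nl <- max(L)
  if (nl > 1 && nrow(L) > 1 && ncol(L) > 1) {
    nr <- nrow(L); nc <- ncol(L)
    a <- L[-nr, -nc]; b <- L[-1, -1]     # down-right diagonal
    cc <- L[-nr, -1]; d <- L[-1, -nc]    # down-left diagonal
    pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                   cbind(as.vector(cc), as.vector(d)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs) > 0) {
      parent <- seq_len(nl)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      root <- vapply(seq_len(nl), find, integer(1))
      new_id <- match(root, sort(unique(root)))
      pos <- L > 0L
      L[pos] <- new_id[L[pos]]
    }
  }
  L
}

#' Binarize a slide scan into a particle mask
#'
#' Applies the brightness/contrast adjustment, thresholds the result (Otsu in
#' automatic mode, the fixed value in manual mode; pixels darker than the
#' threshold are foreground), and removes connected regions smaller than
#' `min_region_area_px`.
#'
#' @param scan A [scan_image()].
#' @param settings A [segmentation_settings()].
#' @return Logical matrix of the scan's dimensions; `TRUE` marks particle
#'   pixels. A constant image yields an empty mask in automatic mode.
#' @export
binarize_scan <- function(scan, settings = segmentation_settings()) {
  stopifnot(inherits(scan, "scan_image"))
  if (!inherits(settings, "segmentation_settings")) {
    settings <- do.call(segmentation_settings, settings)
  }
  px <- scan$pixels
  adj <- settings$contrast_gain * (px - 0.5) + 0.5 + settings$brightness_offset
  adj <- pmin(pmax(adj, 0), 1)
  if (settings$threshold_mode == "automatic") {
    if (diff(range(adj)) == 0) {
      return(matrix(FALSE, nrow(px), ncol(px)))
    }
    thr <- EBImage::otsu(EBImage::Image(t(adj)))
  } else {
    thr <- settings$manual_threshold
  }
  mask <- adj < thr
  if (settings$min_region_area_px > 0 && any(mask)) {
    L <- label_mask(mask)
    sizes <- tabulate(L[L > 0L])
    keep <- sizes >= settings$min_region_area_px
    pos <- L > 0L
    mask[pos] <- keep[L[pos]]
  }
  mask
}

# modal background intensity (255-level histogram mode) used for crop padding
background_mode <- function(pixels, mask) {
  bg <- pixels[!mask]
  if (length(bg) == 0) bg <- pixels
  lv <- round(bg * 255)
  as.numeric(names(which.max(table(lv)))) / 255
}

crop_centered <- function(pixels, center_row, center_col, size, pad) {
  out <- matrix(pad, size, size)
  r0 <- center_row - size %/% 2
  c0 <- center_col - size %/% 2
  rows <- r0:(r0 + size - 1)
  cols <- c0:(c0 + size - 1)
  rok <- rows >= 1 & rows <= nrow(pixels)
  cok <- cols >= 1 & cols <= ncol(pixels)
  out[rok, cok] <- pixels[rows[rok], cols[cok], drop = FALSE]
  out
}

#' Extract measured particle objects from a binarized scan
#'
#' Connected foreground regions (8-connectivity) become particle objects with
#' centroid, bounding box, area, equivalent circular diameter, circularity
#' (`4 * pi * area / perimeter^2`, clipped at 1 to absorb rasterization), and a
#' square crop of side `crop_size_px` centred on the centroid. Crops running
#' over the scan edge are padded with the modal background intensity. Object
#' ids are assigned in raster order (top-to-bottom, then left-to-right) of the
#' centroids.
#'
#' @param scan A [scan_image()].
#' @param mask Logical foreground mask with the scan's dimensions (from
#'   [binarize_scan()]).
#' @param settings A [segmentation_settings()]; `crop_size_px` is used here.
#' @return List of `particle_object`s (possibly empty).
#' @export
extract_particles <- function(scan, mask, settings = segmentation_settings()) {
  stopifnot(inherits(scan, "scan_image"))
  if (!inherits(settings, "segmentation_settings")) {
    settings <- do.call(segmentation_settings, settings)
  }
  if (!all(dim(mask) == dim(scan$pixels))) {
    stop("mask dimensions must equal scan dimensions")
  }
  L <- label_mask(mask)
  n <- max(L)
  if (n == 0) return(list())

  idx <- which(L > 0L)
  pos <- arrayInd(idx, dim(L))
  lab <- L[idx]
  r0 <- pos[, 1] - 1  # 0-based row (y)
  c0 <- pos[, 2] - 1  # 0-based col (x)

  area_px <- tabulate(lab, nbins = n)
  flab <- factor(lab, levels = seq_len(n))  # keep numeric label order
  cy <- as.numeric(tapply(r0, flab, mean))
  cx <- as.numeric(tapply(c0, flab, mean))
  rmin <- as.numeric(tapply(r0, flab, min)); rmax <- as.numeric(tapply(r0, flab, max)) + 1
  cmin <- as.numeric(tapply(c0, flab, min)); cmax <- as.numeric(tapply(c0, flab, max)) + 1

  shp <- EBImage::computeFeatures.shape(EBImage::Image(t(L)))
  perim <- shp[, "s.perimeter"]

  scale <- scan$scale
  area_um2 <- area_px * scale^2
  eq_diam <- 2 * sqrt(area_um2 / pi)
  circ <- ifelse(perim > 0, pmin(1, 4 * pi * area_px / perim^2), 1)

  pad <- background_mode(scan$pixels, mask)
  ord <- order(cy, cx)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- ord[i]
    crop <- crop_centered(scan$pixels, round(cy[k]) + 1, round(cx[k]) + 1,
                          settings$crop_size_px, pad)
    out[[i]] <- structure(
      list(
        object_id = i,
        centroid_um = c(x = cx[k] * scale, y = cy[k] * scale),
        centroid_px = c(x = cx[k], y = cy[k]),
        bbox_px = c(row_min = rmin[k], col_min = cmin[k],
                    row_max = rmax[k], col_max = cmax[k]),
        area_um2 = unname(area_um2[k]),
        equivalent_diameter_um = unname(eq_diam[k]),
        circularity = unname(circ[k]),
        crop = crop
      ),
      class = "particle_object"
    )
  }
  out
}

#' @export
print.particle_object <- function(x, ...) {
  cat(sprintf(
    "<particle_object #%d: (%.1f, %.1f) um, eq. diameter %.1f um, circularity %.2f>\n",
    x$object_id, x$centroid_um["x"], x$centroid_um["y"],
    x$equivalent_diameter_um, x$circularity
  ))
  invisible(x)
}

#' Particle size filter
#'
#' The workflow classifies only particles whose equivalent circular diameter
#' falls in a fixed window, 60–160 micrometres by default: smaller objects are
#' often out of focus, larger ones are usually touching composites.
#'
#' @param min_diameter_um,max_diameter_um Window bounds in micrometres;
#'   `min_diameter_um < max_diameter_um`.
#' @return Object of class `size_filter`.
#' @export
size_filter <- function(min_diameter_um = 60, max_diameter_um = 160) {
  if (!is.numeric(min_diameter_um) || !is.numeric(max_diameter_um) ||
      min_diameter_um <= 0 || max_diameter_um <= 0 ||
      min_diameter_um >= max_diameter_um) {
    stop("size filter requires 0 < min_diameter_um < max_diameter_um")
  }
  structure(
    list(min_diameter_um = as.numeric(min_diameter_um),
         max_diameter_um = as.numeric(max_diameter_um)),
    class = "size_filter"
  )
}

#' Apply the size filter to a particle list
#'
#' Retains exactly the particles with
#' `min_diameter_um <= equivalent_diameter_um <= max_diameter_um`, preserving
#' order, and reports the excluded fraction.
#'
#' @param particles List of `particle_object`s.
#' @param filter A [size_filter()].
#' @return List with elements `particles` (the retained objects), `n_input`,
#'   `n_excluded`, and `excluded_fraction` (0 for empty input).
#' @export
filter_by_size <- function(particles, filter = size_filter()) {
  stopifnot(inherits(filter, "size_filter"))
  if (length(particles) == 0) {
    return(list(particles = list(), n_input = 0L, n_excluded = 0L,
                excluded_fraction = 0))
  }
  d <- vapply(particles, function(p) p$equivalent_diameter_um, numeric(1))
  keep <- d >= filter$min_diameter_um & d <= filter$max_diameter_um
  list(
    particles = particles[keep],
    n_input = length(particles),
    n_excluded = sum(!keep),
    excluded_fraction = mean(!keep)
  )
}

#' Tabulate particle measurements
#'
#' @param particles List of `particle_object`s.
#' @param crop_path Optional character vector of crop file paths (recycled NA
#'   when absent).
#' @return Data frame with columns `object_id`, `x_um`, `y_um`, `area_um2`,
#'   `equiv_diameter_um`, `circularity`, `crop_path`.
#' @export
particle_table <- function(particles, crop_path = NA_character_) {
  data.frame(
    object_id = vapply(particles, function(p) as.numeric(p$object_id), numeric(1)),
    x_um = vapply(particles, function(p) unname(p$centroid_um["x"]), numeric(1)),
    y_um = vapply(particles, function(p) unname(p$centroid_um["y"]), numeric(1)),
    area_um2 = vapply(particles, function(p) p$area_um2, numeric(1)),
    equiv_diameter_um = vapply(particles, function(p) p$equivalent_diameter_um,
                               numeric(1)),
    circularity = vapply(particles, function(p) p$circularity, numeric(1)),
    crop_path = rep_len(crop_path, length(particles)),
    stringsAsFactors = FALSE
  )
}

#' Write a crop gallery and particle table for a scan
#'
#' Crops are written as `<scan_id>_<object_id>.png` plus a `particles.csv`
#' table in the output directory.
#'
#' @param particles List of `particle_object`s.
#' @param scan_id Scan identifier used in file names.
#' @param out_dir Output directory (created if missing).
#' @return The particle table, invisibly.
#' @export
write_particle_gallery <- function(particles, scan_id, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(particles, function(p) {
    f <- file.path(out_dir, sprintf("%s_%d.png", scan_id, p$object_id))
    write_image(p$crop, f)
    f
  }, character(1))
  tab <- particle_table(particles, crop_path = if (length(paths)) paths else NA_character_)
  write.csv(tab, file.path(out_dir, "particles.csv"), row.names = FALSE)
  invisible(tab)
}
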