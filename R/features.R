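# Morphometric feature descriptor for particle crops.
#
# The five categories are distinguished by silhouette structure rather than
# texture at fine scale, so the descriptor combines intensity statistics,
# second-moment shape (eccentricity), a radial darkness profile (separates
# concentric-ring diatoms, latticed shells and solid discs), an angular
# occupancy profile of the outer zone (separates spined and horned forms),
# and boundary roughness. Crops are resampled (bilinear) to a fixed working
# size first; all quantities are computed on the resampled grid.

crop_features <- function(crop, input_size = 64) {
  if (is.null(crop) || length(crop) == 0) stop("invalid input: empty image")
  if (!is.matrix(crop)) stop("invalid input: crop must be a matrix")
  if (nrow(crop) < 1 || ncol(crop) < 1) stop("invalid input: empty image")

  m <- crop
  if (nrow(m) != input_size || ncol(m) != input_size) {
    img <- EBImage::resize(EBImage::Image(t(m)), w = input_size, h = input_size)
    m <- t(EBImage::imageData(img))
  }
  m <- pmin(pmax(m, 0), 1)

  n_rad <- 10L   # radial bins
  n_ang <- 16L   # angular bins
  feat <- c(
    int_mean = mean(m), int_sd = sd(as.vector(m)),
    int_p10 = unname(quantile(m, 0.1)), int_p90 = unname(quantile(m, 0.9)),
    fg_frac = 0, dark_mean = 0, ecc = 0, spread = 0,
    core_dark_sd = 0, radial_contrast = 0,
    ang_sd = 0, ang_occupancy = 0, rim_frac = 0,
    bound_rough = 0, bound_mean_r = 0,
    setNames(numeric(n_rad), paste0("radial_", seq_len(n_rad))),
    setNames(numeric(n_ang), paste0("angocc_", seq_len(n_ang)))
  )

  bg <- unname(quantile(m, 0.9))
  dark <- pmax(bg - m, 0)
  dmax <- max(dark)
  if (dmax < 1e-6) {
    return(feat)  # featureless (constant or near-constant) crop
  }
  dark <- dark / dmax
  fg <- dark > 0.5
  if (!any(fg)) {
    feat["fg_frac"] <- 0
    feat["dark_mean"] <- mean(dark)
    return(feat)
  }
  # crops may show parts of neighbouring particles near the edges; describe
  # only the connected component closest to the crop centre
  L <- label_mask(fg)
  nl <- max(L)
  if (nl > 1) {
    ctr <- (input_size + 1) / 2
    pos_all <- arrayInd(which(L > 0L), dim(L))
    lab_all <- L[L > 0L]
    d2 <- (pos_all[, 1] - ctr)^2 + (pos_all[, 2] - ctr)^2
    best <- as.integer(names(which.min(tapply(d2, lab_all, min))))
    fg <- L == best
    dark[L != best & L > 0L] <- 0
  }
  feat["fg_frac"] <- mean(fg)
  feat["dark_mean"] <- mean(dark)

  pos <- arrayInd(which(fg), dim(m))
  w <- dark[fg]
  cy <- sum(pos[, 1] * w) / sum(w)
  cx <- sum(pos[, 2] * w) / sum(w)

  # second moments -> eccentricity and normalized spread
  dy <- pos[, 1] - cy; dx <- pos[, 2] - cx
  cxx <- sum(w * dx^2) / sum(w); cyy <- sum(w * dy^2) / sum(w)
  cxy <- sum(w * dx * dy) / sum(w)
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  feat["ecc"] <- if (l1 > 1e-9) sqrt(1 - max(l2, 0) / l1) else 0
  feat["spread"] <- sqrt(tr) / input_size

  # polar grid about the darkness centroid
  rows <- matrix(seq_len(input_size), input_size, input_size)
  cols <- t(rows)
  rr <- sqrt((rows - cy)^2 + (cols - cx)^2)
  th <- atan2(rows - cy, cols - cx)
  rfg <- rr[fg]
  rmax <- max(quantile(rfg, 0.98), 1)
  rn <- rr / rmax

  # radial darkness profile on [0, 1.25]
  br <- seq(0, 1.25, length.out = n_rad + 1)
  rbin <- findInterval(pmin(rn, 1.2499), br)
  prof <- vapply(seq_len(n_rad), function(b) {
    v <- dark[rbin == b]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  feat[paste0("radial_", seq_len(n_rad))] <- prof
  feat["radial_contrast"] <- sum(abs(diff(prof)))
  feat["core_dark_sd"] <- {
    v <- dark[rn < 0.6]
    if (length(v) > 1) sd(v) else 0
  }

  # angular occupancy of the outer zone (spines, horns)
  outer <- rn > 0.55 & rn < 1.25
  abin <- pmin(floor((th + pi) / (2 * pi) * n_ang) + 1, n_ang)
  occ <- vapply(seq_len(n_ang), function(b) {
    sel <- outer & abin == b
    if (any(sel)) mean(fg[sel]) else 0
  }, numeric(1))
  occ_sorted <- sort(occ)  # rotation-invariant ordering
  feat[paste0("angocc_", seq_len(n_ang))] <- occ_sorted
  feat["ang_sd"] <- sd(occ)
  feat["ang_occupancy"] <- mean(occ > 0.15)
  rim <- fg[rn > 0.85 & rn < 1.05]
  feat["rim_frac"] <- if (length(rim)) mean(rim) else 0

  # boundary roughness: spread of the outermost foreground radius by angle
  bmax <- vapply(seq_len(n_ang), function(b) {
    v <- rn[fg & abin == b]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  bmax <- bmax[!is.na(bmax)]
  if (length(bmax) > 1) {
    feat["bound_rough"] <- sd(bmax) / mean(bmax)
    feat["bound_mean_r"] <- mean(bmax)
  }
  feat
}
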