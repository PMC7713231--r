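# Synthetic data generators: slide scans with ground truth, single-particle
# training galleries, and Dirichlet confidence tables. The rendered
# morphotypes are parametric caricatures chosen to be visually separable the
# way the real categories are (latticed shell, horned shell, spined sphere,
# concentric-ring valve, irregular debris); they make no claim to anatomical
# realism.

#' Specification of a synthetic slide scan
#'
#' @param image_size_px `c(width, height)` of the scan in pixels.
#' @param scale Micrometres per pixel.
#' @param counts Named integer vector of particles per category (any subset
#'   of [category_levels()]).
#' @param diameter_median_um,diameter_sigma Lognormal diameter distribution
#'   per particle: median in micrometres and log-scale sigma. Either scalars
#'   or named per-category vectors.
#' @param overlap_allowed If `FALSE` (default), particles are placed by
#'   rejection sampling so silhouettes never touch.
#' @param defocus_fraction Fraction of particles rendered with Gaussian
#'   defocus blur, emulating imaging without focus stacking.
#' @param defocus_sigma Blur sigma in pixels for defocused particles.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param background,particle_intensity Background and particle intensities
#'   in \[0, 1\] (light background, dark particles).
#' @param seed Integer seed; generation is fully deterministic under it.
#' @return Object of class `slide_spec`.
#' @export
slide_spec <- function(image_size_px = c(width = 1600, height = 1200),
                       scale = 1,
                       counts = c(Cdv = 10, Cbc = 5, Rad = 20, dtm = 10, oth = 5),
                       diameter_median_um = 100,
                       diameter_sigma = 0.12,
                       overlap_allowed = FALSE,
                       defocus_fraction = 0.2,
                       defocus_sigma = 2.5,
                       noise_sd = 0.02,
                       background = 0.85,
                       particle_intensity = 0.25,
                       seed = 1L) {
  if (any(counts < 0)) stop("counts must be non-negative")
  bad <- setdiff(names(counts), category_levels())
  if (length(bad)) stop("unknown categories in counts: ", paste(bad, collapse = ", "))
  if (any(diameter_median_um <= 0)) stop("diameters must be positive")
  if (defocus_fraction < 0 || defocus_fraction > 1) {
    stop("defocus_fraction must lie in [0, 1]")
  }
  structure(
    list(image_size_px = image_size_px, scale = scale, counts = counts,
         diameter_median_um = diameter_median_um,
         diameter_sigma = diameter_sigma,
         overlap_allowed = isTRUE(overlap_allowed),
         defocus_fraction = defocus_fraction, defocus_sigma = defocus_sigma,
         noise_sd = noise_sd, background = background,
         particle_intensity = particle_intensity, seed = as.integer(seed)),
    class = "slide_spec"
  )
}

per_category <- function(x, cat) {
  if (!is.null(names(x)) && cat %in% names(x)) x[[cat]] else x[[1]]
}

#' Sample particle diameters
#'
#' Lognormal diameters (positive, right-skewed, as is typical of sieved
#' particle populations) with the given median and log-scale sigma.
#'
#' @param n Number of draws.
#' @param median_um Median diameter in micrometres.
#' @param sigma Log-scale standard deviation.
#' @return Numeric vector of diameters in micrometres.
#' @export
sample_diameters <- function(n, median_um = 100, sigma = 0.12) {
  rlnorm(n, meanlog = log(median_um), sdlog = sigma)
}

# --- morphotype silhouettes -------------------------------------------------
# Each renderer maps centred pixel offsets (dx = column, dy = row) to a
# logical mask. `r` is the nominal radius in pixels; `par` holds shape draws.

wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

render_silhouette <- function(category, r, par, tile) {
  off <- (tile + 1) / 2
  dy <- matrix(seq_len(tile) - off, tile, tile)
  dx <- t(dy)
  phi <- par$phi
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)

  if (category == "Cdv") {
    # latticed ellipsoidal shell: solid rim, grid of pores inside
    a <- r; b <- 0.68 * r
    e <- (u / a)^2 + (v / b)^2
    p <- r / 2.2
    hole <- (sin(pi * u / p)^2 > 0.7) & (sin(pi * v / p)^2 > 0.7) & e < 0.78
    e <= 1 & !hole
  } else if (category == "Cbc") {
    # horned shell: ellipse with two forward prongs
    a <- 0.8 * r; b <- 0.55 * r
    ell <- (u / a)^2 + (v / b)^2 <= 1
    horn1 <- u > 0.4 * a & u < 1.55 * a & abs(v - 0.32 * b) < 0.16 * b
    horn2 <- u > 0.4 * a & u < 1.55 * a & abs(v + 0.32 * b) < 0.16 * b
    ell | horn1 | horn2
  } else if (category == "Rad") {
    # spherical test with radial spines
    disc <- rr <= 0.72 * r
    dmin <- Reduce(pmin, lapply(par$spine_angles,
                                function(a) abs(wrap_angle(th - a))))
    spine <- rr > 0.5 * r & rr <= 1.18 * r & (dmin * pmax(rr, 1)) < 0.055 * r
    disc | spine
  } else if (category == "dtm") {
    # centric diatom valve: concentric rings joined by radial spokes
    p <- r / 2.4
    rings <- cos(2 * pi * rr / p) > -0.1
    spoke_angles <- phi + 2 * pi * seq_len(6) / 6
    dmin <- Reduce(pmin, lapply(spoke_angles,
                                function(a) abs(wrap_angle(th - a))))
    spokes <- (dmin * pmax(rr, 1)) < 0.05 * r
    rr <= r & (rings | spokes | rr > 0.88 * r | rr < 0.18 * r)
  } else {
    # irregular debris blob: low-order harmonic radius perturbation
    Rth <- r * (0.62 + par$amp[1] * cos(2 * th + par$ph[1]) +
                  par$amp[2] * cos(3 * th + par$ph[2]) +
                  par$amp[3] * cos(5 * th + par$ph[3]))
    rr <= pmax(Rth, 0.22 * r)
  }
}

draw_shape_params <- function(category) {
  par <- list(phi = runif(1, 0, 2 * pi))
  if (category == "Rad") {
    n_sp <- sample(7:9, 1)
    par$spine_angles <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(n_sp) / n_sp
  }
  if (category == "oth") {
    par$amp <- runif(3, 0.04, 0.16)
    par$ph <- runif(3, 0, 2 * pi)
  }
  par
}

# effective extent (packing radius) of a silhouette, incl. spines/horns
extent_factor <- c(Cdv = 1.05, Cbc = 1.30, Rad = 1.22, dtm = 1.05, oth = 1.15)

#' Generate a synthetic slide scan with ground truth
#'
#' Renders one particle per requested count as a category-specific silhouette
#' (see package vignette), optionally defocus-blurs a fraction of them, adds
#' Gaussian pixel noise, and returns the scan together with a ground-truth
#' table. Placement is uniform; when overlap is disallowed, positions are
#' rejection-sampled so that silhouette extents never touch, and an
#' infeasible packing raises an error after bounded retries.
#'
#' The ground-truth centroid is the rendered silhouette's pixel centroid
#' (0-based scan coordinates), which is what a faithful segmentation should
#' recover.
#'
#' @param spec A [slide_spec()].
#' @return List with `scan` (a [scan_image()]) and `truth` (data frame with
#'   `object_id`, `true_label`, `x_px`, `y_px`, `diameter_um`).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  withr::with_seed(spec$seed, {
    W <- as.integer(spec$image_size_px[[1]])
    H <- as.integer(spec$image_size_px[[2]])
    canvas <- matrix(spec$background, H, W)

    cats <- rep(names(spec$counts), times = spec$counts)
    n <- length(cats)
    diam_um <- vapply(cats, function(cat) {
      sample_diameters(1, per_category(spec$diameter_median_um, cat),
                       per_category(spec$diameter_sigma, cat))
    }, numeric(1))
    r_px <- diam_um / (2 * spec$scale)
    r_eff <- r_px * extent_factor[cats] + 2

    # place large particles first; rejection sampling against placed extents
    ord <- order(-r_px)
    px <- py <- numeric(n)
    placed <- integer(0)
    for (i in ord) {
      ok <- FALSE
      if (2 * r_eff[i] + 2 >= W || 2 * r_eff[i] + 2 >= H) {
        stop("packing error: particle larger than the field")
      }
      for (try in seq_len(600)) {
        x <- runif(1, r_eff[i] + 1, W - r_eff[i] - 1)
        y <- runif(1, r_eff[i] + 1, H - r_eff[i] - 1)
        if (spec$overlap_allowed || length(placed) == 0 ||
            all(sqrt((px[placed] - x)^2 + (py[placed] - y)^2) >
                  r_eff[placed] + r_eff[i])) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("packing error: could not place ", n, " particles without overlap")
      }
      px[i] <- x; py[i] <- y
      placed <- c(placed, i)
    }

    defocus <- runif(n) < spec$defocus_fraction
    cx_out <- cy_out <- numeric(n)
    for (i in seq_len(n)) {
      tile <- 2 * ceiling(r_eff[i]) + 9
      par <- draw_shape_params(cats[i])
      mask <- render_silhouette(cats[i], r_px[i], par, tile)
      # ground truth: rendered-silhouette centroid in 0-based scan coords
      pos <- arrayInd(which(mask), dim(mask))
      c_row <- mean(pos[, 1]); c_col <- mean(pos[, 2])
      # tile row t (1-based) lands on 0-based canvas row
      # round(py) - (tile - 1) / 2 + t - 2
      cy_out[i] <- c_row + round(py[i]) - (tile - 1) / 2 - 2
      cx_out[i] <- c_col + round(px[i]) - (tile - 1) / 2 - 2

      tile_img <- matrix(spec$background, tile, tile)
      tile_img[mask] <- spec$particle_intensity
      if (defocus[i]) {
        tile_img <- gaussian_blur(tile_img, spec$defocus_sigma)
      }
      rows <- (round(py[i]) - (tile - 1) / 2):(round(py[i]) + (tile - 1) / 2)
      cols <- (round(px[i]) - (tile - 1) / 2):(round(px[i]) + (tile - 1) / 2)
      rok <- rows >= 1 & rows <= H
      cok <- cols >= 1 & cols <= W
      canvas[rows[rok], cols[cok]] <- pmin(canvas[rows[rok], cols[cok], drop = FALSE],
                                           tile_img[rok, cok, drop = FALSE])
    }

    if (spec$noise_sd > 0) {
      canvas <- canvas + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
      canvas <- pmin(pmax(canvas, 0), 1)
    }

    list(
      scan = scan_image(canvas, scale = spec$scale,
                        id = paste0("synthetic-", spec$seed)),
      truth = data.frame(
        object_id = seq_len(n),
        true_label = cats,
        x_px = cx_out,
        y_px = cy_out,
        diameter_um = diam_um,
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Generate a synthetic training gallery of single-particle crops
#'
#' Renders `n_per_category` crops per category, each holding one silhouette
#' with random orientation and size, a `defocus_fraction` of them blurred,
#' with Gaussian pixel noise. The result feeds [train_classifier()].
#'
#' @param n_per_category Crops per category.
#' @param categories Categories to include (default all five).
#' @param crop_size_px Crop side length.
#' @param defocus_fraction,defocus_sigma,noise_sd,background,particle_intensity
#'   As in [slide_spec()].
#' @param seed Integer seed.
#' @param ... Augmentation settings passed to [training_gallery()].
#' @return A [training_gallery()].
#' @export
synthetic_gallery <- function(n_per_category = 60,
                              categories = category_levels(),
                              crop_size_px = 128L,
                              defocus_fraction = 0.2,
                              defocus_sigma = 2,
                              noise_sd = 0.02,
                              background = 0.85,
                              particle_intensity = 0.25,
                              seed = 1L, ...) {
  stopifnot(all(categories %in% category_levels()))
  withr::with_seed(seed, {
    images <- list(); labels <- character(0)
    for (cat in categories) {
      for (i in seq_len(n_per_category)) {
        r <- crop_size_px * runif(1, 0.2, 0.3)
        par <- draw_shape_params(cat)
        mask <- render_silhouette(cat, r, par, crop_size_px)
        m <- matrix(background, crop_size_px, crop_size_px)
        m[mask] <- particle_intensity
        if (runif(1) < defocus_fraction) {
          m <- gaussian_blur(m, defocus_sigma)
        }
        if (noise_sd > 0) {
          m <- pmin(pmax(m + matrix(rnorm(length(m), 0, noise_sd),
                                    nrow(m), ncol(m)), 0), 1)
        }
        images[[length(images) + 1L]] <- m
        labels <- c(labels, cat)
      }
    }
    training_gallery(images, labels, seed = seed, ...)
  })
}

#' Specification of a synthetic confidence table
#'
#' @param n_objects Number of objects.
#' @param composition Named non-negative vector over the five categories,
#'   summing to 1 within 1e-9: the true composition labels are drawn from.
#' @param concentration Positive Dirichlet concentration: each object's
#'   confidence vector is drawn from a Dirichlet whose mean puts
#'   `1 - off_target_mass` on the true label, with total concentration
#'   `concentration`. Large values give near-one-hot vectors.
#' @param off_target_mass Mean confidence mass spread uniformly over all five
#'   categories (classifier softness; default 0.02).
#' @param seed Integer seed.
#' @return Object of class `confidence_table_spec`.
#' @export
confidence_table_spec <- function(n_objects, composition, concentration = 50,
                                  off_target_mass = 0.02, seed = 1L) {
  if (is.null(names(composition))) names(composition) <- category_levels()
  if (!setequal(names(composition), category_levels())) {
    stop("composition must be named by the five categories")
  }
  composition <- composition[category_levels()]
  if (any(composition < 0)) stop("composition must be non-negative")
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition must sum to 1 within 1e-9")
  }
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      is.na(concentration) || concentration <= 0) {
    stop("invalid spec: concentration must be positive")
  }
  if (off_target_mass < 0 || off_target_mass >= 1) {
    stop("off_target_mass must lie in [0, 1)")
  }
  structure(
    list(n_objects = as.integer(n_objects), composition = composition,
         concentration = concentration, off_target_mass = off_target_mass,
         seed = as.integer(seed)),
    class = "confidence_table_spec"
  )
}

#' Generate a synthetic per-object confidence table
#'
#' True labels are drawn from the composition; each confidence vector is
#' drawn from a Dirichlet centred on the true label (mean
#' `1 - off_target_mass` on the true category plus a uniform
#' `off_target_mass / 5` everywhere, total concentration `concentration`).
#' Every emitted vector satisfies the confidence-vector invariants; output is
#' deterministic under the seed.
#'
#' @param spec A [confidence_table_spec()].
#' @return List with `records` (data frame `object_id`, `conf_Cdv` ..
#'   `conf_oth`; pass through [assign_records()] to add threshold
#'   assignments) and `truth` (data frame `object_id`, `true_label`).
#' @export
generate_confidence_table <- function(spec) {
  stopifnot(inherits(spec, "confidence_table_spec"))
  k <- length(category_levels())
  withr::with_seed(spec$seed, {
    truth <- sample(category_levels(), spec$n_objects, replace = TRUE,
                    prob = spec$composition)
    base <- spec$concentration * spec$off_target_mass / k
    alpha <- matrix(base, spec$n_objects, k,
                    dimnames = list(NULL, category_levels()))
    idx <- cbind(seq_len(spec$n_objects), match(truth, category_levels()))
    alpha[idx] <- alpha[idx] + spec$concentration * (1 - spec$off_target_mass)
    g <- matrix(rgamma(spec$n_objects * k, shape = alpha), spec$n_objects, k)
    zero <- rowSums(g) <= 0
    if (any(zero)) {
      g[zero, ] <- 0
      g[cbind(which(zero), match(truth[zero], category_levels()))] <- 1
    }
    conf <- g / rowSums(g)
    records <- data.frame(object_id = seq_len(spec$n_objects), conf,
                          stringsAsFactors = FALSE)
    names(records) <- c("object_id", paste0("conf_", category_levels()))
    list(records = records,
         truth = data.frame(object_id = seq_len(spec$n_objects),
                            true_label = truth, stringsAsFactors = FALSE))
  })
}
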