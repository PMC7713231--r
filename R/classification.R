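#' Training gallery of labeled crops
#'
#' A gallery holds crop images (grayscale matrices in \[0, 1\]) with one
#' category label each, plus the augmentation settings used by
#' [augment_gallery()].
#'
#' @param images List of numeric matrices.
#' @param labels Character vector of category codes (see [category_levels()]),
#'   one per image.
#' @param rotation_angles Rotation angles in degrees used for augmentation;
#'   right angles only (lossless on the pixel grid). Default 90, 180, 270.
#' @param blur_fraction Fraction of the rotated set replicated with Gaussian
#'   defocus blur appended as extra copies (emulates out-of-focus imaging).
#' @param blur_sigma Gaussian blur sigma in pixels for the defocus copies.
#' @param seed Integer seed controlling which images receive blur copies.
#' @return Object of class `training_gallery`.
#' @export
training_gallery <- function(images, labels, rotation_angles = c(90, 180, 270),
                             blur_fraction = 0, blur_sigma = 2, seed = 1L) {
  if (!is.list(images)) stop("images must be a list of matrices")
  if (length(images) != length(labels)) {
    stop("images and labels must have the same length")
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), category_levels())
  if (length(bad)) stop("unknown category labels: ", paste(bad, collapse = ", "))
  if (blur_fraction < 0 || blur_fraction > 1) {
    stop("blur_fraction must lie in [0, 1]")
  }
  structure(
    list(images = images, labels = labels,
         rotation_angles = rotation_angles,
         blur_fraction = blur_fraction, blur_sigma = blur_sigma,
         seed = as.integer(seed)),
    class = "training_gallery"
  )
}

#' @export
print.training_gallery <- function(x, ...) {
  cat(sprintf("<training_gallery: %d images (%s)>\n", length(x$images),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a gallery from a directory of per-category crop folders
#'
#' Expects one sub-directory per category code (`Cdv/`, `Cbc/`, `Rad/`,
#' `dtm/`, `oth/`), each holding PNG (or TIFF) crops.
#'
#' @param dir Gallery root directory.
#' @param ... Augmentation settings passed to [training_gallery()].
#' @return A [training_gallery()].
#' @export
read_gallery <- function(dir, ...) {
  images <- list(); labels <- character(0)
  for (cat in category_levels()) {
    d <- file.path(dir, cat)
    if (!dir.exists(d)) next
    files <- sort(list.files(d, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                             ignore.case = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- read_scan(f)$pixels
      labels <- c(labels, cat)
    }
  }
  training_gallery(images, labels, ...)
}

# Gaussian defocus blur; sigma is clamped so the filter brush fits the image
gaussian_blur <- function(m, sigma) {
  max_sigma <- max((min(dim(m)) - 3) / 2, 1) / 7  # brush size 2*ceiling(3.5*s)+1
  s <- min(sigma, max_sigma)
  img <- EBImage::gblur(EBImage::Image(t(m)), sigma = s)
  pmin(pmax(t(EBImage::imageData(img)), 0), 1)
}

# lossless clockwise rotation by k * 90 degrees
rotate_right_angle <- function(m, degrees) {
  k <- (round(degrees / 90) %% 4)
  if (abs(degrees - round(degrees / 90) * 90) > 1e-9) {
    stop("only right-angle rotations are supported")
  }
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

#' Augment a gallery by rotation and defocus copies
#'
#' Every image is replicated at each configured rotation angle (so the output
#' holds `(1 + length(rotation_angles))` copies per input image), then a
#' `blur_fraction` of the rotated set — sampled deterministically under the
#' gallery seed — is appended once more with Gaussian defocus blur. Labels are
#' preserved throughout.
#'
#' @param gallery A [training_gallery()].
#' @return A new `training_gallery` with the augmented image set.
#' @export
augment_gallery <- function(gallery) {
  stopifnot(inherits(gallery, "training_gallery"))
  if (length(gallery$images) == 0) return(gallery)
  if (length(gallery$rotation_angles) == 0) {
    stop("rotation angle set must be non-empty")
  }
  images <- gallery$images
  labels <- gallery$labels
  for (a in gallery$rotation_angles) {
    images <- c(images, lapply(gallery$images, rotate_right_angle, degrees = a))
    labels <- c(labels, gallery$labels)
  }
  n_blur <- round(gallery$blur_fraction * length(images))
  if (n_blur > 0) {
    idx <- withr::with_seed(gallery$seed, sample(length(images), n_blur))
    blurred <- lapply(images[idx], gaussian_blur, sigma = gallery$blur_sigma)
    images <- c(images, blurred)
    labels <- c(labels, labels[idx])
  }
  out <- gallery
  out$images <- images
  out$labels <- labels
  out
}

#' Baseline classifier configuration
#'
#' @param input_size Working image side length; crops are resampled
#'   (bilinear) to this size before feature extraction.
#' @param ntree Number of trees in the random-forest baseline.
#' @param seed Integer seed making training deterministic.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(input_size = 64L, ntree = 300L, seed = 1L) {
  structure(
    list(input_size = as.integer(input_size), ntree = as.integer(ntree),
         seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Train the baseline confidence model
#'
#' The model contract is deliberately minimal: any classifier that maps a crop
#' to a valid confidence vector (five scores in \[0, 1\] summing to ~1) can
#' stand behind [predict_confidences()]. The bundled baseline extracts a
#' morphometric descriptor per crop (radial/angular silhouette profiles,
#' moments, intensity statistics) and fits a random forest; its class votes
#' are the confidence values.
#'
#' @param gallery A [training_gallery()] with at least two categories present
#'   and at least one image per present category.
#' @param config A [classifier_config()].
#' @return Object of class `confidence_model`.
#' @export
train_classifier <- function(gallery, config = classifier_config()) {
  stopifnot(inherits(gallery, "training_gallery"))
  if (length(gallery$images) == 0) {
    stop("invalid gallery: no training images")
  }
  present <- unique(gallery$labels)
  if (length(present) < 2) {
    stop("invalid gallery: at least two categories with images are required")
  }
  X <- t(vapply(gallery$images, crop_features,
                numeric(length(crop_features(gallery$images[[1]],
                                             config$input_size))),
                input_size = config$input_size))
  y <- factor(gallery$labels,
              levels = category_levels()[category_levels() %in% present])
  forest <- withr::with_seed(
    config$seed,
    randomForest::randomForest(x = X, y = y, ntree = config$ntree)
  )
  structure(
    list(forest = forest, input_size = config$input_size,
         categories = levels(y), seed = config$seed),
    class = "confidence_model"
  )
}

#' @export
print.confidence_model <- function(x, ...) {
  cat(sprintf("<confidence_model: random forest, %d trees, categories %s>\n",
              x$forest$ntree, paste(x$categories, collapse = "/")))
  invisible(x)
}

#' Predict the confidence vector for one crop
#'
#' The crop is resampled to the model's working size; the returned vector has
#' one entry per category (zero for categories absent from training) and
#' satisfies the confidence-vector invariants.
#'
#' @param model A [train_classifier()] model.
#' @param crop Numeric matrix in \[0, 1\].
#' @return A [confidence_vector()].
#' @export
predict_confidences <- function(model, crop) {
  stopifnot(inherits(model, "confidence_model"))
  fx <- crop_features(crop, model$input_size)
  p <- predict(model$forest, rbind(fx), type = "prob")[1, ]
  out <- setNames(numeric(length(category_levels())), category_levels())
  out[names(p)] <- p
  s <- sum(out)
  if (s > 0) out <- out / s else out[] <- 1 / length(out)
  confidence_vector(out)
}

#' Classify a set of crops into a record table
#'
#' Produces the classification-record table consumed by the assemblage
#' statistics: one row per object with the five confidences, the threshold
#' used, and the assigned category (or `"unclassified"`).
#'
#' @param model A `confidence_model`.
#' @param crops List of crop matrices, or a list of `particle_object`s.
#' @param threshold Confidence threshold for assignment (default 0.95).
#' @param object_ids Integer ids; defaults to the particle ids when
#'   `particle_object`s are supplied, else `seq_along(crops)`.
#' @return Data frame with columns `object_id`, `conf_Cdv` .. `conf_oth`,
#'   `threshold`, `assigned`.
#' @export
classify_crops <- function(model, crops, threshold = 0.95, object_ids = NULL) {
  if (length(crops) && inherits(crops[[1]], "particle_object")) {
    if (is.null(object_ids)) {
      object_ids <- vapply(crops, function(p) as.integer(p$object_id), integer(1))
    }
    crops <- lapply(crops, function(p) p$crop)
  }
  if (is.null(object_ids)) object_ids <- seq_along(crops)
  conf <- t(vapply(crops, function(cr) predict_confidences(model, cr),
                   setNames(numeric(5), category_levels())))
  records_from_confidences(conf, threshold, object_ids)
}

empty_records <- function() {
  df <- data.frame(object_id = integer(0),
                   matrix(numeric(0), 0, 5), threshold = numeric(0),
                   assigned = character(0), stringsAsFactors = FALSE)
  names(df) <- c("object_id", paste0("conf_", category_levels()),
                 "threshold", "assigned")
  df
}

records_from_confidences <- function(conf, threshold, object_ids) {
  if (length(conf) == 0) return(empty_records())
  conf <- matrix(as.numeric(conf), ncol = 5,
                 dimnames = list(NULL, category_levels()))
  assigned <- apply(conf, 1, assign_category, threshold = threshold)
  df <- data.frame(
    object_id = as.integer(object_ids),
    conf[, , drop = FALSE],
    threshold = threshold,
    assigned = as.character(assigned),
    stringsAsFactors = FALSE
  )
  names(df) <- c("object_id", paste0("conf_", category_levels()),
                 "threshold", "assigned")
  df
}

#' Re-assign record categories at a (new) threshold
#'
#' Recomputes the `assigned` column of a record table from its confidence
#' columns with the strictly-greater-than threshold rule.
#'
#' @param records Record data frame (see [classify_crops()]); the
#'   `threshold`/`assigned` columns may be absent.
#' @param threshold Confidence threshold in \[0, 1\].
#' @return The record table with updated `threshold` and `assigned` columns.
#' @export
assign_records <- function(records, threshold) {
  conf <- as.matrix(records[, paste0("conf_", category_levels())])
  colnames(conf) <- category_levels()
  records$threshold <- threshold
  records$assigned <- apply(conf, 1, assign_category, threshold = threshold)
  records
}

#' Write / read classification record tables
#'
#' The interchange CSV has the fixed column set `object_id`, `conf_Cdv`,
#' `conf_Cbc`, `conf_Rad`, `conf_dtm`, `conf_oth`, `threshold`, `assigned`
#' (comma-separated, UTF-8, `.` decimal, header row required).
#'
#' @param records Record data frame.
#' @param path CSV file path.
#' @return `write_records()`: `path` invisibly; `read_records()`: the record
#'   data frame.
#' @export
write_records <- function(records, path) {
  cols <- c("object_id", paste0("conf_", category_levels()), "threshold", "assigned")
  stopifnot(all(cols %in% names(records)))
  write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
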