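# Shared fixtures, built once per test run.

# Small scan with a single dark disc of the given radius (pixel units).
disc_scan <- function(radius = 25, size = 101, bg = 0.9, fg = 0.2, scale = 1,
                      center = c(size, size) / 2) {
  m <- matrix(bg, size, size)
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  m[(rows - center[1])^2 + (cols - center[2])^2 <= radius^2] <- fg
  scan_image(m, scale = scale, id = "disc")
}

# One record table row per confidence vector given as a list.
records_from <- function(conf_list, threshold) {
  conf <- do.call(rbind, conf_list)
  df <- data.frame(object_id = seq_along(conf_list), conf, threshold = threshold,
                   stringsAsFactors = FALSE)
  names(df) <- c("object_id", paste0("conf_", category_levels()), "threshold")
  df$assigned <- apply(conf, 1, assign_category, threshold = threshold)
  df
}

# A compact trained model shared across classification/pipeline tests.
shared_gallery <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- synthetic_gallery(n_per_category = 40, crop_size_px = 96,
                                seed = 101)
    }
    val
  }
})

shared_split <- function() {
  gal <- shared_gallery()
  n <- length(gal$images)
  test_idx <- withr::with_seed(202, sort(sample(n, round(0.3 * n))))
  list(
    train = training_gallery(gal$images[-test_idx], gal$labels[-test_idx]),
    test_images = gal$images[test_idx],
    test_labels = gal$labels[test_idx]
  )
}

shared_model <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- train_classifier(shared_split()$train,
                               classifier_config(seed = 303))
    }
    val
  }
})
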