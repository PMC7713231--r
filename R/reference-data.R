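# Bundled benchmark data: published per-slide evaluation reports of the two
# CNN classification models (Cdv%v2, trained on 2-megapixel imagery, and
# Cdv%v6R, on 5-megapixel imagery) against expert labels on test slides from
# Southern Ocean sediment core DCR-1PC, plus the worked confidence-value
# example for slide #37 (six example objects, the per-category means over all
# 500 objects, and the per-category counts above the 0.60/0.95 thresholds).

#' Bundled benchmark accuracy reports
#'
#' Per-slide precision/unclassified reports from the published evaluation of
#' the two classification models on sediment-core test slides: model
#' `"Cdv%v2"` at thresholds 0.60 (five slides) and 0.95 (eight slides), and
#' model `"Cdv%v6R"` at 0.95 (eight slides). Precision for the diatom and
#' other-particle categories was not reported at threshold 0.95 (`NA`).
#'
#' @param model Model code: `"Cdv%v2"` or `"Cdv%v6R"`.
#' @param threshold Confidence threshold of the evaluation: 0.60 or 0.95.
#' @return List of [accuracy_report()]s, one per slide.
#' @export
#' @examples
#' reps <- reference_reports("Cdv%v2", 0.60)
#' aggregate_reports(reps)
reference_reports <- function(model = c("Cdv%v2", "Cdv%v6R"), threshold = 0.95) {
  model <- match.arg(model)
  path <- system.file("extdata", "reference_reports.csv", package = "micrassem",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tab <- tab[tab$model == model & abs(tab$threshold - threshold) < 1e-9, ,
             drop = FALSE]
  if (nrow(tab) == 0) {
    stop("no bundled reports for model ", model, " at threshold ", threshold)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    detected <- setNames(as.integer(unlist(row[paste0("det_", category_levels())])),
                         category_levels())
    precision <- setNames(as.numeric(unlist(row[paste0("prec_", category_levels())])),
                          category_levels())
    accuracy_report(detected, precision, row$unclassified_pct,
                    slide_id = as.character(row$slide_code),
                    threshold = row$threshold,
                    total_objects = row$total_images)
  })
}

#' Bundled slide #37 confidence-value example
#'
#' The worked confidence-table example for test slide #37 (500 objects
#' classified with model Cdv%v2): six example object rows rounded to two
#' decimals, the per-category mean confidence over all 500 objects, and the
#' number of objects per category whose confidence exceeds 0.60 and 0.95.
#'
#' @return List with elements `examples` (data frame of six objects),
#'   `category_means` (named numeric over the five categories), and
#'   `threshold_counts` (data frame of per-category counts above each
#'   threshold).
#' @export
reference_slide37 <- function() {
  ex <- read.csv(system.file("extdata", "slide37_confidence_examples.csv",
                             package = "micrassem", mustWork = TRUE),
                 stringsAsFactors = FALSE)
  mn <- read.csv(system.file("extdata", "slide37_category_means.csv",
                             package = "micrassem", mustWork = TRUE),
                 stringsAsFactors = FALSE)
  tc <- read.csv(system.file("extdata", "slide37_threshold_counts.csv",
                             package = "micrassem", mustWork = TRUE),
                 stringsAsFactors = FALSE, check.names = FALSE)
  list(
    examples = ex,
    category_means = setNames(mn$mean_confidence, mn$category),
    threshold_counts = tc
  )
}
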