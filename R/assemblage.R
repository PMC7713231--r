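#' Tally classification records for one slide
#'
#' Counts the objects assigned to each category and the unclassified objects.
#' The counts always sum to the total number of records.
#'
#' @param records Classification record data frame (see [classify_crops()]);
#'   all records must share one threshold.
#' @param slide_id Slide identifier stored in the summary.
#' @return Object of class `slide_summary` with fields `slide_id`,
#'   `total_objects`, `counts` (named per category), `n_unclassified`,
#'   `threshold`.
#' @export
tally <- function(records, slide_id = "slide") {
  if (nrow(records) == 0) {
    return(structure(
      list(slide_id = slide_id, total_objects = 0L,
           counts = setNames(integer(5), category_levels()),
           n_unclassified = 0L, threshold = NA_real_),
      class = "slide_summary"
    ))
  }
  thr <- unique(records$threshold)
  if (length(thr) != 1) stop("all records must share one threshold")
  counts <- vapply(category_levels(),
                   function(cat) sum(records$assigned == cat), integer(1))
  n_unc <- sum(records$assigned == unclassified_label())
  stopifnot(sum(counts) + n_unc == nrow(records))
  structure(
    list(slide_id = slide_id, total_objects = nrow(records),
         counts = counts, n_unclassified = n_unc, threshold = thr),
    class = "slide_summary"
  )
}

#' @export
print.slide_summary <- function(x, ...) {
  cat(sprintf("<slide_summary '%s': %d objects at threshold %.2f>\n",
              x$slide_id, x$total_objects, x$threshold))
  print(c(x$counts, unclassified = x$n_unclassified))
  invisible(x)
}

new_composition_estimate <- function(cdv_pct, method, n_objects) {
  structure(
    list(cdv_pct = cdv_pct, method = method, n_objects = as.integer(n_objects)),
    class = "composition_estimate"
  )
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat(sprintf("<composition_estimate: C. davisiana%% = %.1f (%s, n = %d)>\n",
              x$cdv_pct, x$method, x$n_objects))
  invisible(x)
}

#' Count-based relative abundance of *C. davisiana*
#'
#' The target statistic of the workflow:
#' `C. davisiana % = 100 * n_Cdv / (n_Cdv + n_Cbc + n_Rad)`.
#' The denominator is radiolarians only — diatoms and other particles do not
#' enter. A zero radiolarian denominator is an error (undefined composition,
#' distinct from 0%).
#'
#' @param summary A [tally()] `slide_summary`.
#' @return A `composition_estimate` with `method = "count_based"`;
#'   `n_objects` is the radiolarian count in the denominator.
#' @export
relative_abundance <- function(summary) {
  stopifnot(inherits(summary, "slide_summary"))
  cnt <- summary$counts
  denom <- cnt["Cdv"] + cnt["Cbc"] + cnt["Rad"]
  if (denom == 0) {
    stop("undefined composition: no radiolarians (Cdv + Cbc + Rad = 0)")
  }
  new_composition_estimate(
    cdv_pct = unname(100 * cnt["Cdv"] / denom),
    method = "count_based",
    n_objects = unname(denom)
  )
}

#' Averaged-confidence relative abundance of *C. davisiana*
#'
#' Estimates the composition from the mean confidence value per category over
#' *all* records — no threshold is applied and no object is excluded:
#' `100 * mean(conf_Cdv) / (mean(conf_Cdv) + mean(conf_Cbc) + mean(conf_Rad))`.
#' This trades the per-object accuracy guarantee of thresholded counting for
#' full data retention.
#'
#' @param records Classification record data frame with at least one row; the
#'   `threshold`/`assigned` columns are ignored.
#' @return A `composition_estimate` with `method = "averaged_confidence"`;
#'   `n_objects` is the number of records averaged.
#' @export
averaged_confidence_composition <- function(records) {
  if (nrow(records) < 1) stop("at least one record is required")
  means <- colMeans(records[, paste0("conf_", category_levels())])
  names(means) <- category_levels()
  denom <- means["Cdv"] + means["Cbc"] + means["Rad"]
  if (denom <= 0) {
    stop("undefined composition: radiolarian mean confidences sum to zero")
  }
  new_composition_estimate(
    cdv_pct = unname(100 * means["Cdv"] / denom),
    method = "averaged_confidence",
    n_objects = nrow(records)
  )
}

#' Construct a per-slide accuracy report
#'
#' The report mirrors the published evaluation layout: per category the number
#' of objects the model assigned to it (`detected`) and the precision — the
#' percentage of those whose true label is that category — plus the overall
#' unclassified percentage. Precision is `NA` (undefined, never silently 0)
#' for categories with no detections.
#'
#' @param detected Named integer vector of detections per category.
#' @param precision_pct Named numeric vector of precisions (0–100; `NA` where
#'   `detected` is 0 or the value is unknown).
#' @param unclassified_pct Percentage of all objects left unclassified.
#' @param slide_id,threshold Report metadata.
#' @param total_objects Total objects on the slide (optional, `NA` if unknown).
#' @return Object of class `accuracy_report`.
#' @export
accuracy_report <- function(detected, precision_pct, unclassified_pct,
                            slide_id = "slide", threshold = NA_real_,
                            total_objects = NA_integer_) {
  detected <- detected[category_levels()]
  precision_pct <- precision_pct[category_levels()]
  names(detected) <- names(precision_pct) <- category_levels()
  ok <- !is.na(precision_pct)
  if (any(precision_pct[ok] < 0 | precision_pct[ok] > 100)) {
    stop("precision_pct must lie in [0, 100]")
  }
  if (unclassified_pct < 0 || unclassified_pct > 100) {
    stop("unclassified_pct must lie in [0, 100]")
  }
  structure(
    list(slide_id = slide_id, threshold = threshold,
         total_objects = total_objects,
         detected = detected, precision_pct = precision_pct,
         unclassified_pct = unclassified_pct),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report '%s' (threshold %s): unclassified %.1f%%>\n",
              x$slide_id, format(x$threshold), x$unclassified_pct))
  print(data.frame(detected = x$detected,
                   precision_pct = round(x$precision_pct, 1)))
  invisible(x)
}

#' Evaluate classification records against known true labels
#'
#' @param records Classification record data frame.
#' @param truth Data frame with columns `object_id` and `true_label` covering
#'   every record.
#' @param slide_id Report metadata.
#' @return An [accuracy_report()].
#' @export
evaluate_accuracy <- function(records, truth, slide_id = "slide") {
  m <- match(records$object_id, truth$object_id)
  if (anyNA(m)) {
    missing <- records$object_id[is.na(m)]
    stop("missing truth label for object_id: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  true_label <- as.character(truth$true_label)[m]
  detected <- setNames(integer(5), category_levels())
  precision <- setNames(rep(NA_real_, 5), category_levels())
  for (cat in category_levels()) {
    sel <- records$assigned == cat
    detected[cat] <- sum(sel)
    if (detected[cat] > 0) {
      precision[cat] <- 100 * sum(sel & true_label == cat) / detected[cat]
    }
  }
  unc <- 100 * sum(records$assigned == unclassified_label()) / nrow(records)
  accuracy_report(detected, precision, unc, slide_id = slide_id,
                  threshold = if (nrow(records)) records$threshold[1] else NA_real_,
                  total_objects = nrow(records))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate accuracy reports across slides
#'
#' Computes, per category, the arithmetic mean and the population standard
#' deviation (divisor `n`) of the precision percentages over the reports, and
#' the same for the unclassified percentage. Categories with undefined
#' precision (no detections) on a slide are excluded from that category's
#' aggregation.
#'
#' @param reports List of [accuracy_report()]s (at least one).
#' @return Data frame with one row per category plus an `"unclassified"` row:
#'   columns `category`, `n_slides`, `mean_pct`, `sd_pct`.
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) < 1) stop("at least one report is required")
  stopifnot(all(vapply(reports, inherits, logical(1), "accuracy_report")))
  rows <- lapply(category_levels(), function(cat) {
    v <- vapply(reports, function(r) r$precision_pct[[cat]], numeric(1))
    v <- v[!is.na(v)]
    data.frame(category = cat, n_slides = length(v),
               mean_pct = if (length(v)) mean(v) else NA_real_,
               sd_pct = if (length(v)) pop_sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  u <- vapply(reports, function(r) r$unclassified_pct, numeric(1))
  rows[[length(rows) + 1L]] <- data.frame(
    category = "unclassified", n_slides = length(u),
    mean_pct = mean(u), sd_pct = pop_sd(u), stringsAsFactors = FALSE
  )
  do.call(rbind, rows)
}

#' Fit the manual-count calibration line
#'
#' Ordinary least squares of the manual (expert-count) abundance on the
#' model-estimated abundance, with Pearson's correlation. The regression runs
#' in this direction because the calibration maps model estimates onto actual
#' count data (a slope above 1 reads as model underestimation).
#'
#' @param model_pct Model-estimated abundance series (predictor), not constant.
#' @param manual_pct Manual-count abundance series (response), same length
#'   (>= 2).
#' @return Object of class `calibration_model` with `slope`, `intercept`, `r`,
#'   `n_pairs`.
#' @export
fit_calibration <- function(model_pct, manual_pct) {
  if (length(model_pct) != length(manual_pct)) {
    stop("model_pct and manual_pct must have equal length")
  }
  if (length(model_pct) < 2) stop("at least two pairs are required")
  if (sd(model_pct) == 0) stop("degenerate fit: model_pct is constant")
  fit <- lm(manual_pct ~ model_pct)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = cor(model_pct, manual_pct), n_pairs = length(model_pct)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model: manual = %.3f * model + %.3f, r = %.3f, n = %d>\n",
    x$slope, x$intercept, x$r, x$n_pairs
  ))
  invisible(x)
}

#' Apply a calibration line to model-estimated abundances
#'
#' Elementwise `slope * x + intercept`, clipped to \[0, 100\] (the result is a
#' percentage).
#'
#' @param cal A [fit_calibration()] model.
#' @param model_pct Numeric series of model-estimated abundances.
#' @return Calibrated series.
#' @export
apply_calibration <- function(cal, model_pct) {
  stopifnot(inherits(cal, "calibration_model"))
  pmin(pmax(cal$slope * model_pct + cal$intercept, 0), 100)
}
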