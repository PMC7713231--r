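#' The five particle categories
#'
#' The workflow sorts every segmented particle into one of five fixed
#' categories: the target radiolarian *Cycladophora davisiana* (`Cdv`), the
#' morphologically similar *Cycladophora bicornis* (`Cbc`), all other
#' radiolarians (`Rad`), centric diatoms (`dtm`), and all other particles
#' (`oth`). The order is fixed and is used to break argmax ties
#' deterministically (`Cdv` first).
#'
#' @return Character vector of the five category codes, in canonical order.
#' @export
#' @examples
#' category_levels()
category_levels <- function() {
  c("Cdv", "Cbc", "Rad", "dtm", "oth")
}

#' Sentinel label for objects below the confidence threshold
#' @return The string `"unclassified"`.
#' @export
unclassified_label <- function() "unclassified"

#' Construct and validate a confidence vector
#'
#' A confidence vector holds one score per category, each in \[0, 1\], summing
#' to 1 within a tolerance of 0.02 (published confidence tables are rounded to
#' two decimals, so printed rows may sum to e.g. 0.99).
#'
#' @param x Numeric vector of length 5, optionally named by category; unnamed
#'   vectors are taken in canonical category order.
#' @return Named numeric vector over [category_levels()].
#' @export
#' @examples
#' confidence_vector(c(0.87, 0.08, 0.03, 0.00, 0.01))
confidence_vector <- function(x) {
  if (!is.numeric(x) || length(x) != length(category_levels())) {
    stop("a confidence vector must be numeric of length ", length(category_levels()))
  }
  if (is.null(names(x))) {
    names(x) <- category_levels()
  } else {
    if (!setequal(names(x), category_levels())) {
      stop("confidence vector names must be exactly the five categories")
    }
    x <- x[category_levels()]
  }
  if (anyNA(x)) stop("confidence values must not be NA")
  if (any(x < -1e-9) || any(x > 1 + 1e-9)) {
    stop("confidence values must lie in [0, 1]")
  }
  if (abs(sum(x) - 1) > 0.02) {
    stop("confidence values must sum to 1 within 0.02 (got ", round(sum(x), 4), ")")
  }
  pmin(pmax(x, 0), 1)
}

#' Assign a category from a confidence vector at a threshold
#'
#' The object is assigned to the argmax category if and only if the maximum
#' confidence strictly exceeds the threshold; otherwise it is
#' `"unclassified"`. Ties at the maximum are broken by canonical category
#' order (`Cdv` first). A tie at exactly the threshold yields
#' `"unclassified"` (strictly-greater-than rule).
#'
#' @param conf A [confidence_vector()] (or coercible numeric of length 5).
#' @param threshold Numeric in \[0, 1\]; the workflow's standard operating
#'   points are 0.60 (permissive) and 0.95 (strict).
#' @return A single category code or `"unclassified"`.
#' @export
#' @examples
#' assign_category(c(0.87, 0.08, 0.03, 0.00, 0.01), threshold = 0.60) # "Cdv"
#' assign_category(c(0.87, 0.08, 0.03, 0.00, 0.01), threshold = 0.95) # "unclassified"
assign_category <- function(conf, threshold) {
  conf <- confidence_vector(conf)
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]")
  }
  if (max(conf) > threshold) names(conf)[which.max(conf)] else unclassified_label()
}
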