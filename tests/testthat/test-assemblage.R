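one_hot <- function(cat) {
  v <- setNames(numeric(5), category_levels())
  v[cat] <- 1
  v
}

test_that("tally counts assignments and conserves totals", {
  rec <- records_from(list(one_hot("Cdv"), one_hot("Cdv"),
                           c(0.3, 0.3, 0.2, 0.1, 0.1)), threshold = 0.95)
  s <- tally(rec, "demo")
  expect_equal(unname(s$counts["Cdv"]), 2)
  expect_equal(s$n_unclassified, 1)
  expect_equal(s$total_objects, 3)
  expect_equal(sum(s$counts) + s$n_unclassified, s$total_objects)
  # empty record list -> all-zero summary
  s0 <- tally(rec[0, ], "empty")
  expect_equal(s0$total_objects, 0)
  expect_equal(sum(s0$counts), 0)
})

test_that("nothing is assigned at threshold 1 (strict comparison)", {
  tab <- generate_confidence_table(confidence_table_spec(
    n_objects = 500, composition = c(0.2, 0.2, 0.2, 0.2, 0.2),
    concentration = 1e6, seed = 21
  ))
  rec <- assign_records(tab$records, 1.0)
  s <- tally(rec)
  expect_equal(s$n_unclassified, 500)
})

test_that("tally matches an independent brute-force recount", {
  tab <- generate_confidence_table(confidence_table_spec(
    n_objects = 800,
    composition = c(Cdv = 0.15, Cbc = 0.05, Rad = 0.4, dtm = 0.3, oth = 0.1),
    concentration = 50, seed = 11
  ))
  rec <- assign_records(tab$records, 0.95)
  s <- tally(rec)
  # independent oracle: explicit loop over rows, re-deriving each assignment
  counts <- setNames(integer(5), category_levels())
  unc <- 0L
  for (i in seq_len(nrow(rec))) {
    conf <- as.numeric(rec[i, paste0("conf_", category_levels())])
    if (max(conf) > 0.95) {
      k <- category_levels()[which.max(conf)]
      counts[k] <- counts[k] + 1L
    } else {
      unc <- unc + 1L
    }
  }
  expect_equal(s$counts, counts)
  expect_equal(s$n_unclassified, unc)
})

test_that("count-based relative abundance uses the radiolarian denominator", {
  mk <- function(Cdv, Cbc, Rad, dtm = 0, oth = 0, unc = 0) {
    structure(list(slide_id = "s", total_objects = Cdv + Cbc + Rad + dtm + oth + unc,
                   counts = c(Cdv = Cdv, Cbc = Cbc, Rad = Rad, dtm = dtm, oth = oth),
                   n_unclassified = unc, threshold = 0.95),
              class = "slide_summary")
  }
  # slide #25 detected counts: 117 / (117 + 34 + 858) = 11.6%
  est <- relative_abundance(mk(117, 34, 858))
  expect_equal(round(est$cdv_pct, 1), 11.6)
  expect_equal(est$n_objects, 117 + 34 + 858)
  expect_equal(relative_abundance(mk(0, 5, 95))$cdv_pct, 0)
  # diatoms and other particles never enter the denominator
  expect_equal(relative_abundance(mk(50, 0, 0))$cdv_pct, 100)
  expect_equal(relative_abundance(mk(50, 0, 0, dtm = 1000))$cdv_pct, 100)
  expect_error(relative_abundance(mk(0, 0, 0, dtm = 10)), "undefined composition")
})

test_that("averaged-confidence composition reproduces the worked example", {
  # category means 0.16 / 0.02 / 0.44 -> 100 * 0.16 / 0.62 = 25.8%
  rec <- records_from(list(c(0.16, 0.02, 0.44, 0.33, 0.05)), threshold = 0.95)
  est <- averaged_confidence_composition(rec)
  expect_equal(round(est$cdv_pct, 1), 25.8)
  expect_equal(est$method, "averaged_confidence")
  # one-hot limit agrees with count-based estimation
  rec2 <- records_from(list(one_hot("Cdv"), one_hot("Cdv"), one_hot("Rad")),
                       threshold = 0.5)
  expect_equal(averaged_confidence_composition(rec2)$cdv_pct,
               relative_abundance(tally(rec2))$cdv_pct)
  # uniform confidences -> 33.3%
  unif <- records_from(list(rep(0.2, 5), rep(0.2, 5)), threshold = 0.95)
  expect_equal(averaged_confidence_composition(unif)$cdv_pct, 100 / 3)
  expect_error(averaged_confidence_composition(
    records_from(list(c(0, 0, 0, 0.7, 0.3)), 0.5)), "undefined composition")
})

test_that("averaged-confidence composition ignores the threshold", {
  tab <- generate_confidence_table(confidence_table_spec(
    n_objects = 300, composition = c(0.2, 0.1, 0.4, 0.2, 0.1),
    concentration = 20, seed = 5
  ))
  a <- averaged_confidence_composition(assign_records(tab$records, 0.60))
  b <- averaged_confidence_composition(assign_records(tab$records, 0.95))
  expect_equal(a$cdv_pct, b$cdv_pct)
})

test_that("accuracy evaluation matches an independent confusion matrix", {
  tab <- generate_confidence_table(confidence_table_spec(
    n_objects = 600,
    composition = c(Cdv = 0.2, Cbc = 0.1, Rad = 0.4, dtm = 0.2, oth = 0.1),
    concentration = 10, seed = 13
  ))
  rec <- assign_records(tab$records, 0.60)
  rep <- evaluate_accuracy(rec, tab$truth)
  # independent oracle via table()
  cm <- table(assigned = rec$assigned,
              truth = tab$truth$true_label[match(rec$object_id,
                                                 tab$truth$object_id)])
  for (cat in category_levels()) {
    det <- if (cat %in% rownames(cm)) sum(cm[cat, ]) else 0
    expect_equal(unname(rep$detected[cat]), det)
    if (det > 0) {
      hit <- if (cat %in% colnames(cm)) cm[cat, cat] else 0
      expect_equal(unname(rep$precision_pct[cat]), 100 * hit / det)
    } else {
      expect_true(is.na(rep$precision_pct[cat]))
    }
  }
  expect_equal(rep$unclassified_pct,
               100 * sum(rec$assigned == "unclassified") / nrow(rec))
})

test_that("perfect assignment yields 100% precision and 0% unclassified", {
  rec <- records_from(list(one_hot("Cdv"), one_hot("Rad"), one_hot("dtm")), 0.5)
  truth <- data.frame(object_id = 1:3, true_label = c("Cdv", "Rad", "dtm"))
  rep <- evaluate_accuracy(rec, truth)
  expect_equal(unname(rep$precision_pct[c("Cdv", "Rad", "dtm")]), rep(100, 3))
  expect_equal(rep$unclassified_pct, 0)
  # zero detections stay NA, never 0%
  expect_true(is.na(rep$precision_pct["Cbc"]))
})

test_that("missing truth labels name the offending object", {
  rec <- records_from(list(one_hot("Cdv")), 0.5)
  rec$object_id <- 42L
  expect_error(evaluate_accuracy(rec, data.frame(object_id = 1,
                                                 true_label = "Cdv")), "42")
})

test_that("report aggregation uses the arithmetic mean and population S.D.", {
  vals <- c(26.7, 31.8, 60.4, 77.6, 78.7)
  reports <- lapply(vals, function(v) {
    accuracy_report(detected = c(Cdv = 10L, Cbc = 0L, Rad = 0L, dtm = 0L, oth = 0L),
                    precision_pct = c(Cdv = v, Cbc = NA, Rad = NA, dtm = NA, oth = NA),
                    unclassified_pct = 8.2)
  })
  agg <- aggregate_reports(reports)
  cdv <- agg[agg$category == "Cdv", ]
  expect_equal(cdv$mean_pct, mean(vals))          # 55.04
  expect_equal(cdv$sd_pct, sqrt(mean((vals - mean(vals))^2)))
  expect_equal(round(cdv$sd_pct, 1), 22.1)        # pins the divisor-n convention
  expect_equal(cdv$n_slides, 5)
  # categories undefined everywhere are excluded (n = 0, NA mean)
  expect_equal(agg[agg$category == "Cbc", "n_slides"], 0)
  # single report: mean equals the value, S.D. is zero
  agg1 <- aggregate_reports(reports[1])
  expect_equal(agg1[agg1$category == "Cdv", "mean_pct"], 26.7)
  expect_equal(agg1[agg1$category == "Cdv", "sd_pct"], 0)
})

test_that("calibration fitting recovers exact and noisy linear relations", {
  x <- c(2, 5, 9, 14, 23)
  ident <- fit_calibration(x, x)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r, 1)
  aff <- fit_calibration(x, 1.2 * x + 0.5)
  expect_equal(aff$slope, 1.2)
  expect_equal(aff$intercept, 0.5)
  expect_equal(aff$r, 1)
  expect_error(fit_calibration(rep(3, 4), 1:4), "degenerate")
  expect_error(fit_calibration(1:3, 1:4), "equal length")
  # parameter recovery under noise: slope 1.3 within 3 standard errors
  withr::with_seed(29, {
    mx <- runif(200, 0, 25)
    my <- 1.3 * mx + rnorm(200, 0, 1)
    cal <- fit_calibration(mx, my)
    se <- summary(lm(my ~ mx))$coefficients["mx", "Std. Error"]
    expect_lt(abs(cal$slope - 1.3), 3 * se)
  })
})

test_that("calibration application is affine and clipped to [0, 100]", {
  cal <- structure(list(slope = 1.2, intercept = 0.5, r = 0.99, n_pairs = 8),
                   class = "calibration_model")
  expect_equal(apply_calibration(cal, 10), 12.5)
  expect_equal(apply_calibration(cal, 90), 100)  # clipped
  expect_equal(apply_calibration(cal, -10), 0)   # clipped below
  ident <- structure(list(slope = 1, intercept = 0, r = 1, n_pairs = 2),
                     class = "calibration_model")
  expect_equal(apply_calibration(ident, c(0, 11.6, 100)), c(0, 11.6, 100))
})

test_that("bundled benchmark reports load with the documented layout", {
  reps <- reference_reports("Cdv%v2", 0.60)
  expect_length(reps, 5)
  reps95 <- reference_reports("Cdv%v2", 0.95)
  expect_length(reps95, 8)
  # slide #25 at threshold 0.95: the counts behind the 11.6% worked example
  expect_equal(unname(reps95[[4]]$detected[c("Cdv", "Cbc", "Rad")]),
               c(117L, 34L, 858L))
  expect_true(all(is.na(vapply(reps95, function(r) r$precision_pct[["dtm"]],
                               numeric(1)))))
  s37 <- reference_slide37()
  expect_equal(unname(s37$category_means["Rad"]), 0.44)
  expect_equal(nrow(s37$examples), 6)
})
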