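# Brute-force Dice oracle: explicit pixel-index set arithmetic.
dice_oracle <- function(a, b, cl) {
  wa <- which(a == cl); wb <- which(b == cl)
  if (length(wa) + length(wb) == 0) return(1)
  2 * length(intersect(wa, wb)) / (length(wa) + length(wb))
}

test_that("dice matches the set-arithmetic oracle exactly on random masks", {
  set.seed(11)
  for (i in 1:200) {
    a <- random_mask(32, 32, n_class = 3, seed = i)
    b <- random_mask(32, 32, n_class = 3, seed = i + 1000)
    cl <- sample(0:3, 1)
    expect_identical(dice_coefficient(a, b, cl), dice_oracle(a, b, cl))
  }
})

test_that("dice endpoints, symmetry and conventions", {
  a <- matrix(c(1L, 1L, 0L, 0L), 2)
  expect_equal(dice_coefficient(a, a, 1L), 1)
  b <- matrix(c(0L, 0L, 1L, 1L), 2)
  expect_equal(dice_coefficient(a, b, 1L), 0)
  # |A| = 4, |B| = 6, overlap 3 -> 2*3/10
  a <- matrix(0L, 4, 4); a[1:4] <- 1L
  b <- matrix(0L, 4, 4); b[2:7] <- 1L
  expect_equal(dice_coefficient(a, b, 1L), 0.6)
  expect_equal(dice_coefficient(a, b, 1L), dice_coefficient(b, a, 1L))
  # class absent from both masks counts as perfect agreement
  expect_equal(dice_coefficient(a, b, 9L), 1)
  expect_error(dice_coefficient(matrix(0L, 2, 2), matrix(0L, 3, 3), 1L),
               "dimensions")
})

test_that("dice_report aggregates per class and case", {
  truth <- list(random_mask(16, 16, 2, 1), random_mask(16, 16, 2, 2))
  rep <- dice_report(truth, truth, case_ids = c("a", "b"))
  expect_true(all(rep$per_case$dice == 1))
  expect_equal(rep$overall_mean, 1)
})

test_that("cut-off classification matches brute-force enumeration", {
  ratios <- data.frame(case_id = sprintf("c%d", 1:4),
                       phase = 3L, region = "mcp",
                       ratio = c(1.0, 1.31, 1.32, 2.0))
  cls <- classify_cohort(ratios, cutoff = 1.32)
  expect_identical(cls$n_positive, 2L)   # inclusive boundary: 1.32 counts
  expect_identical(cls$n_total, 4L)
  all_one <- data.frame(case_id = sprintf("c%d", 1:5), phase = 3L,
                        region = "mcp", ratio = 1.0)
  expect_identical(classify_cohort(all_one, 1.32)$n_positive, 0L)
  expect_identical(classify_cohort(all_one, 0)$n_positive, 5L)
  set.seed(21)
  for (i in 1:50) {
    r <- runif(sample(1:30, 1), 0.5, 2.5)
    cut <- runif(1, 0.8, 2)
    df <- data.frame(case_id = sprintf("c%d", seq_along(r)), phase = 3L,
                     region = "mcp", ratio = r)
    expect_identical(classify_cohort(df, cut)$n_positive, sum(r >= cut))
  }
})

test_that("cases lacking the target ratio are excluded with a warning", {
  ratios <- data.frame(case_id = c("a", "a", "b"),
                       phase = c(3L, 1L, 1L),
                       region = c("mcp", "whole_hand", "whole_hand"),
                       ratio = c(1.5, 1.1, 1.2))
  expect_warning(cls <- classify_cohort(ratios, 1.32), "excluded")
  expect_identical(cls$n_total, 1L)
  expect_identical(cls$missing, "b")
})

test_that("sensitivity/specificity match contingency arithmetic exhaustively", {
  expect_equal(sensitivity_specificity(c(TRUE, FALSE), c(TRUE, FALSE)),
               list(sensitivity = 1, specificity = 1, tp = 1L, fp = 0L,
                    tn = 1L, fn = 0L),
               ignore_attr = TRUE)
  mixed <- sensitivity_specificity(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mixed$sensitivity, 1)
  expect_equal(mixed$specificity, 0)
  r <- sensitivity_specificity(rep(c(TRUE, FALSE, FALSE, TRUE), c(9, 4, 9, 3)),
                               rep(c(TRUE, FALSE), c(13, 12)))
  expect_equal(r$sensitivity, 9 / 13, tolerance = 1e-12)
  expect_equal(r$specificity, 9 / 12, tolerance = 1e-12)
  # exhaustive over all 2x2 tables with margins <= 12 (property; larger
  # margins exercised in the acceptance suite)
  for (tp in 0:12) for (fn in 0:3) for (tn in 0:3) for (fp in 0:3) {
    flags <- rep(c(TRUE, FALSE, FALSE, TRUE), c(tp, fn, tn, fp))
    truth <- rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fn, tn, fp))
    got <- sensitivity_specificity(flags, truth)
    expect_equal(got$sensitivity,
                 if (tp + fn > 0) tp / (tp + fn) else NA_real_)
    expect_equal(got$specificity,
                 if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }
  expect_error(sensitivity_specificity(TRUE, c(TRUE, FALSE)), "lengths differ")
})

test_that("undefined metrics are NA, never 0", {
  r <- sensitivity_specificity(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(r$sensitivity))
  expect_equal(r$specificity, 0.5)
})

test_that("ratio summaries use linear-interpolation quantiles", {
  df <- data.frame(case_id = "x", phase = 3L, region = "mcp",
                   ratio = c(1, 2, 3))
  s <- summarise_ratios(df)
  expect_equal(s$median, 2)
  one <- summarise_ratios(data.frame(case_id = "x", phase = 1L,
                                     region = "whole_foot", ratio = 1.4))
  expect_equal(unlist(one[, c("q1", "median", "q3")]),
               c(1.4, 1.4, 1.4), ignore_attr = TRUE)
  four <- summarise_ratios(data.frame(case_id = "x", phase = 3L,
                                      region = "pip", ratio = 1:4))
  expect_equal(four$q1, 1.75)
  expect_equal(four$q3, 3.25)
})
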