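test_that("intensity inversion maps endpoints correctly and is an involution", {
  expect_identical(invert_intensity(matrix(0L)), matrix(255L))
  expect_identical(invert_intensity(matrix(255L)), matrix(0L))
  expect_identical(invert_intensity(matrix(100L, 3, 3)), matrix(155L, 3, 3))
  m <- matrix(sample(0:255, 64, replace = TRUE), 8)
  expect_identical(invert_intensity(invert_intensity(m)), m)
  expect_error(invert_intensity(matrix(300L)), "0, 255")
})

test_that("ROI means are plain arithmetic means with a minimum-size guard", {
  labels <- matrix(0L, 10, 10)
  labels[1:5, 1:5] <- 1L
  legend <- data.frame(label = 1L, region = "mcp", side = "left")
  mask <- tpbs_mask(labels, legend)
  inv <- matrix(150, 10, 10)
  expect_equal(roi_mean(inv, mask, "mcp", "left")$mean, 150)
  inv[1:5, 1:5] <- rep(c(100, 200), length.out = 25)
  small <- matrix(0L, 10, 10); small[1, 1:4] <- 1L
  expect_equal(roi_mean(inv, mask, "mcp", "left", min_roi_pixels = 4)$mean,
               mean(inv[1:5, 1:5]))
  expect_error(roi_mean(inv, tpbs_mask(small, legend), "mcp", "left"),
               "quantification error")
  expect_error(roi_mean(inv, mask, "mcp", "right"), "absent from mask legend")
})

test_that("ratio arithmetic and its guards", {
  expect_equal(compute_ratio(150, 150), 1.0)
  expect_equal(compute_ratio(120, 100), 1.2)
  expect_error(compute_ratio(100, 0), "undefined")
})

test_that("cases yield the scheme's ratio count: 5 for hands, 3 for feet", {
  hand <- quantify_case(tiny_case("hand"))
  expect_identical(nrow(hand), 5L)
  expect_identical(hand$region, c("whole_hand", "whole_hand",
                                  "carpal", "mcp", "pip"))
  foot <- quantify_case(tiny_case("foot"))
  expect_identical(nrow(foot), 3L)
  expect_true(all(foot$region == "whole_foot"))
})

test_that("noiseless symmetric phantoms give ratios of exactly 1", {
  for (ext in c("hand", "foot")) {
    res <- quantify_case(tiny_case(ext, f = 1, noise_sd = 0, seed = 3))
    expect_true(all(abs(res$ratio - 1) < 1e-9))
    expect_true(all(res$mean_ipsi >= 0 & res$mean_ipsi <= 255))
  }
})

test_that("swapping the affected side inverts every ratio exactly", {
  # identical seed => identical geometry; only the ipsi/contra roles swap
  left <- quantify_case(tiny_case("hand", "left", f = 1.6, noise_sd = 0, seed = 8))
  right_case <- tiny_case("hand", "left", f = 1.6, noise_sd = 0, seed = 8)
  right_case$spec$affected_side <- "right"
  right <- quantify_case(right_case)
  expect_equal(right$ratio, 1 / left$ratio, tolerance = 1e-12)
})

test_that("ratios are scale-invariant but offset-sensitive (no silent background handling)", {
  case <- tiny_case("hand", f = 1.5, noise_sd = 0, seed = 4)
  res <- quantify_case(case)
  r_mcp <- res$ratio[res$region == "mcp"]
  inv3 <- invert_intensity(case$images[[3]])
  mask <- case$masks[[3]]
  mi <- roi_mean(inv3 * 0.5, mask, "mcp", "left", 1)$mean
  mc <- roi_mean(inv3 * 0.5, mask, "mcp", "right", 1)$mean
  expect_equal(compute_ratio(mi, mc), r_mcp, tolerance = 1e-12)
  mi <- roi_mean(inv3 + 50, mask, "mcp", "left", 1)$mean
  mc <- roi_mean(inv3 + 50, mask, "mcp", "right", 1)$mean
  expect_false(isTRUE(all.equal(compute_ratio(mi, mc), r_mcp, tolerance = 1e-3)))
})

test_that("missing scheme regions are reported as quantification errors", {
  case <- tiny_case("hand")
  bad <- case$masks
  legend <- data.frame(label = 1:2, region = "carpal",
                       side = c("left", "right"))
  lab <- bad[[3]]$labels
  lab[!lab %in% 1:2] <- 0L
  bad[[3]] <- tpbs_mask(lab, legend)
  expect_error(quantify_case(case, bad), "lacks region")
})

test_that("cohort quantification skips failing cases with a warning", {
  cases <- list(tiny_case("hand", seed = 1), tiny_case("hand", seed = 2))
  masks_list <- list(cases[[1]]$masks, cases[[2]]$masks)
  masks_list[[2]][[3]] <- NULL
  expect_warning(res <- quantify_cohort(cases, masks_list), "skipped")
  expect_identical(unique(res$case_id), cases[[1]]$spec$case_id)
})
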