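test_that("noiseless symmetric phantoms are exact mirror images in every phase", {
  for (ext in c("hand", "foot")) {
    case <- tiny_case(ext, f = 1, noise_sd = 0, seed = 9)
    for (phase in 1:3) {
      px <- case$images[[phase]]$pixels
      expect_identical(px, px[, rev(seq_len(ncol(px)))])
    }
  }
})

test_that("generation is deterministic given the seed", {
  a <- tiny_case("hand", f = 1.5, noise_sd = 8, seed = 123)
  b <- tiny_case("hand", f = 1.5, noise_sd = 8, seed = 123)
  for (phase in 1:3) {
    expect_identical(a$images[[phase]]$pixels, b$images[[phase]]$pixels)
    expect_identical(a$masks[[phase]]$labels, b$masks[[phase]]$labels)
  }
  c2 <- tiny_case("hand", f = 1.5, noise_sd = 8, seed = 124)
  expect_false(identical(a$images[[3]]$pixels, c2$images[[3]]$pixels))
})

test_that("enhanced affected-side regions are darker than contralateral", {
  case <- tiny_case("hand", "left", f = 1.5, enhanced = "mcp", noise_sd = 0)
  img <- case$images[[3]]
  mask <- case$masks[[3]]
  ipsi <- img$pixels[mask$labels == tpbsquant:::mask_label(mask, "mcp", "left")]
  contra <- img$pixels[mask$labels == tpbsquant:::mask_label(mask, "mcp", "right")]
  # dark = high uptake: the enhanced side must have strictly lower values
  expect_lt(mean(ipsi), mean(contra))
  expect_true(all(sort(ipsi) <= sort(contra)))
})

test_that("increasing f monotonically darkens enhanced ROIs and leaves the other side fixed", {
  means_ipsi <- c(); contra_ref <- NULL
  for (f in c(1, 1.3, 1.7, 2)) {
    case <- tiny_case("hand", "left", f = f, noise_sd = 0, seed = 5)
    mask <- case$masks[[3]]
    inv <- invert_intensity(case$images[[3]])
    means_ipsi <- c(means_ipsi,
                    roi_mean(inv, mask, "mcp", "left")$mean)
    contra <- roi_mean(inv, mask, "mcp", "right")$mean
    if (is.null(contra_ref)) contra_ref <- contra
    expect_equal(contra, contra_ref, tolerance = 1e-12)
  }
  expect_true(all(diff(means_ipsi) > 0))
})

test_that("phantom masks satisfy the annotation scheme and minimum ROI sizes", {
  for (ext in c("hand", "foot")) {
    case <- tiny_case(ext)
    for (phase in 1:3) {
      legend <- case$masks[[phase]]$legend
      expect_setequal(unique(legend$region), scheme_regions(ext, phase))
      for (i in seq_len(nrow(legend)))
        expect_gte(sum(case$masks[[phase]]$labels == legend$label[i]), 20)
    }
  }
})

test_that("invalid specs are rejected as configuration errors", {
  expect_error(phantom_spec(image_size = 32), "image_size")
  expect_error(phantom_spec(image_size = 65), "even")
  expect_error(phantom_spec(enhancement_factor = 0), "enhancement_factor")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec("foot", enhanced_regions = "mcp"), "enhanced_regions")
  expect_error(phantom_spec("elbow"), "arg")
})

test_that("cohorts have the requested size, record realised specs, and are reproducible", {
  a <- generate_cohort(10, "hand", enhancement_factors = c(1.2, 1.5, 2),
                       image_size = 64, seed = 77)
  b <- generate_cohort(10, "hand", enhancement_factors = c(1.2, 1.5, 2),
                       image_size = 64, seed = 77)
  expect_length(a, 10)
  fs <- vapply(a, function(cs) cs$spec$enhancement_factor, numeric(1))
  expect_true(all(fs %in% c(1.2, 1.5, 2)))
  expect_gt(length(unique(fs)), 1)
  for (i in seq_along(a)) {
    expect_length(a[[i]]$images, 3)
    expect_identical(a[[i]]$images[[1]]$pixels, b[[i]]$images[[1]]$pixels)
    expect_identical(a[[i]]$spec$seed, b[[i]]$spec$seed)
  }
  expect_error(generate_cohort(0), "n must be")
})

test_that("expected contrast equals f for fully enhanced ROIs and exceeds 1 for mixtures", {
  spec <- tiny_spec("hand", "left", enhancement_factor = 1.5)
  for (rg in c("carpal", "mcp", "pip"))
    expect_equal(expected_contrast(spec, 3, rg), 1.5)
  mix <- expected_contrast(spec, 1, "whole_hand")
  expect_gt(mix, 1)
  expect_lt(mix, 1.5)
  spec1 <- tiny_spec("hand", "left", enhancement_factor = 1)
  expect_equal(expected_contrast(spec1, 3, "mcp"), 1)
})
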