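# Synthetic three-phase bone scintigraphy (TPBS) phantoms.
#
# A phantom is a parametric stand-in for one clinical acquisition: two
# mirror-symmetric limb silhouettes (hand or foot) rendered in the planar
# scintigraphy display convention where HIGHER tracer uptake appears as a
# LOWER (darker) 8-bit pixel value.  Each case carries three phase images
# (flow, blood pool, delayed/bone) plus crisp ground-truth region masks,
# so segmentation, uncertainty and ratio quantification are all testable
# without patient data.

# Display gain: display units per activity unit.  Chosen so that baseline
# bone-region activity (~1.0-1.15) maps to an inverted intensity near
# mid-range (~128), leaving headroom for enhancement factors up to ~2
# before the 8-bit range clips.
TPBS_GAIN <- 100

# Per-phase blur multipliers applied to blur_sigma: phases 1-2 (flow,
# blood pool) are rendered more diffuse than the bone-localised phase 3.
TPBS_PHASE_BLUR <- c(1.8, 1.4, 1.0)

#' Default per-region tracer activity by phase
#'
#' Activity is in arbitrary units; the display mapping multiplies it by a
#' fixed gain of 100 display units per activity unit.  Values emulate the
#' qualitative phase behaviour of TPBS: diffuse soft-tissue dominated
#' uptake in phases 1-2, bone/joint-localised uptake in phase 3.
#'
#' @param extremity `"hand"` or `"foot"`.
#' @return Named list mapping region name to a numeric vector of length 3
#'   (activity in phases 1, 2, 3).
#' @export
default_uptake <- function(extremity = c("hand", "foot")) {
  extremity <- match.arg(extremity)
  if (extremity == "hand") {
    list(
      background  = c(0.02, 0.02, 0.02),
      soft_tissue = c(0.70, 0.80, 0.25),
      carpal      = c(0.85, 0.95, 1.05),
      mcp         = c(0.90, 1.00, 1.15),
      pip         = c(0.85, 0.95, 1.00)
    )
  } else {
    list(
      background  = c(0.02, 0.02, 0.02),
      soft_tissue = c(0.55, 0.65, 0.30),
      whole_foot  = c(0.80, 0.90, 1.05)
    )
  }
}

#' Regions available for enhancement on a given extremity
#' @param extremity `"hand"` or `"foot"`.
#' @return Character vector of region names.
#' @export
phantom_regions <- function(extremity = c("hand", "foot")) {
  extremity <- match.arg(extremity)
  if (extremity == "hand") c("carpal", "mcp", "pip") else "whole_foot"
}

#' Specification of one synthetic TPBS case
#'
#' @param extremity `"hand"` or `"foot"`.
#' @param affected_side `"left"` or `"right"` (image-space laterality: the
#'   left limb occupies the left half of the frame, i.e. lower column
#'   indices; this is NOT patient-space laterality).
#' @param image_size Side length in pixels of the square frame (even,
#'   >= 64; default 400).
#' @param baseline_uptake Named list region -> length-3 activity vector;
#'   defaults to [default_uptake()].
#' @param enhancement_factor Multiplicative uptake factor `f > 0` applied
#'   to `enhanced_regions` on the affected side (all phases).
#' @param enhanced_regions Regions receiving the enhancement; default all
#'   joint regions (hand) or the whole foot.
#' @param noise_sd Standard deviation of additive Gaussian noise in
#'   display-intensity units (>= 0).
#' @param blur_sigma Point-spread smoothing width in pixels for phase 3;
#'   phases 1 and 2 use 1.8x and 1.4x this value.
#' @param jitter If `TRUE`, per-case geometric scale/shift and per-region
#'   uptake variability (identical on both sides) are drawn from the seed.
#' @param seed Integer RNG seed; generation is deterministic given it.
#' @param case_id Identifier attached to images and sidecars.
#' @return A `tpbs_spec` object.
#' @export
phantom_spec <- function(extremity = c("hand", "foot"),
                         affected_side = c("left", "right"),
                         image_size = 400L,
                         baseline_uptake = NULL,
                         enhancement_factor = 1,
                         enhanced_regions = NULL,
                         noise_sd = 6,
                         blur_sigma = 1.2,
                         jitter = TRUE,
                         seed = 1L,
                         case_id = "case001") {
  extremity <- match.arg(extremity)
  affected_side <- match.arg(affected_side)
  image_size <- as.integer(image_size)
  if (length(image_size) != 1L || is.na(image_size) || image_size < 64L)
    stop("config error: image_size must be a single integer >= 64", call. = FALSE)
  if (image_size %% 2L != 0L)
    stop("config error: image_size must be even (the frame is split at the vertical midline)",
         call. = FALSE)
  if (!is.numeric(enhancement_factor) || enhancement_factor <= 0)
    stop("config error: enhancement_factor must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0", call. = FALSE)
  if (blur_sigma < 0) stop("config error: blur_sigma must be >= 0", call. = FALSE)
  if (is.null(baseline_uptake)) baseline_uptake <- default_uptake(extremity)
  if (is.null(enhanced_regions)) enhanced_regions <- phantom_regions(extremity)
  bad <- setdiff(enhanced_regions, phantom_regions(extremity))
  if (length(bad) > 0)
    stop("config error: enhanced_regions not defined for ", extremity, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    extremity = extremity, affected_side = affected_side,
    image_size = image_size, baseline_uptake = baseline_uptake,
    enhancement_factor = enhancement_factor,
    enhanced_regions = enhanced_regions,
    noise_sd = noise_sd, blur_sigma = blur_sigma,
    jitter = isTRUE(jitter), seed = as.integer(seed), case_id = case_id
  ), class = "tpbs_spec")
}

#' @export
print.tpbs_spec <- function(x, ...) {
  cat(sprintf("TPBS phantom spec: %s, affected %s, %dx%d px, f = %g on {%s}, noise_sd = %g\n",
              x$extremity, x$affected_side, x$image_size, x$image_size,
              x$enhancement_factor, paste(x$enhanced_regions, collapse = ", "),
              x$noise_sd))
  invisible(x)
}

# Run code with the RNG seeded locally, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- geometry -------------------------------------------------------------

# Geometry codes in the half-canvas label map.
HAND_CODES <- c(soft_tissue = 1L, carpal = 2L, mcp = 3L, pip = 4L, forearm = 5L)
FOOT_CODES <- c(leg = 1L, whole_foot = 2L)

# Render the LEFT limb on a half canvas (size x size/2 pixels) as an
# integer code map.  Coordinates are in units of the image height: x in
# (0, 0.5] across the half width, y in (0, 1] downward.  jit is a list
# with scale and shift; the same jit is used for both limbs so the frame
# stays mirror-symmetric up to enhancement and noise.
limb_geometry <- function(extremity, size, jit) {
  h <- size; hw <- size %/% 2L
  x <- ((seq_len(hw) - 0.5) / h - 0.25 - jit$dx) / jit$scale + 0.25
  y <- ((seq_len(h) - 0.5) / h - 0.50 - jit$dy) / jit$scale + 0.50
  X <- matrix(x, nrow = h, ncol = hw, byrow = TRUE)
  Y <- matrix(y, nrow = h, ncol = hw)
  g <- matrix(0L, h, hw)
  inside_ellipse <- function(cx, cy, rx, ry)
    ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
  inside_box <- function(cx, hwid, y0, y1)
    abs(X - cx) <= hwid & Y >= y0 & Y <= y1
  if (extremity == "hand") {
    g[inside_box(0.25, 0.060, 0.675, 0.95)] <- HAND_CODES[["forearm"]]
    g[inside_ellipse(0.25, 0.50, 0.135, 0.17)] <- HAND_CODES[["soft_tissue"]]
    fx <- 0.25 + c(-0.12, -0.04, 0.04, 0.12)
    for (cx in fx) g[inside_box(cx, 0.025, 0.10, 0.37)] <- HAND_CODES[["soft_tissue"]]
    g[inside_box(0.25, 0.065, 0.575, 0.675)] <- HAND_CODES[["carpal"]]
    for (cx in fx) g[inside_ellipse(cx, 0.37, 0.034, 0.034)] <- HAND_CODES[["mcp"]]
    for (cx in fx) g[inside_ellipse(cx, 0.22, 0.030, 0.030)] <- HAND_CODES[["pip"]]
  } else {
    g[inside_box(0.25, 0.050, 0.80, 0.97)] <- FOOT_CODES[["leg"]]
    g[inside_ellipse(0.25, 0.45, 0.120, 0.28)] <- FOOT_CODES[["whole_foot"]]
    g[inside_ellipse(0.25, 0.76, 0.095, 0.095)] <- FOOT_CODES[["whole_foot"]]
  }
  g
}

# Map geometry code -> uptake region name.
code_region <- function(extremity) {
  if (extremity == "hand")
    c("soft_tissue", "carpal", "mcp", "pip", "soft_tissue")
  else
    c("soft_tissue", "whole_foot")
}

# Geometry codes belonging to each ANNOTATED region (mask regions).
mask_region_codes <- function(extremity) {
  if (extremity == "hand")
    list(whole_hand = unname(HAND_CODES[c("soft_tissue", "carpal", "mcp", "pip")]),
         carpal = HAND_CODES[["carpal"]],
         mcp = HAND_CODES[["mcp"]],
         pip = HAND_CODES[["pip"]])
  else
    list(whole_foot = FOOT_CODES[["whole_foot"]])
}

# Geometry codes receiving the enhancement factor.
enhanced_codes <- function(extremity, enhanced_regions) {
  codes <- if (extremity == "hand") HAND_CODES else FOOT_CODES
  unname(codes[names(codes) %in% enhanced_regions])
}

# Deterministic scene for a spec: geometry code map (left half) and the
# per-phase activity lookup (region x phase, jittered).  The same RNG
# stream later supplies the pixel noise, so generation order is fixed.
phantom_scene <- function(spec) {
  jit <- list(scale = 1, dx = 0, dy = 0)
  up <- spec$baseline_uptake
  if (spec$jitter) {
    jit <- list(scale = runif(1, 0.92, 1.06),
                dx = runif(1, -0.025, 0.025),
                dy = runif(1, -0.025, 0.025))
    for (r in names(up)) if (r != "background")
      up[[r]] <- up[[r]] * exp(rnorm(3, 0, 0.04))
  }
  geom <- limb_geometry(spec$extremity, spec$image_size, jit)
  list(geom = geom, uptake = up, jit = jit)
}

# Activity for the LEFT half canvas in one phase, without enhancement.
half_activity <- function(scene, extremity, phase) {
  regions <- code_region(extremity)
  up <- scene$uptake
  act <- matrix(up[["background"]][phase], nrow(scene$geom), ncol(scene$geom))
  for (code in seq_along(regions)) {
    sel <- scene$geom == code
    if (any(sel)) act[sel] <- up[[regions[code]]][phase]
  }
  act
}

# --- symmetric separable Gaussian blur ------------------------------------

# Separable Gaussian blur with replicate (edge-clamp) boundary.  Offsets
# +d and -d are summed as a pair before being accumulated, which makes
# the operator EXACTLY equivariant under horizontal mirroring in floating
# point (IEEE addition is commutative), so noiseless symmetric phantoms
# stay bit-mirror-symmetric after smoothing.
gaussian_blur_sym <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  w0 <- w[r + 1L]
  shift_cols <- function(a, d) {
    idx <- pmin(pmax(seq_len(ncol(a)) - d, 1L), ncol(a))
    a[, idx, drop = FALSE]
  }
  shift_rows <- function(a, d) {
    idx <- pmin(pmax(seq_len(nrow(a)) - d, 1L), nrow(a))
    a[idx, , drop = FALSE]
  }
  out <- w0 * m
  for (d in seq_len(r))
    out <- out + w[r + 1L + d] * (shift_cols(m, d) + shift_cols(m, -d))
  m <- out
  out <- w0 * m
  for (d in seq_len(r))
    out <- out + w[r + 1L + d] * (shift_rows(m, d) + shift_rows(m, -d))
  out
}

# --- generation -----------------------------------------------------------

mirror_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Generate one synthetic TPBS case
#'
#' Renders the three phase images and their ground-truth region masks.
#' Per-pixel activity equals the baseline uptake of the pixel's region,
#' multiplied by the enhancement factor inside `enhanced_regions` on the
#' affected side; activity is smoothed with a Gaussian point-spread,
#' mapped to display intensity as `v = clamp(255 - round(100 * activity),
#' 0, 255)` (dark = high uptake), then additive Gaussian noise is applied
#' and the result re-clamped.  Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A `tpbs_case`: list with `images` (3 [tpbs_image]s), `masks`
#'   (3 [tpbs_mask]s, one per phase) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "tpbs_spec"))
  with_seed(spec$seed, {
    scene <- phantom_scene(spec)
    size <- spec$image_size
    ecodes <- enhanced_codes(spec$extremity, spec$enhanced_regions)
    images <- vector("list", 3L)
    masks <- vector("list", 3L)
    enh_mask <- matrix(FALSE, size, size %/% 2L)
    enh_mask[scene$geom %in% ecodes] <- TRUE
    for (phase in 1:3) {
      half <- half_activity(scene, spec$extremity, phase)
      ipsi <- half
      ipsi[enh_mask] <- ipsi[enh_mask] * spec$enhancement_factor
      act <- if (spec$affected_side == "left")
        cbind(ipsi, mirror_cols(half)) else cbind(half, mirror_cols(ipsi))
      act <- gaussian_blur_sym(act, spec$blur_sigma * TPBS_PHASE_BLUR[phase])
      v <- pmin(pmax(255 - round(TPBS_GAIN * act), 0), 255)
      if (spec$noise_sd > 0) {
        v <- v + round(matrix(rnorm(length(v), 0, spec$noise_sd), nrow(v)))
        v <- pmin(pmax(v, 0), 255)
      }
      images[[phase]] <- tpbs_image(matrix(as.integer(v), size, size),
                                    phase = phase, extremity = spec$extremity,
                                    affected_side = spec$affected_side,
                                    case_id = spec$case_id)
      masks[[phase]] <- phantom_mask(scene$geom, spec$extremity, phase)
    }
    structure(list(images = images, masks = masks, spec = spec),
              class = "tpbs_case")
  })
}

# Ground-truth mask for one phase: region labels follow the annotation
# scheme (hand: whole hand in phases 1-2, carpal/MCP/PIP in phase 3;
# foot: whole foot in all phases), with separate left/right labels.
phantom_mask <- function(geom, extremity, phase) {
  regions <- scheme_regions(extremity, phase)
  codes <- mask_region_codes(extremity)
  size <- nrow(geom)
  left <- matrix(0L, size, size %/% 2L)
  right <- left
  legend <- data.frame(label = integer(0), region = character(0),
                       side = character(0), stringsAsFactors = FALSE)
  lab <- 0L
  for (rg in regions) {
    sel <- geom %in% codes[[rg]]
    lab_l <- lab + 1L; lab_r <- lab + 2L; lab <- lab + 2L
    left[sel] <- lab_l
    right[sel] <- lab_r
    legend <- rbind(legend,
                    data.frame(label = c(lab_l, lab_r), region = rg,
                               side = c("left", "right"),
                               stringsAsFactors = FALSE))
  }
  tpbs_mask(cbind(left, mirror_cols(right)), legend)
}

#' Expected ipsilateral/contralateral contrast induced by a phantom spec
#'
#' Computes, from the unsmoothed activity maps and the display mapping,
#' the inverted-intensity ratio a given (phase, region) ROI would show
#' under ideal measurement: the ROI-summed activity with the enhancement
#' factor applied divided by the ROI-summed activity without it.  Serves
#' as the ground truth for parameter-recovery checks; the rendered images
#' deviate from it only through smoothing, quantisation and noise.
#'
#' @param spec A [phantom_spec()].
#' @param phase Phase 1-3.
#' @param region Region name from the annotation scheme for the phase.
#' @return The expected ratio (1 when the ROI contains no enhanced pixels).
#' @export
expected_contrast <- function(spec, phase, region) {
  stopifnot(inherits(spec, "tpbs_spec"))
  scene <- with_seed(spec$seed, phantom_scene(spec))
  codes <- mask_region_codes(spec$extremity)
  if (!region %in% names(codes))
    stop("unknown region for ", spec$extremity, ": ", region, call. = FALSE)
  roi <- scene$geom %in% codes[[region]]
  act <- half_activity(scene, spec$extremity, phase)
  enh <- scene$geom %in% enhanced_codes(spec$extremity, spec$enhanced_regions)
  fmap <- ifelse(enh, spec$enhancement_factor, 1)
  sum(act[roi] * fmap[roi]) / sum(act[roi])
}

#' Generate a reproducible cohort of phantom cases
#'
#' Per-case seeds, affected sides and enhancement factors are drawn
#' reproducibly from the master seed; each case records its realised spec
#' so induced parameters can be recovered later.
#'
#' @param n Number of cases (>= 1).
#' @param extremity `"hand"`, `"foot"` or `"mixed"`.
#' @param enhancement_factors Numeric vector sampled uniformly per case
#'   (a single value fixes `f` for the whole cohort).
#' @param affected_sides Character vector sampled per case.
#' @param image_size,noise_sd,blur_sigma,jitter Passed to [phantom_spec()].
#' @param seed Master seed.
#' @return List of `tpbs_case` objects.
#' @export
generate_cohort <- function(n, extremity = "hand",
                            enhancement_factors = 1,
                            affected_sides = c("left", "right"),
                            image_size = 400L, noise_sd = 6,
                            blur_sigma = 1.2, jitter = TRUE, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("config error: n must be >= 1", call. = FALSE)
  # draw from a set of values; length-1 sets are replicated, never fed to
  # sample() (which would misread a scalar as a range)
  pick <- function(x, n) if (length(x) == 1L) rep(x, n)
          else sample(x, n, replace = TRUE)
  with_seed(seed, {
    case_seeds <- sample.int(2147483000L, n)
    exts <- if (extremity == "mixed")
      pick(c("hand", "foot"), n) else rep(extremity, n)
    sides <- pick(affected_sides, n)
    fs <- pick(enhancement_factors, n)
    lapply(seq_len(n), function(i) {
      spec <- phantom_spec(extremity = exts[i], affected_side = sides[i],
                           image_size = image_size,
                           enhancement_factor = fs[i],
                           noise_sd = noise_sd, blur_sigma = blur_sigma,
                           jitter = jitter, seed = case_seeds[i],
                           case_id = sprintf("case%03d", i))
      generate_phantom(spec)
    })
  })
}
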