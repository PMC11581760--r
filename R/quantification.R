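# Inverted-intensity ROI means and ipsilateral/contralateral ratios.
#
# Display pixels are stored dark = high uptake; before averaging, every
# ROI intensity is inverted as 255 - v so that larger numbers mean more
# tracer accumulation.  The scintigraphy ratio of a region is
#   R = mean inverted intensity (affected side) /
#       mean inverted intensity (unaffected side),
# with R > 1 indicating greater accumulation on the affected side.  No
# background subtraction or normalisation is applied: R is invariant
# under rescaling of the inverted display (v -> a*v) but deliberately NOT
# under offsets, and the pipeline never offsets silently.

#' Annotation scheme: regions quantified per extremity and phase
#'
#' Hands: the whole hand in phases 1-2 and the carpal, MCP and PIP joint
#' subregions in phase 3 (5 ratios per case).  Feet: the whole foot in
#' all three phases (3 ratios per case); joints are not separable on
#' planar foot acquisitions.
#'
#' @param extremity `"hand"` or `"foot"`.
#' @param phase Phase 1-3; omit for the full scheme.
#' @return Character vector of region names (or list phase -> regions).
#' @export
scheme_regions <- function(extremity = c("hand", "foot"), phase = NULL) {
  extremity <- match.arg(extremity)
  scheme <- if (extremity == "hand")
    list(`1` = "whole_hand", `2` = "whole_hand",
         `3` = c("carpal", "mcp", "pip"))
  else
    list(`1` = "whole_foot", `2` = "whole_foot", `3` = "whole_foot")
  if (is.null(phase)) scheme else scheme[[as.character(phase)]]
}

#' Invert display intensities
#'
#' Maps every pixel `v` to `255 - v`, so higher values mean higher tracer
#' uptake.  An involution: applying it twice returns the input.
#'
#' @param pixels Integer matrix (or `tpbs_image`) with values in \[0, 255\].
#' @return Matrix of the same shape, values in \[0, 255\].
#' @export
invert_intensity <- function(pixels) {
  if (inherits(pixels, "tpbs_image")) pixels <- pixels$pixels
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  255L - pixels
}

#' Mean inverted intensity over one ROI
#'
#' @param inverted Inverted intensity matrix (see [invert_intensity()]).
#' @param mask A [tpbs_mask()] aligned to the image.
#' @param region,side ROI selector; must exist in the mask legend.
#' @param min_roi_pixels Minimum ROI size; smaller ROIs raise a
#'   quantification error (guards against segmentation dropouts that
#'   would make the ratio unstable).
#' @return List with `mean` and `n` (pixel count).
#' @export
roi_mean <- function(inverted, mask, region, side, min_roi_pixels = 20L) {
  stopifnot(inherits(mask, "tpbs_mask"))
  if (!all(dim(inverted) == dim(mask$labels)))
    stop("mask/image shape mismatch", call. = FALSE)
  lab <- mask_label(mask, region, side)
  if (is.na(lab))
    stop("quantification error: (", region, ", ", side,
         ") absent from mask legend", call. = FALSE)
  sel <- mask$labels == lab
  n <- sum(sel)
  if (n < min_roi_pixels)
    stop("quantification error: ROI ", region, "/", side, " has ", n,
         " pixels (< ", min_roi_pixels, ")", call. = FALSE)
  list(mean = mean(inverted[sel]), n = n)
}

#' Ipsilateral / contralateral ratio
#'
#' @param mean_ipsi,mean_contra Mean inverted intensities of the affected
#'   and unaffected side.
#' @return `R = mean_ipsi / mean_contra`.
#' @export
compute_ratio <- function(mean_ipsi, mean_contra) {
  if (!is.finite(mean_ipsi) || !is.finite(mean_contra))
    stop("quantification error: non-finite ROI mean", call. = FALSE)
  if (mean_contra <= 0)
    stop("quantification error: contralateral mean is ", mean_contra,
         "; ratio undefined", call. = FALSE)
  mean_ipsi / mean_contra
}

#' Quantify one case: per (phase, region) means and ratios
#'
#' For every region the annotation scheme defines for the case's
#' extremity and phase, computes the mean inverted intensity on the
#' affected (ipsilateral) and unaffected (contralateral) side and their
#' ratio.  Hands yield 5 rows (whole hand in phases 1-2; carpal, MCP and
#' PIP in phase 3); feet yield 3 rows (whole foot per phase).
#'
#' @param case A `tpbs_case` (images plus masks).
#' @param masks Optional list of 3 [tpbs_mask()]s overriding the case's
#'   own masks (e.g. predicted segmentations).
#' @param mask_source Provenance tag recorded in the output
#'   (`"truth"` or `"predicted"`).
#' @param min_roi_pixels Passed to [roi_mean()].
#' @param phases Phases to quantify (default all three); restrict when
#'   only some phases have masks, e.g. predictions from a single-phase
#'   segmentation task.
#' @return `data.frame` with columns `case_id`, `extremity`, `phase`,
#'   `region`, `mean_ipsi`, `mean_contra`, `n_ipsi`, `n_contra`, `ratio`,
#'   `mask_source`.
#' @export
quantify_case <- function(case, masks = NULL, mask_source = "truth",
                          min_roi_pixels = 20L, phases = 1:3) {
  stopifnot(inherits(case, "tpbs_case"), all(phases %in% 1:3))
  if (is.null(masks)) masks <- case$masks
  ipsi <- case$spec$affected_side
  contra <- setdiff(c("left", "right"), ipsi)
  rows <- list()
  for (phase in phases) {
    regions <- scheme_regions(case$spec$extremity, phase)
    mask <- if (phase <= length(masks)) masks[[phase]] else NULL
    if (is.null(mask))
      stop("quantification error: no mask for phase ", phase, " of ",
           case$spec$case_id, call. = FALSE)
    inv <- invert_intensity(case$images[[phase]])
    for (rg in regions) {
      missing <- setdiff(rg, mask$legend$region)
      if (length(missing) > 0)
        stop("quantification error: case ", case$spec$case_id, " phase ",
             phase, " mask lacks region(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      mi <- roi_mean(inv, mask, rg, ipsi, min_roi_pixels)
      mc <- roi_mean(inv, mask, rg, contra, min_roi_pixels)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case$spec$case_id, extremity = case$spec$extremity,
        phase = phase, region = rg,
        mean_ipsi = mi$mean, mean_contra = mc$mean,
        n_ipsi = mi$n, n_contra = mc$n,
        ratio = compute_ratio(mi$mean, mc$mean),
        mask_source = mask_source, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Quantify a cohort of cases
#'
#' @param cases List of `tpbs_case` objects.
#' @param masks_list Optional list (parallel to `cases`) of per-phase mask
#'   lists, e.g. predicted segmentations; default uses each case's own
#'   (ground-truth) masks.
#' @param mask_source,min_roi_pixels,phases See [quantify_case()].
#' @return One tidy `data.frame`, rows = cases x scheme entries.  Cases
#'   failing quantification are dropped with a warning naming them.
#' @export
quantify_cohort <- function(cases, masks_list = NULL, mask_source = "truth",
                            min_roi_pixels = 20L, phases = 1:3) {
  out <- list()
  for (i in seq_along(cases)) {
    masks <- if (is.null(masks_list)) NULL else masks_list[[i]]
    res <- tryCatch(
      quantify_case(cases[[i]], masks, mask_source, min_roi_pixels, phases),
      error = function(e) {
        warning("case ", cases[[i]]$spec$case_id, " skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  if (length(out) == 0)
    stop("quantification error: no case could be quantified", call. = FALSE)
  do.call(rbind, out)
}
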