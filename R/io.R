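# Image and mask containers, TIFF round-trip, preprocessing and the
# case-level train/validation/test split.
#
# Coordinate convention: matrices are indexed [row, column], row 1 at the
# top, column index increasing rightward; "left limb" means the left half
# of the frame (columns 1..W/2), i.e. image-space laterality.

#' A single planar scintigraphy acquisition
#'
#' @param pixels Integer matrix with values in \[0, 255\] (8-bit display
#'   intensities; dark = high uptake under this package's convention).
#' @param phase Acquisition phase: 1 (flow), 2 (blood pool), 3 (delayed/bone).
#' @param extremity `"hand"` or `"foot"`.
#' @param affected_side `"left"` or `"right"` (image-space).
#' @param case_id Case identifier.
#' @return A `tpbs_image` object.
#' @export
tpbs_image <- function(pixels, phase, extremity, affected_side, case_id) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  phase <- as.integer(phase)
  stopifnot(phase %in% 1:3,
            extremity %in% c("hand", "foot"),
            affected_side %in% c("left", "right"))
  structure(list(pixels = pixels, phase = phase, extremity = extremity,
                 affected_side = affected_side, case_id = case_id),
            class = "tpbs_image")
}

#' @export
print.tpbs_image <- function(x, ...) {
  cat(sprintf("TPBS image %s phase %d (%s, affected %s), %dx%d px\n",
              x$case_id, x$phase, x$extremity, x$affected_side,
              nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' An integer region label map with its legend
#'
#' Label 0 is background; every nonzero label must appear in the legend,
#' and each (region, side) pair maps to exactly one label.
#'
#' @param labels Integer matrix of region labels.
#' @param legend `data.frame` with columns `label`, `region`, `side`.
#' @return A `tpbs_mask` object.
#' @export
tpbs_mask <- function(labels, legend) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  stopifnot(is.data.frame(legend),
            all(c("label", "region", "side") %in% names(legend)))
  legend$label <- as.integer(legend$label)
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, legend$label)
  if (length(missing) > 0)
    stop("integrity error: mask labels absent from legend: ",
         paste(missing, collapse = ", "), call. = FALSE)
  key <- paste(legend$region, legend$side)
  if (anyDuplicated(key))
    stop("integrity error: duplicated (region, side) in legend", call. = FALSE)
  structure(list(labels = labels, legend = legend), class = "tpbs_mask")
}

# Label for a (region, side) pair; NA if absent.
mask_label <- function(mask, region, side) {
  hit <- mask$legend$label[mask$legend$region == region & mask$legend$side == side]
  if (length(hit) == 0) NA_integer_ else hit
}

# --- TIFF round-trip ------------------------------------------------------

# Read one single-channel 8-bit TIFF as an integer matrix.  Multi-channel
# or higher bit-depth input is rejected explicitly rather than silently
# converted.
read_gray_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) != 2L)
    stop("unsupported format: ", basename(path),
         " is not single-channel grayscale", call. = FALSE)
  bits <- attr(img, "bits.per.sample")
  if (!is.null(bits) && any(bits != 8L))
    stop("unsupported format: ", basename(path), " is not 8-bit (",
         paste(bits, collapse = ","), " bits per sample)", call. = FALSE)
  if (max(img) > 255L)
    stop("unsupported format: ", basename(path), " exceeds 8-bit range",
         call. = FALSE)
  storage.mode(img) <- "integer"
  attributes(img) <- list(dim = dim(img))
  img
}

write_gray_tiff <- function(m, path) {
  storage.mode(m) <- "integer"
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L, compression = "deflate")
  invisible(path)
}

#' Write a phantom/clinical case to a directory
#'
#' One 8-bit grayscale TIFF per phase, one label TIFF per mask, and a
#' JSON sidecar carrying metadata, the mask legend and (for phantoms) the
#' realised generating spec.
#'
#' @param case A `tpbs_case`.
#' @param dir Output directory (created if needed).
#' @return The case id, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "tpbs_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- case$spec$case_id
  files <- list()
  for (phase in 1:3) {
    img <- case$images[[phase]]
    f <- sprintf("%s_p%d.tif", id, phase)
    write_gray_tiff(img$pixels, file.path(dir, f))
    files[[paste0("p", phase)]] <- f
    if (!is.null(case$masks[[phase]])) {
      fm <- sprintf("%s_p%d_mask.tif", id, phase)
      write_gray_tiff(case$masks[[phase]]$labels, file.path(dir, fm))
      files[[paste0("p", phase, "_mask")]] <- fm
    }
  }
  legends <- lapply(case$masks, function(m) if (is.null(m)) NULL else m$legend)
  spec <- case$spec
  sidecar <- list(
    case_id = id, extremity = spec$extremity,
    affected_side = spec$affected_side, files = files,
    legends = legends,
    spec = list(image_size = spec$image_size,
                enhancement_factor = spec$enhancement_factor,
                enhanced_regions = as.list(spec$enhanced_regions),
                noise_sd = spec$noise_sd, blur_sigma = spec$blur_sigma,
                jitter = spec$jitter, seed = spec$seed,
                baseline_uptake = spec$baseline_uptake)
  )
  jsonlite::write_json(sidecar, file.path(dir, paste0(id, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(id)
}

#' Read a case written by [write_case()]
#'
#' @param dir Directory holding the files.
#' @param case_id Case identifier (sidecar `<case_id>.json` must exist).
#' @return A `tpbs_case`; masks are `NULL` where absent.
#' @export
read_case <- function(dir, case_id) {
  sidecar_path <- file.path(dir, paste0(case_id, ".json"))
  if (!file.exists(sidecar_path))
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  images <- vector("list", 3L)
  masks <- vector("list", 3L)
  for (phase in 1:3) {
    f <- sc$files[[paste0("p", phase)]]
    pix <- read_gray_tiff(file.path(dir, f))
    images[[phase]] <- tpbs_image(pix, phase, sc$extremity,
                                  sc$affected_side, sc$case_id)
    fm <- sc$files[[paste0("p", phase, "_mask")]]
    if (!is.null(fm)) {
      lab <- read_gray_tiff(file.path(dir, fm))
      if (!all(dim(lab) == dim(pix)))
        stop("integrity error: mask/image shape mismatch for ", sc$case_id,
             " phase ", phase, call. = FALSE)
      legend <- as.data.frame(sc$legends[[phase]])
      masks[[phase]] <- tpbs_mask(lab, legend)
    }
  }
  spec_in <- sc$spec
  spec <- phantom_spec(extremity = sc$extremity,
                       affected_side = sc$affected_side,
                       image_size = spec_in$image_size,
                       baseline_uptake = lapply(spec_in$baseline_uptake, as.numeric),
                       enhancement_factor = spec_in$enhancement_factor,
                       enhanced_regions = unlist(spec_in$enhanced_regions),
                       noise_sd = spec_in$noise_sd,
                       blur_sigma = spec_in$blur_sigma,
                       jitter = spec_in$jitter, seed = spec_in$seed,
                       case_id = sc$case_id)
  structure(list(images = images, masks = masks, spec = spec),
            class = "tpbs_case")
}

#' List case ids present in a directory
#' @param dir Directory of written cases.
#' @return Character vector of case ids (sidecar basenames).
#' @export
list_cases <- function(dir) {
  ids <- tools::file_path_sans_ext(list.files(dir, pattern = "\\.json$"))
  # pipeline manifests share the sidecar extension but are not cases
  sort(setdiff(ids, c("split", "manifest", "classification")))
}

# --- preprocessing --------------------------------------------------------

#' Pad to square and resize a raw intensity grid
#'
#' Non-square input is padded symmetrically with the display background
#' value (255, i.e. zero counts under the dark-is-hot convention) so the
#' content's aspect ratio is preserved, then resampled to
#' `target_size x target_size` with bilinear interpolation.
#'
#' @param pixels Numeric or integer matrix in \[0, 255\].
#' @param target_size Output side length in pixels (>= 64; default 400).
#' @param pad_value Padding intensity (default 255 = empty background).
#' @return Integer matrix `target_size x target_size`; the crop/pad
#'   applied is recorded in attribute `"pad"`.
#' @export
preprocess_image <- function(pixels, target_size = 400L, pad_value = 255L) {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("config error: pixels must be a nonempty matrix", call. = FALSE)
  target_size <- as.integer(target_size)
  if (is.na(target_size) || target_size < 64L)
    stop("config error: target_size must be >= 64", call. = FALSE)
  h <- nrow(pixels); w <- ncol(pixels)
  side <- max(h, w)
  pad_top <- (side - h) %/% 2L
  pad_left <- (side - w) %/% 2L
  sq <- matrix(as.numeric(pad_value), side, side)
  sq[pad_top + seq_len(h), pad_left + seq_len(w)] <- pixels
  out <- if (side == target_size) sq
  else EBImage::resize(sq, w = target_size, h = target_size, filter = "bilinear")
  out <- matrix(as.integer(pmin(pmax(round(out), 0), 255)),
                target_size, target_size)
  attr(out, "pad") <- c(top = pad_top, left = pad_left,
                        height = h, width = w)
  out
}

# --- dataset split --------------------------------------------------------

#' Split case ids into train / validation / test partitions
#'
#' Cases (not individual images) are shuffled with the given seed and
#' partitioned; all three phases of a case therefore land in the same
#' partition.  Partition sizes follow the largest-remainder rule:
#' `floor(n * fraction)` per partition, remaining cases assigned in order
#' of descending fractional remainder with ties broken toward the
#' training set (then validation, then test).
#'
#' @param case_ids Character vector of ids (>= 3).
#' @param fractions Length-3 positive fractions summing to 1; default
#'   `c(0.70, 0.20, 0.10)`.
#' @param seed Shuffle seed.
#' @return A `tpbs_split`: list with `train`, `val`, `test`, `fractions`,
#'   `seed`.
#' @export
split_dataset <- function(case_ids, fractions = c(0.70, 0.20, 0.10), seed = 1L) {
  n <- length(case_ids)
  if (n < 3L) stop("config error: need at least 3 cases to split", call. = FALSE)
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("config error: fractions must be 3 positive values", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("config error: fractions must sum to 1", call. = FALSE)
  if (anyDuplicated(case_ids))
    stop("config error: duplicate case ids", call. = FALSE)
  sizes <- split_sizes(n, fractions)
  shuffled <- with_seed(seed, sample(case_ids))
  idx <- cumsum(sizes)
  structure(list(
    train = shuffled[seq_len(sizes[1])],
    val = shuffled[seq(idx[1] + 1L, length.out = sizes[2])],
    test = shuffled[seq(idx[2] + 1L, length.out = sizes[3])],
    fractions = fractions, seed = as.integer(seed)
  ), class = "tpbs_split")
}

# Largest-remainder apportionment; ties toward earlier partitions
# (train, then val, then test).
split_sizes <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  rem <- exact - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    order_idx <- order(-rem, seq_along(rem))
    take <- order_idx[seq_len(short)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

#' @export
print.tpbs_split <- function(x, ...) {
  cat(sprintf("TPBS split: %d train / %d val / %d test (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Write / read a split manifest as JSON
#' @param split A `tpbs_split`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(list(train = split$train, val = split$val,
                            test = split$test, seed = split$seed,
                            fractions = split$fractions),
                       path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.character(x$train), val = as.character(x$val),
                 test = as.character(x$test),
                 fractions = as.numeric(x$fractions),
                 seed = as.integer(x$seed)),
            class = "tpbs_split")
}
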