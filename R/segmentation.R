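# Task-level segmentation API: three task-specific encoder-decoder
# models (whole hand for phases 1-2, hand subregions for phase 3, whole
# foot for phases 1-3), each an ensemble of m independently initialised
# replicas.  Ensemble-mean class probabilities drive both the predicted
# label map (pixelwise argmax) and the per-image uncertainty (mean
# predictive entropy), which feeds out-of-distribution flagging and the
# active-learning loop.
#
# Models predict side-agnostic region classes; left/right assignment
# happens afterwards by splitting at the image vertical midline (both
# limbs are in frame, one per half).

#' Define one of the three segmentation tasks
#'
#' @param name `"hand_whole"` (phases 1-2), `"hand_subregions"`
#'   (phase 3: carpal, MCP, PIP) or `"foot_whole"` (phases 1-3).
#' @return A `tpbs_task` with the ordered class labels (background
#'   first), the phases it applies to, and its extremity.
#' @export
seg_task <- function(name = c("hand_whole", "hand_subregions", "foot_whole")) {
  name <- match.arg(name)
  def <- switch(name,
    hand_whole = list(classes = c("background", "whole_hand"),
                      phases = 1:2, extremity = "hand"),
    hand_subregions = list(classes = c("background", "carpal", "mcp", "pip"),
                           phases = 3L, extremity = "hand"),
    foot_whole = list(classes = c("background", "whole_foot"),
                      phases = 1:3, extremity = "foot"))
  structure(c(list(name = name), def), class = "tpbs_task")
}

#' Default training configuration
#'
#' @param epochs Training epochs per member.
#' @param lr Adam learning rate.
#' @param batch Images per gradient step (gradients averaged).
#' @param members Replicas in the ensemble.
#' @param base Base channel width of the network.
#' @param input_size Model input side length in pixels (multiple of 4).
#' @param dice_weight Weight of the soft-Dice term added to cross-entropy.
#' @param al_epochs Warm-start epochs used by [active_learning_round()].
#' @param seed Master training seed; member k initialises from
#'   `seed + 1000 * k`.
#' @return Named list.
#' @export
train_config <- function(epochs = 20L, lr = 6e-3, batch = 2L, members = 3L,
                         base = 8L, input_size = 96L, dice_weight = 1,
                         al_epochs = 5L, seed = 1L) {
  stopifnot(input_size %% 4L == 0L, members >= 1L, epochs >= 1L)
  list(epochs = as.integer(epochs), lr = lr, batch = as.integer(batch),
       members = as.integer(members), base = as.integer(base),
       input_size = as.integer(input_size), dice_weight = dice_weight,
       al_epochs = as.integer(al_epochs), seed = as.integer(seed))
}

# Images of a case relevant to a task.
task_images <- function(task, case) case$images[task$phases]

# Input tensor for one image: normalised intensity plus two coordinate
# channels (normalised row, midline-folded column).  The folded column
# coordinate |2x - 1| respects the left/right mirror symmetry of the
# frame, matching the side-agnostic classes.
image_input <- function(pixels, input_size) {
  if (nrow(pixels) != input_size || ncol(pixels) != input_size)
    pixels <- preprocess_image(pixels, input_size)
  H <- input_size; W <- input_size
  v <- as.numeric(pixels) / 255
  yn <- rep((seq_len(H) - 0.5) / H, W)
  xf <- rep(abs(2 * (seq_len(W) - 0.5) / W - 1), each = H)
  cbind(v, yn, xf)
}

# Nearest-neighbour resize for integer label maps.
resize_nearest <- function(labels, target) {
  if (all(dim(labels) == target)) return(labels)
  src_r <- pmin(pmax(round((seq_len(target) - 0.5) * nrow(labels) / target + 0.5), 1L),
                nrow(labels))
  src_c <- pmin(pmax(round((seq_len(target) - 0.5) * ncol(labels) / target + 0.5), 1L),
                ncol(labels))
  labels[src_r, src_c, drop = FALSE]
}

#' Collapse a side-aware mask to task class indices
#'
#' @param task A [seg_task()].
#' @param mask A [tpbs_mask()].
#' @return Integer matrix of class indices (1 = background).
#' @export
mask_to_classes <- function(task, mask) {
  stopifnot(inherits(task, "tpbs_task"), inherits(mask, "tpbs_mask"))
  cls <- matrix(1L, nrow(mask$labels), ncol(mask$labels))
  for (i in seq_len(nrow(mask$legend))) {
    ci <- match(mask$legend$region[i], task$classes)
    if (!is.na(ci)) cls[mask$labels == mask$legend$label[i]] <- ci
  }
  cls
}

# Training/validation samples for a task: one (input, target, id) per
# relevant phase image.
task_samples <- function(task, cases, input_size) {
  out <- list()
  for (case in cases) {
    if (case$spec$extremity != task$extremity) next
    for (phase in task$phases) {
      mask <- case$masks[[phase]]
      if (is.null(mask))
        stop("data error: case ", case$spec$case_id,
             " lacks a mask for phase ", phase, call. = FALSE)
      cls <- mask_to_classes(task, mask)
      cls <- resize_nearest(cls, input_size)
      out[[length(out) + 1L]] <- list(
        X = image_input(case$images[[phase]]$pixels, input_size),
        target = as.integer(cls),
        case_id = case$spec$case_id, phase = phase)
    }
  }
  out
}

# Mean foreground-class Dice of argmax predictions for one parameter set.
samples_dice <- function(params, samples, n_class, input_size) {
  ds <- vapply(samples, function(s) {
    fwd <- unet_forward(params, s$X, input_size, input_size)
    pred <- max.col(fwd$probs, ties.method = "first")
    mean(vapply(2:n_class, function(cl) {
      a <- pred == cl; b <- s$target == cl
      den <- sum(a) + sum(b)
      if (den == 0) 1 else 2 * sum(a & b) / den
    }, numeric(1)))
  }, numeric(1))
  mean(ds)
}

# Train one member replica; returns best-validation-Dice checkpoint
# together with the per-epoch log.
train_member <- function(samples, val_samples, n_class, in_ch, config,
                         member_seed, init_params = NULL, epochs = NULL) {
  if (is.null(epochs)) epochs <- config$epochs
  sz <- config$input_size
  params <- if (is.null(init_params))
    unet_init(in_ch, config$base, n_class, member_seed)
  else init_params
  state <- adam_init(params)
  best <- list(dice = -Inf, params = params)
  log <- data.frame(epoch = integer(0), loss = numeric(0), val_dice = numeric(0))
  t <- 0L
  with_seed(member_seed + 1L, {
    for (epoch in seq_len(epochs)) {
      ord <- sample(length(samples))
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        take <- ord[i:min(i + config$batch - 1L, length(ord))]
        i <- i + config$batch
        acc <- NULL
        for (j in take) {
          s <- samples[[j]]
          fwd <- unet_forward(params, s$X, sz, sz, keep_cache = TRUE)
          ls <- seg_loss(fwd$probs, s$target, n_class, config$dice_weight)
          if (!is.finite(ls$loss))
            stop("training failure: non-finite loss at epoch ", epoch,
                 " (sample ", s$case_id, " phase ", s$phase, ")", call. = FALSE)
          losses <- c(losses, ls$loss)
          acc <- grads_add(acc, unet_backward(params, fwd, ls$dz))
        }
        acc <- grads_scale(acc, 1 / length(take))
        t <- t + 1L
        upd <- adam_step(params, acc, state, config$lr, t)
        params <- upd$params; state <- upd$state
      }
      vd <- if (length(val_samples) > 0)
        samples_dice(params, val_samples, n_class, sz) else NA_real_
      log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses),
                                   val_dice = vd))
      if (!is.na(vd) && vd >= best$dice) best <- list(dice = vd, params = params)
    }
  })
  if (!is.finite(best$dice)) best$params <- params
  list(params = best$params, log = log, best_val_dice = best$dice)
}

#' Train a segmentation ensemble for one task
#'
#' Trains `config$members` replicas of the encoder-decoder network that
#' differ only in their seed-derived initialisation and data ordering,
#' keeping each member's best-validation-Dice checkpoint.  The loss is
#' cross-entropy plus a soft-Dice term (robust to the heavy
#' background/foreground class imbalance).
#'
#' @param task A [seg_task()].
#' @param train_cases,val_cases Lists of `tpbs_case` objects with masks.
#' @param config A [train_config()].
#' @return A `tpbs_ensemble` (keeps its training/validation cases so the
#'   active-learning round can extend and retrain it).
#' @export
train_task <- function(task, train_cases, val_cases, config = train_config()) {
  stopifnot(inherits(task, "tpbs_task"))
  if (length(train_cases) < 4L)
    stop("data error: need at least 4 training cases", call. = FALSE)
  n_class <- length(task$classes)
  samples <- task_samples(task, train_cases, config$input_size)
  val_samples <- task_samples(task, val_cases, config$input_size)
  if (length(samples) == 0)
    stop("data error: no training samples match task ", task$name, call. = FALSE)
  members <- vector("list", config$members)
  logs <- vector("list", config$members)
  for (k in seq_len(config$members)) {
    fit <- train_member(samples, val_samples, n_class, 3L, config,
                        member_seed = config$seed + 1000L * k)
    members[[k]] <- fit$params
    logs[[k]] <- fit$log
  }
  structure(list(task = task, members = members, config = config,
                 n_class = n_class, in_ch = 3L,
                 uncertainty_threshold = NA_real_, val_u = NULL,
                 train_cases = train_cases, val_cases = val_cases,
                 logs = logs),
            class = "tpbs_ensemble")
}

#' @export
print.tpbs_ensemble <- function(x, ...) {
  vd <- vapply(x$logs, function(l) max(l$val_dice, na.rm = TRUE), numeric(1))
  cat(sprintf("TPBS ensemble '%s': %d member(s), input %dx%d, best val Dice %s\n",
              x$task$name, length(x$members), x$config$input_size,
              x$config$input_size,
              paste(sprintf("%.3f", vd), collapse = "/")))
  if (!is.na(x$uncertainty_threshold))
    cat(sprintf("  OOD threshold (mean entropy): %.4f\n", x$uncertainty_threshold))
  invisible(x)
}

# Per-pixel entropy of a probability matrix (rows sum to 1), natural log.
row_entropy <- function(p) {
  pl <- p * log(p)
  pl[p == 0] <- 0
  -rowSums(pl)
}

#' Segment one image with an ensemble
#'
#' The label map is the pixelwise argmax of the ensemble-mean class
#' probabilities; the image uncertainty `u` is the mean per-pixel
#' predictive entropy of that mean distribution (`0` iff the mean
#' distribution is one-hot everywhere, at most `log(C)`).
#'
#' @param ensemble A trained `tpbs_ensemble`.
#' @param image A [tpbs_image()] (or raw pixel matrix) of a phase
#'   compatible with the ensemble's task.
#' @return A `tpbs_prediction`: `classes` (class-index matrix at model
#'   resolution), `mask` (side-aware [tpbs_mask()]), `confidence`
#'   (max-probability matrix), `uncertainty`, `ood_flag` (`NA` until the
#'   ensemble is calibrated).
#' @export
predict_image <- function(ensemble, image) {
  stopifnot(inherits(ensemble, "tpbs_ensemble"))
  pixels <- image
  if (inherits(image, "tpbs_image")) {
    if (!image$phase %in% ensemble$task$phases)
      stop("usage error: phase ", image$phase, " incompatible with task ",
           ensemble$task$name, call. = FALSE)
    pixels <- image$pixels
  }
  sz <- ensemble$config$input_size
  X <- image_input(pixels, sz)
  pm <- NULL
  for (params in ensemble$members) {
    fwd <- unet_forward(params, X, sz, sz)
    pm <- if (is.null(pm)) fwd$probs else pm + fwd$probs
  }
  pm <- pm / length(ensemble$members)
  cls <- matrix(max.col(pm, ties.method = "first"), sz, sz)
  u <- mean(row_entropy(pm))
  structure(list(
    classes = cls,
    mask = classes_to_mask(cls, ensemble$task),
    confidence = matrix(pm[cbind(seq_len(sz * sz),
                                 max.col(pm, ties.method = "first"))], sz, sz),
    uncertainty = u,
    ood_flag = if (is.na(ensemble$uncertainty_threshold)) NA
               else u > ensemble$uncertainty_threshold),
    class = "tpbs_prediction")
}

# Side-aware mask from a side-agnostic class map: columns up to the
# vertical midline are "left", the rest "right".
classes_to_mask <- function(cls, task) {
  W <- ncol(cls)
  half <- W %/% 2L
  labels <- matrix(0L, nrow(cls), W)
  legend <- data.frame(label = integer(0), region = character(0),
                       side = character(0), stringsAsFactors = FALSE)
  lab <- 0L
  left_cols <- seq_len(half)
  right_cols <- (half + 1L):W
  for (ci in seq_along(task$classes)[-1]) {
    rg <- task$classes[ci]
    lab_l <- lab + 1L; lab_r <- lab + 2L; lab <- lab + 2L
    sel <- cls == ci
    labels[, left_cols][sel[, left_cols]] <- lab_l
    labels[, right_cols][sel[, right_cols]] <- lab_r
    legend <- rbind(legend, data.frame(label = c(lab_l, lab_r), region = rg,
                                       side = c("left", "right"),
                                       stringsAsFactors = FALSE))
  }
  tpbs_mask(labels, legend)
}

# Case-level uncertainty: mean over the task's phase images.
case_uncertainty <- function(ensemble, case) {
  mean(vapply(task_images(ensemble$task, case),
              function(img) predict_image(ensemble, img)$uncertainty,
              numeric(1)))
}

#' Predicted masks for the task-relevant phases of a case
#'
#' @param ensemble A trained `tpbs_ensemble`.
#' @param case A `tpbs_case` of the matching extremity.
#' @param native_size If `TRUE`, label maps are resized (nearest
#'   neighbour) back to the case's image resolution.
#' @return List indexed by phase; [tpbs_mask()] for the task's phases,
#'   `NULL` elsewhere.
#' @export
segment_case <- function(ensemble, case, native_size = TRUE) {
  masks <- vector("list", 3L)
  for (phase in ensemble$task$phases) {
    pred <- predict_image(ensemble, case$images[[phase]])
    m <- pred$mask
    if (native_size) {
      target <- nrow(case$images[[phase]]$pixels)
      m <- tpbs_mask(resize_nearest(m$labels, target), m$legend)
    }
    masks[[phase]] <- m
  }
  masks
}

#' Calibrate the out-of-distribution threshold on validation cases
#'
#' The threshold is the given percentile (linear-interpolation quantile,
#' type 7) of per-image uncertainties over the validation set; images
#' whose uncertainty exceeds it are flagged as out-of-distribution.
#'
#' @param ensemble A trained `tpbs_ensemble`.
#' @param val_cases Validation cases (>= 3); defaults to the cases the
#'   ensemble was validated on.
#' @param percentile Percentile in (0, 100\]; default 95.
#' @return The ensemble with `uncertainty_threshold` and the validation
#'   uncertainties (`val_u`) stored.
#' @export
calibrate_uncertainty <- function(ensemble, val_cases = NULL, percentile = 95) {
  if (is.null(val_cases)) val_cases <- ensemble$val_cases
  if (length(val_cases) < 3L)
    stop("usage error: need at least 3 validation cases", call. = FALSE)
  u <- unlist(lapply(val_cases, function(case)
    vapply(task_images(ensemble$task, case),
           function(img) predict_image(ensemble, img)$uncertainty, numeric(1))))
  ensemble$val_u <- u
  ensemble$uncertainty_threshold <- uncertainty_threshold_from(u, percentile)
  ensemble
}

# Linear-interpolation (type 7) percentile of the validation
# uncertainties; kept separate so the calibration rule is auditable.
uncertainty_threshold_from <- function(u, percentile = 95) {
  stopifnot(length(u) >= 1, percentile > 0, percentile <= 100)
  stats::quantile(u, percentile / 100, type = 7, names = FALSE)
}

#' One active-learning round
#'
#' Scores every pool case by ensemble uncertainty, selects up to `budget`
#' of the most uncertain, obtains their masks from the oracle, adds them
#' to the training set and retrains all members with a warm start.  A
#' failing oracle call is recorded and the case skipped, not fatal.
#'
#' @param ensemble A trained `tpbs_ensemble` (carrying its train/val cases).
#' @param pool List of unlabeled `tpbs_case`s (their masks are ignored;
#'   labels come from the oracle).
#' @param oracle Function `case -> list of 3 masks` (default: the case's
#'   own ground-truth masks).
#' @param budget Maximum number of cases to label (>= 1).
#' @param epochs Warm-start retraining epochs (default `config$al_epochs`).
#' @return List: `ensemble` (retrained), `audit` (`data.frame` of pool
#'   ids, uncertainties, selection and oracle status), `pre_val_dice`,
#'   `post_val_dice`.
#' @export
active_learning_round <- function(ensemble, pool, oracle = NULL, budget = 1L,
                                  epochs = NULL) {
  stopifnot(inherits(ensemble, "tpbs_ensemble"), length(pool) >= 1L,
            budget >= 1L)
  if (is.null(oracle)) oracle <- function(case) case$masks
  if (is.null(epochs)) epochs <- ensemble$config$al_epochs
  u <- vapply(pool, function(case) case_uncertainty(ensemble, case), numeric(1))
  ids <- vapply(pool, function(case) case$spec$case_id, character(1))
  sel_idx <- order(-u)[seq_len(min(budget, length(pool)))]
  audit <- data.frame(case_id = ids, uncertainty = u,
                      selected = seq_along(pool) %in% sel_idx,
                      labelled = FALSE, stringsAsFactors = FALSE)
  new_cases <- list()
  for (i in sel_idx) {
    masks <- tryCatch(oracle(pool[[i]]), error = function(e) {
      warning("oracle failed for ", ids[i], ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(masks)) next
    case <- pool[[i]]
    case$masks <- masks
    new_cases[[length(new_cases) + 1L]] <- case
    audit$labelled[i] <- TRUE
  }
  config <- ensemble$config
  train_cases <- c(ensemble$train_cases, new_cases)
  samples <- task_samples(ensemble$task, train_cases, config$input_size)
  val_samples <- task_samples(ensemble$task, ensemble$val_cases,
                              config$input_size)
  pre <- mean(vapply(ensemble$members, samples_dice, numeric(1),
                     samples = val_samples, n_class = ensemble$n_class,
                     input_size = config$input_size))
  members <- ensemble$members
  logs <- ensemble$logs
  for (k in seq_along(members)) {
    fit <- train_member(samples, val_samples, ensemble$n_class, ensemble$in_ch,
                        config, member_seed = config$seed + 1000L * k + 500L,
                        init_params = members[[k]], epochs = epochs)
    # Warm-start retraining keeps the better of the previous weights and
    # the best retrained checkpoint, judged on validation Dice.
    if (is.finite(fit$best_val_dice) &&
        fit$best_val_dice >= samples_dice(members[[k]], val_samples,
                                          ensemble$n_class, config$input_size)) {
      members[[k]] <- fit$params
    }
    logs[[k]] <- rbind(logs[[k]], fit$log)
  }
  ensemble$members <- members
  ensemble$logs <- logs
  ensemble$train_cases <- train_cases
  post <- mean(vapply(members, samples_dice, numeric(1),
                      samples = val_samples, n_class = ensemble$n_class,
                      input_size = config$input_size))
  list(ensemble = ensemble, audit = audit,
       pre_val_dice = pre, post_val_dice = post)
}

#' Save / load an ensemble checkpoint
#'
#' The checkpoint embeds a manifest (task, class legend, input size,
#' seeds) alongside the member weights; training cases are dropped to
#' keep the file small, so a reloaded ensemble cannot be warm-started
#' without supplying cases again.
#'
#' @param ensemble A `tpbs_ensemble`.
#' @param path Destination `.rds` path.
#' @return `path` (or the ensemble, for `load_ensemble`).
#' @export
save_ensemble <- function(ensemble, path) {
  slim <- ensemble
  slim$train_cases <- NULL
  slim$val_cases <- NULL
  saveRDS(slim, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "tpbs_ensemble"))
  x
}
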