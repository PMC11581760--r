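# End-to-end pipeline: generate -> split -> train -> segment ->
# quantify -> evaluate -> classify, with a manifest tying every artifact
# to its configuration and seeds.

#' Default pipeline configuration
#'
#' A demo-scale configuration: a small synthetic hand cohort at reduced
#' resolution, one task ensemble, truth- and prediction-based ratio
#' quantification, Dice validation and cut-off classification.
#'
#' @param n_cases Cohort size.
#' @param extremity `"hand"` or `"foot"`.
#' @param image_size Phantom frame side length (even).
#' @param enhancement_factors Per-case enhancement factors sampled
#'   uniformly.
#' @param noise_sd Phantom display noise.
#' @param fractions Train/val/test split fractions.
#' @param cutoff,target_region,target_phase Classification rule.
#' @param train Passed to [train_config()] (list of overrides).
#' @param seed Master seed for generation, split and training.
#' @return Named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(n_cases = 20L, extremity = "hand",
                            image_size = 96L,
                            enhancement_factors = c(1, 1.2, 1.5, 2),
                            noise_sd = 6, fractions = c(0.7, 0.2, 0.1),
                            cutoff = 1.32, target_region = NULL,
                            target_phase = 3L, train = list(), seed = 1L) {
  if (is.null(target_region))
    target_region <- if (extremity == "hand") "mcp" else "whole_foot"
  tc <- do.call(train_config,
                c(train, list(seed = as.integer(seed))[!("seed" %in% names(train))]))
  tc$input_size <- as.integer(min(tc$input_size, image_size))
  list(n_cases = as.integer(n_cases), extremity = extremity,
       image_size = as.integer(image_size),
       enhancement_factors = enhancement_factors, noise_sd = noise_sd,
       fractions = fractions, cutoff = cutoff,
       target_region = target_region, target_phase = as.integer(target_phase),
       train = tc, seed = as.integer(seed))
}

#' Run the full TPBS pipeline
#'
#' Generates a phantom cohort, writes it to `out_dir/images`, splits it
#' by case, trains the task ensembles the extremity requires, calibrates
#' the uncertainty threshold, segments the test cases, and writes
#' `ratios.csv` (truth- and prediction-based), `dice.csv`,
#' `classification.json` and `manifest.json` under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the cohort, split, ensembles, ratio
#'   table, Dice report and classification.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (missing(out_dir) || !nzchar(out_dir))
    stop("config error: out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  cohort <- generate_cohort(config$n_cases, config$extremity,
                            enhancement_factors = config$enhancement_factors,
                            image_size = config$image_size,
                            noise_sd = config$noise_sd, seed = config$seed)
  for (case in cohort) write_case(case, img_dir)
  ids <- vapply(cohort, function(cs) cs$spec$case_id, character(1))
  split <- split_dataset(ids, config$fractions, seed = config$seed)
  write_split(split, file.path(out_dir, "split.json"))
  by_id <- function(wanted) cohort[match(wanted, ids)]
  task_names <- if (config$extremity == "hand")
    c("hand_whole", "hand_subregions") else "foot_whole"
  ensembles <- list()
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  for (tn in task_names) {
    ens <- train_task(seg_task(tn), by_id(split$train), by_id(split$val),
                      config$train)
    ens <- calibrate_uncertainty(ens)
    save_ensemble(ens, file.path(out_dir, "models", paste0(tn, ".rds")))
    ensembles[[tn]] <- ens
  }
  test_cases <- by_id(split$test)
  pred_masks <- lapply(test_cases, function(case) {
    masks <- vector("list", 3L)
    for (ens in ensembles) {
      m <- segment_case(ens, case)
      for (phase in ens$task$phases) masks[[phase]] <- m[[phase]]
    }
    masks
  })
  ratios_truth <- quantify_cohort(cohort, mask_source = "truth")
  ratios_pred <- quantify_cohort(test_cases, pred_masks,
                                 mask_source = "predicted")
  ratios <- rbind(ratios_truth, ratios_pred)
  utils::write.csv(ratios, file.path(out_dir, "ratios.csv"), row.names = FALSE)
  dice_rows <- list()
  for (ci in seq_along(test_cases)) {
    case <- test_cases[[ci]]
    for (phase in 1:3) {
      truth <- case$masks[[phase]]
      pred <- pred_masks[[ci]][[phase]]
      if (is.null(pred)) next
      for (i in seq_len(nrow(truth$legend))) {
        lg <- truth$legend[i, ]
        pl <- mask_label(pred, lg$region, lg$side)
        d <- if (is.na(pl)) 0 else
          dice_coefficient(pred$labels == pl, truth$labels == lg$label, TRUE)
        dice_rows[[length(dice_rows) + 1L]] <- data.frame(
          case_id = case$spec$case_id, phase = phase, region = lg$region,
          side = lg$side, dice = d, stringsAsFactors = FALSE)
      }
    }
  }
  dice_df <- do.call(rbind, dice_rows)
  utils::write.csv(dice_df, file.path(out_dir, "dice.csv"), row.names = FALSE)
  cls <- classify_cohort(ratios_truth, config$cutoff, config$target_region,
                         config$target_phase)
  jsonlite::write_json(
    list(cutoff = cls$cutoff, target_region = cls$target_region,
         target_phase = cls$target_phase, n_positive = cls$n_positive,
         n_total = cls$n_total, fraction = cls$fraction,
         cases = cls$cases),
    file.path(out_dir, "classification.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tpbsquant")),
    config = config[setdiff(names(config), "train")],
    train = config$train,
    split = list(train = split$train, val = split$val, test = split$test),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, split = split, ensembles = ensembles,
                 ratios = ratios, dice = dice_df, classification = cls))
}
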