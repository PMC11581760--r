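# Segmentation validation (Dice), cut-off classification of cohort
# ratios, and sensitivity/specificity reporting.

#' Dice overlap coefficient for one class
#'
#' `D = 2|A n B| / (|A| + |B|)` where A and B are the pixel sets carrying
#' `class_label` in the two masks; 0 means no congruence, 1 perfect
#' congruence.  When the class is absent from both masks the coefficient
#' is defined as 1 (both agree the class is absent); the alternative
#' convention (0) would penalise correctly-absent classes.
#'
#' @param mask_a,mask_b Integer label matrices (or [tpbs_mask()]s) of
#'   equal dimensions.
#' @param class_label Label whose overlap is measured.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b, class_label) {
  if (inherits(mask_a, "tpbs_mask")) mask_a <- mask_a$labels
  if (inherits(mask_b, "tpbs_mask")) mask_b <- mask_b$labels
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("usage error: mask dimensions differ", call. = FALSE)
  a <- mask_a == class_label
  b <- mask_b == class_label
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Dice report over cases and classes
#'
#' @param pred_masks,truth_masks Parallel lists of label matrices or
#'   [tpbs_mask()]s.
#' @param class_labels Integer labels to evaluate (default: all nonzero
#'   labels present in the truth masks).
#' @param case_ids Optional ids for the rows.
#' @return List with `per_case` (`data.frame`: case, class, dice) and
#'   `summary` (mean/median per class and overall).
#' @export
dice_report <- function(pred_masks, truth_masks, class_labels = NULL,
                        case_ids = NULL) {
  stopifnot(length(pred_masks) == length(truth_masks))
  get_labels <- function(m) {
    if (inherits(m, "tpbs_mask")) m <- m$labels
    m
  }
  if (is.null(class_labels)) {
    class_labels <- sort(unique(unlist(lapply(truth_masks, function(m)
      setdiff(unique(as.vector(get_labels(m))), 0L)))))
  }
  if (is.null(case_ids)) case_ids <- as.character(seq_along(pred_masks))
  rows <- expand.grid(case = case_ids, class = class_labels,
                      stringsAsFactors = FALSE)
  rows$dice <- mapply(function(cs, cl) {
    i <- match(cs, case_ids)
    dice_coefficient(pred_masks[[i]], truth_masks[[i]], cl)
  }, rows$case, rows$class)
  summary <- stats::aggregate(dice ~ class, rows, function(d)
    c(mean = mean(d), median = stats::median(d)))
  summary <- data.frame(class = summary$class,
                        mean = summary$dice[, "mean"],
                        median = summary$dice[, "median"])
  list(per_case = rows, summary = summary,
       overall_mean = mean(rows$dice), overall_median = stats::median(rows$dice))
}

#' Classify a cohort of scintigraphy ratios against a cut-off
#'
#' A case counts positive when its target-region ratio satisfies
#' `R >= cutoff` (inclusive boundary; isolated here so the rule is in one
#' place).  The default cut-off 1.32 is the previously published MCP
#' phase-3 threshold for CRPS positivity.
#'
#' @param ratios Tidy ratio `data.frame` from [quantify_cohort()].
#' @param cutoff Decision threshold (default 1.32).
#' @param target_region Region whose ratio is tested (default `"mcp"`).
#' @param target_phase Phase of the target ratio (default 3).
#' @return List with per-case flags, `n_positive`, `n_total`, `fraction`,
#'   and ids of cases lacking the target ratio (excluded with a warning).
#' @export
classify_cohort <- function(ratios, cutoff = 1.32, target_region = "mcp",
                            target_phase = 3L) {
  sel <- ratios$region == target_region & ratios$phase == target_phase
  sub <- ratios[sel, c("case_id", "ratio")]
  all_ids <- unique(ratios$case_id)
  missing <- setdiff(all_ids, sub$case_id)
  if (length(missing) > 0)
    warning("cases lacking the target ratio were excluded: ",
            paste(missing, collapse = ", "), call. = FALSE)
  positive <- ratio_positive(sub$ratio, cutoff)
  list(cutoff = cutoff, target_region = target_region,
       target_phase = as.integer(target_phase),
       cases = data.frame(case_id = sub$case_id, ratio = sub$ratio,
                          positive = positive, stringsAsFactors = FALSE),
       n_positive = sum(positive), n_total = nrow(sub),
       fraction = if (nrow(sub) > 0) sum(positive) / nrow(sub) else NA_real_,
       missing = missing)
}

# The single place the cut-off boundary rule lives: inclusive (R >= c).
ratio_positive <- function(ratio, cutoff) ratio >= cutoff

#' Sensitivity and specificity of binary flags against truth
#'
#' `sens = TP / (TP + FN)`, `spec = TN / (TN + FP)`.  A metric whose
#' denominator is empty (truth all-negative or all-positive) is reported
#' as `NA`, never as 0.
#'
#' @param flags,truth Logical vectors of equal length.
#' @return List with `sensitivity`, `specificity` and the 2x2 counts.
#' @export
sensitivity_specificity <- function(flags, truth) {
  if (length(flags) != length(truth))
    stop("usage error: flags and truth lengths differ", call. = FALSE)
  flags <- as.logical(flags); truth <- as.logical(truth)
  tp <- sum(flags & truth); fn <- sum(!flags & truth)
  tn <- sum(!flags & !truth); fp <- sum(flags & !truth)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Median and quartiles of ratios per (phase, region)
#'
#' Quartiles use the linear-interpolation quantile rule (type 7) so
#' values are reproducible across implementations.
#'
#' @param ratios Tidy ratio `data.frame` from [quantify_cohort()].
#' @return `data.frame` with `phase`, `region`, `n`, `q1`, `median`, `q3`.
#' @export
summarise_ratios <- function(ratios) {
  groups <- unique(ratios[, c("phase", "region")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- ratios$phase == groups$phase[i] & ratios$region == groups$region[i]
    r <- ratios$ratio[sel]
    if (length(r) == 0) {
      warning("empty ratio group omitted: phase ", groups$phase[i], " ",
              groups$region[i], call. = FALSE)
      return(NULL)
    }
    q <- stats::quantile(r, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(phase = groups$phase[i], region = groups$region[i],
               n = length(r), q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
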