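# End-to-end wiring: scan -> preprocessing -> baseline -> segmentation ->
# recognition -> features -> series record.

#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage in one list, mirroring
#' the `[beads]`, `[segmentation]` and `[recognition]` blocks of a pipeline
#' config file.
#'
#' @param beads A [beads_params()] object.
#' @param valley_frac Valley threshold fraction for
#'   [find_separating_columns()].
#' @param min_area_frac Fragment threshold for [split_characters()].
#' @param strip_halfwidth Strip half-width in px (NULL = stroke-width
#'   estimate).
#' @param recognition A [recognition_config()].
#' @param jac_threshold Jaccard acceptance threshold for segmentation
#'   evaluation.
#' @return A named list.
#' @export
last_config <- function(beads = beads_params(),
                        valley_frac = 0.10,
                        min_area_frac = 0.05,
                        strip_halfwidth = NULL,
                        recognition = recognition_config(),
                        jac_threshold = 0.70) {
  list(beads = beads, valley_frac = valley_frac,
       min_area_frac = min_area_frac, strip_halfwidth = strip_halfwidth,
       recognition = recognition, jac_threshold = jac_threshold)
}

#' Process a LAST scan fully automatically
#'
#' Runs the whole pipeline: preprocessing ([preprocess_scan()]), adaptive
#' baseline removal ([adaptive_baseline()]), character separation
#' ([find_separating_columns()], [split_characters()]), model selection and
#' DTW recognition ([select_models()], [classify_characters()]), feature
#' extraction and aggregation ([character_features()],
#' [series_features()]).
#'
#' @param img A [gray_image()] (e.g. from [load_scan()]).
#' @param examiner_n Number of leading examiner characters (sidecar value).
#' @param subject,group Identifiers stored in the record.
#' @param config A [last_config()].
#' @return A list of class `last_result` with `record`, `rois`, `signals`,
#'   `labels`, `aligned`, `models` and the intermediate images.
#' @export
process_scan <- function(img, examiner_n = 5L, subject = "subject",
                         group = NA_character_, config = last_config()) {
  pre <- preprocess_scan(img)
  aligned <- adaptive_baseline(pre$signal, config$beads)
  cols <- find_separating_columns(aligned, config$valley_frac)
  sp <- split_characters(pre$binary, aligned, cols,
                         strip_halfwidth = config$strip_halfwidth,
                         min_area_frac = config$min_area_frac,
                         examiner_n = examiner_n)
  models <- select_models(sp$rois, sp$signals, config$recognition)
  labels <- classify_characters(sp$signals, models,
                                config$recognition$dtw_window)
  examiner <- vapply(sp$rois, function(r) r$examiner, logical(1))
  feats <- vector("list", length(sp$rois))
  for (i in seq_along(sp$rois)) {
    feats[[i]] <- character_features(sp$rois[[i]], sp$signals[[i]],
                                     labels[i],
                                     config$recognition$dtw_window)
  }
  record <- series_features(feats, as.character(labels), examiner, sp$rois,
                            subject = subject, group = group)
  structure(list(record = record, rois = sp$rois, signals = sp$signals,
                 labels = as.character(labels), aligned = aligned,
                 models = models, binary = pre$binary,
                 skeleton = pre$skeleton, separating_columns = cols),
            class = "last_result")
}

#' @exportS3Method base::print
print.last_result <- function(x, ...) {
  cat(sprintf("<last_result> %d characters recognized as %s\n",
              length(x$labels), paste(x$labels, collapse = "")))
  print(x$record)
  invisible(x)
}

#' Extract a series record from ground-truth delineations
#'
#' The expert-delineation analogue of [process_scan()]: character masks and
#' labels are taken from the rendered truth (or a loaded label overlay) and
#' only feature extraction runs. Character signals are the upper envelope
#' of each character's own mask.
#'
#' @param scan A `synthetic_scan` from [render_series()].
#' @param subject,group Identifiers stored in the record.
#' @return A `last_record`.
#' @export
process_truth <- function(scan, subject = "subject", group = NA_character_) {
  truth <- scan$truth
  rois <- truth$rois
  labels <- truth$labels
  examiner <- vapply(rois, function(r) r$examiner, logical(1))
  feats <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    cs <- roi_envelope_signal(rois[[i]])
    feats[[i]] <- character_features(rois[[i]], cs, labels[i])
  }
  series_features(feats, labels, examiner, rois,
                  subject = subject, group = group)
}

# Upper envelope of a single ROI mask as a character signal.
roi_envelope_signal <- function(roi) {
  mask <- roi$mask
  h <- nrow(mask)
  top <- apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w) == 0L) NA_real_ else h - w[1]
  })
  xs <- seq_len(ncol(mask))
  gap <- is.na(top)
  if (any(gap)) top <- approx(xs[!gap], top[!gap], xout = xs, rule = 2)$y
  character_signal(top, roi$bbox[1], roi$bbox[1] + ncol(mask), gap)
}

#' Evaluate automatic segmentation and recognition against an overlay
#'
#' @param result A `last_result` from [process_scan()].
#' @param reference Either a `last_overlay` from [load_label_overlay()] or
#'   the `truth` element of a `synthetic_scan`.
#' @param jac_threshold Jaccard acceptance threshold (default 0.70).
#' @return A list with `segmentation` (the [segmentation_dice()] output)
#'   and `recognition` (per-class Dice over matched characters).
#' @export
evaluate_result <- function(result, reference, jac_threshold = 0.70) {
  man_rois <- reference$rois
  man_labels <- if (!is.null(reference$labels)) reference$labels else
    rep(NA_character_, length(man_rois))
  seg <- segmentation_dice(result$rois, man_rois, jac_threshold)
  rec <- c(R = NA_real_, T = NA_real_)
  if (!anyNA(man_labels) && length(result$labels) == length(man_labels)) {
    # counts agree: characters correspond position-wise
    rec <- recognition_dice(result$labels, man_labels)
  } else if (nrow(seg$matches) > 0L && !anyNA(man_labels)) {
    pred <- result$labels[seg$matches$auto + 1L]
    ref <- man_labels[seg$matches$manual + 1L]
    # unmatched manual characters count against their class
    unmatched <- setdiff(seq_along(man_rois) - 1L, seg$matches$manual)
    for (cls in c("R", "T")) {
      tp <- sum(pred == cls & ref == cls)
      fp <- sum(pred == cls & ref != cls)
      fn <- sum(pred != cls & ref == cls) + sum(man_labels[unmatched + 1L] == cls)
      rec[cls] <- if (2 * tp + fp + fn == 0) NA_real_ else
        2 * tp / (2 * tp + fp + fn) * 100
    }
  }
  list(segmentation = seg, recognition = rec)
}
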