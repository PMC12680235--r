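# The three reliability metrics: mutual information, Spearman correlation
# and area under the precision-recall curve, computed between per-patch
# scores and region-annotation-derived patch labels, plus slide-set
# aggregation with exclusion of annotation-free slides.

#' Mutual information between patch scores and patch labels
#'
#' Plug-in mutual information (natural log, nats) of the joint histogram of
#' quantile-binned scores and binary labels. With the default two bins,
#' scores are split at their median — except probability-like channels
#' (`channel = "patch_prob"`), which are split at 0.5. Constant scores or
#' constant labels carry no information and return 0 (with a
#' `"degenerate"` attribute naming the cause).
#'
#' @param scores Numeric score vector.
#' @param labels Binary label vector of the same length.
#' @param bins Number of quantile bins for the scores (default 2).
#' @param channel Score channel; only `"patch_prob"` changes the default
#'   binarization threshold.
#' @return Non-negative mutual information in nats.
#' @export
mutual_information <- function(scores, labels, bins = 2L,
                               channel = c("attention", "patch_prob",
                                           "selection")) {
  channel <- match.arg(channel)
  check_metric_input(scores, labels)
  if (length(unique(labels)) < 2L)
    return(structure(0, degenerate = "constant_labels"))
  if (bins == 2L) {
    thr <- if (channel == "patch_prob") 0.5 else stats::median(scores)
    xb <- as.integer(scores > thr)
  } else {
    qs <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = bins + 1L)))
    if (length(qs) < 3L) return(structure(0, degenerate = "constant_scores"))
    xb <- as.integer(cut(scores, qs, include.lowest = TRUE))
  }
  if (length(unique(xb)) < 2L)
    return(structure(0, degenerate = "constant_scores"))
  mi_from_table(table(xb, labels))
}

# Plug-in MI of a contingency table, in nats.
mi_from_table <- function(tab) {
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  e <- outer(px, py)
  nz <- pxy > 0
  max(0, sum(pxy[nz] * log(pxy[nz] / e[nz])))
}

#' Spearman correlation between patch scores and patch labels
#'
#' Pearson correlation of mid-ranks (average-rank tie handling). When
#' either ranking has zero variance the correlation is undefined and 0 is
#' returned with a `"degenerate"` attribute.
#'
#' @inheritParams mutual_information
#' @return Correlation in \[-1, 1\].
#' @export
spearman_cor <- function(scores, labels) {
  check_metric_input(scores, labels)
  if (stats::sd(scores) == 0 || stats::sd(labels) == 0)
    return(structure(0, degenerate = "zero_variance"))
  stats::cor(scores, labels, method = "spearman")
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision over descending-score thresholds,
#' `AP = sum_k (R_k - R_{k-1}) P_k`, with tied scores collapsed into a
#' single threshold. The no-skill baseline equals the positive prevalence.
#' With single-class labels the curve is undefined: all-positive labels
#' return 1 and all-negative return 0, both flagged `"degenerate"`.
#'
#' @inheritParams mutual_information
#' @return Average precision in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  check_metric_input(scores, labels)
  npos <- sum(labels)
  if (npos == 0L) return(structure(0, degenerate = "no_positives"))
  if (npos == length(labels)) return(structure(1, degenerate = "no_negatives"))
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]; s <- scores[o]
  tp <- cumsum(l)
  prec <- tp / seq_along(l)
  rec <- tp / npos
  last <- c(s[-1L] != s[-length(s)], TRUE)   # last index of each tie block
  prec <- prec[last]; rec <- rec[last]
  sum(diff(c(0, rec)) * prec)
}

check_metric_input <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (length(scores) < 2L)
    stop("need at least 2 patches")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary")
  invisible(TRUE)
}

#' Evaluate the reliability of a model's patch scores over a slide set
#'
#' Slides without any positive patch label (no annotated region of
#' interest) carry no reliability signal and are excluded, mirroring the
#' convention that normal slides are not considered in reliability
#' assessment. Two aggregations are available: `"per_slide_mean"`
#' (default; each metric computed within each retained slide, then
#' averaged) and `"pooled"` (patches of all retained slides concatenated
#' before computing each metric once).
#'
#' @param score_sets List of [patch_score_set()] (or bare numeric vectors),
#'   one per slide.
#' @param labels List of binary patch-label vectors aligned with
#'   `score_sets`.
#' @param aggregation `"per_slide_mean"` or `"pooled"`.
#' @param model_id,seed Bookkeeping fields copied into the result.
#' @param bins Passed to [mutual_information()].
#' @return A one-row data frame of class `reliability_result` with columns
#'   `model_id`, `seed`, `mi`, `spearman`, `auprc`, `n_slides_used`.
#' @export
evaluate_reliability <- function(score_sets, labels,
                                 aggregation = c("per_slide_mean", "pooled"),
                                 model_id = "model", seed = NA_integer_,
                                 bins = 2L) {
  aggregation <- match.arg(aggregation)
  if (length(score_sets) != length(labels))
    stop("evaluate_reliability: score/label slide sets do not align")
  channel <- if (inherits(score_sets[[1L]], "patch_score_set"))
    score_sets[[1L]]$channel else "attention"
  scores <- lapply(score_sets, function(s)
    if (inherits(s, "patch_score_set")) s$scores else as.numeric(s))
  ok <- vapply(seq_along(scores), function(i) {
    if (length(scores[[i]]) != length(labels[[i]]))
      stop("evaluate_reliability: score/label length mismatch within a slide")
    sum(labels[[i]]) > 0
  }, logical(1L))
  if (!any(ok)) stop("evaluate_reliability: no ROI slides")
  scores <- scores[ok]; labs <- labels[ok]
  if (aggregation == "pooled") {
    s <- unlist(scores); l <- unlist(labs)
    mi <- mutual_information(s, l, bins, channel)
    rs <- spearman_cor(s, l)
    ap <- auprc(s, l)
  } else {
    per <- vapply(seq_along(scores), function(i) {
      c(mutual_information(scores[[i]], labs[[i]], bins, channel),
        spearman_cor(scores[[i]], labs[[i]]),
        auprc(scores[[i]], labs[[i]]))
    }, numeric(3L))
    mi <- mean(per[1L, ]); rs <- mean(per[2L, ]); ap <- mean(per[3L, ])
  }
  structure(
    data.frame(model_id = model_id, seed = seed, mi = as.numeric(mi),
               spearman = as.numeric(rs), auprc = as.numeric(ap),
               n_slides_used = sum(ok), stringsAsFactors = FALSE),
    class = c("reliability_result", "data.frame"))
}
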