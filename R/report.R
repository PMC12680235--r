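# Cross-dataset aggregation, metric-exclusion ranking, repeated-measures
# ANOVA, and grid-heatmap rendering.

#' Half-up rounding
#'
#' Rounds halves away from zero (the convention benchmark tables print
#' with), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.metric_cols <- c("mi", "spearman", "auprc", "auc", "f1")

#' Overall mean of per-dataset benchmark rows
#'
#' Unweighted mean of the per-dataset means for every model, half-up
#' rounded to two decimals for the reliability/classification metrics and
#' to the nearest unit for the size (K) and FLOPs (M) columns. Metrics
#' missing in some datasets are averaged over the datasets that carry them
#' and flagged in the `partial` column.
#'
#' @param table Data frame with columns `model_id`, `dataset` and metric
#'   columns (as produced by [run_benchmark()] or [published_tables()]).
#' @return One row per model.
#' @export
overall_mean <- function(table) {
  metrics <- intersect(c(.metric_cols, "flops_m", "size_k"), names(table))
  out <- lapply(split(table, factor(table$model_id,
                                    levels = unique(table$model_id))),
                function(d) {
    row <- list(model_id = d$model_id[1L], n_datasets = nrow(d))
    partial <- FALSE
    for (m in metrics) {
      v <- d[[m]][!is.na(d[[m]])]
      if (length(v) && length(v) < nrow(d)) partial <- TRUE
      digits <- if (m %in% c("flops_m", "size_k")) 0L else 2L
      row[[m]] <- if (length(v)) round_half_up(mean(v), digits) else NA_real_
    }
    row$partial <- partial
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank models by summed reliability scores
#'
#' Score of a model = sum of the selected reliability metric means over all
#' datasets (equal weight). Models are ordered by descending score; models
#' whose scores agree after half-up rounding to two decimals are reported
#' as tied (equal `rank`).
#'
#' @param table Per-dataset benchmark rows (`model_id`, `dataset`, metric
#'   columns).
#' @param metrics Reliability metrics to include.
#' @param exclude Optional single metric to drop from `metrics`.
#' @return Data frame `model_id`, `score`, `rank`, ordered by rank.
#' @export
rank_models <- function(table, metrics = c("mi", "spearman", "auprc"),
                        exclude = NULL) {
  if (!is.null(exclude)) metrics <- setdiff(metrics, exclude)
  if (!length(metrics)) stop("rank_models: empty metric subset")
  stopifnot(all(metrics %in% names(table)))
  keep <- !Reduce(`|`, lapply(metrics, function(m) is.na(table[[m]])))
  tab <- table[keep, , drop = FALSE]
  score <- vapply(split(tab, tab$model_id), function(d)
    sum(unlist(d[metrics])), numeric(1L))
  rounded <- round_half_up(score, 2L)
  o <- order(rounded, decreasing = TRUE)
  out <- data.frame(model_id = names(score)[o], score = rounded[o],
                    stringsAsFactors = FALSE)
  out$rank <- match(out$score, unique(out$score))  # ties share a rank
  rownames(out) <- NULL
  out
}

#' One-way repeated-measures ANOVA across models
#'
#' Standard decomposition with models as the within factor and datasets
#' (columns) as subjects: `F = MS_model / MS_error` with
#' `df = (k - 1, (k - 1)(n - 1))`. A constant matrix has zero error sum of
#' squares; the F statistic is then undefined and returned as `NA` with
#' `degenerate = TRUE`.
#'
#' @param mat Numeric matrix, models in rows, repeated measures (datasets)
#'   in columns; complete (no missing cells).
#' @param check With fewer than 2 models or 2 measures an error is raised.
#' @return List with `F`, `df1`, `df2`, `p`, sums of squares, and a
#'   `degenerate` flag.
#' @export
rm_anova <- function(mat, check = TRUE) {
  mat <- as.matrix(mat)
  if (any(is.na(mat))) stop("rm_anova: missing cells")
  k <- nrow(mat); n <- ncol(mat)
  if (check && (k < 2L || n < 2L))
    stop("rm_anova: need at least 2 models and 2 repeated measures")
  grand <- mean(mat)
  ss_model <- n * sum((rowMeans(mat) - grand)^2)
  ss_subj <- k * sum((colMeans(mat) - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_err <- ss_total - ss_model - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_err <- ss_err / df2
  tol <- .Machine$double.eps * max(1, abs(grand))^2 * k * n
  if (ss_total <= tol)   # constant matrix: F undefined
    return(list(F = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                ss_model = ss_model, ss_error = ss_err, degenerate = TRUE))
  if (ms_err <= tol) {
    if (ss_model <= tol)   # no model effect, all variance between subjects
      return(list(F = 0, df1 = df1, df2 = df2, p = 1,
                  ss_model = ss_model, ss_error = ss_err, degenerate = FALSE))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0,
                ss_model = ss_model, ss_error = ss_err, degenerate = TRUE))
  }
  Fv <- (ss_model / df1) / ms_err
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       ss_model = ss_model, ss_error = ss_err, degenerate = FALSE)
}

#' Published per-dataset benchmark means
#'
#' The per-dataset mean reliability, classification and computation values
#' for the full aggregator family on the three annotated benchmark
#' datasets, shipped as a CSV fixture so the report-layer arithmetic
#' (overall means, metric-exclusion rankings) is exercised without any
#' training run. Blank cells (models without a given metric) are `NA`.
#'
#' @return Data frame with columns `dataset`, `model_id`, `heads`, `mi`,
#'   `spearman`, `auprc`, `auc`, `f1`, `flops_m`, `size_k`.
#' @export
published_tables <- function() {
  path <- system.file("extdata", "published_tables.csv", package = "milrel")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Render a patch-score heatmap to a PNG file
#'
#' Rasterizes per-patch scores onto the slide's patch grid, colored from
#' low (blue) through white to high (red), with annotation polygon
#' outlines overlaid in green. Cells without a patch are left white.
#' Rendering is deterministic for fixed inputs.
#'
#' @param bag An [instance_bag()] providing coords and patch size.
#' @param score_set A [patch_score_set()] (or numeric vector) aligned with
#'   the bag.
#' @param ann Optional [annotation_set()] to overlay.
#' @param path Output PNG path.
#' @param scale Rendered pixels per patch cell.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(bag, score_set, ann = NULL, path, scale = 8L) {
  stopifnot(inherits(bag, "instance_bag"))
  scores <- if (inherits(score_set, "patch_score_set")) score_set$scores
            else as.numeric(score_set)
  if (length(scores) != nrow(bag$coords))
    stop("render_heatmap: scores do not align with bag coords")
  ps <- bag$patch_size
  col <- bag$coords[, 1L] %/% ps
  row <- bag$coords[, 2L] %/% ps
  ncols <- max(col) + 1L; nrows <- max(row) + 1L
  rng <- range(scores)
  v <- if (rng[1L] == rng[2L]) rep(0.5, length(scores))
       else (scores - rng[1L]) / (rng[2L] - rng[1L])
  # blue -> white -> red
  r_ch <- ifelse(v < 0.5, 2 * v, 1)
  b_ch <- ifelse(v < 0.5, 1, 2 * (1 - v))
  g_ch <- 1 - abs(2 * v - 1)
  img <- array(1, dim = c(nrows, ncols, 3L))
  for (i in seq_along(scores)) {
    img[row[i] + 1L, col[i] + 1L, ] <- c(r_ch[i], g_ch[i], b_ch[i])
  }
  big <- array(0, dim = c(nrows * scale, ncols * scale, 3L))
  for (ch in 1:3) big[, , ch] <- kronecker(img[, , ch], matrix(1, scale, scale))
  if (!is.null(ann)) {
    for (rgn in ann$regions) {
      poly <- rbind(rgn$polygon, rgn$polygon[1L, ])
      for (e in seq_len(nrow(poly) - 1L)) {
        p0 <- poly[e, ] / ps * scale; p1 <- poly[e + 1L, ] / ps * scale
        len <- max(abs(p1 - p0))
        ts <- seq(0, 1, length.out = max(2L, ceiling(len) * 2L))
        xs <- pmin(pmax(round(p0[1L] + ts * (p1[1L] - p0[1L])), 1L),
                   ncols * scale)
        ys <- pmin(pmax(round(p0[2L] + ts * (p1[2L] - p0[2L])), 1L),
                   nrows * scale)
        for (j in seq_along(ts)) {
          big[ys[j], xs[j], ] <- c(0, 0.8, 0)
        }
      }
    }
  }
  png::writePNG(big, path)
  invisible(path)
}
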