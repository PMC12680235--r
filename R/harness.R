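# Training and evaluation protocol: Adam at a fixed learning rate, one bag
# per optimizer step, cross-entropy (plus architecture-specific auxiliary
# losses), weight decay selected on validation loss, repetition over seeds,
# and assembly of benchmark rows (mean +/- sd over seeds).

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs (no early stopping).
#' @param weight_decay_grid Candidate L2 weight decays; the one minimizing
#'   the final-epoch validation loss is kept.
#' @param seed Seed controlling initialization, bag shuffling and any
#'   stochastic architecture components for one run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 50L,
                         weight_decay_grid = c(1e-5, 1e-4, 1e-3),
                         seed = 1L) {
  stopifnot(epochs >= 0L, length(weight_decay_grid) >= 1L)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 weight_decay_grid = weight_decay_grid,
                 seed = as.integer(seed)),
            class = "train_config")
}

run_epochs <- function(model, bags, val_bags, cfg, wd) {
  state <- adam_init(model$params)
  log <- NULL
  n_classes <- model$cfg$n_classes
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(bags))
    losses <- numeric(0)
    logits_log <- matrix(0, length(bags), n_classes)
    y_log <- integer(length(bags))
    for (j in seq_along(ord)) {
      bag <- bags[[ord[j]]]
      lg <- mil_loss_grads(model, bag$features, bag$bag_label)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      st <- adam_step(model$params, lg$grads, state, lr = cfg$lr,
                      weight_decay = wd)
      model$params <- st$params
      state <- st$state
      losses <- c(losses, lg$loss)
      logits_log[j, ] <- lg$logits
      y_log[j] <- bag$bag_label
    }
    val_loss <- mean(vapply(val_bags, function(b)
      bag_loss(model, b), numeric(1L)))
    train_auc <- tryCatch(
      classification_metrics(softmax_rows(logits_log), y_log)$auc,
      error = function(e) NA_real_)
    log <- rbind(log, data.frame(weight_decay = wd, epoch = epoch,
                                 train_loss = mean(losses),
                                 val_loss = val_loss,
                                 train_auc = train_auc))
  }
  if (cfg$epochs == 0L)
    log <- data.frame(weight_decay = wd, epoch = 0L, train_loss = NA_real_,
                      val_loss = mean(vapply(val_bags, function(b)
                        bag_loss(model, b), numeric(1L))),
                      train_auc = NA_real_)
  list(model = model, log = log)
}

# Validation uses the same objective as training but a deterministic
# forward (canonical dtfd partition, no sampling).
bag_loss <- function(model, bag) {
  out <- mil_forward(model, bag)
  -log(max(out$prob[bag$bag_label + 1L], 1e-12))
}

#' Train a MIL model with weight-decay selection
#'
#' For every candidate weight decay the model is retrained from the same
#' seeded initialization for `cfg$epochs` epochs (Adam, one bag per step);
#' the decay minimizing the final validation loss is selected. The whole
#' procedure is deterministic given `cfg$seed`.
#'
#' @param model_cfg A [model_config()].
#' @param train_bags,val_bags Lists of [instance_bag()].
#' @param cfg A [train_config()].
#' @return A list with the fitted `model`, the per-epoch `log` (one block
#'   per weight decay: train/val loss and training AUC), and the
#'   `chosen_decay`.
#' @export
train_mil <- function(model_cfg, train_bags, val_bags, cfg = train_config()) {
  stopifnot(length(train_bags) >= 1L, length(val_bags) >= 1L)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  fits <- list(); logs <- NULL
  for (wd in cfg$weight_decay_grid) {
    set.seed(cfg$seed)
    model <- build_model(model_cfg)
    set.seed(cfg$seed + 1L)   # shared shuffling/partition stream
    fit <- run_epochs(model, train_bags, val_bags, cfg, wd)
    fits[[length(fits) + 1L]] <- fit$model
    logs <- rbind(logs, fit$log)
  }
  chosen <- select_weight_decay(logs)
  best <- match(chosen, cfg$weight_decay_grid)
  list(model = fits[[best]], log = logs, chosen_decay = chosen)
}

#' Re-derive the selected weight decay from a training log
#'
#' @param log Training log as produced by [train_mil()].
#' @return The weight decay whose final epoch has the lowest validation
#'   loss (ties broken toward the smaller decay).
#' @export
select_weight_decay <- function(log) {
  fin <- do.call(rbind, lapply(split(log, log$weight_decay), function(d)
    d[which.max(d$epoch), c("weight_decay", "val_loss")]))
  fin <- fin[order(fin$weight_decay), ]
  fin$weight_decay[which.min(fin$val_loss)]
}

#' Slide-level classification metrics
#'
#' Binary problems: AUC of the positive-class probability (rank statistic,
#' ties counted half) and F1 of the positive class at the argmax decision.
#' Multi-class: macro one-vs-rest AUC and macro F1.
#'
#' @param prob Matrix of class probabilities (slides x classes), or a
#'   vector of positive-class probabilities for binary problems.
#' @param labels Integer class labels (0-based).
#' @return A list with elements `auc` and `f1`.
#' @export
classification_metrics <- function(prob, labels) {
  if (is.null(dim(prob))) prob <- cbind(1 - prob, prob)
  labels <- as.integer(labels)
  C <- ncol(prob)
  if (length(unique(labels)) < 2L)
    stop("classification_metrics: need at least two classes in labels")
  pred <- max.col(prob, ties.method = "first") - 1L
  if (C == 2L) {
    auc <- binary_auc(prob[, 2L], as.integer(labels == 1L))
    f1 <- f1_score(pred == 1L, labels == 1L)
  } else {
    present <- sort(unique(labels))
    auc <- mean(vapply(present, function(c)
      binary_auc(prob[, c + 1L], as.integer(labels == c)), numeric(1L)))
    f1 <- mean(vapply(0:(C - 1L), function(c)
      f1_score(pred == c, labels == c), numeric(1L)))
  }
  list(auc = auc, f1 = f1)
}

# Rank-based AUC (equals the fraction of correctly ordered pairs, ties 0.5).
binary_auc <- function(score, pos) {
  n1 <- sum(pos); n0 <- sum(1 - pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

f1_score <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' The benchmark model registry
#'
#' Named list of [model_config()]s for the standard aggregator family.
#'
#' @param n_classes Number of classes.
#' @param heads Head count for the multi-head models.
#' @param additive Include the additive reformulation's score channels for
#'   attention models.
#' @param input_dim,embed_dim Feature and embedding dimensions.
#' @return Named list of configs keyed by [model_name()].
#' @export
model_registry <- function(n_classes = 2L, heads = 2L, additive = FALSE,
                           input_dim = 1024L, embed_dim = 512L) {
  archs <- MIL_ARCHS
  cfgs <- lapply(archs, function(a)
    model_config(a, n_classes = n_classes, input_dim = input_dim,
                 embed_dim = embed_dim, heads = heads,
                 additive = additive &&
                   a %in% c("abmil", "clam_lite", "madmil", "acmil_lite")))
  stats::setNames(cfgs, vapply(cfgs, model_name, ""))
}

#' Train and evaluate a model family on one dataset
#'
#' For every model and every seed: train on the `train` split (weight decay
#' selected on `val`), compute slide-level classification metrics on the
#' `test` split, and reliability metrics for every score channel the model
#' emits (slides without regions of interest excluded). Returns one row per
#' model id and score channel with mean and sample sd over seeds; models
#' without patch scores (mean pooling) carry `NA` reliability cells.
#'
#' @param dataset A dataset list (`bags`, `annotations`, `labels`) as from
#'   [make_dataset()] or [read_dataset()].
#' @param model_cfgs Named list of [model_config()]s, e.g.
#'   [model_registry()].
#' @param train_cfg A [train_config()]; its seed is replaced by each
#'   element of `seeds`.
#' @param seeds Integer vector of training seeds.
#' @param dataset_id Dataset label for the output rows.
#' @param aggregation Reliability aggregation, see
#'   [evaluate_reliability()].
#' @return A `benchmark_table` data frame.
#' @export
run_benchmark <- function(dataset, model_cfgs, train_cfg = train_config(),
                          seeds = 1:5, dataset_id = "synthetic",
                          aggregation = "per_slide_mean") {
  splits <- split(seq_along(dataset$bags), dataset$labels$split)
  bags_of <- function(s) dataset$bags[splits[[s]]]
  test_bags <- bags_of("test")
  test_labels <- vapply(test_bags, `[[`, 0L, "bag_label")
  patch_labels <- lapply(splits$test, function(i) {
    b <- dataset$bags[[i]]
    if (!is.null(b$patch_labels)) b$patch_labels
    else assign_patch_labels(b, dataset$annotations[[i]])
  })
  rows <- list()
  per_seed_log <- NULL
  for (mname in names(model_cfgs)) {
    per_seed <- list()
    for (seed in seeds) {
      cfg <- model_cfgs[[mname]]
      cfg$seed <- as.integer(seed)
      tc <- train_cfg; tc$seed <- as.integer(seed)
      fit <- train_mil(cfg, bags_of("train"), bags_of("val"), tc)
      outs <- lapply(test_bags, function(b) mil_forward(fit$model, b))
      prob <- do.call(rbind, lapply(outs, `[[`, "prob"))
      cls <- classification_metrics(prob, test_labels)
      rels <- list()
      if (length(outs[[1L]]$score_sets)) {
        for (k in seq_along(outs[[1L]]$score_sets)) {
          variant <- attr(outs[[1L]]$score_sets[[k]], "variant")
          rid <- if (nzchar(variant)) paste(mname, variant, sep = "-") else mname
          sets <- lapply(outs, function(o) o$score_sets[[k]])
          rels[[rid]] <- evaluate_reliability(sets, patch_labels,
                                              aggregation = aggregation,
                                              model_id = rid, seed = seed)
        }
      }
      per_seed[[length(per_seed) + 1L]] <-
        list(cls = cls, rels = rels, params = count_params(fit$model),
             flops = count_flops(fit$model))
      for (rid in names(rels)) {
        per_seed_log <- rbind(per_seed_log, data.frame(
          model_id = rid, seed = seed, mi = rels[[rid]]$mi,
          spearman = rels[[rid]]$spearman, auprc = rels[[rid]]$auprc,
          auc = cls$auc, f1 = cls$f1, stringsAsFactors = FALSE))
      }
    }
    rel_ids <- names(per_seed[[1L]]$rels)
    if (!length(rel_ids)) rel_ids <- mname   # mean pooling: blank reliability
    for (rid in rel_ids) {
      msd <- function(x) c(mean(x), stats::sd(x))
      get_rel <- function(metric) vapply(per_seed, function(ps)
        if (is.null(ps$rels[[rid]])) NA_real_ else ps$rels[[rid]][[metric]],
        numeric(1L))
      mi <- msd(get_rel("mi")); rs <- msd(get_rel("spearman"))
      ap <- msd(get_rel("auprc"))
      auc <- msd(vapply(per_seed, function(ps) ps$cls$auc, 0))
      f1 <- msd(vapply(per_seed, function(ps) ps$cls$f1, 0))
      primary <- rid == rel_ids[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = rid, dataset = dataset_id,
        mi = mi[1L], mi_sd = mi[2L], spearman = rs[1L], spearman_sd = rs[2L],
        auprc = ap[1L], auprc_sd = ap[2L],
        auc = if (primary) auc[1L] else NA_real_,
        auc_sd = if (primary) auc[2L] else NA_real_,
        f1 = if (primary) f1[1L] else NA_real_,
        f1_sd = if (primary) f1[2L] else NA_real_,
        params = per_seed[[1L]]$params, flops = per_seed[[1L]]$flops,
        n_seeds = length(seeds), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (length(seeds) == 1L)
    out[, grep("_sd$", names(out))] <- 0
  attr(out, "per_seed") <- per_seed_log
  class(out) <- c("benchmark_table", "data.frame")
  out
}
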