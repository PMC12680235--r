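# The MIL aggregator family. Every architecture maps a bag of patch
# features (N x input_dim) to class logits plus zero or more per-patch
# score sets, through a shared ReLU compression layer (input_dim -> D).
# Training gradients are written out analytically per architecture.

MIL_ARCHS <- c("mean_pool", "max_pool", "mean_pool_ins", "max_pool_ins",
               "abmil", "clam_lite", "madmil", "dtfd", "acmil_lite")

#' MIL model configuration
#'
#' @param arch Architecture name, one of `"mean_pool"`, `"max_pool"`,
#'   `"mean_pool_ins"`, `"max_pool_ins"`, `"abmil"`, `"clam_lite"`,
#'   `"madmil"`, `"dtfd"`, `"acmil_lite"`.
#' @param n_classes Number of slide classes.
#' @param input_dim Patch feature dimensionality (1024 for ResNet50 bags).
#' @param embed_dim Compressed embedding width `D` (512).
#' @param attn_dim Gated-attention hidden width (256; for `madmil` both the
#'   embedding and this width are split evenly across heads).
#' @param heads Attention heads / branches for `madmil` and `acmil_lite`.
#' @param pseudo_bags Number of pseudo-bags `M` for `dtfd`.
#' @param additive Emit the exact additive reformulation's score sets
#'   (attention plus per-instance contribution) for attention
#'   architectures. With the linear classifier head used here the additive
#'   bag logit is identical to the base model's, so training is unchanged.
#' @param instance_k Instances drawn from each attention extreme for the
#'   `clam_lite` auxiliary instance loss.
#' @param instance_loss_weight Weight of that auxiliary loss.
#' @param diversity_weight Weight of the `acmil_lite` branch-diversity
#'   (mean pairwise cosine) penalty.
#' @param seed Seed used for weight initialization by [build_model()].
#' @return An object of class `model_config`.
#' @export
model_config <- function(arch, n_classes = 2L, input_dim = 1024L,
                         embed_dim = 512L, attn_dim = 256L, heads = 2L,
                         pseudo_bags = 8L, additive = FALSE,
                         instance_k = 8L, instance_loss_weight = 0.3,
                         diversity_weight = 0.1, seed = 1L) {
  arch <- match.arg(arch, MIL_ARCHS)
  cfg <- list(arch = arch, n_classes = as.integer(n_classes),
              input_dim = as.integer(input_dim),
              embed_dim = as.integer(embed_dim),
              attn_dim = as.integer(attn_dim), heads = as.integer(heads),
              pseudo_bags = as.integer(pseudo_bags),
              additive = isTRUE(additive), instance_k = as.integer(instance_k),
              instance_loss_weight = instance_loss_weight,
              diversity_weight = diversity_weight, seed = as.integer(seed))
  if (cfg$n_classes < 2L) stop("model_config: need n_classes >= 2")
  if (arch == "madmil") {
    if (cfg$heads < 1L || cfg$embed_dim %% cfg$heads != 0L ||
        cfg$attn_dim %% cfg$heads != 0L)
      stop("model_config: madmil needs embed_dim and attn_dim divisible by heads")
  }
  if (arch == "acmil_lite" && cfg$heads < 1L)
    stop("model_config: acmil_lite needs heads >= 1")
  if (arch == "dtfd" && cfg$pseudo_bags < 2L)
    stop("model_config: dtfd needs pseudo_bags >= 2")
  if (cfg$additive &&
      !arch %in% c("abmil", "clam_lite", "madmil", "acmil_lite"))
    stop("model_config: additive reformulation applies to attention architectures")
  structure(cfg, class = "model_config")
}

#' Canonical display name of a configured model
#'
#' Multi-head models carry their head count (`"MADMIL/4"` etc.), matching
#' the usual shorthand.
#'
#' @param cfg A [model_config()].
#' @return Character scalar.
#' @export
model_name <- function(cfg) {
  base <- switch(cfg$arch,
    mean_pool = "MEAN-POOL", max_pool = "MAX-POOL",
    mean_pool_ins = "MEAN-POOL-INS", max_pool_ins = "MAX-POOL-INS",
    abmil = "ABMIL", clam_lite = "CLAM", dtfd = "DTFD",
    madmil = sprintf("MADMIL/%d", cfg$heads),
    acmil_lite = sprintf("ACMIL/%d", cfg$heads))
  base
}

#' Build a MIL model with freshly initialized weights
#'
#' @param cfg A [model_config()]; `cfg$seed` fixes the initialization.
#' @return An object of class `mil_model` (config plus parameter list).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  D <- cfg$embed_dim; A <- cfg$attn_dim; C <- cfg$n_classes; H <- cfg$heads
  p <- list(comp = init_linear(cfg$input_dim, D))
  p <- c(p, switch(cfg$arch,
    mean_pool = , max_pool = , mean_pool_ins = , max_pool_ins =
      list(cls = init_linear(D, C)),
    abmil = list(att = init_gated_attention(D, A), cls = init_linear(D, C)),
    clam_lite = list(att = init_gated_attention(D, A),
                     cls = init_linear(D, C),
                     inst = lapply(seq_len(C), function(i) init_linear(D, C))),
    madmil = list(att_heads = lapply(seq_len(H), function(h)
                    init_gated_attention(D %/% H, A %/% H)),
                  cls = init_linear(D, C)),
    dtfd = list(att1 = init_gated_attention(D, A), cls1 = init_linear(D, C),
                att2 = init_gated_attention(D, A), cls2 = init_linear(D, C)),
    acmil_lite = list(att = list(V = matrix(stats::rnorm(D * A, sd = sqrt(2 / D)), D, A),
                                 bv = numeric(A),
                                 U = matrix(stats::rnorm(D * A, sd = sqrt(2 / D)), D, A),
                                 bu = numeric(A)),
                      branch = lapply(seq_len(H), function(h)
                        list(w = stats::rnorm(A, sd = sqrt(1 / A)), bw = 0)),
                      cls = init_linear(D, C))))
  structure(list(cfg = cfg, params = p), class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> %s: %s parameters\n", model_name(x$cfg),
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

# Fraction of matrix columns whose maximum is attained by each row, with
# ties split equally; sums to one over rows.
selection_scores <- function(M) {
  mx <- apply(M, 2L, max)
  hit <- t(t(M) == mx)
  as.vector(hit %*% (1 / colSums(hit))) / ncol(M)
}

positive_context <- function(cfg, logits) {
  if (cfg$n_classes == 2L) 2L else which.max(logits)
}

# madmil column blocks
head_cols <- function(D, H) {
  dh <- D %/% H
  lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
}

# Deterministic, permutation-equivariant pseudo-bag partition used at
# inference: instances ordered by a content hash (feature row sums, then
# first feature) and dealt round-robin over the pseudo-bags.
dtfd_partition_canonical <- function(X, M) {
  n <- nrow(X)
  m_eff <- min(M, n)
  ord <- order(rowSums(X), X[, 1L])
  g <- integer(n)
  g[ord] <- rep_len(seq_len(m_eff), n)
  g
}

#' Forward pass of a MIL model over one bag
#'
#' Runs the aggregator and extracts its per-patch score sets. Score sets
#' carry a `variant` tag: `""` for the model's primary reliability channel,
#' `"PATCH"` for secondary instance-probability channels (max-pool-instance
#' probabilities, two-tier gradient attribution), `"ADD-ATT"` /
#' `"ADD-PATCH"` for the additive reformulation's channels.
#'
#' @param model A [build_model()] result.
#' @param bag An [instance_bag()] or a bare feature matrix.
#' @return A list with `logits` (length `n_classes`), `prob`
#'   (softmax of logits, except instance-mean pooling where it is the mean
#'   instance probability), and `score_sets` (list of [patch_score_set()]
#'   with a `variant` attribute). Mean pooling emits no score sets.
#' @export
mil_forward <- function(model, bag) {
  X <- if (inherits(bag, "instance_bag")) bag$features else as.matrix(bag)
  slide_id <- if (inherits(bag, "instance_bag")) bag$slide_id else "bag"
  cfg <- model$cfg; p <- model$params
  if (ncol(X) != cfg$input_dim)
    stop("mil_forward: feature dimension does not match model input_dim")
  n <- nrow(X)
  H <- pmax(lin_fwd(X, p$comp), 0)
  sets <- list()
  add_set <- function(sets, scores, channel, variant, ctx = NA_integer_) {
    ss <- patch_score_set(slide_id, scores, channel, ctx)
    attr(ss, "variant") <- variant
    c(sets, list(ss))
  }
  prob <- NULL

  if (cfg$arch == "mean_pool") {
    logits <- drop(crossprod(colMeans(H), p$cls$W)) + p$cls$b
  } else if (cfg$arch == "max_pool") {
    m <- apply(H, 2L, max)
    logits <- drop(crossprod(m, p$cls$W)) + p$cls$b
    sets <- add_set(sets, selection_scores(H), "selection", "")
  } else if (cfg$arch == "mean_pool_ins") {
    P <- softmax_rows(lin_fwd(H, p$cls))
    pbar <- colMeans(P)
    logits <- log(pmax(pbar, 1e-12))
    prob <- pbar
    ctx <- positive_context(cfg, logits)
    sets <- add_set(sets, P[, ctx], "patch_prob", "", ctx)
  } else if (cfg$arch == "max_pool_ins") {
    L <- lin_fwd(H, p$cls)
    logits <- apply(L, 2L, max)
    ctx <- positive_context(cfg, logits)
    sets <- add_set(sets, selection_scores(L), "selection", "")
    sets <- add_set(sets, softmax_rows(L)[, ctx], "patch_prob", "PATCH", ctx)
  } else if (cfg$arch %in% c("abmil", "clam_lite")) {
    fw <- gatt_fwd(H, p$att)
    m <- drop(fw$a %*% H)
    logits <- drop(crossprod(m, p$cls$W)) + p$cls$b
    sets <- additive_sets(add_set, sets, cfg, fw$a, H, p$cls, logits, n)
  } else if (cfg$arch == "madmil") {
    cols <- head_cols(cfg$embed_dim, cfg$heads)
    a_heads <- matrix(0, n, cfg$heads)
    m <- numeric(cfg$embed_dim)
    rmat <- matrix(0, n, cfg$embed_dim)
    for (h in seq_len(cfg$heads)) {
      Hh <- H[, cols[[h]], drop = FALSE]
      fw <- gatt_fwd(Hh, p$att_heads[[h]])
      a_heads[, h] <- fw$a
      rmat[, cols[[h]]] <- fw$a * Hh
      m[cols[[h]]] <- drop(fw$a %*% Hh)
    }
    logits <- drop(crossprod(m, p$cls$W)) + p$cls$b
    abar <- rowMeans(a_heads)
    abar <- abar / sum(abar)
    if (cfg$additive) {
      sets <- add_set(sets, abar, "attention", "ADD-ATT")
      Cmat <- sweep(rmat %*% p$cls$W, 2L, p$cls$b / n, "+")
      ctx <- positive_context(cfg, logits)
      sets <- add_set(sets, softmax_rows(Cmat)[, ctx], "patch_prob",
                      "ADD-PATCH", ctx)
      attr(sets[[length(sets)]], "contributions") <- Cmat
    } else {
      sets <- add_set(sets, abar, "attention", "")
    }
  } else if (cfg$arch == "acmil_lite") {
    G <- tanh(sweep(H %*% p$att$V, 2L, p$att$bv, "+")) *
      stats::plogis(sweep(H %*% p$att$U, 2L, p$att$bu, "+"))
    a_heads <- vapply(p$branch, function(br)
      softmax_vec(drop(G %*% br$w) + br$bw), numeric(n))
    a_heads <- matrix(a_heads, n, cfg$heads)
    abar <- rowMeans(a_heads)
    m <- drop(abar %*% H)
    logits <- drop(crossprod(m, p$cls$W)) + p$cls$b
    sets <- additive_sets(add_set, sets, cfg, abar, H, p$cls, logits, n,
                          renorm = TRUE)
  } else if (cfg$arch == "dtfd") {
    M <- cfg$pseudo_bags
    g <- dtfd_partition_canonical(X, M)
    m_eff <- max(g)
    Fm <- matrix(0, m_eff, cfg$embed_dim)
    a_within <- numeric(n)
    for (b in seq_len(m_eff)) {
      idx <- which(g == b)
      fwb <- gatt_fwd(H[idx, , drop = FALSE], p$att1)
      a_within[idx] <- fwb$a
      Fm[b, ] <- drop(fwb$a %*% H[idx, , drop = FALSE])
    }
    fw2 <- gatt_fwd(Fm, p$att2)
    gvec <- drop(fw2$a %*% Fm)
    logits <- drop(crossprod(gvec, p$cls2$W)) + p$cls2$b
    att_comb <- fw2$a[g] * a_within
    sets <- add_set(sets, att_comb, "attention", "")
    chat <- which.max(logits)
    raw <- att_comb * pmax(drop(H %*% p$cls2$W[, chat]), 0)
    if (max(raw) > 0) raw <- raw / max(raw)
    sets <- add_set(sets, raw, "patch_prob", "PATCH", chat)
  }
  if (is.null(prob)) prob <- softmax_vec(logits)
  list(logits = logits, prob = prob, score_sets = sets)
}

# Attention + (optionally) additive-contribution score sets for models whose
# bag representation is sum_i a_i h_i with a linear classifier head; the
# per-instance contribution c_i = W' (a_i h_i) + b/N sums exactly to the bag
# logits.
additive_sets <- function(add_set, sets, cfg, a, H, cls, logits, n,
                          renorm = FALSE) {
  a_out <- if (renorm) a / sum(a) else a
  if (!cfg$additive) return(add_set(sets, a_out, "attention", ""))
  sets <- add_set(sets, a_out, "attention", "ADD-ATT")
  Cmat <- sweep((a * H) %*% cls$W, 2L, cls$b / n, "+")
  ctx <- positive_context(cfg, logits)
  sets <- add_set(sets, softmax_rows(Cmat)[, ctx], "patch_prob", "ADD-PATCH", ctx)
  attr(sets[[length(sets)]], "contributions") <- Cmat
  sets
}
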