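# Exact computational accounting: trainable parameter counts and per-bag
# multiply-accumulate (MAC) counts of the inference forward pass.

#' Count trainable parameters of a MIL model
#'
#' Exact count of trainable scalars (weights and biases) over the whole
#' parameter tree.
#'
#' @param model A [build_model()] result or a [model_config()].
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  if (inherits(model, "model_config")) model <- build_model(model)
  stopifnot(inherits(model, "mil_model"))
  count <- function(x) if (is.list(x)) sum(vapply(x, count, 0)) else length(x)
  as.integer(count(model$params))
}

#' Count forward-pass FLOPs of a MIL model
#'
#' Multiply-accumulate count of one inference forward pass at a given bag
#' size: weight multiplications only (biases and nonlinearities excluded),
#' instance-wise layers counted once per instance, bag-level classifiers
#' once per bag. Training-only components (the clam_lite instance heads)
#' are not part of the inference pass and are not counted. At
#' `n_instances = 0` only the bag-level classifier remains.
#'
#' @param model A [build_model()] result or a [model_config()].
#' @param n_instances Bag size used for the accounting (120 by convention).
#' @return Numeric MAC count.
#' @export
count_flops <- function(model, n_instances = 120L) {
  cfg <- if (inherits(model, "model_config")) model else model$cfg
  n <- as.numeric(n_instances)
  d_in <- cfg$input_dim; D <- cfg$embed_dim; A <- cfg$attn_dim
  C <- cfg$n_classes; H <- cfg$heads; M <- cfg$pseudo_bags
  compress <- n * d_in * D
  gatt <- function(d, a) 2 * d * a + a          # V, U, then w
  flops <- switch(cfg$arch,
    mean_pool = , max_pool = compress + D * C,
    mean_pool_ins = , max_pool_ins = compress + n * D * C,
    abmil = , clam_lite = compress + n * gatt(D, A) + D * C,
    acmil_lite = compress + n * (2 * D * A + H * A) + D * C,
    madmil = compress + n * H * gatt(D / H, A / H) + D * C,
    dtfd = compress + n * gatt(D, A) + min(M, n) * D * C +
      min(M, n) * gatt(D, A) + D * C)
  if (isTRUE(cfg$additive)) flops <- flops - D * C + n * D * C
  flops
}

#' Format counts the way benchmark tables print them
#'
#' `"526 K"` for parameter counts, `"94 M"` for FLOPs (half-up rounding to
#' the nearest unit).
#'
#' @param x Numeric count.
#' @param unit `"K"` or `"M"`.
#' @return Character scalar.
#' @export
format_count <- function(x, unit = c("K", "M")) {
  unit <- match.arg(unit)
  div <- if (unit == "K") 1e3 else 1e6
  sprintf("%d %s", as.integer(round_half_up(x / div, 0)), unit)
}
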