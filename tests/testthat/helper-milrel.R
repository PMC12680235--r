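# Shared helpers for the test suite: tiny hand-built bags and models with
# controllable weights.

# A bag on a g x g lattice of 256-px patches, features supplied row-wise.
toy_bag <- function(features, label = 1L, slide_id = "toy", grid = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  g <- if (is.null(grid)) ceiling(sqrt(n)) else grid
  cells <- seq_len(n) - 1L
  coords <- cbind((cells %% g) * 256L, (cells %/% g) * 256L)
  instance_bag(slide_id, features, coords, label)
}

# Rectangle polygon (x0, y0) - (x1, y1).
rect_poly <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# Overwrite a built model's compress layer with an identity map so that
# embeddings equal the (zero-padded) inputs; requires input_dim <= embed_dim.
identity_compress <- function(model) {
  d_in <- model$cfg$input_dim; D <- model$cfg$embed_dim
  W <- matrix(0, d_in, D)
  W[cbind(seq_len(d_in), seq_len(d_in))] <- 1
  model$params$comp$W <- W
  model$params$comp$b <- numeric(D)
  model
}

# Independent plug-in MI oracle for a 2x2 count table, written directly
# from the definition.
mi_oracle_2x2 <- function(tab) {
  n <- sum(tab)
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    p <- tab[i, j] / n
    if (p > 0) s <- s + p * log(p / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  s
}
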