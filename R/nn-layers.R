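# Minimal dense-layer machinery used by the MIL aggregators: linear layers,
# gated attention, softmax cross-entropy, and an Adam optimizer over nested
# parameter lists. Everything is plain matrix algebra so gradients are
# written out analytically per architecture.

softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

softmax_rows <- function(L) {
  Z <- exp(L - apply(L, 1L, max))
  Z / rowSums(Z)
}

init_linear <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

lin_fwd <- function(X, p) sweep(X %*% p$W, 2L, p$b, "+")

# Gated attention over instance embeddings H (N x d):
#   a = softmax( w . ( tanh(H V + bv) * sigmoid(H U + bu) ) + bw )
init_gated_attention <- function(d, a_dim) {
  list(V = matrix(stats::rnorm(d * a_dim, sd = sqrt(2 / d)), d, a_dim),
       bv = numeric(a_dim),
       U = matrix(stats::rnorm(d * a_dim, sd = sqrt(2 / d)), d, a_dim),
       bu = numeric(a_dim),
       w = stats::rnorm(a_dim, sd = sqrt(1 / a_dim)),
       bw = 0)
}

gatt_fwd <- function(H, p) {
  Tt <- tanh(sweep(H %*% p$V, 2L, p$bv, "+"))
  S <- stats::plogis(sweep(H %*% p$U, 2L, p$bu, "+"))
  G <- Tt * S
  e <- drop(G %*% p$w) + p$bw
  a <- softmax_vec(e)
  list(a = a, cache = list(Tt = Tt, S = S, G = G))
}

# Backward through gated attention given d(loss)/d(a). Returns the gradient
# with respect to H plus parameter gradients.
gatt_bwd <- function(da, H, p, fw) {
  a <- fw$a; Tt <- fw$cache$Tt; S <- fw$cache$S; G <- fw$cache$G
  de <- a * (da - sum(da * a))                 # softmax Jacobian
  dG <- outer(de, p$w)
  dZt <- dG * S * (1 - Tt^2)
  dZs <- dG * Tt * S * (1 - S)
  list(dH = dZt %*% t(p$V) + dZs %*% t(p$U),
       grads = list(V = crossprod(H, dZt), bv = colSums(dZt),
                    U = crossprod(H, dZs), bu = colSums(dZs),
                    w = drop(crossprod(G, de)), bw = sum(de)))
}

# Softmax cross-entropy on a logit vector; y is a 0-based class index.
ce_loss <- function(logits, y) {
  p <- softmax_vec(logits)
  d <- p
  d[y + 1L] <- d[y + 1L] - 1
  list(loss = -log(max(p[y + 1L], 1e-12)), dlogits = d)
}

# --- Adam over nested parameter lists ---------------------------------------

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# Plain Adam with L2 weight decay folded into the gradient.
adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    if (is.null(g)) g <- p * 0
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# Elementwise sum of two parameter/gradient trees (NULL counts as zero).
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    nm <- union(names(a), names(b))
    out <- stats::setNames(lapply(nm, function(k) tree_add(a[[k]], b[[k]])), nm)
    return(out)
  }
  a + b
}
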