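test_that("the compression layer is an instance-wise rectified affine map", {
  cfg <- model_config("mean_pool", input_dim = 6L, embed_dim = 4L, seed = 2L)
  m <- build_model(cfg)
  # layer parameter count at the full default sizes: 1024*512 + 512
  full <- build_model(model_config("mean_pool"))
  expect_identical(length(full$params$comp$W) + length(full$params$comp$b),
                   524800L)
  # zero weights map anything to zero
  m0 <- m
  m0$params$comp$W[] <- 0; m0$params$comp$b[] <- 0
  H <- pmax(milrel:::lin_fwd(matrix(rnorm(18), 3, 6), m0$params$comp), 0)
  expect_true(all(H == 0))
  # row-wise independence: shared rows produce identical embeddings
  X1 <- matrix(rnorm(6), 1, 6)
  X5 <- rbind(X1, matrix(rnorm(24), 4, 6))
  H1 <- pmax(milrel:::lin_fwd(X1, m$params$comp), 0)
  H5 <- pmax(milrel:::lin_fwd(X5, m$params$comp), 0)
  expect_equal(H5[1, ], H1[1, ])
})

test_that("gated attention produces simplex weights with known special cases", {
  set.seed(4)
  p <- milrel:::init_gated_attention(3L, 2L)
  # singleton bag
  expect_equal(milrel:::gatt_fwd(matrix(rnorm(3), 1, 3), p)$a, 1)
  # identical instances share weight equally
  H <- matrix(rep(rnorm(3), each = 4), 4, 3)
  expect_equal(milrel:::gatt_fwd(H, p)$a, rep(0.25, 4))
  # hand-set parameters, 2 instances, D = 2, attn_dim = 1
  ph <- list(V = matrix(c(0.5, -0.2), 2, 1), bv = 0.1,
             U = matrix(c(0.3, 0.4), 2, 1), bu = -0.2,
             w = 2, bw = 0.05)
  H2 <- rbind(c(1, 0.5), c(-0.6, 1.2))
  e <- sapply(1:2, function(i) {
    h <- H2[i, ]
    2 * (tanh(sum(h * ph$V) + 0.1) * plogis(sum(h * ph$U) - 0.2)) + 0.05
  })
  expect_equal(milrel:::gatt_fwd(H2, ph)$a, exp(e) / sum(exp(e)))
})

test_that("instance-mean pooling averages instance probabilities", {
  cfg <- model_config("mean_pool_ins", input_dim = 2L, embed_dim = 2L, seed = 1L)
  m <- identity_compress(build_model(cfg))
  # classifier taking logit difference (class1 - class0) = h1 - h2
  m$params$cls$W <- cbind(c(0, 1), c(1, 0))
  m$params$cls$b <- c(0, 0)
  d1 <- log(0.8 / 0.2)   # instance probs 0.8 and 0.2
  out <- mil_forward(m, toy_bag(rbind(c(d1, 0), c(0, d1))))
  expect_equal(out$prob[2], 0.5, tolerance = 1e-12)
  expect_equal(out$score_sets[[1]]$scores, c(0.8, 0.2), tolerance = 1e-12)
  expect_identical(out$score_sets[[1]]$channel, "patch_prob")
})

test_that("max-pool selection scores are argmax occupancy fractions", {
  cfg <- model_config("max_pool", input_dim = 2L, embed_dim = 2L, seed = 1L)
  m <- identity_compress(build_model(cfg))
  out <- mil_forward(m, toy_bag(rbind(c(1, 0), c(0, 1))))
  expect_equal(out$score_sets[[1]]$scores, c(0.5, 0.5))
  expect_identical(out$score_sets[[1]]$channel, "selection")
})

test_that("attention pooling over identical instances equals mean pooling", {
  cfg_a <- model_config("abmil", input_dim = 8L, embed_dim = 4L, attn_dim = 3L,
                        seed = 6L)
  ma <- build_model(cfg_a)
  mm <- build_model(model_config("mean_pool", input_dim = 8L, embed_dim = 4L,
                                 seed = 7L))
  mm$params$comp <- ma$params$comp
  mm$params$cls <- ma$params$cls
  bag <- toy_bag(matrix(rep(rnorm(8), each = 5), 5, 8))
  expect_equal(mil_forward(ma, bag)$logits, mil_forward(mm, bag)$logits)
})

test_that("additive models decompose the bag logit exactly", {
  set.seed(10)
  bag <- toy_bag(matrix(rnorm(7 * 12), 7, 12))
  for (arch in c("abmil", "clam_lite", "madmil", "acmil_lite")) {
    cfg <- model_config(arch, input_dim = 12L, embed_dim = 8L, attn_dim = 4L,
                        heads = 2L, additive = TRUE, seed = 8L)
    out <- mil_forward(build_model(cfg), bag)
    patch <- out$score_sets[[2]]
    expect_identical(attr(patch, "variant"), "ADD-PATCH")
    contrib <- attr(patch, "contributions")
    expect_lt(max(abs(colSums(contrib) - out$logits)), 1e-5)
  }
})

test_that("all aggregators are permutation invariant and equivariant", {
  set.seed(12)
  X <- matrix(rnorm(11 * 10), 11, 10)
  bag <- toy_bag(X)
  perm <- sample(11)
  bag_p <- instance_bag("toy", X[perm, ], bag$coords[perm, ], 1L)
  for (arch in milrel:::MIL_ARCHS) {
    cfg <- model_config(arch, input_dim = 10L, embed_dim = 6L, attn_dim = 4L,
                        heads = 2L, pseudo_bags = 3L, seed = 13L)
    m <- build_model(cfg)
    o1 <- mil_forward(m, bag)
    o2 <- mil_forward(m, bag_p)
    expect_equal(o1$logits, o2$logits, tolerance = 1e-10)
    for (k in seq_along(o1$score_sets)) {
      expect_equal(o1$score_sets[[k]]$scores[perm], o2$score_sets[[k]]$scores,
                   tolerance = 1e-10)
    }
  }
})

test_that("score channels respect their ranges", {
  set.seed(14)
  bag <- toy_bag(matrix(rnorm(9 * 10), 9, 10))
  for (arch in setdiff(milrel:::MIL_ARCHS, "mean_pool")) {
    cfg <- model_config(arch, input_dim = 10L, embed_dim = 6L, attn_dim = 4L,
                        heads = 2L, pseudo_bags = 4L,
                        additive = arch %in% c("abmil", "madmil"), seed = 15L)
    out <- mil_forward(build_model(cfg), bag)
    expect_gte(length(out$score_sets), 1L)
    for (ss in out$score_sets) {
      if (ss$channel == "attention") {
        expect_equal(sum(ss$scores), 1, tolerance = 1e-6)
        expect_true(all(ss$scores >= 0))
      } else {
        expect_true(all(ss$scores >= 0 & ss$scores <= 1))
      }
    }
  }
  # mean pooling emits no score sets
  out <- mil_forward(build_model(model_config("mean_pool", input_dim = 10L,
                                              embed_dim = 6L)), bag)
  expect_length(out$score_sets, 0L)
})

test_that("singleton bags are handled by every aggregator", {
  bag <- toy_bag(matrix(rnorm(10), 1, 10))
  for (arch in setdiff(milrel:::MIL_ARCHS, "mean_pool")) {
    cfg <- model_config(arch, input_dim = 10L, embed_dim = 6L, attn_dim = 4L,
                        heads = 2L, pseudo_bags = 2L, seed = 16L)
    out <- mil_forward(build_model(cfg), bag)
    att <- Filter(function(s) s$channel == "attention", out$score_sets)
    for (ss in att) expect_equal(ss$scores, 1)
  }
})

test_that("training gradients agree with finite differences", {
  set.seed(17)
  X <- matrix(rnorm(8 * 10), 8, 10)
  get_leaf <- function(p, path) { for (k in path) p <- p[[k]]; p }
  set_scalar <- function(p, path, i, v) {
    leaf <- get_leaf(p, path); leaf[i] <- v
    expr <- p
    assign_rec <- function(p, path, val) {
      if (!length(path)) return(val)
      p[[path[1]]] <- assign_rec(p[[path[1]]], path[-1], val)
      p
    }
    assign_rec(p, path, leaf)
  }
  for (arch in c("mean_pool_ins", "abmil", "clam_lite", "madmil", "dtfd",
                 "acmil_lite")) {
    cfg <- model_config(arch, n_classes = 2L, input_dim = 10L, embed_dim = 6L,
                        attn_dim = 4L, heads = 2L, pseudo_bags = 3L,
                        instance_k = 2L, seed = 18L)
    m <- build_model(cfg)
    set.seed(19)
    lg <- milrel:::mil_loss_grads(m, X, 1L)
    # probe a few scalar coordinates spread over the parameter tree
    paths <- list(c("comp", "W"), c("comp", "b"))
    if (!is.null(m$params$cls)) paths <- c(paths, list(c("cls", "W")))
    if (!is.null(m$params$cls2)) paths <- c(paths, list(c("cls2", "W")))
    if (!is.null(m$params$att) && !is.null(m$params$att$V))
      paths <- c(paths, list(c("att", "V")))
    if (!is.null(m$params$att1)) paths <- c(paths, list(c("att1", "V")))
    eps <- 1e-6
    for (pth in paths) {
      i <- length(get_leaf(m$params, pth)) %/% 2L + 1L
      g <- get_leaf(lg$grads, pth)[i]
      v0 <- get_leaf(m$params, pth)[i]
      m2 <- m
      m2$params <- set_scalar(m$params, pth, i, v0 + eps)
      set.seed(19); up <- milrel:::mil_loss_grads(m2, X, 1L)$loss
      m2$params <- set_scalar(m$params, pth, i, v0 - eps)
      set.seed(19); dn <- milrel:::mil_loss_grads(m2, X, 1L)$loss
      expect_equal(g, (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})
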