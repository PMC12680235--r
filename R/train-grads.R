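# Analytic loss gradients for each aggregator (one bag per step). Returns
# the total training loss (cross-entropy plus any architecture-specific
# auxiliary terms), the bag logits, and a gradient tree mirroring
# model$params. The dtfd pseudo-bag partition is drawn from the current RNG
# stream, so training is deterministic under a fixed seed.

mil_loss_grads <- function(model, X, y) {
  cfg <- model$cfg; p <- model$params
  n <- nrow(X)
  Z0 <- lin_fwd(X, p$comp)
  H <- pmax(Z0, 0)
  D <- cfg$embed_dim

  finish <- function(loss, logits, dH, extra_grads = list()) {
    dZ0 <- dH * (Z0 > 0)
    grads <- c(list(comp = list(W = crossprod(X, dZ0), b = colSums(dZ0))),
               extra_grads)
    list(loss = loss, logits = logits, grads = grads)
  }

  if (cfg$arch == "mean_pool") {
    m <- colMeans(H)
    logits <- drop(crossprod(m, p$cls$W)) + p$cls$b
    ce <- ce_loss(logits, y)
    dm <- drop(p$cls$W %*% ce$dlogits)
    dH <- matrix(dm, n, D, byrow = TRUE) / n
    return(finish(ce$loss, logits, dH,
                  list(cls = list(W = outer(m, ce$dlogits), b = ce$dlogits))))
  }

  if (cfg$arch == "max_pool") {
    idx <- max.col(t(H), ties.method = "first")
    m <- H[cbind(idx, seq_len(D))]
    logits <- drop(crossprod(m, p$cls$W)) + p$cls$b
    ce <- ce_loss(logits, y)
    dm <- drop(p$cls$W %*% ce$dlogits)
    dH <- matrix(0, n, D)
    dH[cbind(idx, seq_len(D))] <- dm
    return(finish(ce$loss, logits, dH,
                  list(cls = list(W = outer(m, ce$dlogits), b = ce$dlogits))))
  }

  if (cfg$arch == "mean_pool_ins") {
    L <- lin_fwd(H, p$cls)
    P <- softmax_rows(L)
    pbar <- colMeans(P)
    loss <- -log(max(pbar[y + 1L], 1e-12))
    logits <- log(pmax(pbar, 1e-12))
    dpbar <- numeric(cfg$n_classes)
    dpbar[y + 1L] <- -1 / max(pbar[y + 1L], 1e-12)
    dP <- matrix(dpbar, n, cfg$n_classes, byrow = TRUE) / n
    dL <- P * (dP - rowSums(dP * P))
    return(finish(loss, logits, dL %*% t(p$cls$W),
                  list(cls = list(W = crossprod(H, dL), b = colSums(dL)))))
  }

  if (cfg$arch == "max_pool_ins") {
    L <- lin_fwd(H, p$cls)
    idx <- max.col(t(L), ties.method = "first")
    logits <- L[cbind(idx, seq_len(cfg$n_classes))]
    ce <- ce_loss(logits, y)
    dL <- matrix(0, n, cfg$n_classes)
    dL[cbind(idx, seq_len(cfg$n_classes))] <- ce$dlogits
    return(finish(ce$loss, logits, dL %*% t(p$cls$W),
                  list(cls = list(W = crossprod(H, dL), b = colSums(dL)))))
  }

  if (cfg$arch %in% c("abmil", "clam_lite")) {
    fw <- gatt_fwd(H, p$att)
    a <- fw$a
    m <- drop(a %*% H)
    logits <- drop(crossprod(m, p$cls$W)) + p$cls$b
    ce <- ce_loss(logits, y)
    dm <- drop(p$cls$W %*% ce$dlogits)
    da <- drop(H %*% dm)
    bw <- gatt_bwd(da, H, p$att, fw)
    dH <- outer(a, dm) + bw$dH
    loss <- ce$loss
    extra <- list(att = bw$grads,
                  cls = list(W = outer(m, ce$dlogits), b = ce$dlogits))
    if (cfg$arch == "clam_lite") {
      k <- max(1L, min(cfg$instance_k, n %/% 2L))
      ord <- order(a, decreasing = TRUE)
      sel <- ord[seq_len(k)]
      tgt <- rep(y, k)
      if (cfg$n_classes == 2L) {   # bottom-k get the complementary class
        sel <- c(sel, ord[seq.int(n, by = -1L, length.out = k)])
        tgt <- c(tgt, rep(1L - y, k))
      }
      head <- p$inst[[y + 1L]]
      Lh <- lin_fwd(H[sel, , drop = FALSE], head)
      Ph <- softmax_rows(Lh)
      ll <- -mean(log(pmax(Ph[cbind(seq_along(sel), tgt + 1L)], 1e-12)))
      loss <- loss + cfg$instance_loss_weight * ll
      dLh <- Ph
      dLh[cbind(seq_along(sel), tgt + 1L)] <-
        dLh[cbind(seq_along(sel), tgt + 1L)] - 1
      dLh <- dLh * (cfg$instance_loss_weight / length(sel))
      dH[sel, ] <- dH[sel, , drop = FALSE] + dLh %*% t(head$W)
      inst_g <- lapply(seq_len(cfg$n_classes), function(i)
        list(W = head$W * 0, b = head$b * 0))
      inst_g[[y + 1L]] <- list(W = crossprod(H[sel, , drop = FALSE], dLh),
                               b = colSums(dLh))
      extra$inst <- inst_g
    }
    return(finish(loss, logits, dH, extra))
  }

  if (cfg$arch == "madmil") {
    cols <- head_cols(D, cfg$heads)
    fws <- vector("list", cfg$heads)
    m <- numeric(D)
    for (h in seq_len(cfg$heads)) {
      Hh <- H[, cols[[h]], drop = FALSE]
      fws[[h]] <- gatt_fwd(Hh, p$att_heads[[h]])
      m[cols[[h]]] <- drop(fws[[h]]$a %*% Hh)
    }
    logits <- drop(crossprod(m, p$cls$W)) + p$cls$b
    ce <- ce_loss(logits, y)
    dm <- drop(p$cls$W %*% ce$dlogits)
    dH <- matrix(0, n, D)
    att_g <- vector("list", cfg$heads)
    for (h in seq_len(cfg$heads)) {
      Hh <- H[, cols[[h]], drop = FALSE]
      dmh <- dm[cols[[h]]]
      da <- drop(Hh %*% dmh)
      bwh <- gatt_bwd(da, Hh, p$att_heads[[h]], fws[[h]])
      dH[, cols[[h]]] <- outer(fws[[h]]$a, dmh) + bwh$dH
      att_g[[h]] <- bwh$grads
    }
    return(finish(ce$loss, logits, dH,
                  list(att_heads = att_g,
                       cls = list(W = outer(m, ce$dlogits), b = ce$dlogits))))
  }

  if (cfg$arch == "acmil_lite") {
    Zt <- sweep(H %*% p$att$V, 2L, p$att$bv, "+")
    Zs <- sweep(H %*% p$att$U, 2L, p$att$bu, "+")
    Tt <- tanh(Zt); S <- stats::plogis(Zs)
    G <- Tt * S
    Hh <- cfg$heads
    A <- vapply(p$branch, function(br)
      softmax_vec(drop(G %*% br$w) + br$bw), numeric(n))
    A <- matrix(A, n, Hh)
    abar <- rowMeans(A)
    m <- drop(abar %*% H)
    logits <- drop(crossprod(m, p$cls$W)) + p$cls$b
    ce <- ce_loss(logits, y)
    dm <- drop(p$cls$W %*% ce$dlogits)
    dA <- matrix(drop(H %*% dm), n, Hh) / Hh   # through abar
    dH <- outer(abar, dm)
    loss <- ce$loss
    # branch-diversity penalty: mean pairwise cosine of attention vectors
    if (Hh > 1L && cfg$diversity_weight > 0) {
      nrm <- sqrt(colSums(A^2))
      npairs <- Hh * (Hh - 1L) / 2
      for (h1 in seq_len(Hh - 1L)) {
        for (h2 in seq.int(h1 + 1L, Hh)) {
          u <- A[, h1]; v <- A[, h2]
          cs <- sum(u * v) / (nrm[h1] * nrm[h2])
          loss <- loss + cfg$diversity_weight * cs / npairs
          wpair <- cfg$diversity_weight / npairs
          dA[, h1] <- dA[, h1] +
            wpair * (v / (nrm[h1] * nrm[h2]) - cs * u / nrm[h1]^2)
          dA[, h2] <- dA[, h2] +
            wpair * (u / (nrm[h1] * nrm[h2]) - cs * v / nrm[h2]^2)
        }
      }
    }
    dG <- matrix(0, n, ncol(G))
    br_g <- vector("list", Hh)
    for (h in seq_len(Hh)) {
      a <- A[, h]; da <- dA[, h]
      de <- a * (da - sum(da * a))
      dG <- dG + outer(de, p$branch[[h]]$w)
      br_g[[h]] <- list(w = drop(crossprod(G, de)), bw = sum(de))
    }
    dZt <- dG * S * (1 - Tt^2)
    dZs <- dG * Tt * S * (1 - S)
    dH <- dH + dZt %*% t(p$att$V) + dZs %*% t(p$att$U)
    att_g <- list(V = crossprod(H, dZt), bv = colSums(dZt),
                  U = crossprod(H, dZs), bu = colSums(dZs))
    return(finish(loss, logits, dH,
                  list(att = att_g, branch = br_g,
                       cls = list(W = outer(m, ce$dlogits), b = ce$dlogits))))
  }

  if (cfg$arch == "dtfd") {
    m_eff <- min(cfg$pseudo_bags, n)
    g <- sample(rep_len(seq_len(m_eff), n))   # random pseudo-bag partition
    Fm <- matrix(0, m_eff, D)
    fws <- vector("list", m_eff)
    idxs <- split(seq_len(n), g)
    for (b in seq_len(m_eff)) {
      Hb <- H[idxs[[b]], , drop = FALSE]
      fws[[b]] <- gatt_fwd(Hb, p$att1)
      Fm[b, ] <- drop(fws[[b]]$a %*% Hb)
    }
    L1 <- lin_fwd(Fm, p$cls1)                 # tier-1 pseudo-bag logits
    P1 <- softmax_rows(L1)
    loss1 <- -mean(log(pmax(P1[, y + 1L], 1e-12)))
    fw2 <- gatt_fwd(Fm, p$att2)
    gvec <- drop(fw2$a %*% Fm)
    logits <- drop(crossprod(gvec, p$cls2$W)) + p$cls2$b
    ce <- ce_loss(logits, y)
    loss <- loss1 + ce$loss

    dgvec <- drop(p$cls2$W %*% ce$dlogits)
    da2 <- drop(Fm %*% dgvec)
    bw2 <- gatt_bwd(da2, Fm, p$att2, fw2)
    dF <- outer(fw2$a, dgvec) + bw2$dH
    dL1 <- P1
    dL1[, y + 1L] <- dL1[, y + 1L] - 1
    dL1 <- dL1 / m_eff
    dF <- dF + dL1 %*% t(p$cls1$W)

    dH <- matrix(0, n, D)
    att1_g <- NULL
    for (b in seq_len(m_eff)) {
      idx <- idxs[[b]]
      Hb <- H[idx, , drop = FALSE]
      df <- dF[b, ]
      da <- drop(Hb %*% df)
      bwb <- gatt_bwd(da, Hb, p$att1, fws[[b]])
      dH[idx, ] <- outer(fws[[b]]$a, df) + bwb$dH
      att1_g <- tree_add(att1_g, bwb$grads)
    }
    return(finish(loss, logits, dH,
                  list(att1 = att1_g,
                       cls1 = list(W = crossprod(Fm, dL1), b = colSums(dL1)),
                       att2 = bw2$grads,
                       cls2 = list(W = outer(gvec, ce$dlogits), b = ce$dlogits))))
  }
  stop("mil_loss_grads: unhandled architecture ", cfg$arch)
}
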