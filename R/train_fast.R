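# Batched training kernels.
#
# With one attention layer and readout at the 900 bp (or 90-mer) level,
# only the readout nodes' neighborhoods influence the loss, and for the
# two-layer GCN variant only the readout nodes' two-hop neighborhoods do.
# The trainers below therefore precompute per-record "views" restricted to
# those neighborhoods and run each Adam step as a handful of large matrix
# operations over the whole minibatch instead of per-graph passes. The
# mathematics is identical to the full-graph update; only dead computation
# is skipped.

# --- attention (one layer) -------------------------------------------------

build_gsa_views <- function(bundles, d) {
  nrec <- length(bundles)
  Hq <- vector("list", nrec); Hk <- vector("list", nrec)
  si <- vector("list", nrec); di <- vector("list", nrec)
  rel <- vector("list", nrec); slots <- vector("list", nrec)
  xconst <- matrix(0, nrec, READOUT_SLOTS * d)
  for (r in seq_len(nrec)) {
    ar <- bundles[[r]]
    ro <- ar$ro_rows
    inro <- logical(ar$na); inro[ro] <- TRUE
    keep <- inro[ar$src]
    vsrc <- ar$src[keep]; vdst <- ar$dst[keep]
    si_l <- match(vsrc, ro)
    uk <- unique(vdst)
    Hq[[r]] <- ar$H[ro, , drop = FALSE]
    Hk[[r]] <- ar$H[uk, , drop = FALSE]
    si[[r]] <- si_l
    di[[r]] <- match(vdst, uk)
    rel[[r]] <- ar$rel_row[keep]
    slots[[r]] <- ar$ro_slots
    # readout nodes without neighbors keep their input representation
    lonely <- setdiff(seq_along(ro), unique(si_l))
    for (t in lonely) {
      xconst[r, ((ar$ro_slots[t] - 1L) * d + 1L):(ar$ro_slots[t] * d)] <-
        ar$H[ro[t], ]
    }
  }
  list(Hq = Hq, Hk = Hk, si = si, di = di, rel = rel, slots = slots,
       xconst = xconst,
       nq = vapply(Hq, nrow, integer(1)),
       nk = vapply(Hk, nrow, integer(1)),
       ne = lengths(si))
}

# Assemble the concatenated arrays for one minibatch of records.
gather_gsa_batch <- function(vw, idx) {
  b <- length(idx)
  nq <- vw$nq[idx]; nk <- vw$nk[idx]; ne <- vw$ne[idx]
  qoff <- cumsum(c(0L, nq[-b]))
  koff <- cumsum(c(0L, nk[-b]))
  list(
    Hq = do.call(rbind, vw$Hq[idx]),
    Hk = do.call(rbind, vw$Hk[idx]),
    si = unlist(vw$si[idx], use.names = FALSE) + rep(qoff, ne),
    di = unlist(vw$di[idx], use.names = FALSE) + rep(koff, ne),
    rel = unlist(vw$rel[idx], use.names = FALSE),
    q_rec = rep(seq_len(b), nq),
    q_slot = unlist(vw$slots[idx], use.names = FALSE),
    nqb = sum(nq)
  )
}

# Linear indices of the readout slots inside the b x (10 d) design matrix.
slot_linear_index <- function(q_rec, q_slot, b, d) {
  nqb <- length(q_rec)
  matrix(q_rec, nqb, d) +
    b * (matrix((q_slot - 1L) * d, nqb, d) +
           matrix(0:(d - 1L), nqb, d, byrow = TRUE))
}

# Forward: attention over every readout node of the batch at once.
gsa_fast_forward <- function(gb, params, use_relpos) {
  d <- params$d; dh <- params$dh
  sc <- sqrt(params$d_scale %||% d)
  ho <- matrix(0, gb$nqb, d)
  alphas <- vector("list", params$heads)
  Qs <- vector("list", params$heads)
  Ks <- vector("list", params$heads)
  Vs <- vector("list", params$heads)
  for (i in seq_len(params$heads)) {
    cols <- head_cols(i, dh)
    Q <- gb$Hq %*% params$Wq[, cols, drop = FALSE]
    K <- gb$Hk %*% params$Wk[, cols, drop = FALSE]
    V <- gb$Hk %*% params$Wv[, cols, drop = FALSE]
    kk <- K[gb$di, , drop = FALSE]
    if (use_relpos) kk <- kk + params$R[gb$rel, cols, drop = FALSE]
    lg <- rowSums(Q[gb$si, , drop = FALSE] * kk) / sc
    alpha <- grouped_softmax(lg, gb$si, gb$nqb)
    ho[, cols] <- rowsum_mat(V[gb$di, , drop = FALSE] * alpha, gb$si,
                             gb$nqb)
    alphas[[i]] <- alpha
    Qs[[i]] <- Q; Ks[[i]] <- K; Vs[[i]] <- V
  }
  list(U = ho %*% params$Wo, ho = ho, alphas = alphas,
       Qs = Qs, Ks = Ks, Vs = Vs)
}

# Backward: parameter gradients only (node features are fixed inputs).
gsa_fast_backward <- function(dU, fw, gb, params, use_relpos) {
  d <- params$d; dh <- params$dh
  sc <- sqrt(params$d_scale %||% d)
  grads <- list(Wq = params$Wq * 0, Wk = params$Wk * 0,
                Wv = params$Wv * 0, Wo = t(fw$ho) %*% dU,
                R = params$R * 0)
  dho <- dU %*% t(params$Wo)
  for (i in seq_len(params$heads)) {
    cols <- head_cols(i, dh)
    alpha <- fw$alphas[[i]]
    Q <- fw$Qs[[i]]; K <- fw$Ks[[i]]; V <- fw$Vs[[i]]
    dho_e <- dho[gb$si, cols, drop = FALSE]
    vd <- V[gb$di, , drop = FALSE]
    dalpha <- rowSums(dho_e * vd)
    dV <- rowsum_mat(dho_e * alpha, gb$di, nrow(gb$Hk))
    s <- rowsum_vec(alpha * dalpha, gb$si, gb$nqb)
    dlg <- alpha * (dalpha - s[gb$si]) / sc
    kk <- K[gb$di, , drop = FALSE]
    if (use_relpos) kk <- kk + params$R[gb$rel, cols, drop = FALSE]
    qs <- Q[gb$si, , drop = FALSE]
    dQ <- rowsum_mat(kk * dlg, gb$si, gb$nqb)
    dK <- rowsum_mat(qs * dlg, gb$di, nrow(gb$Hk))
    if (use_relpos) {
      grads$R[, cols] <- rowsum_mat(qs * dlg, gb$rel, nrow(params$R))
    }
    grads$Wq[, cols] <- t(gb$Hq) %*% dQ
    grads$Wk[, cols] <- t(gb$Hk) %*% dK
    grads$Wv[, cols] <- t(gb$Hk) %*% dV
  }
  grads
}

# --- plain GCN variant -----------------------------------------------------

# Two-hop view of one record for the GCN variant, built directly from the
# edge arrays: symmetric unweighted adjacency with self-loops, restricted
# to the readout nodes (rows) and their neighborhood (columns), plus the
# constant first propagation over that neighborhood.
build_gcn_view_one <- function(ar) {
  na <- ar$na
  key <- c(ar$src, ar$dst) * (na + 1) + c(ar$dst, ar$src)
  keep <- !duplicated(key)
  us <- c(ar$src, ar$dst)[keep]
  ud <- c(ar$dst, ar$src)[keep]
  deg <- tabulate(us, na) + 1
  ro <- ar$ro_rows
  inro <- logical(na); inro[ro] <- TRUE
  nb <- sort(unique(c(ro, ud[inro[us]])))
  nnb <- length(nb)
  # rows of the normalized adjacency at the readout nodes
  A <- matrix(0, length(ro), nnb)
  sel <- inro[us]
  ri <- match(us[sel], ro)
  ci <- match(ud[sel], nb)
  A[cbind(ri, ci)] <- 1 / sqrt(deg[us[sel]] * deg[ud[sel]])
  A[cbind(seq_along(ro), match(ro, nb))] <- 1 / deg[ro]
  # first propagation restricted to the neighborhood rows
  innb <- logical(na); innb[nb] <- TRUE
  seln <- innb[us]
  m1 <- rowsum_mat(ar$H[ud[seln], , drop = FALSE] /
                     sqrt(deg[us[seln]] * deg[ud[seln]]),
                   match(us[seln], nb), nnb)
  m1 <- m1 + ar$H[nb, , drop = FALSE] / deg[nb]
  list(M1 = m1, A = A, slots = ar$ro_slots, nnb = nnb)
}

build_gcn_views <- function(bundles) {
  lapply(bundles, build_gcn_view_one)
}

# Readout-level output of the GCN variant for one view.
gcn_view_output <- function(vw, gcnp) {
  z1 <- pmax(vw$M1 %*% gcnp$Wg1, 0)
  (vw$A %*% z1) %*% gcnp$Wg2
}

train_loop_gcn_fast <- function(views, y, wts, params, opt, cfg, d,
                                perm_seeds) {
  nrec <- length(views)
  yhot <- diag(2)[y, , drop = FALSE]
  trace <- numeric(0)
  nnb <- vapply(views, `[[`, integer(1), "nnb")
  M1_list <- lapply(views, `[[`, "M1")
  for (epoch in seq_len(cfg$epochs)) {
    withr::with_seed(perm_seeds[epoch], perm <- sample.int(nrec))
    ep_loss <- 0
    for (s in seq.int(1L, nrec, by = cfg$batch)) {
      idx <- perm[s:min(s + cfg$batch - 1L, nrec)]
      b <- length(idx)
      M1b <- do.call(rbind, M1_list[idx])
      off <- cumsum(c(0L, nnb[idx][-b]))
      z1 <- pmax(M1b %*% params$Wg1, 0)
      X <- matrix(0, b, READOUT_SLOTS * d)
      m2 <- vector("list", b)
      for (j in seq_len(b)) {
        vj <- views[[idx[j]]]
        rows <- off[j] + seq_len(vj$nnb)
        m2[[j]] <- vj$A %*% z1[rows, , drop = FALSE]
        U <- m2[[j]] %*% params$Wg2
        for (sl in seq_along(vj$slots)) {
          X[j, ((vj$slots[sl] - 1L) * d + 1L):(vj$slots[sl] * d)] <- U[sl, ]
        }
      }
      rp <- list(W1 = params$W1, b1 = params$b1, W2 = params$W2,
                 b2 = params$b2)
      fwro <- readout_forward(X, rp)
      st <- loss_and_dlogits(fwro$prob, y[idx], wts[idx], yhot[idx, ,
                                                               drop = FALSE])
      ep_loss <- ep_loss + st$loss * b
      grads <- readout_backward(st$dlogits, fwro, X, rp)
      dX <- grads$dX
      grads$dX <- NULL

      dz1 <- matrix(0, nrow(M1b), ncol(params$Wg1))
      dWg2 <- params$Wg2 * 0
      for (j in seq_len(b)) {
        vj <- views[[idx[j]]]
        nro <- length(vj$slots)
        dz2 <- matrix(0, nro, d)
        for (sl in seq_len(nro)) {
          dz2[sl, ] <- dX[j, ((vj$slots[sl] - 1L) * d + 1L):
                            (vj$slots[sl] * d)]
        }
        dWg2 <- dWg2 + t(m2[[j]]) %*% dz2
        rows <- off[j] + seq_len(vj$nnb)
        dz1[rows, ] <- t(vj$A) %*% (dz2 %*% t(params$Wg2))
      }
      dpre <- dz1 * (z1 > 0)
      grads$Wg1 <- t(M1b) %*% dpre
      grads$Wg2 <- dWg2
      upd <- adam_step(params, grads, opt, cfg$lr)
      params <- upd$params
      opt <- upd$state
    }
    trace <- c(trace, ep_loss / nrec)
  }
  list(params = params, trace = trace)
}

train_loop_gsa_fast <- function(views, y, wts, params, opt, cfg, d,
                                perm_seeds, gsa_template) {
  nrec <- length(views$nq)
  yhot <- diag(2)[y, , drop = FALSE]
  trace <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    withr::with_seed(perm_seeds[epoch], perm <- sample.int(nrec))
    ep_loss <- 0
    for (s in seq.int(1L, nrec, by = cfg$batch)) {
      idx <- perm[s:min(s + cfg$batch - 1L, nrec)]
      b <- length(idx)
      gb <- gather_gsa_batch(views, idx)
      gp <- gsa_template
      gp[c("Wq", "Wk", "Wv", "Wo", "R")] <-
        params[c("Wq", "Wk", "Wv", "Wo", "R")]
      fw <- gsa_fast_forward(gb, gp, cfg$use_relpos)
      lin <- slot_linear_index(gb$q_rec, gb$q_slot, b, d)
      X <- views$xconst[idx, , drop = FALSE]
      X[lin] <- fw$U
      rp <- list(W1 = params$W1, b1 = params$b1, W2 = params$W2,
                 b2 = params$b2)
      fwro <- readout_forward(X, rp)
      st <- loss_and_dlogits(fwro$prob, y[idx], wts[idx],
                             yhot[idx, , drop = FALSE])
      ep_loss <- ep_loss + st$loss * b
      grads <- readout_backward(st$dlogits, fwro, X, rp)
      dU <- matrix(grads$dX[lin], gb$nqb, d)
      grads$dX <- NULL
      grads <- c(grads, gsa_fast_backward(dU, fw, gb, gp, cfg$use_relpos))
      upd <- adam_step(params, grads, opt, cfg$lr)
      params <- upd$params
      opt <- upd$state
    }
    trace <- c(trace, ep_loss / nrec)
  }
  list(params = params, trace = trace)
}

# Weighted cross-entropy and its logit gradient.
loss_and_dlogits <- function(prob, y, w, yhot) {
  ce <- -log(pmax(prob[cbind(seq_along(y), y)], 1e-12))
  list(loss = sum(w * ce) / sum(w),
       dlogits = (prob - yhot) * (w / sum(w)))
}

# Readout head backward; returns W1/b1/W2/b2 gradients plus dX.
readout_backward <- function(dlogits, fwro, X, rp) {
  g <- list(W2 = t(fwro$hid) %*% dlogits, b2 = colSums(dlogits))
  dhid <- (dlogits %*% t(rp$W2)) * (fwro$hid > 0)
  g$W1 <- t(X) %*% dhid
  g$b1 <- colSums(dhid)
  g$dX <- dhid %*% t(rp$W1)
  g
}

# --- generic (stacked layers / residual) -----------------------------------

# Per-graph full backprop through an arbitrary attention stack. Slower than
# the batched single-layer path; used when layers > 1 or residual updates
# are configured.
train_loop_gsa_generic <- function(bundles, y, wts, params, opt, cfg, d,
                                   perm_seeds, gsa_template) {
  nrec <- length(bundles)
  yhot <- diag(2)[y, , drop = FALSE]
  trace <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    withr::with_seed(perm_seeds[epoch], perm <- sample.int(nrec))
    ep_loss <- 0
    for (s in seq.int(1L, nrec, by = cfg$batch)) {
      idx <- perm[s:min(s + cfg$batch - 1L, nrec)]
      b <- length(idx)
      X <- matrix(0, b, READOUT_SLOTS * d)
      caches <- vector("list", b)
      gp <- gsa_template
      gp[c("Wq", "Wk", "Wv", "Wo", "R")] <-
        params[c("Wq", "Wk", "Wv", "Wo", "R")]
      for (j in seq_len(b)) {
        ar <- bundles[[idx[j]]]
        H <- ar$H
        lcache <- vector("list", cfg$layers)
        for (l in seq_len(cfg$layers)) {
          aq <- if (l == cfg$layers) ar$ro_rows else NULL
          fw <- attend_forward(H, ar$src, ar$dst, ar$rel_row, gp,
                               use_relpos = cfg$use_relpos, active_q = aq)
          lcache[[l]] <- fw$cache
          H <- if (cfg$residual) H + fw$U else fw$U
        }
        caches[[j]] <- lcache
        X[j, ] <- readout_concat(H, ar$ro_rows, ar$ro_slots, d)
      }
      rp <- list(W1 = params$W1, b1 = params$b1, W2 = params$W2,
                 b2 = params$b2)
      fwro <- readout_forward(X, rp)
      st <- loss_and_dlogits(fwro$prob, y[idx], wts[idx],
                             yhot[idx, , drop = FALSE])
      ep_loss <- ep_loss + st$loss * b
      grads <- readout_backward(st$dlogits, fwro, X, rp)
      dX <- grads$dX
      grads$dX <- NULL

      acc <- list(Wq = params$Wq * 0, Wk = params$Wk * 0,
                  Wv = params$Wv * 0, Wo = params$Wo * 0, R = params$R * 0)
      for (j in seq_len(b)) {
        ar <- bundles[[idx[j]]]
        dU <- matrix(0, ar$na, d)
        for (sl in seq_along(ar$ro_rows)) {
          cols <- ((ar$ro_slots[sl] - 1L) * d + 1L):(ar$ro_slots[sl] * d)
          dU[ar$ro_rows[sl], ] <- dX[j, cols]
        }
        for (l in rev(seq_len(cfg$layers))) {
          bw <- attend_backward(dU, caches[[j]][[l]], gp)
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + bw$grads[[nm]]
          dU <- if (cfg$residual) dU + bw$dH else bw$dH
        }
      }
      grads <- c(grads, acc)
      upd <- adam_step(params, grads, opt, cfg$lr)
      params <- upd$params
      opt <- upd$state
    }
    trace <- c(trace, ep_loss / nrec)
  }
  list(params = params, trace = trace)
}
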