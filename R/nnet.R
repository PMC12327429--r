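# Compact convolutional network for PRP classification, implemented with
# Toeplitz/block-diagonal matmul convolutions and hand-written
# backpropagation.
#
# Architecture (EEGNet-8,2 shape): temporal convolution (8 filters,
# kernel length fs/2, same padding) -> depthwise spatial filtering
# across electrodes (2 filters per temporal filter, max-norm <= 1) ->
# ELU -> average pool -> dropout -> separable convolution (depthwise
# temporal kernel + pointwise mixing) -> ELU -> average pool -> dropout
# -> dense soft-max. Convolutions carry no bias; one per-channel bias is
# applied after the spatial stage and one after the pointwise stage.
# The same backward pass drives both training gradients and
# reference-based attribution (the two differ only in the elementwise
# multiplier used at the two ELU stages), which is what makes the
# completeness axiom of the attribution exact here.

elu <- function(z) {
  neg <- z < 0
  z[neg] <- expm1(z[neg])
  z
}

elu_grad <- function(z) {
  pos <- z > 0
  z[!pos] <- exp(z[!pos])
  z[pos] <- 1
  z
}

# Index bookkeeping for a 'same'-padding Toeplitz convolution of kernel
# length k on signals of length len: out[t] = sum_k w[k] x[t + k - ctr].
toeplitz_index <- function(len, k) {
  ctr <- floor(k / 2)
  tt <- rep(seq_len(len), each = k)
  kk <- rep(seq_len(k), len)
  row <- tt + kk - ctr - 1L
  ok <- row >= 1L & row <= len
  list(len = len, k = k,
       pos0 = row[ok] + (tt[ok] - 1L) * len,  # linear index, len x len block
       kidx = kk[ok])
}

# Gather indices for nf stacked blocks of the same Toeplitz pattern:
# fill positions into a len x (len*nf) matrix, and the grouping that
# accumulates the kernel gradient back out of it. The gather is stored
# sorted by group so the gradient accumulation is a cumsum pass.
toeplitz_multi <- function(ti, nf) {
  np <- length(ti$pos0)
  fill <- rep(ti$pos0, nf) + rep((seq_len(nf) - 1L) * ti$len^2, each = np)
  grp <- rep(ti$kidx, nf) + rep((seq_len(nf) - 1L) * ti$k, each = np)
  stopifnot(length(unique(grp)) == nf * ti$k)   # every kernel tap reachable
  ord <- order(grp)
  ends <- cumsum(tabulate(grp, nbins = nf * ti$k))
  list(np = np, fill = fill, grp = grp, k = ti$k, nf = nf, len = ti$len,
       fill_sorted = fill[ord], grp_ends = ends)
}

# Sum vals (already gathered through fill_sorted) within each group.
grouped_sums <- function(vals, ends) {
  cs <- cumsum(vals)
  cs[ends] - c(0, cs[ends[-length(ends)]])
}

pool_matrix <- function(len, p) {
  nout <- floor(len / p)
  out <- matrix(0, len, nout)
  for (j in seq_len(nout)) out[((j - 1) * p + 1):(j * p), j] <- 1 / p
  out
}

#' Classifier specification
#'
#' Hyperparameters of the compact convolutional PRP classifier and its
#' cross-validation protocol. Defaults follow the published compact
#' EEG-classifier recipe: 8 temporal filters, 2 spatial filters per
#' temporal filter, dropout 0.5, Adam at initial learning rate 0.001
#' decayed by a factor 0.7 every 100 epochs, batch size 16, at most 300
#' epochs with the checkpoint at the lowest validation loss, 20-fold
#' cross-validation (5% test folds) and a random 15% of the non-test
#' data as the validation set.
#'
#' @param n_temporal,spatial_per_temporal,f2 filter counts (temporal,
#'   depthwise-per-temporal, separable).
#' @param dropout dropout probability after each pooling stage.
#' @param lr,lr_decay,decay_every,max_epochs,batch_size optimizer
#'   schedule.
#' @param patience stop early after this many epochs without validation
#'   improvement (Inf reproduces the fixed-epoch protocol).
#' @param min_epochs never stop before this many epochs.
#' @param folds number of cross-validation folds (test fraction 1/folds).
#' @param val_fraction fraction of non-test data used for validation.
#' @param kernel1_frac temporal kernel length as a fraction of fs.
#' @param kernel2,pool1,pool2 separable kernel length and pooling widths.
#' @return object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(n_temporal = 8, spatial_per_temporal = 2,
                            f2 = 16, dropout = 0.5, lr = 0.001,
                            lr_decay = 0.7, decay_every = 100,
                            max_epochs = 300, batch_size = 16,
                            patience = Inf, min_epochs = 0, folds = 20,
                            val_fraction = 0.15, kernel1_frac = 0.5,
                            kernel2 = 16, pool1 = 4, pool2 = 8) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stopf("val_fraction must be in (0, 1)")
  if (folds < 2) stopf("folds must be >= 2")
  out <- as.list(environment())
  class(out) <- "classifier_spec"
  out
}

#' Reduced-cost classifier specification for desk-scale cohorts
#'
#' Same architecture as \code{\link{classifier_spec}} with a shorter
#' training schedule and 4-fold
#' cross-validation, sized for the default 12-phoneme, 16-electrode
#' synthetic cohorts. Training stops once the validation loss has not
#' improved for 12 epochs (after at least 50).
#' @export
desk_classifier_spec <- function() {
  classifier_spec(max_epochs = 200, patience = 12, min_epochs = 50,
                  folds = 4)
}

net_init <- function(E, Tn, K, fs, spec, seed) {
  F1 <- spec$n_temporal
  D <- spec$spatial_per_temporal
  C1 <- F1 * D
  F2 <- spec$f2
  K1 <- min(Tn, max(2L, round(spec$kernel1_frac * fs)))
  p1 <- min(spec$pool1, Tn)
  T1 <- max(1L, floor(Tn / p1))
  K2 <- min(spec$kernel2, T1)
  p2 <- min(spec$pool2, T1)
  T2 <- max(1L, floor(T1 / p2))
  params <- with_seed(seed, {
    gl <- function(n_in, n_out, dims) {
      array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (n_in + n_out)), dims)
    }
    list(W1 = gl(K1, 1, c(K1, F1)),
         S  = gl(E, 1, c(D, E, F1)),
         b1 = numeric(C1),
         W3 = gl(K2, 1, c(K2, C1)),
         W4 = gl(C1, F2, c(C1, F2)),
         b4 = numeric(F2),
         W5 = gl(F2 * T2, K, c(F2 * T2, K)),
         b5 = numeric(K))
  })
  # Block-diagonal fill indices for the depthwise spatial stage:
  # Sblock[(d,f), (e,f)] = S[d,e,f].
  dd <- rep(seq_len(D), E * F1)
  ee <- rep(rep(seq_len(E), each = D), F1)
  ff <- rep(seq_len(F1), each = D * E)
  s_fill <- (dd + (ff - 1L) * D) + ((ee + (ff - 1L) * E) - 1L) * C1
  # Block-diagonal fill for the depthwise temporal stage:
  # Mbig[(c,t1), (c,t2)] = W3[k, c] per the Toeplitz pattern.
  ti3 <- toeplitz_index(T1, K2)
  np3 <- length(ti3$pos0)
  t1i <- ((ti3$pos0 - 1L) %% T1) + 1L
  t2i <- ((ti3$pos0 - 1L) %/% T1) + 1L
  cc <- rep(seq_len(C1), each = np3)
  m_fill <- (cc + (rep(t1i, C1) - 1L) * C1) +
    ((cc + (rep(t2i, C1) - 1L) * C1) - 1L) * (C1 * T1)
  m_val <- rep(ti3$kidx, C1) + (cc - 1L) * K2   # index into W3 (K2 x C1)
  m_ord <- order(m_val)
  m_ends <- cumsum(tabulate(m_val, nbins = K2 * C1))
  # gather indices for the compiled spatial-first evaluation order:
  # Sstack[(d,f), e] = S[d,e,f]
  dd2 <- rep(seq_len(D), E * F1)
  ee2 <- rep(rep(seq_len(E), each = D), F1)
  ff2 <- rep(seq_len(F1), each = D * E)
  list(params = params,
       dims = list(E = E, Tn = Tn, K = K, F1 = F1, D = D, C1 = C1,
                   F2 = F2, K1 = K1, K2 = K2, T1 = T1, T2 = T2,
                   Pflat = F2 * T2),
       tm1 = toeplitz_multi(toeplitz_index(Tn, K1), F1),
       tm1s = toeplitz_multi(toeplitz_index(Tn, K1), 1L),
       s2_lin = (dd2 + (ff2 - 1L) * D) + (ee2 - 1L) * C1,
       s_fill = s_fill,
       m_fill = m_fill, m_val = m_val,
       m_fill_sorted = m_fill[m_ord], m_ends = m_ends,
       pool1 = pool_matrix(Tn, p1),
       pool2 = pool_matrix(T1, p2),
       fs = fs, spec = spec)
}

# Forward pass. X: B x E x T array. Returns logits, probs and the cache
# needed for the backward pass. Dropout masks (inverted dropout) are
# supplied by the caller during training; NULL disables dropout.
net_forward <- function(model, X, masks = NULL) {
  d <- model$dims
  p <- model$params
  B <- dim(X)[1]
  M0 <- X
  dim(M0) <- c(B * d$E, d$Tn)
  tm <- model$tm1
  W1mat <- matrix(0, d$Tn, d$Tn * d$F1)
  W1mat[tm$fill] <- p$W1[tm$grp]
  Z1 <- M0 %*% W1mat                              # (B*E) x (Tn*F1)
  dim(Z1) <- c(B, d$E, d$Tn, d$F1)
  M1 <- aperm(Z1, c(2, 4, 1, 3))                  # E, F1, B, Tn
  dim(M1) <- c(d$E * d$F1, B * d$Tn)
  Sblock <- matrix(0, d$C1, d$E * d$F1)
  Sblock[model$s_fill] <- p$S
  Z2 <- Sblock %*% M1                             # C1 x (B*Tn)
  dim(Z2) <- c(d$C1, B, d$Tn)
  Zb <- aperm(Z2, c(2, 1, 3))                     # B, C1, Tn
  Zb <- Zb + rep(p$b1, each = B)                  # recycles over Tn
  ZbM <- Zb
  dim(ZbM) <- c(B * d$C1, d$Tn)
  A3 <- elu(ZbM)
  P1 <- A3 %*% model$pool1                        # (B*C1) x T1
  if (!is.null(masks)) P1 <- P1 * masks$m1
  A4 <- P1
  dim(A4) <- c(B, d$C1 * d$T1)
  Mbig <- matrix(0, d$C1 * d$T1, d$C1 * d$T1)
  Mbig[model$m_fill] <- p$W3[model$m_val]
  Z4 <- A4 %*% Mbig                               # B x (C1*T1)
  dim(Z4) <- c(B, d$C1, d$T1)
  M4 <- aperm(Z4, c(1, 3, 2))                     # B, T1, C1
  dim(M4) <- c(B * d$T1, d$C1)
  Z5 <- M4 %*% p$W4
  Z5 <- sweep(Z5, 2, p$b4, `+`)                   # (B*T1) x F2
  A5 <- elu(Z5)
  dim(A5) <- c(B, d$T1, d$F2)
  P2in <- aperm(A5, c(1, 3, 2))                   # B, F2, T1
  dim(P2in) <- c(B * d$F2, d$T1)
  P2 <- P2in %*% model$pool2                      # (B*F2) x T2
  if (!is.null(masks)) P2 <- P2 * masks$m2
  Xf <- P2
  dim(Xf) <- c(B, d$Pflat)
  logits <- sweep(Xf %*% p$W5, 2, p$b5, `+`)
  pr <- exp(logits - apply(logits, 1, max))
  probs <- pr / rowSums(pr)
  list(logits = logits, probs = probs,
       cache = list(B = B, M0 = M0, W1mat = W1mat, M1 = M1,
                    Sblock = Sblock, ZbM = ZbM, A4 = A4, Mbig = Mbig,
                    M4 = M4, Z5 = Z5, Xf = Xf, masks = masks))
}

# Backward pass from a gradient (or attribution multiplier) at the
# logits. mult1/mult2 are the elementwise multipliers applied at the two
# ELU stages: elu_grad(Z) for training, finite-difference ratios for
# reference-based attribution. Returns parameter gradients and the
# gradient/multiplier at the input.
net_backward <- function(model, cache, dlogits, mult1, mult2,
                         want_param_grads = TRUE) {
  d <- model$dims
  p <- model$params
  B <- cache$B
  g <- list()
  if (want_param_grads) {
    g$W5 <- crossprod(cache$Xf, dlogits)
    g$b5 <- colSums(dlogits)
  }
  dP2 <- tcrossprod(dlogits, p$W5)
  dim(dP2) <- c(B * d$F2, d$T2)
  if (!is.null(cache$masks)) dP2 <- dP2 * cache$masks$m2
  dP2in <- tcrossprod(dP2, model$pool2)           # (B*F2) x T1
  dim(dP2in) <- c(B, d$F2, d$T1)
  dA5 <- aperm(dP2in, c(1, 3, 2))
  dim(dA5) <- c(B * d$T1, d$F2)
  dZ5 <- dA5 * mult2
  if (want_param_grads) {
    g$b4 <- colSums(dZ5)
    g$W4 <- crossprod(cache$M4, dZ5)
  }
  dM4 <- tcrossprod(dZ5, p$W4)
  dim(dM4) <- c(B, d$T1, d$C1)
  dZ4 <- aperm(dM4, c(1, 3, 2))
  dim(dZ4) <- c(B, d$C1 * d$T1)
  dA4 <- tcrossprod(dZ4, cache$Mbig)              # B x (C1*T1)
  if (want_param_grads) {
    G <- crossprod(cache$A4, dZ4)                 # (C1*T1) x (C1*T1)
    g$W3 <- matrix(grouped_sums(G[model$m_fill_sorted], model$m_ends),
                   d$K2, d$C1)
  }
  dP1 <- dA4
  dim(dP1) <- c(B * d$C1, d$T1)
  if (!is.null(cache$masks)) dP1 <- dP1 * cache$masks$m1
  dA3 <- tcrossprod(dP1, model$pool1)             # (B*C1) x Tn
  dZb <- dA3 * mult1
  dim(dZb) <- c(B, d$C1, d$Tn)
  if (want_param_grads) g$b1 <- rowSums(colSums(dZb, dims = 1))
  dZ2 <- aperm(dZb, c(2, 1, 3))                   # C1, B, Tn
  dim(dZ2) <- c(d$C1, B * d$Tn)
  if (want_param_grads) {
    dSblock <- dZ2 %*% t(cache$M1)                # C1 x (E*F1)
    g$S <- array(dSblock[model$s_fill], dim(p$S))
  }
  dM1 <- crossprod(cache$Sblock, dZ2)             # (E*F1) x (B*Tn)
  dim(dM1) <- c(d$E, d$F1, B, d$Tn)
  dZ1 <- aperm(dM1, c(3, 1, 4, 2))                # B, E, Tn, F1
  dim(dZ1) <- c(B * d$E, d$Tn * d$F1)
  if (want_param_grads) {
    G1 <- crossprod(cache$M0, dZ1)                # Tn x (Tn*F1)
    tm <- model$tm1
    g$W1 <- matrix(grouped_sums(G1[tm$fill_sorted], tm$grp_ends),
                   d$K1, d$F1)
  }
  dM0 <- tcrossprod(dZ1, cache$W1mat)
  dim(dM0) <- c(B, d$E, d$Tn)
  list(grads = g, dinput = dM0)
}

make_dropout_masks <- function(model, B, p_drop) {
  d <- model$dims
  list(m1 = matrix((stats::runif(B * d$C1 * d$T1) >= p_drop) / (1 - p_drop),
                   B * d$C1, d$T1),
       m2 = matrix((stats::runif(B * d$F2 * d$T2) >= p_drop) / (1 - p_drop),
                   B * d$F2, d$T2))
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / (1 - beta1^st$t)) /
        (sqrt(st$v[[nm]] / (1 - beta2^st$t)) + eps)
  }
  # Max-norm constraint on the depthwise spatial filters.
  S <- params$S
  for (f in seq_len(dim(S)[3])) for (dd in seq_len(dim(S)[1])) {
    nrm <- sqrt(sum(S[dd, , f]^2))
    if (nrm > 1) S[dd, , f] <- S[dd, , f] / nrm
  }
  params$S <- S
  list(params = params, state = st)
}

cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

# Train on train_idx with checkpointing at the lowest validation loss.
# Deterministic under the seed (init, shuffling and dropout streams).
# The default engine is the compiled training loop (src/net_train.cpp),
# an operation-for-operation port of the R reference loop below; the R
# engine is kept for cross-validation of the implementation.
net_train <- function(X, y, K, fs, spec, train_idx, val_idx, seed,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  E <- dim(X)[2]; Tn <- dim(X)[3]
  model <- net_init(E, Tn, K, fs, spec, seed = child_seed(seed, 1L, 41L))
  st <- adam_init(model$params)
  Xtr <- X[train_idx, , , drop = FALSE]
  ytr <- y[train_idx]
  Xval <- X[val_idx, , , drop = FALSE]
  yval <- y[val_idx]
  n <- length(ytr)
  if (engine == "cpp") {
    fit <- with_seed(child_seed(seed, 2L, 42L), {
      .cpp_net_train(model, Xtr, as.integer(ytr), Xval, as.integer(yval),
                     spec$lr, spec$lr_decay, as.integer(spec$decay_every),
                     as.integer(spec$max_epochs),
                     as.integer(spec$batch_size), spec$dropout,
                     as.double(spec$patience),
                     as.integer(spec$min_epochs %||% 0))
    })
    model$params <- lapply(fit$params, identity)
    model$val_loss <- fit$val_loss
    model$best_epoch <- fit$best_epoch
    return(model)
  }
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  since_best <- 0L
  with_seed(child_seed(seed, 2L, 42L), {
    for (epoch in seq_len(spec$max_epochs)) {
      lr <- spec$lr * spec$lr_decay^floor((epoch - 1) / spec$decay_every)
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = spec$batch_size)) {
        idx <- ord[b0:min(b0 + spec$batch_size - 1, n)]
        B <- length(idx)
        masks <- if (spec$dropout > 0) make_dropout_masks(model, B, spec$dropout)
        fw <- net_forward(model, Xtr[idx, , , drop = FALSE], masks)
        dlog <- fw$probs
        dlog[cbind(seq_len(B), ytr[idx])] <-
          dlog[cbind(seq_len(B), ytr[idx])] - 1
        dlog <- dlog / B
        bw <- net_backward(model, fw$cache, dlog,
                           mult1 = elu_grad(fw$cache$ZbM),
                           mult2 = elu_grad(fw$cache$Z5))
        upd <- adam_step(model$params, bw$grads, st, lr)
        model$params <- upd$params
        st <- upd$state
      }
      vloss <- cross_entropy(net_forward(model, Xval)$probs, yval)
      if (vloss < best$loss) {
        best <- list(loss = vloss, params = model$params, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= spec$patience && epoch >= spec$min_epochs) break
      }
    }
  })
  model$params <- best$params
  model$val_loss <- best$loss
  model$best_epoch <- best$epoch
  model
}

net_predict <- function(model, X) {
  net_forward(model, X)$probs
}
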