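# Conditional masked autoregressive flow (MAF).
#
# A stack of affine autoregressive transforms, each parameterized by a
# single-hidden-layer MADE conditioned on the observation vector. The flow
# maps a parameter vector u (in an unconstrained representation) to standard
# normal noise z; its exact log-density plus the change-of-variables term
# gives the conditional log-posterior used as the (negative) training loss.
# Forward pass, log-density, reverse-mode gradients and the sequential
# inverse (sampling) are implemented directly with dense matrix algebra:
# dimensionality is small (<= 6 parameters, tens of observation points), so
# BLAS-level operations are all that is needed.
#
# Autoregressive masks follow the MADE construction with two hidden
# layers: hidden unit j carries degree m_j in {1, ..., d-1}; the
# input-to-hidden mask allows connections from inputs with index <= m_j,
# hidden-to-hidden from units with degree <= the receiving degree, the
# hidden-to-output mask allows outputs with index > m_j, and a direct
# input-to-output mask allows strictly lower indices. Output i of each
# transform therefore depends only on inputs 1..i-1 (plus the unrestricted
# conditioning vector, which feeds both hidden layers). Successive
# transforms reverse the variable order so that every dimension is
# eventually conditioned on every other.

.maf_masks <- function(d, H) {
  if (d < 2L) stop("MAF requires at least 2 parameter dimensions")
  m1 <- rep(seq_len(d - 1L), length.out = H)
  m2 <- rep(seq_len(d - 1L), length.out = H)
  M1 <- outer(m1, seq_len(d), `>=`) * 1          # H x d, input -> hidden1
  M12 <- outer(m2, m1, `>=`) * 1                 # H x H, hidden1 -> hidden2
  M2 <- outer(seq_len(d), m2, `>`) * 1           # d x H, hidden2 -> output
  Md <- outer(seq_len(d), seq_len(d), `>`) * 1   # d x d, strictly lower
  list(M1 = M1, M12 = M12, M2 = M2, Md = Md)
}

.maf_init <- function(d, k, H = 50L, K = 5L, amax = 4) {
  masks <- .maf_masks(d, H)
  layers <- vector("list", K)
  for (t in seq_len(K)) {
    layers[[t]] <- list(
      W1 = matrix(stats::rnorm(H * d, sd = 1 / sqrt(d)), H, d) * masks$M1,
      b1 = numeric(H),
      Wc = matrix(stats::rnorm(H * k, sd = 1 / sqrt(k)), H, k),
      W12 = matrix(stats::rnorm(H * H, sd = 1 / sqrt(H)), H, H) * masks$M12,
      b2 = numeric(H),
      Wc2 = matrix(stats::rnorm(H * k, sd = 1 / sqrt(k)), H, k),
      # heads start at zero so the initial flow is the identity map
      Wmu = matrix(0, d, H), bmu = numeric(d),
      Wa = matrix(0, d, H), ba = numeric(d),
      Amu = matrix(0, d, d), Aa = matrix(0, d, d)
    )
  }
  perms <- lapply(seq_len(K), function(t) if (t %% 2L == 0L) rev(seq_len(d))
                  else seq_len(d))
  structure(list(d = d, k = k, H = H, K = K, amax = amax,
                 masks = masks, layers = layers, perms = perms),
            class = "maf_flow")
}

# Forward pass through one transform; returns output and cache for backprop.
.maf_layer_forward <- function(ly, masks, amax, v, ctx) {
  B <- nrow(v)
  h1 <- tanh(v %*% t(ly$W1 * masks$M1) + ctx %*% t(ly$Wc) +
               matrix(ly$b1, B, length(ly$b1), byrow = TRUE))
  h2 <- tanh(h1 %*% t(ly$W12 * masks$M12) + ctx %*% t(ly$Wc2) +
               matrix(ly$b2, B, length(ly$b2), byrow = TRUE))
  mu <- h2 %*% t(ly$Wmu * masks$M2) + v %*% t(ly$Amu * masks$Md) +
    matrix(ly$bmu, B, length(ly$bmu), byrow = TRUE)
  araw <- h2 %*% t(ly$Wa * masks$M2) + v %*% t(ly$Aa * masks$Md) +
    matrix(ly$ba, B, length(ly$ba), byrow = TRUE)
  a <- amax * tanh(araw / amax)
  z <- (v - mu) * exp(-a)
  list(h1 = h1, h2 = h2, mu = mu, a = a, z = z, v = v)
}

# Log-density of rows of u under the flow, conditioned on rows of ctx.
# With cache = TRUE also returns everything needed for the backward pass.
.maf_forward <- function(flow, u, ctx, cache = FALSE) {
  B <- nrow(u)
  logdet <- numeric(B)
  caches <- if (cache) vector("list", flow$K)
  cur <- u
  for (t in seq_len(flow$K)) {
    v <- cur[, flow$perms[[t]], drop = FALSE]
    fw <- .maf_layer_forward(flow$layers[[t]], flow$masks, flow$amax, v, ctx)
    logdet <- logdet - rowSums(fw$a)
    if (cache) caches[[t]] <- fw
    cur <- fw$z
  }
  lp <- -0.5 * rowSums(cur^2) - 0.5 * flow$d * log(2 * pi) + logdet
  if (cache) list(logprob = lp, z = cur, caches = caches) else lp
}

# Reverse-mode gradients of the mean negative log-likelihood over the batch
# with respect to every weight. Returns a list of per-layer gradient lists
# mirroring flow$layers.
.maf_backward <- function(flow, u, ctx) {
  fw <- .maf_forward(flow, u, ctx, cache = TRUE)
  B <- nrow(u)
  M1 <- flow$masks$M1; M12 <- flow$masks$M12
  M2 <- flow$masks$M2; Md <- flow$masks$Md
  grads <- vector("list", flow$K)
  gz <- fw$z  # d(NLL_sum)/dz_K, per sample
  for (t in rev(seq_len(flow$K))) {
    ly <- flow$layers[[t]]; ca <- fw$caches[[t]]
    ea <- exp(-ca$a)
    ga <- gz * (-ca$z) + 1          # + 1 from the sum(a) log-det term
    graw <- ga * (1 - (ca$a / flow$amax)^2)
    gmu <- -gz * ea
    gv <- gz * ea
    gh2 <- gmu %*% (ly$Wmu * M2) + graw %*% (ly$Wa * M2)
    gv <- gv + gmu %*% (ly$Amu * Md) + graw %*% (ly$Aa * Md)
    gpre2 <- gh2 * (1 - ca$h2^2)
    gh1 <- gpre2 %*% (ly$W12 * M12)
    gpre1 <- gh1 * (1 - ca$h1^2)
    gv <- gv + gpre1 %*% (ly$W1 * M1)
    grads[[t]] <- list(
      W1 = (t(gpre1) %*% ca$v) * M1 / B,
      b1 = colSums(gpre1) / B,
      Wc = t(gpre1) %*% ctx / B,
      W12 = (t(gpre2) %*% ca$h1) * M12 / B,
      b2 = colSums(gpre2) / B,
      Wc2 = t(gpre2) %*% ctx / B,
      Wmu = (t(gmu) %*% ca$h2) * M2 / B,
      bmu = colSums(gmu) / B,
      Wa = (t(graw) %*% ca$h2) * M2 / B,
      ba = colSums(graw) / B,
      Amu = (t(gmu) %*% ca$v) * Md / B,
      Aa = (t(graw) %*% ca$v) * Md / B
    )
    gu <- gv
    gu[, flow$perms[[t]]] <- gv  # undo the permutation
    gz <- gu
  }
  list(grads = grads, nll = -mean(fw$logprob))
}

# Draw m samples conditioned on a single observation vector. The affine
# autoregressive inverse is sequential over the d dimensions of each
# transform; the masked forward pass is simply re-evaluated per dimension.
.maf_sample <- function(flow, ctx_row, m) {
  ctx <- matrix(ctx_row, m, length(ctx_row), byrow = TRUE)
  cur <- matrix(stats::rnorm(m * flow$d), m, flow$d)
  for (t in rev(seq_len(flow$K))) {
    ly <- flow$layers[[t]]
    v <- matrix(0, m, flow$d)
    for (i in seq_len(flow$d)) {
      fw <- .maf_layer_forward(ly, flow$masks, flow$amax, v, ctx)
      v[, i] <- cur[, i] * exp(fw$a[, i]) + fw$mu[, i]
    }
    u <- v
    u[, flow$perms[[t]]] <- v
    cur <- u
  }
  cur
}

# Adam update on nested weight lists; state holds first/second moments.
.adam_step <- function(layers, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (t in seq_along(layers)) {
    for (nm in names(layers[[t]])) {
      g <- grads[[t]][[nm]]
      state$m[[t]][[nm]] <- beta1 * state$m[[t]][[nm]] + (1 - beta1) * g
      state$v[[t]][[nm]] <- beta2 * state$v[[t]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[t]][[nm]] / corr1
      vhat <- state$v[[t]][[nm]] / corr2
      layers[[t]][[nm]] <- layers[[t]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

.adam_init <- function(layers) {
  zero <- lapply(layers, function(ly) lapply(ly, function(w) w * 0))
  list(m = zero, v = zero, t = 0L)
}

# Full training loop: minibatch Adam with a validation split and early
# stopping on validation NLL; returns the best-validation flow.
# `refresh_ctx`, when supplied, is called once per epoch with the training
# row indices and must return fresh context rows for them (used to resample
# observation noise each epoch, an exact augmentation when the noise model
# is known); validation rows keep their original fixed context.
.maf_train <- function(u, ctx, H = 50L, K = 5L, lr = 1e-3, batch = 128L,
                       max_epochs = 300L, patience = 30L, val_frac = 0.1,
                       amax = 4, lr_decay = 0.3, refresh_ctx = NULL,
                       verbose = FALSE) {
  n <- nrow(u)
  n_val <- max(2L, floor(n * val_frac))
  if (n - n_val < batch)
    stop("training set too small: need at least ", batch + n_val,
         " simulations for a ", batch, "-sample minibatch plus ",
         "a ", val_frac * 100, "% validation split")
  idx <- sample.int(n)
  val <- idx[seq_len(n_val)]
  trn <- idx[-seq_len(n_val)]
  flow <- .maf_init(ncol(u), ncol(ctx), H = H, K = K, amax = amax)
  state <- .adam_init(flow$layers)
  val_nll0 <- -mean(.maf_forward(flow, u[val, , drop = FALSE],
                                 ctx[val, , drop = FALSE]))
  best <- list(nll = val_nll0, layers = flow$layers, epoch = 0L)
  curve <- val_nll0
  stall <- 0L
  cur_lr <- lr
  half <- max(2L, patience %/% 2L)
  for (ep in seq_len(max_epochs)) {
    if (!is.null(refresh_ctx)) ctx[trn, ] <- refresh_ctx(trn)
    ord <- sample(trn)
    for (b in split(ord, ceiling(seq_along(ord) / batch))) {
      if (length(b) < 2L) next
      bk <- .maf_backward(flow, u[b, , drop = FALSE], ctx[b, , drop = FALSE])
      up <- .adam_step(flow$layers, bk$grads, state, cur_lr)
      flow$layers <- up$layers
      state <- up$state
    }
    val_nll <- -mean(.maf_forward(flow, u[val, , drop = FALSE],
                                  ctx[val, , drop = FALSE]))
    curve <- c(curve, val_nll)
    if (is.finite(val_nll) && val_nll < best$nll - 1e-6) {
      best <- list(nll = val_nll, layers = flow$layers, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      # on plateau, restart from the best weights at a lower learning rate
      if (stall == half) {
        cur_lr <- cur_lr * lr_decay
        flow$layers <- best$layers
      }
    }
    if (verbose && ep %% 10L == 0L)
      message(sprintf("epoch %d: val NLL %.4f (best %.4f @ %d)",
                      ep, val_nll, best$nll, best$epoch))
    if (stall >= patience) break
  }
  flow$layers <- best$layers
  flow$val_curve <- curve
  flow$best_epoch <- best$epoch
  flow$best_val_nll <- best$nll
  flow$init_val_nll <- val_nll0
  flow
}
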