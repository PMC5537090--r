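# Minimal convolutional-network engine.
#
# Layers operate on batches laid out as [H, W, C, N] arrays; convolutions
# are im2col (C++) + BLAS GEMM. Each parameterized layer carries a `group`
# name so whole layer groups can be frozen for the layer-wise fine-tuning
# harness. Everything is deterministic given the R RNG state.
#
# Convolutions optionally fuse per-channel batch normalization (learnable
# scale/shift, running statistics for inference) — the standard
# conditioner for training deep stacks from scratch with plain SGD. The
# GEMM output is already laid out with one column per channel, so the
# normalization runs in place on it.

nn_conv <- function(k, stride, pad, cin, cout, group, relu = TRUE,
                    bn = FALSE) {
  fan_in <- k * k * cin
  layer <- list(type = "conv", k = k, stride = stride, pad = pad, cin = cin,
                cout = cout, group = group, relu = relu, bn = bn,
                W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                           fan_in, cout),
                b = numeric(cout))
  if (bn) {
    layer$gamma <- rep(1, cout)
    layer$beta <- numeric(cout)
    layer$run_mean <- numeric(cout)
    layer$run_var <- rep(1, cout)
    layer$bn_momentum <- 0.9
    layer$eps <- 1e-5
  }
  layer
}

nn_fc <- function(nin, nout, group, relu = FALSE) {
  list(type = "fc", nin = nin, nout = nout, group = group, relu = relu,
       W = matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

nn_pool <- function() list(type = "max2")
nn_gap <- function() list(type = "gap")
nn_flatten <- function() list(type = "flatten")

nn_inception <- function(group, cin, c1, reduce3, c3, bn = FALSE) {
  list(type = "inception", group = group, cin = cin, cout = c1 + c3,
       branches = list(
         list(nn_conv(1, 1, 0, cin, c1, group, bn = bn)),
         list(nn_conv(1, 1, 0, cin, reduce3, group, bn = bn),
              nn_conv(3, 1, 1, reduce3, c3, group, bn = bn))))
}

conv_fwd <- function(layer, x, keep = TRUE, train = keep) {
  d <- dim(x)
  oh <- (d[1] + 2 * layer$pad - layer$k) %/% layer$stride + 1
  ow <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1
  X <- im2col_batch(x, d[1], d[2], d[3], d[4], layer$k, layer$stride, layer$pad)
  Y <- X %*% layer$W
  Ypre <- NULL; mu <- NULL; istd <- NULL
  if (isTRUE(layer$bn)) {
    if (train && !isTRUE(layer$bn_freeze)) {
      st <- col_stats(Y)
      mu <- st[1, ]
      v <- st[2, ]
      istd <- 1 / sqrt(v + layer$eps)
      layer$run_mean <- layer$bn_momentum * layer$run_mean +
        (1 - layer$bn_momentum) * mu
      layer$run_var <- layer$bn_momentum * layer$run_var +
        (1 - layer$bn_momentum) * v
    } else {
      mu <- layer$run_mean
      istd <- 1 / sqrt(layer$run_var + layer$eps)
    }
    if (train && keep) Ypre <- Y + 0  # copy: Y is transformed in place below
    if (keep) {
      bn_fwd_inplace(Y, mu, istd, layer$gamma, layer$beta, FALSE)
      if (layer$relu) {
        neg <- Y < 0
        Y[neg] <- 0
      } else neg <- NULL
    } else {
      bn_fwd_inplace(Y, mu, istd, layer$gamma, layer$beta, layer$relu)
      neg <- NULL
    }
  } else if (keep) {
    bias_relu_inplace(Y, layer$b, FALSE)
    if (layer$relu) {
      neg <- Y < 0
      Y[neg] <- 0
    } else neg <- NULL
  } else {
    bias_relu_inplace(Y, layer$b, layer$relu)
    neg <- NULL
  }
  npos <- oh * ow
  out <- aperm(array(Y, c(npos, d[4], layer$cout)), c(1, 3, 2))
  dim(out) <- c(oh, ow, layer$cout, d[4])
  cache <- if (keep) list(X = X, neg = neg, din = d, oh = oh, ow = ow,
                          Ypre = Ypre, mu = mu, istd = istd) else NULL
  list(out = out, cache = cache, layer = layer)
}

conv_bwd <- function(layer, dout, cache) {
  d <- cache$din
  npos <- cache$oh * cache$ow
  dY <- aperm(array(dout, c(npos, layer$cout, d[4])), c(1, 3, 2))
  dim(dY) <- c(npos * d[4], layer$cout)
  if (!is.null(cache$neg)) dY[cache$neg] <- 0
  dgamma <- NULL; dbeta <- NULL
  if (isTRUE(layer$bn)) {
    g <- bn_bwd_inplace(dY, cache$Ypre, cache$mu, cache$istd, layer$gamma,
                        isTRUE(layer$bn_freeze))
    dgamma <- g$dgamma
    dbeta <- g$dbeta
    db <- numeric(layer$cout)   # no bias under batch normalization
  } else {
    db <- colSums(dY)
  }
  dW <- crossprod(cache$X, dY)
  dX <- col2im_batch(dY %*% t(layer$W), d[1], d[2], d[3], d[4],
                     layer$k, layer$stride, layer$pad)
  list(dx = dX, dW = dW, db = db, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(x) {
  d <- dim(x)
  out <- maxpool2(x, d[1], d[2], d[3], d[4])
  list(out = out, cache = list(x = x, out = out))
}

pool_bwd <- function(dout, cache) {
  d <- dim(cache$x)
  ri <- rep(seq_len(d[1] %/% 2), each = 2)
  ci <- rep(seq_len(d[2] %/% 2), each = 2)
  up_out <- cache$out[ri, ci, , , drop = FALSE]
  up_d <- dout[ri, ci, , , drop = FALSE]
  (cache$x == up_out) * up_d
}

nn_build <- function(layers, input_shape, n_out) {
  groups <- unique(unlist(lapply(layers, function(l) l$group)))
  structure(list(layers = layers, input_shape = input_shape, n_out = n_out,
                 groups = groups, frozen = character(0)),
            class = "baa_net")
}

# Forward pass; when train = TRUE per-layer caches are kept for backward.
# Returns the (possibly updated) net as well: batch-normalized layers
# refresh their running statistics during training passes.
nn_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    if (layer$type == "conv") {
      r <- conv_fwd(layer, x, keep = train, train = train)
      x <- r$out; caches[[li]] <- r$cache
      if (train) net$layers[[li]] <- r$layer
    } else if (layer$type == "max2") {
      r <- pool_fwd(x)
      x <- r$out; if (train) caches[[li]] <- r$cache
    } else if (layer$type == "gap") {
      d <- dim(x)
      caches[[li]] <- d
      x <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
    } else if (layer$type == "flatten") {
      d <- dim(x)
      caches[[li]] <- d
      x <- matrix(x, prod(d[1:3]), d[4])
    } else if (layer$type == "fc") {
      Y <- crossprod(layer$W, x) + layer$b
      if (layer$relu) {
        neg <- Y < 0; Y[neg] <- 0
      } else neg <- NULL
      caches[[li]] <- if (train) list(x = x, neg = neg) else NULL
      x <- Y
    } else if (layer$type == "inception") {
      d <- dim(x)
      outs <- vector("list", length(layer$branches))
      bc <- vector("list", length(layer$branches))
      for (bi in seq_along(layer$branches)) {
        xb <- x
        sub <- vector("list", length(layer$branches[[bi]]))
        for (si in seq_along(layer$branches[[bi]])) {
          r <- conv_fwd(layer$branches[[bi]][[si]], xb, keep = train,
                        train = train)
          xb <- r$out; sub[[si]] <- r$cache
          if (train) layer$branches[[bi]][[si]] <- r$layer
        }
        outs[[bi]] <- xb; bc[[bi]] <- sub
      }
      if (train) net$layers[[li]] <- layer
      do <- dim(outs[[1]])
      x <- array(0, c(do[1], do[2], layer$cout, d[4]))
      at <- 0L
      for (bi in seq_along(outs)) {
        nc <- dim(outs[[bi]])[3]
        x[, , at + seq_len(nc), ] <- outs[[bi]]
        at <- at + nc
      }
      if (train) caches[[li]] <- list(bc = bc, din = d,
                                      widths = vapply(outs, function(o) dim(o)[3], 0))
    } else stop("unknown layer type")
  }
  list(out = x, caches = caches, net = net)
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# Backward pass: returns list of per-layer gradients (NULL for unparameterized)
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    layer <- net$layers[[li]]
    if (layer$type == "conv") {
      g <- conv_bwd(layer, dout, caches[[li]])
      grads[[li]] <- g[c("dW", "db", "dgamma", "dbeta")]
      dout <- g$dx
    } else if (layer$type == "max2") {
      dout <- pool_bwd(dout, caches[[li]])
    } else if (layer$type == "gap") {
      d <- caches[[li]]
      dout <- array(rep(as.numeric(dout) / (d[1] * d[2]),
                        each = d[1] * d[2]), d)
    } else if (layer$type == "flatten") {
      dim(dout) <- caches[[li]]
    } else if (layer$type == "fc") {
      cc <- caches[[li]]
      if (!is.null(cc$neg)) dout[cc$neg] <- 0
      grads[[li]] <- list(dW = cc$x %*% t(dout), db = rowSums(dout))
      dout <- layer$W %*% dout
    } else if (layer$type == "inception") {
      cc <- caches[[li]]
      dx <- NULL
      at <- 0L
      bg <- vector("list", length(layer$branches))
      for (bi in seq_along(layer$branches)) {
        nc <- cc$widths[bi]
        dslice <- dout[, , at + seq_len(nc), , drop = FALSE]
        at <- at + nc
        sub <- layer$branches[[bi]]
        sg <- vector("list", length(sub))
        for (si in rev(seq_along(sub))) {
          g <- conv_bwd(sub[[si]], dslice, cc$bc[[bi]][[si]])
          sg[[si]] <- g[c("dW", "db", "dgamma", "dbeta")]
          dslice <- g$dx
        }
        bg[[bi]] <- sg
        dx <- if (is.null(dx)) dslice else dx + dslice
      }
      grads[[li]] <- list(branches = bg)
      dout <- dx
    }
  }
  grads
}

# One SGD step with momentum + weight decay; `state` holds velocity
# buffers. Weight decay never touches batch-normalization scale/shift.
nn_update <- function(net, grads, state, lr, momentum, weight_decay) {
  upd1 <- function(layer, g, st) {
    if (is.null(st)) {
      st <- list(vW = layer$W * 0, vb = layer$b * 0)
      if (isTRUE(layer$bn)) {
        st$vg <- layer$gamma * 0
        st$vbeta <- layer$beta * 0
      }
    }
    st$vW <- momentum * st$vW - lr * (g$dW + weight_decay * layer$W)
    layer$W <- layer$W + st$vW
    if (isTRUE(layer$bn)) {
      st$vg <- momentum * st$vg - lr * g$dgamma
      st$vbeta <- momentum * st$vbeta - lr * g$dbeta
      layer$gamma <- layer$gamma + st$vg
      layer$beta <- layer$beta + st$vbeta
    } else {
      st$vb <- momentum * st$vb - lr * g$db
      layer$b <- layer$b + st$vb
    }
    list(layer = layer, st = st)
  }
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    if (is.null(grads[[li]]) || (layer$group %in% net$frozen)) next
    if (layer$type == "inception") {
      if (is.null(state[[li]]))
        state[[li]] <- list(branches = lapply(layer$branches, function(b)
          vector("list", length(b))))
      for (bi in seq_along(layer$branches)) {
        for (si in seq_along(layer$branches[[bi]])) {
          r <- upd1(layer$branches[[bi]][[si]],
                    grads[[li]]$branches[[bi]][[si]],
                    state[[li]]$branches[[bi]][[si]])
          layer$branches[[bi]][[si]] <- r$layer
          state[[li]]$branches[[bi]][[si]] <- r$st
        }
      }
      net$layers[[li]] <- layer
    } else {
      r <- upd1(layer, grads[[li]], state[[li]])
      net$layers[[li]] <- r$layer
      state[[li]] <- r$st
    }
  }
  list(net = net, state = state)
}

# Epoch boundaries (1-based epochs after which the LR is multiplied by
# gamma): evenly spaced at floor(E/4), floor(E/2), floor(3E/4).
lr_step_epochs <- function(epochs) {
  unique(pmax(1L, floor(epochs * c(1, 2, 3) / 4)))
}

nn_predict_probs <- function(net, x, chunk = 512L) {
  d <- dim(x)
  n <- d[4]
  out <- matrix(0, net$n_out, n)
  at <- 1L
  while (at <= n) {
    take <- min(chunk, n - at + 1L)
    xb <- x[, , , at:(at + take - 1L), drop = FALSE]
    out[, at:(at + take - 1L)] <- softmax_cols(nn_forward(net, xb)$out)
    at <- at + take
  }
  out
}

# Core SGD training loop shared by the detector and the classifier.
#
# x: [H,W,C,N] array; y: integer labels 1..n_out. Returns the
# best-by-validation-accuracy snapshot plus the per-epoch history.
nn_train <- function(net, x, y, val_x, val_y, epochs, base_lr, gamma,
                     momentum = 0.9, weight_decay = 0.005, batch_size = 96L,
                     seed = 1L, augment_fn = NULL, verbose = FALSE) {
  n <- dim(x)[4]
  steps <- lr_step_epochs(epochs)
  state <- vector("list", length(net$layers))
  best <- list(acc = -Inf, layers = net$layers, epoch = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  run_epoch <- function(lr) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, batch_size)) {
      take <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[, , , take, drop = FALSE]
      if (!is.null(augment_fn)) {
        for (q in seq_along(take)) xb[, , 1L, q] <- augment_fn(xb[, , 1L, q])
      }
      yb <- y[take]
      fw <- nn_forward(net, xb, train = TRUE)
      net <<- fw$net   # batch-norm running statistics
      p <- softmax_cols(fw$out)
      m <- length(take)
      loss <- -mean(log(pmax(p[cbind(yb, seq_len(m))], 1e-12)))
      if (!is.finite(loss))
        baa_stop("baa_training_failure", "loss diverged (NaN/Inf)")
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      dlogits <- p
      dlogits[cbind(yb, seq_len(m))] <- dlogits[cbind(yb, seq_len(m))] - 1
      dlogits <- dlogits / m
      grads <- nn_backward(net, fw$caches, dlogits)
      r <- nn_update(net, grads, state, lr, momentum, weight_decay)
      net <<- r$net; state <<- r$state
    }
    ep_loss / nb
  }
  log_epoch <- function(ep, lr, ep_loss) {
    val_p <- nn_predict_probs(net, val_x)
    val_acc <- mean(apply(val_p, 2, which.max) == val_y)
    history <<- rbind(history, data.frame(
      epoch = ep, loss = ep_loss, val_accuracy = val_acc))
    # ties go to the later (more converged) epoch
    if (val_acc >= best$acc)
      best <<- list(acc = val_acc, layers = net$layers, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  lr %.4g  loss %.4f  val %.3f",
                      ep, lr, ep_loss, val_acc))
  }
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      lr <- base_lr * gamma^sum(steps < ep)
      log_epoch(ep, lr, run_epoch(lr))
    }
    # Frozen-statistics polish: re-estimate the normalization statistics
    # over the full training set, then fine-tune the weights against the
    # inference-mode normalization for a short final phase. This closes
    # the small-batch gap between training-mode and inference-mode
    # predictions; it is skipped for networks without batch norm.
    polish <- net_has_bn(net) * max(0L, epochs %/% 3L)
    if (polish > 0L) {
      net <- nn_recalibrate_bn(net, x, batch_size)
      net$layers <- set_bn_freeze(net$layers, TRUE)
      # frozen-stats gradients are much larger than batch-normalized
      # ones (no self-centering), so the polish rate is far smaller
      lr <- base_lr * gamma^3 * 0.05
      for (ep in epochs + seq_len(polish)) log_epoch(ep, lr, run_epoch(lr))
      net$layers <- set_bn_freeze(net$layers, FALSE)
    }
  })
  # the polished weights are tuned against the re-estimated (then frozen)
  # statistics, so the final state keeps them verbatim
  final <- net
  net$layers <- set_bn_freeze(best$layers, FALSE)
  if (best$epoch <= epochs)  # main-phase snapshot: stats lag the weights
    net <- nn_recalibrate_bn(net, x, batch_size)
  list(net = net, final_net = final, history = history,
       best_epoch = best$epoch, best_val_accuracy = best$acc)
}

net_has_bn <- function(net) {
  any(vapply(net$layers, function(l) {
    isTRUE(l$bn) || (l$type == "inception" &&
                       any(vapply(unlist(l$branches, recursive = FALSE),
                                  function(s) isTRUE(s$bn), TRUE)))
  }, TRUE))
}

set_bn_freeze <- function(layers, on) {
  fix1 <- function(l) {
    if (isTRUE(l$bn)) l$bn_freeze <- on
    if (identical(l$type, "inception"))
      l$branches <- lapply(l$branches, function(b) lapply(b, fix1))
    l
  }
  lapply(layers, fix1)
}

# Re-estimate batch-normalization running statistics as the exact average
# over the training set ("precise statistics"): with small mini-batches
# the momentum-tracked statistics lag the data statistics, which hurts
# inference-mode predictions. Weights are untouched.
nn_recalibrate_bn <- function(net, x, batch_size = 32L) {
  has_bn <- any(vapply(net$layers, function(l) {
    isTRUE(l$bn) || (l$type == "inception" &&
                       any(vapply(unlist(l$branches, recursive = FALSE),
                                  function(s) isTRUE(s$bn), TRUE)))
  }, TRUE))
  if (!has_bn) return(net)
  set_mom <- function(l, m) {
    if (isTRUE(l$bn)) l$bn_momentum <- m
    if (l$type == "inception")
      l$branches <- lapply(l$branches, function(b) lapply(b, set_mom, m = m))
    l
  }
  n <- dim(x)[4]
  i <- 0L
  for (start in seq(1L, n, batch_size)) {
    i <- i + 1L
    net$layers <- lapply(net$layers, set_mom, m = (i - 1) / i)
    xb <- x[, , , start:min(start + batch_size - 1L, n), drop = FALSE]
    net <- nn_forward(net, xb, train = TRUE)$net
  }
  net$layers <- lapply(net$layers, set_mom, m = 0.9)
  net
}

# Flatten all trainable parameters of a group into one numeric vector
# (used to verify frozen groups stay bit-identical).
nn_group_params <- function(net, group) {
  acc <- c()
  grab1 <- function(l) {
    c(as.numeric(l$W), as.numeric(l$b),
      if (isTRUE(l$bn)) c(l$gamma, l$beta))
  }
  for (l in net$layers) {
    if (l$type == "inception") {
      if (identical(l$group, group))
        for (b in l$branches) for (s in b) acc <- c(acc, grab1(s))
    } else if (!is.null(l$W) && identical(l$group, group)) {
      acc <- c(acc, grab1(l))
    }
  }
  acc
}
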