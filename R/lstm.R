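## A compact LSTM/BiLSTM engine for sequence classification.
##
## Implements stacked (bi)directional LSTM layers over variable-length
## multichannel sequences, temporal mean pooling over valid timesteps, a dense
## softmax head, inverted dropout, cross-entropy loss and Adam. Everything is
## plain R matrix algebra and fully deterministic under a fixed seed, which is
## what the rest of the package needs: the window activity classifier and the
## stride-sequence fall-risk models are both expressed as architecture specs
## consumed by this engine.
##
## Sequences are lists of C x T matrices. Internally a minibatch is padded to
## its longest sequence with a 0/1 validity mask; padded steps carry hidden and
## cell states through unchanged so padding never influences the pooled output.

#' Define a recurrent sequence-classifier architecture
#'
#' @param layers list of layers, each `list(type = "lstm"|"bilstm",
#'   units = <int>, dropout = <fraction>)`, applied in order.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param name optional label.
#' @return an object of class `lstm_spec`.
#' @export
lstm_spec <- function(layers = list(list(type = "bilstm", units = 16, dropout = 0.4)),
                      epochs = 20, lr = 0.01, batch_size = 32, name = "custom") {
  for (ly in layers) {
    stopifnot(ly$type %in% c("lstm", "bilstm"), ly$units >= 1,
              ly$dropout >= 0, ly$dropout < 1)
  }
  structure(list(layers = layers, epochs = epochs, lr = lr,
                 batch_size = batch_size, name = name), class = "lstm_spec")
}

#' Published sequence-model architectures
#'
#' `arch_lstm2()` is an LSTM(290) + 30\% dropout + BiLSTM(10) + 40\% dropout
#' stack trained for 55 epochs; `arch_lstm3()` stacks LSTM(85)/55\%,
#' LSTM(85)/55\%, LSTM(235)/45\% trained for 125 epochs. Both end in a dense
#' softmax head and use Adam. These are full-scale configurations; tests and
#' examples use reduced specs via [lstm_spec()].
#' @return an `lstm_spec`.
#' @export
arch_lstm2 <- function() {
  lstm_spec(list(list(type = "lstm", units = 290, dropout = 0.30),
                 list(type = "bilstm", units = 10, dropout = 0.40)),
            epochs = 55, name = "LSTM2")
}

#' @rdname arch_lstm2
#' @export
arch_lstm3 <- function() {
  lstm_spec(list(list(type = "lstm", units = 85, dropout = 0.55),
                 list(type = "lstm", units = 85, dropout = 0.55),
                 list(type = "lstm", units = 235, dropout = 0.45)),
            epochs = 125, name = "LSTM3")
}

## ---- parameter initialisation -------------------------------------------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

## One directional LSTM cell's parameters. Gate order along columns: input,
## forget, cell candidate, output (4 blocks of `units`).
init_cell <- function(n_in, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1  # forget-gate bias 1: stable gradients early
  list(Wx = glorot(n_in, 4 * units), Wh = glorot(units, 4 * units), b = b)
}

init_params <- function(spec, n_in, n_class) {
  layers <- list()
  d <- n_in
  for (ly in spec$layers) {
    u <- ly$units
    if (ly$type == "bilstm") {
      layers[[length(layers) + 1]] <- list(type = "bilstm", units = u,
                                           dropout = ly$dropout,
                                           fwd = init_cell(d, u),
                                           bwd = init_cell(d, u))
      d <- 2 * u
    } else {
      layers[[length(layers) + 1]] <- list(type = "lstm", units = u,
                                           dropout = ly$dropout,
                                           fwd = init_cell(d, u))
      d <- u
    }
  }
  list(layers = layers, Wd = glorot(d, n_class), bd = numeric(n_class), d_out = d)
}

sigm <- function(x) 1 / (1 + exp(-x))

## ---- forward/backward for one direction ---------------------------------

## X: list over t of B x d_in matrices; mask: B x T (1 valid, 0 pad).
## Padded steps carry state through. Returns hidden sequence + caches.
cell_forward <- function(cell, X, mask) {
  Tn <- length(X); B <- nrow(X[[1]]); u <- ncol(cell$Wh)
  u <- u  # 4u columns; true units:
  units <- ncol(cell$Wh) / 4
  h <- matrix(0, B, units); c0 <- matrix(0, B, units)
  H <- vector("list", Tn); cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    z <- X[[t]] %*% cell$Wx + h %*% cell$Wh
    z <- sweep(z, 2, cell$b, "+")
    i <- sigm(z[, 1:units, drop = FALSE])
    f <- sigm(z[, (units + 1):(2 * units), drop = FALSE])
    g <- tanh(z[, (2 * units + 1):(3 * units), drop = FALSE])
    o <- sigm(z[, (3 * units + 1):(4 * units), drop = FALSE])
    cn <- f * c0 + i * g
    hn <- o * tanh(cn)
    m <- mask[, t]
    hkeep <- hn * m + h * (1 - m)
    ckeep <- cn * m + c0 * (1 - m)
    cache[[t]] <- list(x = X[[t]], hprev = h, cprev = c0, i = i, f = f,
                       g = g, o = o, c = cn, m = m)
    h <- hkeep; c0 <- ckeep
    H[[t]] <- hkeep
  }
  list(H = H, cache = cache)
}

## dH: list over t of B x units gradients w.r.t. the (masked) hidden outputs.
cell_backward <- function(cell, fwd, dH) {
  Tn <- length(dH); units <- ncol(cell$Wh) / 4
  B <- nrow(dH[[1]])
  dWx <- cell$Wx * 0; dWh <- cell$Wh * 0; db <- cell$b * 0
  dh_next <- matrix(0, B, units); dc_next <- matrix(0, B, units)
  dX <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    ca <- fwd$cache[[t]]
    m <- ca$m
    dh <- dH[[t]] + dh_next
    ## masked step: gradient flows through the cell only where valid;
    ## where padded, state passed through so gradient passes straight back.
    dh_cell <- dh * m
    dh_pass <- dh * (1 - m)
    dc <- dc_next * m
    dc_pass <- dc_next * (1 - m)
    tc <- tanh(ca$c)
    do_ <- dh_cell * tc
    dcn <- dh_cell * ca$o * (1 - tc^2) + dc
    di <- dcn * ca$g
    df <- dcn * ca$cprev
    dg <- dcn * ca$i
    dcprev <- dcn * ca$f
    dzi <- di * ca$i * (1 - ca$i)
    dzf <- df * ca$f * (1 - ca$f)
    dzg <- dg * (1 - ca$g^2)
    dzo <- do_ * ca$o * (1 - ca$o)
    dz <- cbind(dzi, dzf, dzg, dzo)
    dWx <- dWx + crossprod(ca$x, dz)
    dWh <- dWh + crossprod(ca$hprev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(cell$Wx)
    dh_next <- dz %*% t(cell$Wh) + dh_pass
    dc_next <- dcprev + dc_pass
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

reverse_seq <- function(X, mask) {
  ## reverse each sequence's valid part in place, keeping padding at the end
  Tn <- length(X); B <- nrow(X[[1]])
  lens <- rowSums(mask)
  Xr <- lapply(X, function(m) m * 0)
  for (b in seq_len(B)) {
    lb <- lens[b]
    if (lb >= 1) for (t in seq_len(lb)) Xr[[t]][b, ] <- X[[lb - t + 1]][b, ]
  }
  Xr
}

layer_forward <- function(layer, X, mask, drop_masks = NULL) {
  f <- cell_forward(layer$fwd, X, mask)
  if (layer$type == "bilstm") {
    Xr <- reverse_seq(X, mask)
    bwd <- cell_forward(layer$bwd, Xr, mask)
    Hb <- reverse_seq(bwd$H, mask)
    H <- mapply(function(a, b) cbind(a, b), f$H, Hb, SIMPLIFY = FALSE)
    out <- list(H = H, fwd = f, bwd = bwd, Xr = Xr)
  } else {
    out <- list(H = f$H, fwd = f)
  }
  if (!is.null(drop_masks)) {
    out$H <- mapply(function(h, dm) h * dm, out$H, drop_masks, SIMPLIFY = FALSE)
  }
  out
}

layer_backward <- function(layer, fwd_out, dH, drop_masks = NULL, mask) {
  if (!is.null(drop_masks)) {
    dH <- mapply(function(g, dm) g * dm, dH, drop_masks, SIMPLIFY = FALSE)
  }
  units <- layer$units
  if (layer$type == "bilstm") {
    dHf <- lapply(dH, function(g) g[, 1:units, drop = FALSE])
    dHb <- lapply(dH, function(g) g[, (units + 1):(2 * units), drop = FALSE])
    bf <- cell_backward(layer$fwd, fwd_out$fwd, dHf)
    dHb_r <- reverse_seq(dHb, mask)
    bb <- cell_backward(layer$bwd, fwd_out$bwd, dHb_r)
    dXb <- reverse_seq(bb$dX, mask)
    dX <- mapply(function(a, b) a + b, bf$dX, dXb, SIMPLIFY = FALSE)
    list(grads = list(fwd = bf[c("dWx", "dWh", "db")],
                      bwd = bb[c("dWx", "dWh", "db")]), dX = dX)
  } else {
    bf <- cell_backward(layer$fwd, fwd_out$fwd, dH)
    list(grads = list(fwd = bf[c("dWx", "dWh", "db")]), dX = bf$dX)
  }
}

## ---- full network over a padded minibatch --------------------------------

net_forward <- function(params, X, mask, training = FALSE, spec = NULL) {
  acts <- list(); cur <- X
  drop_all <- list()
  for (li in seq_along(params$layers)) {
    layer <- params$layers[[li]]
    dm <- NULL
    if (training && layer$dropout > 0) {
      p <- layer$dropout
      dm <- lapply(seq_along(cur), function(t) {
        d <- if (layer$type == "bilstm") 2 * layer$units else layer$units
        matrix(stats::rbinom(nrow(mask) * d, 1, 1 - p) / (1 - p), nrow(mask), d)
      })
    }
    out <- layer_forward(layer, cur, mask, dm)
    acts[[li]] <- out; drop_all[li] <- list(dm)
    cur <- out$H
  }
  ## masked temporal mean pooling
  lens <- rowSums(mask)
  pool <- Reduce(`+`, mapply(function(h, t) h * mask[, t], cur,
                             seq_along(cur), SIMPLIFY = FALSE))
  pool <- pool / pmax(lens, 1)
  logits <- sweep(pool %*% params$Wd, 2, params$bd, "+")
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(acts = acts, drop = drop_all, pool = pool, probs = probs, inputs = X)
}

net_backward <- function(params, fw, X, mask, y_onehot) {
  B <- nrow(mask)
  dlogits <- (fw$probs - y_onehot) / B
  gWd <- crossprod(fw$pool, dlogits)
  gbd <- colSums(dlogits)
  dpool <- dlogits %*% t(params$Wd)
  lens <- pmax(rowSums(mask), 1)
  nl <- length(params$layers)
  dH <- lapply(seq_len(ncol(mask)), function(t) dpool * (mask[, t] / lens))
  grads <- vector("list", nl)
  for (li in rev(seq_len(nl))) {
    layer <- params$layers[[li]]
    bk <- layer_backward(layer, fw$acts[[li]], dH, fw$drop[[li]], mask)
    grads[[li]] <- bk$grads
    dH <- bk$dX
  }
  list(layers = grads, dWd = gWd, dbd = gbd)
}

## ---- Adam ----------------------------------------------------------------

adam_state <- function(params) rapply(params, function(x) x * 0, how = "replace",
                                      classes = c("matrix", "numeric"))

flatten_grads <- function(params, grads) {
  ## walk both trees in lockstep; returns list of (get, set, grad) closures is
  ## overkill in R — instead update in place via recursion in adam_update.
  NULL
}

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  upd_cell <- function(cell, g, st) {
    for (nm in c("Wx", "Wh", "b")) {
      gn <- switch(nm, Wx = g$dWx, Wh = g$dWh, b = g$db)
      st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gn
      st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gn^2
      mh <- st$m[[nm]] / (1 - beta1^t)
      vh <- st$v[[nm]] / (1 - beta2^t)
      cell[[nm]] <- cell[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
    list(cell = cell, st = st)
  }
  for (li in seq_along(params$layers)) {
    r <- upd_cell(params$layers[[li]]$fwd, grads$layers[[li]]$fwd,
                  state$layers[[li]]$fwd)
    params$layers[[li]]$fwd <- r$cell; state$layers[[li]]$fwd <- r$st
    if (params$layers[[li]]$type == "bilstm") {
      r <- upd_cell(params$layers[[li]]$bwd, grads$layers[[li]]$bwd,
                    state$layers[[li]]$bwd)
      params$layers[[li]]$bwd <- r$cell; state$layers[[li]]$bwd <- r$st
    }
  }
  state$m_Wd <- beta1 * state$m_Wd + (1 - beta1) * grads$dWd
  state$v_Wd <- beta2 * state$v_Wd + (1 - beta2) * grads$dWd^2
  params$Wd <- params$Wd - lr * (state$m_Wd / (1 - beta1^t)) /
    (sqrt(state$v_Wd / (1 - beta2^t)) + eps)
  state$m_bd <- beta1 * state$m_bd + (1 - beta1) * grads$dbd
  state$v_bd <- beta2 * state$v_bd + (1 - beta2) * grads$dbd^2
  params$bd <- params$bd - lr * (state$m_bd / (1 - beta1^t)) /
    (sqrt(state$v_bd / (1 - beta2^t)) + eps)
  list(params = params, state = state)
}

init_adam <- function(params) {
  zc <- function(cell) list(m = list(Wx = cell$Wx * 0, Wh = cell$Wh * 0, b = cell$b * 0),
                            v = list(Wx = cell$Wx * 0, Wh = cell$Wh * 0, b = cell$b * 0))
  st <- list(layers = lapply(params$layers, function(ly) {
    s <- list(fwd = zc(ly$fwd))
    if (ly$type == "bilstm") s$bwd <- zc(ly$bwd)
    s
  }))
  st$m_Wd <- params$Wd * 0; st$v_Wd <- params$Wd * 0
  st$m_bd <- params$bd * 0; st$v_bd <- params$bd * 0
  st
}

## ---- batching helpers ----------------------------------------------------

pad_batch <- function(seqs) {
  ## seqs: list of C x T matrices -> list(X = list over t of B x C, mask B x T)
  B <- length(seqs)
  lens <- vapply(seqs, ncol, 1L)
  Tm <- max(lens)
  C <- nrow(seqs[[1]])
  mask <- matrix(0, B, Tm)
  for (b in seq_len(B)) mask[b, seq_len(lens[b])] <- 1
  X <- lapply(seq_len(Tm), function(t) {
    m <- matrix(0, B, C)
    for (b in seq_len(B)) if (t <= lens[b]) m[b, ] <- seqs[[b]][, t]
    m
  })
  list(X = X, mask = mask)
}

#' Train a recurrent sequence classifier
#'
#' @param seqs list of channels-by-time numeric matrices (channel count must be
#'   constant; lengths may vary).
#' @param labels binary labels (factor, logical or 0/1); the second level /
#'   value 1 is the positive class.
#' @param spec an [lstm_spec()].
#' @param seed integer seed; training is deterministic given the seed.
#' @param epochs optional override of `spec$epochs`.
#' @param normalize z-score each channel using training-set statistics
#'   (default TRUE).
#' @param verbose print per-epoch loss.
#' @return an object of class `lstm_model` with `$predict`able parameters.
#' @export
lstm_train <- function(seqs, labels, spec, seed = 1, epochs = NULL,
                       normalize = TRUE, verbose = FALSE) {
  stopifnot(inherits(spec, "lstm_spec"), length(seqs) == length(labels))
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2) stop("training data contain a single class")
  lev <- levels(as.factor(labels))
  epochs <- if (is.null(epochs)) spec$epochs else epochs
  C <- nrow(seqs[[1]])
  norm <- list(mu = numeric(C), sd = rep(1, C))
  if (normalize) {
    all_mat <- do.call(cbind, seqs)
    norm$mu <- rowMeans(all_mat)
    norm$sd <- apply(all_mat, 1, stats::sd)
    norm$sd[norm$sd < 1e-12] <- 1
    seqs <- lapply(seqs, function(m) (m - norm$mu) / norm$sd)
  }
  set.seed(seed)
  params <- init_params(spec, C, 2L)
  state <- init_adam(params)
  n <- length(seqs)
  bs <- min(spec$batch_size, n)
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      pb <- pad_batch(seqs[idx])
      yb <- y[idx]
      onehot <- cbind(1 - yb, yb)
      fw <- net_forward(params, pb$X, pb$mask, training = TRUE, spec = spec)
      eps <- 1e-12
      losses <- c(losses, -mean(log(fw$probs[cbind(seq_along(idx), yb + 1L)] + eps)))
      gr <- net_backward(params, fw, pb$X, pb$mask, onehot)
      step <- step + 1
      r <- adam_update(params, gr, state, spec$lr, step)
      params <- r$params; state <- r$state
    }
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, mean(losses)))
  }
  structure(list(params = params, spec = spec, norm = norm, levels = lev,
                 n_channels = C), class = "lstm_model")
}

#' Decision scores from a trained sequence classifier
#'
#' @param model an `lstm_model`.
#' @param seqs list of channels-by-time matrices.
#' @return numeric vector of posterior probabilities for the positive
#'   (second-level) class, in `[0, 1]`.
#' @export
lstm_scores <- function(model, seqs) {
  stopifnot(inherits(model, "lstm_model"))
  if (nrow(seqs[[1]]) != model$n_channels) {
    stop("input channel count does not match the trained model")
  }
  seqs <- lapply(seqs, function(m) (m - model$norm$mu) / model$norm$sd)
  out <- numeric(length(seqs))
  bs <- 64L
  for (start in seq(1, length(seqs), by = bs)) {
    idx <- start:min(start + bs - 1, length(seqs))
    pb <- pad_batch(seqs[idx])
    fw <- net_forward(model$params, pb$X, pb$mask, training = FALSE)
    out[idx] <- fw$probs[, 2]
  }
  out
}

#' @export
predict.lstm_model <- function(object, newdata, ...) lstm_scores(object, newdata)
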