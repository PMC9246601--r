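# Lightweight CNN engine used to train candidate architectures. Activations
# are arrays (H, W, C, N); convolution is im2col + BLAS matrix products with
# same-padding and stride 1; pooling is strided (stride = pool side, full
# blocks only). A softmax classification head (dense, K units) is appended
# to every instantiated network. Optimizer: Adam.

# ---- shape propagation ------------------------------------------------------

# shape is either c(H, W, C) (spatial) or a single integer (flat)
propagate_shapes <- function(layers, input_shape) {
  shp <- as.integer(input_shape)
  shapes <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    spatial <- length(shp) == 3L
    shp <- switch(l$kind,
      C2D = {
        if (!spatial) stop(sprintf("layer %d (C2D): requires image input", i))
        c(shp[1], shp[2], l$params$filters)
      },
      MP = ,
      AP = {
        if (!spatial) stop(sprintf("layer %d (%s): requires image input", i, l$kind))
        p <- l$params$pool
        h <- shp[1] %/% p; w <- shp[2] %/% p
        if (h < 1L || w < 1L) {
          stop(sprintf("layer %d (%s): pooling below 1x1 (input %dx%d, pool %d)",
                       i, l$kind, shp[1], shp[2], p))
        }
        c(h, w, shp[3])
      },
      F = {
        if (!spatial) stop(sprintf("layer %d (F): requires image input", i))
        prod(shp)
      },
      DE = {
        if (spatial) stop(sprintf("layer %d (DE): requires flattened input", i))
        l$params$units
      },
      BN = shp,
      DO = shp,
      stop(sprintf("layer %d: unknown kind %s", i, l$kind))
    )
    shapes[[i]] <- shp
  }
  shapes
}

#' Count trainable parameters of an architecture
#'
#' Sums trainable weights and biases over the listed layers under the
#' network conventions: convolution is same-padding stride 1 with
#' `kernel^2 * channels_in * filters` weights plus one bias per filter;
#' dense is `inputs * units + units`; batch normalization contributes two
#' trainable terms (scale, shift) per channel; pooling, flatten and dropout
#' contribute nothing. The classification head appended at instantiation is
#' not part of the architecture and is not counted here.
#'
#' @param arch an [architecture()].
#' @param input_shape `(H, W, C)` image shape, or a single integer for an
#'   already-flat input.
#' @return integer parameter count.
#' @examples
#' a <- architecture(list(layer_spec("C2D", filters = 2, kernel = 3),
#'                        layer_spec("F"), layer_spec("DE", units = 3)),
#'                   input_shape = c(8, 8, 1))
#' count_parameters(a)  # 407
#' @export
count_parameters <- function(arch, input_shape = arch$input_shape) {
  stopifnot(inherits(arch, "architecture"))
  shapes <- propagate_shapes(arch$layers, input_shape)
  shp <- as.integer(input_shape)
  total <- 0
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    total <- total + switch(l$kind,
      C2D = l$params$kernel^2 * shp[3] * l$params$filters + l$params$filters,
      DE  = shp * l$params$units + l$params$units,
      BN  = 2 * (if (length(shp) == 3L) shp[3] else shp),
      0
    )
    shp <- shapes[[i]]
  }
  as.numeric(total)
}

# ---- instantiation ----------------------------------------------------------

#' Instantiate a trainable network from an architecture
#'
#' Builds layer state (weights, batch-norm statistics, optimizer slots) for
#' the architecture plus a dense softmax classification head with
#' `n_classes` units. Weight initialization is He-scaled Gaussian and is
#' deterministic given `seed`.
#'
#' @param arch an [architecture()]; must be structurally valid.
#' @param input_shape `(H, W, C)` image shape.
#' @param n_classes number of output classes.
#' @param seed optional integer for deterministic initialization.
#' @return a `swarm_network` object.
#' @export
instantiate_network <- function(arch, input_shape = arch$input_shape,
                                n_classes = 5L, seed = NULL) {
  stopifnot(inherits(arch, "architecture"))
  if (any(input_shape < 1)) stop("input_shape must be positive")
  if (!is.null(seed)) set.seed(seed)
  shapes <- propagate_shapes(arch$layers, input_shape)
  out_shape <- shapes[[length(shapes)]]
  if (length(out_shape) == 3L) {
    stop("architecture output is not flattened; the classification head requires a flat input")
  }
  layers <- list()
  shp <- as.integer(input_shape)
  mk_dense <- function(D, U, act) {
    e <- new.env(parent = emptyenv())
    e$type <- "DE"; e$D <- D; e$U <- U; e$act <- act
    e$W <- matrix(stats::rnorm(D * U, sd = sqrt(2 / D)), D, U)
    e$b <- numeric(U)
    e
  }
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    e <- new.env(parent = emptyenv())
    e$type <- l$kind
    if (l$kind == "C2D") {
      k <- l$params$kernel; Cin <- shp[3]; Fout <- l$params$filters
      e$k <- k; e$Cin <- Cin; e$Fout <- Fout
      e$W <- matrix(stats::rnorm(k * k * Cin * Fout, sd = sqrt(2 / (k * k * Cin))),
                    k * k * Cin, Fout)
      e$b <- numeric(Fout)
    } else if (l$kind == "BN") {
      nc <- if (length(shp) == 3L) shp[3] else shp
      e$spatial <- length(shp) == 3L
      e$C <- nc
      e$gamma <- rep(1, nc); e$beta <- numeric(nc)
      e$rmean <- numeric(nc); e$rvar <- rep(1, nc)
    } else if (l$kind %in% c("MP", "AP")) {
      e$pool <- l$params$pool
    } else if (l$kind == "DO") {
      e$rate <- l$params$rate
    } else if (l$kind == "DE") {
      e <- mk_dense(shp, l$params$units, "relu")
    }
    layers[[length(layers) + 1L]] <- e
    shp <- shapes[[i]]
  }
  layers[[length(layers) + 1L]] <- mk_dense(out_shape, as.integer(n_classes), "linear")
  net <- structure(list(layers = layers, arch = arch,
                        input_shape = as.integer(input_shape),
                        n_classes = as.integer(n_classes)),
                   class = "swarm_network")
  net
}

#' Trainable parameter count of an instantiated network (head included)
#' @param net a `swarm_network`.
#' @return numeric count.
#' @export
network_parameters <- function(net) {
  stopifnot(inherits(net, "swarm_network"))
  tot <- 0
  for (e in net$layers) {
    if (e$type %in% c("C2D", "DE")) tot <- tot + length(e$W) + length(e$b)
    if (e$type == "BN") tot <- tot + 2 * e$C
  }
  tot
}

# ---- layer forward / backward ----------------------------------------------

conv_fwd <- function(e, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; k <- e$k
  padT <- (k - 1L) %/% 2L; padB <- k - 1L - padT
  P <- array(0, c(H + k - 1L, W + k - 1L, C, N))
  P[padT + seq_len(H), padT + seq_len(W), , ] <- x
  X <- matrix(0, H * W * N, k * k * C)
  col <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    patch <- P[i:(i + H - 1L), j:(j + W - 1L), , , drop = FALSE]
    X[, col + seq_len(C)] <- matrix(aperm(patch, c(1, 2, 4, 3)), H * W * N, C)
    col <- col + C
  }
  Y <- X %*% e$W
  Y <- sweep(Y, 2, e$b, "+")
  pre <- aperm(array(Y, c(H, W, N, e$Fout)), c(1, 2, 4, 3))
  out <- pre
  out[out < 0] <- 0
  list(out = out, cache = list(X = X, mask = pre > 0, H = H, W = W, C = C, N = N,
                               padT = padT))
}

conv_bwd <- function(e, cache, dout) {
  dout <- dout * cache$mask
  H <- cache$H; W <- cache$W; C <- cache$C; N <- cache$N; k <- e$k
  dYm <- matrix(aperm(dout, c(1, 2, 4, 3)), H * W * N, e$Fout)
  e$dW <- crossprod(cache$X, dYm)
  e$db <- colSums(dYm)
  dX <- dYm %*% t(e$W)
  dP <- array(0, c(H + k - 1L, W + k - 1L, C, N))
  col <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    blk <- aperm(array(dX[, col + seq_len(C)], c(H, W, N, C)), c(1, 2, 4, 3))
    dP[i:(i + H - 1L), j:(j + W - 1L), , ] <-
      dP[i:(i + H - 1L), j:(j + W - 1L), , , drop = FALSE] + blk
    col <- col + C
  }
  padT <- cache$padT
  dP[padT + seq_len(H), padT + seq_len(W), , , drop = FALSE]
}

pool_fwd <- function(e, x, type) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; p <- e$pool
  Ho <- H %/% p; Wo <- W %/% p
  if (Ho < 1L || Wo < 1L) stop("pooling below 1x1 at runtime")
  rows <- function(i) seq(i, Ho * p, by = p)
  cols <- function(j) seq(j, Wo * p, by = p)
  if (type == "MP") {
    out <- array(-Inf, c(Ho, Wo, C, N))
    idx <- array(0L, c(Ho, Wo, C, N))
    o <- 0L
    for (j in seq_len(p)) for (i in seq_len(p)) {
      o <- o + 1L
      s <- x[rows(i), cols(j), , , drop = FALSE]
      upd <- s > out
      out[upd] <- s[upd]
      idx[upd] <- o
    }
    list(out = out, cache = list(idx = idx, H = H, W = W, C = C, N = N))
  } else {
    out <- array(0, c(Ho, Wo, C, N))
    for (j in seq_len(p)) for (i in seq_len(p)) {
      out <- out + x[rows(i), cols(j), , , drop = FALSE]
    }
    list(out = out / (p * p), cache = list(H = H, W = W, C = C, N = N))
  }
}

pool_bwd <- function(e, cache, dout, type) {
  p <- e$pool
  d <- dim(dout); Ho <- d[1]; Wo <- d[2]
  dx <- array(0, c(cache$H, cache$W, cache$C, cache$N))
  rows <- function(i) seq(i, Ho * p, by = p)
  cols <- function(j) seq(j, Wo * p, by = p)
  o <- 0L
  for (j in seq_len(p)) for (i in seq_len(p)) {
    o <- o + 1L
    g <- if (type == "MP") dout * (cache$idx == o) else dout / (p * p)
    dx[rows(i), cols(j), , ] <- dx[rows(i), cols(j), , , drop = FALSE] + g
  }
  dx
}

bn_fwd <- function(e, x, training, momentum = 0.9, eps = 1e-5) {
  spatial <- length(dim(x)) == 4L
  if (spatial) {
    d <- dim(x)
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  } else xm <- x
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    e$rmean <- momentum * e$rmean + (1 - momentum) * mu
    e$rvar <- momentum * e$rvar + (1 - momentum) * v
  } else {
    mu <- e$rmean; v <- e$rvar
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
  ym <- sweep(sweep(xhat, 2, e$gamma, "*"), 2, e$beta, "+")
  out <- if (spatial) {
    d <- dim(x)
    aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else ym
  list(out = out, cache = list(xhat = xhat, istd = istd, spatial = spatial,
                               dims = dim(x)))
}

bn_bwd <- function(e, cache, dout) {
  if (cache$spatial) {
    d <- cache$dims
    dym <- matrix(aperm(dout, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  } else dym <- dout
  xhat <- cache$xhat
  e$dgamma <- colSums(dym * xhat)
  e$dbeta <- colSums(dym)
  m <- nrow(dym)
  t1 <- sweep(dym, 2, colMeans(dym))
  t2 <- sweep(xhat, 2, colMeans(dym * xhat), "*")
  dxm <- sweep(t1 - t2, 2, e$gamma * cache$istd, "*")
  if (cache$spatial) {
    d <- cache$dims
    aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else dxm
}

dense_fwd <- function(e, x) {
  pre <- sweep(x %*% e$W, 2, e$b, "+")
  out <- if (e$act == "relu") pmax(pre, 0) else pre
  list(out = out, cache = list(x = x, mask = if (e$act == "relu") pre > 0 else NULL))
}

dense_bwd <- function(e, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  e$dW <- crossprod(cache$x, dout)
  e$db <- colSums(dout)
  dout %*% t(e$W)
}

net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    e <- net$layers[[i]]
    r <- switch(e$type,
      C2D = conv_fwd(e, x),
      MP  = pool_fwd(e, x, "MP"),
      AP  = pool_fwd(e, x, "AP"),
      BN  = bn_fwd(e, x, training),
      DO  = {
        if (training) {
          mask <- array(stats::runif(length(x)) >= e$rate, dim = dim(x) %||% length(x))
          list(out = x * mask / (1 - e$rate), cache = list(mask = mask))
        } else list(out = x, cache = NULL)
      },
      F   = {
        d <- dim(x)
        list(out = t(matrix(x, prod(d[1:3]), d[4])), cache = list(dims = d))
      },
      DE  = dense_fwd(e, x)
    )
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(logits = x, caches = caches)
}

net_backward <- function(net, caches, dlogits) {
  g <- dlogits
  for (i in rev(seq_along(net$layers))) {
    e <- net$layers[[i]]
    g <- switch(e$type,
      C2D = conv_bwd(e, caches[[i]], g),
      MP  = pool_bwd(e, caches[[i]], g, "MP"),
      AP  = pool_bwd(e, caches[[i]], g, "AP"),
      BN  = bn_bwd(e, caches[[i]], g),
      DO  = g * caches[[i]]$mask / (1 - e$rate),
      F   = array(t(g), caches[[i]]$dims),
      DE  = dense_bwd(e, caches[[i]], g)
    )
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

adam_step <- function(net, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  net$t_adam <- (net$t_adam %||% 0) + 1
  t <- net$t_adam
  for (e in net$layers) {
    slots <- if (e$type %in% c("C2D", "DE")) c("W", "b")
             else if (e$type == "BN") c("gamma", "beta") else character(0)
    for (s in slots) {
      gname <- paste0("d", sub("W", "W", s))
      g <- switch(s, W = e$dW, b = e$db, gamma = e$dgamma, beta = e$dbeta)
      if (is.null(g)) next
      ms <- paste0("m_", s); vs <- paste0("v_", s)
      if (is.null(e[[ms]])) { e[[ms]] <- g * 0; e[[vs]] <- g * 0 }
      e[[ms]] <- beta1 * e[[ms]] + (1 - beta1) * g
      e[[vs]] <- beta2 * e[[vs]] + (1 - beta2) * g^2
      mhat <- e[[ms]] / (1 - beta1^t)
      vhat <- e[[vs]] / (1 - beta2^t)
      e[[s]] <- e[[s]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  net
}

# ---- prediction / training --------------------------------------------------

#' Predict class probabilities
#'
#' @param net a `swarm_network`.
#' @param x image array `(H, W, C, N)`.
#' @param batch_size prediction chunk size.
#' @return `N x n_classes` probability matrix.
#' @export
predict_network <- function(net, x, batch_size = 64L) {
  n <- dim(x)[4]
  out <- matrix(0, n, net$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- x[, , , idx, drop = FALSE]
    out[idx, ] <- softmax_rows(net_forward(net, xb, training = FALSE)$logits)
  }
  out
}

#' Train a network with minibatch Adam
#'
#' Cross-entropy loss; optional early stopping on validation accuracy with
#' `patience` non-improving epochs (a minimum of one epoch is always run).
#' When a validation split is given and `restore_best` is `TRUE`, the
#' parameters from the best-validation-accuracy epoch are restored at the
#' end, so the returned network is the best checkpoint rather than the
#' last. A non-finite loss marks the run as diverged and training stops.
#'
#' @param net a `swarm_network` (modified in place and returned).
#' @param x,y training images `(H, W, C, N)` and integer labels in
#'   `0..n_classes-1`.
#' @param epochs number of passes over the data (0 = no training).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param x_val,y_val optional validation split for early stopping.
#' @param patience early-stop rounds (0 disables early stopping).
#' @param restore_best keep the best-validation checkpoint (default TRUE
#'   when a validation split is supplied).
#' @return list with `net`, per-epoch `history` (loss, val_accuracy),
#'   `best_epoch`, `diverged` flag.
#' @export
train_network <- function(net, x, y, epochs = 1L, batch_size = 32L, lr = 1e-3,
                          x_val = NULL, y_val = NULL, patience = 0L,
                          restore_best = TRUE) {
  n <- dim(x)[4]
  y1 <- as.integer(y) + 1L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_accuracy = numeric(0))
  diverged <- FALSE
  best_val <- -Inf; bad <- 0L; best_epoch <- NA_integer_
  snapshot <- NULL
  param_slots <- c("W", "b", "gamma", "beta", "rmean", "rvar")
  take_snapshot <- function() {
    lapply(net$layers, function(e) {
      s <- list()
      for (p in param_slots) if (!is.null(e[[p]])) s[[p]] <- e[[p]]
      s
    })
  }
  if (epochs >= 1L) for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y1[idx]
      fw <- net_forward(net, xb, training = TRUE)
      probs <- softmax_rows(fw$logits)
      m <- length(idx)
      loss <- -mean(log(pmax(probs[cbind(seq_len(m), yb)], 1e-12)))
      if (!is.finite(loss)) { diverged <- TRUE; break }
      onehot <- matrix(0, m, net$n_classes)
      onehot[cbind(seq_len(m), yb)] <- 1
      net_backward(net, fw$caches, (probs - onehot) / m)
      net <- adam_step(net, lr = lr)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    if (diverged) break
    va <- NA_real_
    if (!is.null(x_val)) {
      pv <- predict_network(net, x_val, batch_size)
      va <- mean(max.col(pv) - 1L == as.integer(y_val))
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / max(nb, 1L),
                                   val_accuracy = va))
    if (!is.na(va)) {
      if (va > best_val + 1e-12) {
        best_val <- va; bad <- 0L; best_epoch <- ep
        if (restore_best) snapshot <- take_snapshot()
      } else {
        bad <- bad + 1L
        if (patience > 0L && bad >= patience) break
      }
    }
  }
  if (!is.null(snapshot) && !diverged) {
    for (i in seq_along(net$layers)) {
      for (p in names(snapshot[[i]])) net$layers[[i]][[p]] <- snapshot[[i]][[p]]
    }
  }
  list(net = net, history = hist, best_epoch = best_epoch, diverged = diverged)
}
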