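# Edge-aware message-passing network (GINE-style) for per-atom binary
# classification, implemented directly on dense matrices with explicit
# backpropagation. Layout per model:
#   L conv layers:  msg = relu(h[src] + E %*% We + be)
#                   z   = (h + sum_in msg) %*% W + b ; batchnorm ; leakyrelu
#   context pool:   u = [h, sum-pooled graph vector broadcast to nodes]
#   head:           n_mlp hidden layers (linear, batchnorm, leakyrelu,
#                   dropout), then linear -> sigmoid

#' GNN model configuration
#'
#' @param n_conv_layers Number of graph-convolution layers (default 4).
#' @param hidden_width Width of the convolution layers (default 500).
#' @param mlp_width Width of the classification-head hidden layers
#'   (default 888).
#' @param n_mlp_hidden_layers Hidden layers in the head (default 2).
#' @param dropout_rate Dropout rate in the head (default 0.2).
#' @param leaky_slope Negative slope of the leaky ReLU (default 0.01).
#' @param d_node,d_edge Input feature widths; defaults match
#'   [node_features()]/[edge_features()] under the default
#'   [feature_config()].
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_conv_layers = 4L, hidden_width = 500L,
                         mlp_width = 888L, n_mlp_hidden_layers = 2L,
                         dropout_rate = 0.2, leaky_slope = 0.01,
                         d_node = 27L, d_edge = 6L) {
  if (n_conv_layers < 1 || hidden_width < 1 || mlp_width < 1 ||
      n_mlp_hidden_layers < 1) {
    stop("config error: layer counts and widths must be positive")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("config error: dropout_rate must lie in [0, 1)")
  }
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 hidden_width = as.integer(hidden_width),
                 mlp_width = as.integer(mlp_width),
                 n_mlp_hidden_layers = as.integer(n_mlp_hidden_layers),
                 dropout_rate = dropout_rate, leaky_slope = leaky_slope,
                 d_node = as.integer(d_node), d_edge = as.integer(d_edge)),
            class = "model_config")
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise one ensemble member
#'
#' Deterministic given `(config, seed)`: the seed drives Glorot-uniform
#' weight initialisation (and later, batch shuffling during training).
#'
#' @param config A [model_config()].
#' @param seed Integer seed recorded in the returned object.
#' @return An object of class `model_parameters`: named list of weight
#'   matrices/vectors, batch-norm states, `config` and `seed`.
#' @export
init_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  H <- config$hidden_width
  par <- list(); bn <- list()
  d_in <- config$d_node
  for (l in seq_len(config$n_conv_layers)) {
    par[[paste0("We", l)]] <- .glorot(config$d_edge, d_in)
    par[[paste0("be", l)]] <- numeric(d_in)
    # the linear layers feeding batch norm carry no bias (redundant: the
    # normalization removes it and beta takes its role)
    par[[paste0("W", l)]] <- .glorot(d_in, H)
    par[[paste0("gamma", l)]] <- rep(1, H)
    par[[paste0("beta", l)]] <- numeric(H)
    bn[[paste0("conv", l)]] <- list(mean = numeric(H), var = rep(1, H))
    d_in <- H
  }
  d_u <- 2L * H
  for (m in seq_len(config$n_mlp_hidden_layers)) {
    par[[paste0("Wm", m)]] <- .glorot(d_u, config$mlp_width)
    par[[paste0("gammam", m)]] <- rep(1, config$mlp_width)
    par[[paste0("betam", m)]] <- numeric(config$mlp_width)
    bn[[paste0("mlp", m)]] <- list(mean = numeric(config$mlp_width),
                                   var = rep(1, config$mlp_width))
    d_u <- config$mlp_width
  }
  par[["Wout"]] <- .glorot(d_u, 1L)
  par[["bout"]] <- numeric(1)
  structure(list(par = par, bn = bn, config = config, seed = as.integer(seed)),
            class = "model_parameters")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Assemble a mini-batch from featurized molecules
#'
#' Stacks node/edge feature matrices of several molecules into one
#' block-diagonal batch with global node indexing.
#'
#' @param feats List with one element per molecule, each a list with `X`
#'   (node features), `E` (edge features with `src`/`dst` attributes) and
#'   optionally `y` (labels).
#' @return A `gnn_batch`: `X`, `E`, `src`, `dst`, `graph_id`, `n_graphs`,
#'   `y`.
#' @export
gnn_batch <- function(feats) {
  offs <- 0L; Xs <- list(); Es <- list(); src <- integer(0); dst <- integer(0)
  gid <- integer(0); y <- integer(0)
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    Xs[[k]] <- f$X
    Es[[k]] <- f$E
    src <- c(src, attr(f$E, "src") + offs)
    dst <- c(dst, attr(f$E, "dst") + offs)
    gid <- c(gid, rep(k, nrow(f$X)))
    if (!is.null(f$y)) y <- c(y, f$y)
    offs <- offs + nrow(f$X)
  }
  X <- do.call(rbind, Xs)
  m <- length(src)
  # sparse scatter matrices: S_dst %*% msg sums incoming messages per node,
  # S_src^T scatters node gradients back to directed edges
  structure(list(X = X, E = do.call(rbind, Es),
                 src = src, dst = dst, graph_id = gid,
                 n_graphs = length(feats),
                 dst_unique = sort(unique(dst)),
                 src_unique = sort(unique(src)),
                 y = if (length(y)) y else NULL),
            class = "gnn_batch")
}

# recycle a length-k vector across the rows of an n x k matrix
.byrow <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# scatter-add rows of `val` (one per directed edge) onto the `n` nodes
# indexed by `idx`; `idx_unique` is the precomputed sorted unique index set
.scatter_add <- function(n, idx, idx_unique, val) {
  out <- matrix(0, n, ncol(val))
  out[idx_unique, ] <- rowsum(val, group = idx, reorder = TRUE)
  out
}

.lrelu <- function(x, slope) x * (slope + (1 - slope) * (x > 0))

# batch norm, normalization and affine fused into one scale/shift;
# training mode caches (z, mu, sd_inv) for the backward pass
.bn_forward <- function(z, gamma, beta, state, training, momentum = 0.1,
                        eps = 1e-5) {
  if (training && nrow(z) > 1) {
    mu <- colMeans(z)
    v <- colMeans(z^2) - mu^2
    v[v < 0] <- 0
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean; v <- state$var
  }
  sd_inv <- 1 / sqrt(v + eps)
  n <- nrow(z)
  a <- gamma * sd_inv
  out <- z * .byrow(a, n) + .byrow(beta - mu * a, n)
  list(out = out, z = z, mu = mu, sd_inv = sd_inv, state = state)
}

.bn_backward <- function(dout, bnc, gamma, training) {
  n <- nrow(dout)
  xhat <- (bnc$z - .byrow(bnc$mu, n)) * .byrow(bnc$sd_inv, n)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  if (training) {
    t1 <- dout - .byrow(colMeans(dout), n)
    t2 <- xhat * .byrow(colMeans(dout * xhat), n)
    dx <- (t1 - t2) * .byrow(gamma * bnc$sd_inv, n)
  } else {
    dx <- dout * .byrow(gamma * bnc$sd_inv, n)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Forward pass. training=TRUE uses batch statistics, applies dropout with
# the member's RNG stream and caches intermediates for the backward pass.
.gnn_forward <- function(model, batch, training = FALSE) {
  cfg <- model$config; par <- model$par
  slope <- cfg$leaky_slope
  n <- nrow(batch$X)
  h <- batch$X
  cache <- list(h_in = list(), premsg = list(), agg = list(), bnc = list(),
                act = list())
  for (l in seq_len(cfg$n_conv_layers)) {
    Eproj <- batch$E %*% par[[paste0("We", l)]] +
      .byrow(par[[paste0("be", l)]], nrow(batch$E))
    premsg <- h[batch$src, , drop = FALSE] + Eproj
    msg <- premsg * (premsg > 0)
    agg <- h + .scatter_add(n, batch$dst, batch$dst_unique, msg)
    z <- agg %*% par[[paste0("W", l)]]
    bnf <- .bn_forward(z, par[[paste0("gamma", l)]], par[[paste0("beta", l)]],
                       model$bn[[paste0("conv", l)]], training)
    model$bn[[paste0("conv", l)]] <- bnf$state
    a <- .lrelu(bnf$out, slope)
    if (training) {
      cache$h_in[[l]] <- h; cache$premsg[[l]] <- premsg
      cache$agg[[l]] <- agg
      cache$bnc[[l]] <- bnf[c("z", "mu", "sd_inv")]
      cache$act[[l]] <- bnf$out
    }
    h <- a
  }
  g <- rowsum(h, group = batch$graph_id)
  ctx <- g[batch$graph_id, , drop = FALSE]
  u <- cbind(h, ctx)
  cache$h_final <- h; cache$u <- u
  cache$mlp <- list()
  x <- u
  for (m in seq_len(cfg$n_mlp_hidden_layers)) {
    z <- x %*% par[[paste0("Wm", m)]]
    bnf <- .bn_forward(z, par[[paste0("gammam", m)]],
                       par[[paste0("betam", m)]],
                       model$bn[[paste0("mlp", m)]], training)
    model$bn[[paste0("mlp", m)]] <- bnf$state
    a <- .lrelu(bnf$out, slope)
    if (training && cfg$dropout_rate > 0) {
      mask <- (matrix(stats::runif(length(a)), nrow(a)) >=
                 cfg$dropout_rate) / (1 - cfg$dropout_rate)
      a <- a * mask
    } else mask <- NULL
    if (training) {
      cache$mlp[[m]] <- list(x = x, bn = bnf[c("z", "mu", "sd_inv")],
                             preact = bnf$out, mask = mask)
    }
    x <- a
  }
  logit <- unname(drop(x %*% par[["Wout"]])) + par[["bout"]]
  p <- 1 / (1 + exp(-logit))
  cache$head_in <- x
  list(p = p, logit = logit, cache = if (training) cache else NULL,
       model = model)
}

# Backward pass given dL/dlogit; returns gradients in the same structure as
# model$par.
.gnn_backward <- function(model, batch, cache, dlogit) {
  cfg <- model$config; par <- model$par
  slope <- cfg$leaky_slope
  n <- nrow(batch$X)
  grads <- list()
  dlogit <- matrix(dlogit, ncol = 1)
  grads[["Wout"]] <- crossprod(cache$head_in, dlogit)
  grads[["bout"]] <- sum(dlogit)
  dx <- dlogit %*% t(par[["Wout"]])
  for (m in rev(seq_len(cfg$n_mlp_hidden_layers))) {
    mc <- cache$mlp[[m]]
    if (!is.null(mc$mask)) dx <- dx * mc$mask
    dpre <- dx * (slope + (1 - slope) * (mc$preact > 0))
    bnb <- .bn_backward(dpre, mc$bn, par[[paste0("gammam", m)]],
                        training = TRUE)
    grads[[paste0("gammam", m)]] <- bnb$dgamma
    grads[[paste0("betam", m)]] <- bnb$dbeta
    dz <- bnb$dx
    grads[[paste0("Wm", m)]] <- crossprod(mc$x, dz)
    dx <- dz %*% t(par[[paste0("Wm", m)]])
  }
  H <- cfg$hidden_width
  dh <- dx[, seq_len(H), drop = FALSE]
  dctx <- dx[, H + seq_len(H), drop = FALSE]
  dg <- rowsum(dctx, group = batch$graph_id)
  dh <- dh + dg[batch$graph_id, , drop = FALSE]
  for (l in rev(seq_len(cfg$n_conv_layers))) {
    dpre <- dh * (slope + (1 - slope) * (cache$act[[l]] > 0))
    bnb <- .bn_backward(dpre, cache$bnc[[l]], par[[paste0("gamma", l)]],
                        training = TRUE)
    grads[[paste0("gamma", l)]] <- bnb$dgamma
    grads[[paste0("beta", l)]] <- bnb$dbeta
    dz <- bnb$dx
    grads[[paste0("W", l)]] <- crossprod(cache$agg[[l]], dz)
    dagg <- dz %*% t(par[[paste0("W", l)]])
    dmsg <- dagg[batch$dst, , drop = FALSE]
    dpremsg <- dmsg * (cache$premsg[[l]] > 0)
    grads[[paste0("We", l)]] <- crossprod(batch$E, dpremsg)
    grads[[paste0("be", l)]] <- colSums(dpremsg)
    dh <- dagg + .scatter_add(n, batch$src, batch$src_unique, dpremsg)
  }
  grads
}

#' Forward pass of a single model
#'
#' Runs the network in inference mode (running batch-norm statistics,
#' dropout disabled): outputs are deterministic, lie strictly in (0, 1),
#' are equivariant under atom renumbering and independent of which other
#' molecules share the batch.
#'
#' @param model A [init_model()] `model_parameters` object.
#' @param batch A [gnn_batch()] (or list of per-molecule feature lists,
#'   which is converted).
#' @return Numeric vector of per-atom SOM probabilities.
#' @export
gnn_forward <- function(model, batch) {
  stopifnot(inherits(model, "model_parameters"))
  if (!inherits(batch, "gnn_batch")) batch <- gnn_batch(batch)
  if (ncol(batch$X) != model$config$d_node ||
      ncol(batch$E) != model$config$d_edge) {
    stop("contract error: feature widths do not match model config")
  }
  .gnn_forward(model, batch, training = FALSE)$p
}

# AdamW step; state holds first/second moments and the step counter.
.adamw_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 1e-2) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  decayed <- c("Wout", grep("^W(e?)[0-9]+$|^Wm[0-9]+$", names(par),
                            value = TRUE))
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    wd <- if (nm %in% decayed) weight_decay * par[[nm]] else 0
    par[[nm]] <- par[[nm]] - lr * (upd + wd)
  }
  list(par = par, state = state)
}
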