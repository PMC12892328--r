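# Batched training engine.  Graphs in a minibatch are stacked into one
# node-feature matrix plus an edge list (block-diagonal adjacency), so a
# whole batch is processed with a handful of matrix products and grouped
# sums; gradients are analytic.  The single-graph layer primitives in
# gnn_layers.R define the semantics; the test suite checks the two paths
# agree and validates every gradient against finite differences.

prepare_graph <- function(g) {
  A <- as.matrix(g$adj)
  n <- nrow(A)
  idx <- which(A == 1, arr.ind = TRUE)
  r <- idx[, 1]; s <- idx[, 2]
  d <- rowSums(A)
  list(x = as.matrix(g$x), n = n, r = r, s = s, self = r == s,
       coef = 1 / sqrt(d[r] * d[s]), label = g$label)
}

make_batch <- function(prepared) {
  ns <- vapply(prepared, `[[`, 0L, "n")
  offsets <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(prepared, `[[`, "x"))
  r <- unlist(mapply(function(p, o) p$r + o, prepared, offsets,
                     SIMPLIFY = FALSE))
  s <- unlist(mapply(function(p, o) p$s + o, prepared, offsets,
                     SIMPLIFY = FALSE))
  self <- unlist(lapply(prepared, `[[`, "self"))
  coef <- unlist(lapply(prepared, `[[`, "coef"))
  n_nodes_total <- sum(ns)
  graph_id <- rep(seq_along(prepared), ns)
  ord <- order(r, s)
  r <- r[ord]; s <- s[ord]; self <- self[ord]; coef <- coef[ord]
  # edges sorted by receiver: ragged receiver groups as an NA-padded index
  # matrix, so per-receiver maxima reduce to a few column-wise pmax calls
  deg <- tabulate(r, n_nodes_total)
  maxdeg <- max(deg)
  gidx <- matrix(NA_integer_, n_nodes_total, maxdeg)
  gidx[cbind(r, sequence(deg))] <- seq_along(r)
  self_edge_of_node <- which(self)[order(r[self])]
  list(X = X, r = r, s = s, self = self, coef = coef,
       graph_id = graph_id, n_graphs = length(prepared),
       n_nodes = ns, n_total = n_nodes_total, gidx = gidx,
       self_edge_of_node = self_edge_of_node,
       labels = vapply(prepared, function(p) p$label %||% NA_real_, 0),
       edge_order = ord)
}

agg_rows <- function(m, group, n) {
  out <- matrix(0, n, ncol(m))
  if (!nrow(m)) return(out)
  rs <- rowsum(m, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# per-receiver maximum over the NA-padded edge-index matrix (column-wise
# pmax; the first column is never NA because every node has a self-loop)
group_max <- function(v, gidx) {
  m <- matrix(v[gidx], nrow(gidx))
  out <- m[, 1]
  if (ncol(m) > 1)
    for (k in 2:ncol(m)) out <- pmax(out, m[, k], na.rm = TRUE)
  out
}

agg_vec <- function(v, group, n) {
  out <- numeric(n)
  if (!length(v)) return(out)
  rs <- rowsum(matrix(v, ncol = 1), group)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

draw_dropout_masks <- function(config, dims) {
  p <- config$dropout_rate
  lapply(dims, function(d) {
    if (p == 0) NULL
    else matrix(stats::rbinom(prod(d), 1, 1 - p), d[1], d[2]) / (1 - p)
  })
}

apply_mask <- function(m, mask) if (is.null(mask)) m else m * mask

# Forward pass over a batch.  `ew` is an optional per-edge weight vector
# (explainer masks); `masks` an optional list of pre-drawn dropout masks
# (training).  Returns predictions and a cache for the backward pass.
engine_forward <- function(batch, params, config, ew = NULL, masks = NULL) {
  if (is.null(ew)) ew <- rep(1, length(batch$r))
  X <- batch$X
  r <- batch$r; s <- batch$s
  nt <- batch$n_total
  cache <- list(batch = batch, ew = ew, masks = masks, config = config,
                params = params)
  group_mean <- function(node_scores)
    agg_vec(node_scores, batch$graph_id, batch$n_graphs) / batch$n_nodes
  if (config$architecture == "GCN") {
    cw <- batch$coef * ew
    P1 <- X %*% params$W1
    M1 <- agg_rows(cw * P1[s, , drop = FALSE], r, nt)
    Z1 <- relu(M1)
    D1 <- apply_mask(Z1, masks[[1]])
    P2 <- D1 %*% params$W2
    M2 <- agg_rows(cw * P2[s, , drop = FALSE], r, nt)
    pred <- group_mean(M2[, 1])
    cache <- c(cache, list(P1 = P1, M1 = M1, D1 = D1, P2 = P2))
  } else if (config$architecture == "GIN") {
    ns <- !batch$self
    wself <- ew[batch$self_edge_of_node]
    S <- agg_rows(ew[ns] * X[s[ns], , drop = FALSE], r[ns], nt)
    pre <- (1 + params$eps) * wself * X + S
    U <- sweep(pre %*% params$W1, 2, params$b1, `+`)
    V <- relu(U)
    G <- sweep(V %*% params$W2, 2, params$b2, `+`)
    Z <- relu(G)
    D <- apply_mask(Z, masks[[1]])
    q <- agg_rows(D, batch$graph_id, batch$n_graphs)
    if (config$pooling == "mean") q <- q / batch$n_nodes
    pred <- as.numeric(q %*% params$Wout + params$bout)
    cache <- c(cache, list(wself = wself, pre = pre, U = U, V = V, G = G,
                           D = D, q = q))
  } else {  # GAT
    l1 <- gat_head_forward_batch(batch, X, params$heads1, ew)
    A1 <- relu(l1$H)
    D <- apply_mask(A1, masks[[1]])
    l2 <- gat_head_forward_batch(batch, D, list(params$head2), ew)
    pred <- group_mean(l2$H[, 1])
    cache <- c(cache, list(l1 = l1, A1 = A1, D = D, l2 = l2))
  }
  cache$pred <- pred
  cache
}

gat_head_forward_batch <- function(batch, X, heads, ew) {
  r <- batch$r; s <- batch$s
  nt <- batch$n_total
  per_head <- lapply(heads, function(hd) {
    Z <- X %*% t(hd$Ws)
    Tm <- X %*% t(hd$Wt)
    U <- Z[r, , drop = FALSE] + Tm[s, , drop = FALSE]
    G <- leaky_relu(U)
    sc <- as.numeric(G %*% hd$a)
    gmax <- group_max(sc, batch$gidx)
    e <- exp(sc - gmax[r])
    den <- agg_vec(e, r, nt)
    alpha <- e / den[r]
    q <- Tm[s, , drop = FALSE]
    q[batch$self, ] <- Z[r[batch$self], , drop = FALSE]
    msg <- (alpha * ew) * q
    Hh <- agg_rows(msg, r, nt)
    list(Z = Z, Tm = Tm, U = U, G = G, alpha = alpha, q = q, Hh = Hh)
  })
  list(H = do.call(cbind, lapply(per_head, `[[`, "Hh")), per_head = per_head)
}

gat_head_backward_batch <- function(batch, X, heads, layer_cache, dH, ew) {
  r <- batch$r; s <- batch$s
  nt <- batch$n_total
  d_prime <- ncol(layer_cache$per_head[[1]]$Z)
  dX <- matrix(0, nrow(X), ncol(X))
  dew <- numeric(length(ew))
  grads <- vector("list", length(heads))
  for (m in seq_along(heads)) {
    hd <- heads[[m]]
    hc <- layer_cache$per_head[[m]]
    cols <- (m - 1L) * d_prime + seq_len(d_prime)
    dHh <- dH[, cols, drop = FALSE]
    dmsg <- dHh[r, , drop = FALSE]
    dot_mq <- rowSums(dmsg * hc$q)
    dalpha <- ew * dot_mq
    dew <- dew + hc$alpha * dot_mq
    dq <- (hc$alpha * ew) * dmsg
    sf <- batch$self
    dZ <- agg_rows(dq[sf, , drop = FALSE], r[sf], nt)
    dT <- agg_rows(dq[!sf, , drop = FALSE], s[!sf], nt)
    gsum <- agg_vec(hc$alpha * dalpha, r, nt)
    dsc <- hc$alpha * (dalpha - gsum[r])
    da <- as.numeric(t(hc$G) %*% dsc)
    dU <- (dsc %o% hd$a) * (1 - 0.8 * (hc$U < 0))
    dZ <- dZ + agg_rows(dU, r, nt)
    dT <- dT + agg_rows(dU, s, nt)
    grads[[m]] <- list(Ws = t(dZ) %*% X, Wt = t(dT) %*% X, a = da)
    dX <- dX + dZ %*% hd$Ws + dT %*% hd$Wt
  }
  list(grads = grads, dX = dX, dew = dew)
}

# Backward pass: gradient of sum(dpred * pred) w.r.t. parameters and,
# when requested, inputs (node features, edge weights).
engine_backward <- function(cache, dpred, want_inputs = FALSE) {
  batch <- cache$batch
  config <- cache$config
  params <- cache$params
  ew <- cache$ew
  X <- batch$X
  r <- batch$r; s <- batch$s
  nt <- batch$n_total
  dnode <- (dpred / batch$n_nodes)[batch$graph_id]
  if (config$architecture == "GCN") {
    cw <- batch$coef * ew
    dM2 <- matrix(dnode, ncol = 1)
    dP2 <- agg_rows(cw * dM2[r, , drop = FALSE], s, nt)
    gW2 <- t(cache$D1) %*% dP2
    dD1 <- dP2 %*% t(params$W2)
    dew2 <- batch$coef * rowSums(dM2[r, , drop = FALSE] *
                                 cache$P2[s, , drop = FALSE])
    dZ1 <- apply_mask(dD1, cache$masks[[1]])
    dM1 <- dZ1 * (cache$M1 > 0)
    dP1 <- agg_rows(cw * dM1[r, , drop = FALSE], s, nt)
    gW1 <- t(X) %*% dP1
    out <- list(grads = list(W1 = gW1, W2 = gW2))
    if (want_inputs) {
      out$dX <- dP1 %*% t(params$W1)
      out$dew <- dew2 + batch$coef * rowSums(dM1[r, , drop = FALSE] *
                                             cache$P1[s, , drop = FALSE])
    }
    out
  } else if (config$architecture == "GIN") {
    dq <- matrix(dpred, ncol = 1) %*% t(params$Wout)
    gWout <- t(cache$q) %*% matrix(dpred, ncol = 1)
    gbout <- sum(dpred)
    dD <- dq[batch$graph_id, , drop = FALSE]
    if (config$pooling == "mean")
      dD <- dD / batch$n_nodes[batch$graph_id]
    dZ <- apply_mask(dD, cache$masks[[1]])
    dG <- dZ * (cache$G > 0)
    gW2 <- t(cache$V) %*% dG
    gb2 <- colSums(dG)
    dV <- dG %*% t(params$W2)
    dU <- dV * (cache$U > 0)
    gW1 <- t(cache$pre) %*% dU
    gb1 <- colSums(dU)
    dpre <- dU %*% t(params$W1)
    ns <- !batch$self
    geps <- sum(cache$wself * rowSums(dpre * X))
    out <- list(grads = list(eps = geps, W1 = gW1, b1 = gb1, W2 = gW2,
                             b2 = gb2, Wout = gWout, bout = gbout))
    if (want_inputs) {
      dX <- (1 + params$eps) * cache$wself * dpre +
        agg_rows(ew[ns] * dpre[r[ns], , drop = FALSE], s[ns], nt)
      dew <- numeric(length(ew))
      dew[batch$self_edge_of_node] <- (1 + params$eps) * rowSums(dpre * X)
      dew[ns] <- rowSums(dpre[r[ns], , drop = FALSE] * X[s[ns], , drop = FALSE])
      out$dX <- dX
      out$dew <- dew
    }
    out
  } else {  # GAT
    dH2 <- matrix(dnode, ncol = 1)
    b2 <- gat_head_backward_batch(batch, cache$D, list(params$head2),
                                  cache$l2, dH2, ew)
    dD <- b2$dX
    dA1 <- apply_mask(dD, cache$masks[[1]])
    dH1 <- dA1 * (cache$l1$H > 0)
    b1 <- gat_head_backward_batch(batch, X, params$heads1, cache$l1, dH1, ew)
    out <- list(grads = list(heads1 = b1$grads, head2 = b2$grads[[1]]))
    if (want_inputs) {
      out$dX <- b1$dX
      out$dew <- b1$dew + b2$dew
    }
    out
  }
}

# ---- loss functions -------------------------------------------------------

#' Regression loss value
#'
#' `"mse"`: mean squared error.  `"l1"`: mean absolute error.
#' `"smooth_l1"` with beta = 0.5: mean of `e^2/(2 beta)` for `|e| < beta`,
#' else `|e| - beta/2`.
#'
#' @param pred,target numeric vectors of equal length.
#' @param kind `"mse"`, `"l1"` or `"smooth_l1"`.
#' @param beta smooth-L1 transition point.
#' @return scalar loss.
#' @export
loss_value <- function(pred, target, kind = c("mse", "l1", "smooth_l1"),
                       beta = 0.5) {
  kind <- match.arg(kind)
  if (!length(pred) || length(pred) != length(target))
    stop("pred and target must be non-empty vectors of equal length")
  e <- pred - target
  switch(kind,
         mse = mean(e^2),
         l1 = mean(abs(e)),
         smooth_l1 = mean(ifelse(abs(e) < beta, e^2 / (2 * beta),
                                 abs(e) - beta / 2)))
}

loss_grad <- function(pred, target, kind, beta = 0.5) {
  e <- pred - target
  n <- length(e)
  switch(kind,
         mse = 2 * e / n,
         l1 = sign(e) / n,
         smooth_l1 = ifelse(abs(e) < beta, e / beta, sign(e)) / n)
}

# ---- parameter-tree utilities and Adam ------------------------------------

param_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i)
      param_map(f, a[[i]], if (is.null(b)) NULL else b[[i]]))
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

adam_init <- function(params)
  list(m = param_map(function(p) p * 0, params),
       v = param_map(function(p) p * 0, params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- param_map(function(m) m / bc1, state$m)
  upd <- param_map(function(m, v) m / (sqrt(v / bc2) + eps), mhat, state$v)
  params <- param_map(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

# dropout mask dimensions of the hidden representation, per architecture
hidden_dims <- function(config, n_nodes) {
  h <- config$hidden_channels
  w <- if (config$architecture == "GAT") config$n_heads * h else h
  list(c(n_nodes, w))
}

#' Predict pKa for a list of graphs
#'
#' Deterministic evaluation-mode forward pass.
#'
#' @param params trained parameters.
#' @param config the matching [model_config()].
#' @param graphs list of [residue_graph()] objects.
#' @return numeric vector of predictions.
#' @export
predict_graphs <- function(params, config, graphs) {
  prepared <- lapply(graphs, prepare_graph)
  batch <- make_batch(prepared)
  engine_forward(batch, params, config)$pred
}

#' Train a model with Adam and early stopping
#'
#' Minibatch gradient training (Adam) with per-epoch validation; stops
#' when the validation loss has not improved for `config$patience`
#' consecutive epochs (or at `config$max_epochs`), and returns the
#' parameters of the best validation epoch.  Fully reproducible given
#' `config$seed`, which drives weight initialization, epoch shuffling
#' and dropout.
#'
#' @param train_graphs,val_graphs non-empty lists of [residue_graph()].
#' @param config a [model_config()].
#' @param verbose print per-epoch losses.
#' @return list with `params` (best epoch), `history` (data frame of
#'   epoch, train and validation loss), `best_epoch`,
#'   `best_val_loss`, `epochs_run`, `config`.
#' @export
train_model <- function(train_graphs, val_graphs, config, verbose = FALSE) {
  if (!length(train_graphs) || !length(val_graphs))
    stop("training and validation sets must be non-empty")
  prepared <- lapply(train_graphs, prepare_graph)
  y_train <- vapply(train_graphs, function(g) g$label, 0)
  if (anyNA(y_train)) stop("training graphs must carry labels")
  val_batch <- make_batch(lapply(val_graphs, prepare_graph))
  y_val <- vapply(val_graphs, function(g) g$label, 0)
  params <- init_params(config, in_dim = ncol(train_graphs[[1]]$x))
  opt <- adam_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  stall <- 0L
  n <- length(prepared)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_loss <- 0
      for (b in starts) {
        take <- idx[b:min(b + config$batch_size - 1L, n)]
        batch <- make_batch(prepared[take])
        masks <- draw_dropout_masks(config, hidden_dims(config, batch$n_total))
        cache <- engine_forward(batch, params, config, masks = masks)
        lv <- loss_value(cache$pred, y_train[take], config$loss)
        if (!is.finite(lv))
          stop("non-finite training loss at epoch ", epoch,
               " (architecture ", config$architecture,
               ", lr ", config$learning_rate, ")")
        dpred <- loss_grad(cache$pred, y_train[take], config$loss)
        bk <- engine_backward(cache, dpred)
        stepped <- adam_step(params, bk$grads, opt, config$learning_rate)
        params <- stepped$params
        opt <- stepped$state
        epoch_loss <- epoch_loss + lv * length(take)
      }
      val_pred <- engine_forward(val_batch, params, config)$pred
      val_loss <- loss_value(val_pred, y_val, config$loss)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                  val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d train %.4f val %.4f", epoch,
                        epoch_loss / n, val_loss))
      if (val_loss < best$val - 1e-12) {
        best <- list(val = val_loss, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  list(params = best$params, history = history, best_epoch = best$epoch,
       best_val_loss = best$val, epochs_run = nrow(history), config = config)
}
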