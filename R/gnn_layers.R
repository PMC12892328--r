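# Graph-network layer primitives, written directly from their
# message-passing update equations.  These single-graph functions are the
# reference semantics; training uses an equivalent batched implementation
# (gnn_engine.R) that is cross-checked against them in the test suite.

relu <- function(x) pmax(x, 0)
# arithmetic form: much faster than ifelse on large matrices
leaky_relu <- function(x, slope = 0.2) x * (1 - (1 - slope) * (x < 0))

check_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(A != t(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 1)) stop("adjacency must carry self-loops (unit diagonal)")
  if (any(!A %in% c(0, 1))) stop("adjacency must be binary")
  A
}

#' Graph convolution layer
#'
#' Symmetric-normalized neighbourhood aggregation: each node's update is
#' the sum over its closed neighbourhood of the shared linear transform
#' of the neighbour features, scaled by `1/sqrt(d_i d_j)` where degrees
#' count the closed neighbourhood (self-loop included), then passed
#' through a rectified linear activation (or left linear for the
#' regression output layer).
#'
#' @param H N x d node feature matrix.
#' @param A adjacency with self-loops (binary, symmetric).
#' @param W d x d' weight matrix.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return N x d' updated node features.
#' @export
gcn_layer <- function(H, A, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  H <- as.matrix(H); A <- check_adjacency(A)
  if (nrow(H) != nrow(A)) stop("H and A disagree on node count")
  if (ncol(H) != nrow(W)) stop("feature width does not match W")
  d <- rowSums(A)
  s <- 1 / sqrt(d)
  out <- (s * (A %*% (s * (H %*% W))))
  if (activation == "relu") relu(out) else out
}

#' Graph isomorphism layer
#'
#' Sums the open-neighbourhood features, adds the node's own features
#' scaled by `(1 + eps)`, and transforms the result with a two-layer MLP
#' (linear - ReLU - linear).  Self-loops in the adjacency are ignored for
#' the neighbour sum; the self term is carried by `(1 + eps)`.
#'
#' @param H N x d node feature matrix.
#' @param A adjacency with self-loops.
#' @param eps learnable scalar weighting the central node.
#' @param mlp list with `W1` (d x h), `b1` (h), `W2` (h x d'), `b2` (d').
#' @return N x d' matrix.
#' @export
gin_layer <- function(H, A, eps, mlp) {
  H <- as.matrix(H); A <- check_adjacency(A)
  if (nrow(H) != nrow(A)) stop("H and A disagree on node count")
  A_open <- A; diag(A_open) <- 0
  pre <- (1 + eps) * H + A_open %*% H
  U <- sweep(pre %*% mlp$W1, 2, mlp$b1, `+`)
  V <- relu(U)
  sweep(V %*% mlp$W2, 2, mlp$b2, `+`)
}

#' Attention coefficients for one GATv2 head
#'
#' For each ordered pair (i, j) in the closed neighbourhood of i, the
#' unnormalized score is `a . LeakyReLU(W_s h_i + W_t h_j)` (negative
#' slope 0.2); coefficients are a softmax over j in N(i) and i itself,
#' computed with max-subtraction for overflow safety.  Rows sum to one
#' over the closed neighbourhood; entries outside it are zero.
#'
#' @param H N x d node features.
#' @param A adjacency with self-loops.
#' @param Ws,Wt d' x d source/target transforms.
#' @param a attention score vector of length d'.
#' @return N x N coefficient matrix.
#' @export
gat_attention <- function(H, A, Ws, Wt, a) {
  H <- as.matrix(H); A <- check_adjacency(A)
  n <- nrow(H)
  Z <- H %*% t(Ws)
  Tm <- H %*% t(Wt)
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    scores <- as.numeric(leaky_relu(sweep(Tm[nb, , drop = FALSE], 2, Z[i, ], `+`)) %*% a)
    e <- exp(scores - max(scores))
    alpha[i, nb] <- e / sum(e)
  }
  alpha
}

#' Multi-head GATv2 layer
#'
#' Per head, the update is `alpha_ii W_s h_i + sum_j alpha_ij W_t h_j`
#' over the open neighbourhood, with coefficients from
#' [gat_attention()]; heads are concatenated in index order.
#'
#' @param H N x d node features.
#' @param A adjacency with self-loops.
#' @param heads list of heads, each a list `Ws`, `Wt` (d' x d), `a` (d').
#' @return N x (M d') matrix.
#' @export
gat_layer <- function(H, A, heads) {
  H <- as.matrix(H); A <- check_adjacency(A)
  out <- lapply(heads, function(hd) {
    alpha <- gat_attention(H, A, hd$Ws, hd$Wt, hd$a)
    Z <- H %*% t(hd$Ws)
    Tm <- H %*% t(hd$Wt)
    alpha_off <- alpha; diag(alpha_off) <- 0
    diag(alpha) * Z + alpha_off %*% Tm
  })
  do.call(cbind, out)
}

#' Permutation-invariant global pooling
#'
#' @param H N x d node representation matrix.
#' @param mode `"mean"` (column means) or `"add"` (column sums).
#' @return d-vector.
#' @export
global_pool <- function(H, mode = c("mean", "add")) {
  mode <- match.arg(mode)
  H <- as.matrix(H)
  if (!nrow(H)) stop("cannot pool an empty graph")
  if (mode == "mean") colMeans(H) else colSums(H)
}

#' Model configuration
#'
#' Gathers every tunable hyperparameter of the three architectures.
#' Grid-search defaults in the study varied hidden channels over
#' 16/32/48/64, batch size over 16/24/32/40, dropout over 0.2-0.5,
#' attention heads over 4/6/8, GIN pooling over mean/add, and the loss
#' over smooth-L1 (beta 0.5), L1 and MSE.
#'
#' @param architecture `"GCN"`, `"GIN"` or `"GAT"`.
#' @param hidden_channels width of the hidden layer.
#' @param dropout_rate dropout fraction applied after the hidden layer.
#' @param n_heads attention heads (GAT only).
#' @param pooling `"mean"` or `"add"` (tunable for GIN; GCN/GAT pool by
#'   mean).
#' @param loss `"mse"`, `"l1"` or `"smooth_l1"` (beta = 0.5).
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed driving weight init, shuffling and dropout.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @return a `model_config` object.
#' @export
model_config <- function(architecture = c("GCN", "GIN", "GAT"),
                         hidden_channels = 32, dropout_rate = 0.2,
                         n_heads = 4, pooling = c("mean", "add"),
                         loss = c("mse", "l1", "smooth_l1"),
                         learning_rate = 0.01, batch_size = 32, seed = 1L,
                         max_epochs = 500L, patience = 20L) {
  architecture <- match.arg(toupper(architecture), c("GCN", "GIN", "GAT"))
  pooling <- match.arg(pooling)
  loss <- match.arg(loss)
  stopifnot(hidden_channels >= 1, dropout_rate >= 0, dropout_rate < 1,
            n_heads >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(architecture = architecture,
                 hidden_channels = as.integer(hidden_channels),
                 dropout_rate = dropout_rate, n_heads = as.integer(n_heads),
                 pooling = pooling, loss = loss,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("model_config %s: hidden %d, dropout %.2f, lr %g, batch %d, loss %s",
              x$architecture, x$hidden_channels, x$dropout_rate,
              x$learning_rate, x$batch_size, x$loss))
  if (x$architecture == "GAT") cat(sprintf(", heads %d", x$n_heads))
  if (x$architecture == "GIN") cat(sprintf(", pooling %s", x$pooling))
  cat(sprintf(", seed %d\n", x$seed))
  invisible(x)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model parameters
#'
#' Glorot-style uniform initialization scaled by fan, seeded from the
#' configuration for reproducibility.  GIN's epsilon starts at zero.
#'
#' @param config a [model_config()].
#' @param in_dim input feature width (26 for the standard schema).
#' @return named list of parameter arrays.
#' @export
init_params <- function(config, in_dim = 26L) {
  h <- config$hidden_channels
  with_seed(config$seed, switch(config$architecture,
    GCN = list(W1 = glorot(in_dim, h), W2 = glorot(h, 1L)),
    GIN = list(eps = 0,
               W1 = glorot(in_dim, h), b1 = numeric(h),
               W2 = glorot(h, h), b2 = numeric(h),
               Wout = glorot(h, 1L), bout = numeric(1)),
    GAT = list(
      heads1 = lapply(seq_len(config$n_heads), function(m)
        list(Ws = t(glorot(in_dim, h)), Wt = t(glorot(in_dim, h)),
             a = stats::runif(h, -sqrt(6 / (h + 1)), sqrt(6 / (h + 1))))),
      head2 = list(Ws = t(glorot(config$n_heads * h, 1L)),
                   Wt = t(glorot(config$n_heads * h, 1L)),
                   a = stats::runif(1, -1, 1)))
  ))
}

#' Forward pass of a configured model on one residue graph
#'
#' Reference single-graph implementation built from the layer
#' primitives.  GCN: graph convolution (26 to hidden, ReLU), dropout,
#' graph convolution (hidden to 1, linear), mean pool.  GIN: GIN layer
#' (MLP to hidden), ReLU, dropout, mean/add pool, linear readout.  GAT:
#' multi-head GATv2 layer (concat), ReLU, dropout, single-head GATv2
#' layer to width 1, mean pool.  Dropout fires only with
#' `training = TRUE` (drawn from the current RNG stream); evaluation is
#' deterministic given the parameters.
#'
#' @param graph a [residue_graph()] (or list with `x` and `adj`).
#' @param config a [model_config()].
#' @param params parameters from [init_params()] or [train_model()].
#' @param training logical; enables (inverted) dropout.
#' @return predicted pKa (scalar).
#' @export
model_forward <- function(graph, config, params, training = FALSE) {
  X <- as.matrix(graph$x)
  A <- as.matrix(graph$adj)
  p <- config$dropout_rate
  dropmask <- function(mat) {
    if (!training || p == 0) return(mat)
    keep <- matrix(stats::rbinom(length(mat), 1, 1 - p), nrow(mat)) / (1 - p)
    mat * keep
  }
  switch(config$architecture,
    GCN = {
      if (ncol(X) != nrow(params$W1)) stop("feature width does not match model")
      Z <- gcn_layer(X, A, params$W1, activation = "relu")
      Z <- dropmask(Z)
      S <- gcn_layer(Z, A, params$W2, activation = "identity")
      as.numeric(global_pool(S, "mean"))
    },
    GIN = {
      if (ncol(X) != nrow(params$W1)) stop("feature width does not match model")
      G <- gin_layer(X, A, params$eps,
                     list(W1 = params$W1, b1 = params$b1,
                          W2 = params$W2, b2 = params$b2))
      Z <- dropmask(relu(G))
      q <- global_pool(Z, config$pooling)
      as.numeric(q %*% params$Wout + params$bout)
    },
    GAT = {
      if (ncol(X) != ncol(params$heads1[[1]]$Ws))
        stop("feature width does not match model")
      H1 <- gat_layer(X, A, params$heads1)
      Z <- dropmask(relu(H1))
      S <- gat_layer(Z, A, list(params$head2))
      as.numeric(global_pool(S, "mean"))
    })
}
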