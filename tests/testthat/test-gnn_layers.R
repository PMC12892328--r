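# Literal, loop-level implementations of the three update equations serve
# as independent oracles for the vectorized layers.

random_adjacency <- function(n) {
  A <- diag(1, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < 0.5) A[i, j] <- A[j, i] <- 1
  A
}

dense_gcn <- function(H, A, W) {
  n <- nrow(H)
  d <- rowSums(A)
  out <- matrix(0, n, ncol(W))
  for (i in 1:n) for (j in 1:n) if (A[i, j] == 1)
    out[i, ] <- out[i, ] + (1 / sqrt(d[i] * d[j])) * as.numeric(H[j, ] %*% W)
  pmax(out, 0)
}

dense_gin <- function(H, A, eps, mlp) {
  n <- nrow(H)
  agg <- matrix(0, n, ncol(H))
  for (i in 1:n) {
    agg[i, ] <- (1 + eps) * H[i, ]
    for (j in setdiff(which(A[i, ] == 1), i)) agg[i, ] <- agg[i, ] + H[j, ]
  }
  u <- sweep(agg %*% mlp$W1, 2, mlp$b1, `+`)
  sweep(pmax(u, 0) %*% mlp$W2, 2, mlp$b2, `+`)
}

dense_lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)

dense_gat_alpha <- function(H, A, Ws, Wt, a) {
  n <- nrow(H)
  alpha <- matrix(0, n, n)
  for (i in 1:n) {
    nb <- which(A[i, ] == 1)
    e <- vapply(nb, function(j)
      exp(sum(a * dense_lrelu(Ws %*% H[i, ] + Wt %*% H[j, ]))), 0)
    alpha[i, nb] <- e / sum(e)
  }
  alpha
}

dense_gat_layer <- function(H, A, heads) {
  do.call(cbind, lapply(heads, function(hd) {
    alpha <- dense_gat_alpha(H, A, hd$Ws, hd$Wt, hd$a)
    n <- nrow(H)
    out <- matrix(0, n, nrow(hd$Ws))
    for (i in 1:n) {
      out[i, ] <- alpha[i, i] * as.numeric(hd$Ws %*% H[i, ])
      for (j in setdiff(which(A[i, ] == 1), i))
        out[i, ] <- out[i, ] + alpha[i, j] * as.numeric(hd$Wt %*% H[j, ])
    }
    out
  }))
}

test_that("gcn_layer matches the dense normalized-aggregation equation", {
  set.seed(41)
  for (draw in 1:50) {
    n <- sample(1:6, 1)
    A <- random_adjacency(n)
    H <- matrix(stats::rnorm(n * 3), n, 3)
    W <- matrix(stats::rnorm(3 * 4), 3, 4)
    expect_equal(gcn_layer(H, A, W), dense_gcn(H, A, W), tolerance = 1e-6)
  }
  # closed forms
  W <- diag(2)
  h <- matrix(c(0.5, 1.2), 1)
  expect_equal(gcn_layer(h, matrix(1), W), h)  # single node, unit normalization
  expect_equal(gcn_layer(matrix(0, 3, 2), random_adjacency(3), W),
               matrix(0, 3, 2))
})

test_that("gin_layer matches the dense (1+eps) + open-neighbourhood sum equation", {
  set.seed(42)
  for (draw in 1:50) {
    n <- sample(1:6, 1)
    A <- random_adjacency(n)
    H <- matrix(stats::rnorm(n * 3), n, 3)
    mlp <- list(W1 = matrix(stats::rnorm(12), 3, 4), b1 = stats::rnorm(4),
                W2 = matrix(stats::rnorm(8), 4, 2), b2 = stats::rnorm(2))
    eps <- stats::rnorm(1)
    expect_equal(gin_layer(H, A, eps, mlp), dense_gin(H, A, eps, mlp),
                 tolerance = 1e-6)
  }
  # identity MLP, eps 0: isolated node keeps its features, an edge sums them
  id_mlp <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  h <- matrix(c(1, 2, 4, 1), 2, byrow = TRUE)  # non-negative: ReLU transparent
  expect_equal(gin_layer(h[1, , drop = FALSE], matrix(1), 0, id_mlp),
               h[1, , drop = FALSE])
  edge <- matrix(1, 2, 2)
  expect_equal(gin_layer(h, edge, 0, id_mlp),
               rbind(h[1, ] + h[2, ], h[1, ] + h[2, ]))
})

test_that("gat attention matches the softmax equation and rows sum to one", {
  set.seed(43)
  for (draw in 1:50) {
    n <- sample(1:6, 1)
    A <- random_adjacency(n)
    H <- matrix(stats::rnorm(n * 3), n, 3)
    hd <- list(Ws = matrix(stats::rnorm(6), 2, 3),
               Wt = matrix(stats::rnorm(6), 2, 3), a = stats::rnorm(2))
    alpha <- gat_attention(H, A, hd$Ws, hd$Wt, hd$a)
    expect_equal(alpha, dense_gat_alpha(H, A, hd$Ws, hd$Wt, hd$a),
                 tolerance = 1e-7)
    expect_equal(unname(rowSums(alpha)), rep(1, n), tolerance = 1e-9)
    expect_true(all(alpha[A == 0] == 0))
  }
  # one-term softmax and the symmetric 2-clique
  h1 <- matrix(c(1, -1), 1)
  hd <- list(Ws = matrix(stats::rnorm(4), 2, 2),
             Wt = matrix(stats::rnorm(4), 2, 2), a = stats::rnorm(2))
  expect_equal(gat_attention(h1, matrix(1), hd$Ws, hd$Wt, hd$a),
               matrix(1))
  h2 <- rbind(c(1, 2), c(1, 2))
  same <- list(Ws = hd$Ws, Wt = hd$Ws, a = hd$a)
  expect_equal(gat_attention(h2, matrix(1, 2, 2), same$Ws, same$Wt, same$a),
               matrix(0.5, 2, 2), tolerance = 1e-12)
})

test_that("gat_layer matches its dense evaluation and concatenates heads", {
  set.seed(44)
  for (draw in 1:50) {
    n <- sample(1:6, 1)
    A <- random_adjacency(n)
    H <- matrix(stats::rnorm(n * 3), n, 3)
    heads <- lapply(1:2, function(m)
      list(Ws = matrix(stats::rnorm(6), 2, 3),
           Wt = matrix(stats::rnorm(6), 2, 3), a = stats::rnorm(2)))
    expect_equal(gat_layer(H, A, heads), dense_gat_layer(H, A, heads),
                 tolerance = 1e-6)
  }
  # output width is M * d-prime for the grid's head counts
  H <- matrix(stats::rnorm(12), 4, 3)
  A <- random_adjacency(4)
  for (M in c(4, 6, 8)) {
    heads <- lapply(seq_len(M), function(m)
      list(Ws = matrix(stats::rnorm(9), 3, 3),
           Wt = matrix(stats::rnorm(9), 3, 3), a = stats::rnorm(3)))
    expect_equal(ncol(gat_layer(H, A, heads)), M * 3)
  }
  # single node, one head: alpha_ii = 1 so output is Ws h
  h1 <- matrix(c(0.4, -0.7, 2), 1)
  hd <- list(Ws = matrix(stats::rnorm(6), 2, 3),
             Wt = matrix(stats::rnorm(6), 2, 3), a = stats::rnorm(2))
  expect_equal(gat_layer(h1, matrix(1), list(hd)),
               matrix(as.numeric(hd$Ws %*% h1[1, ]), 1), tolerance = 1e-12)
})

test_that("global pooling follows its arithmetic definition", {
  H <- matrix(stats::rnorm(15), 5, 3)
  expect_equal(global_pool(H, "mean"), colMeans(H))
  expect_equal(global_pool(H, "add"), colSums(H))
  expect_equal(global_pool(H, "add"), 5 * global_pool(H, "mean"))
  v <- c(1, 2, 3)
  expect_equal(global_pool(rbind(v, v, v), "mean"), v)
  expect_error(global_pool(matrix(0, 0, 3)), "empty")
})

test_that("model_forward: zero params give zero, eval is deterministic, node order irrelevant", {
  g <- toy9_graphs[[2]]
  for (arch in c("GCN", "GIN", "GAT")) {
    cfg <- model_config(arch, hidden_channels = 6, n_heads = 2,
                        dropout_rate = 0.3, seed = 3)
    par <- init_params(cfg)
    zero <- pkagraph:::param_map(function(p) p * 0, par)
    expect_equal(model_forward(g, cfg, zero), 0)
    p1 <- model_forward(g, cfg, par)
    expect_identical(p1, model_forward(g, cfg, par))  # training = FALSE
    # permute nodes and adjacency consistently
    set.seed(8)
    perm <- sample(nrow(g$x))
    gp <- g
    gp$x <- g$x[perm, , drop = FALSE]
    gp$adj <- g$adj[perm, perm]
    expect_equal(model_forward(gp, cfg, par), p1, tolerance = 1e-8)
  }
})
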