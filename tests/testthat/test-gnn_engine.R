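# The batched training engine must agree with the single-graph layer
# semantics and with finite-difference gradients.

numerical_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, 0)
}

test_that("batched forward equals the single-graph reference for all architectures", {
  for (arch in c("GCN", "GIN", "GAT")) {
    cfg <- model_config(arch, hidden_channels = 8, dropout_rate = 0,
                        n_heads = 3, pooling = "add", seed = 11)
    par <- init_params(cfg)
    single <- vapply(toy9_graphs, function(g) model_forward(g, cfg, par), 0)
    expect_equal(predict_graphs(par, cfg, toy9_graphs), single,
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences for parameters, features and edges", {
  set.seed(2)
  y <- stats::rnorm(length(toy9_graphs))
  for (arch in c("GCN", "GIN", "GAT")) {
    cfg <- model_config(arch, hidden_channels = 4, dropout_rate = 0,
                        n_heads = 2, seed = 5, loss = "mse")
    par <- init_params(cfg)
    prepared <- lapply(toy9_graphs, pkagraph:::prepare_graph)
    batch <- pkagraph:::make_batch(prepared)
    cache <- pkagraph:::engine_forward(batch, par, cfg)
    dpred <- pkagraph:::loss_grad(cache$pred, y, "mse")
    bk <- pkagraph:::engine_backward(cache, dpred, want_inputs = TRUE)
    f_par <- function(v)
      loss_value(pkagraph:::engine_forward(batch, utils::relist(v, par),
                                           cfg)$pred, y, "mse")
    expect_lt(max(abs(unlist(bk$grads) - numerical_gradient(f_par, unlist(par)))),
              1e-6)
    X0 <- batch$X
    f_x <- function(v) {
      b <- batch; b$X <- matrix(v, nrow(X0))
      loss_value(pkagraph:::engine_forward(b, par, cfg)$pred, y, "mse")
    }
    expect_lt(max(abs(as.numeric(bk$dX) -
                      numerical_gradient(f_x, as.numeric(X0)))), 1e-6)
    f_ew <- function(v)
      loss_value(pkagraph:::engine_forward(batch, par, cfg, ew = v)$pred,
                 y, "mse")
    expect_lt(max(abs(bk$dew -
                      numerical_gradient(f_ew, rep(1, length(batch$r))))),
              1e-6)
  }
})

test_that("loss functions match their closed forms", {
  x <- c(1, 2, 3)
  for (kind in c("mse", "l1", "smooth_l1"))
    expect_equal(loss_value(x, x, kind), 0)
  expect_equal(loss_value(0.25, 0, "smooth_l1"), 0.0625)  # e^2 / (2 beta)
  expect_equal(loss_value(2, 0, "l1"), 2)
  expect_equal(loss_value(2, 0, "mse"), 4)
  expect_equal(loss_value(2, 0, "smooth_l1"), 1.75)  # |e| - beta/2
  expect_error(loss_value(numeric(0), numeric(0), "mse"), "non-empty")
})

test_that("training is reproducible and early stopping respects its patience", {
  gs <- tiny_planted$graphs
  idx <- seq_along(gs)
  val <- idx[idx %% 4 == 0]
  tr <- setdiff(idx, val)
  cfg <- model_config("GCN", hidden_channels = 8, dropout_rate = 0.2,
                      learning_rate = 0.01, batch_size = 8, seed = 21,
                      max_epochs = 40, patience = 10)
  fit1 <- train_model(gs[tr], gs[val], cfg)
  fit2 <- train_model(gs[tr], gs[val], cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  # stopped no later than best epoch + patience (or the epoch cap)
  expect_lte(fit1$epochs_run,
             min(fit1$best_epoch + cfg$patience, cfg$max_epochs))
  # returned parameters are those of the best epoch
  expect_equal(loss_value(predict_graphs(fit1$params, cfg, gs[val]),
                          vapply(gs[val], function(g) g$label, 0), cfg$loss),
               fit1$best_val_loss, tolerance = 1e-12)
})

test_that("a planted linear mechanism is recovered to near the noise floor", {
  # sigma = 0.1: validation MAE should approach E|N(0, 0.1)| ~ 0.08
  ds <- make_planted_dataset(60, sigma = 0.1, seed = 3,
                             residues_per_protein = 6L)
  idx <- seq_along(ds$graphs)
  val <- idx[idx %% 5 == 0]
  tr <- setdiff(idx, val)
  cfg <- model_config("GCN", hidden_channels = 64, dropout_rate = 0,
                      learning_rate = 0.01, batch_size = 16, seed = 1,
                      max_epochs = 300, patience = 30)
  fit <- train_model(ds$graphs[tr], ds$graphs[val], cfg)
  pred <- predict_graphs(fit$params, cfg, ds$graphs[val])
  yv <- vapply(ds$graphs[val], function(g) g$label, 0)
  expect_lt(mean(abs(pred - yv)), 0.1 + 0.1)
})

test_that("dropout fires only in training mode", {
  g <- toy9_graphs[[1]]
  cfg <- model_config("GCN", hidden_channels = 16, dropout_rate = 0.5,
                      seed = 2)
  par <- init_params(cfg)
  eval1 <- model_forward(g, cfg, par, training = FALSE)
  eval2 <- model_forward(g, cfg, par, training = FALSE)
  expect_identical(eval1, eval2)
  set.seed(1); tr1 <- model_forward(g, cfg, par, training = TRUE)
  set.seed(2); tr2 <- model_forward(g, cfg, par, training = TRUE)
  expect_false(identical(tr1, tr2))
})
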