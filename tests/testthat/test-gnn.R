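# network forward pass, losses, gradients, and the training loop

test_that("state initialization is shaped, seeded, and Glorot-scaled", {
  dims <- gnn_dims(2, 2, 2)
  s1 <- init_gnn_state(10, dims, seed = 3)
  s2 <- init_gnn_state(10, dims, seed = 3)
  s3 <- init_gnn_state(10, dims, seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(s1$Wco_train, s3$Wco_train))
  expect_equal(dim(s1$Wco_train), c(10, 2))
  expect_equal(dim(s1$Winclu_train), c(6, 6))
  expect_equal(length(s1$w_out), 6)
  expect_equal(s1$b_out, 0)
})

test_that("dimension constraint for the MI stage is enforced", {
  expect_error(gnn_dims(2, 2, 2, dsq = 0), "positive")
  fx <- tiny_graph_fixture()
  fit <- train_gnn(fx$graph, fx$corpus, dims = gnn_dims(2, 2, 2, dsq = 5),
                   epochs = 2)
  expect_error(find_motifs(fit, fx$graph, fx$corpus), "dsq = dc \\+ ds \\+ dj")
})

test_that("zero weights propagate to an indifferent classifier", {
  fx <- tiny_graph_fixture()
  state <- init_gnn_state(fx$graph$m, gnn_dims(2, 2, 2), seed = 1)
  for (nm in c("Wco_train", "Wsim_train", "Wjac_train", "Winclu_train")) {
    state[[nm]] <- state[[nm]] * 0
  }
  fwd <- gnn_forward(fx$graph, state)
  expect_equal(unname(fwd$y_hat), rep(0.5, fx$graph$n))
  expect_true(all(fwd$Msc == 0))
})

test_that("forward outputs respect shapes, signs, and view isolation", {
  fx <- tiny_graph_fixture()
  dims <- gnn_dims(2, 3, 4)
  state <- init_gnn_state(fx$graph$m, dims, seed = 2)
  fwd <- gnn_forward(fx$graph, state)
  expect_equal(ncol(fwd$Msc), 9)
  expect_true(all(fwd$Msc >= 0) && all(fwd$Esq >= 0))
  expect_true(all(fwd$y_hat > 0 & fwd$y_hat < 1))
  # flipping the co-occurrence weights cannot touch the other views
  state2 <- state
  state2$Wco_train <- -state2$Wco_train
  fwd2 <- gnn_forward(fx$graph, state2)
  expect_equal(fwd$Msc[, 3:9], fwd2$Msc[, 3:9])
  # shape mismatch is rejected up front
  expect_error(gnn_forward(fx$graph, init_gnn_state(3, dims, seed = 1)),
               "m = 3")
})

test_that("binary cross-entropy and the iterative loss match closed forms", {
  expect_lt(bce_loss(1, 1 - 1e-12), 1e-10)
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(0, 0.5), log(2))
  expect_true(all(bce_loss(c(0, 1), c(0.99, 0.01)) > 0))

  # epoch 1: cached loss is 0, so iterloss reduces to BCE exactly
  expect_equal(iter_loss(0, 0.7), 0.7)
  expect_equal(iter_loss(1, 0.2), plogis(1) + 0.2)
  expect_equal(iter_loss(0, 0), 0)
  # the carried term is non-negative, so iterloss always dominates BCE
  prev <- runif(50, 0, 3)
  curr <- runif(50, 0, 3)
  expect_true(all(iter_loss(prev, curr) >= curr))
})

test_that("analytic gradients agree with finite differences", {
  fx <- tiny_graph_fixture(seed = 7, n_pairs = 5, len = 14, lenk = 3)
  graph <- fx$graph
  dims <- gnn_dims(3, 3, 3)
  state <- init_gnn_state(graph$m, dims, seed = 9)
  ord <- match(graph$seq_ids, fx$corpus$id)
  y <- fx$corpus$label[ord]
  train_mask <- fx$corpus$split[ord] == "train"
  prop <- motifgraph:::graph_propagation(graph)
  loss_at <- function(st) {
    fwd <- gnn_forward(graph, st, prop)
    mean(bce_loss(y, fwd$y_hat)[train_mask])
  }
  fwd <- gnn_forward(graph, state, prop)
  grads <- motifgraph:::gnn_backprop(graph, state, prop, fwd, y, train_mask)
  eps <- 1e-6
  set.seed(11)
  for (nm in c("Wco_train", "Wsim_train", "Wjac_train", "Winclu_train",
               "w_out")) {
    for (rep in 1:2) {
      idx <- sample(length(state[[nm]]), 1)
      plus <- state; plus[[nm]][idx] <- plus[[nm]][idx] + eps
      minus <- state; minus[[nm]][idx] <- minus[[nm]][idx] - eps
      fd <- (loss_at(plus) - loss_at(minus)) / (2 * eps)
      an <- grads[[nm]][idx]
      denom <- max(abs(fd), abs(an), 1e-8)
      expect_lt(abs(fd - an) / denom, 1e-4)
    }
  }
  plus <- state; plus$b_out <- plus$b_out + eps
  minus <- state; minus$b_out <- minus$b_out - eps
  fd <- (loss_at(plus) - loss_at(minus)) / (2 * eps)
  expect_lt(abs(fd - grads$b_out) / max(abs(fd), 1e-8), 1e-4)
})

test_that("masked validation and test nodes contribute no gradient", {
  fx <- tiny_graph_fixture(seed = 13, n_pairs = 6)
  corpus2 <- fx$corpus
  flip <- corpus2$split != "train"
  corpus2$label[flip] <- 1L - corpus2$label[flip]
  f1 <- train_gnn(fx$graph, fx$corpus, dims = gnn_dims(2, 2, 2), epochs = 3,
                  seed = 5)
  f2 <- train_gnn(fx$graph, corpus2, dims = gnn_dims(2, 2, 2), epochs = 3,
                  seed = 5)
  expect_equal(f1$state, f2$state)
  expect_equal(f1$predictions$score, f2$predictions$score)
})

test_that("iterloss equals plain BCE over the first epoch's update", {
  fx <- tiny_graph_fixture(seed = 3, n_pairs = 6)
  f_iter <- train_gnn(fx$graph, fx$corpus, dims = gnn_dims(2, 2, 2),
                      epochs = 1, loss = "iterloss", seed = 2)
  f_bce <- train_gnn(fx$graph, fx$corpus, dims = gnn_dims(2, 2, 2),
                     epochs = 1, loss = "bce", seed = 2)
  expect_equal(f_iter$state, f_bce$state)
  expect_equal(f_iter$history$train_loss, f_bce$history$train_loss)
})

test_that("training is deterministic and decays the learning rate", {
  fx <- tiny_graph_fixture(seed = 17, n_pairs = 6)
  f1 <- train_gnn(fx$graph, fx$corpus, dims = gnn_dims(3, 3, 3), epochs = 4,
                  seed = 8)
  f2 <- train_gnn(fx$graph, fx$corpus, dims = gnn_dims(3, 3, 3), epochs = 4,
                  seed = 8)
  expect_equal(f1$state, f2$state, tolerance = 1e-12)
  expect_equal(f1$history$lr, 0.001 * exp(-0.001 * (0:3)))
})

test_that("training reduces the loss on an easily separable planted corpus", {
  pwm <- make_pwm(8, ic_per_col = 2, seed = 6)
  sim <- simulate_corpus(30, seq_len = 61, motifs = pwm, seed = 4)
  corpus <- prepare_corpus(sim$sequences, seed = 4)
  graph <- build_graph(corpus, lenk = 5)
  fit <- train_gnn(graph, corpus, dims = gnn_dims(10, 10, 10), epochs = 30,
                   seed = 4)
  h <- fit$history
  expect_lt(h$train_loss[30], h$train_loss[1])
  expect_gt(h$val_auc[30], 0.5)
})

test_that("checkpoints round-trip through disk", {
  fx <- tiny_graph_fixture(seed = 19, n_pairs = 6)
  fit <- train_gnn(fx$graph, fx$corpus, dims = gnn_dims(2, 2, 2), epochs = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(fit, path)
  back <- read_checkpoint(path)
  expect_equal(back$state, fit$state)
  expect_equal(back$history, fit$history)
  hist_tsv <- sub("\\.rds$", "_history.tsv", path)
  expect_true(file.exists(hist_tsv))
})

test_that("tidy and glance summarize fits as tibbles", {
  fx <- tiny_graph_fixture(seed = 23, n_pairs = 6)
  fit <- train_gnn(fx$graph, fx$corpus, dims = gnn_dims(2, 2, 2), epochs = 3)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_named(gl, c("epochs", "train_loss", "val_auc", "test_auc"))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("a hyperparameter sweep reports validation AUC per combination", {
  sequences <- random_corpus(12, 20, seed = 55)
  corpus <- prepare_corpus(sequences, seed = 55)
  grid <- tibble::tibble(lenk = c(3, 3), dc = c(2, 4), ds = c(2, 4),
                         dj = c(2, 4), epochs = c(2, 2))
  out <- sweep_hyperparams(corpus, grid, seed = 1)
  expect_equal(nrow(out), 2)
  expect_true(all(out$val_auc >= 0 & out$val_auc <= 1))
  expect_true(!is.unsorted(rev(out$val_auc)))
})
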