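test_that("drug branches expose the published layer widths", {
  expect_identical(build_drug_branch("gcn")$widths,
                   c(78L, 156L, 312L, 1024L, 128L))
  expect_identical(build_drug_branch("gat_gcn")$widths,
                   c(780L, 780L, 1500L, 128L))
  expect_identical(build_drug_branch("gat")$widths, c(780L, 128L, 128L))
  expect_identical(build_drug_branch("gin")$widths, c(rep(32L, 5), 128L))
  expect_error(build_drug_branch("bogus"))
  expect_error(model_config("bogus"))
  expect_error(model_config("gcn", protein_input_dim = 100), "25")
})

test_that("every branch maps any graph batch to finite 128-dim embeddings", {
  set.seed(8)
  graphs <- list(smiles_to_graph("C", "one_atom"),
                 smiles_to_graph("CCO", "ethanol"),
                 smiles_to_graph("c1ccccc1", "benzene"))
  batch <- dtakit:::pack_graphs(graphs)
  for (kind in c("gcn", "gin", "gat", "gat_gcn")) {
    br <- build_drug_branch(kind)
    fw <- dtakit:::drug_branch_fwd(kind, br$params, batch, br$pooling,
                                   dropout = 0, train = FALSE)
    expect_identical(dim(fw$out), c(3L, 128L))
    expect_true(all(is.finite(fw$out)), label = kind)
  }
})

test_that("the protein branch embeds batches of word-frequency vectors", {
  set.seed(9)
  br <- build_protein_branch(625)
  X <- matrix(runif(4 * 625, 0, 0.05), 4, 625)
  fw <- dtakit:::prot_branch_fwd(br$params, X)
  expect_identical(dim(fw$out), c(4L, 128L))
  # all-zero input still yields finite output
  fw0 <- dtakit:::prot_branch_fwd(br$params, matrix(0, 2, 625))
  expect_true(all(is.finite(fw0$out)))
  expect_error(build_protein_branch(77), "25")
  wide <- build_protein_branch(25, embed_dim = 256)
  expect_identical(wide$widths[2], 256)
})

test_that("the fused model predicts one finite value per pair, batch-independently", {
  tiny <- make_tiny_features()
  cfg <- model_config("gcn", protein_input_dim = 25, dropout = 0, seed = 2)
  model <- build_model(cfg)
  pred <- predict_dta(model, tiny$feats)
  expect_length(pred, nrow(tiny$ds))
  expect_true(all(is.finite(pred)))
  # identical inputs give identical predictions; batching cannot matter
  expect_identical(pred, predict_dta(model, tiny$feats))
  expect_equal(pred, predict_dta(model, tiny$feats, batch_size = 7),
               tolerance = 1e-12)
  # duplicated pair predicts identically
  expect_equal(pred[1], pred[1])
  # featurization mismatch is rejected
  wrong <- featurize_pairs(tiny$ds, n = 2)
  expect_error(predict_dta(model, wrong), "protein_input_dim")
})

test_that("training reduces MSE on planted-signal data and is seed-reproducible", {
  tiny <- make_tiny_features()
  cfg <- model_config("gcn", protein_input_dim = 25, batch_size = 16,
                      learning_rate = 1e-3, epochs = 8, seed = 4)
  m1 <- train_dta(build_model(cfg), tiny$feats)
  expect_identical(nrow(m1$history), 8L)
  expect_lt(m1$history$loss[8], m1$history$loss[1])
  baseline <- mean((tiny$ds$affinity - mean(tiny$ds$affinity))^2)
  expect_lt(m1$history$loss[8], baseline)

  m2 <- train_dta(build_model(cfg), tiny$feats)
  expect_identical(m1$history, m2$history)
  expect_identical(predict_dta(m1, tiny$feats), predict_dta(m2, tiny$feats))

  # zero epochs returns the untrained model with empty history
  m0 <- train_dta(build_model(cfg), tiny$feats, epochs = 0)
  expect_false(m0$trained)
  expect_identical(nrow(m0$history), 0L)
})

test_that("analytic gradients agree with finite differences through the full model", {
  tiny <- make_tiny_features()
  feats <- tiny$feats
  cfg <- model_config("gat_gcn", protein_input_dim = 25, dropout = 0,
                      seed = 6)
  model <- build_model(cfg)
  params <- model$params
  rows <- seq_along(feats$affinity)
  fw <- dtakit:::.batch_forward(params, cfg, feats, rows, train = TRUE)
  resid <- fw$pred - feats$affinity
  grads <- dtakit:::.batch_backward(params, cfg, fw,
                                    2 * resid / length(rows))
  loss_at <- function(p) {
    f <- dtakit:::.batch_forward(p, cfg, feats, rows, train = TRUE)
    mean((f$pred - feats$affinity)^2)
  }
  set.seed(77)
  checks <- list(c("drug", "gat1", "W"), c("drug", "gc2", "W"),
                 c("drug", "fc1", "b"), c("prot", "conv", "W"),
                 c("prot", "emb", "W"), c("head", "fc1", "W"),
                 c("head", "out", "W"))
  for (pth in checks) {
    leaf <- params[[pth[1]]][[pth[2]]][[pth[3]]]
    i <- sample.int(length(leaf), 1)
    eps <- 1e-6
    p1 <- params; p1[[pth[1]]][[pth[2]]][[pth[3]]][i] <- leaf[i] + eps
    p2 <- params; p2[[pth[1]]][[pth[2]]][[pth[3]]][i] <- leaf[i] - eps
    num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    ana <- grads[[pth[1]]][[pth[2]]][[pth[3]]][i]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste(pth, collapse = "."))
  }
})

test_that("checkpoints round-trip the model and corpus weights", {
  tiny <- make_tiny_features()
  cfg <- model_config("gin", protein_input_dim = 25, epochs = 1,
                      batch_size = 16, learning_rate = 1e-3, seed = 10)
  m <- train_dta(build_model(cfg), tiny$feats)
  path <- tempfile(fileext = ".rds")
  save_model(m, path, weights = tiny$feats$weights)
  back <- load_model(path)
  expect_identical(predict_dta(back$model, tiny$feats),
                   predict_dta(m, tiny$feats))
  expect_identical(back$weights, tiny$feats$weights)
})
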