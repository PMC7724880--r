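# Build a model whose latent factors are constant vectors: identity encoder
# with zero weights so every factor equals the encoder bias.
constant_factor_model <- function(bundle, u, v, h, w, b = 0, eta = 0.7) {
  d <- length(u); l <- length(w)
  model <- init_model(bundle, latent_dim = d, memory_dim = l, eta = eta,
                      activation_enc = "identity", seed = 1)
  for (nm in c("W1", "V1")) {
    model$drug_ae[[nm]][] <- 0
    model$disease_ae[[nm]][] <- 0
  }
  model$drug_ae$b_enc <- u
  model$disease_ae$b_enc <- v
  model$fusion$h <- h
  model$fusion$w <- w
  model$fusion$b <- b
  model
}

test_that("fused score reduces to closed forms at the eta extremes", {
  b <- tiny_bundle(seed = 21)
  m1 <- constant_factor_model(b, c(1, 1), c(1, 1), h = c(1, 1), w = c(0, 0), eta = 1)
  expect_equal(predict_score(m1, 1, 1), plogis(2), tolerance = 1e-12)
  m0 <- constant_factor_model(b, c(1, 1), c(2, 2), h = c(5, 5), w = c(0, 0), eta = 0)
  for (j in 1:3) expect_equal(predict_score(m0, 2, j), 0.5, tolerance = 1e-12)
})

test_that("matrix scoring agrees with pairwise scoring", {
  b <- tiny_bundle(seed = 22)
  cfg <- amn_config(epochs = 3, batch_size = 64, seed = 6)
  model <- train_amnet(b, 4, 3, 0.6, config = cfg)
  S <- predict_matrix(model)
  for (i in seq_len(nrow(S))) {
    for (j in seq_len(ncol(S))) {
      expect_equal(S[i, j], predict_score(model, i, j), tolerance = 1e-12)
    }
  }
  expect_true(all(S > 0 & S < 1))
})

test_that("bce loss matches closed forms and an elementwise oracle", {
  expect_equal(bce_loss(1, 0.8), -log(0.8))
  expect_equal(bce_loss(rep(1, 7), rep(0.5, 7)), 7 * log(2))
  expect_equal(bce_loss(rep(0, 3), rep(0.5, 3)), 3 * log(2))
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    r <- rbinom(n, 1, 0.5); s <- runif(n)
    batch <- data.frame(drug = 1, disease = 1, label = r)
    expect_equal(bce_loss(batch, s), oracle_bce(r, s), tolerance = 1e-12)
  }
  expect_error(bce_loss(c(1, 0), 0.5), class = "amnet_shape_error")
})

test_that("total loss is the weighted sum of its components", {
  cfg0 <- amn_config(phi = 0, psi = 0)
  expect_equal(total_loss(3.5, 10, 20, cfg0), 3.5)
  cfg1 <- amn_config(phi = 1, psi = 1)
  expect_equal(total_loss(1, 2, 3, cfg1), 6)
  # linear in phi and psi with slopes L_d and L_p
  set.seed(8)
  for (rep in 1:10) {
    comp <- runif(3, 0, 10); w <- runif(2, 0, 2)
    cfg <- amn_config(phi = w[1], psi = w[2])
    expect_equal(total_loss(comp[1], comp[2], comp[3], cfg),
                 comp[1] + w[1] * comp[2] + w[2] * comp[3], tolerance = 1e-12)
    cfg2 <- amn_config(phi = w[1] + 1, psi = w[2])
    expect_equal(total_loss(comp[1], comp[2], comp[3], cfg2) -
                   total_loss(comp[1], comp[2], comp[3], cfg), comp[2],
                 tolerance = 1e-12)
  }
  expect_error(total_loss(Inf, 1, 1, cfg0), class = "amnet_value_error")
})

test_that("negative sampling is uniform over zero cells and reproducible", {
  v <- matrix(0, 4, 5); v[cbind(1:4, 1:4)] <- 1
  a <- association_matrix(v, sprintf("D%d", 1:4), sprintf("P%d", 1:5))
  neg <- sample_negatives(a, 1, seed = 2, epoch = 1)
  expect_equal(nrow(neg), 4)
  expect_true(all(a$values[cbind(neg$drug, neg$disease)] == 0))
  expect_identical(neg, sample_negatives(a, 1, seed = 2, epoch = 1))
  expect_false(identical(neg, sample_negatives(a, 1, seed = 2, epoch = 2)))

  # frequency of each zero cell across many epochs: within 3 sigma of uniform
  counts <- matrix(0, 4, 5)
  draws <- 2500
  for (ep in 1:draws) {
    s <- sample_negatives(a, 1, seed = 11, epoch = ep)
    counts[cbind(s$drug, s$disease)] <- counts[cbind(s$drug, s$disease)] + 1
  }
  zeros <- which(a$values == 0)
  p_sel <- 4 / 16  # 4 of 16 zero cells per epoch
  sigma <- sqrt(draws * p_sel * (1 - p_sel))
  expect_true(all(abs(counts[zeros] - draws * p_sel) <= 3 * sigma))
  expect_error(sample_negatives(a, 10, 1, 1), class = "amnet_value_error")
})

test_that("training reduces the joint loss and is bit-reproducible", {
  b <- tiny_bundle(50, 30, 4, 0.05, seed = 7)
  cfg <- amn_config(epochs = 5, learning_rate = 0.001, seed = 3)
  m1 <- train_amnet(b, 8, 8, 0.7, config = cfg)
  expect_lt(m1$trace$loss[5], m1$trace$loss[1])
  m2 <- train_amnet(b, 8, 8, 0.7, config = cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(predict_matrix(m1), predict_matrix(m2))
})

test_that("eta gates the two information paths", {
  b <- tiny_bundle(seed = 25)
  cfg <- amn_config(epochs = 4, seed = 5)
  m_lat <- train_amnet(b, 4, 3, eta = 1, config = cfg)
  S <- predict_matrix(m_lat)
  m_pert <- m_lat
  m_pert$memory <- matrix(rnorm(length(m_pert$memory)), nrow(m_pert$memory))
  expect_identical(predict_matrix(m_pert), S)

  m_nb <- train_amnet(b, 4, 3, eta = 0, config = cfg)
  S0 <- predict_matrix(m_nb)
  m_nb$fusion$h <- rnorm(4)
  expect_identical(predict_matrix(m_nb), S0)
})

test_that("a saved model reloads with identical structure and predictions", {
  b <- tiny_bundle(seed = 26)
  model <- train_amnet(b, 4, 3, 0.7, config = amn_config(epochs = 3, seed = 2))
  dir <- withr::local_tempdir()
  save_amnet(model, dir)
  m2 <- load_amnet(dir)
  expect_equal(m2$train, model$train)
  expect_equal(predict_matrix(m2), predict_matrix(model), tolerance = 1e-9)
})

test_that("grid enumeration and selection behave as specified", {
  expect_equal(nrow(enumerate_grid(default_grid())), 5 * 5 * 5 * 5 * 5 * 3 * 3 * 4)
  b <- tiny_bundle(seed = 27)
  single <- list(latent_dim = 4, memory_dim = 4, eta = 0.5)
  res <- grid_search_amnet(b, single, scorer = function(row) 0.9)
  expect_equal(res$best$eta, 0.5)
  expect_equal(nrow(res$results), 1)
  # a strictly dominant configuration wins under a rigged metric
  two <- list(eta = c(0.3, 0.9))
  res2 <- grid_search_amnet(b, two, scorer = function(row) if (row$eta > 0.5) 1 else 0)
  expect_equal(res2$best$eta, 0.9)
  expect_error(enumerate_grid(list()), class = "amnet_value_error")
})

test_that("validation-based early stopping halts before the epoch budget", {
  b <- tiny_bundle(30, 20, 3, 0.1, seed = 28)
  sp <- cv_split(b$associations, 5, seed = 1)[[1]]
  a <- b$associations
  tv <- a$values; tv[sp$test_positives] <- 0
  tb <- dataset_bundle(association_matrix(tv, a$drug_ids, a$disease_ids),
                       b$drug_sim, b$disease_sim)
  cfg <- amn_config(epochs = 60, seed = 4, patience = 3)
  m <- train_amnet(tb, 4, 4, 0.7, config = cfg, validation = sp)
  expect_lte(nrow(m$trace), 60)
})
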