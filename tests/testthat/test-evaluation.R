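test_that("AUC matches pair counting, handles ties and monotone transforms", {
  expect_equal(auc_score(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auc_score(rep(0.4, 10), c(1, rep(0, 9))), 0.5)
  set.seed(19)
  for (rep in 1:25) {
    n <- 50
    s <- round(runif(n), 2)  # rounding forces ties
    l <- rbinom(n, 1, 0.4)
    if (sum(l) == 0 || sum(l) == n) next
    expect_equal(auc_score(s, l), oracle_auc(s, l))
    expect_equal(auc_score(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), l),
                 auc_score(s, l))
  }
  # independent library cross-check on a tie-free instance
  set.seed(20)
  s <- runif(80); l <- rbinom(80, 1, 0.3)
  expect_equal(auc_score(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<"))))
  # random scores are uninformative: AUC near one half
  set.seed(77)
  s <- runif(4000); l <- rbinom(4000, 1, 0.2)
  expect_lt(abs(auc_score(s, l) - 0.5), 0.05)
  expect_error(auc_score(c(1, 2), c(1, 1)), class = "amnet_value_error")
})

test_that("AUPR matches hand enumeration and a brute-force threshold sweep", {
  expect_equal(aupr_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aupr_score(c(0.4, 0.3, 0.2, 0.1), c(0, 0, 0, 1)), 0.25)
  set.seed(29)
  for (rep in 1:25) {
    s <- round(runif(50), 2)
    l <- rbinom(50, 1, 0.3)
    if (sum(l) == 0) next
    expect_equal(aupr_score(s, l), oracle_aupr(s, l), tolerance = 1e-12)
  }
  expect_error(aupr_score(c(1, 2), c(0, 0)), class = "amnet_value_error")
})

test_that("hit ratio ranks candidates exhaustively with index tie-breaks", {
  set.seed(33)
  for (rep in 1:20) {
    m <- 6; n <- 9
    S <- matrix(round(runif(m * n), 1), m, n)  # coarse scores force ties
    train <- matrix(rbinom(m * n, 1, 0.2), m, n)
    pos <- which(train == 0, arr.ind = TRUE)
    tp <- pos[sample(nrow(pos), 4), , drop = FALSE]
    kmax <- min(rowSums(train[tp[, 1], , drop = FALSE] == 0))
    for (k in unique(pmin(c(1, 3, 5), kmax))) {
      expect_equal(amnet:::hr_from_scores(S, tp, train, k),
                   oracle_hr(S, tp, train, k))
    }
  }
  # monotone in k, and HR at the full candidate list is 1
  S <- matrix(runif(30), 5, 6)
  train <- matrix(0, 5, 6)
  tp <- cbind(1:5, c(2, 4, 1, 6, 3))
  vals <- vapply(1:6, function(k) amnet:::hr_from_scores(S, tp, train, k), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[6], 1)
})

test_that("hr_at_k on a model agrees with ranking its score matrix", {
  b <- tiny_bundle(seed = 31)
  sp <- cv_split(b$associations, 4, seed = 2)[[1]]
  a <- b$associations
  train_vals <- a$values
  train_vals[sp$test_positives] <- 0
  tb <- dataset_bundle(association_matrix(train_vals, a$drug_ids, a$disease_ids),
                       b$drug_sim, b$disease_sim)
  model <- train_amnet(tb, 4, 3, 0.7, config = amn_config(epochs = 3, seed = 1))
  tv <- model$train
  S <- predict_matrix(model)
  expect_equal(hr_at_k(model, sp$test_positives, tv, 3),
               oracle_hr(S, sp$test_positives, tv$values, 3))
  expect_error(hr_at_k(model, sp$test_positives, tv, 10000),
               class = "amnet_value_error")
})

test_that("cross-validation folds partition the positives near-equally", {
  v <- matrix(0, 12, 6)
  v[amnet:::with_seed(3, sample(72, 10))] <- 1
  a <- association_matrix(v, sprintf("D%d", 1:12), sprintf("P%d", 1:6))
  folds <- cv_split(a, 10, seed = 1)
  expect_true(all(vapply(folds, function(f) nrow(f$test_positives), numeric(1)) == 1))
  all_test <- do.call(rbind, lapply(folds, `[[`, "test_positives"))
  expect_equal(nrow(unique(as.data.frame(all_test))), 10)
  pos <- which(a$values == 1, arr.ind = TRUE); dimnames(pos) <- NULL
  expect_equal(all_test[order(all_test[, 1], all_test[, 2]), ],
               pos[order(pos[, 1], pos[, 2]), ])
  for (f in folds) {
    both <- rbind(f$train_positives, f$test_positives)
    expect_equal(nrow(both), 10)  # train and test are disjoint and exhaustive
    expect_true(all(a$values[f$test_negatives] == 0))
  }
  expect_identical(cv_split(a, 10, seed = 1), folds)
  expect_error(cv_split(a, 11, seed = 1), class = "amnet_value_error")
})

test_that("a 1933-positive matrix splits into fold sizes 193 and 194", {
  v <- matrix(0, 593, 313)
  v[amnet:::with_seed(5, sample(593 * 313, 1933))] <- 1
  a <- association_matrix(v, sprintf("D%d", 1:593), sprintf("P%d", 1:313))
  sizes <- vapply(cv_split(a, 10, seed = 7), function(f) nrow(f$test_positives),
                  numeric(1))
  expect_setequal(unique(sizes), c(193, 194))
  expect_equal(sum(sizes), 1933)
})

test_that("cold-start split removes exactly the singleton drugs", {
  v <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 0), c(1, 1, 1, 0))
  a <- association_matrix(v, sprintf("D%d", 1:4), sprintf("P%d", 1:4))
  sp <- cold_start_split(a)
  expect_equal(sp$removed_drugs, c(1L, 3L))
  expect_equal(nrow(sp$test_positives), 2)
  expect_equal(rowSums(sp$train$values), c(0, 2, 0, 3), ignore_attr = TRUE)
  expect_true(all(sp$train$values[sp$test_positives] == 0))

  none <- association_matrix(rbind(c(1, 1), c(1, 1)), c("a", "b"), c("x", "y"))
  sp0 <- cold_start_split(none)
  expect_equal(nrow(sp0$test_positives), 0)
  expect_identical(sp0$train$values, none$values)
})

test_that("evaluate_model computes its metrics from the model's score matrix", {
  # stub model with hand-set scores: test positives scored 1, all else 0
  train <- matrix(0, 4, 5)
  train[1, 1] <- 1
  tp <- cbind(c(2, 3), c(2, 3))
  S <- matrix(0, 4, 5); S[tp] <- 1
  stub <- structure(list(train = list(values = train)), class = "stub_model")
  .S3method("predict_matrix", "stub_model", function(model) S)
  zeros <- which(train == 0, arr.ind = TRUE)
  keep <- !(paste(zeros[, 1], zeros[, 2]) %in% paste(tp[, 1], tp[, 2]))
  sp <- list(test_positives = tp, test_negatives = zeros[keep, ])
  ev <- evaluate_model(stub, sp)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$aupr, 1.0)
  expect_equal(unname(ev$hr_at["1"]), 1.0)
  # inverted scores: complete separation the wrong way round
  .S3method("predict_matrix", "stub_model", function(model) 1 - S)
  expect_equal(evaluate_model(stub, sp)$auc, 0.0)
  expect_error(evaluate_model(stub, list(test_positives = tp[0, , drop = FALSE])),
               class = "amnet_value_error")
})
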