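#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive is scored above a
#' uniformly chosen negative, with ties counted one half (midrank
#' convention). Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores.
#' @param labels binary labels aligned with `scores`; both classes must be
#'   present.
#' @return real in \[0,1\].
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) amn_stop("lengths disagree", "shape_error")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    amn_stop("AUC requires at least one positive and one negative", "value_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation `sum((R_k - R_{k-1}) * P_k)` over descending score
#' thresholds, grouping tied scores into a single threshold (no trapezoid
#' interpolation). More informative than AUC under the heavy class imbalance
#' typical of association matrices.
#'
#' @inheritParams auc_score
#' @export
aupr_score <- function(scores, labels) {
  if (length(scores) != length(labels)) amn_stop("lengths disagree", "shape_error")
  npos <- sum(labels == 1)
  if (npos == 0) amn_stop("AUPR requires at least one positive", "value_error")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  ctp <- cumsum(l); cfp <- cumsum(1 - l)
  last <- which(c(s[-length(s)] != s[-1], TRUE))  # last index of each tie group
  tp <- ctp[last]; fp <- cfp[last]
  P <- tp / (tp + fp); R <- tp / npos
  sum((R - c(0, R[-length(R)])) * P)
}

#' Hit ratio at k
#'
#' For each held-out positive pair (i, j), disease j is ranked by predicted
#' score among all diseases with no training association to drug i (ties
#' broken by ascending disease index); the pair is a hit when its rank is at
#' most k. HR@k is the fraction of hits over all held-out positives.
#'
#' @param model an `amn_model` trained on `train`.
#' @param test_positives 2-column matrix of (drug, disease) index pairs.
#' @param train the training [association_matrix()].
#' @param k cutoff rank, at least 1 and no larger than any candidate list.
#' @return real in \[0,1\].
#' @export
hr_at_k <- function(model, test_positives, train, k) {
  if (k < 1) amn_stop("k must be >= 1", "value_error")
  S <- predict_matrix(model)
  hr_from_scores(S, test_positives, train$values, k, strict = TRUE)
}

hr_from_scores <- function(S, test_positives, train_values, k, strict = FALSE) {
  test_positives <- matrix(as.integer(test_positives), ncol = 2)
  hits <- 0L; total <- nrow(test_positives); feasible <- TRUE
  for (r in seq_len(total)) {
    i <- test_positives[r, 1]; j <- test_positives[r, 2]
    cand <- which(train_values[i, ] == 0)
    if (k > length(cand)) {
      if (strict) amn_stop("k exceeds the candidate list length", "value_error")
      feasible <- FALSE
      next
    }
    pos_in_cand <- match(j, cand)
    if (is.na(pos_in_cand)) {
      amn_stop("test positive is a training association; cannot be ranked",
               "value_error")
    }
    ord <- order(-S[i, cand], cand)
    if (match(j, cand[ord]) <= k) hits <- hits + 1L
  }
  if (!feasible) return(NA_real_)
  hits / total
}

#' Ten-fold cross-validation split of the positive pairs
#'
#' Shuffles the known associations under a seed and partitions them into
#' `n_folds` near-equal folds (sizes differ by at most one). Per fold, the
#' held-out positives form the test positives and all unverified (zero)
#' cells of the matrix form the test negatives; the remaining positives
#' train the model.
#'
#' @param a an [association_matrix()].
#' @param n_folds number of folds.
#' @param seed integer seed; splits are bit-reproducible.
#' @return list of fold objects, each with `fold_id` (0-based),
#'   `train_positives`, `test_positives`, `test_negatives` (2-column index
#'   matrices).
#' @export
cv_split <- function(a, n_folds = 10L, seed = 42L) {
  pos <- which(a$values == 1, arr.ind = TRUE)
  dimnames(pos) <- NULL
  npos <- nrow(pos)
  if (npos < n_folds) amn_stop("fewer positives than folds", "value_error")
  perm <- with_seed(derive_seed(seed, 5L, 0L), sample(npos))
  base <- npos %/% n_folds; extra <- npos %% n_folds
  sizes <- rep(base, n_folds) + c(rep(1L, extra), rep(0L, n_folds - extra))
  zeros <- which(a$values == 0, arr.ind = TRUE)
  dimnames(zeros) <- NULL
  offsets <- cumsum(c(0L, sizes))
  lapply(seq_len(n_folds), function(f) {
    test_idx <- perm[(offsets[f] + 1L):offsets[f + 1L]]
    list(fold_id = f - 1L,
         train_positives = pos[-test_idx, , drop = FALSE],
         test_positives = pos[test_idx, , drop = FALSE],
         test_negatives = zeros)
  })
}

#' Cold-start ("new drug") split
#'
#' Every drug with exactly one known association has that association moved
#' to the test set, emptying its training row — the model must then score
#' the removed association from similarity side information and the
#' neighborhood of the disease alone.
#'
#' @param a an [association_matrix()].
#' @return list with `train` (an [association_matrix()] with singleton rows
#'   emptied), `test_positives`, `test_negatives` (zero cells of the input),
#'   and `removed_drugs` (indices of the singleton drugs).
#' @export
cold_start_split <- function(a) {
  rs <- rowSums(a$values)
  singles <- which(rs == 1)
  test_pos <- if (length(singles) > 0) {
    cbind(singles, vapply(singles, function(i) which(a$values[i, ] == 1), integer(1)))
  } else {
    matrix(integer(0), 0, 2)
  }
  dimnames(test_pos) <- NULL
  train_vals <- a$values
  if (nrow(test_pos) > 0) train_vals[test_pos] <- 0
  zeros <- which(a$values == 0, arr.ind = TRUE)
  dimnames(zeros) <- NULL
  list(train = association_matrix(train_vals, a$drug_ids, a$disease_ids),
       test_positives = test_pos, test_negatives = zeros,
       removed_drugs = singles)
}

#' Evaluate a trained model on a held-out split
#'
#' Scores all test positives and test negatives with the model and computes
#' AUC, AUPR and HR at k in {1, 5, 10} (full-ranking candidate lists; an HR
#' value is `NA` when some candidate list is shorter than k).
#'
#' @param model an `amn_model` trained on the split's training associations.
#' @param split a fold from [cv_split()] or the output of
#'   [cold_start_split()].
#' @return object of class `amn_eval`: list with `auc`, `aupr`, `hr_at`
#'   (named vector for k = 1, 5, 10), `n_test_pos`, `n_test_neg`.
#' @export
evaluate_model <- function(model, split) {
  tp <- split$test_positives
  if (is.null(tp) || nrow(tp) == 0) {
    amn_stop("split has no test positives", "value_error")
  }
  tn <- split$test_negatives
  S <- predict_matrix(model)
  sc <- c(S[tp], S[tn])
  lb <- c(rep(1, nrow(tp)), rep(0, nrow(tn)))
  hr <- vapply(c(1, 5, 10), function(k) {
    hr_from_scores(S, tp, model$train$values, k)
  }, numeric(1))
  names(hr) <- c("1", "5", "10")
  structure(list(auc = auc_score(sc, lb), aupr = aupr_score(sc, lb),
                 hr_at = hr, n_test_pos = nrow(tp), n_test_neg = nrow(tn)),
            class = "amn_eval")
}

#' @export
print.amn_eval <- function(x, ...) {
  cat(sprintf("<amn_eval> AUC %.4f  AUPR %.4f  HR@1 %.3f  HR@5 %.3f  HR@10 %.3f\n",
              x$auc, x$aupr, x$hr_at["1"], x$hr_at["5"], x$hr_at["10"]))
  invisible(x)
}

#' Ten-fold cross-validation of the full pipeline
#'
#' Splits the positives, trains one model per fold on the remaining
#' positives (similarities unchanged) and evaluates on the held-out
#' positives against all unverified cells.
#'
#' @inheritParams train_amnet
#' @param n_folds number of folds.
#' @param split_seed seed of the fold split (training randomness is governed
#'   by `config$seed`).
#' @return list with `folds` (list of `amn_eval`), `summary` (one-row
#'   data.frame of means across folds) and `splits`.
#' @export
cross_validate <- function(bundle, n_folds = 10L, split_seed = 42L,
                           latent_dim = 64L, memory_dim = 64L, eta = 0.7,
                           config = amn_config(), verbose = FALSE) {
  a <- bundle$associations
  splits <- cv_split(a, n_folds, split_seed)
  folds <- lapply(splits, function(sp) {
    train_vals <- a$values
    train_vals[sp$test_positives] <- 0
    tb <- dataset_bundle(association_matrix(train_vals, a$drug_ids, a$disease_ids),
                         bundle$drug_sim, bundle$disease_sim)
    model <- train_amnet(tb, latent_dim, memory_dim, eta, config = config)
    ev <- evaluate_model(model, sp)
    if (verbose) {
      message(sprintf("fold %d: AUC %.4f AUPR %.4f", sp$fold_id, ev$auc, ev$aupr))
    }
    ev
  })
  summary <- data.frame(
    auc = mean(vapply(folds, `[[`, numeric(1), "auc")),
    aupr = mean(vapply(folds, `[[`, numeric(1), "aupr")),
    hr1 = mean(vapply(folds, function(f) f$hr_at["1"], numeric(1))),
    hr5 = mean(vapply(folds, function(f) f$hr_at["5"], numeric(1))),
    hr10 = mean(vapply(folds, function(f) f$hr_at["10"], numeric(1)))
  )
  list(folds = folds, summary = summary, splits = splits)
}
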