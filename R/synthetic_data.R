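#' Specification for a synthetic drug-disease dataset
#'
#' Defines a generative model with planted structure that mirrors the
#' assumptions of the prediction model: drugs and diseases have nonnegative
#' latent factors, true treatment propensity is their (row-normalized) inner
#' product, and similarity side information is the cosine similarity of the
#' planted factors — so "similar drugs treat similar diseases" holds by
#' construction and the signal is learnable from both the association matrix
#' and the similarities.
#'
#' @param m_drugs,n_diseases positive integers.
#' @param rank planted latent dimension, at most `min(m_drugs, n_diseases)`.
#' @param target_sparsity fraction of pairs set to 1, in (0,1); realized
#'   count is `round(target_sparsity * m * n)` exactly.
#' @param similarity_noise_sd sd of symmetric Gaussian noise added to the
#'   cosine similarities (then clipped to \[0,1\], diagonal reset to 1).
#' @param seed integer seed; identical specs generate identical datasets.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(m_drugs, n_diseases, rank, target_sparsity,
                       similarity_noise_sd = 0.05, seed = 1L) {
  if (m_drugs < 1 || n_diseases < 1) amn_stop("dimensions must be positive", "value_error")
  if (rank < 1 || rank > min(m_drugs, n_diseases)) {
    amn_stop("rank must be in [1, min(m_drugs, n_diseases)]", "value_error")
  }
  if (target_sparsity <= 0 || target_sparsity >= 1) {
    amn_stop("target_sparsity must be in (0,1)", "value_error")
  }
  if (round(target_sparsity * m_drugs * n_diseases) < 1) {
    amn_stop("target_sparsity implies fewer than one association", "value_error")
  }
  if (similarity_noise_sd < 0) amn_stop("similarity_noise_sd must be >= 0", "value_error")
  structure(list(m_drugs = as.integer(m_drugs), n_diseases = as.integer(n_diseases),
                 rank = as.integer(rank), target_sparsity = target_sparsity,
                 similarity_noise_sd = similarity_noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

cosine_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(X / nrm)
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Generate a synthetic dataset bundle with planted structure
#'
#' Draws nonnegative factors `U` (drugs) and `V` (diseases) as absolute
#' values of standard Gaussians, forms the true score matrix
#' `S = row-normalized U V^T`, marks the top `round(target_sparsity * m * n)`
#' scoring pairs as associations (deterministic thresholding, so the realized
#' sparsity is exact), and builds similarity matrices as the cosine
#' similarity of the factor rows perturbed by symmetric noise.
#'
#' Because associations are exactly the top-scoring pairs, ranking all pairs
#' by the returned `truth` matrix separates positives from negatives
#' perfectly (AUC 1) — the ceiling a learned model is recovering towards.
#'
#' @param spec a [synth_spec()].
#' @return list with `bundle` (a [dataset_bundle()]) and `truth`
#'   (the m x n true score matrix).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synth_spec")) amn_stop("spec must be a synth_spec", "value_error")
  m <- spec$m_drugs; n <- spec$n_diseases; r <- spec$rank
  with_seed(spec$seed, {
    U <- abs(matrix(rnorm(m * r), m, r))
    V <- abs(matrix(rnorm(n * r), n, r))
    S <- U %*% t(V)
    S <- S / rowSums(S)
    q <- round(spec$target_sparsity * m * n)
    A <- matrix(0, m, n)
    A[order(S, decreasing = TRUE)[seq_len(q)]] <- 1
    noisy_sim <- function(X) {
      C <- cosine_rows(X)
      k <- nrow(C)
      if (spec$similarity_noise_sd > 0 && k > 1) {
        E <- matrix(0, k, k)
        up <- upper.tri(E)
        E[up] <- rnorm(sum(up), 0, spec$similarity_noise_sd)
        E <- E + t(E)
        C <- pmin(pmax(C + E, 0), 1)
        diag(C) <- 1
      }
      C
    }
    ds <- noisy_sim(U)
    ps <- noisy_sim(V)
    drug_ids <- sprintf("D%d", seq_len(m))
    disease_ids <- sprintf("P%d", seq_len(n))
    bundle <- dataset_bundle(
      association_matrix(A, drug_ids, disease_ids),
      similarity_matrix(ds, drug_ids, "drug"),
      similarity_matrix(ps, disease_ids, "disease")
    )
    list(bundle = bundle, truth = S)
  })
}

#' Generate a dataset with a controlled number of singleton drugs
#'
#' Runs [generate_dataset()] and then edits rows so that exactly
#' `n_singletons` drugs have exactly one association — the population the
#' cold-start ("new drug") protocol removes into the test set. Chosen drugs
#' keep only their highest-truth association; drugs outside the chosen set
#' that happen to have a single association get their next-best association
#' added so the singleton count is exact. With `n_singletons = 0` the
#' dataset is returned unedited (chance singletons remain).
#'
#' @inheritParams generate_dataset
#' @param n_singletons number of singleton drugs, `< m_drugs`.
#' @return list with `bundle` and `truth` as in [generate_dataset()].
#' @export
generate_cold_start_dataset <- function(spec, n_singletons) {
  if (n_singletons >= spec$m_drugs) {
    amn_stop("n_singletons must be smaller than m_drugs", "value_error")
  }
  out <- generate_dataset(spec)
  if (n_singletons == 0) return(out)
  A <- out$bundle$associations$values
  S <- out$truth
  m <- nrow(A); n <- ncol(A)
  chosen <- with_seed(derive_seed(spec$seed, 1L, 1L),
                      sample(which(rowSums(A) >= 1)))
  if (length(chosen) < n_singletons) {
    amn_stop("too few drugs with associations to plant singletons", "value_error")
  }
  chosen <- sort(chosen[seq_len(n_singletons)])
  for (i in chosen) {
    keep <- which(A[i, ] == 1)
    keep <- keep[which.max(S[i, keep])]
    A[i, ] <- 0
    A[i, keep] <- 1
  }
  others <- setdiff(which(rowSums(A) == 1), chosen)
  for (i in others) {
    cand <- which(A[i, ] == 0)
    if (length(cand) == 0) amn_stop("cannot de-singleton a full row", "value_error")
    A[i, cand[which.max(S[i, cand])]] <- 1
  }
  out$bundle <- dataset_bundle(
    association_matrix(A, out$bundle$associations$drug_ids,
                       out$bundle$associations$disease_ids),
    out$bundle$drug_sim, out$bundle$disease_sim
  )
  out
}
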