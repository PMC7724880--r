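# Programmatic fixtures; no data files.

tiny_bundle <- function(m = 12, n = 8, rank = 3, sparsity = 0.15, seed = 7) {
  generate_dataset(synth_spec(m, n, rank, sparsity, 0.02, seed))$bundle
}

# A random association matrix in which every drug and disease has at least
# one association (required for exact TSV edge-list round trips).
random_assoc_full <- function(m, n, extra = 0.1, seed = 1) {
  amnet:::with_seed(seed, {
    v <- matrix(0, m, n)
    v[cbind(seq_len(m), sample(n, m, replace = TRUE))] <- 1
    v[cbind(sample(m, n, replace = TRUE), seq_len(n))] <- 1
    v[runif(m * n) < extra] <- 1
    association_matrix(v, sprintf("D%d", seq_len(m)), sprintf("P%d", seq_len(n)))
  })
}

random_similarity <- function(k, seed = 1, axis = "drug") {
  amnet:::with_seed(seed, {
    A <- matrix(runif(k * k), k, k)
    S <- (A + t(A)) / 2
    diag(S) <- 1
    similarity_matrix(S, sprintf("%s%d", toupper(substr(axis, 1, 1)), seq_len(k)), axis)
  })
}

# Batch of all positives plus seeded negatives.
full_batch <- function(a, seed = 1, neg_ratio = 1) {
  pos <- which(a$values == 1, arr.ind = TRUE)
  rbind(data.frame(drug = as.integer(pos[, 1]), disease = as.integer(pos[, 2]),
                   label = 1),
        sample_negatives(a, neg_ratio, seed, 1))
}
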