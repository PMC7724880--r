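#' Drugs associated with a disease (the neighbor set)
#'
#' The neighborhood view scores a candidate pair (i, j) from the drugs
#' already known to treat disease j. This returns those drug indices in
#' ascending order, optionally excluding the target drug itself — required
#' during training so a positive pair cannot attend to its own label.
#'
#' @param a an [association_matrix()] (the training associations).
#' @param disease_j disease column index.
#' @param exclude_drug optional drug index removed from the set.
#' @return integer vector of drug indices (possibly empty).
#' @export
neighbor_set <- function(a, disease_j, exclude_drug = NULL) {
  if (disease_j < 1 || disease_j > ncol(a$values)) {
    amn_stop("disease index out of range", "index_error")
  }
  idx <- which(a$values[, disease_j] == 1)
  if (!is.null(exclude_drug)) {
    if (exclude_drug < 1 || exclude_drug > nrow(a$values)) {
      amn_stop("drug index out of range", "index_error")
    }
    idx <- setdiff(idx, exclude_drug)
  }
  idx
}

#' Preference scores of a target drug against its neighbors
#'
#' The inner product of the target drug's latent factor with each neighbor
#' drug's latent factor: neighbors similar to the target in latent space get
#' large preference values and, after softmax normalization, dominate the
#' neighborhood representation.
#'
#' @param drug_factor_i numeric vector of length d (target drug factor).
#' @param neighbor_factors numeric matrix, one row per neighbor, d columns.
#' @return numeric vector of preferences, one per neighbor.
#' @export
preference_scores <- function(drug_factor_i, neighbor_factors) {
  neighbor_factors <- as.matrix(neighbor_factors)
  if (nrow(neighbor_factors) == 0) return(numeric(0))
  if (ncol(neighbor_factors) != length(drug_factor_i)) {
    amn_stop("factor dimensions disagree", "shape_error")
  }
  as.vector(neighbor_factors %*% drug_factor_i)
}

#' Softmax attention weights over neighbor preferences
#'
#' Normalizes preference scores into strictly positive weights summing to 1,
#' computed with max-subtraction so that preferences of any magnitude are
#' handled without overflow.
#'
#' @param p nonempty numeric vector of finite preferences.
#' @return numeric vector of the same length, positive, summing to 1.
#' @export
attention_weights <- function(p) {
  if (length(p) == 0) amn_stop("preference vector is empty", "value_error")
  if (any(!is.finite(p))) amn_stop("preferences must be finite", "value_error")
  e <- exp(p - max(p))
  e / sum(e)
}

#' Attention-pooled neighborhood representation
#'
#' Pools the external memory rows of the neighbor drugs with the attention
#' weights: `o = sum_n q_n * c_n`. The memory table is a trainable parameter
#' matrix, one row per drug, storing each drug's neighbor-role information;
#' its dimension is independent of the latent factor dimension. An empty
#' neighbor set yields the zero vector, so the fused predictor degrades to
#' the latent-factor path for diseases without known drugs.
#'
#' @param q attention weights (length = number of neighbors; may be empty).
#' @param memory_rows matrix of memory vectors, one row per neighbor.
#' @return numeric vector of length `ncol(memory_rows)`.
#' @export
neighborhood_representation <- function(q, memory_rows) {
  memory_rows <- as.matrix(memory_rows)
  if (length(q) != nrow(memory_rows)) {
    amn_stop("attention and memory row counts disagree", "shape_error")
  }
  if (length(q) == 0) return(numeric(ncol(memory_rows)))
  as.vector(crossprod(memory_rows, q))
}

# Trainable memory table: one row per drug, Gaussian init (mean 0, sd 0.1).
init_memory <- function(m_drugs, memory_dim, seed, init_sd = 0.1) {
  with_seed(seed, matrix(rnorm(m_drugs * memory_dim, 0, init_sd),
                         m_drugs, memory_dim))
}
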