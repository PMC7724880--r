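#' Denoising autoencoder parameters for one side (drug or disease)
#'
#' Each side owns one encoder and two decoder heads. The encoder maps the
#' (corrupted) association profile together with the (corrupted) similarity
#' profile to a latent factor of dimension `d`:
#' `z = g(W1 s + V1 sim + b_enc)`. One decoder reconstructs the clean
#' association profile, the other the clean similarity profile. For drugs
#' the association profile is a row of the association matrix (length
#' `n_diseases`) and the similarity profile a row of the drug-drug
#' similarity matrix (length `m_drugs`); the disease side mirrors this with
#' columns and the disease-disease similarity.
#'
#' @param assoc_dim length of the association profile input.
#' @param sim_dim length of the similarity profile input.
#' @param latent_dim latent dimension d.
#' @param activation_enc encoder activation `g` (`"relu"`, `"identity"`,
#'   `"tanh"`, `"logistic"`).
#' @param activation_dec decoder activation `f` (`"logistic"` recommended:
#'   targets are binary associations and \[0,1\] similarities).
#' @param seed integer seed for the Gaussian initialization (sd 0.1).
#' @param init_sd initialization standard deviation.
#' @return object of class `ae_params` with fields `W1` (d x assoc_dim),
#'   `V1` (d x sim_dim), `b_enc` (d), `W2` (assoc_dim x d), `b_rec_assoc`,
#'   `V2` (sim_dim x d), `b_rec_sim`, `d`, `activation_enc`, `activation_dec`.
#' @export
init_autoencoder <- function(assoc_dim, sim_dim, latent_dim,
                             activation_enc = "relu",
                             activation_dec = "logistic",
                             seed = 1L, init_sd = 0.1) {
  act_fun(activation_enc); act_fun(activation_dec)  # validate names
  with_seed(seed, {
    p <- list(
      W1 = matrix(rnorm(latent_dim * assoc_dim, 0, init_sd), latent_dim, assoc_dim),
      V1 = matrix(rnorm(latent_dim * sim_dim, 0, init_sd), latent_dim, sim_dim),
      b_enc = numeric(latent_dim),
      W2 = matrix(rnorm(assoc_dim * latent_dim, 0, init_sd), assoc_dim, latent_dim),
      b_rec_assoc = numeric(assoc_dim),
      V2 = matrix(rnorm(sim_dim * latent_dim, 0, init_sd), sim_dim, latent_dim),
      b_rec_sim = numeric(sim_dim),
      d = as.integer(latent_dim),
      activation_enc = activation_enc,
      activation_dec = activation_dec
    )
    structure(p, class = "ae_params")
  })
}

#' Input corruption configuration
#'
#' Masking (dropout-style) noise: each input entry is independently zeroed
#' with probability `mask_rate`. Masking is the standard denoising choice
#' for sparse binary profiles; `mask_rate = 0` recovers a plain autoencoder.
#' Corruption is applied during training only.
#'
#' @param mask_rate probability of zeroing an entry, in \[0,1\].
#' @param seed integer seed.
#' @export
corruption_config <- function(mask_rate = 0.3, seed = 1L) {
  if (mask_rate < 0 || mask_rate > 1) amn_stop("mask_rate must be in [0,1]", "value_error")
  structure(list(mask_rate = mask_rate, seed = as.integer(seed)),
            class = "corruption_config")
}

#' Corrupt a vector by random masking
#'
#' @param x finite numeric vector.
#' @param cfg a [corruption_config()].
#' @return `x` with each entry independently zeroed with probability
#'   `cfg$mask_rate`; deterministic under a fixed seed.
#' @export
corrupt <- function(x, cfg) {
  if (any(!is.finite(x))) amn_stop("input to corrupt must be finite", "value_error")
  if (cfg$mask_rate == 0) return(x)
  with_seed(cfg$seed, x * (runif(length(x)) >= cfg$mask_rate))
}

#' Encode an input pair into a latent factor
#'
#' `g(W1 s_tilde + V1 sim_tilde + b_enc)`.
#'
#' @param s_tilde (corrupted) association profile.
#' @param sim_tilde (corrupted) similarity profile.
#' @param p an `ae_params` object.
#' @return numeric latent vector of length `p$d`.
#' @export
encode <- function(s_tilde, sim_tilde, p) {
  if (length(s_tilde) != ncol(p$W1) || length(sim_tilde) != ncol(p$V1)) {
    amn_stop("input lengths do not match encoder weights", "shape_error")
  }
  g <- act_fun(p$activation_enc)
  as.vector(g(p$W1 %*% s_tilde + p$V1 %*% sim_tilde + p$b_enc))
}

#' Decode a latent factor to the association space
#'
#' `f(W2 z + b_rec_assoc)`; with logistic `f` the reconstruction lies in
#' (0,1), matching binary association targets.
#'
#' @param latent latent vector of length `p$d`.
#' @param p an `ae_params` object.
#' @export
decode_association <- function(latent, p) {
  if (length(latent) != p$d) amn_stop("latent length does not match d", "shape_error")
  f <- act_fun(p$activation_dec)
  as.vector(f(p$W2 %*% latent + p$b_rec_assoc))
}

#' Decode a latent factor to the similarity space
#'
#' `f(V2 z + b_rec_sim)`.
#'
#' @inheritParams decode_association
#' @export
decode_similarity <- function(latent, p) {
  if (length(latent) != p$d) amn_stop("latent length does not match d", "shape_error")
  f <- act_fun(p$activation_dec)
  as.vector(f(p$V2 %*% latent + p$b_rec_sim))
}

#' Balance and regularization weights of the autoencoder losses
#'
#' `alpha` (drug side) and `beta` (disease side) balance the association
#' reconstruction error against the similarity reconstruction error;
#' `lambda` and `delta` weight the squared-norm penalty on the side's four
#' weight matrices (encoder W1/V1 and decoders W2/V2; biases unpenalized).
#'
#' @param alpha,beta reals in \[0,1\].
#' @param lambda,delta nonnegative reals.
#' @export
ae_loss_weights <- function(alpha = 0.5, beta = 0.5, lambda = 0.001, delta = 0.001) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    amn_stop("alpha and beta must be in [0,1]", "value_error")
  }
  if (lambda < 0 || delta < 0) amn_stop("lambda and delta must be >= 0", "value_error")
  structure(list(alpha = alpha, beta = beta, lambda = lambda, delta = delta),
            class = "ae_loss_weights")
}

#' Denoising autoencoder loss for one input pair
#'
#' `a * ||s - s_hat||^2 + (1 - a) * ||sim - sim_hat||^2 + l * (sum of squared
#' weight-matrix norms)`, where `(a, l)` is `(alpha, lambda)` for the drug
#' side and `(beta, delta)` for the disease side. Reconstruction targets are
#' the clean (uncorrupted) profiles.
#'
#' @param s,s_hat clean association profile and its reconstruction.
#' @param sim,sim_hat clean similarity profile and its reconstruction.
#' @param weights an [ae_loss_weights()].
#' @param params an `ae_params` object supplying the penalized weight
#'   matrices, or `NULL` for no penalty term.
#' @param side `"drug"` or `"disease"`.
#' @return nonnegative scalar loss.
#' @export
ae_loss <- function(s, s_hat, sim, sim_hat, weights, params = NULL,
                    side = c("drug", "disease")) {
  side <- match.arg(side)
  if (length(s) != length(s_hat) || length(sim) != length(sim_hat)) {
    amn_stop("reconstruction lengths disagree", "shape_error")
  }
  a <- if (side == "drug") weights$alpha else weights$beta
  l <- if (side == "drug") weights$lambda else weights$delta
  if (a < 0 || a > 1) amn_stop("balance weight outside [0,1]", "value_error")
  reg <- 0
  if (!is.null(params) && l > 0) {
    reg <- l * (sum(params$W1^2) + sum(params$V1^2) +
                sum(params$W2^2) + sum(params$V2^2))
  }
  a * sum((s - s_hat)^2) + (1 - a) * sum((sim - sim_hat)^2) + reg
}
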