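#' Training configuration
#'
#' Hyperparameters of the joint objective
#' `L = L_r + phi * L_d + psi * L_p`, where `L_r` is the binary
#' cross-entropy over positive pairs and sampled negatives and `L_d`, `L_p`
#' are the drug- and disease-side autoencoder losses, and of the optimizer
#' (minibatch adaptive-moment gradient descent).
#'
#' @param alpha,beta,lambda,delta see [ae_loss_weights()].
#' @param phi,psi nonnegative weights of the two autoencoder losses in the
#'   total objective.
#' @param neg_ratio negatives sampled per positive, each epoch.
#' @param learning_rate optimizer step size.
#' @param epochs number of passes; 0 returns the initialized (untrained)
#'   model, useful as a baseline.
#' @param batch_size minibatch size.
#' @param mask_rate input corruption rate of the denoising autoencoders.
#' @param seed integer seed controlling initialization, negative sampling,
#'   corruption masks and shuffling; identical configurations are
#'   bit-reproducible.
#' @param patience early-stopping patience (epochs without validation AUC
#'   improvement) when a validation split is supplied to [train_amnet()].
#' @export
amn_config <- function(alpha = 0.5, beta = 0.5, lambda = 0.001, delta = 0.001,
                       phi = 0.1, psi = 0.1, neg_ratio = 1L,
                       learning_rate = 0.01, epochs = 100L, batch_size = 512L,
                       mask_rate = 0.3, seed = 42L, patience = 10L) {
  w <- ae_loss_weights(alpha, beta, lambda, delta)
  if (phi < 0 || psi < 0) amn_stop("phi and psi must be >= 0", "value_error")
  if (neg_ratio < 1) amn_stop("neg_ratio must be a positive integer", "value_error")
  if (learning_rate <= 0) amn_stop("learning_rate must be positive", "value_error")
  if (epochs < 0) amn_stop("epochs must be >= 0", "value_error")
  if (batch_size < 1) amn_stop("batch_size must be positive", "value_error")
  if (mask_rate < 0 || mask_rate > 1) amn_stop("mask_rate must be in [0,1]", "value_error")
  structure(list(alpha = w$alpha, beta = w$beta, lambda = w$lambda,
                 delta = w$delta, phi = phi, psi = psi,
                 neg_ratio = as.integer(neg_ratio),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), mask_rate = mask_rate,
                 seed = as.integer(seed), patience = as.integer(patience)),
            class = "amn_config")
}

#' Initialize an untrained model on a dataset bundle
#'
#' Gaussian initialization (sd 0.1) of both autoencoders, the per-drug
#' external memory table, and the fusion output layer.
#'
#' @param bundle a [dataset_bundle()].
#' @param latent_dim latent factor dimension d.
#' @param memory_dim external memory dimension (independent of d).
#' @param eta balance in \[0,1\] between the latent-factor output
#'   (`eta`) and the neighborhood output (`1 - eta`).
#' @param activation_enc,activation_dec autoencoder activations.
#' @param seed integer seed.
#' @return object of class `amn_model` with fields `drug_ae`, `disease_ae`,
#'   `memory`, `fusion` (`h`, `w`, `b`, `eta`, `out_activation`), `train`
#'   (the frozen neighbor source), `drug_sim`, `disease_sim`.
#' @export
init_model <- function(bundle, latent_dim = 64L, memory_dim = 64L, eta = 0.7,
                       activation_enc = "relu", activation_dec = "logistic",
                       seed = 42L) {
  if (eta < 0 || eta > 1) amn_stop("eta must be in [0,1]", "value_error")
  a <- bundle$associations
  m <- nrow(a$values); n <- ncol(a$values)
  drug_ae <- init_autoencoder(n, m, latent_dim, activation_enc, activation_dec,
                              seed = derive_seed(seed, 0L, 0L))
  disease_ae <- init_autoencoder(m, n, latent_dim, activation_enc, activation_dec,
                                 seed = derive_seed(seed, 0L, 1L))
  memory <- init_memory(m, memory_dim, derive_seed(seed, 0L, 2L))
  fus <- with_seed(derive_seed(seed, 0L, 3L), list(
    h = rnorm(latent_dim, 0, 0.1),
    w = rnorm(memory_dim, 0, 0.1),
    b = 0,
    eta = eta,
    out_activation = "logistic"
  ))
  structure(list(drug_ae = drug_ae, disease_ae = disease_ae, memory = memory,
                 fusion = fus, train = a, drug_sim = bundle$drug_sim,
                 disease_sim = bundle$disease_sim,
                 latent_dim = as.integer(latent_dim),
                 memory_dim = as.integer(memory_dim),
                 trace = NULL, config = NULL),
            class = "amn_model")
}

#' @export
print.amn_model <- function(x, ...) {
  cat(sprintf(paste0("<amn_model> d=%d, memory_dim=%d, eta=%.2f, ",
                     "%d drugs x %d diseases, %s\n"),
              x$latent_dim, x$memory_dim, x$fusion$eta,
              nrow(x$train$values), ncol(x$train$values),
              if (is.null(x$trace)) "untrained" else
                sprintf("trained %d epochs", max(x$trace$epoch))))
  invisible(x)
}

# Flat parameter view used by the optimizer and the gradient checker.
get_params <- function(model) {
  da <- model$drug_ae; ea <- model$disease_ae
  list(dW1 = da$W1, dV1 = da$V1, db = da$b_enc, dW2 = da$W2, dba = da$b_rec_assoc,
       dV2 = da$V2, dbs = da$b_rec_sim,
       eW1 = ea$W1, eV1 = ea$V1, eb = ea$b_enc, eW2 = ea$W2, eba = ea$b_rec_assoc,
       eV2 = ea$V2, ebs = ea$b_rec_sim,
       C = model$memory, h = model$fusion$h, w = model$fusion$w,
       b = model$fusion$b)
}

set_params <- function(model, p) {
  model$drug_ae$W1 <- p$dW1; model$drug_ae$V1 <- p$dV1
  model$drug_ae$b_enc <- p$db; model$drug_ae$W2 <- p$dW2
  model$drug_ae$b_rec_assoc <- p$dba; model$drug_ae$V2 <- p$dV2
  model$drug_ae$b_rec_sim <- p$dbs
  model$disease_ae$W1 <- p$eW1; model$disease_ae$V1 <- p$eV1
  model$disease_ae$b_enc <- p$eb; model$disease_ae$W2 <- p$eW2
  model$disease_ae$b_rec_assoc <- p$eba; model$disease_ae$V2 <- p$eV2
  model$disease_ae$b_rec_sim <- p$ebs
  model$memory <- p$C; model$fusion$h <- p$h; model$fusion$w <- p$w
  model$fusion$b <- p$b
  model
}

pack_params <- function(p) unlist(p, use.names = FALSE)

unpack_params <- function(template, v) {
  out <- template; pos <- 0L
  for (nm in names(template)) {
    len <- length(template[[nm]])
    x <- v[pos + seq_len(len)]
    if (is.matrix(template[[nm]])) dim(x) <- dim(template[[nm]])
    out[[nm]] <- x
    pos <- pos + len
  }
  out
}

# Draw corruption masks for one epoch: corrupted copies of the association
# matrix (independently for each side) and of the two similarity matrices.
make_masks <- function(model, mask_rate, seed) {
  R <- model$train$values; DS <- model$drug_sim$values; PS <- model$disease_sim$values
  if (mask_rate == 0) {
    return(list(Rd = R, DSd = DS, Re = R, PSe = PS))
  }
  with_seed(seed, list(
    Rd = R * (matrix(runif(length(R)), nrow(R)) >= mask_rate),
    DSd = DS * (matrix(runif(length(DS)), nrow(DS)) >= mask_rate),
    Re = R * (matrix(runif(length(R)), nrow(R)) >= mask_rate),
    PSe = PS * (matrix(runif(length(PS)), nrow(PS)) >= mask_rate)
  ))
}

#' Joint objective and analytic gradient
#'
#' Evaluates the total loss `L_r + phi * L_d + psi * L_p` on a batch of
#' labelled pairs under fixed corruption masks, together with its exact
#' gradient with respect to every trainable parameter (both autoencoders,
#' the memory table and the output layer), obtained by backpropagation
#' through the attention softmax, the memory pooling and the encoders. The
#' same function drives the optimizer and the finite-difference gradient
#' tests. `L_d`/`L_p` sum over all drugs/diseases; `L_r` over the batch.
#'
#' During training the latent factors fed to the prediction path are the
#' encodings of the corrupted inputs (denoising convention); pass
#' `masks = NULL` for the clean forward pass.
#'
#' @param model an `amn_model`.
#' @param batch data.frame with integer columns `drug`, `disease` and binary
#'   `label`.
#' @param masks corruption masks from the internal mask generator, or `NULL`
#'   for no corruption.
#' @param weights an [ae_loss_weights()].
#' @param phi,psi autoencoder loss weights in the total objective.
#' @return list with `loss`, `bce`, `l_d`, `l_p` and `grad` (named list
#'   matching the internal flat parameter view).
#' @export
amn_objective <- function(model, batch, masks = NULL,
                          weights = ae_loss_weights(), phi = 0.1, psi = 0.1) {
  R <- model$train$values; DS <- model$drug_sim$values; PS <- model$disease_sim$values
  m <- nrow(R); n <- ncol(R)
  if (is.null(masks)) masks <- list(Rd = R, DSd = DS, Re = R, PSe = PS)
  p <- get_params(model)
  g <- act_fun(model$drug_ae$activation_enc)
  gp <- act_deriv(model$drug_ae$activation_enc)
  f <- act_fun(model$drug_ae$activation_dec)
  fp <- act_deriv(model$drug_ae$activation_dec)
  eta <- model$fusion$eta
  alpha <- weights$alpha; beta <- weights$beta
  lambda <- weights$lambda; delta <- weights$delta

  ## ---- forward: drug autoencoder over all drugs (columns of U) ----
  preU <- p$dW1 %*% t(masks$Rd) + p$dV1 %*% t(masks$DSd) + p$db   # d x m
  U <- g(preU)
  preSd <- p$dW2 %*% U + p$dba                                    # n x m
  Shat <- f(preSd)
  preDd <- p$dV2 %*% U + p$dbs                                    # m x m
  DShat <- f(preDd)
  Ed1 <- Shat - t(R); Ed2 <- DShat - t(DS)
  l_d <- alpha * sum(Ed1^2) + (1 - alpha) * sum(Ed2^2) +
    lambda * (sum(p$dW1^2) + sum(p$dV1^2) + sum(p$dW2^2) + sum(p$dV2^2))

  ## ---- forward: disease autoencoder over all diseases (columns of V) ----
  preV <- p$eW1 %*% masks$Re + p$eV1 %*% t(masks$PSe) + p$eb      # d x n
  V <- g(preV)
  preSe <- p$eW2 %*% V + p$eba                                    # m x n
  Rhat <- f(preSe)
  preDe <- p$eV2 %*% V + p$ebs                                    # n x n
  PShat <- f(preDe)
  Ee1 <- Rhat - R; Ee2 <- PShat - t(PS)
  l_p <- beta * sum(Ee1^2) + (1 - beta) * sum(Ee2^2) +
    delta * (sum(p$eW1^2) + sum(p$eV1^2) + sum(p$eW2^2) + sum(p$eV2^2))

  ## ---- forward + backward: prediction loss, grouped by disease ----
  d <- model$latent_dim
  dU <- matrix(0, d, m); dV <- matrix(0, d, n)
  dC <- matrix(0, nrow(p$C), ncol(p$C))
  dh <- numeric(d); dw <- numeric(length(p$w)); db0 <- 0
  bce <- 0
  groups <- split(seq_len(nrow(batch)), batch$disease)
  for (jc in names(groups)) {
    j <- as.integer(jc)
    rows <- groups[[jc]]
    I <- batch$drug[rows]; r <- batch$label[rows]
    t_n <- length(I)
    N <- which(R[, j] == 1)
    k <- length(N)
    uI <- U[, I, drop = FALSE]; vj <- V[, j]
    lat <- as.vector(crossprod(uI, p$h * vj))
    if (k > 0) {
      A <- U[, N, drop = FALSE]
      P <- crossprod(A, uI)                       # k x t
      selfpos <- match(I, N)
      hit <- which(!is.na(selfpos))
      if (length(hit)) P[cbind(selfpos[hit], hit)] <- -Inf
      mx <- apply(P, 2, max)
      mx[!is.finite(mx)] <- 0
      Eq <- exp(P - rep(mx, each = k))
      ssum <- colSums(Eq)
      denom <- ifelse(ssum > 0, ssum, 1)
      Q <- Eq / rep(denom, each = k)
      Cn <- p$C[N, , drop = FALSE]                # k x l
      O <- crossprod(Cn, Q)                       # l x t
      nb <- as.vector(crossprod(O, p$w))
    } else {
      nb <- numeric(t_n)
    }
    z <- eta * lat + (1 - eta) * nb + p$b
    rhat <- plogis(z)
    rh <- pmin(pmax(rhat, 1e-12), 1 - 1e-12)
    bce <- bce - sum(r * log(rh) + (1 - r) * log(1 - rh))
    dz <- rhat - r
    db0 <- db0 + sum(dz)
    dh <- dh + eta * as.vector((uI * vj) %*% dz)
    dU[, I] <- dU[, I] + eta * outer(p$h * vj, dz)
    dV[, j] <- dV[, j] + eta * p$h * as.vector(uI %*% dz)
    if (k > 0) {
      dw <- dw + (1 - eta) * as.vector(O %*% dz)
      dO <- (1 - eta) * outer(p$w, dz)            # l x t
      dC[N, ] <- dC[N, ] + Q %*% t(dO)
      dQ <- Cn %*% dO                             # k x t
      dP <- Q * (dQ - rep(colSums(Q * dQ), each = k))
      dU[, N] <- dU[, N] + uI %*% t(dP)
      dU[, I] <- dU[, I] + A %*% dP
    }
  }

  ## ---- backward: drug autoencoder ----
  dpreSd <- 2 * alpha * Ed1 * fp(preSd, Shat)
  dpreDd <- 2 * (1 - alpha) * Ed2 * fp(preDd, DShat)
  gW2d <- dpreSd %*% t(U) + 2 * lambda * p$dW2
  gV2d <- dpreDd %*% t(U) + 2 * lambda * p$dV2
  dU_ld <- crossprod(p$dW2, dpreSd) + crossprod(p$dV2, dpreDd)
  dpreU <- (dU + phi * dU_ld) * gp(preU, U)
  grad <- list(
    dW1 = dpreU %*% masks$Rd + phi * 2 * lambda * p$dW1,
    dV1 = dpreU %*% masks$DSd + phi * 2 * lambda * p$dV1,
    db = rowSums(dpreU),
    dW2 = phi * gW2d,
    dba = phi * rowSums(dpreSd),
    dV2 = phi * gV2d,
    dbs = phi * rowSums(dpreDd)
  )

  ## ---- backward: disease autoencoder ----
  dpreSe <- 2 * beta * Ee1 * fp(preSe, Rhat)
  dpreDe <- 2 * (1 - beta) * Ee2 * fp(preDe, PShat)
  gW2e <- dpreSe %*% t(V) + 2 * delta * p$eW2
  gV2e <- dpreDe %*% t(V) + 2 * delta * p$eV2
  dV_lp <- crossprod(p$eW2, dpreSe) + crossprod(p$eV2, dpreDe)
  dpreV <- (dV + psi * dV_lp) * gp(preV, V)
  grad$eW1 <- dpreV %*% t(masks$Re) + psi * 2 * delta * p$eW1
  grad$eV1 <- dpreV %*% masks$PSe + psi * 2 * delta * p$eV1
  grad$eb <- rowSums(dpreV)
  grad$eW2 <- psi * gW2e
  grad$eba <- psi * rowSums(dpreSe)
  grad$eV2 <- psi * gV2e
  grad$ebs <- psi * rowSums(dpreDe)

  grad$C <- dC; grad$h <- dh; grad$w <- dw; grad$b <- db0
  grad <- grad[names(p)]

  list(loss = bce + phi * l_d + psi * l_p, bce = bce, l_d = l_d, l_p = l_p,
       grad = grad)
}

# Clean-input latent factors for all drugs (columns of U) and diseases (V).
latent_factors <- function(model) {
  p <- get_params(model)
  g <- act_fun(model$drug_ae$activation_enc)
  R <- model$train$values
  U <- g(p$dW1 %*% t(R) + p$dV1 %*% t(model$drug_sim$values) + p$db)
  V <- g(p$eW1 %*% R + p$eV1 %*% t(model$disease_sim$values) + p$eb)
  list(U = U, V = V)
}

#' Predicted association score for one drug-disease pair
#'
#' Composes the three model components on clean inputs: the latent factors
#' of drug `i` and disease `j` from the autoencoders, the attention-pooled
#' neighborhood representation of the drugs associated with `j` in the
#' training matrix (with drug `i` excluded from its own neighbor set), and
#' the fused output
#' `F_out(eta * h'(drug_i * disease_j) + (1 - eta) * w'o_ij + b)`.
#'
#' @param model a trained (or initialized) `amn_model`.
#' @param drug_i,disease_j indices into the training matrix.
#' @return scalar score in (0,1) for the logistic output activation.
#' @export
predict_score <- function(model, drug_i, disease_j) {
  R <- model$train$values
  if (drug_i < 1 || drug_i > nrow(R)) amn_stop("drug index out of range", "index_error")
  if (disease_j < 1 || disease_j > ncol(R)) amn_stop("disease index out of range", "index_error")
  uv <- latent_factors(model)
  u <- uv$U[, drug_i]; v <- uv$V[, disease_j]
  N <- neighbor_set(model$train, disease_j, exclude_drug = drug_i)
  if (length(N) > 0) {
    pref <- preference_scores(u, t(uv$U[, N, drop = FALSE]))
    q <- attention_weights(pref)
    o <- neighborhood_representation(q, model$memory[N, , drop = FALSE])
  } else {
    o <- numeric(model$memory_dim)
  }
  fus <- model$fusion
  z <- fus$eta * sum(fus$h * (u * v)) + (1 - fus$eta) * sum(fus$w * o) + fus$b
  as.vector(act_fun(fus$out_activation)(z))
}

#' Score matrix for all drug-disease pairs
#'
#' Vectorized equivalent of calling [predict_score()] on every pair; used by
#' the evaluation protocols.
#'
#' @param model an `amn_model`.
#' @return m x n numeric matrix of scores.
#' @export
predict_matrix <- function(model) UseMethod("predict_matrix")

#' @export
predict_matrix.amn_model <- function(model) {
  R <- model$train$values
  m <- nrow(R); n <- ncol(R)
  uv <- latent_factors(model)
  fus <- model$fusion
  lat <- t(uv$U * fus$h) %*% uv$V                  # m x n
  nb <- matrix(0, m, n)
  if (fus$eta < 1) {
    for (j in seq_len(n)) {
      N <- which(R[, j] == 1)
      k <- length(N)
      if (k == 0) next
      P <- crossprod(uv$U[, N, drop = FALSE], uv$U)  # k x m
      P[cbind(seq_len(k), N)] <- -Inf                # self-exclusion
      mx <- apply(P, 2, max)
      mx[!is.finite(mx)] <- 0
      Eq <- exp(P - rep(mx, each = k))
      ssum <- colSums(Eq)
      Q <- Eq / rep(ifelse(ssum > 0, ssum, 1), each = k)
      O <- crossprod(model$memory[N, , drop = FALSE], Q)  # l x m
      nb[, j] <- as.vector(crossprod(O, fus$w))
    }
  }
  act_fun(fus$out_activation)(fus$eta * lat + (1 - fus$eta) * nb + fus$b)
}

#' Binary cross-entropy prediction loss
#'
#' `-sum(r * log(rhat) + (1 - r) * log(1 - rhat))` over a batch, with scores
#' clipped to `[1e-12, 1 - 1e-12]` to guard `log(0)`.
#'
#' @param batch data.frame with a binary `label` column, or a bare binary
#'   vector of labels.
#' @param scores predicted scores in (0,1), aligned with the batch.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(batch, scores) {
  r <- if (is.data.frame(batch)) batch$label else batch
  if (length(r) != length(scores)) amn_stop("batch and score lengths disagree", "shape_error")
  s <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  -sum(r * log(s) + (1 - r) * log(1 - s))
}

#' Total training loss
#'
#' `L = L_r + phi * L_d + psi * L_p`.
#'
#' @param bce prediction loss `L_r`.
#' @param drug_ae_loss,disease_ae_loss autoencoder losses `L_d`, `L_p`.
#' @param config an [amn_config()] supplying `phi` and `psi`.
#' @export
total_loss <- function(bce, drug_ae_loss, disease_ae_loss, config) {
  if (!all(is.finite(c(bce, drug_ae_loss, disease_ae_loss)))) {
    amn_stop("loss components must be finite", "value_error")
  }
  bce + config$phi * drug_ae_loss + config$psi * disease_ae_loss
}

#' Sample negative training pairs
#'
#' Uniform sample without replacement from the zero cells of the
#' association matrix, of size `neg_ratio` times the number of positives.
#' The effective seed is derived from `(seed, epoch)`, so each epoch draws a
#' fresh but reproducible sample.
#'
#' @param a an [association_matrix()].
#' @param neg_ratio negatives per positive.
#' @param seed base integer seed.
#' @param epoch epoch number (1-based).
#' @return data.frame with columns `drug`, `disease`, `label` (all 0).
#' @export
sample_negatives <- function(a, neg_ratio = 1L, seed = 42L, epoch = 1L) {
  zeros <- which(a$values == 0, arr.ind = TRUE)
  need <- neg_ratio * sum(a$values)
  if (nrow(zeros) < need) {
    amn_stop("not enough zero cells for the requested negative sample", "value_error")
  }
  idx <- with_seed(derive_seed(seed, epoch, 0L), sample(nrow(zeros), need))
  data.frame(drug = as.integer(zeros[idx, 1]), disease = as.integer(zeros[idx, 2]),
             label = 0)
}

adam_step <- function(p, grad, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(p)) {
    g <- grad[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(p = p, state = state)
}

#' Train the fused model
#'
#' Joint minibatch training of both denoising autoencoders, the external
#' memory table and the fusion output layer under
#' `L = L_r + phi * L_d + psi * L_p`, with adaptive-moment gradient updates.
#' Each epoch resamples `neg_ratio` negatives per positive and fresh
#' corruption masks; all randomness derives from `config$seed`, so runs are
#' bit-reproducible (single-threaded).
#'
#' @inheritParams init_model
#' @param config an [amn_config()].
#' @param validation optional list with `test_positives` and
#'   `test_negatives` (2-column index matrices); when supplied, training
#'   stops early after `config$patience` epochs without validation AUC
#'   improvement and the best-epoch parameters are returned.
#' @param pretrain_epochs optional number of epochs minimizing only
#'   `phi * L_d + psi * L_p` before joint training (off by default).
#' @param verbose print per-epoch losses.
#' @return a trained `amn_model`; `$trace` holds the per-epoch loss
#'   components (`epoch`, `loss`, `bce`, `l_d`, `l_p`).
#' @export
train_amnet <- function(bundle, latent_dim = 64L, memory_dim = 64L, eta = 0.7,
                        activation_enc = "relu", activation_dec = "logistic",
                        config = amn_config(), validation = NULL,
                        pretrain_epochs = 0L, verbose = FALSE) {
  a <- bundle$associations
  if (sum(a$values) < 1) amn_stop("training requires at least one positive", "value_error")
  model <- init_model(bundle, latent_dim, memory_dim, eta, activation_enc,
                      activation_dec, seed = config$seed)
  model$config <- config
  if (config$epochs == 0) return(model)
  weights <- ae_loss_weights(config$alpha, config$beta, config$lambda, config$delta)
  p <- get_params(model)
  state <- list(t = 0L,
                m = lapply(p, function(x) x * 0),
                v = lapply(p, function(x) x * 0))
  pos <- which(a$values == 1, arr.ind = TRUE)
  pos_df <- data.frame(drug = as.integer(pos[, 1]), disease = as.integer(pos[, 2]),
                       label = 1)
  trace <- vector("list", config$epochs)
  best <- list(auc = -Inf, p = p, since = 0L)
  run_epoch <- function(ep, p, state, joint) {
    masks <- make_masks(model, config$mask_rate, derive_seed(config$seed, ep, 1L))
    if (joint) {
      negs <- sample_negatives(a, config$neg_ratio, config$seed, ep)
      batch <- rbind(pos_df, negs)
      ord <- with_seed(derive_seed(config$seed, ep, 2L), sample(nrow(batch)))
      batch <- batch[ord, , drop = FALSE]
    } else {
      batch <- pos_df[0, , drop = FALSE]  # autoencoder pretraining only
    }
    nb <- max(1L, nrow(batch))
    starts <- seq(1L, nb, by = config$batch_size)
    ep_bce <- 0; l_d <- NA_real_; l_p <- NA_real_
    for (s in starts) {
      mb <- if (nrow(batch) > 0) {
        batch[s:min(s + config$batch_size - 1L, nrow(batch)), , drop = FALSE]
      } else batch
      model_s <- set_params(model, p)
      obj <- amn_objective(model_s, mb, masks, weights, config$phi, config$psi)
      if (!is.finite(obj$loss)) {
        amn_stop(sprintf("non-finite loss at epoch %d", ep), "training_error")
      }
      upd <- adam_step(p, obj$grad, state, config$learning_rate)
      p <- upd$p; state <- upd$state
      ep_bce <- ep_bce + obj$bce; l_d <- obj$l_d; l_p <- obj$l_p
    }
    list(p = p, state = state, bce = ep_bce, l_d = l_d, l_p = l_p)
  }
  if (pretrain_epochs > 0) {
    for (ep in seq_len(pretrain_epochs)) {
      res <- run_epoch(-ep, p, state, joint = FALSE)
      p <- res$p; state <- res$state
    }
    state <- list(t = 0L, m = lapply(p, function(x) x * 0),
                  v = lapply(p, function(x) x * 0))
  }
  stopped <- config$epochs
  for (ep in seq_len(config$epochs)) {
    res <- run_epoch(ep, p, state, joint = TRUE)
    p <- res$p; state <- res$state
    trace[[ep]] <- data.frame(epoch = ep,
                              loss = res$bce + config$phi * res$l_d +
                                config$psi * res$l_p,
                              bce = res$bce, l_d = res$l_d, l_p = res$l_p)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  bce %.4f  l_d %.2f  l_p %.2f",
                      ep, trace[[ep]]$loss, res$bce, res$l_d, res$l_p))
    }
    if (!is.null(validation)) {
      model_s <- set_params(model, p)
      S <- predict_matrix(model_s)
      sc <- c(S[validation$test_positives], S[validation$test_negatives])
      lb <- c(rep(1, nrow(validation$test_positives)),
              rep(0, nrow(validation$test_negatives)))
      va <- auc_score(sc, lb)
      if (va > best$auc) {
        best <- list(auc = va, p = p, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= config$patience) { stopped <- ep; break }
      }
    }
  }
  if (!is.null(validation) && is.finite(best$auc)) p <- best$p
  model <- set_params(model, p)
  model$trace <- do.call(rbind, trace[seq_len(stopped)])
  model
}

#' Save a trained model as a directory of text files
#'
#' Weight matrices are written as plain CSV (17 significant digits), the
#' training associations in MatrixMarket format with their id sidecar, the
#' similarity matrices in the standard CSV layout, and scalars/enums in a
#' JSON manifest. [load_amnet()] restores the model.
#'
#' @param model an `amn_model`.
#' @param dir output directory (created if needed).
#' @export
save_amnet <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- get_params(model)
  for (nm in names(p)) {
    write_dense_csv(as.matrix(p[[nm]]), file.path(dir, paste0(nm, ".csv")))
  }
  write_association_matrix(model$train, file.path(dir, "train.mtx"), "mtx")
  write_similarity_matrix(model$drug_sim, file.path(dir, "drug_sim.csv"))
  write_similarity_matrix(model$disease_sim, file.path(dir, "disease_sim.csv"))
  manifest <- list(latent_dim = model$latent_dim, memory_dim = model$memory_dim,
                   eta = model$fusion$eta, b = model$fusion$b,
                   out_activation = model$fusion$out_activation,
                   activation_enc = model$drug_ae$activation_enc,
                   activation_dec = model$drug_ae$activation_dec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Load a model saved by [save_amnet()]
#'
#' @param dir directory written by [save_amnet()].
#' @return an `amn_model`.
#' @export
load_amnet <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  train <- read_association_edges(file.path(dir, "train.mtx"), "mtx")
  drug_sim <- read_similarity_matrix(file.path(dir, "drug_sim.csv"), "drug")
  disease_sim <- read_similarity_matrix(file.path(dir, "disease_sim.csv"), "disease")
  bundle <- dataset_bundle(train, drug_sim, disease_sim)
  model <- init_model(bundle, manifest$latent_dim, manifest$memory_dim,
                      manifest$eta, manifest$activation_enc,
                      manifest$activation_dec, seed = 1L)
  p <- get_params(model)
  for (nm in names(p)) {
    x <- read_dense_csv(file.path(dir, paste0(nm, ".csv")))
    p[[nm]] <- if (is.matrix(p[[nm]])) x else as.vector(x)
  }
  p$b <- as.vector(p$b)
  model <- set_params(model, p)
  model$fusion$b <- as.numeric(model$fusion$b)
  model$fusion$out_activation <- manifest$out_activation
  model
}

# Plain numeric matrix CSV (no ids), 17 significant digits: lossless for
# doubles in practice.
write_dense_csv <- function(m, path) {
  lines <- apply(m, 1, function(row) paste(formatC(row, digits = 17, format = "g"),
                                           collapse = ","))
  writeLines(lines, path)
}

read_dense_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE, colClasses = "numeric"))
}

#' Default hyperparameter search grid
#'
#' The full grid: memory and latent dimensions in {16, 32, 64, 128, 256},
#' `eta`, `alpha`, `beta` in {0.1, 0.3, 0.5, 0.7, 0.9}, `lambda`, `delta` in
#' {0.1, 0.01, 0.001} and learning rate in {0.0001, 0.001, 0.05, 0.01}.
#'
#' @return named list of candidate values per hyperparameter.
#' @export
default_grid <- function() {
  list(memory_dim = c(16, 32, 64, 128, 256),
       latent_dim = c(16, 32, 64, 128, 256),
       eta = c(0.1, 0.3, 0.5, 0.7, 0.9),
       alpha = c(0.1, 0.3, 0.5, 0.7, 0.9),
       beta = c(0.1, 0.3, 0.5, 0.7, 0.9),
       lambda = c(0.1, 0.01, 0.001),
       delta = c(0.1, 0.01, 0.001),
       learning_rate = c(0.0001, 0.001, 0.05, 0.01))
}

#' Enumerate the Cartesian product of a hyperparameter grid
#'
#' @param grid named list of candidate values.
#' @return data.frame with one row per configuration, in lexicographic
#'   enumeration order (first hyperparameter varies fastest).
#' @export
enumerate_grid <- function(grid) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    amn_stop("grid must be nonempty", "value_error")
  }
  expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Grid search over hyperparameters
#'
#' Exhaustively evaluates configurations (optionally a random subsample) on
#' a held-out validation split of the positive pairs, selecting the argmax
#' of the validation metric; ties break toward the earliest configuration in
#' enumeration order.
#'
#' @param bundle a [dataset_bundle()].
#' @param grid named list of candidate values; entries may cover
#'   `latent_dim`, `memory_dim`, `eta`, `alpha`, `beta`, `lambda`, `delta`,
#'   `learning_rate`.
#' @param metric `"auc"` or `"aupr"` on the validation split.
#' @param val_fraction fraction of positives held out for validation.
#' @param config base [amn_config()]; grid values override its fields.
#' @param seed seed for the validation split and subsampling.
#' @param max_configs optional cap; configurations are subsampled uniformly.
#' @param scorer optional `function(config_row) -> numeric` replacing the
#'   train-and-validate evaluation (used for testing selection logic).
#' @return list with `best` (one-row data.frame), `results` (all evaluated
#'   configurations with their scores).
#' @export
grid_search_amnet <- function(bundle, grid = default_grid(),
                              metric = c("auc", "aupr"), val_fraction = 0.1,
                              config = amn_config(), seed = 1L,
                              max_configs = NULL, scorer = NULL) {
  metric <- match.arg(metric)
  configs <- enumerate_grid(grid)
  if (!is.null(max_configs) && nrow(configs) > max_configs) {
    keep <- with_seed(derive_seed(seed, 3L, 3L),
                      sort(sample(nrow(configs), max_configs)))
    configs <- configs[keep, , drop = FALSE]
  }
  if (is.null(scorer)) {
    a <- bundle$associations
    pos <- which(a$values == 1, arr.ind = TRUE)
    nval <- max(1L, round(val_fraction * nrow(pos)))
    vidx <- with_seed(derive_seed(seed, 4L, 3L), sample(nrow(pos), nval))
    val_pos <- pos[vidx, , drop = FALSE]
    train_vals <- a$values
    train_vals[val_pos] <- 0
    train_bundle <- dataset_bundle(
      association_matrix(train_vals, a$drug_ids, a$disease_ids),
      bundle$drug_sim, bundle$disease_sim)
    val_neg <- which(a$values == 0, arr.ind = TRUE)
    scorer <- function(row) {
      cfg <- config
      for (nm in intersect(names(row), names(cfg))) cfg[[nm]] <- row[[nm]]
      model <- train_amnet(train_bundle,
                           latent_dim = row$latent_dim %||% 64L,
                           memory_dim = row$memory_dim %||% 64L,
                           eta = row$eta %||% 0.7,
                           config = cfg)
      S <- predict_matrix(model)
      sc <- c(S[val_pos], S[val_neg])
      lb <- c(rep(1, nrow(val_pos)), rep(0, nrow(val_neg)))
      if (metric == "auc") auc_score(sc, lb) else aupr_score(sc, lb)
    }
  }
  scores <- vapply(seq_len(nrow(configs)),
                   function(i) scorer(configs[i, , drop = FALSE]), numeric(1))
  configs$score <- scores
  list(best = configs[which.max(scores), , drop = FALSE], results = configs)
}
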