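# Independent brute-force oracles used to verify the vectorized
# implementations. Each is written in the most naive form available
# (elementwise loops, pair counting, threshold sweeps) so it shares no code
# path with the functions it checks.

# Softmax via the overflow-safe identity q_i = 1 / sum_k exp(p_k - p_i),
# a different algebraic route than max-subtraction.
oracle_softmax <- function(p) {
  vapply(seq_along(p), function(i) 1 / sum(exp(p - p[i])), numeric(1))
}

oracle_weighted_sum <- function(q, rows) {
  out <- numeric(ncol(rows))
  for (n in seq_along(q)) out <- out + q[n] * rows[n, ]
  out
}

oracle_inner <- function(x, y) sum(mapply(`*`, x, y))

oracle_encode <- function(s, sim, p, g) {
  d <- p$d
  out <- numeric(d)
  for (k in seq_len(d)) {
    out[k] <- g(oracle_inner(p$W1[k, ], s) + oracle_inner(p$V1[k, ], sim) + p$b_enc[k])
  }
  out
}

oracle_decode <- function(z, W, b, f) {
  vapply(seq_len(nrow(W)), function(k) f(oracle_inner(W[k, ], z) + b[k]), numeric(1))
}

oracle_ae_loss <- function(s, s_hat, sim, sim_hat, a, l, params = NULL) {
  res <- 0
  for (k in seq_along(s)) res <- res + a * (s[k] - s_hat[k])^2
  for (k in seq_along(sim)) res <- res + (1 - a) * (sim[k] - sim_hat[k])^2
  if (!is.null(params)) {
    for (W in list(params$W1, params$V1, params$W2, params$V2)) {
      res <- res + l * sum(W * W)
    }
  }
  res
}

oracle_bce <- function(labels, scores) {
  tot <- 0
  for (k in seq_along(labels)) {
    s <- min(max(scores[k], 1e-12), 1 - 1e-12)
    tot <- tot - (labels[k] * log(s) + (1 - labels[k]) * log(1 - s))
  }
  tot
}

# AUC by exhaustive positive/negative pair counting, ties worth 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# AUPR by a from-scratch sweep over every distinct score threshold.
oracle_aupr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prevR <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    P <- sum(labels[sel] == 1) / sum(sel)
    R <- sum(labels[sel] == 1) / npos
    area <- area + (R - prevR) * P
    prevR <- R
  }
  area
}

# Hit ratio by explicit candidate enumeration and stable sorting.
oracle_hr <- function(S, test_positives, train_values, k) {
  hits <- 0
  for (r in seq_len(nrow(test_positives))) {
    i <- test_positives[r, 1]; j <- test_positives[r, 2]
    cand <- which(train_values[i, ] == 0)
    ranked <- cand[order(-S[i, cand], cand)]
    if (which(ranked == j) <= k) hits <- hits + 1
  }
  hits / nrow(test_positives)
}

# Score composition from the exported building blocks plus scalar
# arithmetic, mirroring the fused predictor step by step.
oracle_fused_score <- function(model, i, j) {
  g <- function(x) pmax(x, 0)
  da <- model$drug_ae; ea <- model$disease_ae
  R <- model$train$values
  u <- oracle_encode(R[i, ], model$drug_sim$values[i, ], da, g)
  v <- oracle_encode(R[, j], model$disease_sim$values[j, ], ea, g)
  N <- setdiff(which(R[, j] == 1), i)
  o <- numeric(model$memory_dim)
  if (length(N) > 0) {
    pref <- vapply(N, function(nn) {
      un <- oracle_encode(R[nn, ], model$drug_sim$values[nn, ], da, g)
      oracle_inner(u, un)
    }, numeric(1))
    q <- oracle_softmax(pref)
    o <- oracle_weighted_sum(q, model$memory[N, , drop = FALSE])
  }
  fus <- model$fusion
  z <- fus$eta * oracle_inner(fus$h, u * v) + (1 - fus$eta) * oracle_inner(fus$w, o) + fus$b
  1 / (1 + exp(-z))
}

# Central finite differences of the joint objective over the flat
# parameter vector.
fd_gradient <- function(model, batch, masks, weights, phi, psi, h = 1e-5) {
  p0 <- amnet:::get_params(model)
  v0 <- amnet:::pack_params(p0)
  fd <- numeric(length(v0))
  for (k in seq_along(v0)) {
    vp <- v0; vp[k] <- vp[k] + h
    vm <- v0; vm[k] <- vm[k] - h
    lp <- amn_objective(amnet:::set_params(model, amnet:::unpack_params(p0, vp)),
                        batch, masks, weights, phi, psi)$loss
    lm <- amn_objective(amnet:::set_params(model, amnet:::unpack_params(p0, vm)),
                        batch, masks, weights, phi, psi)$loss
    fd[k] <- (lp - lm) / (2 * h)
  }
  fd
}
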