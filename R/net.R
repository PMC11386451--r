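# Minimal feed-forward softmax network trained with minibatch Adam.
# Shared by the patch classifier head and the probability-fusion model.
# hidden_units = 0 gives plain multinomial logistic regression.

mlp_init <- function(d, hidden_units, n_classes, seed) {
  with_seed(seed, {
    if (hidden_units > 0) {
      list(W1 = matrix(stats::rnorm(d * hidden_units, 0, sqrt(2 / d)),
                       d, hidden_units),
           b1 = rep(0, hidden_units),
           W2 = matrix(0, hidden_units, n_classes),
           b2 = rep(0, n_classes))
    } else {
      list(W2 = matrix(0, d, n_classes), b2 = rep(0, n_classes))
    }
  })
}

mlp_forward <- function(params, X, want_hidden = FALSE) {
  if (!is.null(params$W1)) {
    H <- X %*% params$W1
    H <- sweep(H, 2, params$b1, "+")
    H[H < 0] <- 0
  } else {
    H <- X
  }
  Z <- H %*% params$W2
  Z <- sweep(Z, 2, params$b2, "+")
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  if (want_hidden) list(P = P, H = H) else P
}

# One cross-entropy gradient step worth of gradients for a minibatch.
mlp_gradients <- function(params, X, y, n_classes) {
  f <- mlp_forward(params, X, want_hidden = TRUE)
  n <- nrow(X)
  G <- f$P
  G[cbind(seq_len(n), y)] <- G[cbind(seq_len(n), y)] - 1
  G <- G / n
  g <- list(W2 = crossprod(f$H, G), b2 = colSums(G))
  if (!is.null(params$W1)) {
    GH <- G %*% t(params$W2)
    GH[f$H <= 0] <- 0
    g$W1 <- crossprod(X, GH)
    g$b1 <- colSums(GH)
  }
  g
}

#' @noRd
mlp_train <- function(X, y, n_classes, hidden_units = 32, epochs = 15,
                      learning_rate = 1e-4, batch_size = 64, weights = NULL,
                      weight_decay = 0, seed = 1, epoch_callback = NULL) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (any(y < 1 | y > n_classes)) stop_input("labels outside 1..n_classes")
  n <- nrow(X)
  params <- mlp_init(ncol(X), hidden_units, n_classes,
                     seed = sub_seed(seed, "init"))
  M <- lapply(params, function(p) p * 0)
  V <- M
  t <- 0
  b1 <- 0.9; b2m <- 0.999; eps <- 1e-8
  if (is.null(weights)) weights <- rep(1, n)
  best <- list(score = -Inf, params = params)
  trace <- numeric(epochs)
  with_seed(sub_seed(seed, "epochs"), {
    for (ep in seq_len(epochs)) {
      # weighted sampling with replacement: one epoch = n draws
      ord <- sample.int(n, n, replace = TRUE, prob = weights)
      for (s in seq(1, n, by = batch_size)) {
        ii <- ord[s:min(s + batch_size - 1, n)]
        g <- mlp_gradients(params, X[ii, , drop = FALSE], y[ii], n_classes)
        if (!all(vapply(g, function(z) all(is.finite(z)), logical(1)))) {
          stop_input("non-finite loss gradient at epoch %d", ep)
        }
        t <- t + 1
        for (nm in names(params)) {
          M[[nm]] <- b1 * M[[nm]] + (1 - b1) * g[[nm]]
          V[[nm]] <- b2m * V[[nm]] + (1 - b2m) * g[[nm]]^2
          params[[nm]] <- params[[nm]] - learning_rate *
            (M[[nm]] / (1 - b1^t)) / (sqrt(V[[nm]] / (1 - b2m^t)) + eps)
          if (weight_decay > 0 && nm %in% c("W1", "W2")) {
            params[[nm]] <- params[[nm]] * (1 - learning_rate * weight_decay)
          }
        }
      }
      if (!is.null(epoch_callback)) {
        sc <- epoch_callback(params)
        trace[ep] <- sc
        if (sc > best$score) best <- list(score = sc, params = params)
      }
    }
  })
  if (is.null(epoch_callback)) best <- list(score = NA_real_, params = params)
  list(params = best$params, best_score = best$score,
       hidden_units = hidden_units, n_classes = n_classes,
       epoch_trace = if (!is.null(epoch_callback)) trace else NULL)
}

#' @noRd
mlp_predict <- function(net, X) {
  mlp_forward(net$params, X)
}
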