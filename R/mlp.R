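# A compact dense feed-forward network for binary classification, supporting
# the tunable axes of the evaluation grid: arbitrary hidden layer sizes,
# tanh/relu activations, sgd (with momentum 0.9) or adam, and the initial
# learning rate. Full support for two-hidden-layer architectures is the
# reason this is implemented here rather than delegated to nnet (single
# hidden layer, logistic only).

mlp_init <- function(sizes) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    limit <- sqrt(6 / (fan_in + fan_out))   # Glorot uniform
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
    b[[l]] <- rep(0, fan_out)
  }
  list(W = W, b = b)
}

mlp_act <- function(z, activation) {
  switch(activation, tanh = tanh(z), relu = pmax(z, 0),
         ls_stop("invalid_config", "unknown activation: %s", activation))
}

mlp_act_grad <- function(a, activation) {
  switch(activation, tanh = 1 - a^2, relu = (a > 0) * 1)
}

mlp_forward <- function(net, X, activation) {
  A <- list(X)
  L <- length(net$W)
  for (l in seq_len(L - 1)) {
    A[[l + 1]] <- mlp_act(sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+"), activation)
  }
  z <- sweep(A[[L]] %*% net$W[[L]], 2, net$b[[L]], "+")
  A[[L + 1]] <- 1 / (1 + exp(-z))   # logistic output
  A
}

# Train with mini-batch gradient descent on binary cross-entropy.
mlp_fit <- function(X, y, hidden = c(50), activation = "relu", solver = "adam",
                    learning_rate_init = 0.001, max_iter = 200, batch_size = 32,
                    tol = 1e-4, n_iter_no_change = 10, seed = 42) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  sizes <- c(p, hidden, 1)
  with_stream(seed, "mlp_fit", {
    net <- mlp_init(sizes)
    L <- length(net$W)
    mom <- lapply(net$W, function(w) w * 0)
    momb <- lapply(net$b, function(b) b * 0)
    mW <- mom; vW <- mom; mB <- momb; vB <- momb
    best_loss <- Inf; stall <- 0; t_adam <- 0
    converged <- FALSE
    for (epoch in seq_len(max_iter)) {
      ord <- sample(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        A <- mlp_forward(net, Xb, activation)
        m <- length(idx)
        delta <- (A[[L + 1]] - yb) / m   # dLoss/dz for logistic + cross-entropy
        gW <- vector("list", L); gB <- vector("list", L)
        for (l in L:1) {
          gW[[l]] <- crossprod(A[[l]], delta)
          gB[[l]] <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(net$W[[l]])) * mlp_act_grad(A[[l]], activation)
          }
        }
        if (solver == "sgd") {
          for (l in seq_len(L)) {
            mom[[l]] <- 0.9 * mom[[l]] - learning_rate_init * gW[[l]]
            momb[[l]] <- 0.9 * momb[[l]] - learning_rate_init * gB[[l]]
            net$W[[l]] <- net$W[[l]] + mom[[l]]
            net$b[[l]] <- net$b[[l]] + momb[[l]]
          }
        } else if (solver == "adam") {
          t_adam <- t_adam + 1
          b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
          for (l in seq_len(L)) {
            mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
            vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
            mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB[[l]]
            vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB[[l]]^2
            lr <- learning_rate_init * sqrt(1 - b2^t_adam) / (1 - b1^t_adam)
            net$W[[l]] <- net$W[[l]] - lr * mW[[l]] / (sqrt(vW[[l]]) + eps)
            net$b[[l]] <- net$b[[l]] - lr * mB[[l]] / (sqrt(vB[[l]]) + eps)
          }
        } else {
          ls_stop("invalid_config", "unknown solver: %s", solver)
        }
      }
      pr <- mlp_forward(net, X, activation)[[L + 1]]
      pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
      loss <- -mean(y * log(pr) + (1 - y) * log(1 - pr))
      if (loss < best_loss - tol) { best_loss <- loss; stall <- 0 } else stall <- stall + 1
      if (stall >= n_iter_no_change) { converged <- TRUE; break }
    }
    structure(list(net = net, activation = activation, solver = solver,
                   hidden = hidden, converged = converged, loss = best_loss),
              class = "ligandscreen_mlp")
  })
}

mlp_predict <- function(model, X) {
  A <- mlp_forward(model$net, as.matrix(X), model$activation)
  as.numeric(A[[length(A)]])
}
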