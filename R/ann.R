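#' Two-layer feedforward network
#'
#' A feedforward network with one tan-sigmoid (tanh) hidden layer and either a
#' linear output (regression) or a softmax output (classification). Following
#' the convention of the toolbox trainers this package mirrors, softmax
#' networks are trained against one-hot targets with a squared-error objective
#' on the linear output activations; the softmax is applied at inference.
#'
#' @param n_in number of inputs.
#' @param n_hidden hidden units (default 10).
#' @param n_out number of outputs.
#' @param out_act `"linear"` or `"softmax"`.
#' @param seed RNG seed for the layer-wise uniform weight initialization.
#' @return an `ffnet` object with weight matrices `w1` (`n_hidden x n_in`),
#'   `b1`, `w2` (`n_out x n_hidden`), `b2`.
#' @export
ffnet <- function(n_in, n_hidden = 10, n_out = 1,
                  out_act = c("linear", "softmax"), seed = NULL) {
  out_act <- match.arg(out_act)
  local_seed(seed, {
    r1 <- sqrt(6 / (n_in + n_hidden))
    r2 <- sqrt(6 / (n_hidden + n_out))
    net <- structure(
      list(
        w1 = matrix(runif(n_hidden * n_in, -r1, r1), n_hidden, n_in),
        b1 = runif(n_hidden, -r1, r1),
        w2 = matrix(runif(n_out * n_hidden, -r2, r2), n_out, n_hidden),
        b2 = runif(n_out, -r2, r2),
        n_in = n_in, n_hidden = n_hidden, n_out = n_out,
        out_act = out_act, trained = FALSE, train_state = NULL
      ),
      class = "ffnet"
    )
    net
  })
}

#' @export
print.ffnet <- function(x, ...) {
  cat(sprintf("<ffnet %d-%d-%d, tanh hidden, %s output%s>\n",
              x$n_in, x$n_hidden, x$n_out, x$out_act,
              if (x$trained) ", trained" else ""))
  invisible(x)
}

n_params <- function(net) {
  net$n_hidden * net$n_in + net$n_hidden + net$n_out * net$n_hidden + net$n_out
}

pack_params <- function(net) c(as.vector(net$w1), net$b1, as.vector(net$w2), net$b2)

unpack_params <- function(net, theta) {
  h <- net$n_hidden; p <- net$n_in; k <- net$n_out
  i <- 0
  net$w1 <- matrix(theta[i + seq_len(h * p)], h, p); i <- i + h * p
  net$b1 <- theta[i + seq_len(h)]; i <- i + h
  net$w2 <- matrix(theta[i + seq_len(k * h)], k, h); i <- i + k * h
  net$b2 <- theta[i + seq_len(k)]
  net
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# hidden activations and linear outputs for an n x p input matrix
forward_linear <- function(net, x) {
  a1 <- tanh(sweep(x %*% t(net$w1), 2, net$b1, "+"))
  list(a1 = a1, y = sweep(a1 %*% t(net$w2), 2, net$b2, "+"))
}

#' Forward pass
#'
#' @param net an [ffnet()].
#' @param x numeric matrix `n x n_in` (a vector is treated as one row).
#' @return `n x n_out` matrix of outputs; softmax rows sum to one.
#' @export
forward <- function(net, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$n_in) {
    abort(sprintf("input has %d columns but the network expects %d", ncol(x), net$n_in))
  }
  y <- forward_linear(net, x)$y
  if (net$out_act == "softmax") softmax_rows(y) else y
}

# Jacobian of the linear outputs w.r.t. all parameters.
# Residual rows are ordered column-major in the n x k output matrix,
# i.e. row index i + (k - 1) * n.
ffnet_jacobian <- function(net, x, fw = NULL) {
  fw <- fw %||% forward_linear(net, x)
  n <- nrow(x); h <- net$n_hidden; p <- net$n_in; k <- net$n_out
  d <- 1 - fw$a1^2                    # n x h, tanh'
  nw <- n_params(net)
  J <- matrix(0, n * k, nw)
  off_b1 <- h * p
  off_w2 <- off_b1 + h
  off_b2 <- off_w2 + k * h
  for (kk in seq_len(k)) {
    rows <- (kk - 1) * n + seq_len(n)
    m <- d * matrix(net$w2[kk, ], n, h, byrow = TRUE)  # n x h
    for (l in seq_len(p)) {
      J[rows, (l - 1) * h + seq_len(h)] <- m * x[, l]
    }
    J[rows, off_b1 + seq_len(h)] <- m
    J[rows, off_w2 + (kk - 1) * h + seq_len(h)] <- fw$a1
    J[rows, off_b2 + kk] <- 1
  }
  J
}

#' Random 70/30 train/test split
#'
#' Uniform random permutation; the first `round(frac * n)` indices form the
#' training set (for the study-sized n = 134 this gives 94 training and 40
#' testing samples).
#'
#' @param n number of samples (`>= 2`).
#' @param seed RNG seed.
#' @param frac training fraction (default 0.70).
#' @return list with `train_idx`, `test_idx`, `frac`, `seed`.
#' @export
split_data <- function(n, seed = NULL, frac = 0.7) {
  stopifnot(n >= 2)
  local_seed(seed, {
    perm <- sample.int(n)
    n_train <- round(frac * n)
    list(train_idx = perm[seq_len(n_train)],
         test_idx = perm[seq.int(n_train + 1, n)],
         frac = frac, seed = seed)
  })
}

#' Train a network by Bayesian-regularized Levenberg-Marquardt
#'
#' Minimizes `F = beta * E_D + alpha * E_W`, where `E_D` is the sum of squared
#' errors on the linear outputs and `E_W` the sum of squared weights, using
#' Levenberg-Marquardt steps `-(H + mu I)^-1 g` with the Gauss-Newton Hessian
#' `H = 2 beta J'J + 2 alpha I`; the damping `mu` is divided/multiplied by 10
#' on accepted/rejected steps. After each accepted step the evidence
#' (MacKay) updates are applied: the effective number of parameters
#' `gamma = N_w - 2 alpha tr(H^-1)`, then `alpha = gamma / (2 E_W)` and
#' `beta = (n_obs - gamma) / (2 E_D)`, with `n_obs = n_samples * n_outputs`
#' (per-scalar observation counting). No validation split is needed: the
#' regularization itself suppresses overfitting. Set `bayes = FALSE` to freeze
#' `alpha = 0` (plain unregularized Levenberg-Marquardt).
#'
#' @param net an [ffnet()].
#' @param x training inputs (`n x n_in`), ideally normalized to `[-1, 1]`.
#' @param y training targets (`n x n_out`): one-hot rows for softmax networks,
#'   standardized continuous values for linear ones.
#' @param max_epochs maximum number of accepted steps (default 300).
#' @param mu initial damping (default 0.005); `mu_max` stops training.
#' @param grad_tol stop when the gradient max-norm falls below this.
#' @param bayes apply the evidence updates (default `TRUE`).
#' @param burn_in number of initial unregularized epochs before the evidence
#'   updates start (default 25); lets the data fit organize before the prior
#'   starts shrinking weights, which otherwise traps small over-parameterized
#'   problems at the zero-weight solution.
#' @return the trained `ffnet`, with a `train_state` list (final `alpha`,
#'   `beta`, `mu`, `gamma`, `sse_data`, `sse_weights`, `epochs`, `stop`) and a
#'   per-epoch `trace` tibble.
#' @export
train_bayesian_regularization <- function(net, x, y, max_epochs = 300,
                                          mu = 0.005, mu_max = 1e10,
                                          grad_tol = 1e-7, bayes = TRUE,
                                          burn_in = 25) {
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stopifnot(nrow(x) == nrow(y), ncol(x) == net$n_in, ncol(y) == net$n_out)
  n <- nrow(x); k <- net$n_out
  nobs <- n * k
  nw <- n_params(net)
  theta <- pack_params(net)
  alpha <- 0   # Foresee-Hagan: first step unregularized
  beta <- 1
  gamma <- nw
  objective <- function(th) {
    fw <- forward_linear(unpack_params(net, th), x)
    r <- as.vector(fw$y - y)
    list(r = r, ed = sum(r^2), ew = sum(th^2), fw = fw)
  }
  ob <- objective(theta)
  if (!is.finite(ob$ed)) abort("non-finite training loss at initialization")
  trace <- vector("list", max_epochs)
  stop_reason <- "max_epochs"
  epoch <- 0
  while (epoch < max_epochs) {
    epoch <- epoch + 1
    J <- ffnet_jacobian(unpack_params(net, theta), x, ob$fw)
    jtj <- crossprod(J)
    if (bayes && epoch > burn_in) {
      h_gn <- 2 * beta * jtj + diag(2 * alpha, nw)
      tr_inv <- tryCatch(sum(diag(solve(h_gn))), error = function(e) {
        ev <- eigen(h_gn, symmetric = TRUE, only.values = TRUE)$values
        sum(1 / pmax(ev, 1e-12))
      })
      gamma <- clamp(nw - 2 * alpha * tr_inv, 0, nw)
      alpha <- gamma / (2 * max(ob$ew, 1e-8))
      beta <- max(nobs - gamma, 1) / (2 * max(ob$ed, 1e-12))
    }
    f_cur <- beta * ob$ed + alpha * ob$ew
    grad <- 2 * beta * crossprod(J, ob$r)[, 1] + 2 * alpha * theta
    if (max(abs(grad)) < grad_tol) { stop_reason <- "gradient"; epoch <- epoch - 1; break }
    accepted <- FALSE
    while (!accepted && mu <= mu_max) {
      h_damp <- 2 * beta * jtj + diag(2 * alpha + mu, nw)
      step <- tryCatch(-solve(h_damp, grad), error = function(e) NULL)
      if (is.null(step)) { mu <- mu * 10; next }
      ob_new <- objective(theta + step)
      f_new <- beta * ob_new$ed + alpha * ob_new$ew
      if (!is.finite(f_new)) abort("non-finite loss during training; check input scaling")
      if (f_new < f_cur) {
        theta <- theta + step
        ob <- ob_new
        mu <- max(mu / 10, 1e-20)
        accepted <- TRUE
        trace[[epoch]] <- tibble(
          epoch = epoch, alpha = alpha, beta = beta, mu = mu, gamma = gamma,
          sse_data = ob$ed, sse_weights = ob$ew,
          f_before = f_cur, f_after = f_new
        )
      } else {
        mu <- mu * 10
      }
    }
    if (!accepted) { stop_reason <- "mu_max"; epoch <- epoch - 1; break }
  }
  net <- unpack_params(net, theta)
  net$trained <- TRUE
  net$train_state <- list(
    alpha = alpha, beta = beta, mu = mu, gamma = gamma,
    sse_data = ob$ed, sse_weights = ob$ew,
    epochs = epoch, stop = stop_reason, n_obs = nobs, n_params = nw,
    trace = dplyr::bind_rows(trace[!vapply(trace, is.null, logical(1))])
  )
  net
}

#' Predictions from a trained network
#'
#' `predict_class()` returns the argmax label of the softmax scores together
#' with the score matrix; `predict_values()` returns the continuous linear
#' outputs (de-standardize them with whatever scaling the targets were trained
#' under).
#'
#' @param net a trained softmax [ffnet()].
#' @param x input matrix.
#' @param levels optional class labels (defaults to `class1..classK`).
#' @return `predict_class()`: list with `label` (factor) and `scores`;
#'   `predict_values()`: numeric matrix.
#' @export
predict_class <- function(net, x, levels = NULL) {
  if (net$out_act != "softmax") abort("predict_class needs a softmax network")
  scores <- forward(net, x)
  levels <- levels %||% paste0("class", seq_len(net$n_out))
  colnames(scores) <- levels
  list(label = factor(levels[max.col(scores, ties.method = "first")], levels = levels),
       scores = scores)
}

#' @rdname predict_class
#' @export
predict_values <- function(net, x) {
  if (net$out_act != "linear") abort("predict_values needs a linear-output network")
  forward(net, x)
}

#' @rdname tidy
#' @export
tidy.ffnet <- function(x, ...) {
  tibble(
    parameter = c(
      paste0("w1[", rep(seq_len(x$n_hidden), x$n_in), ",",
             rep(seq_len(x$n_in), each = x$n_hidden), "]"),
      paste0("b1[", seq_len(x$n_hidden), "]"),
      paste0("w2[", rep(seq_len(x$n_out), x$n_hidden), ",",
             rep(seq_len(x$n_hidden), each = x$n_out), "]"),
      paste0("b2[", seq_len(x$n_out), "]")
    ),
    value = pack_params(x)
  )
}

#' @rdname tidy
#' @export
glance.ffnet <- function(x, ...) {
  s <- x$train_state
  if (is.null(s)) return(tibble(trained = FALSE, n_params = n_params(x)))
  tibble(trained = TRUE, n_params = s$n_params, epochs = s$epochs,
         alpha = s$alpha, beta = s$beta, gamma = s$gamma,
         sse_data = s$sse_data, sse_weights = s$sse_weights, stop = s$stop)
}

#' Save / load a network as JSON
#'
#' @param net an [ffnet()].
#' @param path JSON file path.
#' @export
write_ffnet <- function(net, path) {
  s <- net$train_state
  jsonlite::write_json(
    list(
      n_in = net$n_in, n_hidden = net$n_hidden, n_out = net$n_out,
      out_act = net$out_act, trained = net$trained,
      w1 = net$w1, b1 = net$b1, w2 = net$w2, b2 = net$b2,
      train_summary = if (!is.null(s)) s[setdiff(names(s), "trace")]
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_ffnet
#' @export
read_ffnet <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- ffnet(j$n_in, j$n_hidden, j$n_out, j$out_act)
  net$w1 <- matrix(j$w1, j$n_hidden, j$n_in)
  net$b1 <- as.numeric(j$b1)
  net$w2 <- matrix(j$w2, j$n_out, j$n_hidden)
  net$b2 <- as.numeric(j$b2)
  net$trained <- isTRUE(j$trained)
  net$train_state <- j$train_summary
  net
}
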