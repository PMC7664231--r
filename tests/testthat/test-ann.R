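test_that("forward pass reduces to the closed form on degenerate nets", {
  net <- ffnet(2, 3, 1, "linear", seed = 1)
  net$w1[] <- 0; net$b1[] <- 0; net$w2[] <- 0; net$b2 <- 0.7
  expect_equal(as.vector(forward(net, matrix(rnorm(10), 5, 2))), rep(0.7, 5))
  sm <- ffnet(2, 3, 3, "softmax", seed = 1)
  sm$w1[] <- 0; sm$b1[] <- 0; sm$w2[] <- 0; sm$b2[] <- 0
  out <- forward(sm, matrix(rnorm(4), 2, 2))
  expect_equal(out, matrix(1 / 3, 2, 3), tolerance = 1e-12)
  expect_error(forward(net, matrix(1, 1, 5)), "expects")
})

test_that("a one-hidden-unit net matches hand arithmetic", {
  net <- ffnet(1, 1, 1, "linear")
  net$w1[1, 1] <- 0.5; net$b1 <- -0.2; net$w2[1, 1] <- 2; net$b2 <- 0.1
  x <- 0.8
  expect_equal(forward(net, matrix(x))[1, 1], 2 * tanh(0.5 * 0.8 - 0.2) + 0.1,
               tolerance = 1e-12)
})

test_that("softmax scores are proper probabilities", {
  net <- ffnet(4, 5, 3, "softmax", seed = 2)
  s <- forward(net, matrix(rnorm(40), 10, 4))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(rowSums(s), rep(1, 10))
})

test_that("the 70/30 split reproduces the study arithmetic", {
  s <- split_data(134, seed = 1)
  expect_equal(length(s$train_idx), 94L)
  expect_equal(length(s$test_idx), 40L)
  expect_equal(sort(c(s$train_idx, s$test_idx)), 1:134)
  expect_equal(split_data(10, seed = 2)$train_idx |> length(), 7L)
  expect_identical(split_data(50, seed = 3), split_data(50, seed = 3))
})

test_that("analytic Jacobian matches central finite differences", {
  net <- ffnet(1, 1, 1, "linear", seed = 5) # 4 parameters
  x <- matrix(c(-0.5, 0.1, 0.9), 3, 1)
  J <- sheepvitals:::ffnet_jacobian(net, x)
  th <- sheepvitals:::pack_params(net)
  eps <- 1e-6
  for (p in seq_along(th)) {
    tp <- th; tm <- th
    tp[p] <- tp[p] + eps; tm[p] <- tm[p] - eps
    yp <- forward(sheepvitals:::unpack_params(net, tp), x)
    ym <- forward(sheepvitals:::unpack_params(net, tm), x)
    fd <- (yp - ym) / (2 * eps)
    expect_true(max(abs(J[, p] - as.vector(fd))) < 1e-6 * max(1, max(abs(fd))),
                label = sprintf("parameter %d", p))
  }
})

test_that("a noiseless linear map is fit to numerical precision", {
  X <- matrix(seq(-1, 1, length.out = 25))
  Y <- 2 * X
  net <- train_bayesian_regularization(ffnet(1, 4, 1, "linear", seed = 3), X, Y,
                                       max_epochs = 200)
  mse <- mean((predict_values(net, X) - Y)^2)
  expect_lt(mse, 1e-6)
  expect_lt(net$train_state$gamma, net$train_state$n_params)
})

test_that("XOR is learned to 100% training accuracy across seeds", {
  X <- matrix(c(-1, -1, -1, 1, 1, -1, 1, 1), 4, 2, byrow = TRUE)
  Y <- matrix(c(1, 0, 0, 1, 0, 1, 1, 0), 4, 2, byrow = TRUE)
  accs <- vapply(1:5, function(s) {
    net <- train_bayesian_regularization(ffnet(2, 10, 2, "softmax", seed = s), X, Y,
                                         max_epochs = 200)
    mean(max.col(forward(net, X)) == max.col(Y))
  }, numeric(1))
  expect_equal(accs, rep(1, 5))
})

test_that("the regularized objective never increases over accepted steps", {
  set.seed(6)
  X <- matrix(runif(60, -1, 1), 30, 2)
  Y <- matrix(sin(2 * X[, 1]) + rnorm(30, sd = 0.2), 30, 1)
  net <- train_bayesian_regularization(ffnet(2, 6, 1, "linear", seed = 1), X, Y,
                                       max_epochs = 120)
  tr <- net$train_state$trace
  expect_true(all(tr$f_after <= tr$f_before + 1e-12))
})

test_that("evidence updates shrink the effective parameter count on noise", {
  set.seed(9)
  X <- matrix(runif(60, -1, 1), 30, 2)
  Y <- matrix(rnorm(30), 30, 1)
  br <- train_bayesian_regularization(ffnet(2, 10, 1, "linear", seed = 4), X, Y,
                                      max_epochs = 150)
  lm <- train_bayesian_regularization(ffnet(2, 10, 1, "linear", seed = 4), X, Y,
                                      max_epochs = 150, bayes = FALSE)
  expect_gt(br$train_state$alpha, 0)
  expect_lt(br$train_state$gamma, 0.5 * br$train_state$n_params)
  expect_lt(br$train_state$sse_weights, lm$train_state$sse_weights)
})

test_that("regularization does not hurt held-out error (median over seeds)", {
  gen <- function(seed, n = 40) {
    set.seed(seed)
    x <- matrix(runif(n, -1, 1))
    list(x = x, y = matrix(sin(3 * x) + rnorm(n, sd = 0.25)))
  }
  deltas <- vapply(1:10, function(s) {
    tr <- gen(s); te <- gen(s + 100)
    br <- train_bayesian_regularization(ffnet(1, 8, 1, "linear", seed = s), tr$x, tr$y,
                                        max_epochs = 80)
    lm <- train_bayesian_regularization(ffnet(1, 8, 1, "linear", seed = s), tr$x, tr$y,
                                        max_epochs = 80, bayes = FALSE)
    mean((predict_values(br, te$x) - te$y)^2) - mean((predict_values(lm, te$x) - te$y)^2)
  }, numeric(1))
  expect_lte(median(deltas), 0)
})

test_that("training is deterministic given seed and round-trips through JSON", {
  X <- matrix(runif(30, -1, 1), 15, 2)
  Y <- matrix(X[, 1] - X[, 2])
  n1 <- train_bayesian_regularization(ffnet(2, 4, 1, "linear", seed = 7), X, Y, max_epochs = 50)
  n2 <- train_bayesian_regularization(ffnet(2, 4, 1, "linear", seed = 7), X, Y, max_epochs = 50)
  expect_identical(sheepvitals:::pack_params(n1), sheepvitals:::pack_params(n2))
  path <- withr::local_tempfile(fileext = ".json")
  write_ffnet(n1, path)
  n3 <- read_ffnet(path)
  expect_equal(forward(n3, X), forward(n1, X), tolerance = 1e-12)
})
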