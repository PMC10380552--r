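# The loss functions and the compiled network engine.

test_that("trace weights follow the tanh ramp from 2 down to 1", {
  w <- trace_weights(128)
  expect_equal(round(w[1]), 2)
  expect_equal(round(w[128]), 1)
  expect_equal(w[64], 1.5)  # tanh(0) = 0 at i = N/2
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 1 & w < 2))
  # closed form at the endpoints
  expect_equal(w[1], 1 + (1 - tanh(8 / 128 * 1 - 4)) / 2)
  expect_equal(w[128], 1 + (1 - tanh(8 / 128 * 128 - 4)) / 2)
})

test_that("weighted MSE matches hand-computed cases", {
  N <- 5
  y <- matrix(rnorm(2 * N), 2, N)
  expect_equal(weighted_mse(y, y, rep(1, N)), 0)
  expect_equal(weighted_mse(y + 1, y, rep(1, N)), 2)
  expect_equal(weighted_mse(matrix(c(3, 4), 2, 1),
                            matrix(c(0, 0), 2, 1), 2), 50)
  expect_error(weighted_mse(y, y[, -1], rep(1, N)), "shape")
})

test_that("focal loss matches its closed form and reduces to scaled BCE", {
  expect_equal(focal_loss(0.5, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.25 * log(2))
  expect_lt(focal_loss(1 - 1e-9, 1), 1e-6)
  withr::with_seed(99, {
    p <- runif(1e4, 0.001, 0.999)
    y <- rbinom(1e4, 1, 0.5)
    lhs <- focal_loss(p, y, alpha = 0.5, gamma = 0)
    rhs <- 0.5 * focal_loss(p, y, mode = "bce")
    expect_lt(max(abs(lhs - rhs)), 1e-12)
  })
})

test_that("analytic gradients agree with directional finite differences", {
  # the engine runs in single precision, so the check compares the
  # directional derivative along a random direction in parameter space
  # (aggregating the whole gradient) rather than per-element differences
  lt <- asNamespace("leaftrace")
  # median over several random directions: single directions occasionally
  # cross LeakyReLU kinks at finite eps and overshoot
  dircheck <- function(arch, loss_cfg, X, Y, valid = NULL, eps = 3e-3,
                       n_dir = 5) {
    init <- lt$init_params(arch, seed = 2)
    res <- lt$cpp_loss_grads(arch, init$params, init$running, X, Y, valid,
                             loss_cfg, TRUE)
    rels <- vapply(seq_len(n_dir), function(k) {
      dirs <- lapply(init$params, function(M) array(rnorm(length(M)), dim(M)))
      nrm <- sqrt(sum(unlist(lapply(dirs, function(d) sum(d^2)))))
      dirs <- lapply(dirs, function(d) d / nrm)
      pp <- mapply(function(M, d) M + eps * d, init$params, dirs,
                   SIMPLIFY = FALSE)
      pm <- mapply(function(M, d) M - eps * d, init$params, dirs,
                   SIMPLIFY = FALSE)
      lp <- lt$cpp_loss_grads(arch, pp, init$running, X, Y, valid,
                              loss_cfg, TRUE)$loss
      lm_ <- lt$cpp_loss_grads(arch, pm, init$running, X, Y, valid,
                               loss_cfg, TRUE)$loss
      num <- (lp - lm_) / (2 * eps)
      ana <- sum(unlist(mapply(function(g, d) sum(g * d), res$grads, dirs)))
      abs(num - ana) / max(abs(num), abs(ana), 1e-8)
    }, numeric(1))
    median(rels)
  }
  withr::with_seed(5, {
    arch1 <- lt$encoder_arch(16L, 4L, c(4L, 6L), 8L, "linear")
    X1 <- array(runif(16 * 16 * 4 * 3), c(16, 16, 4, 3))
    Y1 <- matrix(rnorm(8 * 3), 8, 3)
    expect_lt(dircheck(arch1, list(mode = "wmse", weights = trace_weights(4)),
                       X1, Y1), 0.06)
    arch2 <- lt$encoder_arch(16L, 3L, c(4L, 6L), 18L, "softmax9")
    X2 <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
    Y2 <- matrix(rbinom(27, 1, 0.4), 9, 3)
    expect_lt(dircheck(arch2, list(mode = "focal", alpha = 0.25, gamma = 2),
                       X2, Y2), 0.06)
    expect_lt(dircheck(arch2, list(mode = "bce"), X2, Y2), 0.06)
    arch3 <- lt$unet_arch(16L, 3L, c(4L, 6L))
    X3 <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
    Y3 <- matrix(rbinom(512, 1, 0.3), 256, 2)
    V3 <- matrix(rbinom(512, 1, 0.9), 256, 2)
    expect_lt(dircheck(arch3, list(mode = "focal", alpha = 0.25, gamma = 2),
                       X3, Y3, V3), 0.06)
  })
})

test_that("network outputs honour their contracts", {
  lt <- asNamespace("leaftrace")
  withr::with_seed(6, {
    # grower head: probability pairs, softmax-normalised
    arch <- lt$encoder_arch(16L, 3L, c(4L, 6L), 18L, "softmax9")
    init <- lt$init_params(arch, 1)
    X <- array(runif(16 * 16 * 3 * 5), c(16, 16, 3, 5))
    out <- lt$cpp_forward(arch, init$params, init$running, X, 4L)
    expect_equal(dim(out), c(9L, 5L))
    expect_true(all(out > 0 & out < 1))
    # tracer head: finite, unbounded linear outputs of the right shape
    archt <- lt$encoder_arch(16L, 4L, c(4L, 6L), 64L, "linear")
    initt <- lt$init_params(archt, 1)
    Xt <- array(runif(16 * 16 * 4 * 2), c(16, 16, 4, 2))
    outt <- lt$cpp_forward(archt, initt$params, initt$running, Xt, 4L)
    expect_equal(dim(outt), c(64L, 2L))
    expect_true(all(is.finite(outt)))
    # U-Net: per-pixel sigmoid map matching the tile size
    archu <- lt$unet_arch(16L, 3L, c(4L, 6L))
    initu <- lt$init_params(archu, 1)
    outu <- lt$cpp_forward(archu, initu$params, initu$running, Xt[, , 1:3, ,
                                                                 drop = FALSE], 4L)
    expect_equal(dim(outu), c(256L, 2L))
    expect_true(all(outu >= 0 & outu <= 1))
  })
})

test_that("early stopping halts `patience` epochs past the best checkpoint", {
  lt <- asNamespace("leaftrace")
  withr::with_seed(8, {
    arch <- lt$encoder_arch(8L, 3L, c(3L), 2L, "linear")
    X <- array(runif(8 * 8 * 3 * 12), c(8, 8, 3, 12))
    # validation targets unrelated to the training targets: the validation
    # loss bottoms out early and then worsens as the model fits the training
    # set, so early stopping must fire
    Y <- matrix(rnorm(2 * 12), 2, 12)
    Yval <- matrix(rnorm(2 * 12), 2, 12)
    init <- lt$init_params(arch, 1)
    loss <- list(mode = "wmse", weights = rep(1, 1))
    fit <- lt$cpp_train(arch, init$params, init$running, X, Y, X, Yval,
                        NULL, NULL, loss,
                        list(epochs = 400L, batch = 12L, patience = 5L,
                             lr = 5e-3, seed = 1L))
    expect_lt(fit$epochs_run, 400L)
    # stopping happens exactly `patience` consecutive non-improvements after
    # the best validation epoch
    expect_equal(fit$epochs_run, fit$best_epoch + 5L)
    expect_equal(fit$best_val, min(fit$history$val_loss))
    # cap respected when patience never runs out
    fit2 <- lt$cpp_train(arch, init$params, init$running, X, Y, X, Y,
                         NULL, NULL, loss,
                         list(epochs = 4L, batch = 4L, patience = 20L,
                              lr = 1e-3, seed = 1L))
    expect_equal(fit2$epochs_run, 4L)
    # determinism: same seed, same history
    fit3 <- lt$cpp_train(arch, init$params, init$running, X, Y, X, Y,
                         NULL, NULL, loss,
                         list(epochs = 4L, batch = 4L, patience = 20L,
                              lr = 1e-3, seed = 1L))
    expect_equal(fit2$history$train_loss, fit3$history$train_loss)
  })
})
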