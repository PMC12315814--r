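test_that("relu maps negatives to zero, keeps positives, and is idempotent", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  set.seed(91)
  for (rep in 1:5) {
    x <- rnorm(100, 0, 5)
    expect_identical(relu(relu(x)), relu(x))
  }
})

test_that("softmax rows are normalized, uniform for constants, shift invariant", {
  expect_equal(softmax(rep(0, 5)), rep(0.2, 5))
  set.seed(92)
  M <- matrix(rnorm(40, 0, 3), 8, 5)
  P <- softmax(M)
  expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-9)
  expect_equal(softmax(M + 7), P, tolerance = 1e-9)
})

test_that("cross-entropy has its closed-form values and obeys Gibbs' inequality", {
  expect_equal(cross_entropy(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 0)
  expect_equal(cross_entropy(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)),
               log(2), tolerance = 1e-12)
  set.seed(93)
  for (rep in 1:10) {
    P <- matrix(stats::rgamma(8, 1), 2); P <- P / rowSums(P)
    Q <- matrix(stats::rgamma(8, 1), 2); Q <- Q / rowSums(Q)
    expect_gte(cross_entropy(P, Q), cross_entropy(P, P) - 1e-12)
  }
  expect_error(cross_entropy(matrix(1, 1, 2), matrix(1, 1, 3)), "shape")
})

test_that("architecture shapes chain consistently and are validated", {
  a <- cnn_architecture(100, 3)
  dense <- a$layers[[which(vapply(a$layers, `[[`, "", "type") == "dense")]]
  # conv(9): 92, pool(4): 23, conv(9): 15, pool(4): 3 -> 3 * 32 features
  expect_equal(dense$in_features, 3L * 32L)
  expect_error(cnn_architecture(10, 2, layers = list(
    list(type = "conv", filters = 2L, width = 50L))), "width")
})

test_that("analytic gradients match central finite differences", {
  set.seed(94)
  arch <- cnn_architecture(24, 3, layers = list(
    list(type = "conv", filters = 3L, width = 5L),
    list(type = "relu"),
    list(type = "pool", width = 2L)))
  params <- sersml:::cnn_init(arch, 7)
  x <- matrix(rnorm(5 * 24), 5, 24)
  oh <- diag(3)[sample(1:3, 5, TRUE), ]
  fwd <- sersml:::cnn_forward(params, arch, x)
  gr <- sersml:::cnn_backward(params, arch, fwd, oh)
  loss_at <- function(p) cross_entropy(oh, sersml:::cnn_forward(p, arch, x)$probs)
  worst <- 0
  for (li in seq_along(params)) {
    if (is.null(params[[li]])) next
    for (nm in c("W", "b")) {
      w <- params[[li]][[nm]]
      for (ix in seq_along(w)) {
        h <- 1e-5
        pp <- params
        pp[[li]][[nm]][ix] <- w[ix] + h
        f1 <- loss_at(pp)
        pp[[li]][[nm]][ix] <- w[ix] - h
        f0 <- loss_at(pp)
        num <- (f1 - f0) / (2 * h)
        worst <- max(worst, abs(num - gr[[li]][[nm]][ix]) /
                       max(1e-6, abs(num) + abs(gr[[li]][[nm]][ix])))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("max pooling downsamples by its stated factor", {
  arch <- cnn_architecture(40, 2, layers = list(list(type = "pool", width = 4L)))
  params <- sersml:::cnn_init(arch, 1)
  x <- matrix(seq_len(40), 1, 40)
  fwd <- sersml:::cnn_forward(params, arch, x)
  pooled_dim <- dim(fwd$caches[[1]]$argmax)
  expect_equal(pooled_dim[2], 10L)
  # max of consecutive quadruples of an increasing ramp is its last element
  first_pool <- arch$layers[[1]]
  expect_equal(first_pool$out_length, 10L)
})

test_that("the network overfits a tiny high-SNR two-class set", {
  axis <- short_axis()
  p1 <- trimmed_preset("cancer-like", axis, noise_sd = 2)
  p2 <- trimmed_preset("normal-like", axis, noise_sd = 2)
  d <- simulate_dataset(list(p1, p2), 10, axis = axis, seed = 5)
  fit <- train_cnn(d, config = train_config(max_epochs = 40, batch_size = 4,
                                            seed = 2))
  pr <- cnn_predict(fit$model, d)
  expect_equal(mean(pr$classes == d$labels), 1)
  # descent sanity: final training loss below the initial one
  expect_lt(utils::tail(fit$curves$iter_loss, 1), fit$curves$iter_loss[1])
})

test_that("training is deterministic under the seed", {
  axis <- seq(400, 800, by = 2)
  p1 <- trimmed_preset("cancer-like", axis)
  p2 <- trimmed_preset("hek-like", axis)
  d <- simulate_dataset(list(p1, p2), 6, axis = axis, seed = 7)
  cfg <- train_config(max_epochs = 3, batch_size = 4, seed = 9)
  f1 <- train_cnn(d, config = cfg)
  f2 <- train_cnn(d, config = cfg)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("prediction rows are probabilities over the class set", {
  axis <- seq(400, 800, by = 2)
  profs <- lapply(c("a549-like", "beas2b-like", "hela-like"), function(nm) {
    trimmed_preset(nm, axis)
  })
  d <- simulate_dataset(profs, 5, axis = axis, seed = 8)
  fit <- train_cnn(d, config = train_config(max_epochs = 2, seed = 1))
  pr <- cnn_predict(fit$model, d)
  expect_equal(rowSums(pr$probabilities), rep(1, 15), tolerance = 1e-9)
  expect_true(all(pr$classes %in% fit$model$class_names))
  expect_error(cnn_predict(fit$model, matrix(0, 2, 10)), "length")
})

test_that("a class present only in validation raises a label error", {
  axis <- seq(400, 800, by = 2)
  p1 <- trimmed_preset("a549-like", axis)
  p2 <- trimmed_preset("hek-like", axis)
  p3 <- trimmed_preset("hela-like", axis)
  tr <- simulate_dataset(list(p1, p2), 4, axis = axis, seed = 2)
  va <- simulate_dataset(list(p3), 2, axis = axis, seed = 3)
  expect_error(train_cnn(tr, va, config = train_config(max_epochs = 1)),
               "absent")
})

test_that("training curves export to CSV", {
  axis <- seq(400, 800, by = 2)
  p1 <- trimmed_preset("a549-like", axis)
  p2 <- trimmed_preset("hek-like", axis)
  d <- simulate_dataset(list(p1, p2), 4, axis = axis, seed = 2)
  fit <- train_cnn(d, config = train_config(max_epochs = 2, seed = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_training_curves(fit$curves, f)
  got <- utils::read.csv(f)
  expect_named(got, c("iteration", "train_loss", "train_accuracy"))
  expect_equal(nrow(got), length(fit$curves$iter_loss))
})
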