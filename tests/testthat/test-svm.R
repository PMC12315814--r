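# dual objective sum(a) - 1/2 (a*y)' K (a*y), used to compare solvers
dual_obj <- function(alpha, y, K) {
  ay <- alpha * y
  sum(alpha) - 0.5 * as.numeric(t(ay) %*% K %*% ay)
}

# dense QP solution of the SVM dual via kernlab's interior-point solver
qp_dual <- function(K, y, C) {
  n <- length(y)
  H <- (y %o% y) * K + diag(1e-10, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = H,
                       A = matrix(y, 1), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n), sigf = 9)
  kernlab::primal(sol)
}

test_that("the two-point problem has the known analytic dual solution", {
  X <- matrix(c(1, -1), 2, 1)
  y <- c("pos", "neg")             # "neg" sorts first and sits at x = -1
  m <- train_svm(X, y, svm_config("linear", 1e6, 1), tol = 1e-8)
  # alphas 0.5 each, both support vectors, zero bias
  expect_equal(m$alphas, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sort(m$support_indices), c(1L, 2L))
  expect_equal(m$bias, 0, tolerance = 1e-6)
  # decision function f(z) = -z (positive class "neg" lives at -1)
  expect_equal(svm_predict(m, matrix(c(-2, 0.5)))$scores, c(2, -0.5),
               tolerance = 1e-6)
  # the midpoint scores exactly 0 and ties go to the first class name
  mid <- svm_predict(m, matrix(0))
  expect_equal(mid$scores, 0, tolerance = 1e-9)
  expect_equal(mid$classes, "neg")
})

test_that("trained models satisfy the dual constraints", {
  for (seed in 1:3) {
    b <- blob_data(n = 15, gap = 4, seed = seed)
    for (kern in c("linear", "gaussian")) {
      C <- 10
      m <- train_svm(b$X, b$y, svm_config(kern, C, 2), tol = 1e-8)
      expect_lt(abs(sum(m$alphas * m$labels_pm1)), 1e-6 * C)
      expect_true(all(m$alphas >= -1e-12 & m$alphas <= C + 1e-12))
      expect_lte(m$kkt_gap, 1e-4 * C)
    }
  }
})

test_that("SMO matches a dense QP oracle on small problems", {
  for (seed in 1:4) {
    set.seed(seed)
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    X <- rbind(matrix(rnorm(2 * n1), n1, 2),
               matrix(rnorm(2 * n2, mean = 2.5), n2, 2))
    y <- rep(c("a", "b"), c(n1, n2))
    ypm <- ifelse(y == "a", 1, -1)
    for (kern in c("linear", "gaussian")) {
      cfg <- svm_config(kern, C <- 5, 1.5)
      K <- kernel_matrix(X, X, cfg)
      m <- train_svm(X, y, cfg, tol = 1e-9)
      a_qp <- qp_dual(K, ypm, C)
      o_smo <- dual_obj(m$alphas, ypm, K)
      o_qp <- dual_obj(a_qp, ypm, K)
      expect_equal(o_smo, o_qp, tolerance = 1e-6)
      expect_equal(svm_dual_objective(m), o_smo, tolerance = 1e-9)
    }
  }
})

test_that("three separated clusters are perfectly classified one-vs-one", {
  set.seed(77)
  X <- rbind(matrix(rnorm(40, 0), 20, 2),
             matrix(rnorm(40, 8), 20, 2),
             cbind(rnorm(20, 8), rnorm(20, -8)))
  y <- rep(c("u", "v", "w"), each = 20)
  m <- train_svm(X, y, svm_config("linear", 10, 1))
  pr <- svm_predict(m, X)
  expect_equal(pr$classes, y)
  expect_equal(ncol(pr$scores), 3L)   # one column per pair
})

test_that("sign of the score reproduces labels on separable training data", {
  b <- blob_data(n = 30, gap = 6, seed = 5)
  m <- train_svm(b$X, b$y, svm_config("gaussian", 50, 3))
  pr <- svm_predict(m, b$X)
  expect_equal(pr$classes, b$y)
})

test_that("doubling kernel_scale equals halving the features (linear kernel)", {
  b <- blob_data(n = 20, gap = 4, seed = 6)
  m1 <- train_svm(b$X, b$y, svm_config("linear", 10, 2), tol = 1e-8)
  m2 <- train_svm(b$X / 2, b$y, svm_config("linear", 10, 1), tol = 1e-8)
  Z <- matrix(rnorm(20), 10, 2)
  expect_equal(svm_predict(m1, Z)$scores, svm_predict(m2, Z / 2)$scores,
               tolerance = 1e-5)
})

test_that("degenerate inputs raise errors", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(train_svm(X, rep("a", 5)), "two classes")
  expect_error(train_svm(matrix(c(Inf, rnorm(9)), 5, 2),
                         rep(c("a", "b"), length.out = 5)), "finite")
  m <- train_svm(X, c("a", "b", "a", "b", "a"), svm_config())
  expect_error(svm_predict(m, matrix(0, 2, 3)), "dimension")
  expect_error(svm_config(box_constraint = -1), "positive")
})

test_that("cross-validation partitions every sample exactly once and is seeded", {
  b <- blob_data(n = 50, gap = 10, seed = 7)
  cv <- cv_loss(b$X, b$y, svm_config("linear", 10, 1), folds = 5, seed = 3)
  expect_equal(as.numeric(cv), 0)
  folds <- attr(cv, "folds")
  expect_equal(length(folds), 100L)
  expect_true(all(table(folds) == 20L))
  cv2 <- cv_loss(b$X, b$y, svm_config("linear", 10, 1), folds = 5, seed = 3)
  expect_identical(attr(cv2, "folds"), folds)
  expect_error(cv_loss(b$X[1:4, ], b$y[1:4], folds = 5), "fold")
})

test_that("Platt calibration is symmetric, monotone, and recovers parameters", {
  # perfectly separated toy scores: probability 0.5 at the midpoint
  X <- matrix(c(-2, -1, 1, 2), 4, 1)
  y <- c("n", "n", "p", "p")
  m <- train_svm(X, y, svm_config("linear", 100, 1), tol = 1e-8)
  cal <- platt_calibrate(m, X, y)
  sc0 <- svm_predict(m, matrix(0))$scores
  expect_equal(platt_predict(cal, sc0), 0.5, tolerance = 0.05)
  s_grid <- seq(-3, 3, length.out = 21)
  p_grid <- platt_predict(cal, if (cal$A >= 0) s_grid else rev(s_grid))
  expect_true(all(diff(p_grid) >= -1e-12))

  # parameter recovery on large simulated logistic data
  set.seed(88)
  s <- rnorm(2000, 0, 2)
  pr <- stats::plogis(2.5 * s + 0.4)
  lab <- stats::runif(2000) < pr
  rec <- platt_fit(s, lab)
  expect_lt(abs(rec$A - 2.5) / 2.5, 0.1)

  expect_error(platt_calibrate(m, X, rep("p", 4)), "both classes")
})

test_that("models serialize to JSON and predict identically after reload", {
  b <- blob_data(n = 12, gap = 5, seed = 9)
  m <- train_svm(b$X, b$y, svm_config("gaussian", 7, 1.3))
  f <- withr::local_tempfile(fileext = ".json")
  write_svm_model(m, f)
  back <- read_svm_model(f)
  Z <- matrix(rnorm(16), 8, 2)
  expect_equal(svm_predict(back, Z)$scores, svm_predict(m, Z)$scores,
               tolerance = 1e-12)

  set.seed(10)
  X3 <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2),
              matrix(rnorm(20, -6), 10, 2))
  y3 <- rep(c("a", "b", "c"), each = 10)
  m3 <- train_svm(X3, y3, svm_config("linear", 5, 1))
  write_svm_model(m3, f)
  b3 <- read_svm_model(f)
  expect_equal(svm_predict(b3, X3)$classes, svm_predict(m3, X3)$classes)
})
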