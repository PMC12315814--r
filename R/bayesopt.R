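# Minimal Gaussian-process regression on [0,1]^d with a squared-exponential
# kernel, used as the surrogate for hyperparameter search.
gp_fit <- function(X, y, lengthscale = 0.2, nugget = 1e-6) {
  sigma2 <- max(stats::var(y), 1e-12)
  K <- sigma2 * exp(-as.matrix(stats::dist(X))^2 / (2 * lengthscale^2))
  diag(K) <- diag(K) + sigma2 * nugget + 1e-10
  L <- chol(K)
  mu <- mean(y)
  alpha <- backsolve(L, backsolve(L, y - mu, transpose = TRUE))
  list(X = X, L = L, alpha = alpha, mu = mu, sigma2 = sigma2,
       lengthscale = lengthscale)
}

gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rep(1, nrow(gp$X))) +
    outer(rep(1, nrow(Xnew)), rowSums(gp$X^2)) - 2 * Xnew %*% t(gp$X)
  Ks <- gp$sigma2 * exp(-pmax(d2, 0) / (2 * gp$lengthscale^2))
  mean_ <- gp$mu + Ks %*% gp$alpha
  v <- backsolve(gp$L, t(Ks), transpose = TRUE)
  var_ <- pmax(gp$sigma2 - colSums(v^2), 1e-12)
  list(mean = as.numeric(mean_), sd = sqrt(var_))
}

expected_improvement <- function(mean_, sd_, best) {
  imp <- best - mean_
  z <- imp / sd_
  ei <- imp * stats::pnorm(z) + sd_ * stats::dnorm(z)
  ei[sd_ <= 0] <- pmax(imp[sd_ <= 0], 0)
  ei
}

#' Bayesian optimization of SVM hyperparameters
#'
#' Minimizes an objective (by default the 5-fold [cv_loss()]) over
#' `(log10 C, log10 s)` using a Gaussian-process surrogate with a
#' squared-exponential kernel and expected-improvement acquisition. A seeded
#' initial design of `n_init` points is evaluated first; each further point
#' maximizes expected improvement over a seeded candidate cloud. Fully
#' deterministic under `seed`.
#'
#' @param X Feature matrix or [sers_set()].
#' @param y Class labels (defaults to the set's labels).
#' @param space List with elements `logC` and `logS`, each `c(lower,
#'   upper)` in log10 units.
#' @param n_iter Total number of objective evaluations (>= 1).
#' @param seed Integer seed (also fixes the cross-validation folds).
#' @param folds Cross-validation folds for the default objective.
#' @param kernel SVM kernel for the default objective.
#' @param n_init Number of initial space-filling points (capped at
#'   `n_iter`).
#' @param objective Optional replacement objective
#'   `function(c(log10C, log10s)) -> numeric`; when supplied, `X` and `y`
#'   are not touched.
#' @return A list with `best_config` (an [svm_config()]), `best_objective`,
#'   and `trace`, a data.frame with columns `log10C`, `log10s`, `objective`
#'   and the non-increasing `best_so_far`.
#' @export
bayes_optimize <- function(X = NULL, y = NULL,
                           space = list(logC = c(-3, 6), logS = c(-3, 6)),
                           n_iter = 30L, seed = 1L, folds = 5L,
                           kernel = "linear", n_init = 5L,
                           objective = NULL) {
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  lo <- c(space$logC[1L], space$logS[1L])
  hi <- c(space$logC[2L], space$logS[2L])
  if (any(!is.finite(c(lo, hi))) || any(lo >= hi)) {
    stop("space bounds must be finite with lower < upper", call. = FALSE)
  }
  if (is.null(objective)) {
    if (inherits(X, "sers_set")) {
      if (is.null(y)) y <- X$labels
      X <- X$matrix
    }
    objective <- function(p) {
      cv_loss(X, y, svm_config(kernel, 10^p[1L], 10^p[2L]), folds,
              seed = seed, max_iter = 5000L)
    }
  }
  n_init <- min(n_init, n_iter)
  pts <- with_seed(seed, {
    matrix(stats::runif(n_init * 2L), ncol = 2L)
  })
  evaluated <- matrix(numeric(0), ncol = 2L)
  obj <- numeric(0)
  eval_point <- function(u) {
    p <- lo + u * (hi - lo)
    evaluated <<- rbind(evaluated, u)
    obj <<- c(obj, objective(p))
  }
  for (i in seq_len(n_init)) eval_point(pts[i, ])
  i <- n_init
  while (i < n_iter) {
    i <- i + 1L
    cand <- with_seed((seed * 131071 + i * 524287) %% 2147483647, {
      matrix(stats::runif(512L * 2L), ncol = 2L)
    })
    gp <- gp_fit(evaluated, obj)
    pr <- gp_predict(gp, cand)
    ei <- expected_improvement(pr$mean, pr$sd, min(obj))
    eval_point(cand[which.max(ei), ])
  }
  params <- sweep(sweep(evaluated, 2L, hi - lo, `*`), 2L, lo, `+`)
  best_so_far <- cummin(obj)
  best <- which.min(obj)
  trace <- data.frame(log10C = params[, 1L], log10s = params[, 2L],
                      objective = obj, best_so_far = best_so_far)
  list(best_config = svm_config(kernel, 10^params[best, 1L],
                                10^params[best, 2L]),
       best_objective = obj[best],
       trace = trace)
}
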