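#' Rectified linear unit
#'
#' Elementwise `max(0, x)`: negative values map to zero, positive values are
#' unchanged.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape.
#' @export
relu <- function(x) {
  stopifnot(all(is.finite(x)))
  pmax(x, 0)
}

#' Row-wise softmax
#'
#' `softmax(in)_k = exp(in_k) / sum_j exp(in_j)`, computed stably; each row
#' sums to 1 and the result is invariant to adding a constant to a row.
#'
#' @param x Numeric matrix (rows = samples) or vector.
#' @return Matrix (or vector) of probabilities.
#' @export
softmax <- function(x) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  e <- exp(m - apply(m, 1L, max))
  out <- e / rowSums(e)
  if (vec) as.numeric(out) else out
}

#' Mean cross-entropy between distribution rows
#'
#' `H(P, Q) = mean over rows of -sum_k P_k log Q_k`, with Q clipped away
#' from zero at 1e-12. Non-negative for one-hot P; by Gibbs' inequality
#' `H(P, Q) >= H(P, P)`.
#'
#' @param P True distribution rows (matrix, rows sum to 1).
#' @param Q Predicted distribution rows, same shape.
#' @return Scalar mean cross-entropy (nats).
#' @export
cross_entropy <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) {
    stop("P and Q must have identical shape", call. = FALSE)
  }
  mean(-rowSums(P * log(pmax(Q, 1e-12))))
}

#' CNN architecture specification
#'
#' Ordered layer list for a 1-D CNN ending in a fully-connected layer and
#' softmax. The default stack is
#' conv1d(16 filters, width 9) - relu - maxpool(4) - conv1d(32, 9) - relu -
#' maxpool(4) - fully_connected(d) - softmax: the smallest stack exercising
#' every layer type (convolution, activation, pooling, dense, softmax),
#' with pooling wide enough to keep the dense head small relative to the
#' sample sizes typical of SERS studies.
#'
#' @param input_length Number of spectral points.
#' @param n_classes Number of classes d (>= 2).
#' @param layers Optional list of layer descriptors
#'   (`list(type = "conv", filters =, width =)`, `list(type = "relu")`,
#'   `list(type = "pool", width =)`); the dense + softmax head is appended
#'   automatically.
#' @return A list of class `cnn_architecture` with the resolved shape chain.
#' @export
cnn_architecture <- function(input_length, n_classes, layers = NULL) {
  stopifnot(n_classes >= 2L, input_length >= 8L)
  if (is.null(layers)) {
    layers <- list(
      list(type = "conv", filters = 16L, width = 9L),
      list(type = "relu"),
      list(type = "pool", width = 4L),
      list(type = "conv", filters = 32L, width = 9L),
      list(type = "relu"),
      list(type = "pool", width = 4L))
  }
  layers <- c(layers, list(list(type = "dense"), list(type = "softmax")))
  len <- input_length; ch <- 1L
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      if (ly$width > len) stop("conv width exceeds input length",
                               call. = FALSE)
      layers[[i]]$in_channels <- ch
      len <- len - ly$width + 1L
      ch <- ly$filters
    } else if (ly$type == "pool") {
      if (ly$width > len) stop("pool width exceeds input length",
                               call. = FALSE)
      len <- len %/% ly$width
    } else if (ly$type == "dense") {
      layers[[i]]$in_features <- len * ch
      layers[[i]]$out_features <- n_classes
    }
    layers[[i]]$out_length <- len
    layers[[i]]$out_channels <- ch
  }
  structure(list(layers = layers, input_length = input_length,
                 n_classes = n_classes),
            class = "cnn_architecture")
}

# He-uniform initialisation, seeded; biases start at zero.
cnn_init <- function(arch, seed) {
  with_seed(seed, {
    lapply(arch$layers, function(ly) {
      if (ly$type == "conv") {
        fan_in <- ly$width * ly$in_channels
        lim <- sqrt(6 / fan_in)
        list(W = matrix(stats::runif(fan_in * ly$filters, -lim, lim),
                        fan_in, ly$filters),
             b = numeric(ly$filters))
      } else if (ly$type == "dense") {
        lim <- sqrt(6 / ly$in_features)
        list(W = matrix(stats::runif(ly$in_features * ly$out_features,
                                     -lim, lim),
                        ly$in_features, ly$out_features),
             b = numeric(ly$out_features))
      } else NULL
    })
  })
}

# im2col: input array (B, L, C) -> matrix (B*P, width*C), P = L - width + 1;
# col2im accumulates the transpose operation. Both are compiled.
im2col <- function(x, width) {
  d <- dim(x)
  im2col_c(x, d[1L], d[2L], d[3L], as.integer(width))
}

col2im <- function(dM, width, dims) {
  col2im_c(dM, dims[1L], dims[2L], dims[3L], as.integer(width))
}

# Forward pass: x (B, L) matrix of spectra. Returns final probabilities and
# per-layer caches for backprop.
cnn_forward <- function(params, arch, x) {
  B <- nrow(x)
  a <- array(x, c(B, ncol(x), 1L))
  caches <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      M <- im2col(a, ly$width)
      out <- M %*% params[[i]]$W
      out <- sweep(out, 2L, params[[i]]$b, `+`)
      caches[[i]] <- list(M = M, dims = dim(a))
      a <- array(out, c(B, nrow(out) %/% B, ly$filters))
    } else if (ly$type == "relu") {
      caches[[i]] <- list(mask = a > 0)
      a <- pmax(a, 0)
    } else if (ly$type == "pool") {
      dd <- dim(a)
      pooled <- maxpool_fwd_c(a, dd[1L], dd[2L], dd[3L],
                              as.integer(ly$width))
      caches[[i]] <- list(argmax = pooled$argmax, in_dims = dd)
      a <- pooled$out
    } else if (ly$type == "dense") {
      flat <- matrix(a, B, length(a) %/% B)
      out <- sweep(flat %*% params[[i]]$W, 2L, params[[i]]$b, `+`)
      caches[[i]] <- list(flat = flat, in_dims = dim(a))
      a <- out
    } else if (ly$type == "softmax") {
      caches[[i]] <- list(logits = a)
      a <- softmax(a)
    }
  }
  list(probs = a, caches = caches)
}

# Backward pass from softmax + cross-entropy against one-hot targets.
cnn_backward <- function(params, arch, fwd, onehot) {
  B <- nrow(onehot)
  grads <- vector("list", length(arch$layers))
  d <- (fwd$probs - onehot) / B        # d loss / d logits
  for (i in rev(seq_along(arch$layers))) {
    ly <- arch$layers[[i]]
    cache <- fwd$caches[[i]]
    if (ly$type == "softmax") {
      # combined with cross-entropy above; nothing to do
    } else if (ly$type == "dense") {
      grads[[i]] <- list(W = t(cache$flat) %*% d, b = colSums(d))
      d <- array(d %*% t(params[[i]]$W), cache$in_dims)
    } else if (ly$type == "pool") {
      dims <- cache$in_dims
      d <- maxpool_bwd_c(d, cache$argmax, dims[1L], dims[2L], dims[3L],
                         as.integer(ly$width))
    } else if (ly$type == "relu") {
      d <- d * cache$mask
    } else if (ly$type == "conv") {
      dmat <- matrix(d, dim(d)[1L] * dim(d)[2L], dim(d)[3L])
      grads[[i]] <- list(W = t(cache$M) %*% dmat, b = colSums(dmat))
      d <- col2im(dmat %*% t(params[[i]]$W), ly$width, cache$dims)
    }
  }
  grads
}

#' Training configuration for the CNN
#'
#' Adam with the stated defaults: at most 60 training rounds (epochs) and an
#' initial learning rate of 0.01.
#'
#' @param max_epochs Number of epochs (>= 1).
#' @param learning_rate Initial Adam step size (> 0).
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for weight initialisation and shuffling.
#' @param grad_clip Global L2-norm gradient clipping threshold; stabilizes
#'   training at the stated learning rate. `Inf` disables clipping.
#' @param l2 L2 weight-decay coefficient added to the loss
#'   (`l2/2 * sum(W^2)`, biases excluded).
#' @param lr_decay Per-epoch multiplicative decay of the learning rate
#'   (1 = constant rate).
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_epochs = 60L, learning_rate = 0.01,
                         batch_size = 16L, seed = 1L, grad_clip = 1,
                         l2 = 1e-3, lr_decay = 0.92) {
  stopifnot(max_epochs >= 1L, learning_rate > 0, batch_size >= 1L,
            grad_clip > 0, l2 >= 0, lr_decay > 0, lr_decay <= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), grad_clip = grad_clip, l2 = l2,
                 lr_decay = lr_decay),
            class = "train_config")
}

normalize_rows <- function(X) {
  m <- apply(abs(X), 1L, max)
  X / pmax(m, 1e-12)
}

#' Train a 1-D convolutional neural network on spectra
#'
#' Minimizes mean cross-entropy by Adam over mini-batches. Spectra are
#' per-spectrum max-normalized before entering the network. Fully seeded
#' (weight initialisation and epoch shuffling), so identical seeds give
#' identical final weights.
#'
#' @param train,val [sers_set()] objects sharing the axis; every class in
#'   `val` must appear in `train`.
#' @param arch Optional [cnn_architecture()]; defaults to the standard
#'   stack for the training set's length and class count.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A list with `model` (class `cnn_model`: parameters, architecture,
#'   class names) and `curves` (class `training_curves`: per-iteration
#'   training loss/accuracy and per-epoch validation loss/accuracy).
#' @export
train_cnn <- function(train, val = NULL, arch = NULL,
                      config = train_config(), verbose = FALSE) {
  X <- normalize_rows(train$matrix)
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  if (!is.null(val) && !all(unique(val$labels) %in% classes)) {
    stop("validation set contains a class absent from training",
         call. = FALSE)
  }
  if (is.null(arch)) arch <- cnn_architecture(ncol(X), length(classes))
  yi <- match(train$labels, classes)
  onehot_all <- diag(length(classes))[yi, , drop = FALSE]
  params <- cnn_init(arch, config$seed)
  zero_like <- function(p) {
    if (is.null(p)) NULL else list(W = p$W * 0, b = p$b * 0)
  }
  m_st <- lapply(params, zero_like)
  v_st <- lapply(params, zero_like)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  iter_loss <- numeric(0); iter_acc <- numeric(0)
  val_loss <- numeric(0); val_acc <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$learning_rate * config$lr_decay^(epoch - 1L)
    ord <- with_seed((config$seed * 2654435761 + epoch) %% 2147483647,
                     sample.int(n))
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      ohb <- onehot_all[idx, , drop = FALSE]
      fwd <- cnn_forward(params, arch, xb)
      grads <- cnn_backward(params, arch, fwd, ohb)
      if (config$l2 > 0) {
        for (i in seq_along(grads)) {
          if (!is.null(grads[[i]])) {
            grads[[i]]$W <- grads[[i]]$W + config$l2 * params[[i]]$W
          }
        }
      }
      if (is.finite(config$grad_clip)) {
        gn <- sqrt(sum(vapply(grads, function(g) {
          if (is.null(g)) 0 else sum(g$W^2) + sum(g$b^2)
        }, 0)))
        if (gn > config$grad_clip) {
          sc <- config$grad_clip / gn
          grads <- lapply(grads, function(g) {
            if (is.null(g)) NULL else list(W = g$W * sc, b = g$b * sc)
          })
        }
      }
      step <- step + 1L
      for (i in seq_along(params)) {
        if (is.null(params[[i]])) next
        for (nm in c("W", "b")) {
          g <- grads[[i]][[nm]]
          m_st[[i]][[nm]] <- b1 * m_st[[i]][[nm]] + (1 - b1) * g
          v_st[[i]][[nm]] <- b2 * v_st[[i]][[nm]] + (1 - b2) * g^2
          mhat <- m_st[[i]][[nm]] / (1 - b1^step)
          vhat <- v_st[[i]][[nm]] / (1 - b2^step)
          params[[i]][[nm]] <- params[[i]][[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
      }
      iter_loss <- c(iter_loss, cross_entropy(ohb, fwd$probs))
      iter_acc <- c(iter_acc,
                    mean(apply(fwd$probs, 1L, which.max) ==
                           match(train$labels[idx], classes)))
    }
    if (!is.null(val)) {
      vp <- cnn_forward(params, arch, normalize_rows(val$matrix))$probs
      voh <- diag(length(classes))[match(val$labels, classes), ,
                                   drop = FALSE]
      val_loss <- c(val_loss, cross_entropy(voh, vp))
      val_acc <- c(val_acc, mean(classes[apply(vp, 1L, which.max)] ==
                                   val$labels))
    }
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f%s", epoch,
                      mean(utils::tail(iter_loss, length(starts))),
                      if (!is.null(val))
                        sprintf(", val acc %.3f", utils::tail(val_acc, 1L))
                      else ""))
    }
  }
  model <- structure(list(params = params, arch = arch,
                          class_names = classes),
                     class = "cnn_model")
  curves <- structure(list(iter_loss = iter_loss, iter_acc = iter_acc,
                           val_loss = val_loss, val_acc = val_acc,
                           epochs = config$max_epochs),
                      class = "training_curves")
  list(model = model, curves = curves)
}

#' Class probabilities and predictions from a trained CNN
#'
#' Each row of the output is the softmax of the final fully-connected
#' layer's output; rows sum to 1. The predicted class is the argmax, ties
#' resolved toward the smallest class index.
#'
#' @param model A `cnn_model` from [train_cnn()].
#' @param X A [sers_set()] or spectra matrix with the trained input length.
#' @return A list with `probabilities` (n x d matrix, columns named by
#'   class) and `classes` (character vector).
#' @export
cnn_predict <- function(model, X) {
  M <- if (inherits(X, "sers_set")) X$matrix else as.matrix(X)
  if (ncol(M) != model$arch$input_length) {
    stop("input length does not match the trained network", call. = FALSE)
  }
  probs <- cnn_forward(model$params, model$arch, normalize_rows(M))$probs
  colnames(probs) <- model$class_names
  list(probabilities = probs,
       classes = model$class_names[apply(probs, 1L, which.max)])
}

#' Export training curves as a CSV
#'
#' @param curves A `training_curves` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_training_curves <- function(curves, path) {
  n <- length(curves$iter_loss)
  df <- data.frame(iteration = seq_len(n), train_loss = curves$iter_loss,
                   train_accuracy = curves$iter_acc)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
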