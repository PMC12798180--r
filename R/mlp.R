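#' Fit a small feed-forward neural network
#'
#' A plain multi-layer perceptron with rectified-linear hidden layers,
#' trained with Adam on minibatches. For binary classification the output
#' unit is a sigmoid trained on cross-entropy; for (multi-output)
#' regression the output layer is linear trained on mean squared error.
#' This is deliberately minimal: the package uses it for the 2- and
#' 3-layer network candidates (hidden widths 128/64 and 128/64/32) and
#' for the embedding-to-norm mapping roster.
#'
#' @param x Numeric matrix of predictors (rows = samples).
#' @param y 0/1 vector (binary task) or numeric matrix (regression).
#' @param hidden Integer vector of hidden-layer widths.
#' @param task `"binary"` or `"regression"`.
#' @param epochs,batch_size,lr Training schedule; defaults 100, 32, 1e-3.
#' @param seed Seed for weight initialization and minibatch shuffling.
#' @return List with class `dct_mlp` (weights, dims, task).
#' @export
mlp_fit <- function(x, y, hidden = c(128, 64),
                    task = c("binary", "regression"),
                    epochs = 100, batch_size = 32, lr = 1e-3, seed = 1L) {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (task == "binary") {
    y <- matrix(as.numeric(y), ncol = 1)
  } else {
    y <- as.matrix(y)
  }
  stopifnot(nrow(x) == nrow(y), all(is.finite(x)), all(is.finite(y)))
  dims <- c(ncol(x), hidden, ncol(y))
  L <- length(dims) - 1
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
             dims[l], dims[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0
    n <- nrow(x)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        # forward
        A <- vector("list", L + 1)
        A[[1]] <- xb
        for (l in seq_len(L)) {
          z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
          A[[l + 1]] <- if (l < L) pmax(z, 0)
                        else if (task == "binary") stats::plogis(z) else z
        }
        # backward: both losses give delta = (pred - y) / batch at output
        delta <- (A[[L + 1]] - yb) / length(idx)
        t_step <- t_step + 1
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^t_step)
          vhW <- vW[[l]] / (1 - beta2^t_step)
          mhb <- mb[[l]] / (1 - beta1^t_step)
          vhb <- vb[[l]] / (1 - beta2^t_step)
          W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
    }
    structure(list(W = W, b = b, dims = dims, task = task), class = "dct_mlp")
  })
}

#' Predict from a fitted MLP
#'
#' @param object A `dct_mlp` from [mlp_fit()].
#' @param newdata Numeric matrix of predictors.
#' @param ... Unused.
#' @return For binary task, a probability vector; for regression, a
#'   numeric matrix.
#' @export
predict.dct_mlp <- function(object, newdata, ...) {
  a <- as.matrix(newdata)
  L <- length(object$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    a <- if (l < L) pmax(z, 0)
         else if (object$task == "binary") stats::plogis(z) else z
  }
  if (object$task == "binary") as.vector(a) else a
}
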