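#' DSR network architecture specification
#'
#' The diffusion super-resolution (DSR) network is a fully connected model:
#' each hidden block is dense -> batch normalization -> ReLU, and the output
#' is a dense layer with no activation. The default maps the flattened
#' 3x3x3 x 44 input (1188 values) through three 1000-unit blocks to the
#' 2x2x2 x 44 output (352 values).
#'
#' @param input_dim Input vector length.
#' @param hidden Integer vector of hidden-layer widths.
#' @param output_dim Output vector length.
#' @return A list of class `dsr_spec`.
#' @export
dsr_model_spec <- function(input_dim = 1188, hidden = c(1000, 1000, 1000),
                          output_dim = 352) {
  stopifnot(input_dim >= 1, output_dim >= 1, length(hidden) >= 1,
            all(hidden >= 1))
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim)),
            class = "dsr_spec")
}

#' Trainable-parameter count of a DSR specification
#'
#' Dense weights and biases plus the two trainable batch-norm parameters
#' (scale and shift) per hidden unit. The default architecture has
#' 3,549,352 parameters (3.5 million at coarse precision); the 5x5x5-input
#' variant (5500 inputs) counts 7,861,352.
#'
#' @param spec A [dsr_model_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "dsr_spec"))
  dims <- c(spec$input_dim, spec$hidden)
  total <- 0
  for (i in seq_along(spec$hidden)) {
    total <- total + dims[i] * dims[i + 1] + dims[i + 1] +  # dense W + b
      2 * dims[i + 1]                                       # BN gamma + beta
  }
  total <- total + dims[length(dims)] * spec$output_dim + spec$output_dim
  as.integer(total)
}

#' Training configuration
#'
#' Mean-squared-error loss with the Adam optimizer; defaults are batch size
#' 512, 100 epochs, learning rate 1e-3.
#'
#' @param batch_size Minibatch size (>= 2; batch normalization needs at
#'   least two examples).
#' @param epochs Number of passes over the training set.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 512, epochs = 100,
                         learning_rate = 1e-3, seed = 1) {
  stopifnot(batch_size >= 2, epochs >= 1, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

bn_eps <- 1e-3
bn_momentum <- 0.99

init_dsr_params <- function(spec) {
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  dims <- c(spec$input_dim, spec$hidden)
  layers <- lapply(seq_along(spec$hidden), function(i) {
    h <- dims[i + 1]
    list(W = glorot(dims[i], h), b = numeric(h),
         gamma = rep(1, h), beta = numeric(h),
         run_mean = numeric(h), run_var = rep(1, h))
  })
  out <- list(W = glorot(dims[length(dims)], spec$output_dim),
              b = numeric(spec$output_dim))
  list(layers = layers, out = out)
}

# forward pass; training = TRUE uses batch statistics and returns the caches
# needed for backprop, training = FALSE uses running statistics
dsr_forward <- function(params, X, training = FALSE) {
  n <- nrow(X)
  caches <- vector("list", length(params$layers))
  A <- X
  for (i in seq_along(params$layers)) {
    L <- params$layers[[i]]
    Z <- A %*% L$W + rep(L$b, each = n)
    if (training) {
      mu <- colMeans(Z)
      zc <- Z - rep(mu, each = n)
      var <- colMeans(zc^2)
      inv <- 1 / sqrt(var + bn_eps)
      Zhat <- zc * rep(inv, each = n)
    } else {
      mu <- L$run_mean
      inv <- 1 / sqrt(L$run_var + bn_eps)
      Zhat <- (Z - rep(mu, each = n)) * rep(inv, each = n)
      var <- L$run_var
    }
    H <- Zhat * rep(L$gamma, each = n) + rep(L$beta, each = n)
    Anew <- H * (H > 0)
    if (training)
      caches[[i]] <- list(A_in = A, Zhat = Zhat, inv = inv, mu = mu,
                          var = var, H = H)
    A <- Anew
  }
  pred <- A %*% params$out$W + rep(params$out$b, each = n)
  list(pred = pred, A_last = A, caches = caches)
}

# gradients of mean-over-all-entries squared error
dsr_backward <- function(params, X, Y, fwd) {
  n <- nrow(X)
  grads <- list(layers = vector("list", length(params$layers)), out = NULL)
  dPred <- 2 * (fwd$pred - Y) / length(Y)
  grads$out <- list(W = crossprod(fwd$A_last, dPred), b = colSums(dPred))
  dA <- tcrossprod(dPred, params$out$W)  # dPred %*% t(W)
  for (i in rev(seq_along(params$layers))) {
    L <- params$layers[[i]]
    cc <- fwd$caches[[i]]
    dH <- dA * (cc$H > 0)
    dgamma <- colSums(dH * cc$Zhat)
    dbeta <- colSums(dH)
    dZhat <- dH * rep(L$gamma, each = n)
    s1 <- colSums(dZhat)
    s2 <- colSums(dZhat * cc$Zhat)
    dZ <- (dZhat - rep(s1 / n, each = n) -
             cc$Zhat * rep(s2 / n, each = n)) * rep(cc$inv, each = n)
    grads$layers[[i]] <- list(W = crossprod(cc$A_in, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    if (i > 1) dA <- tcrossprod(dZ, L$W)
  }
  grads
}

adam_state <- function(params) rapply(params, function(p) p * 0, how = "replace")

adam_update <- function(params, grads, m, v, t, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, mm, vv) {
    mm <- beta1 * mm + (1 - beta1) * g
    vv <- beta2 * vv + (1 - beta2) * g^2
    mh <- mm / (1 - beta1^t)
    vh <- vv / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = mm, v = vv)
  }
  # walk the gradient structure only: batch-norm running statistics live in
  # `params` but are not trainable and carry no gradient
  walk <- function(p, g, mm, vv) {
    if (is.list(g)) {
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (k in keys) {
        res <- walk(p[[k]], g[[k]], mm[[k]], vv[[k]])
        p[[k]] <- res$p; mm[[k]] <- res$m; vv[[k]] <- res$v
      }
      list(p = p, m = mm, v = vv)
    } else upd(p, g, mm, vv)
  }
  walk(params, grads, m, v)
}

#' Train the DSR network
#'
#' Minimizes the mean squared error between predicted and target
#' high-resolution SH blocks with Adam, using per-batch statistics for batch
#' normalization during training and exponentially averaged running
#' statistics at inference. Fully seeded: two runs with the same data, spec
#' and configuration produce identical weights and losses.
#'
#' @param data A [patch_dataset()] (or any list with numeric matrices
#'   `inputs` and `targets`) used for training.
#' @param spec A [dsr_model_spec()]; defaults to the dimensions of `data`.
#' @param config A [train_config()].
#' @param val Optional validation dataset of the same form; per-epoch
#'   validation MSE is recorded in inference mode.
#' @return An object of class `dsr_model`: `params`, `spec`, `config`, and
#'   `history` (tibble with `epoch`, `train_mse`, optional `val_mse`).
#' @export
train_dsr <- function(data, spec = NULL, config = train_config(), val = NULL) {
  X <- data$inputs; Y <- data$targets
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y), nrow(X) >= 2)
  if (is.null(spec))
    spec <- dsr_model_spec(ncol(X), c(1000, 1000, 1000), ncol(Y))
  stopifnot(ncol(X) == spec$input_dim, ncol(Y) == spec$output_dim)
  n <- nrow(X)

  withr::with_seed(config$seed, {
    params <- init_dsr_params(spec)
    m <- adam_state(params); v <- adam_state(params)
    t <- 0L
    hist_train <- numeric(config$epochs)
    hist_val <- if (is.null(val)) NULL else numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c(); sizes <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1L, n)]
        if (length(ix) < 2) next  # batch norm needs >= 2 examples
        Xb <- X[ix, , drop = FALSE]; Yb <- Y[ix, , drop = FALSE]
        fwd <- dsr_forward(params, Xb, training = TRUE)
        loss <- mean((fwd$pred - Yb)^2)
        grads <- dsr_backward(params, Xb, Yb, fwd)
        t <- t + 1L
        st <- adam_update(params, grads, m, v, t, config$learning_rate)
        params <- st$p; m <- st$m; v <- st$v
        # running batch-norm statistics follow the post-update caches
        for (i in seq_along(params$layers)) {
          cc <- fwd$caches[[i]]
          params$layers[[i]]$run_mean <-
            bn_momentum * params$layers[[i]]$run_mean +
            (1 - bn_momentum) * cc$mu
          params$layers[[i]]$run_var <-
            bn_momentum * params$layers[[i]]$run_var +
            (1 - bn_momentum) * cc$var
        }
        losses <- c(losses, loss); sizes <- c(sizes, length(ix))
      }
      hist_train[ep] <- sum(losses * sizes) / sum(sizes)
      if (!is.null(val)) {
        pv <- dsr_forward(params, val$inputs)$pred
        hist_val[ep] <- mean((pv - val$targets)^2)
      }
    }
    history <- tibble::tibble(epoch = seq_len(config$epochs),
                              train_mse = hist_train)
    if (!is.null(hist_val)) history$val_mse <- hist_val
    structure(list(params = params, spec = spec, config = config,
                   history = history),
              class = "dsr_model")
  })
}

#' Predict with a trained DSR network
#'
#' @param object A `dsr_model`.
#' @param newdata Matrix of input rows (length `spec$input_dim`) or a
#'   [patch_dataset()].
#' @param ... Unused.
#' @return Matrix of predicted output rows.
#' @export
predict.dsr_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else newdata$inputs
  stopifnot(ncol(X) == object$spec$input_dim)
  dsr_forward(object$params, X)$pred
}

#' @export
print.dsr_model <- function(x, ...) {
  cat(sprintf("<dsr_model> %d -> [%s] -> %d, %s parameters, %d epochs (final train MSE %.3g)\n",
              x$spec$input_dim, paste(x$spec$hidden, collapse = ", "),
              x$spec$output_dim,
              format(count_parameters(x$spec), big.mark = ","),
              nrow(x$history), utils::tail(x$history$train_mse, 1)))
  invisible(x)
}

#' Broom-style accessors for a trained DSR model
#'
#' `tidy()` returns the per-epoch loss history in long form; `glance()` a
#' one-row summary (parameter count, epochs, final/best losses).
#'
#' @param x A `dsr_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dsr_model <- function(x, ...) {
  h <- x$history
  out <- tibble::tibble(epoch = h$epoch, metric = "train_mse",
                        value = h$train_mse)
  if ("val_mse" %in% names(h))
    out <- rbind(out, tibble::tibble(epoch = h$epoch, metric = "val_mse",
                                     value = h$val_mse))
  out
}

#' @rdname tidy.dsr_model
#' @export
glance.dsr_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = count_parameters(x$spec),
    epochs = nrow(x$history),
    final_train_mse = utils::tail(x$history$train_mse, 1),
    best_train_mse = min(x$history$train_mse),
    final_val_mse = if ("val_mse" %in% names(x$history))
      utils::tail(x$history$val_mse, 1) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Loss-history plot for a trained DSR model
#'
#' @param object A `dsr_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dsr_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared error", colour = NULL)
}
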