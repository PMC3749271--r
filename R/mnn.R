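# Five-layer autoencoder (nonlinear PCA network): widths (N, h, M, h, N),
# activations (sigmoid, linear, sigmoid, linear); the bottleneck activations
# are the nonlinear principal components.

sigmoidFn <- function(z) 1 / (1 + exp(-z))

#' Build the five-layer nonlinear-PC network
#'
#' @param nIn input (and output) width.
#' @param mBottleneck bottleneck width, `1 <= mBottleneck < nIn`.
#' @param h width of the two nonlinear layers (default `2 * nIn`; the
#'   approximation layers should be wider than the bottleneck).
#' @param seed integer seed for the small-uniform weight initialization.
#' @param learningRate initial back-propagation learning rate (default 0.3).
#' @param momentum momentum coefficient (default 0.8).
#' @param activation `"sigmoid"`, or `"identity"` for the linear test mode in
#'   which the network reduces to a linear autoencoder.
#' @return An [MnnModel-class].
#' @export
buildMnn <- function(nIn, mBottleneck, h = 2L * nIn, seed = 1L,
                     learningRate = 0.3, momentum = 0.8,
                     activation = c("sigmoid", "identity")) {
  activation <- match.arg(activation)
  if (mBottleneck < 1 || mBottleneck >= nIn)
    stop("configuration error: 1 <= mBottleneck < nIn is required",
         call. = FALSE)
  sizes <- as.integer(c(nIn, h, mBottleneck, h, nIn))
  withSeed(seed, {
    weights <- list(); biases <- list(); velocity <- list()
    for (l in 1:4) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      weights[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
                             sizes[l], sizes[l + 1])
      biases[[l]] <- numeric(sizes[l + 1])
      velocity[[l]] <- list(W = weights[[l]] * 0, b = biases[[l]] * 0)
    }
    new("MnnModel", sizes = sizes, weights = weights, biases = biases,
        activation = activation, learningRate = learningRate,
        momentum = momentum, velocity = velocity)
  })
}

# Forward pass; returns activations per layer (samples x width).
mnnForward <- function(model, X) {
  act <- if (model@activation == "sigmoid") sigmoidFn else identity
  a <- list(X)
  for (l in 1:4) {
    z <- a[[l]] %*% model@weights[[l]] +
      matrix(model@biases[[l]], nrow(X), length(model@biases[[l]]),
             byrow = TRUE)
    a[[l + 1]] <- if (l %in% c(1, 3)) act(z) else z  # layers 1,3 nonlinear
  }
  a
}

#' Train the network by back-propagation
#'
#' Full-batch gradient descent on the mean squared reconstruction error with
#' momentum and an adaptive learning rate: the rate grows by 5% after an
#' epoch that lowers the loss and is halved (with the step undone) after an
#' epoch that raises it.
#'
#' @param model an [MnnModel-class].
#' @param data samples x nIn matrix.
#' @param epochs training epochs (0 leaves the model unchanged).
#' @return A list with `model` (trained) and `loss` (per-epoch MSE).
#' @export
trainMnn <- function(model, data, epochs = 100L) {
  X <- as.matrix(data)
  stopDim(ncol(X) == model@sizes[1], "data width must equal the input width")
  n <- nrow(X)
  lr <- model@learningRate
  loss <- numeric(0)
  prevLoss <- Inf
  W <- model@weights; b <- model@biases; vel <- model@velocity
  sig <- model@activation == "sigmoid"
  for (ep in seq_len(epochs)) {
    # forward
    a <- list(X); zs <- list()
    for (l in 1:4) {
      z <- a[[l]] %*% W[[l]] + matrix(b[[l]], n, length(b[[l]]), byrow = TRUE)
      zs[[l]] <- z
      a[[l + 1]] <- if (l %in% c(1, 3) && sig) sigmoidFn(z) else z
    }
    err <- a[[5]] - X
    mse <- mean(err^2)
    if (!is.finite(mse))
      stop("training diverged (non-finite loss)", call. = FALSE)
    loss <- c(loss, mse)
    if (mse > prevLoss) {
      # reject the step: restore, damp the rate, retry from the restored point
      W <- Wprev; b <- bprev
      vel <- lapply(vel, function(v) list(W = v$W * 0, b = v$b * 0))
      lr <- lr / 2
      next
    }
    lr <- lr * 1.05
    prevLoss <- mse
    Wprev <- W; bprev <- b
    # backward
    delta <- 2 * err / (n * ncol(X))
    for (l in 4:1) {
      gW <- t(a[[l]]) %*% delta
      gb <- colSums(delta)
      if (l > 1) {
        delta <- delta %*% t(W[[l]])
        if ((l - 1) %in% c(1, 3) && sig) {
          s <- a[[l]]
          delta <- delta * s * (1 - s)
        }
      }
      vel[[l]]$W <- model@momentum * vel[[l]]$W - lr * gW
      vel[[l]]$b <- model@momentum * vel[[l]]$b - lr * gb
      W[[l]] <- W[[l]] + vel[[l]]$W
      b[[l]] <- b[[l]] + vel[[l]]$b
    }
  }
  model@weights <- W; model@biases <- b; model@velocity <- vel
  model@learningRate <- lr
  list(model = model, loss = loss)
}

#' Extract nonlinear principal components
#'
#' Forward pass truncated at the bottleneck (layer 2 of the hidden stack):
#' returns the samples x M matrix of bottleneck activations.
#'
#' @param model a trained [MnnModel-class].
#' @param data samples x nIn matrix.
#' @return samples x mBottleneck component matrix.
#' @export
extractNonlinearPcs <- function(model, data) {
  X <- as.matrix(data)
  stopDim(ncol(X) == model@sizes[1], "data width must equal the input width")
  mnnForward(model, X)[[3]]
}
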