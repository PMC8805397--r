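# LSTM autoencoder for two-point clinical time series.
#
# Encoder: a standard LSTM cell (input, forget, output gates, tanh candidate)
# unrolled over the two time points H0, H1; the final hidden state is
# projected linearly to a latent vector z ("deep features"). Decoder: a
# second LSTM that receives z at each step and reconstructs the two input
# vectors through a linear readout. Trained full-batch with Adam on mean
# squared reconstruction error, so a fixed seed gives a bit-reproducible fit.
# Implemented directly in R: the unroll depth is 2 and widths are tens of
# units, so hand-written backpropagation-through-time over matrix ops is
# both fast enough and dependency-free.

#' Autoencoder configuration
#'
#' @param latent_dim width of the extracted representation (default 8); must
#'   not exceed the number of paired features.
#' @param hidden_units LSTM state width of encoder and decoder (default 32).
#' @param epochs full-batch Adam steps (default 30).
#' @param learning_rate Adam step size (default 0.01).
#' @param seed integer RNG seed for the parameter initialization.
#' @return an object of class `niv_ae_spec`.
#' @export
autoencoder_spec <- function(latent_dim = 8L, hidden_units = 32L, epochs = 30L,
                             learning_rate = 0.01, seed = 1L) {
  check_field(latent_dim >= 1, "latent_dim", "must be >= 1")
  check_field(hidden_units >= 1, "hidden_units", "must be >= 1")
  check_field(epochs >= 1, "epochs", "must be >= 1")
  check_field(learning_rate > 0, "learning_rate", "must be > 0")
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "niv_ae_spec")
}

#' Stack paired H0/H1 columns into sequences
#'
#' @param matrix feature `data.frame` of standardized measurements.
#' @param pairs a [paired_feature_map()] result.
#' @return an `n x 2 x d` array; `[, 1, ]` is H0, `[, 2, ]` is H1.
#' @export
paired_sequences <- function(matrix, pairs) {
  X0 <- as.matrix(matrix[pairs$h0]); X1 <- as.matrix(matrix[pairs$h1])
  arr <- array(0, dim = c(nrow(X0), 2, ncol(X0)),
               dimnames = list(NULL, c("H0", "H1"), pairs$base))
  arr[, 1, ] <- X0; arr[, 2, ] <- X1
  arr
}

sigm <- function(x) 1 / (1 + exp(-x))

ae_init <- function(d, H, L, seed) {
  gl <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -r, r), nr, nc)
  }
  with_seed(seed, {
    p <- list(Wx = gl(d, 4 * H), Wh = gl(H, 4 * H), b = rep(0, 4 * H),
              Wz = gl(H, L), bz = rep(0, L),
              Wxd = gl(L, 4 * H), Whd = gl(H, 4 * H), bd = rep(0, 4 * H),
              Wy = gl(H, d), by = rep(0, d))
    # forget-gate bias at 1: standard LSTM initialization
    p$b[(H + 1):(2 * H)] <- 1
    p$bd[(H + 1):(2 * H)] <- 1
    p
  })
}

lstm_step <- function(X, h_prev, c_prev, Wx, Wh, b, H) {
  A <- X %*% Wx + h_prev %*% Wh + matrix(b, nrow(X), length(b), byrow = TRUE)
  i <- sigm(A[, 1:H, drop = FALSE])
  f <- sigm(A[, (H + 1):(2 * H), drop = FALSE])
  o <- sigm(A[, (2 * H + 1):(3 * H), drop = FALSE])
  g <- tanh(A[, (3 * H + 1):(4 * H), drop = FALSE])
  c_new <- f * c_prev + i * g
  tc <- tanh(c_new)
  list(h = o * tc, c = c_new, i = i, f = f, o = o, g = g, tc = tc,
       X = X, h_prev = h_prev, c_prev = c_prev)
}

# backward through one cell; returns upstream grads and accumulates dW
lstm_step_back <- function(cache, dh, dc, Wx, Wh) {
  H <- ncol(cache$h)
  dc <- dc + dh * cache$o * (1 - cache$tc^2)
  do <- dh * cache$tc
  di <- dc * cache$g
  df <- dc * cache$c_prev
  dg <- dc * cache$i
  dA <- cbind(di * cache$i * (1 - cache$i),
              df * cache$f * (1 - cache$f),
              do * cache$o * (1 - cache$o),
              dg * (1 - cache$g^2))
  list(dWx = crossprod(cache$X, dA),
       dWh = crossprod(cache$h_prev, dA),
       db = colSums(dA),
       dX = dA %*% t(Wx),
       dh_prev = dA %*% t(Wh),
       dc_prev = dc * cache$f)
}

ae_forward <- function(p, X0, X1, H) {
  n <- nrow(X0)
  z0 <- matrix(0, n, H)
  e1 <- lstm_step(X0, z0, z0, p$Wx, p$Wh, p$b, H)
  e2 <- lstm_step(X1, e1$h, e1$c, p$Wx, p$Wh, p$b, H)
  z <- e2$h %*% p$Wz + matrix(p$bz, n, length(p$bz), byrow = TRUE)
  d1 <- lstm_step(z, z0, z0, p$Wxd, p$Whd, p$bd, H)
  d2 <- lstm_step(z, d1$h, d1$c, p$Wxd, p$Whd, p$bd, H)
  Y1 <- d1$h %*% p$Wy + matrix(p$by, n, length(p$by), byrow = TRUE)
  Y2 <- d2$h %*% p$Wy + matrix(p$by, n, length(p$by), byrow = TRUE)
  loss <- (sum((Y1 - X0)^2) + sum((Y2 - X1)^2)) / (2 * n * ncol(X0))
  list(loss = loss, z = z, e1 = e1, e2 = e2, d1 = d1, d2 = d2, Y1 = Y1, Y2 = Y2)
}

ae_backward <- function(p, fw, X0, X1, H) {
  n <- nrow(X0); d <- ncol(X0)
  scale <- 1 / (n * 2 * d)
  dY1 <- 2 * (fw$Y1 - X0) * scale
  dY2 <- 2 * (fw$Y2 - X1) * scale
  g <- list(Wy = crossprod(fw$d1$h, dY1) + crossprod(fw$d2$h, dY2),
            by = colSums(dY1) + colSums(dY2))
  dh2 <- dY2 %*% t(p$Wy)
  b2 <- lstm_step_back(fw$d2, dh2, matrix(0, n, H), p$Wxd, p$Whd)
  dh1 <- dY1 %*% t(p$Wy) + b2$dh_prev
  b1 <- lstm_step_back(fw$d1, dh1, b2$dc_prev, p$Wxd, p$Whd)
  g$Wxd <- b1$dWx + b2$dWx; g$Whd <- b1$dWh + b2$dWh; g$bd <- b1$db + b2$db
  dz <- b1$dX + b2$dX
  g$Wz <- crossprod(fw$e2$h, dz); g$bz <- colSums(dz)
  dhe2 <- dz %*% t(p$Wz)
  eb2 <- lstm_step_back(fw$e2, dhe2, matrix(0, n, H), p$Wx, p$Wh)
  eb1 <- lstm_step_back(fw$e1, eb2$dh_prev, eb2$dc_prev, p$Wx, p$Wh)
  g$Wx <- eb1$dWx + eb2$dWx; g$Wh <- eb1$dWh + eb2$dWh; g$b <- eb1$db + eb2$db
  g
}

#' Fit the LSTM autoencoder
#'
#' @param sequences an `n x 2 x d` array from [paired_sequences()] of
#'   standardized, imputed measurements (all finite).
#' @param spec an [autoencoder_spec()]; `latent_dim` must be at most `d`.
#' @return an object of class `niv_autoencoder` with the fitted parameters,
#'   the per-epoch training-loss trace, the initial loss, and the input
#'   feature ordering.
#' @seealso [encode_features()]
#' @export
fit_autoencoder <- function(sequences, spec = autoencoder_spec()) {
  stopifnot(inherits(spec, "niv_ae_spec"), length(dim(sequences)) == 3,
            dim(sequences)[2] == 2)
  if (!all(is.finite(sequences))) stop("sequences must be finite (impute first)")
  d <- dim(sequences)[3]
  if (spec$latent_dim > d)
    stop("latent_dim (", spec$latent_dim, ") exceeds number of paired features (", d, ")")
  X0 <- sequences[, 1, , drop = TRUE]; X1 <- sequences[, 2, , drop = TRUE]
  if (is.null(dim(X0))) { X0 <- matrix(X0, ncol = d); X1 <- matrix(X1, ncol = d) }
  H <- spec$hidden_units
  p <- ae_init(d, H, spec$latent_dim, spec$seed)

  m <- lapply(p, function(w) w * 0); v <- m
  b1 <- 0.9; b2 <- 0.999; epsd <- 1e-8
  initial_loss <- ae_forward(p, X0, X1, H)$loss
  trace <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    fw <- ae_forward(p, X0, X1, H)
    gr <- ae_backward(p, fw, X0, X1, H)
    for (nm in names(p)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^ep); vhat <- v[[nm]] / (1 - b2^ep)
      p[[nm]] <- p[[nm]] - spec$learning_rate * mhat / (sqrt(vhat) + epsd)
    }
    trace[ep] <- ae_forward(p, X0, X1, H)$loss
  }
  structure(list(params = p, spec = spec, initial_loss = initial_loss,
                 loss_trace = trace,
                 feature_names = dimnames(sequences)[[3]] %||% paste0("f", 1:d)),
            class = "niv_autoencoder")
}

#' @export
print.niv_autoencoder <- function(x, ...) {
  cat("<niv_autoencoder>", length(x$feature_names), "paired features ->",
      x$spec$latent_dim, "latent units; loss", signif(x$initial_loss, 4),
      "->", signif(x$loss_trace[length(x$loss_trace)], 4), "\n")
  invisible(x)
}

#' Encode sequences to deep features
#'
#' Runs the fitted encoder and returns the latent representation extracted
#' from the final hidden state.
#'
#' @param model a fitted `niv_autoencoder`.
#' @param sequences an `n x 2 x d` array with the same feature ordering as
#'   at fit time.
#' @return an `n x latent_dim` `data.frame` with columns `deep_1..`, tagged
#'   `deep` in its provenance attribute.
#' @export
encode_features <- function(model, sequences) {
  stopifnot(inherits(model, "niv_autoencoder"))
  d <- length(model$feature_names)
  if (length(dim(sequences)) != 3 || dim(sequences)[2] != 2 ||
      dim(sequences)[3] != d)
    stop("sequences must be n x 2 x ", d, " (feature ordering as at fit time)")
  nm <- dimnames(sequences)[[3]]
  if (!is.null(nm) && !identical(nm, model$feature_names))
    stop("feature ordering differs from training")
  X0 <- sequences[, 1, , drop = TRUE]; X1 <- sequences[, 2, , drop = TRUE]
  if (is.null(dim(X0))) { X0 <- matrix(X0, ncol = d); X1 <- matrix(X1, ncol = d) }
  z <- ae_forward(model$params, X0, X1, model$spec$hidden_units)$z
  out <- as.data.frame(z)
  names(out) <- paste0("deep_", seq_len(ncol(z)))
  set_provenance(out, names(out), "deep")
}

#' Reconstruction mean squared error of the autoencoder
#' @param model a fitted `niv_autoencoder`.
#' @param sequences an `n x 2 x d` array.
#' @return mean squared reconstruction error over all cells.
#' @export
reconstruction_mse <- function(model, sequences) {
  d <- length(model$feature_names)
  X0 <- sequences[, 1, , drop = TRUE]; X1 <- sequences[, 2, , drop = TRUE]
  if (is.null(dim(X0))) { X0 <- matrix(X0, ncol = d); X1 <- matrix(X1, ncol = d) }
  ae_forward(model$params, X0, X1, model$spec$hidden_units)$loss
}
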