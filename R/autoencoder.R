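#' Autoencoder architecture and training specification
#'
#' A symmetric autoencoder: the encoder maps `input_dim` through the strictly
#' decreasing `hidden_dims` to `code_dim`, the decoder mirrors it back to
#' `input_dim`. Every layer uses a sigmoid activation, so codes lie in (0, 1).
#' Training minimises the summed squared reconstruction error over all rows
#' with full-batch Adam.
#'
#' @param input_dim width of the input feature vectors.
#' @param hidden_dims integer vector of encoder hidden widths (decoder
#'   mirrors them); default 512.
#' @param code_dim width of the code layer; default 128.
#' @param epochs number of full-batch gradient steps; default 200.
#' @param learning_rate Adam step size; default 1e-3.
#' @param seed integer seed for weight initialisation.
#' @return an `autoencoder_spec` list.
#' @export
autoencoder_spec <- function(input_dim, hidden_dims = 512, code_dim = 128,
                             epochs = 200, learning_rate = 1e-3, seed = 1L) {
  stopifnot(code_dim < input_dim, epochs >= 1, learning_rate > 0)
  if (length(hidden_dims) > 0) {
    # encoder-side widths must decrease towards the code; the first hidden
    # layer may be overcomplete (wider than the input)
    stopifnot(all(diff(c(hidden_dims, code_dim)) < 0))
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 code_dim = as.integer(code_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "autoencoder_spec")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Glorot-uniform initialisation for a stack of affine layers.
init_layers <- function(dims, seed) {
  set.seed(seed)
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim),
                    fan_in, fan_out),
         b = numeric(fan_out))
  })
}

# Forward pass through sigmoid layers; returns list of activations
# (activations[[1]] is the input).
mlp_forward <- function(x, layers) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- x
  for (l in seq_along(layers)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- sigmoid(z)
  }
  acts
}

adam_init <- function(layers) {
  lapply(layers, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      mk <- paste0("m", nm); vk <- paste0("v", nm)
      state[[l]][[mk]] <- beta1 * state[[l]][[mk]] + (1 - beta1) * g
      state[[l]][[vk]] <- beta2 * state[[l]][[vk]] + (1 - beta2) * g^2
      mhat <- state[[l]][[mk]] / (1 - beta1^t)
      vhat <- state[[l]][[vk]] / (1 - beta2^t)
      layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

#' Train an autoencoder on node feature vectors
#'
#' @param x numeric feature matrix, one node per row; row names carried into
#'   the code matrix.
#' @param spec an [autoencoder_spec()]; its `input_dim` must match `ncol(x)`.
#' @return an object of class `mda_autoencoder` with elements `layers`
#'   (trained weights), `spec`, `codes` (nodes x code_dim embedding matrix),
#'   `loss` (per-epoch summed squared reconstruction error), and
#'   `n_encoder_layers`.
#' @export
train_autoencoder <- function(x, spec) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (ncol(x) != spec$input_dim) {
    stop("feature width ", ncol(x), " does not match spec input_dim ",
         spec$input_dim, call. = FALSE)
  }
  dims <- c(spec$input_dim, spec$hidden_dims, spec$code_dim,
            rev(spec$hidden_dims), spec$input_dim)
  layers <- init_layers(dims, spec$seed)
  n_enc <- length(spec$hidden_dims) + 1L
  state <- adam_init(layers)
  loss <- numeric(spec$epochs)
  for (epoch in seq_len(spec$epochs)) {
    acts <- mlp_forward(x, layers)
    recon <- acts[[length(acts)]]
    resid <- recon - x
    loss[epoch] <- sum(resid^2)
    if (!is.finite(loss[epoch])) {
      stop("autoencoder training diverged (non-finite loss at epoch ", epoch,
           "); lower the learning rate", call. = FALSE)
    }
    grads <- vector("list", length(layers))
    d_act <- 2 * resid
    for (l in rev(seq_along(layers))) {
      a_out <- acts[[l + 1L]]
      d_z <- d_act * a_out * (1 - a_out)
      grads[[l]] <- list(W = crossprod(acts[[l]], d_z), b = colSums(d_z))
      if (l > 1L) d_act <- d_z %*% t(layers[[l]]$W)
    }
    upd <- adam_step(layers, grads, state, spec$learning_rate, epoch)
    layers <- upd$layers
    state <- upd$state
  }
  model <- structure(list(layers = layers, spec = spec,
                          n_encoder_layers = n_enc, loss = loss),
                     class = "mda_autoencoder")
  model$codes <- encode(model, x)
  model
}

#' Encode feature vectors to their low-dimensional codes
#'
#' @param model a trained [train_autoencoder()] object.
#' @param x feature matrix with `ncol(x) == input_dim`.
#' @return codes matrix, nodes x code_dim, values in (0, 1).
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "mda_autoencoder"))
  if (ncol(x) != model$spec$input_dim) {
    stop("input width does not match trained input_dim", call. = FALSE)
  }
  enc <- model$layers[seq_len(model$n_encoder_layers)]
  acts <- mlp_forward(x, enc)
  out <- acts[[length(acts)]]
  rownames(out) <- rownames(x)
  out
}

#' Decode codes back to reconstructions
#'
#' @param model a trained [train_autoencoder()] object.
#' @param y codes matrix with `ncol(y) == code_dim`.
#' @return reconstruction matrix, nodes x input_dim.
#' @export
decode <- function(model, y) {
  stopifnot(inherits(model, "mda_autoencoder"))
  if (ncol(y) != model$spec$code_dim) {
    stop("code width does not match trained code_dim", call. = FALSE)
  }
  dec <- model$layers[-seq_len(model$n_encoder_layers)]
  acts <- mlp_forward(y, dec)
  out <- acts[[length(acts)]]
  rownames(out) <- rownames(y)
  out
}

#' @export
print.mda_autoencoder <- function(x, ...) {
  s <- x$spec
  cat("<mda_autoencoder> ", s$input_dim, " -> ",
      paste(c(s$hidden_dims, s$code_dim), collapse = " -> "),
      " (mirrored decoder); final loss ",
      format(x$loss[length(x$loss)], digits = 6), "\n", sep = "")
  invisible(x)
}
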