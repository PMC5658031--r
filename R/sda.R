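# Stacked denoising autoencoder with tied weights: sigmoid encoding, affine
# decoding, greedy layer-wise denoising pretraining and supervised
# fine-tuning under a coordinate-RMSD objective.

#' Elementwise logistic sigmoid
#' @param x Numeric.
#' @return `1 / (1 + exp(-x))`, same shape; saturates gracefully.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

new_sda_layer <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out), b_prime = numeric(n_in))
}

#' Hidden-layer widths from decrease ratios
#'
#' Each hidden layer is a fixed fraction of the previous width:
#' `h_k = floor(ratio_k * h_(k-1))`, starting from the input dimension.
#' The defaults 0.9, 0.8, 0.7 give three progressively narrower layers.
#'
#' @param input_dim Input width (`13 * L` for an `L`-residue target).
#' @param ratios Numeric vector of per-layer decrease ratios in `(0, 1)`.
#' @return Integer vector of hidden widths.
#' @export
hidden_widths <- function(input_dim, ratios = c(0.9, 0.8, 0.7)) {
  if (any(ratios <= 0 | ratios >= 1)) stop("ratios must lie in (0, 1)")
  w <- integer(length(ratios)); prev <- input_dim
  for (k in seq_along(ratios)) { w[k] <- as.integer(ratios[k] * prev); prev <- w[k] }
  if (any(w < 1)) stop("degenerate architecture: a hidden width fell below 1")
  w
}

#' Construct an untrained stacked autoencoder model
#'
#' Tied-weight layers: each layer stores `W` (n_in x n_out), a hidden bias
#' `b` and a reconstruction bias `b_prime`; decoding always uses `t(W)`.
#' Weights are initialized uniformly in `+/- sqrt(6 / (n_in + n_out))` under
#' the given seed.
#'
#' @param input_dim Input width.
#' @param ratios Hidden decrease ratios (see [hidden_widths()]).
#' @param seed Integer RNG seed for initialization.
#' @return An object of class `sda_model`.
#' @export
new_sda_model <- function(input_dim, ratios = c(0.9, 0.8, 0.7), seed = 1) {
  widths <- hidden_widths(input_dim, ratios)
  layers <- with_seed(seed, {
    dims <- c(input_dim, widths)
    lapply(seq_along(widths), function(k) new_sda_layer(dims[k], dims[k + 1]))
  })
  structure(list(layers = layers, input_dim = input_dim, widths = widths,
                 ratios = ratios, scale = NULL, seed = seed,
                 centroid = NULL, reference = NULL,
                 training_log = tibble::tibble(phase = character(),
                                               layer = integer(),
                                               epoch = integer(),
                                               loss = numeric())),
            class = "sda_model")
}

#' @export
print.sda_model <- function(x, ...) {
  cat(sprintf("<sda_model> input_dim %d -> hidden %s (tied weights)\n",
              x$input_dim, paste(x$widths, collapse = " -> ")))
  if (nrow(x$training_log))
    cat(sprintf("  trained: %d logged epochs, final loss %.6g\n",
                nrow(x$training_log), utils::tail(x$training_log$loss, 1)))
  invisible(x)
}

check_layer_input <- function(x, n_in, what) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != n_in)
    stop(what, ": dimension mismatch (got ", ncol(X), ", expected ", n_in, ")")
  X
}

#' Encode through one layer
#' @param x Input vector (length `n_in`) or matrix with such rows.
#' @param layer An SDA layer (`W`, `b`, `b_prime`).
#' @return `sigmoid(x W + b)`, values in `(0, 1)`.
#' @export
encode_layer <- function(x, layer) {
  X <- check_layer_input(x, nrow(layer$W), "encode_layer")
  Y <- sigmoid(sweep(X %*% layer$W, 2, layer$b, `+`))
  if (is.matrix(x)) Y else as.vector(Y)
}

#' Decode through one layer (tied weights)
#'
#' Affine map `z = t(W) y + b_prime` using the transpose of the encoding
#' matrix; no output nonlinearity.  An optional clamp restricts the result to
#' `[0, 1]` as a post-processing step.
#'
#' @param y Hidden vector (length `n_out`) or matrix with such rows.
#' @param layer An SDA layer.
#' @param clamp01 Clamp output into `[0, 1]`? Default `FALSE`.
#' @return Reconstruction of the layer input.
#' @export
decode_layer <- function(y, layer, clamp01 = FALSE) {
  Y <- check_layer_input(y, ncol(layer$W), "decode_layer")
  Z <- sweep(tcrossprod(Y, layer$W), 2, layer$b_prime, `+`)
  if (clamp01) Z <- pmin(pmax(Z, 0), 1)
  if (is.matrix(y)) Z else as.vector(Z)
}

# Forward pass keeping all activations (for backprop).
sda_forward_cache <- function(model, X) {
  K <- length(model$layers)
  H <- vector("list", K + 1); H[[1]] <- X
  for (k in seq_len(K))
    H[[k + 1]] <- sigmoid(sweep(H[[k]] %*% model$layers[[k]]$W, 2,
                                model$layers[[k]]$b, `+`))
  D <- vector("list", K + 1); D[[K + 1]] <- H[[K + 1]]
  for (k in rev(seq_len(K)))
    D[[k]] <- sweep(tcrossprod(D[[k + 1]], model$layers[[k]]$W), 2,
                    model$layers[[k]]$b_prime, `+`)
  list(H = H, D = D, output = D[[1]])
}

#' Full forward pass through the mirrored stack
#'
#' Encodes through all layers in order, then decodes back through them in
#' reverse with tied weights; output length equals input length.
#'
#' @param model An `sda_model`.
#' @param x Feature vector of length `input_dim`, or a matrix with such rows.
#' @param clamp01 Clamp the final output into `[0, 1]`?
#' @return Reconstruction, same shape as `x`.
#' @export
sda_forward <- function(model, x, clamp01 = FALSE) {
  X <- check_layer_input(x, model$input_dim, "sda_forward")
  out <- sda_forward_cache(model, X)$output
  if (clamp01) out <- pmin(pmax(out, 0), 1)
  if (is.matrix(x)) out else as.vector(out)
}

#' Coordinate RMSD loss between feature vectors
#'
#' RMSD over the included coordinate channels only: residue-type channels and
#' zero-filled vacant positions are excluded, and `n` counts atoms (triples of
#' channels), not channels.  In normalized units this equals the Angstrom
#' RMSD divided by the scale's compression ratio `N`.
#'
#' @param pred,label Feature vectors of equal length.
#' @param include Integer indices of the included coordinate channels
#'   (a multiple of 3 of them); defaults to all coordinate channels.
#' @return Non-negative loss (normalized units).
#' @export
rmsd_loss <- function(pred, label, include = NULL) {
  if (length(pred) != length(label)) stop("pred and label differ in length")
  include <- include %||% setdiff(seq_along(pred),
                                  residue_channel_idx(length(pred) %/% 13))
  if (!length(include)) stop("empty inclusion set")
  n_atoms <- length(include) / 3
  sqrt(sum((pred[include] - label[include])^2) / n_atoms)
}

# Batch mean RMSD loss and its gradient wrt predictions.
batch_rmsd_loss <- function(P, Y, include) {
  n_atoms <- length(include) / 3
  E <- P[, include, drop = FALSE] - Y[, include, drop = FALSE]
  per <- sqrt(rowSums(E^2) / n_atoms)
  G <- matrix(0, nrow(P), ncol(P))
  nz <- per > 0
  if (any(nz))
    G[nz, include] <- E[nz, , drop = FALSE] /
      (per[nz] * n_atoms * nrow(P))
  list(loss = mean(per), grad = G)
}

# Backpropagate dL/d(output) through the mirrored tied-weight stack.
# Returns per-layer gradients (dW, db, db_prime).
sda_backprop <- function(model, cache, Gout) {
  K <- length(model$layers)
  grads <- lapply(model$layers, function(l)
    list(dW = matrix(0, nrow(l$W), ncol(l$W)),
         db = numeric(length(l$b)), db_prime = numeric(length(l$b_prime))))
  # decode path: D[[k]] = D[[k+1]] %*% t(W_k) + b'_k
  G <- Gout                                    # dL/dD[[1]]
  for (k in seq_len(K)) {
    grads[[k]]$db_prime <- colSums(G)
    grads[[k]]$dW <- grads[[k]]$dW + crossprod(G, cache$D[[k + 1]])
    G <- G %*% model$layers[[k]]$W             # dL/dD[[k+1]]
  }
  # encode path: H[[k+1]] = sigmoid(H[[k]] %*% W_k + b_k); dL/dH[[K+1]] = G
  for (k in rev(seq_len(K))) {
    A <- cache$H[[k + 1]]
    delta <- G * A * (1 - A)
    grads[[k]]$db <- colSums(delta)
    grads[[k]]$dW <- grads[[k]]$dW + crossprod(cache$H[[k]], delta)
    if (k > 1) G <- tcrossprod(delta, model$layers[[k]]$W)
  }
  grads
}

# Single gradient evaluation of the fine-tuning objective on a batch; used by
# finetune() and by the finite-difference gradient checks.
sda_gradients <- function(model, X, Y, include) {
  cache <- sda_forward_cache(model, X)
  bl <- batch_rmsd_loss(cache$output, Y, include)
  list(loss = bl$loss, grads = sda_backprop(model, cache, bl$grad))
}

apply_grads <- function(model, grads, lr) {
  for (k in seq_along(model$layers)) {
    model$layers[[k]]$W <- model$layers[[k]]$W - lr * grads[[k]]$dW
    model$layers[[k]]$b <- model$layers[[k]]$b - lr * grads[[k]]$db
    model$layers[[k]]$b_prime <- model$layers[[k]]$b_prime - lr * grads[[k]]$db_prime
  }
  model
}

log_epoch <- function(model, phase, layer, epoch, loss) {
  model$training_log <- rbind(model$training_log,
                              tibble::tibble(phase = phase, layer = layer,
                                             epoch = epoch, loss = loss))
  model
}

#' Greedy layer-wise denoising pretraining
#'
#' Each layer in turn is trained as a one-layer denoising autoencoder: it
#' reconstructs its clean input from a copy whose entries were masked to zero
#' with probability `mask_fraction`, under a squared-error objective and
#' mini-batch gradient descent with tied weights.  Deeper layers consume the
#' previous layer's clean encodings.  At the first layer the residue-type
#' channels are never corrupted.
#'
#' @param model An `sda_model`.
#' @param data Matrix of training feature rows (`input_dim` columns).
#' @param epochs Epochs per layer (0 leaves the model unchanged).
#' @param learning_rate Step size (default 0.05).
#' @param mask_fraction Corruption probability in `[0, 1]`.
#' @param seed Integer RNG seed (shuffling and masking).
#' @param batch_size Mini-batch size.
#' @return The updated model with per-layer losses appended to the training
#'   log.
#' @export
pretrain_layerwise <- function(model, data, epochs = 100, learning_rate = 0.05,
                               mask_fraction = 0.3, seed = 1, batch_size = 20) {
  data <- check_layer_input(data, model$input_dim, "pretrain_layerwise")
  if (epochs == 0) return(model)
  if (nrow(data) < 2)
    message("pretrain_layerwise: training on a single data row (degenerate)")
  with_seed(seed, {
    A <- data
    is_feature_layer <- model$input_dim %% 13 == 0
    for (k in seq_along(model$layers)) {
      layer <- model$layers[[k]]
      protect <- if (k == 1 && is_feature_layer)
        residue_channel_idx(model$input_dim %/% 13) else integer(0)
      maskable <- setdiff(seq_len(ncol(A)), protect)
      n <- nrow(A)
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0; nb <- 0
        for (start in seq(1, n, by = batch_size)) {
          rows <- ord[start:min(start + batch_size - 1, n)]
          Xc <- A[rows, , drop = FALSE]
          Xn <- Xc
          if (mask_fraction > 0) {
            m <- matrix(runif(length(rows) * length(maskable)) < mask_fraction,
                        length(rows), length(maskable))
            Xn[, maskable][m] <- 0
          }
          Yh <- sigmoid(sweep(Xn %*% layer$W, 2, layer$b, `+`))
          Z <- sweep(tcrossprod(Yh, layer$W), 2, layer$b_prime, `+`)
          G <- 2 * (Z - Xc) / length(Z)
          delta <- (G %*% layer$W) * Yh * (1 - Yh)
          layer$W <- layer$W - learning_rate *
            (crossprod(G, Yh) + crossprod(Xn, delta))
          layer$b <- layer$b - learning_rate * colSums(delta)
          layer$b_prime <- layer$b_prime - learning_rate * colSums(G)
          ep_loss <- ep_loss + mean((Z - Xc)^2); nb <- nb + 1
        }
        model <- log_epoch(model, "pretrain", k, ep, ep_loss / nb)
      }
      model$layers[[k]] <- layer
      A <- sigmoid(sweep(A %*% layer$W, 2, layer$b, `+`))   # clean encoding
    }
    model
  })
}

#' Supervised fine-tuning under the coordinate-RMSD objective
#'
#' End-to-end mini-batch gradient descent on the mean per-sample
#' [rmsd_loss()] between `sda_forward(x)` and the label (the template native
#' coordinates).  Batch order is reshuffled deterministically per seed each
#' epoch.  Inputs are used uncorrupted unless `corrupt_fraction > 0`.
#'
#' @param model An `sda_model`.
#' @param inputs,labels Matrices with one feature row per decoy; equal
#'   dimensions.
#' @param epochs Number of epochs (default 300).
#' @param learning_rate Step size (default 0.01).
#' @param batch_size Mini-batch size (default 20).
#' @param seed Integer RNG seed.
#' @param include Coordinate channels entering the loss (see [rmsd_loss()]).
#' @param corrupt_fraction Optional masking probability applied to inputs
#'   each epoch (default 0 = off).
#' @param lr_decay,lr_decay_every Step-decay schedule: the learning rate is
#'   multiplied by `lr_decay` every `lr_decay_every` epochs.  The RMSD
#'   objective has a gradient of near-constant magnitude close to its
#'   minimum, so constant-step SGD orbits the optimum at a distance
#'   proportional to the step size; diminishing steps are required for
#'   convergence.  Set `lr_decay = 1` for a constant rate.
#' @return The updated model; per-epoch mean losses are appended to the
#'   training log.
#' @export
finetune <- function(model, inputs, labels, epochs = 300, learning_rate = 0.01,
                     batch_size = 20, seed = 1, include = NULL,
                     corrupt_fraction = 0, lr_decay = 0.5,
                     lr_decay_every = 50) {
  X <- check_layer_input(inputs, model$input_dim, "finetune")
  Y <- check_layer_input(labels, model$input_dim, "finetune labels")
  if (nrow(X) != nrow(Y)) stop("inputs and labels differ in row count")
  include <- include %||% setdiff(seq_len(model$input_dim),
                                  residue_channel_idx(model$input_dim %/% 13))
  with_seed(seed, {
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      lr_ep <- learning_rate * lr_decay^((ep - 1) %/% lr_decay_every)
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1, n)]
        Xb <- X[rows, , drop = FALSE]
        if (corrupt_fraction > 0) {
          L <- model$input_dim %/% 13
          maskable <- setdiff(seq_len(ncol(Xb)), residue_channel_idx(L))
          m <- matrix(runif(length(rows) * length(maskable)) < corrupt_fraction,
                      length(rows), length(maskable))
          Xb[, maskable][m] <- 0
        }
        g <- sda_gradients(model, Xb, Y[rows, , drop = FALSE], include)
        if (!is.finite(g$loss))
          stop("finetune: non-finite loss at epoch ", ep,
               " (diverged; lower the learning rate)")
        model <- apply_grads(model, g$grads, lr_ep)
        ep_loss <- ep_loss + g$loss; nb <- nb + 1
      }
      model <- log_epoch(model, "finetune", NA_integer_, ep, ep_loss / nb)
    }
    model
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a versioned RDS container holding layer shapes and
#' parameters, the frozen normalization scale, seeds and the training log.
#' Loading validates the layer shape chain and rejects inconsistent files.
#'
#' @param model An `sda_model`.
#' @param path Checkpoint file path.
#' @return `save_sda` invisibly returns `path`; `load_sda` returns the model.
#' @export
save_sda <- function(model, path) {
  stopifnot(inherits(model, "sda_model"))
  saveRDS(list(format = "prsda_sda_checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_sda
#' @export
load_sda <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "prsda_sda_checkpoint"))
    stop("not an SDA checkpoint file: ", path)
  model <- obj$model
  dims <- c(model$input_dim, model$widths)
  for (k in seq_along(model$layers)) {
    l <- model$layers[[k]]
    if (!identical(dim(l$W), c(as.integer(dims[k]), as.integer(dims[k + 1]))) ||
        length(l$b) != dims[k + 1] || length(l$b_prime) != dims[k])
      stop("shape-inconsistent checkpoint: layer ", k)
  }
  model
}
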