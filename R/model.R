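#' Model configuration
#'
#' Architecture of the displacement-prediction network. Per-point local
#' features come from a k-NN graph convolution: each point's `k_feat` nearest
#' neighbors are lifted to edge features, passed through a shared multilayer
#' perceptron (widths `encoder_widths`, ReLU), and mean-aggregated over the
#' neighbors (the graph convolution). A global descriptor is the max-pool of the per-point features
#' over the whole set. The displacement head is an MLP (`decoder_widths`,
#' ReLU on hidden layers, linear 3-wide output) consuming the concatenation
#' of per-point and global features; its output is an *additive* displacement
#' — the residual connection is realized by adding the prediction to the
#' input coordinates, so a zero-weight head is the identity denoiser.
#'
#' `edge_features = "relative"` (default) uses neighbor-minus-point offsets
#' only, which makes the whole network exactly translation-covariant;
#' `"dgcnn"` appends the absolute point coordinates, the DGCNN concat
#' convention, trading that exact covariance for positional context.
#'
#' @param encoder_widths Integer vector starting at 3 (the point dimension);
#'   default `c(3, 256, 512, 1024, 2048)`.
#' @param decoder_widths Hidden-to-output widths of the head, ending in 3;
#'   default `c(1024, 512, 256, 3)` (the head input is twice the final
#'   encoder width because of the global concat).
#' @param k_feat k-NN neighborhood size for feature extraction (default 16).
#' @param dropout Dropout rate on the head's hidden layers, `[0, 1)`.
#' @param weight_decay L2 regularization strength used by the optimizer.
#' @param edge_features `"relative"` or `"dgcnn"`.
#' @param seed Parameter-initialization seed.
#' @return A `model_config` list.
#' @export
model_config <- function(encoder_widths = c(3L, 256L, 512L, 1024L, 2048L),
                         decoder_widths = c(1024L, 512L, 256L, 3L),
                         k_feat = 16L, dropout = 0.1, weight_decay = 1e-4,
                         edge_features = c("relative", "dgcnn"), seed = 1L) {
  encoder_widths <- as.integer(encoder_widths)
  decoder_widths <- as.integer(decoder_widths)
  if (length(encoder_widths) < 2L || encoder_widths[1] != 3L) {
    stopf("encoder_widths must start at 3 (the point dimension)")
  }
  if (utils::tail(decoder_widths, 1L) != 3L) stopf("decoder_widths must end in 3")
  structure(list(encoder_widths = encoder_widths,
                 decoder_widths = decoder_widths,
                 k_feat = check_count(k_feat, "k_feat"),
                 dropout = check_scalar(dropout, "dropout", 0, 1 - 1e-12),
                 weight_decay = check_scalar(weight_decay, "weight_decay", lower = 0),
                 edge_features = match.arg(edge_features),
                 seed = as.integer(seed)),
            class = "model_config")
}

# Desk-scale config used throughout the test fixtures.
desk_model_config <- function(seed = 1L, ...) {
  model_config(encoder_widths = c(3L, 64L, 128L, 256L),
               decoder_widths = c(128L, 64L, 3L),
               dropout = 0, weight_decay = 0, seed = seed, ...)
}

#' Initialize a displacement model
#'
#' Allocates the network parameters (He-initialized weights, zero biases),
#' deterministically under `config$seed`.
#'
#' @param config A [model_config()].
#' @return A `displacement_model` (config + parameter list).
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  in_dim <- if (config$edge_features == "relative") 3L else 6L
  enc_in <- c(in_dim, config$encoder_widths[-c(1L, length(config$encoder_widths))])
  enc_out <- config$encoder_widths[-1L]
  w_feat <- utils::tail(config$encoder_widths, 1L)
  dec_in <- c(2L * w_feat, utils::head(config$decoder_widths, -1L))
  dec_out <- config$decoder_widths
  params <- withr::with_seed(config$seed, {
    make_layer <- function(din, dout) {
      list(W = matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
           b = numeric(dout))
    }
    p <- list(encoder = purrr::map2(enc_in, enc_out, make_layer),
              decoder = purrr::map2(dec_in, dec_out, make_layer))
    # Zero-initialized output layer: the residual head starts as the identity
    # denoiser and learns displacements from there, which stabilizes the
    # early epochs (the loss starts at the variance of the target rather
    # than at the variance of a random field).
    nl <- length(p$decoder)
    p$decoder[[nl]]$W[] <- 0
    p$decoder[[nl]]$b[] <- 0
    p
  })
  structure(list(config = config, params = params), class = "displacement_model")
}

#' @export
print.displacement_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(purrr::map_dbl(c(x$params$encoder, x$params$decoder),
                           ~ length(.x$W) + length(.x$b)))
  cat(sprintf("<displacement_model> encoder %s | decoder %s | k_feat %d | %s edges | %s params\n",
              paste(cfg$encoder_widths, collapse = "-"),
              paste(cfg$decoder_widths, collapse = "-"),
              cfg$k_feat, cfg$edge_features, format(np, big.mark = ",")))
  invisible(x)
}

#' k-nearest-neighbor graph
#'
#' For each point, the indices of its `k_feat` nearest *other* points
#' (self excluded), Euclidean distance, ties broken by lower index.
#'
#' @param points n x 3 matrix or [point_cloud()].
#' @param k_feat Neighborhood size, `< n`.
#' @return n x k_feat integer index matrix.
#' @export
knn_graph <- function(points, k_feat) {
  pts <- if (is_point_cloud(points)) as_matrix(points) else points
  n <- nrow(pts)
  if (n < 2L) stopf("need at least 2 points for a k-NN graph")
  k_feat <- check_count(k_feat, "k_feat")
  if (k_feat >= n) stopf("k_feat = %d must be < n = %d", k_feat, n)
  knn_brute(pts, pts, k_feat, exclude = seq_len(n))
}

# Edge-feature matrix, (n*k) x d, neighbor-major blocks of n rows.
edge_input <- function(X, nb, type) {
  n <- nrow(X); k <- ncol(nb)
  xi <- X[rep.int(seq_len(n), k), , drop = FALSE]
  rel <- X[as.vector(nb), , drop = FALSE] - xi
  if (type == "relative") rel else cbind(rel, xi)
}

# Full forward pass. Returns prediction plus (optionally) every intermediate
# needed by the hand-derived backward pass.
model_forward <- function(model, X, training = FALSE, dropout_seed = NULL,
                          keep_cache = FALSE) {
  cfg <- model$config
  n <- nrow(X)
  if (n <= cfg$k_feat) stopf("need more than k_feat = %d points, got %d", cfg$k_feat, n)
  nb <- knn_graph(X, cfg$k_feat)
  E <- edge_input(X, nb, cfg$edge_features)
  acts <- list(E)
  A <- E
  for (layer in model$params$encoder) {
    A <- pmax(sweep(A %*% layer$W, 2, layer$b, "+"), 0)
    acts[[length(acts) + 1L]] <- A
  }
  W <- ncol(A)
  # mean aggregation over the k neighbor edges of each point (GCN-style);
  # the global descriptor below stays a max-pool over points
  Fm <- A[seq_len(n), , drop = FALSE]
  if (cfg$k_feat > 1L) {
    for (j in 2:cfg$k_feat) {
      Fm <- Fm + A[((j - 1L) * n + 1L):(j * n), , drop = FALSE]
    }
  }
  Fm <- Fm / cfg$k_feat
  g <- apply(Fm, 2, max)
  gi <- apply(Fm, 2, which.max)
  D <- cbind(Fm, matrix(g, n, W, byrow = TRUE))
  dec_acts <- list(D)
  masks <- list()
  A <- D
  nd <- length(model$params$decoder)
  for (l in seq_len(nd)) {
    layer <- model$params$decoder[[l]]
    Z <- sweep(A %*% layer$W, 2, layer$b, "+")
    if (l < nd) {
      A <- pmax(Z, 0)
      if (training && cfg$dropout > 0) {
        mask <- withr::with_seed(mix_seed(dropout_seed %||% 0L, l),
                                 matrix(runif(length(A)) >= cfg$dropout, nrow(A)) /
                                   (1 - cfg$dropout))
        A <- A * mask
        masks[[l]] <- mask
      }
    } else {
      A <- Z
    }
    dec_acts[[l + 1L]] <- A
  }
  pred <- A
  if (!all(is.finite(pred))) stopf("non-finite activations in forward pass")
  out <- list(pred = pred, point_features = Fm, global = g)
  if (keep_cache) {
    out$cache <- list(n = n, W = W, k = cfg$k_feat, acts = acts,
                      gi = gi, dec_acts = dec_acts, masks = masks)
  }
  out
}

#' Per-point and global features of a point set
#'
#' Runs the feature-extraction half of the network: k-NN edge features,
#' shared MLP, neighbor mean aggregation (per-point features) and point
#' max-pool (global descriptor). Deterministic given the model parameters;
#' permutation-equivariant in the per-point features.
#'
#' @param points n x 3 matrix or [point_cloud()].
#' @param model A `displacement_model` from [init_model()].
#' @return List with `point_features` (n x W) and `global` (length-W vector).
#' @export
extract_features <- function(points, model) {
  stopifnot(inherits(model, "displacement_model"))
  X <- if (is_point_cloud(points)) as_matrix(points) else points
  fw <- model_forward(model, X, training = FALSE)
  fw[c("point_features", "global")]
}

#' Predict per-point displacement vectors
#'
#' The displacement field aligned index-wise with the input: adding it to the
#' input coordinates gives the denoised positions (the residual-output
#' convention). Evaluation mode — dropout disabled, bit-reproducible.
#'
#' This is a generic so test oracles (e.g. a model that returns the exact
#' training target) can stand in for a trained network in [denoise()].
#'
#' @param model A `displacement_model` or oracle model.
#' @param points n x 3 matrix or [point_cloud()], `n > k_feat`.
#' @param ... Unused.
#' @return An n x 3 matrix of displacements (class `displacement_field`).
#' @export
predict_displacements <- function(model, points, ...) {
  UseMethod("predict_displacements")
}

#' @export
predict_displacements.displacement_model <- function(model, points, ...) {
  X <- if (is_point_cloud(points)) as_matrix(points) else points
  fw <- model_forward(model, X, training = FALSE)
  structure(fw$pred, class = c("displacement_field", "matrix", "array"))
}

#' Oracle displacement model for testing
#'
#' Knows the base (singly-noisy) cloud and, fed any displaced version of it,
#' returns the exact regression target `-2 * (points - base)`. In
#' [denoise()]'s double mode with one realization this reproduces the
#' pseudo-clean cloud algebraically, which makes the Monte-Carlo averaging
#' behavior of the inference path checkable without any training.
#'
#' @param base The base `point_cloud` (or n x 3 matrix).
#' @return An `oracle_displacement_model`.
#' @export
oracle_displacement_model <- function(base) {
  X <- if (is_point_cloud(base)) as_matrix(base) else base
  structure(list(base = X), class = "oracle_displacement_model")
}

#' @export
predict_displacements.oracle_displacement_model <- function(model, points, ...) {
  X <- if (is_point_cloud(points)) as_matrix(points) else points
  if (!identical(dim(X), dim(model$base))) stopf("oracle base and input sizes differ")
  structure(-2 * (X - model$base), class = c("displacement_field", "matrix", "array"))
}

# ---- parameter flattening + checkpoints --------------------------------

flatten_params <- function(params) {
  unlist(purrr::map(c(params$encoder, params$decoder), ~ c(.x$W, .x$b)))
}

map_params <- function(a, b = NULL, f) {
  walk2 <- function(x, y) {
    purrr::map2(x, y, function(lx, ly) list(W = f(lx$W, ly$W), b = f(lx$b, ly$b)))
  }
  if (is.null(b)) b <- a
  list(encoder = walk2(a$encoder, b$encoder),
       decoder = walk2(a$decoder, b$decoder))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding a versioned list:
#' `format` (`"pcdenoise-checkpoint-1"`), the `model_config`, the parameter
#' list, and optionally the `train_config` and training history of the run
#' that produced it.
#'
#' @param model A `displacement_model` or a fit from [train_denoiser()].
#' @param path Destination file.
#' @param ... Extra fields to embed (e.g. `train_config`, `history`).
#' @return `path` invisibly; `read_checkpoint()` returns the stored fit or
#'   model.
#' @export
write_checkpoint <- function(model, path, ...) {
  obj <- if (inherits(model, "denoise_fit")) {
    list(format = "pcdenoise-checkpoint-1", model_config = model$model$config,
         params = model$model$params, train_config = model$config,
         history = model$history)
  } else {
    list(format = "pcdenoise-checkpoint-1", model_config = model$config,
         params = model$params, ...)
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "pcdenoise-checkpoint-1")) {
    stopf("not a pcdenoise checkpoint: %s", path)
  }
  model <- structure(list(config = obj$model_config, params = obj$params),
                     class = "displacement_model")
  if (!is.null(obj$train_config)) {
    structure(list(model = model, config = obj$train_config, history = obj$history),
              class = "denoise_fit")
  } else {
    model
  }
}

# Gradients of all parameters given d(loss)/d(pred). Mirrors model_forward:
# decoder MLP -> global-concat split -> neighbor un-pooling -> encoder MLP.
model_backward <- function(model, cache, dpred) {
  n <- cache$n; W <- cache$W; k <- cache$k
  dec <- model$params$decoder
  enc <- model$params$encoder
  nd <- length(dec)
  grads <- list(encoder = vector("list", length(enc)),
                decoder = vector("list", nd))
  dA <- dpred
  for (l in nd:1) {
    A_out <- cache$dec_acts[[l + 1L]]
    A_in <- cache$dec_acts[[l]]
    if (l < nd) {
      # A_out = mask * relu(Z); both dropout and ReLU zero A_out wherever
      # they block the gradient, so (A_out > 0) is the exact pass-through set.
      m <- if (length(cache$masks) >= l) cache$masks[[l]] else NULL
      dZ <- dA * (A_out > 0)
      if (!is.null(m)) dZ <- dZ * m
    } else {
      dZ <- dA
    }
    grads$decoder[[l]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, dec[[l]]$W)
  }
  dF <- dA[, seq_len(W), drop = FALSE]
  dg <- colSums(dA[, W + seq_len(W), drop = FALSE])
  ix <- cbind(cache$gi, seq_len(W))
  dF[ix] <- dF[ix] + dg
  # un-pool the neighbor mean: every edge row of a point shares its gradient
  dA <- dF[rep.int(seq_len(n), k), , drop = FALSE] / k
  for (l in length(enc):1) {
    A_out <- cache$acts[[l + 1L]]
    A_in <- cache$acts[[l]]
    dZ <- dA * (A_out > 0)
    grads$encoder[[l]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
    if (l > 1L) dA <- tcrossprod(dZ, enc[[l]]$W)
  }
  grads
}
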