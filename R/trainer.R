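#' Training configuration
#'
#' Defaults follow the published recipe: Adam at base learning rate 0.001
#' annealed by a cosine schedule to `eta_min`, 200 epochs, batches of 128
#' samples, Gaussian noise of level 0.1 (normalized units) for the double
#' noising, and loss weight `gamma = 5e-4`. A "sample" is a fixed-size point
#' set of `patch_points` points drawn from one of the dataset clouds, so
#' batches are rectangular tensors; clouds are recycled when the dataset has
#' fewer clouds than `batch_size`. `steps_per_epoch` forces a minimum number
#' of optimizer steps per epoch regardless of dataset size (useful for tiny
#' fixture datasets); the default 1 reproduces
#' `ceiling(n_clouds / batch_size)` batches per epoch.
#'
#' `preset = "desk"` switches every size-related default to the reduced
#' test-scale setting: widths 3-64-128-256 (decoder 128-64-3), batch 8,
#' 50 epochs, 256-point patches, 4 steps per epoch, base lr 3e-3 (the
#' shorter schedule takes a proportionally larger step size), and no
#' dropout/weight decay (a 200-step run on a small model underfits; extra
#' regularization only slows what little fitting there is).
#'
#' @param base_lr Initial learning rate.
#' @param eta_min Final learning rate of the cosine schedule.
#' @param epochs Number of epochs.
#' @param batch_size Samples per batch.
#' @param patch_points Points per sample.
#' @param steps_per_epoch Minimum optimizer steps per epoch.
#' @param sample_strategy How samples are drawn from clouds (see
#'   [sample_fixed()]); default `"patch"`, which preserves local density so
#'   the k-NN features match between training patches and full-cloud
#'   inference.
#' @param noise A [noise_spec()] for the injected noise M.
#' @param loss A [loss_config()].
#' @param model A [model_config()].
#' @param seed Master seed for batching, noise streams and dropout.
#' @param preset `NULL` or `"desk"`.
#' @return A `train_config` list.
#' @export
train_config <- function(base_lr = 1e-3, eta_min = 1e-5, epochs = 200L,
                         batch_size = 128L, patch_points = 2048L,
                         steps_per_epoch = 1L,
                         sample_strategy = c("patch", "random", "fps"),
                         noise = noise_spec(sigma = 0.1),
                         loss = loss_config(),
                         model = model_config(),
                         seed = 1L, preset = NULL) {
  if (identical(preset, "desk")) {
    cl <- match.call()
    if (is.null(cl$epochs)) epochs <- 50L
    if (is.null(cl$batch_size)) batch_size <- 8L
    if (is.null(cl$patch_points)) patch_points <- 256L
    if (is.null(cl$steps_per_epoch)) steps_per_epoch <- 4L
    if (is.null(cl$base_lr)) base_lr <- 3e-3
    if (is.null(cl$model)) model <- desk_model_config(seed = seed)
    if (is.null(cl$noise)) noise <- noise_spec(sigma = 0.02)
  }
  cfg <- list(base_lr = check_scalar(base_lr, "base_lr", lower = 1e-12),
              eta_min = check_scalar(eta_min, "eta_min", lower = 0),
              epochs = check_count(epochs, "epochs"),
              batch_size = check_count(batch_size, "batch_size"),
              patch_points = check_count(patch_points, "patch_points", min = 2L),
              steps_per_epoch = check_count(steps_per_epoch, "steps_per_epoch"),
              sample_strategy = match.arg(sample_strategy),
              noise = noise, loss = loss, model = model,
              seed = as.integer(seed))
  if (cfg$base_lr <= cfg$eta_min) stopf("base_lr must exceed eta_min")
  stopifnot(inherits(noise, "noise_spec"), inherits(loss, "loss_config"),
            inherits(model, "model_config"))
  structure(cfg, class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `eta_min + (base_lr - eta_min) * (1 + cos(pi * epoch / epochs)) / 2`,
#' the standard cosine annealing schedule: `base_lr` at epoch 0, `eta_min`
#' at the final epoch.
#'
#' @param epoch Epoch index from 0, `0 <= epoch <= epochs`.
#' @param config A [train_config()].
#' @return The learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, config) {
  stopifnot(inherits(config, "train_config"))
  if (any(epoch < 0 | epoch > config$epochs)) {
    stopf("epoch must be in [0, %d]", config$epochs)
  }
  config$eta_min + (config$base_lr - config$eta_min) *
    (1 + cos(pi * epoch / config$epochs)) / 2
}

#' Assemble the training batches of one epoch
#'
#' Shuffles the dataset deterministically from `(seed, epoch)`, recycles
#' clouds to fill `batch_size` slots per batch, and draws each sample as a
#' random fixed-size patch via [sample_fixed()]. Each batch is a list of
#' `point_cloud` patches of exactly `patch_points` points.
#'
#' @param dataset List of (noisy, normalized) `point_cloud`s.
#' @param config A [train_config()].
#' @param epoch Epoch index from 0.
#' @return List of batches; each batch is a list of `point_cloud`s.
#' @export
make_batches <- function(dataset, config, epoch = 0L) {
  stopifnot(inherits(config, "train_config"), length(dataset) >= 1L)
  small <- purrr::map_int(dataset, nrow) < config$patch_points
  if (any(small)) {
    stopf("cloud %d has fewer than patch_points = %d points",
          which(small)[1], config$patch_points)
  }
  n_batches <- max(config$steps_per_epoch,
                   ceiling(length(dataset) / config$batch_size))
  slots <- n_batches * config$batch_size
  order_idx <- withr::with_seed(mix_seed(config$seed, epoch, 7L),
                                sample.int(length(dataset)))
  cloud_idx <- rep_len(order_idx, slots)
  purrr::map(seq_len(n_batches), function(b) {
    purrr::map(seq_len(config$batch_size), function(s) {
      slot <- (b - 1L) * config$batch_size + s
      ci <- cloud_idx[slot]
      sample_fixed(dataset[[ci]], min(config$patch_points, nrow(dataset[[ci]])),
                   strategy = config$sample_strategy,
                   seed = mix_seed(config$seed, epoch, slot, ci))
    })
  })
}

# One Adam step over the nested parameter list; weight decay added to the
# gradient (classic L2 coupling).
adam_step <- function(params, grads, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd_layer <- function(p, g, m, v) {
    g$W <- g$W + wd * p$W  # biases are not decayed
    m$W <- beta1 * m$W + (1 - beta1) * g$W
    m$b <- beta1 * m$b + (1 - beta1) * g$b
    v$W <- beta2 * v$W + (1 - beta2) * g$W^2
    v$b <- beta2 * v$b + (1 - beta2) * g$b^2
    cor1 <- 1 - beta1^t; cor2 <- 1 - beta2^t
    p$W <- p$W - lr * (m$W / cor1) / (sqrt(v$W / cor2) + eps)
    p$b <- p$b - lr * (m$b / cor1) / (sqrt(v$b / cor2) + eps)
    list(p = p, m = m, v = v)
  }
  for (part in c("encoder", "decoder")) {
    for (l in seq_along(params[[part]])) {
      r <- upd_layer(params[[part]][[l]], grads[[part]][[l]],
                     state$m[[part]][[l]], state$v[[part]][[l]])
      params[[part]][[l]] <- r$p
      state$m[[part]][[l]] <- r$m
      state$v[[part]][[l]] <- r$v
    }
  }
  list(params = params, state = state)
}

zero_like <- function(params) {
  map_params(params, f = function(a, b) a * 0)
}

# Loss + parameter gradients for one sample (a normalized noisy patch).
sample_loss_grads <- function(model, patch, config, seed, with_grads = TRUE) {
  pair <- double_noise_pair(patch, config$noise, seed = seed)
  Xd <- as_matrix(pair$double)
  fw <- model_forward(model, Xd, training = with_grads,
                      dropout_seed = mix_seed(seed, 13L), keep_cache = with_grads)
  pred <- fw$pred
  n <- nrow(pred)
  target <- 2 * pair$d_dot
  res <- pred - target
  l_mse <- mean(rowSums(res * res))
  ptld <- as_matrix(pseudo_clean(pair))
  k_rep <- min(config$loss$k_rep, n)
  nb_idx <- pseudo_neighborhoods(ptld, as_matrix(pair$base), k_rep)
  den <- Xd + pred
  rep_res <- rep_max_sqdist(den, nb_idx, ptld)
  l_rep <- mean(rep_res$value)
  total <- l_mse + config$loss$gamma * l_rep
  out <- list(l_mse = l_mse, l_rep = l_rep, total = total)
  if (with_grads) {
    dpred <- 2 * res / n
    far <- ptld[nb_idx[cbind(seq_len(n), rep_res$argmax)], , drop = FALSE]
    dpred <- dpred + config$loss$gamma * 2 * (den - far) / n
    out$grads <- model_backward(model, fw$cache, dpred)
  }
  out
}

#' Train the displacement denoiser (unsupervised)
#'
#' The loop never sees clean coordinates: its only input is a list of noisy,
#' normalized clouds. Each epoch it re-draws the batches, builds a fresh
#' double-noise pair per sample (a new M every time, so the regression sees
#' the full noise distribution), runs the network on the double-noisy patch,
#' and takes one Adam step per batch on the combined objective at the
#' cosine-annealed learning rate. Fully reproducible from `config$seed`.
#'
#' @param dataset List of noisy `point_cloud`s in the normalized frame (a
#'   single cloud may be passed bare).
#' @param config A [train_config()].
#' @param verbose Print one line per `verbose` epochs (0 = silent).
#' @return A `denoise_fit`: list with `model` (trained `displacement_model`),
#'   `config`, and `history` (a tibble with one row per epoch: `epoch`, `lr`,
#'   `l_mse`, `l_rep`, `total`). Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
train_denoiser <- function(dataset, config = train_config(), verbose = 0L) {
  stopifnot(inherits(config, "train_config"))
  if (is_point_cloud(dataset)) dataset <- list(dataset)
  if (length(dataset) == 0L) stopf("empty training dataset")
  bad_frame <- !purrr::map_lgl(dataset, ~ pc_frame(.x) == "normalized")
  if (any(bad_frame)) {
    stopf("cloud %d is not in the normalized frame; run normalize_cloud() first",
          which(bad_frame)[1])
  }
  model <- init_model(config$model)
  state <- list(t = 0L, m = zero_like(model$params), v = zero_like(model$params))
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- cosine_lr(epoch, config)
    batches <- make_batches(dataset, config, epoch)
    ep_mse <- ep_rep <- ep_tot <- 0
    n_seen <- 0L
    for (b in seq_along(batches)) {
      batch <- batches[[b]]
      acc <- NULL
      b_mse <- b_rep <- b_tot <- 0
      for (s in seq_along(batch)) {
        sg <- sample_loss_grads(model, batch[[s]], config,
                                seed = mix_seed(config$seed, epoch, b, s))
        if (!is.finite(sg$total)) {
          stopf("non-finite loss in epoch %d, batch %d, sample %d", epoch, b, s)
        }
        b_mse <- b_mse + sg$l_mse; b_rep <- b_rep + sg$l_rep; b_tot <- b_tot + sg$total
        acc <- if (is.null(acc)) sg$grads else map_params(acc, sg$grads, `+`)
      }
      nb <- length(batch)
      acc <- map_params(acc, f = function(a, b) a / nb)
      upd <- adam_step(model$params, acc, state, lr, config$model$weight_decay)
      model$params <- upd$params
      state <- upd$state
      ep_mse <- ep_mse + b_mse; ep_rep <- ep_rep + b_rep; ep_tot <- ep_tot + b_tot
      n_seen <- n_seen + nb
    }
    hist[[epoch + 1L]] <- tibble::tibble(epoch = epoch, lr = lr,
                                         l_mse = ep_mse / n_seen,
                                         l_rep = ep_rep / n_seen,
                                         total = ep_tot / n_seen)
    if (verbose > 0 && (epoch %% verbose == 0 || epoch == config$epochs - 1L)) {
      message(sprintf("epoch %3d  lr %.2e  mse %.5g  rep %.5g  total %.5g",
                      epoch, lr, ep_mse / n_seen, ep_rep / n_seen, ep_tot / n_seen))
    }
  }
  structure(list(model = model, config = config,
                 history = dplyr::bind_rows(hist)),
            class = "denoise_fit")
}

#' @export
print.denoise_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<denoise_fit> %d epochs | final total loss %.5g (first %.5g)\n",
              nrow(h), h$total[nrow(h)], h$total[1]))
  print(x$model)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname train_denoiser
#' @param x A `denoise_fit`.
#' @param ... Unused.
#' @method tidy denoise_fit
#' @export
tidy.denoise_fit <- function(x, ...) x$history

#' @rdname train_denoiser
#' @method glance denoise_fit
#' @export
glance.denoise_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_total = h$total[nrow(h)],
                 final_l_mse = h$l_mse[nrow(h)],
                 final_l_rep = h$l_rep[nrow(h)],
                 first_total = h$total[1],
                 base_lr = x$config$base_lr,
                 sigma = x$config$noise$sigma,
                 gamma = x$config$loss$gamma)
}

#' Denoise a point cloud with a trained model
#'
#' Two inference protocols are available because the training input
#' distribution is double-noisy:
#' * `mode = "double"` (default): inject a fresh noise realization M (drawn
#'   from the training [noise_spec()]), predict displacements on the
#'   double-noisy cloud and form `double + prediction`; average this over
#'   `realizations` independent M draws. This matches the distribution the
#'   network was trained on; averaging shrinks the injected-noise residual
#'   like `1/sqrt(realizations)`.
#' * `mode = "direct_half"`: feed the noisy cloud itself and add *half* the
#'   predicted displacement (the doubling identity in reverse). No extra
#'   noise is injected, at the cost of a train/test input mismatch.
#'
#' @param fit A `denoise_fit`, `displacement_model`, or any object with a
#'   [predict_displacements()] method.
#' @param noisy A normalized-frame `point_cloud` with more than `k_feat`
#'   points.
#' @param mode `"double"` or `"direct_half"`.
#' @param realizations Number of M draws averaged in double mode.
#' @param seed Seed for the M draws.
#' @param noise Override of the injection [noise_spec()] (defaults to the
#'   fit's training spec).
#' @return A denoised `point_cloud`, order aligned with the input.
#' @export
denoise <- function(fit, noisy, mode = c("double", "direct_half"),
                    realizations = 1L, seed = 1L, noise = NULL) {
  mode <- match.arg(mode)
  stopifnot(is_point_cloud(noisy))
  model <- if (inherits(fit, "denoise_fit")) fit$model else fit
  spec <- noise %||% (if (inherits(fit, "denoise_fit")) fit$config$noise else noise_spec())
  realizations <- check_count(realizations, "realizations")
  X <- as_matrix(noisy)
  if (mode == "direct_half") {
    d <- predict_displacements(model, X)
    return(pc_replace_coords(noisy, X + d / 2))
  }
  acc <- matrix(0, nrow(X), 3L)
  for (r in seq_len(realizations)) {
    m <- draw_noise(nrow(X), spec, mix_seed(seed, r, 29L))
    Xd <- X + m
    d <- predict_displacements(model, Xd)
    acc <- acc + (Xd + d)
  }
  pc_replace_coords(noisy, acc / realizations)
}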