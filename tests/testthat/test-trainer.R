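# Tiny throwaway training configuration: seconds, not minutes.
tiny_train_config <- function(epochs = 2L, seed = 1L, ...) {
  train_config(epochs = epochs, batch_size = 2L, patch_points = 48L,
               steps_per_epoch = 1L,
               noise = noise_spec(sigma = 0.02),
               model = model_config(encoder_widths = c(3L, 8L, 12L),
                                    decoder_widths = c(8L, 3L), k_feat = 4L,
                                    dropout = 0, weight_decay = 0, seed = seed),
               seed = seed, ...)
}

test_that("cosine schedule hits its closed-form anchor points", {
  cfg <- train_config()
  expect_equal(cosine_lr(0, cfg), 0.001)
  expect_equal(cosine_lr(cfg$epochs, cfg), cfg$eta_min)
  expect_equal(cosine_lr(cfg$epochs / 2, cfg), (0.001 + cfg$eta_min) / 2)
  # monotone decreasing across the whole schedule
  lrs <- cosine_lr(0:cfg$epochs, cfg)
  expect_true(all(diff(lrs) < 0))
  expect_error(cosine_lr(cfg$epochs + 1, cfg), "epoch")
})

test_that("make_batches sizes, reproducibility, and epoch reshuffling", {
  dataset <- lapply(1:8, function(i) random_cloud(80, seed = i, frame = "normalized"))
  cfg <- train_config(batch_size = 4L, patch_points = 64L,
                      model = model_config(seed = 1), seed = 3)
  b <- make_batches(dataset, cfg, epoch = 0)
  expect_length(b, 2L)   # 8 clouds / batch 4
  expect_length(b[[1]], 4L)
  expect_true(all(vapply(b[[1]], nrow, integer(1)) == 64L))

  b2 <- make_batches(dataset, cfg, epoch = 0)
  expect_identical(lapply(b, function(x) lapply(x, as_matrix)),
                   lapply(b2, function(x) lapply(x, as_matrix)))

  b3 <- make_batches(dataset, cfg, epoch = 1)
  expect_false(identical(lapply(b, function(x) lapply(x, as_matrix)),
                         lapply(b3, function(x) lapply(x, as_matrix))))

  small <- list(random_cloud(10, seed = 9, frame = "normalized"))
  expect_error(make_batches(small, cfg), "patch_points")
})

test_that("shuffling permutes 256 items differently across epochs", {
  dataset <- lapply(1:256, function(i) random_cloud(4, seed = i, frame = "normalized"))
  cfg <- train_config(batch_size = 128L, patch_points = 4L,
                      model = model_config(seed = 1), seed = 5)
  first_pts <- function(batches) {
    unlist(lapply(batches, function(b) vapply(b, function(p) p$x[1], double(1))))
  }
  e0 <- first_pts(make_batches(dataset, cfg, epoch = 0))
  e1 <- first_pts(make_batches(dataset, cfg, epoch = 1))
  expect_length(e0, 256L)
  expect_false(identical(e0, e1))
  expect_setequal(round(e0, 12), round(e1, 12))
})

test_that("zero learning rate leaves parameters untouched", {
  noisy <- noisy_sphere(n = 100, seed = 21)$noisy
  cfg <- tiny_train_config(epochs = 1L)
  cfg$base_lr <- 1e-300  # effectively zero but satisfies base_lr > eta_min
  cfg$eta_min <- 0
  fit <- train_denoiser(noisy, cfg)
  expect_equal(nrow(fit$history), 1L)
  expect_equal(fit$model$params, init_model(cfg$model)$params,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("training is reproducible and records the exact lr schedule", {
  noisy <- noisy_sphere(n = 100, seed = 22)$noisy
  f1 <- train_denoiser(noisy, tiny_train_config(epochs = 3L, seed = 7))
  f2 <- train_denoiser(noisy, tiny_train_config(epochs = 3L, seed = 7))
  expect_equal(f1$history$total, f2$history$total, tolerance = 1e-6)
  expect_identical(f1$model$params, f2$model$params)
  cfg <- tiny_train_config(epochs = 3L, seed = 7)
  expect_equal(f1$history$lr, cosine_lr(0:2, cfg))

  # the unsupervised contract: the loop only ever sees the noisy cloud
  expect_named(formals(train_denoiser), c("dataset", "config", "verbose"))
})

test_that("tidy/glance/autoplot expose the fit", {
  noisy <- noisy_sphere(n = 100, seed = 23)$noisy
  fit <- train_denoiser(noisy, tiny_train_config(epochs = 2L))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "lr", "l_mse", "l_rep", "total"))
  gl <- generics::glance(fit)
  expect_equal(gl$epochs, 2L)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(ggplot2::autoplot(noisy), "ggplot")
})

test_that("denoise with the oracle model reproduces the pseudo-clean identity", {
  s <- noisy_sphere(n = 150, seed = 24)
  spec <- noise_spec(sigma = 0.03)
  oracle <- oracle_displacement_model(s$noisy)
  # R = 1: output = double + (-2M) = noisy - M = pseudo-clean of that pair
  out <- denoise(oracle, s$noisy, mode = "double", realizations = 1, seed = 31,
                 noise = spec)
  m <- pcdenoise:::draw_noise(150, spec, pcdenoise:::mix_seed(31, 1, 29L))
  expect_equal(as_matrix(out), as_matrix(s$noisy) - m, tolerance = 1e-12)

  # direct_half with oracle: base - (base) = exact identity at zero displacement
  expect_equal(as_matrix(denoise(oracle, s$noisy, mode = "direct_half")),
               as_matrix(s$noisy), tolerance = 1e-12)
})

test_that("Monte-Carlo averaging error shrinks like 1/sqrt(R)", {
  s <- noisy_sphere(n = 200, seed = 25)
  spec <- noise_spec(sigma = 0.05)
  oracle <- oracle_displacement_model(s$noisy)
  rms <- vapply(c(1, 4, 16), function(R) {
    out <- denoise(oracle, s$noisy, mode = "double", realizations = R,
                   seed = 77, noise = spec)
    sqrt(mean((as_matrix(out) - as_matrix(s$noisy))^2))
  }, double(1))
  expect_true(all(diff(rms) < 0))
  slope <- coef(lm(log(rms) ~ log(c(1, 4, 16))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.2)
})
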