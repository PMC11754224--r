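test_that("knn_graph matches the exhaustive oracle and handles edge cases", {
  # 3 collinear points at 0, 1, 3: nearest neighbors are [2, 1, 2]
  pts <- cbind(c(0, 1, 3), 0, 0)
  expect_equal(as.vector(knn_graph(pts, 1)), c(2L, 1L, 2L))

  pts <- withr::with_seed(1, matrix(rnorm(600), 200, 3))
  expect_equal(knn_graph(pts, 16), brute_knn(pts, pts, 16, exclude_self = TRUE))

  # k = n - 1: every other index, each row a permutation of the complement
  small <- withr::with_seed(2, matrix(rnorm(18), 6, 3))
  g <- knn_graph(small, 5)
  for (i in 1:6) expect_setequal(g[i, ], setdiff(1:6, i))

  expect_error(knn_graph(small, 6), "k_feat")
  expect_error(knn_graph(small[1, , drop = FALSE], 1), "at least 2")
})

test_that("init_model is seed-deterministic with contracted shapes", {
  cfg <- model_config(seed = 31)
  m1 <- init_model(cfg)
  m2 <- init_model(cfg)
  expect_identical(m1$params, m2$params)

  # first encoder layer lifts the 3-d relative edge vector toward 256
  expect_equal(dim(m1$params$encoder[[1]]$W), c(3L, 256L))
  # final decoder layer emits 3-d displacements
  last <- m1$params$decoder[[length(m1$params$decoder)]]
  expect_equal(ncol(last$W), 3L)
  # head input is twice the final encoder width (global concat)
  expect_equal(nrow(m1$params$decoder[[1]]$W), 2L * 2048L)

  m3 <- init_model(model_config(seed = 32))
  expect_false(identical(m1$params$encoder[[1]]$W, m3$params$encoder[[1]]$W))
})

test_that("extract_features is deterministic, equivariant, and shaped", {
  m <- tiny_model(seed = 3)
  X <- withr::with_seed(4, matrix(rnorm(240), 80, 3))
  f1 <- extract_features(X, m)
  f2 <- extract_features(X, m)
  expect_identical(f1, f2)
  expect_equal(dim(f1$point_features), c(80L, 12L))
  expect_length(f1$global, 12L)

  p <- withr::with_seed(5, sample(80))
  fp <- extract_features(X[p, ], m)
  expect_equal(fp$point_features, f1$point_features[p, ], tolerance = 1e-12)
  expect_equal(fp$global, f1$global, tolerance = 1e-12)
})

test_that("predict_displacements is permutation-equivariant and translation-covariant", {
  m <- tiny_model(seed = 6, k_feat = 8)
  X <- withr::with_seed(7, matrix(rnorm(1536), 512, 3))
  d <- predict_displacements(m, X)
  expect_equal(dim(unclass(d)), c(512L, 3L))
  expect_true(all(is.finite(d)))

  p <- withr::with_seed(8, sample(512))
  dp <- predict_displacements(m, X[p, ])
  expect_lt(max(abs(dp - d[p, ])), 1e-5)

  t3 <- c(5, -3, 11)
  dt <- predict_displacements(m, sweep(X, 2, t3, "+"))
  expect_lt(max(abs(dt - d)), 1e-5)  # displacements unchanged => output translates
})

test_that("zero-weight head yields the identity denoiser", {
  m <- tiny_model(seed = 9)
  nl <- length(m$params$decoder)
  m$params$decoder[[nl]]$W[] <- 0
  m$params$decoder[[nl]]$b[] <- 0
  X <- withr::with_seed(10, matrix(rnorm(150), 50, 3))
  expect_true(all(predict_displacements(m, X) == 0))
  noisy <- random_cloud(50, seed = 11, frame = "normalized")
  out <- denoise(m, noisy, mode = "direct_half")
  expect_identical(as_matrix(out), as_matrix(noisy))
})

test_that("backprop gradients match central finite differences", {
  cfg <- model_config(encoder_widths = c(3, 5, 6), decoder_widths = c(4, 3),
                      k_feat = 3, dropout = 0, weight_decay = 0, seed = 13)
  m <- init_model(cfg)
  # perturb the zero-initialized head so gradients flow everywhere
  nl <- length(m$params$decoder)
  m$params$decoder[[nl]]$W[] <- withr::with_seed(
    14, rnorm(length(m$params$decoder[[nl]]$W), sd = 0.3))
  X <- withr::with_seed(15, matrix(rnorm(36), 12, 3))
  tgt <- withr::with_seed(16, matrix(rnorm(36), 12, 3)) * 0.1
  lossfn <- function(model) {
    fw <- pcdenoise:::model_forward(model, X)
    mean(rowSums((fw$pred - tgt)^2))
  }
  fw <- pcdenoise:::model_forward(m, X, keep_cache = TRUE)
  gr <- pcdenoise:::model_backward(m, fw$cache, 2 * (fw$pred - tgt) / 12)
  eps <- 1e-6
  for (part in c("encoder", "decoder")) {
    for (l in seq_along(m$params[[part]])) {
      for (nm in c("W", "b")) {
        arr <- m$params[[part]][[l]][[nm]]
        idx <- withr::with_seed(l * 10 + nchar(nm),
                                sample(length(arr), min(6, length(arr))))
        for (i in idx) {
          mp <- m; mp$params[[part]][[l]][[nm]][i] <- arr[i] + eps
          mm <- m; mm$params[[part]][[l]][[nm]][i] <- arr[i] - eps
          num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
          ana <- gr[[part]][[l]][[nm]][i]
          expect_equal(ana, num, tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("checkpoints round-trip models and fits", {
  m <- tiny_model(seed = 17)
  f <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(m, f)
  m2 <- read_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config$encoder_widths, m$config$encoder_widths)

  saveRDS(list(format = "other"), f)
  expect_error(read_checkpoint(f), "checkpoint")
})
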