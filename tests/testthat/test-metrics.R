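test_that("correspondence building: identity pairing and brute-force nearest", {
  a <- random_cloud(40, seed = 1)
  expect_identical(build_correspondence(a, a, "paired")$mapping, 1:40)
  expect_identical(build_correspondence(a, a, "nearest")$mapping, 1:40)

  b <- random_cloud(25, seed = 2)
  corr <- build_correspondence(a, b, "nearest")
  oracle <- as.vector(brute_knn(as_matrix(b), as_matrix(a), 1))
  expect_identical(corr$mapping, oracle)
  expect_error(build_correspondence(a, b, "paired"), "equal point counts")
})

test_that("pc_mse: zero at identity, unit offset, nearest-mode oracle", {
  a <- random_cloud(60, seed = 3)
  expect_equal(pc_mse(a, a), 0)
  off <- point_cloud(sweep(as_matrix(a), 2, c(1, 0, 0), "+"))
  expect_equal(pc_mse(a, off), 1)

  b <- random_cloud(45, seed = 4)
  corr <- build_correspondence(a, b, "nearest")
  got <- pc_mse(a, b, corr)
  am <- as_matrix(a); bm <- as_matrix(b)
  oracle <- mean(vapply(1:45, function(i) {
    min(colSums((t(am) - bm[i, ])^2))
  }, double(1)))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("pc_snr follows the log law and closed forms", {
  a <- random_cloud(100, seed = 5)
  expect_identical(pc_snr(a, a), Inf)

  resid <- withr::with_seed(6, matrix(rnorm(300, sd = 0.01), 100, 3))
  e1 <- point_cloud(as_matrix(a) + resid)
  e10 <- point_cloud(as_matrix(a) + 10 * resid)
  expect_equal(pc_snr(a, e1) - pc_snr(a, e10), 20, tolerance = 1e-9)

  # hand case: Ps = 100 * Pn gives exactly 20 dB
  ref <- point_cloud(matrix(c(10, 0, 0), 1, 3))
  est <- point_cloud(matrix(c(9, 0, 0), 1, 3))  # Pn = 1, Ps = 100
  expect_equal(pc_snr(ref, est), 20)

  # monotone link: snr strictly decreases as residuals scale up
  snrs <- vapply(c(0.5, 1, 2, 4), function(s) {
    pc_snr(a, point_cloud(as_matrix(a) + s * resid))
  }, double(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("hausdorff distances: identity, 3-4-5 case, O(n^2) oracle", {
  a <- random_cloud(30, seed = 7)
  expect_equal(hausdorff_oneway(a, a), 0)
  expect_equal(hausdorff_oneway(matrix(0, 1, 3), matrix(c(3, 4, 0), 1, 3)), 5)

  A <- withr::with_seed(8, matrix(rnorm(600), 200, 3))
  B <- withr::with_seed(9, matrix(rnorm(600), 200, 3))
  oracle <- max(vapply(seq_len(200), function(i) {
    sqrt(min(colSums((t(B) - A[i, ])^2)))
  }, double(1)))
  expect_identical(hausdorff_oneway(A, B), oracle)
  expect_gte(hausdorff_distance(A, B), hausdorff_oneway(A, B))
  expect_gte(hausdorff_distance(A, B), hausdorff_oneway(B, A))
})

test_that("ssim3d: self-identity, translation invariance, reimplementation oracle", {
  x <- random_cloud(120, seed = 10)
  expect_equal(ssim3d(x, x), 1, tolerance = 1e-9)

  moved <- point_cloud(sweep(as_matrix(x), 2, c(3, -1, 2), "+"))
  expect_equal(ssim3d(x, moved), 1, tolerance = 1e-9)

  est <- point_cloud(as_matrix(x) +
                       withr::with_seed(11, matrix(rnorm(360, sd = 0.05), 120, 3)))
  k <- 8; K1 <- 0.01; K2 <- 0.03
  L <- sqrt(sum((apply(as_matrix(x), 2, max) - apply(as_matrix(x), 2, min))^2))
  # independent step-by-step recomputation
  sig <- function(pts) {
    t(vapply(seq_len(nrow(pts)), function(i) {
      d <- sqrt(colSums((t(pts) - pts[i, ])^2)); d[i] <- Inf
      nb <- pts[order(d)[1:k], , drop = FALSE]
      cen <- colMeans(nb)
      sort(sqrt(rowSums(sweep(nb, 2, cen)^2)))
    }, double(k)))
  }
  sx <- sig(as_matrix(x)); sy <- sig(as_matrix(est))
  c1 <- (K1 * L)^2; c2 <- (K2 * L)^2
  vals <- vapply(seq_len(120), function(i) {
    mx <- mean(sx[i, ]); my <- mean(sy[i, ])
    vx <- mean(sx[i, ]^2) - mx^2; vy <- mean(sy[i, ]^2) - my^2
    cxy <- mean(sx[i, ] * sy[i, ]) - mx * my
    ((2 * mx * my + c1) * (2 * cxy + c2)) / ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }, double(1))
  expect_equal(ssim3d(x, est, k_ssim = k), mean(vals), tolerance = 1e-9)
  expect_lt(ssim3d(x, est, k_ssim = k), 1)
  expect_error(ssim3d(x, est, k_ssim = 120), "k_ssim")
})

test_that("metrics are invariant to a common permutation", {
  a <- random_cloud(80, seed = 12)
  est <- point_cloud(as_matrix(a) +
                       withr::with_seed(13, matrix(rnorm(240, sd = 0.03), 80, 3)))
  p <- withr::with_seed(14, sample(80))
  ap <- point_cloud(as_matrix(a)[p, ])
  ep <- point_cloud(as_matrix(est)[p, ])
  expect_equal(pc_mse(a, est), pc_mse(ap, ep))
  expect_equal(pc_snr(a, est), pc_snr(ap, ep))
  expect_equal(hausdorff_oneway(a, est), hausdorff_oneway(ap, ep))
  expect_equal(ssim3d(a, est, k_ssim = 8), ssim3d(ap, ep, k_ssim = 8),
               tolerance = 1e-9)
})

test_that("evaluate_denoising assembles a faithful two-row report", {
  s <- noisy_sphere(n = 150, seed = 15)
  rep <- evaluate_denoising(s$nclean, s$noisy, s$nclean)
  den_row <- rep[rep$cloud == "denoised", ]
  expect_equal(den_row$mse, 0)
  expect_equal(den_row$hausdorff, 0)
  expect_equal(den_row$ssim, 1, tolerance = 1e-9)
  expect_identical(den_row$snr_db, Inf)
  st <- attr(rep, "settings")
  expect_identical(st$corr_mode, "paired")
  expect_identical(st$frame, "normalized")
  expect_true(jsonlite::validate(report_json(rep)))

  raw <- denormalize_cloud(s$noisy)
  expect_error(evaluate_denoising(s$nclean, raw, s$nclean), "frame mismatch")
})

test_that("evaluate_many mean/std footer matches direct recomputation", {
  triples <- lapply(1:5, function(i) {
    s <- noisy_sphere(n = 80, seed = 20 + i)
    list(ref = s$nclean, noisy = s$noisy,
         den = point_cloud(as_matrix(s$nclean) +
                             withr::with_seed(i, matrix(rnorm(240, sd = 0.005), 80, 3)),
                           frame = "normalized", norm = pc_norm(s$nclean)))
  })
  tab <- evaluate_many(lapply(triples, `[[`, "ref"),
                       lapply(triples, `[[`, "noisy"),
                       lapply(triples, `[[`, "den"), k_ssim = 8)
  body <- tab[!grepl("^_", tab$id) & tab$cloud == "denoised", ]
  foot_mean <- tab[tab$id == "_mean" & tab$cloud == "denoised", ]
  foot_std <- tab[tab$id == "_std" & tab$cloud == "denoised", ]
  expect_equal(foot_mean$mse, mean(body$mse))
  expect_equal(foot_std$ssim, sd(body$ssim))
})
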