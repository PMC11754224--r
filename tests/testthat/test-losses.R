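test_that("mse_loss matches hand arithmetic and a loop-based oracle", {
  d <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(mse_loss(2 * d, d), 0)
  expect_equal(mse_loss(matrix(0, 1, 3), d), 4)  # ||-2 e1||^2

  pred <- withr::with_seed(1, matrix(rnorm(150), 50, 3))
  d_dot <- withr::with_seed(2, matrix(rnorm(150), 50, 3))
  loop <- mean(vapply(1:50, function(i) sum((pred[i, ] - 2 * d_dot[i, ])^2),
                      double(1)))
  expect_equal(mse_loss(pred, d_dot), loop, tolerance = 1e-12)
  expect_error(mse_loss(pred, d_dot[1:10, ]), "pred")
})

test_that("constant prediction minimizing mse_loss is the mean of 2*d_dot", {
  d_dot <- withr::with_seed(3, matrix(rnorm(60), 20, 3))
  best <- colMeans(2 * d_dot)
  at <- function(v) mse_loss(matrix(v, 20, 3, byrow = TRUE), d_dot)
  for (delta in list(c(0.01, 0, 0), c(0, -0.02, 0), c(0.005, 0.005, -0.005))) {
    expect_gt(at(best + delta), at(best))
  }
})

test_that("pseudo_clean equals base - injected and the direct formula", {
  pc <- random_cloud(80, seed = 4, frame = "normalized")
  pair <- double_noise_pair(pc, noise_spec(sigma = 0.06), seed = 5)
  pt <- as_matrix(pseudo_clean(pair))
  expect_equal(pt, as_matrix(pair$base) - pair$injected, tolerance = 1e-15)
  expect_equal(pt, as_matrix(pair$double) + 2 * pair$d_dot, tolerance = 1e-12)

  z <- double_noise_pair(pc, noise_spec(sigma = 0), seed = 5)
  expect_identical(as_matrix(pseudo_clean(z)), as_matrix(pc))
})

test_that("pseudo_neighborhood matches an exhaustive sort with index ties", {
  pts <- withr::with_seed(6, matrix(rnorm(300), 100, 3))
  q <- pts[17, ]
  nb <- pseudo_neighborhood(pts, q, 4)
  d <- sqrt(colSums((t(pts) - q)^2))
  expect_equal(nb, pts[order(d)[1:4], ])

  expect_equal(nrow(pseudo_neighborhood(pts, q, 100)), 100L)  # k = n
  expect_equal(pseudo_neighborhood(pts, q, 1), pts[17, , drop = FALSE])
  expect_error(pseudo_neighborhood(pts, q, 101), "exceeds")
})

test_that("repulsion_loss equals the loop-based max-distance oracle", {
  den <- withr::with_seed(7, matrix(rnorm(90), 30, 3))
  ptld <- withr::with_seed(8, matrix(rnorm(120), 40, 3))
  nb_idx <- pcdenoise:::pseudo_neighborhoods(ptld, den, 5)
  got <- repulsion_loss(den, nb_idx, ptld)
  loop <- mean(vapply(1:30, function(i) {
    max(vapply(nb_idx[i, ], function(j) sum((den[i, ] - ptld[j, ])^2), double(1)))
  }, double(1)))
  expect_equal(got, loop, tolerance = 1e-12)

  # coincident neighborhood contributes zero; single far neighbor gives d^2
  one <- matrix(0, 1, 3)
  expect_equal(repulsion_loss(one, list(matrix(0, 3, 3))), 0)
  expect_equal(repulsion_loss(one, list(matrix(c(2, 0, 0), 1, 3))), 4)
  expect_error(repulsion_loss(one, list(matrix(numeric(0), 0, 3))), "empty")
})

test_that("total_loss combines components with gamma exactly", {
  cfg <- loss_config(gamma = 5e-4)
  lb <- total_loss(1, 2, cfg)
  expect_equal(lb$total, 1.001)
  expect_equal(total_loss(3, 7, loss_config(gamma = 0))$total, 3)
  for (i in 1:10) {
    lm <- withr::with_seed(i, runif(1)); lr <- withr::with_seed(i + 50, runif(1))
    expect_equal(total_loss(lm, lr, cfg)$total - lm - cfg$gamma * lr, 0,
                 tolerance = 1e-15)
  }
  expect_error(loss_config(gamma = -1), "gamma")
})

test_that("losses are permutation-covariant", {
  pred <- withr::with_seed(9, matrix(rnorm(60), 20, 3))
  d_dot <- withr::with_seed(10, matrix(rnorm(60), 20, 3))
  p <- withr::with_seed(11, sample(20))
  expect_equal(mse_loss(pred, d_dot), mse_loss(pred[p, ], d_dot[p, ]))

  ptld <- withr::with_seed(12, matrix(rnorm(90), 30, 3))
  nb <- pcdenoise:::pseudo_neighborhoods(ptld, pred, 4)
  expect_equal(repulsion_loss(pred, nb, ptld),
               repulsion_loss(pred[p, ], nb[p, ], ptld))
})
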