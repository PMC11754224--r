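#' Loss configuration
#'
#' The training objective is `total = l_mse + gamma * l_rep`: a displacement
#' mean-squared-error term plus a weighted repulsion term that keeps denoised
#' points from collapsing onto each other. `gamma` defaults to 5e-4.
#' `k_rep` is the size of the pseudo-clean neighborhood the repulsion term
#' scans (default 4, a small neighborhood in line with the repulsion-loss
#' lineage). `center_neighborhoods` translates each neighborhood to its query
#' point before the distance computation; this leaves the repulsion distances
#' unchanged and is off by default (exposed for experimentation).
#'
#' @param gamma Repulsion weight, `>= 0`.
#' @param k_rep Neighborhood size, `>= 1`.
#' @param center_neighborhoods Logical; see above.
#' @return A `loss_config` list.
#' @export
loss_config <- function(gamma = 5e-4, k_rep = 4L, center_neighborhoods = FALSE) {
  structure(list(gamma = check_scalar(gamma, "gamma", lower = 0),
                 k_rep = check_count(k_rep, "k_rep", min = 1L),
                 center_neighborhoods = isTRUE(center_neighborhoods)),
            class = "loss_config")
}

#' Displacement mean-squared-error loss
#'
#' Mean over points of the squared Euclidean norm of `pred - 2 * d_dot`: the
#' network's predicted displacement is regressed onto twice the known
#' base-to-double displacement (see [training_target()]).
#'
#' @param pred n x 3 matrix of predicted displacements.
#' @param d_dot n x 3 matrix of base-to-double displacements (`-M`).
#' @return A non-negative scalar.
#' @export
mse_loss <- function(pred, d_dot) {
  if (!identical(dim(pred), dim(d_dot))) {
    stopf("pred is %s but d_dot is %s", paste(dim(pred), collapse = "x"),
          paste(dim(d_dot), collapse = "x"))
  }
  r <- pred - 2 * d_dot
  mean(rowSums(r * r))
}

#' Pseudo-clean point cloud
#'
#' `P~ = double + 2 * d_dot`, which algebraically equals `base - M`: the base
#' cloud pushed away from the injected noise. It is not actually clean, but
#' it serves as the surrogate reference the repulsion term measures against.
#'
#' @param pair A [double_noise_pair()].
#' @return A `point_cloud` in the pair's frame, order aligned to the pair.
#' @export
pseudo_clean <- function(pair) {
  stopifnot(inherits(pair, "double_noise_pair"))
  pc_replace_coords(pair$double, as_matrix(pair$double) + 2 * pair$d_dot)
}

#' Pseudo-clean neighborhood of a query point
#'
#' The `k_rep` points of the pseudo-clean cloud nearest (Euclidean) to the
#' query, ties broken by lower index. During training the query is the base
#' (singly-noisy) point, assumed less noise-affected than the double cloud.
#'
#' @param p_tilde Pseudo-clean `point_cloud` (or n x 3 matrix).
#' @param query A single 3-vector.
#' @param k_rep Neighborhood size, `<= n`.
#' @return A `k_rep` x 3 matrix of neighborhood points.
#' @export
pseudo_neighborhood <- function(p_tilde, query, k_rep) {
  pts <- if (is_point_cloud(p_tilde)) as_matrix(p_tilde) else p_tilde
  k_rep <- check_count(k_rep, "k_rep")
  if (k_rep > nrow(pts)) stopf("k_rep = %d exceeds pseudo-clean size %d", k_rep, nrow(pts))
  idx <- knn_brute(matrix(query, 1L, 3L), pts, k_rep)
  pts[idx[1L, ], , drop = FALSE]
}

# All k_rep-neighborhood index sets at once: row i = indices into p_tilde of
# the neighbors of query point i.
pseudo_neighborhoods <- function(p_tilde_mat, queries_mat, k_rep) {
  knn_brute(queries_mat, p_tilde_mat, k_rep)
}

#' Repulsion loss
#'
#' Mean over points of the per-point *maximum* squared distance from the
#' denoised position `double + pred` to its pseudo-clean neighborhood. Note
#' the objective as printed minimizes a maximum distance to neighbors — it
#' pulls each denoised point toward the far edge of its neighborhood rather
#' than pushing points apart; it is implemented exactly as stated and its
#' small default weight keeps it a mild regularizer.
#'
#' @param denoised n x 3 matrix of denoised positions.
#' @param neighborhoods List of n matrices (k x 3), one per point, or an
#'   n x k index matrix paired with `p_tilde`.
#' @param p_tilde Optional pseudo-clean matrix/cloud when `neighborhoods` is
#'   an index matrix.
#' @return A non-negative scalar.
#' @export
repulsion_loss <- function(denoised, neighborhoods, p_tilde = NULL) {
  n <- nrow(denoised)
  if (is.matrix(neighborhoods) && !is.null(p_tilde)) {
    pts <- if (is_point_cloud(p_tilde)) as_matrix(p_tilde) else p_tilde
    per_point <- rep_max_sqdist(denoised, neighborhoods, pts)$value
    return(mean(per_point))
  }
  if (length(neighborhoods) != n) stopf("need one neighborhood per point")
  vals <- vapply(seq_len(n), function(i) {
    nb <- neighborhoods[[i]]
    if (is.null(nb) || nrow(nb) == 0L) stopf("empty neighborhood for point %d", i)
    max(rowSums(sweep(nb, 2, denoised[i, ])^2))
  }, double(1))
  mean(vals)
}

# Max squared distance (and argmax) from each denoised point to its
# neighborhood rows of p_tilde given an n x k index matrix. Vectorized.
rep_max_sqdist <- function(denoised, nb_idx, p_tilde) {
  n <- nrow(denoised); k <- ncol(nb_idx)
  nb <- p_tilde[as.vector(nb_idx), , drop = FALSE]          # (n*k) x 3, column-major over k
  diff <- nb - denoised[rep(seq_len(n), times = k), , drop = FALSE]
  d2 <- matrix(rowSums(diff * diff), n, k)
  j <- max.col(d2, ties.method = "first")
  list(value = d2[cbind(seq_len(n), j)], argmax = j)
}

#' Combine loss components
#'
#' @param l_mse Displacement MSE component.
#' @param l_rep Repulsion component.
#' @param config A [loss_config()].
#' @return A `loss_breakdown` list with `l_mse`, `l_rep`, `total`
#'   (`= l_mse + gamma * l_rep`).
#' @export
total_loss <- function(l_mse, l_rep, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  l_mse <- check_scalar(l_mse, "l_mse", lower = 0)
  l_rep <- check_scalar(l_rep, "l_rep", lower = 0)
  structure(list(l_mse = l_mse, l_rep = l_rep,
                 total = l_mse + config$gamma * l_rep),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss> total %.6g = mse %.6g + gamma*rep %.6g\n",
              x$total, x$l_mse, x$total - x$l_mse))
  invisible(x)
}
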