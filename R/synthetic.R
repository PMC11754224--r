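#' Parameters of a synthetic tree
#'
#' Describes a simple tree-like shape: a vertical cylinder trunk (surface
#' sampled) topped by an ellipsoidal crown. Defaults are sized like a small
#' plantation conifer and produce desk-scale clouds (2048 points), in the
#' spirit of segmented single-tree LiDAR clouds of 10^3–10^4 points.
#'
#' @param trunk_height Trunk height (m).
#' @param trunk_radius Trunk radius (m).
#' @param crown_radii Three ellipsoid semi-axes (m).
#' @param crown_center_height Height of the crown center (m).
#' @param n_trunk,n_crown Point counts on trunk and crown.
#' @param seed Integer seed.
#' @return A `tree_params` list.
#' @export
tree_params <- function(trunk_height = 8, trunk_radius = 0.25,
                        crown_radii = c(2.5, 2.5, 4), crown_center_height = 9,
                        n_trunk = 512L, n_crown = 1536L, seed = 1L) {
  stopifnot(trunk_height > 0, trunk_radius > 0, all(crown_radii > 0),
            crown_center_height > 0)
  n_trunk <- check_count(n_trunk, "n_trunk", min = 0L)
  n_crown <- check_count(n_crown, "n_crown", min = 0L)
  if (n_trunk + n_crown < 1L) stopf("need at least one point")
  structure(list(trunk_height = trunk_height, trunk_radius = trunk_radius,
                 crown_radii = as.double(crown_radii),
                 crown_center_height = crown_center_height,
                 n_trunk = n_trunk, n_crown = n_crown, seed = as.integer(seed)),
            class = "tree_params")
}

#' Generate a clean synthetic tree
#'
#' Trunk points are sampled uniformly on the cylinder side surface (axis =
#' z, base at z = 0); crown points on the ellipsoid surface centered at
#' `crown_center_height`. Surface (not volume) sampling mirrors how LiDAR
#' returns arise and keeps distance-to-geometry well defined. Deterministic
#' given the seed.
#'
#' @param params A [tree_params()].
#' @return A `scene_truth`: list with `clean` (raw-frame `point_cloud` whose
#'   `label` column is `"trunk"`/`"crown"`) and `tree_id` (integer vector).
#' @export
generate_tree <- function(params = tree_params()) {
  stopifnot(inherits(params, "tree_params"))
  pts <- withr::with_seed(params$seed, {
    trunk <- if (params$n_trunk > 0) {
      theta <- runif(params$n_trunk, 0, 2 * pi)
      h <- runif(params$n_trunk, 0, params$trunk_height)
      cbind(params$trunk_radius * cos(theta), params$trunk_radius * sin(theta), h)
    }
    crown <- if (params$n_crown > 0) {
      u <- matrix(rnorm(3L * params$n_crown), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      sweep(u, 2L, params$crown_radii, "*") +
        matrix(c(0, 0, params$crown_center_height), params$n_crown, 3L, byrow = TRUE)
    }
    rbind(trunk, crown)
  })
  label <- c(rep("trunk", params$n_trunk), rep("crown", params$n_crown))
  cloud <- point_cloud(tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                      label = label))
  structure(list(clean = cloud, tree_id = rep(1L, nrow(cloud))),
            class = "scene_truth")
}

#' Generate a clean synthetic forest plot
#'
#' Places `n_trees` trees at seeded uniform positions inside a square of side
#' `area_side`, rejecting draws closer than `min_spacing` to an accepted
#' tree; optionally adds uniform ground-plane points at z = 0. Tree shape
#' parameters are drawn per tree from the given ranges. Defaults give a
#' 5-tree mini-plot.
#'
#' @param n_trees Number of trees.
#' @param area_side Plot side length (m).
#' @param min_spacing Minimum distance between tree centers (m).
#' @param height_range,crown_radius_range Uniform ranges for per-tree trunk
#'   height and horizontal crown radius.
#' @param points_per_tree Points per tree (split 1:3 trunk:crown).
#' @param n_ground Ground points at z = 0 (0 disables).
#' @param seed Integer seed.
#' @return A `scene_truth` with per-point `label` (`trunk`/`crown`/`ground`)
#'   and `tree_id` (0 for ground).
#' @export
generate_plot <- function(n_trees = 5L, area_side = 30, min_spacing = 4,
                          height_range = c(6, 12), crown_radius_range = c(1.5, 3),
                          points_per_tree = 2048L, n_ground = 0L, seed = 1L) {
  n_trees <- check_count(n_trees, "n_trees")
  centers <- withr::with_seed(mix_seed(seed, 1L), {
    acc <- matrix(numeric(0), 0L, 2L)
    tries <- 0L
    while (nrow(acc) < n_trees) {
      tries <- tries + 1L
      if (tries > 1000L * n_trees) {
        stopf("cannot place %d trees with spacing %g in a %g m square",
              n_trees, min_spacing, area_side)
      }
      cand <- runif(2L, 0, area_side)
      if (nrow(acc) == 0L || all(sqrt(rowSums(sweep(acc, 2L, cand)^2)) >= min_spacing)) {
        acc <- rbind(acc, cand)
      }
    }
    acc
  })
  pieces <- purrr::map(seq_len(n_trees), function(i) {
    dims <- withr::with_seed(mix_seed(seed, 2L, i), {
      list(h = runif(1L, height_range[1], height_range[2]),
           cr = runif(1L, crown_radius_range[1], crown_radius_range[2]))
    })
    tp <- tree_params(trunk_height = dims$h, crown_radii = c(dims$cr, dims$cr, dims$h / 2.5),
                      crown_center_height = dims$h + dims$h / 3,
                      n_trunk = round(points_per_tree / 4),
                      n_crown = points_per_tree - round(points_per_tree / 4),
                      seed = mix_seed(seed, 3L, i))
    st <- generate_tree(tp)
    df <- tibble::as_tibble(st$clean)
    df$x <- df$x + centers[i, 1]
    df$y <- df$y + centers[i, 2]
    df$tree_id <- i
    df
  })
  df <- dplyr::bind_rows(pieces)
  if (n_ground > 0L) {
    g <- withr::with_seed(mix_seed(seed, 4L), {
      tibble::tibble(x = runif(n_ground, 0, area_side),
                     y = runif(n_ground, 0, area_side),
                     z = 0, label = "ground", tree_id = 0L)
    })
    df <- dplyr::bind_rows(df, g)
  }
  cloud <- point_cloud(df[, c("x", "y", "z", "label")])
  structure(list(clean = cloud, tree_id = df$tree_id, centers = centers),
            class = "scene_truth")
}

#' Generate a clean geometric primitive
#'
#' Uniform surface samples of unit-scale primitives, used as analytic ground
#' truth in denoising tests: `sphere` (unit radius, centered at the origin),
#' `plane` (unit square at z = 0, centered), `cylinder` (unit radius, side
#' surface, z in [-1, 1]).
#'
#' @param shape `"sphere"`, `"plane"` or `"cylinder"`.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return A raw-frame [point_cloud()].
#' @export
generate_primitive <- function(shape = c("sphere", "plane", "cylinder"),
                               n = 2048L, seed = 1L) {
  shape <- match.arg(shape)
  n <- check_count(n, "n")
  pts <- withr::with_seed(as.integer(seed), {
    switch(shape,
           sphere = {
             u <- matrix(rnorm(3L * n), ncol = 3L)
             u / sqrt(rowSums(u^2))
           },
           plane = cbind(runif(n, -0.5, 0.5), runif(n, -0.5, 0.5), 0),
           cylinder = {
             theta <- runif(n, 0, 2 * pi)
             cbind(cos(theta), sin(theta), runif(n, -1, 1))
           })
  })
  point_cloud(pts)
}

#' Analytic distance to a primitive's surface
#'
#' The ground-truth channel for denoising-recovery tests: clean primitives
#' have distance 0 by construction, and isotropic noise of level sigma gives
#' an RMS distance-to-surface close to sigma (the off-surface normal
#' component). `sphere`: `| ||p|| - radius |`; `plane`: `|z|`; `cylinder`:
#' radial distance to the side surface (end caps ignored).
#'
#' @param cloud A `point_cloud` (raw frame of the primitive).
#' @param shape Primitive name.
#' @param radius Sphere/cylinder radius (default 1).
#' @return Numeric vector of distances, one per point.
#' @export
distance_to_surface <- function(cloud, shape = c("sphere", "plane", "cylinder"),
                                radius = 1) {
  shape <- match.arg(shape)
  pts <- if (is_point_cloud(cloud)) as_matrix(cloud) else cloud
  switch(shape,
         sphere = abs(sqrt(rowSums(pts^2)) - radius),
         plane = abs(pts[, 3]),
         cylinder = abs(sqrt(pts[, 1]^2 + pts[, 2]^2) - radius))
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d points, %d tree(s)\n",
              nrow(x$clean), length(unique(x$tree_id[x$tree_id > 0L]))))
  invisible(x)
}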