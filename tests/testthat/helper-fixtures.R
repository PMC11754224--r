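# Shared fixtures, all generated in code at test time.

random_cloud <- function(n, seed = 1L, frame = c("raw", "normalized")) {
  frame <- match.arg(frame)
  pts <- withr::with_seed(seed, matrix(rnorm(3L * n), n, 3L))
  pc <- point_cloud(pts)
  if (frame == "normalized") normalize_cloud(pc) else pc
}

noisy_sphere <- function(n = 400L, sigma = 0.02, seed = 1L) {
  clean <- generate_primitive("sphere", n, seed = seed)
  nclean <- normalize_cloud(clean)
  list(clean = clean, nclean = nclean,
       noisy = inject_noise(nclean, noise_spec(sigma = sigma, seed = seed + 100L)))
}

tiny_model <- function(seed = 1L, k_feat = 4L, dropout = 0) {
  init_model(model_config(encoder_widths = c(3L, 8L, 12L),
                          decoder_widths = c(8L, 3L),
                          k_feat = k_feat, dropout = dropout,
                          weight_decay = 0, seed = seed))
}

# O(n^2) reference k-NN: exhaustive distance sort, lower-index tie-break.
brute_knn <- function(query, ref, k, exclude_self = FALSE) {
  t(vapply(seq_len(nrow(query)), function(i) {
    d <- sqrt(colSums((t(ref) - query[i, ])^2))
    if (exclude_self) d[i] <- Inf
    order(d)[seq_len(k)]
  }, integer(k)))
}
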