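# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm runif sd cor
NULL

# Deterministic integer mixing for derived seed streams (splitmix-style).
# Keeps results strictly below 2^31 so they are valid R integer seeds.
mix_seed <- function(...) {
  parts <- vapply(list(...), function(x) as.double(x) %% 2147483647, double(1))
  h <- 104729
  for (p in parts) {
    h <- (h * 31 + p + 1) %% 2147483647
    h <- (h * 2654435761) %% 2147483647
  }
  as.integer(h %% 2147483629L + 1L)
}

stopf <- function(fmt, ..., class = "pcdenoise_error") {
  abort(sprintf(fmt, ...), class = class)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stopf("`%s` must be a single integer >= %d, got %s", name, min,
          paste(format(x), collapse = ", "))
  }
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lower || x > upper) {
    stopf("`%s` must be a single finite number in [%s, %s]", name,
          format(lower), format(upper))
  }
  as.double(x)
}

# Pairwise squared Euclidean distances between rows of a (m x 3) and b (n x 3).
cross_sqdist <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# k nearest neighbours of each `query` row among `ref` rows, brute force,
# chunked to bound memory; ties broken by lower reference index (stable order).
# Returns an (nrow(query) x k) index matrix into `ref`.
knn_brute <- function(query, ref, k, exclude = NULL, chunk = 2048L) {
  nq <- nrow(query)
  nr <- nrow(ref)
  if (k > nr - (if (is.null(exclude)) 0L else 1L)) {
    stopf("k = %d exceeds the number of available neighbours (%d)", k, nr)
  }
  out <- matrix(NA_integer_, nq, k)
  for (start in seq(1L, nq, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nq)
    d2 <- cross_sqdist(query[idx, , drop = FALSE], ref)
    if (!is.null(exclude)) {
      d2[cbind(seq_along(idx), exclude[idx])] <- Inf
    }
    for (r in seq_along(idx)) {
      ord <- order(d2[r, ])  # radix sort: stable, ties -> lower index
      out[idx[r], ] <- ord[seq_len(k)]
    }
  }
  out
}
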