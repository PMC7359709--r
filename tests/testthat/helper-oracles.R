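# Independent oracles, deliberately naive: scalar stack-based breadth-first
# flood fill, used to validate the vectorized wand implementation.

naive_flood_fill <- function(slice, seed, lo, hi) {
  nr <- nrow(slice); nc <- ncol(slice)
  inr <- function(r, c) slice[r, c] >= lo && slice[r, c] <= hi
  mask <- matrix(FALSE, nr, nc)
  if (!inr(seed[1], seed[2])) return(mask)
  stack <- list(seed)
  mask[seed[1], seed[2]] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
          !mask[q[1], q[2]] && inr(q[1], q[2])) {
        mask[q[1], q[2]] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  mask
}

# exhaustive nearest-in-mask-pixel-to-centroid scan
naive_centroid_seed <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  best <- Inf; best_p <- NULL
  for (i in seq_len(nrow(idx))) {
    d <- sum((idx[i, ] - ctr)^2)
    if (d < best) { best <- d; best_p <- idx[i, ] }
  }
  as.integer(best_p)
}

random_test_image <- function(n = 32, levels = 0:4) {
  arr <- array(sample(levels, n * n, replace = TRUE), c(1, n, n))
  voxel_image(arr, rep(0.1, 3))
}
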