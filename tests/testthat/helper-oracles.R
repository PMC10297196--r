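# Independent brute-force oracles, deliberately naive: these never call the
# package's own code paths.

# 8-connected component labelling by explicit stack-based flood fill.
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (sr in seq_len(nr)) for (sc in seq_len(nc)) {
    if (!mask[sr, sc] || lab[sr, sc] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(sr, sc))
    lab[sr, sc] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# ROI parameters computed by per-pixel accumulation over an oracle labelling.
oracle_roi_params <- function(values, spacing, cutoff = 0.2) {
  lab <- oracle_flood_fill(values > cutoff)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rois <- lapply(ids, function(id) {
    acc <- c(n = 0, sum = 0, max = -Inf, r = 0, c = 0)
    probs <- numeric(0)
    for (r in seq_len(nrow(values))) for (c in seq_len(ncol(values))) {
      if (lab[r, c] == id) {
        acc["n"] <- acc["n"] + 1
        acc["sum"] <- acc["sum"] + values[r, c]
        acc["max"] <- max(acc["max"], values[r, c])
        acc["r"] <- acc["r"] + r
        acc["c"] <- acc["c"] + c
        probs <- c(probs, values[r, c])
      }
    }
    data.frame(pixel_count = acc[["n"]],
               area_mm2 = acc[["n"]] * spacing^2,
               woap = acc[["sum"]] * spacing^2,
               prob_mean = acc[["sum"]] / acc[["n"]],
               prob_median = median(probs),
               prob_max = acc[["max"]],
               centroid_row = acc[["r"]] / acc[["n"]],
               centroid_col = acc[["c"]] / acc[["n"]])
  })
  do.call(rbind, rois)
}

# Least squares through the raw normal equations.
oracle_normal_equations <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Spearman via the classical no-ties formula 1 - 6 sum(d^2) / (n (n^2 - 1)).
oracle_spearman_no_ties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Random probability map with a few smooth blobs, for oracle comparisons.
random_blob_map <- function(n = 32, spacing = 1, n_blobs = 3) {
  vals <- matrix(0, n, n)
  for (i in seq_len(n_blobs)) {
    ctr <- runif(2, 5, n - 4)
    peak <- runif(1, 0.3, 1)
    s <- runif(1, 1.5, 4)
    d2 <- outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, "+")
    vals <- pmax(vals, peak * exp(-d2 / (2 * s^2)))
  }
  probability_map(vals, spacing, image_id = "random")
}
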