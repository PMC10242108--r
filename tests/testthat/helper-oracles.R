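# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration or direct definition, never by calling
# the implementation under test.

# direct sliding-window grayscale closing/opening with a spherical
# structuring element (the rolling ball), O(H*W*r^2)
oracle_ball <- function(img, r, closing = TRUE) {
  H <- nrow(img); W <- ncol(img)
  offs <- expand.grid(a = -floor(r):floor(r), b = -floor(r):floor(r))
  offs <- offs[offs$a^2 + offs$b^2 <= r^2, ]
  z <- sqrt(r^2 - offs$a^2 - offs$b^2)
  trans <- function(src, dilate) {
    out <- matrix(if (dilate) -Inf else Inf, H, W)
    for (k in seq_len(nrow(offs))) {
      a <- offs$a[k]; b <- offs$b[k]
      rr <- max(1, 1 + a):min(H, H + a)
      cc <- max(1, 1 + b):min(W, W + b)
      v <- src[rr - a, cc - b, drop = FALSE] + if (dilate) z[k] else -z[k]
      out[rr, cc] <- if (dilate) pmax(out[rr, cc], v) else pmin(out[rr, cc], v)
    }
    out
  }
  if (closing) trans(trans(img, TRUE), FALSE)
  else trans(trans(img, FALSE), TRUE)
}

# exhaustive optimum of 1-D 3-means: tries every contiguous 2-breakpoint
# partition of the sorted values
oracle_kmeans3_sse <- function(x) {
  x <- sort(x)
  n <- length(x)
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  best <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      s <- sse(x[1:i]) + sse(x[(i + 1):j]) + sse(x[(j + 1):n])
      if (s < best) best <- s
    }
  }
  best
}

# AUC as mean pairwise concordance over all (positive, negative) pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# exhaustive cut-off search over midpoints between consecutive scores
oracle_best_cutoff <- function(scores, labels, method = "youden") {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  crit <- vapply(cand, function(t) {
    sens <- mean(scores[labels == 1] > t)
    spec <- mean(scores[labels == 0] <= t)
    if (method == "youden") sens + spec - 1 else sens * spec
  }, numeric(1))
  max(crit)
}

# Spearman rho from the textbook d^2 formula (no ties)
oracle_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

make_scene <- function(...) {
  sp <- scene_spec(...)
  list(spec = sp, scene = render_scene(sp))
}
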