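# Independent oracles, deliberately written from definitions rather than by
# reusing package code.

# BH step-up by its definition: q_i = min over j with p_(j) >= p_(i) of
# m * p_(j) / j, capped at 1.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exhaustive grid search over the probability simplex (step `res`) minimising
# the least-squares objective ||S x - y||^2; small numbers of types only.
grid_simplex_fit <- function(S, y, res = 0.01) {
  k <- ncol(S)
  steps <- round(1 / res)
  grid <- if (k == 2) {
    a <- seq(0, steps) / steps
    cbind(a, 1 - a)
  } else if (k == 3) {
    pts <- list()
    for (a in 0:steps) for (b in 0:(steps - a)) {
      pts[[length(pts) + 1]] <- c(a, b, steps - a - b) / steps
    }
    do.call(rbind, pts)
  } else {
    stop("grid oracle supports 2 or 3 types")
  }
  obj <- colSums((S %*% t(grid) - y)^2)
  list(x = grid[which.min(obj), ], objective = min(obj))
}

# Inverse-variance pooling spelled out long-hand.
pool_brute_force <- function(effects, ses) {
  w <- 1 / ses^2
  est <- sum(effects * w) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- est / se
  list(est = est, se = se, z = z, p = 2 * (1 - pnorm(abs(z))))
}
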