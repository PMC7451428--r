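# Shared fixtures, built in code at test time.

# small 4D volume with a diagonal affine
tiny_vol <- function(sdim = c(6, 6, 6), nt = 20, tr = 2.5, voxel = 3,
                     origin = c(0, 0, 0), data = NULL, mask = NULL,
                     seed = 1) {
  if (is.null(data)) {
    data <- withr::with_seed(seed, array(rnorm(prod(sdim) * nt), c(sdim, nt)))
  }
  vol4d(data, make_affine(voxel, origin), tr, mask)
}

# constant-free motion matrix with an optional step
motion_fixture <- function(n = 10, step_at = NULL, step = c(0.1, 0, 0, 0, 0, 0)) {
  m <- matrix(0, n, 6)
  if (!is.null(step_at)) {
    for (j in 1:6) m[step_at:n, j] <- m[step_at:n, j] + step[j]
  }
  m
}

# two-node spec: seed -> target edge b, autoregression a
two_node_spec <- function(b = 0.4, a = 0.3, b_rest = b) {
  A <- matrix(c(a, b_rest, 0, a), 2, 2)   # column-major: A[2,1] = b_rest
  network_spec(c("seed", "target"), rbind(c(0, 0, 0), c(30, 0, 0)),
               A_rest = A, A_task_SZ = A, A_task_HC = A)
}

# OLS oracle: full normal-equations solve, independent of the package path
ols_oracle <- function(X, y) {
  b <- solve(t(X) %*% X) %*% t(X) %*% y
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  se <- sqrt(as.numeric(t(res) %*% res) / df * diag(solve(t(X) %*% X)))
  list(coef = as.numeric(b), se = se, resid = as.numeric(res), df = df)
}

# lag-1 path coefficient oracle via lm() on z-scored series
pc_oracle <- function(x, y, lag = 1) {
  xz <- as.numeric(scale(x)); yz <- as.numeric(scale(y))
  n <- length(x)
  d <- data.frame(yt = yz[(lag + 1):n], ylag = yz[1:(n - lag)],
                  xlag = xz[1:(n - lag)])
  unname(coef(lm(yt ~ ylag + xlag, d))["xlag"])
}
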