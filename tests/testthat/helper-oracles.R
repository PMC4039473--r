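# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own computational paths.

# Dense "same"-size correlation with replicate padding; even kernels anchored
# at tap offset a - s/2 (mirrors the documented convention).
oracle_conv2 <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  sh <- nrow(k); sw <- ncol(k)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (ki in 1:sh) for (kj in 1:sw) {
      ii <- min(max(i + ki - 1 - sh %/% 2, 1), H)
      jj <- min(max(j + kj - 1 - sw %/% 2, 1), W)
      acc <- acc + k[ki, kj] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Five-way labeling from two response maps (ties to the first orientation).
oracle_classify <- function(r0, r90, eps) {
  lab <- matrix(0L, nrow(r0), ncol(r0))
  for (i in seq_len(nrow(r0))) for (j in seq_len(ncol(r0))) {
    a0 <- abs(r0[i, j]); a90 <- abs(r90[i, j])
    m <- max(a0, a90)
    if (m >= eps && m > 0) {
      lab[i, j] <- if (a0 >= a90) {
        if (r0[i, j] > 0) 1L else 2L
      } else {
        if (r90[i, j] > 0) 3L else 4L
      }
    }
  }
  lab
}

# Scalar per-pixel, per-category recursion for the adaptation dynamics with
# the persistence gate, starting from activation 1 and onset semantics.
# labels: vector over updates for one pixel. Returns the 4 final activations
# and the per-update total for that pixel.
oracle_adapt_pixel <- function(labels, dt, tau_d = 4, tau_r = 6,
                               prev0 = NA_integer_) {
  fd <- exp(-dt / tau_d)
  fr <- exp(-dt / tau_r)
  a <- rep(1, 4)
  prev <- prev0
  totals <- numeric(length(labels))
  for (t in seq_along(labels)) {
    l <- labels[t]
    eff <- if (!is.na(prev) && l == prev) l else 0L
    for (c in 1:4) {
      a[c] <- if (eff == c) a[c] * fd else 1 - (1 - a[c]) * fr
    }
    prev <- l
    totals[t] <- sum(a)
  }
  list(activation = a, totals = totals)
}

# Dense log-grid trapezoid evaluation of the JZS marginal likelihood using
# full N x N covariance matrices and the explicit Inverse-Gamma(1/2, r^2/2)
# prior density (independent of the package's Woodbury + adaptive
# Gauss-Hermite path).
oracle_jzs_logml <- function(y, Xlist, rvec, npts = 121, lo = -14, hi = 14) {
  N <- length(y); one <- rep(1, N); d <- length(Xlist)
  lg <- seq(lo, hi, length.out = npts)
  dlg <- lg[2] - lg[1]
  logprior <- function(g, r) {
    0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g)
  }
  grid <- as.matrix(expand.grid(rep(list(lg), d)))
  f <- apply(grid, 1, function(lgv) {
    g <- exp(lgv)
    Sig <- diag(N)
    for (k in seq_len(d)) Sig <- Sig + g[k] * tcrossprod(Xlist[[k]])
    ch <- chol(Sig)
    Si1 <- backsolve(ch, forwardsolve(t(ch), one))
    Siy <- backsolve(ch, forwardsolve(t(ch), y))
    a <- sum(one * Si1); b <- sum(one * Siy); cc <- sum(y * Siy)
    S <- cc - b^2 / a
    -sum(log(diag(ch))) - 0.5 * log(a) - (N - 1) / 2 * log(S) +
      sum(mapply(logprior, g, rvec)) + sum(lgv)
  })
  m <- max(f)
  lgamma((N - 1) / 2) - (N - 1) / 2 * log(pi) +
    m + log(sum(exp(f - m))) + d * log(dlg)
}

# Sum-to-zero design columns, duplicated from first principles for oracle use.
oracle_effect_design <- function(f) {
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  H <- stats::contr.helmert(nlevels(f))
  Z %*% sweep(H, 2, sqrt(colSums(H^2)), "/")
}

# Narrowest-interval scan written independently of cfsim::hdi.
oracle_hdi <- function(x, prob) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(prob * n)
  best <- c(xs[1], xs[n]); bw <- Inf
  for (i in seq_len(n - m)) {
    w <- xs[i + m] - xs[i]
    if (w < bw) { bw <- w; best <- c(xs[i], xs[i + m]) }
  }
  best
}

# Small geometry for fast rendering tests.
tiny_geometry <- function(side = 32, n_elements = 30L) {
  display_geometry(pixels_per_degree = side / 7.32, n_elements = n_elements)
}

# Run a staircase against an observer until n_main main-phase trials have
# been recorded; returns the final state and main-phase history.
run_staircase_sim <- function(observer, condition, n_main, step = 0.05,
                              start = 0.5, seed = 1) {
  st <- staircase(start, step = step, condition = condition)
  set.seed(seed)
  main_correct <- logical(0)
  n <- 0
  while (n < n_main) {
    p <- p_correct(observer, condition, 10^st$level)
    ok <- runif(1) < p
    in_main <- st$phase == "main"
    st <- staircase_update(st, ok)
    if (in_main) {
      main_correct <- c(main_correct, ok)
      n <- n + 1
    }
  }
  list(state = st, main_correct = main_correct)
}
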