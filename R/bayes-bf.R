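#' Default-prior (JZS) Bayes factors for repeated-measures ANOVA designs
#'
#' Compares linear models for a participants x conditions table using the
#' default scaled-g prior framework: each effect group (mask speed, target
#' speed, their interaction, participants) receives sum-to-zero-projected
#' design columns with a zero-centered normal prior of variance `g_j sigma^2`,
#' and each `g_j` carries an Inverse-Gamma(1/2, r_j^2/2) prior (equivalently a
#' scaled half-Cauchy on the effect scale). The grand mean and error variance
#' get the Jeffreys prior. Conditional on g the marginal likelihood is
#' available in closed form; g is integrated out numerically.
#'
#' Available models (every model includes the participant term):
#' `"null"`, `"mask_speed"`, `"target_speed"`, `"additive"`
#' (mask + target), `"full"` (mask + target + interaction).
#'
#' @param data A [rm_dataset()].
#' @param model_a,model_b Model labels to compare.
#' @param rscale_fixed Prior scale r for fixed-effect groups (default 0.5).
#' @param rscale_random Prior scale r for the participant group (default 1).
#' @param method `"quadrature"` (Gauss-Hermite product rule over the g
#'   groups; default) or `"montecarlo"` (prior sampling fallback).
#' @param nodes Gauss-Hermite nodes per dimension; default 24 for up to two
#'   g groups, 12 for three, 10 for four.
#' @param mc_draws Monte-Carlo draws for `method = "montecarlo"`.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return A list of class `cfs_bayes_factor` with `models`, `bf`
#'   (Bayes factor of `model_a` over `model_b`), `log_bf`, and `logml`
#'   (the two log marginal likelihoods).
#' @export
#' @examples
#' \dontrun{
#' bf <- jzs_anova_bf(dataset, "mask_speed", "null")
#' bf$bf
#' }
jzs_anova_bf <- function(data, model_a, model_b,
                         rscale_fixed = 0.5, rscale_random = 1,
                         method = c("quadrature", "montecarlo"),
                         nodes = NULL, mc_draws = 20000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(data, "cfs_rm_dataset"))
  la <- jzs_log_marginal(data, model_a, rscale_fixed, rscale_random, method,
                         nodes, mc_draws, seed)
  lb <- jzs_log_marginal(data, model_b, rscale_fixed, rscale_random, method,
                         nodes, mc_draws, seed + 1L)
  structure(list(models = c(model_a, model_b), bf = exp(la - lb),
                 log_bf = la - lb, logml = c(la, lb)),
            class = "cfs_bayes_factor")
}

#' @export
print.cfs_bayes_factor <- function(x, ...) {
  cat(sprintf("<cfs_bayes_factor> BF(%s vs %s) = %.6g\n",
              x$models[1], x$models[2], x$bf))
  invisible(x)
}

jzs_models <- function() {
  c("null", "mask_speed", "target_speed", "additive", "full")
}

# Orthonormal basis of the orthogonal complement of the constant vector in
# R^a: normalized Helmert contrasts.
sum_to_zero_basis <- function(a) {
  H <- stats::contr.helmert(a)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

indicator <- function(f) {
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

# Design-column groups for a model label. Each entry: list(X, r).
jzs_design <- function(data, model, rscale_fixed, rscale_random) {
  if (!model %in% jzs_models()) {
    stop_invalid("unknown model label: ", model, "; choose from ",
                 paste(jzs_models(), collapse = ", "))
  }
  has_target <- !is.null(data$target_speed)
  if (!has_target && model %in% c("target_speed", "additive", "full")) {
    stop_invalid("model '", model, "' requires a target_speed factor")
  }
  Xc <- indicator(data$condition) %*% sum_to_zero_basis(nlevels(data$condition))
  Xs <- indicator(data$participant) %*%
    sum_to_zero_basis(nlevels(data$participant))
  groups <- list()
  if (model %in% c("mask_speed", "additive", "full")) {
    groups <- c(groups, list(list(X = Xc, r = rscale_fixed)))
  }
  if (model %in% c("target_speed", "additive", "full")) {
    Xt <- indicator(data$target_speed) %*%
      sum_to_zero_basis(nlevels(data$target_speed))
    groups <- c(groups, list(list(X = Xt, r = rscale_fixed)))
  }
  if (model == "full") {
    cell <- interaction(data$condition, data$target_speed, lex.order = TRUE)
    Qi <- kronecker(sum_to_zero_basis(nlevels(data$condition)),
                    sum_to_zero_basis(nlevels(data$target_speed)))
    Xi <- indicator(cell) %*% Qi
    groups <- c(groups, list(list(X = Xi, r = rscale_fixed)))
  }
  groups <- c(groups, list(list(X = Xs, r = rscale_random)))
  groups
}

# log p(y | g) up to the model-independent constant
# lgamma((N-1)/2) - (N-1)/2 log(pi), computed via the Woodbury identity from
# precomputed cross-products. gvec holds one g value per design column.
jzs_logf <- function(pre, gvec) {
  M <- pre$XtX + diag(1 / gvec, length(gvec))
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  u1 <- backsolve(R, forwardsolve(t(R), pre$Xt1))
  uy <- backsolve(R, forwardsolve(t(R), pre$Xty))
  a <- pre$N - sum(pre$Xt1 * u1)       # 1' Sigma^-1 1
  cc <- pre$yty - sum(pre$Xty * uy)    # y' Sigma^-1 y
  b <- pre$s1y - sum(pre$Xt1 * uy)     # 1' Sigma^-1 y
  S <- cc - b * b / a
  if (S <= 0 || a <= 0) return(-Inf)
  logdetSigma <- 2 * sum(log(diag(R))) + sum(log(gvec))
  -0.5 * logdetSigma - 0.5 * log(a) - (pre$N - 1) / 2 * log(S)
}

jzs_precompute <- function(y, groups) {
  X <- do.call(cbind, lapply(groups, `[[`, "X"))
  list(XtX = crossprod(X), Xty = drop(crossprod(X, y)),
       Xt1 = drop(crossprod(X, rep(1, length(y)))),
       yty = sum(y^2), s1y = sum(y), N = length(y),
       k = vapply(groups, function(g) ncol(g$X), 0L),
       r = vapply(groups, `[[`, 0, "r"))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log of the Inverse-Gamma(1/2, r^2/2) prior density
log_g_prior <- function(g, r) {
  0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g)
}

jzs_log_marginal <- function(data, model, rscale_fixed, rscale_random,
                             method = "quadrature", nodes = NULL,
                             mc_draws = 20000L, seed = 1L) {
  groups <- jzs_design(data, model, rscale_fixed, rscale_random)
  pre <- jzs_precompute(data$value, groups)
  d <- length(groups)
  const <- lgamma((pre$N - 1) / 2) - (pre$N - 1) / 2 * log(pi)
  if (method == "montecarlo") {
    lf <- with_seed(seed, {
      vapply(seq_len(mc_draws), function(i) {
        g <- pre$r^2 / rnorm(d)^2
        jzs_logf(pre, rep(g, times = pre$k))
      }, 0)
    })
    return(const + logsumexp(lf) - log(mc_draws))
  }
  # adaptive Gauss-Hermite in v = log g: locate the mode of the integrand,
  # scale the rule by the local curvature, so sharp likelihood peaks at
  # large g (strong effects) are resolved.
  h <- function(v) {
    g <- exp(v)
    jzs_logf(pre, rep(g, times = pre$k)) +
      sum(log_g_prior(g, pre$r)) + sum(v)
  }
  v0 <- if (d == 1L) {
    stats::optimize(function(v) -h(v), c(-25, 25), tol = 1e-9)$minimum
  } else {
    stats::optim(rep(0, d), function(v) -h(v), method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))$par
  }
  eps <- 1e-3
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- rep(0, d)
      ei[i] <- eps; ej[j] <- eps
      H[i, j] <- H[j, i] <-
        (h(v0 + ei + ej) - h(v0 + ei - ej) - h(v0 - ei + ej) +
           h(v0 - ei - ej)) / (4 * eps^2)
    }
  }
  Sg <- tryCatch(solve(-H), error = function(e) NULL)
  L <- if (!is.null(Sg)) tryCatch(t(chol(Sg)), error = function(e) NULL)
  if (is.null(L)) L <- diag(1 / sqrt(pmax(diag(-H), 1e-4)), d)
  if (is.null(nodes)) nodes <- c(24L, 20L, 12L, 10L)[min(d, 4L)]
  gh <- pracma::gaussHermite(nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nodes)), d)))
  lw <- log(gh$w) + gh$x^2
  lf <- vapply(seq_len(nrow(grid)), function(i) {
    idx <- grid[i, ]
    v <- v0 + sqrt(2) * drop(L %*% gh$x[idx])
    h(v) + sum(lw[idx])
  }, 0)
  const + logsumexp(lf) + d / 2 * log(2) + sum(log(diag(L)))
}
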