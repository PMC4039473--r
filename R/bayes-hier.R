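#' Repeated-measures dataset of normalized thresholds
#'
#' Validates and standardizes a participants x conditions (optionally x
#' target speed) table of positive normalized thresholds for the hierarchical
#' analyses.
#'
#' @param df Data frame with columns `participant`, `condition`, optionally
#'   `target_speed`, and a value column.
#' @param value Name of the value column (default `"normalized"`).
#' @return An object of class `cfs_rm_dataset` (a standardized data frame).
#' @export
rm_dataset <- function(df, value = "normalized") {
  need <- c("participant", "condition", value)
  if (!all(need %in% names(df))) {
    stop_invalid("df must contain columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    participant = factor(df$participant),
    condition = factor(df$condition, levels = unique(df$condition)),
    value = df[[value]])
  if ("target_speed" %in% names(df) && !all(is.na(df$target_speed))) {
    out$target_speed <- factor(df$target_speed, levels = unique(df$target_speed))
  }
  if ("threshold" %in% names(df)) out$threshold <- df$threshold
  if (any(!is.finite(out$value)) || any(out$value <= 0)) {
    stop_invalid("values must be positive and finite")
  }
  cells <- if (is.null(out$target_speed)) {
    table(out$participant, out$condition)
  } else {
    table(out$participant, out$condition, out$target_speed)
  }
  if (any(cells != 1L)) {
    stop_invalid("design must be a complete crossing with one value per cell")
  }
  class(out) <- c("cfs_rm_dataset", "data.frame")
  out
}

jags_model_oneway <- function(likelihood) {
  lik <- if (likelihood == "t") {
    "y[i] ~ dt(mu[i], tauE, nu)"
  } else {
    "y[i] ~ dnorm(mu[i], tauE)"
  }
  nu_prior <- if (likelihood == "t") "nu ~ dunif(1, 100)" else ""
  # non-centered deflection groups: robust mixing when a group-level spread
  # is near zero (e.g. participant effects after per-participant normalization)
  sprintf("
model {
  for (i in 1:N) {
    %s
    mu[i] <- b0 + bC[cond[i]] + bS[subj[i]]
  }
  for (j in 1:J) { bC[j] <- sigmaC * zC[j]
                   zC[j] ~ dnorm(0, 1) }
  for (s in 1:S) { bS[s] <- sigmaS * zS[s]
                   zS[s] ~ dnorm(0, 1) }
  b0 ~ dnorm(0, 1.0E-6)
  sigmaC ~ dt(0, 1, 1) T(0,)
  sigmaS ~ dt(0, 1, 1) T(0,)
  sigmaE ~ dt(0, 1, 1) T(0,)
  tauE <- pow(sigmaE, -2)
  %s
}", lik, nu_prior)
}

jags_model_twoway <- function(likelihood) {
  lik <- if (likelihood == "t") {
    "y[i] ~ dt(mu[i], tauE, nu)"
  } else {
    "y[i] ~ dnorm(mu[i], tauE)"
  }
  nu_prior <- if (likelihood == "t") "nu ~ dunif(1, 100)" else ""
  sprintf("
model {
  for (i in 1:N) {
    %s
    mu[i] <- b0 + bC[cond[i]] + bT[targ[i]] + bI[cond[i], targ[i]] + bS[subj[i]]
  }
  for (j in 1:J) { bC[j] <- sigmaC * zC[j]
                   zC[j] ~ dnorm(0, 1) }
  for (k in 1:K) { bT[k] <- sigmaT * zT[k]
                   zT[k] ~ dnorm(0, 1) }
  for (j in 1:J) { for (k in 1:K) { bI[j, k] <- sigmaI * zI[j, k]
                                    zI[j, k] ~ dnorm(0, 1) } }
  for (s in 1:S) { bS[s] <- sigmaS * zS[s]
                   zS[s] ~ dnorm(0, 1) }
  b0 ~ dnorm(0, 1.0E-6)
  sigmaC ~ dt(0, 1, 1) T(0,)
  sigmaT ~ dt(0, 1, 1) T(0,)
  sigmaI ~ dt(0, 1, 1) T(0,)
  sigmaS ~ dt(0, 1, 1) T(0,)
  sigmaE ~ dt(0, 1, 1) T(0,)
  tauE <- pow(sigmaE, -2)
  %s
}", lik, nu_prior)
}

run_jags <- function(model_string, data_list, monitor, chains, iter, warmup,
                     adapt, seed) {
  chain_seeds <- derive_seeds(seed, chains)
  inits <- lapply(chain_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con, data = data_list, inits = inits,
                          n.chains = chains, n.adapt = adapt, quiet = TRUE)
  if (warmup > 0) invisible(stats::update(jm, warmup, progress.bar = "none"))
  rjags::coda.samples(jm, monitor, n.iter = iter, progress.bar = "none")
}

# Sum-to-zero centering of raw deflection draws (matrix draws x params) for
# one chain; returns the centered matrix with renamed columns.
center_oneway <- function(m, cond_levels, subj_levels, likelihood) {
  J <- length(cond_levels)
  S <- length(subj_levels)
  bC <- m[, sprintf("bC[%d]", 1:J), drop = FALSE]
  bS <- m[, sprintf("bS[%d]", 1:S), drop = FALSE]
  mC <- rowMeans(bC)
  mS <- rowMeans(bS)
  out <- cbind(b0 = m[, "b0"] + mC + mS,
               bC - mC, bS - mS,
               sigma = m[, "sigmaE"])
  nm <- c("b0", paste0("bC[", cond_levels, "]"),
          paste0("bS[", subj_levels, "]"), "sigma")
  if (likelihood == "t") {
    out <- cbind(out, nu = m[, "nu"])
    nm <- c(nm, "nu")
  }
  colnames(out) <- nm
  out
}

center_twoway <- function(m, cond_levels, targ_levels, subj_levels, likelihood) {
  J <- length(cond_levels)
  K <- length(targ_levels)
  S <- length(subj_levels)
  n <- nrow(m)
  bC <- m[, sprintf("bC[%d]", 1:J), drop = FALSE]
  bT <- m[, sprintf("bT[%d]", 1:K), drop = FALSE]
  bS <- m[, sprintf("bS[%d]", 1:S), drop = FALSE]
  # cell effects per draw: n x J x K
  cell <- array(0, dim = c(n, J, K))
  for (j in 1:J) for (k in 1:K) {
    cell[, j, k] <- bC[, j] + bT[, k] + m[, sprintf("bI[%d,%d]", j, k)]
  }
  grand <- apply(cell, 1, mean)
  rowm <- apply(cell, c(1, 2), mean) # n x J
  colm <- apply(cell, c(1, 3), mean) # n x K
  bC_c <- rowm - grand
  bT_c <- colm - grand
  bI_c <- matrix(0, n, J * K)
  nmI <- character(J * K)
  idx <- 0L
  for (k in 1:K) for (j in 1:J) {
    idx <- idx + 1L
    bI_c[, idx] <- cell[, j, k] - rowm[, j] - colm[, k] + grand
    nmI[idx] <- paste0("bI[", cond_levels[j], ",", targ_levels[k], "]")
  }
  mS <- rowMeans(bS)
  out <- cbind(b0 = m[, "b0"] + grand + mS,
               bC_c, bT_c, bI_c, bS - mS, sigma = m[, "sigmaE"])
  nm <- c("b0", paste0("bC[", cond_levels, "]"),
          paste0("bT[", targ_levels, "]"), nmI,
          paste0("bS[", subj_levels, "]"), "sigma")
  if (likelihood == "t") {
    out <- cbind(out, nu = m[, "nu"])
    nm <- c(nm, "nu")
  }
  colnames(out) <- nm
  out
}

finish_fit <- function(chains_centered, model, data, cond_levels, targ_levels,
                       subj_levels, likelihood, rhat_max, on_nonconvergence) {
  ml <- coda::as.mcmc.list(lapply(chains_centered, coda::mcmc))
  keep <- apply(do.call(rbind, chains_centered), 2, function(x) sd(x) > 1e-12)
  rhat <- if (length(chains_centered) >= 2L) {
    gd <- coda::gelman.diag(ml[, names(keep)[keep], drop = FALSE],
                            autoburnin = FALSE, multivariate = FALSE)
    gd$psrf[, 1]
  } else {
    setNames(rep(NA_real_, sum(keep)), names(keep)[keep])
  }
  ess <- coda::effectiveSize(ml)
  bad <- names(rhat)[is.finite(rhat) & rhat > rhat_max]
  if (length(bad)) {
    msg <- paste0("convergence failure (split R-hat > ", rhat_max, ") for: ",
                  paste(bad, collapse = ", "))
    if (on_nonconvergence == "error") stop_invalid(msg)
    if (on_nonconvergence == "warn") warning(msg, call. = FALSE)
  }
  structure(
    list(draws = do.call(rbind, chains_centered), chains = chains_centered,
         rhat = rhat, ess = ess, model = model,
         condition_levels = cond_levels, target_levels = targ_levels,
         participant_levels = subj_levels, likelihood = likelihood,
         data = data),
    class = "cfs_posterior")
}

#' @export
print.cfs_posterior <- function(x, ...) {
  cat(sprintf(
    "<cfs_posterior> %s %s model: %d draws (%d chains), max R-hat %.3f\n",
    x$likelihood, x$model, nrow(x$draws), length(x$chains),
    max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Fit the hierarchical robust-t one-way repeated-measures model
#'
#' The normalized thresholds are modeled as draws from a t distribution with
#' unknown degrees of freedom (uniform prior on `[1, 100]`, accommodating
#' outliers), whose location is a linear combination of a grand mean,
#' per-condition deflections and per-participant deflections. Each deflection
#' group has a zero-centered hierarchical normal prior with its own
#' half-Cauchy group-level spread, so estimates for one condition (or
#' participant) inform the others. Sampling is by MCMC (JAGS); draws are
#' post-hoc centered so each deflection group sums to zero, and split R-hat
#' and effective sample size are computed for all reported parameters.
#'
#' @param data A [rm_dataset()] (one-way: no target_speed column used).
#' @param chains Number of MCMC chains (default 4).
#' @param iter Retained iterations per chain (default 2500).
#' @param warmup Burn-in iterations (default 1000).
#' @param adapt JAGS adaptation steps (default 500).
#' @param seed Integer seed (per-chain RNG seeds are derived from it).
#' @param likelihood `"t"` (default, robust) or `"normal"` (ablation).
#' @param rhat_max Convergence threshold for split R-hat (default 1.01).
#' @param on_nonconvergence `"error"` (default), `"warn"`, or `"ignore"`.
#' @return A `cfs_posterior` object; `draws` columns are `b0`,
#'   `bC[<condition>]`, `bS[<participant>]`, `sigma`, and `nu`.
#' @export
fit_one_way <- function(data, chains = 4, iter = 2500, warmup = 1000,
                        adapt = 500, seed = 1L,
                        likelihood = c("t", "normal"), rhat_max = 1.01,
                        on_nonconvergence = c("error", "warn", "ignore")) {
  likelihood <- match.arg(likelihood)
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(inherits(data, "cfs_rm_dataset"))
  if (nlevels(data$participant) < 3L) stop_invalid("need at least 3 participants")
  cond_levels <- levels(data$condition)
  subj_levels <- levels(data$participant)
  dl <- list(y = data$value, cond = as.integer(data$condition),
             subj = as.integer(data$participant),
             N = nrow(data), J = length(cond_levels), S = length(subj_levels))
  monitor <- c("b0", "bC", "bS", "sigmaE", if (likelihood == "t") "nu")
  samp <- run_jags(jags_model_oneway(likelihood), dl, monitor, chains, iter,
                   warmup, adapt, seed)
  centered <- lapply(samp, function(ch) {
    center_oneway(as.matrix(ch), cond_levels, subj_levels, likelihood)
  })
  finish_fit(centered, "oneway", data, cond_levels, NULL, subj_levels,
             likelihood, rhat_max, on_nonconvergence)
}

#' Fit the hierarchical robust-t two-way repeated-measures model
#'
#' As [fit_one_way()], with additional deflection groups for target speed and
#' the mask-speed x target-speed interaction, each with its own hierarchical
#' spread. Deflections are centered so that condition and target groups sum
#' to zero and interaction deflections sum to zero over both margins.
#'
#' @inheritParams fit_one_way
#' @param data A [rm_dataset()] with a `target_speed` column.
#' @return A `cfs_posterior` with additional columns `bT[<target>]` and
#'   `bI[<condition>,<target>]`.
#' @export
fit_two_way <- function(data, chains = 4, iter = 2500, warmup = 1000,
                        adapt = 500, seed = 1L,
                        likelihood = c("t", "normal"), rhat_max = 1.01,
                        on_nonconvergence = c("error", "warn", "ignore")) {
  likelihood <- match.arg(likelihood)
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(inherits(data, "cfs_rm_dataset"))
  if (is.null(data$target_speed)) {
    stop_invalid("two-way fit requires a target_speed factor")
  }
  cond_levels <- levels(data$condition)
  targ_levels <- levels(data$target_speed)
  subj_levels <- levels(data$participant)
  dl <- list(y = data$value, cond = as.integer(data$condition),
             targ = as.integer(data$target_speed),
             subj = as.integer(data$participant),
             N = nrow(data), J = length(cond_levels),
             K = length(targ_levels), S = length(subj_levels))
  monitor <- c("b0", "bC", "bT", "bI", "bS", "sigmaE",
               if (likelihood == "t") "nu")
  samp <- run_jags(jags_model_twoway(likelihood), dl, monitor, chains, iter,
                   warmup, adapt, seed)
  centered <- lapply(samp, function(ch) {
    center_twoway(as.matrix(ch), cond_levels, targ_levels, subj_levels,
                  likelihood)
  })
  finish_fit(centered, "twoway", data, cond_levels, targ_levels, subj_levels,
             likelihood, rhat_max, on_nonconvergence)
}

#' Highest density interval of a sample
#'
#' The narrowest interval containing `prob` of the draws, found by scanning
#' all windows of the required length over the sorted sample.
#'
#' @param x Numeric sample.
#' @param prob Probability mass (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
hdi <- function(x, prob = 0.95) {
  if (prob <= 0 || prob >= 1) stop_invalid("prob must be in (0, 1)")
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(xs[1], xs[n]))
  widths <- xs[(m + 1):n] - xs[1:(n - m)]
  i <- which.min(widths)
  c(xs[i], xs[i + m])
}

#' Posterior contrast with HDI decision rule
#'
#' Computes the per-draw weighted sum of condition deflections for a
#' zero-sum weight vector and summarizes it by its highest density interval.
#' The compared conditions are declared different exactly when the interval
#' excludes zero; because the whole joint posterior is examined, any number
#' of contrasts can be computed without a multiplicity correction.
#'
#' @param samples A `cfs_posterior`.
#' @param weights Named numeric vector of contrast coefficients over (a
#'   subset of) the condition levels; must sum to zero.
#' @param prob HDI probability (default 0.95).
#' @param target_level For two-way fits, compute the contrast at this target
#'   speed level (uses `bC + bI[, target]`); `NULL` uses the mask-speed main
#'   effect deflections.
#' @return A list of class `cfs_contrast` with `weights`, `samples` (per-draw
#'   contrast values), `hdi`, `excludes_zero`, `mean`.
#' @export
contrast_hdi <- function(samples, weights, prob = 0.95, target_level = NULL) {
  stopifnot(inherits(samples, "cfs_posterior"))
  if (prob <= 0 || prob >= 1) stop_invalid("prob must be in (0, 1)")
  if (abs(sum(weights)) > 1e-8) stop_invalid("contrast weights must sum to zero")
  lv <- samples$condition_levels
  if (is.null(names(weights)) || !all(names(weights) %in% lv)) {
    stop_invalid("weights must be named by condition levels")
  }
  eff <- sapply(names(weights), function(l) {
    v <- samples$draws[, paste0("bC[", l, "]")]
    if (!is.null(target_level)) {
      v <- v + samples$draws[, paste0("bI[", l, ",", target_level, "]")]
    }
    v
  })
  cs <- drop(eff %*% weights)
  h <- if (all(cs == cs[1])) c(cs[1], cs[1]) else hdi(cs, prob)
  structure(list(weights = weights, samples = cs, hdi = h,
                 excludes_zero = (h[1] > 0 || h[2] < 0), mean = mean(cs),
                 prob = prob, target_level = target_level),
            class = "cfs_contrast")
}

#' @export
print.cfs_contrast <- function(x, ...) {
  cat(sprintf("<cfs_contrast> mean %.4f, %d%% HDI [%.4f, %.4f] -> %s\n",
              x$mean, round(100 * x$prob), x$hdi[1], x$hdi[2],
              if (x$excludes_zero) "credibly different" else "not different"))
  invisible(x)
}

#' Posterior predictive check
#'
#' Every retained MCMC draw generates one replicate dataset from the fitted
#' likelihood at each design cell's posterior location, scale and degrees of
#' freedom. The observed value of each cell is compared with its central
#' predictive interval.
#'
#' @param samples A `cfs_posterior`.
#' @param data The [rm_dataset()] the model was fitted to (must match the
#'   fit's design).
#' @param prob Predictive interval probability (default 0.95).
#' @param seed Seed for the replicate noise draws.
#' @return A list with `yrep` (draws x cells matrix), `cells` (data frame
#'   with observed value, predictive mean and interval, and an `inside`
#'   flag), and `coverage` (fraction of observed cells inside their interval).
#' @export
posterior_predictive <- function(samples, data, prob = 0.95, seed = 1L) {
  stopifnot(inherits(samples, "cfs_posterior"))
  if (!identical(levels(data$condition), samples$condition_levels) ||
      !identical(levels(data$participant), samples$participant_levels)) {
    stop_invalid("data design does not match the fitted design")
  }
  d <- samples$draws
  n_draws <- nrow(d)
  n_cells <- nrow(data)
  mu <- matrix(d[, "b0"], n_draws, n_cells)
  mu <- mu + d[, paste0("bC[", as.character(data$condition), "]"), drop = FALSE]
  if (samples$model == "twoway") {
    if (is.null(data$target_speed) ||
        !identical(levels(data$target_speed), samples$target_levels)) {
      stop_invalid("data design does not match the fitted design")
    }
    mu <- mu + d[, paste0("bT[", as.character(data$target_speed), "]"),
                 drop = FALSE]
    mu <- mu + d[, paste0("bI[", as.character(data$condition), ",",
                          as.character(data$target_speed), "]"), drop = FALSE]
  }
  mu <- mu + d[, paste0("bS[", as.character(data$participant), "]"),
               drop = FALSE]
  sig <- d[, "sigma"]
  yrep <- with_seed(seed, {
    noise <- if (samples$likelihood == "t") {
      matrix(rt(n_draws * n_cells, df = rep(d[, "nu"], n_cells)),
             n_draws, n_cells)
    } else {
      matrix(rnorm(n_draws * n_cells), n_draws, n_cells)
    }
    mu + sig * noise
  })
  a <- (1 - prob) / 2
  lo <- apply(yrep, 2, quantile, probs = a)
  hi <- apply(yrep, 2, quantile, probs = 1 - a)
  cells <- data.frame(participant = data$participant,
                      condition = data$condition,
                      observed = data$value,
                      pred_mean = colMeans(yrep), lo = lo, hi = hi)
  if (!is.null(data$target_speed)) cells$target_speed <- data$target_speed
  cells$inside <- cells$observed >= lo & cells$observed <= hi
  list(yrep = yrep, cells = cells, coverage = mean(cells$inside))
}
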