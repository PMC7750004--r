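# MCMC machinery: correlation-matrix transforms, slice and adaptive
# Metropolis updates, a blocked Gibbs sampler for the hierarchical
# Gaussian reading-time model, and split-chain diagnostics.

# ---- canonical partial correlation (CPC) parameterization -----------------
# A correlation matrix is parameterized by its canonical partial
# correlations w = tanh(z); the Cholesky factor is built row by row.
# Under an LKJ(eta) prior the CPC in "tree" j is (scaled) Beta
# distributed with shape eta + (K - 1 - j) / 2, which gives a fully
# normalized prior density directly on z.

cpc_to_chol <- function(w, K) {
  L <- diag(K)
  idx <- 0L
  if (K >= 2) for (i in 2:K) {
    rem <- 1
    for (j in 1:(i - 1)) {
      idx <- idx + 1L
      L[i, j] <- w[idx] * sqrt(rem)
      rem <- rem - L[i, j]^2
    }
    L[i, i] <- sqrt(max(rem, 0))
  }
  L
}

chol_to_cpc <- function(L) {
  K <- nrow(L)
  w <- numeric(K * (K - 1) / 2)
  idx <- 0L
  if (K >= 2) for (i in 2:K) {
    rem <- 1
    for (j in 1:(i - 1)) {
      idx <- idx + 1L
      w[idx] <- L[i, j] / sqrt(rem)
      rem <- rem - L[i, j]^2
    }
  }
  w
}

# log prior density of unconstrained correlation parameters z inducing
# LKJ(eta) on the correlation matrix (includes the tanh Jacobian);
# CPCs are ordered (i = 2..K, j = 1..i-1) so the tree index is
# sequence(1:(K-1))
lkj_cpc_logprior <- function(z, K, eta) {
  if (length(z) == 0L) return(0)
  w <- tanh(z)
  a <- eta + (K - 1 - sequence(seq_len(K - 1))) / 2
  sum(stats::dbeta((w + 1) / 2, a, a, log = TRUE)) -
    length(w) * log(2) + sum(log1p(-w^2))
}

# half-Normal(0, s) log density
dhalfnorm_log <- function(x, s) {
  ifelse(x >= 0, log(2) + stats::dnorm(x, 0, s, log = TRUE), -Inf)
}

# ---- generic univariate slice sampler (stepping out, Neal 2003) -----------
slice_sample1 <- function(x0, log_f, w = 1, max_steps = 50) {
  ly <- log_f(x0) - stats::rexp(1)
  u <- stats::runif(1)
  l <- x0 - w * u
  r <- l + w
  steps <- 0L
  while (log_f(l) > ly && steps < max_steps) { l <- l - w; steps <- steps + 1L }
  steps <- 0L
  while (log_f(r) > ly && steps < max_steps) { r <- r + w; steps <- steps + 1L }
  repeat {
    x1 <- stats::runif(1, l, r)
    if (log_f(x1) >= ly) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

# ---- split-chain diagnostics ----------------------------------------------

#' Split-chain convergence diagnostic (R-hat)
#'
#' Classic potential-scale-reduction statistic computed after splitting
#' each chain in half.
#'
#' @param draws matrix (iterations x chains) of draws of one parameter,
#'   or a list of per-chain vectors.
#' @return the split-chain R-hat.
#' @export
split_rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based effective sample size using Geyer's initial
#' positive sequence, pooled over chains.
#'
#' @inheritParams split_rhat
#' @return estimated effective sample size.
#' @export
ess_basic <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (stats::var(as.vector(draws)) == 0) return(n * m)
  max_lag <- min(n - 1, 200)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    stats::acf(draws[, j], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[-1]
  }, numeric(max_lag)))
  # initial positive sequence on paired sums
  tau <- 1
  k <- 1
  while (k + 1 <= max_lag) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, n * m / tau)
}

# ---- blocked Gibbs sampler for the hierarchical Gaussian model ------------
# y = X beta + Z_p u_p + Z_i u_i + eps, with random-effect design Z
# (by default the full fixed-effect design; reduced models drop a
# fixed-effect column but keep its random slopes), full covariance
# matrices Sigma = D(tau) R D(tau), half-Normal priors on tau and
# sigma, LKJ(eta) on R, independent Normal priors on beta.
#
# Returns per-chain draws of beta, sigma, tau, correlations, and the
# unconstrained variance parameters (for bridge sampling over the
# collapsed posterior).
#
# The default engine is the compiled implementation (src/gibbs_lmm.cpp);
# the pure-R reference below defines the sampler and is exercised
# against the compiled one in the test suite.
gibbs_lmm <- function(y, X, Z, pid, iid, prior, chains = 4,
                      warmup = 1000, iter = 1000, seed = 1L,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    zidx <- match(colnames(X), colnames(Z))
    return(lapply(seq_len(chains), function(chain) {
      set.seed(derive_seed(seed, paste0("chain", chain)))
      gibbs_lmm_chain(y, X, Z, as.integer(pid), as.integer(iid),
                      as.integer(zidx), prior$beta_mean, prior$beta_sd,
                      prior$re_sd_scale, prior$sigma_scale, prior$lkj_eta,
                      warmup, iter)
    }))
  }
  gibbs_lmm_r(y, X, Z, pid, iid, prior, chains = chains, warmup = warmup,
              iter = iter, seed = seed)
}

gibbs_lmm_r <- function(y, X, Z, pid, iid, prior, chains = 4,
                        warmup = 1000, iter = 1000, seed = 1L) {
  n <- length(y)
  pf <- ncol(X)
  p <- ncol(Z)
  np <- max(pid)
  ni <- max(iid)
  q <- p * (p - 1) / 2
  XtX <- crossprod(X)

  Cp <- lapply(seq_len(np), function(j) crossprod(Z[pid == j, , drop = FALSE]))
  Ci <- lapply(seq_len(ni), function(j) crossprod(Z[iid == j, , drop = FALSE]))
  XtXi <- lapply(seq_len(ni), function(j) crossprod(X[iid == j, , drop = FALSE]))
  ZtXi <- lapply(seq_len(ni), function(j) {
    crossprod(Z[iid == j, , drop = FALSE], X[iid == j, , drop = FALSE])
  })
  # random-effect columns matched by a fixed effect (reduced models
  # drop a fixed effect but keep its random slopes)
  zidx <- match(colnames(X), colnames(Z))

  prior_prec <- diag(1 / prior$beta_sd^2, pf)
  prior_mb <- prior$beta_mean / prior$beta_sd^2

  # Sigma^(-1) and log-likelihood of group effects from (log tau, z)
  sigma_chol <- function(theta) {
    tau <- exp(theta[seq_len(p)])
    L <- cpc_to_chol(tanh(theta[p + seq_len(q)]), p)
    tau * L   # row scaling: D(tau) %*% L, lower-triangular Cholesky of Sigma
  }
  re_logprior <- function(theta, sd_scale) {
    ltau <- theta[seq_len(p)]
    tau <- exp(ltau)
    # tau is positive by construction, so the half-Normal needs no gate
    p * log(2) + sum(stats::dnorm(tau, 0, sd_scale, log = TRUE)) + sum(ltau) +
      lkj_cpc_logprior(theta[p + seq_len(q)], p, prior$lkj_eta)
  }
  # likelihood of N group effects with scatter matrix Su = crossprod(U)
  re_loglik <- function(theta, Su, N) {
    Lc <- sigma_chol(theta)
    ld <- diag(Lc)
    if (any(ld <= 0)) return(-Inf)
    -N * sum(log(ld)) - 0.5 * sum(chol2inv(t(Lc)) * Su)
  }

  draw_mvn <- function(Q, b) {
    # draw from N(Q^-1 b, Q^-1)
    R <- chol(Q)
    m <- backsolve(R, backsolve(R, b, transpose = TRUE))
    m + backsolve(R, stats::rnorm(length(b)))
  }

  run_chain <- function(chain) {
    set.seed(derive_seed(seed, paste0("chain", chain)))
    # initialization: least squares + jittered variance params
    beta <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(0, pf))
    beta[is.na(beta)] <- 0
    beta <- beta + stats::rnorm(pf, 0, 0.05)
    sigma <- max(stats::sd(y - X %*% beta), 0.05) * exp(stats::rnorm(1, 0, 0.1))
    th_p <- c(log(rep(0.1, p)) + stats::rnorm(p, 0, 0.2), rep(0, q))
    th_i <- c(log(rep(0.1, p)) + stats::rnorm(p, 0, 0.2), rep(0, q))
    u_p <- matrix(0, np, p)
    u_i <- matrix(0, ni, p)

    total <- warmup + iter
    keep_beta <- matrix(NA_real_, iter, pf)
    keep_sigma <- numeric(iter)
    keep_tau <- matrix(NA_real_, iter, 2 * p)
    keep_cor <- matrix(NA_real_, iter, 2 * q)
    keep_uc <- matrix(NA_real_, iter, 1 + 2 * (p + q))

    for (t in seq_len(total)) {
      sig2 <- sigma^2
      Sp_chol <- sigma_chol(th_p)
      Si_chol <- sigma_chol(th_i)
      Sp_inv <- chol2inv(t(Sp_chol))
      Si_inv <- chol2inv(t(Si_chol))

      # participant effects
      fe <- drop(X %*% beta)
      r <- y - fe - rowSums(Z * u_i[iid, , drop = FALSE])
      Bp <- rowsum(Z * r, pid)
      for (j in seq_len(np)) {
        u_p[j, ] <- draw_mvn(Sp_inv + Cp[[j]] / sig2, Bp[j, ] / sig2)
      }

      # fixed effects, with the item random effects integrated out
      # analytically (block-diagonal Woodbury over items); the item
      # effects are redrawn from their full conditional further down,
      # keeping the partially collapsed scan valid
      r0 <- y - rowSums(Z * u_p[pid, , drop = FALSE])
      B0z <- rowsum(Z * r0, iid)
      B0x <- rowsum(X * r0, iid)
      Q <- prior_prec
      bvec <- prior_mb
      for (j in seq_len(ni)) {
        Rj <- chol(sig2 * Si_inv + Ci[[j]])
        W <- backsolve(Rj, backsolve(Rj, ZtXi[[j]], transpose = TRUE))
        Q <- Q + (XtXi[[j]] - crossprod(ZtXi[[j]], W)) / sig2
        bvec <- bvec + (B0x[j, ] - drop(crossprod(W, B0z[j, ]))) / sig2
      }
      beta <- draw_mvn(Q, bvec)

      # location sweep: move mass along the likelihood-invariant
      # direction (beta + delta, u_p - delta) to break the posterior
      # ridge between fixed effects and participant-effect means
      Qs <- np * Sp_inv[zidx, zidx, drop = FALSE] + prior_prec
      bs <- drop(Sp_inv %*% colSums(u_p))[zidx] -
        drop(prior_prec %*% (beta - prior$beta_mean))
      delta <- draw_mvn(Qs, bs)
      beta <- beta + delta
      u_p[, zidx] <- sweep(u_p[, zidx, drop = FALSE], 2, delta)

      # mean exchange between the random-effect blocks along the
      # likelihood-invariant direction (u_p + delta, u_i - delta);
      # without it, columns whose fixed effect is absent (reduced
      # models) mix slowly because the two blocks trade off their means
      Qd <- np * Sp_inv + ni * Si_inv
      bd <- drop(Si_inv %*% colSums(u_i)) - drop(Sp_inv %*% colSums(u_p))
      delta <- draw_mvn(Qd, bd)
      u_p <- sweep(u_p, 2, -delta)
      u_i <- sweep(u_i, 2, delta)

      # residual scale: slice on log sigma with the item effects
      # integrated out analytically (partially collapsed update; the
      # item blocks of the collapsed precision are block-diagonal).
      # The item effects are redrawn from their full conditional
      # immediately below, which keeps the scan valid.
      fe <- drop(X %*% beta)
      r_ni <- y - fe - rowSums(Z * u_p[pid, , drop = FALSE])
      Bi <- rowsum(Z * r_ni, iid)
      rss_ni <- sum(r_ni^2)
      logdet_Si <- 2 * sum(log(diag(Si_chol)))
      log_sigma <- slice_sample1(log(sigma), function(ls) {
        s2 <- exp(2 * ls)
        ld <- 0
        quad_corr <- 0
        for (j in seq_len(ni)) {
          Rj <- tryCatch(chol(s2 * Si_inv + Ci[[j]]), error = function(e) NULL)
          if (is.null(Rj)) return(-Inf)
          ld <- ld + 2 * sum(log(diag(Rj)))
          wj <- backsolve(Rj, backsolve(Rj, Bi[j, ], transpose = TRUE))
          quad_corr <- quad_corr + sum(Bi[j, ] * wj)
        }
        logdet_V <- 2 * (n - p * ni) * ls + ni * logdet_Si + ld
        s <- exp(ls)
        -0.5 * (logdet_V + (rss_ni - quad_corr) / s2) +
          dhalfnorm_log(s, prior$sigma_scale) + ls
      }, w = 0.3)
      sigma <- exp(log_sigma)
      sig2 <- sigma^2

      # item effects
      for (j in seq_len(ni)) {
        u_i[j, ] <- draw_mvn(Si_inv + Ci[[j]] / sig2, Bi[j, ] / sig2)
      }

      # second residual-scale update with the participant effects
      # integrated out (and redrawn after): collapsing each grouping
      # in turn breaks both sigma/random-effect couplings
      r_np <- y - fe - rowSums(Z * u_i[iid, , drop = FALSE])
      Bp2 <- rowsum(Z * r_np, pid)
      rss_np <- sum(r_np^2)
      logdet_Sp <- 2 * sum(log(diag(Sp_chol)))
      log_sigma <- slice_sample1(log(sigma), function(ls) {
        s2 <- exp(2 * ls)
        ld <- 0
        quad_corr <- 0
        for (j in seq_len(np)) {
          Rj <- tryCatch(chol(s2 * Sp_inv + Cp[[j]]), error = function(e) NULL)
          if (is.null(Rj)) return(-Inf)
          ld <- ld + 2 * sum(log(diag(Rj)))
          wj <- backsolve(Rj, backsolve(Rj, Bp2[j, ], transpose = TRUE))
          quad_corr <- quad_corr + sum(Bp2[j, ] * wj)
        }
        logdet_V <- 2 * (n - p * np) * ls + np * logdet_Sp + ld
        s <- exp(ls)
        -0.5 * (logdet_V + (rss_np - quad_corr) / s2) +
          dhalfnorm_log(s, prior$sigma_scale) + ls
      }, w = 0.3)
      sigma <- exp(log_sigma)
      sig2 <- sigma^2

      # participant effects redrawn from their full conditional
      for (j in seq_len(np)) {
        u_p[j, ] <- draw_mvn(Sp_inv + Cp[[j]] / sig2, Bp2[j, ] / sig2)
      }

      # covariance blocks: component-wise slice sampling on the
      # unconstrained scale (log SDs and atanh partial correlations)
      Su_p <- crossprod(u_p)
      post_p <- function(th) re_loglik(th, Su_p, np) +
        re_logprior(th, prior$re_sd_scale)
      for (j in seq_along(th_p)) {
        th_p[j] <- slice_sample1(th_p[j], function(v) {
          th <- th_p; th[j] <- v; post_p(th)
        }, w = 0.5)
      }

      Su_i <- crossprod(u_i)
      post_i <- function(th) re_loglik(th, Su_i, ni) +
        re_logprior(th, prior$re_sd_scale)
      for (j in seq_along(th_i)) {
        th_i[j] <- slice_sample1(th_i[j], function(v) {
          th <- th_i; th[j] <- v; post_i(th)
        }, w = 0.5)
      }

      if (t > warmup) {
        k <- t - warmup
        keep_beta[k, ] <- beta
        keep_sigma[k] <- sigma
        tau_p <- exp(th_p[seq_len(p)])
        tau_i <- exp(th_i[seq_len(p)])
        keep_tau[k, ] <- c(tau_p, tau_i)
        Rp <- tcrossprod(cpc_to_chol(tanh(th_p[p + seq_len(q)]), p))
        Ri <- tcrossprod(cpc_to_chol(tanh(th_i[p + seq_len(q)]), p))
        keep_cor[k, ] <- c(Rp[lower.tri(Rp)], Ri[lower.tri(Ri)])
        keep_uc[k, ] <- c(log(sigma), th_p, th_i)
      }
    }
    list(beta = keep_beta, sigma = keep_sigma, tau = keep_tau,
         cor = keep_cor, uc = keep_uc)
  }

  lapply(seq_len(chains), run_chain)
}
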