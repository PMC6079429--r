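# Independent oracles used across the suite. These deliberately share no
# code with the package: dense-covariance densities via explicit Cholesky,
# pair-enumeration Jaccard, a step-up BH reimplementation, and exhaustive
# signed-rank enumeration.

# Dense multivariate normal log density, explicit Cholesky.
dense_mvn_logpdf <- function(x, mu, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z * z))
}

cs_cov_dense <- function(n, sigma2, rho) {
  sigma2 * ((1 - rho) * diag(n) + rho * matrix(1, n, n))
}

# Dense log density of one probe vector (case block then control block)
# under one cluster's parameters.
dense_cluster_logpdf <- function(xc, xn, p) {
  dense_mvn_logpdf(xc, rep(p$mu_c, length(xc)),
                   cs_cov_dense(length(xc), p$sigma2_c, p$rho_c)) +
    dense_mvn_logpdf(xn, rep(p$mu_n, length(xn)),
                     cs_cov_dense(length(xn), p$sigma2_n, p$rho_n))
}

# Dense mixture log-likelihood and responsibilities for a dataset whose
# columns are cases first.
dense_mixture <- function(values, m_c, model) {
  G <- nrow(values)
  ld <- sapply(1:3, function(k) {
    p <- model$clusters[[k]]
    apply(values, 1, function(row)
      dense_cluster_logpdf(row[seq_len(m_c)], row[-seq_len(m_c)], p))
  })
  ld <- matrix(ld, nrow = G)
  lw <- sweep(ld, 2, log(model$pi), "+")
  mx <- apply(lw, 1, max)
  se <- exp(lw - mx)
  list(loglik = sum(mx + log(rowSums(se))), resp = se / rowSums(se))
}

# Pair-counting Jaccard by explicit enumeration of all probe pairs.
jaccard_enum <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
  }
  if (n11 + n10 + n01 == 0) 0 else n11 / (n11 + n10 + n01)
}

# Independent Benjamini-Hochberg step-up.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Exact two-sided signed-rank p by enumerating all sign patterns
# (no ties in |d| assumed).
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vnull <- signs %*% r
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(Vnull >= V), mean(Vnull <= V)))
}

# Small dataset of iid N(0,1) noise (null / plumbing tests).
make_noise_dataset <- function(G, m_c, m_n, seed) {
  set.seed(seed)
  expression_dataset(matrix(rnorm(G * (m_c + m_n)), nrow = G),
                     rep(c("case", "control"), c(m_c, m_n)))
}

# Hand-built dv_calls table for validation-workflow tests.
make_calls <- function(ids, dv, direction) {
  out <- data.frame(probe_id = ids,
                    label = ifelse(dv, ifelse(direction > 0, "OV", "UV"), "EV"),
                    dv = dv, direction = direction,
                    stringsAsFactors = FALSE)
  class(out) <- c("dv_calls", "data.frame")
  out
}

# Direct numerical MLE of a single exchangeable-normal block (dense
# likelihood, box-constrained quasi-Newton over mu, log sigma2, rho).
exchangeable_mle <- function(x_rows) {
  n <- ncol(x_rows)
  lo <- -1 / (n - 1) + 1e-6
  nll <- function(par) {
    S <- cs_cov_dense(n, exp(par[2]), par[3])
    -sum(apply(x_rows, 1, dense_mvn_logpdf, mu = rep(par[1], n), Sigma = S))
  }
  fit <- optim(c(mean(x_rows), log(var(as.vector(x_rows))), 0.05), nll,
               method = "L-BFGS-B",
               lower = c(-Inf, -20, lo), upper = c(Inf, 20, 0.999))
  list(mu = fit$par[1], sigma2 = exp(fit$par[2]), rho = fit$par[3])
}

# Direct numerical maximization of the dense-covariance mixture likelihood
# in the same constrained space as the package's model (EV shares one
# variance), started from a given model. Returns the optimized loglik.
polish_mixture_loglik <- function(values, m_c, m_n, model, maxit = 500) {
  # same feasible correlation region as the fitted model: a relative 1e-6
  # inside the positive-definite range, where the likelihood is bounded
  rho_box <- function(n) {
    lo <- -1 / (n - 1)
    c(lo + 1e-6 * (1 - lo), 1 - 1e-6 * (1 - lo))
  }
  lo_c <- rho_box(m_c)[1]; hi_c <- rho_box(m_c)[2]
  lo_n <- rho_box(m_n)[1]; hi_n <- rho_box(m_n)[2]
  pack <- function(m) c(
    log(pmax(m$pi[1:2], 1e-8) / max(m$pi[3], 1e-8)),
    unlist(lapply(m$clusters, function(p) c(p$mu_c, p$mu_n))),
    log(c(m$clusters[[1]]$sigma2_c, m$clusters[[1]]$sigma2_n,
          m$clusters[[2]]$sigma2_c,
          m$clusters[[3]]$sigma2_c, m$clusters[[3]]$sigma2_n)),
    vapply(m$clusters, function(p) p$rho_c, 0),
    vapply(m$clusters, function(p) p$rho_n, 0))
  unpack <- function(par) {
    pi <- exp(c(par[1:2], 0)); pi <- pi / sum(pi)
    mus <- matrix(par[3:8], 2)
    s2 <- exp(par[9:13])
    mk <- function(i, s2c, s2n) list(
      mu_c = mus[1, i], sigma2_c = s2c, rho_c = par[13 + i],
      mu_n = mus[2, i], sigma2_n = s2n, rho_n = par[16 + i])
    list(pi = pi, clusters = list(mk(1, s2[1], s2[2]),
                                  mk(2, s2[3], s2[3]),
                                  mk(3, s2[4], s2[5])))
  }
  nll <- function(par) -dense_mixture(values, m_c, unpack(par))$loglik
  opt <- optim(pack(model), nll, method = "L-BFGS-B",
               lower = c(rep(-Inf, 13), rep(lo_c, 3), rep(lo_n, 3)),
               upper = c(rep(Inf, 13), rep(hi_c, 3), rep(hi_n, 3)),
               control = list(maxit = maxit))
  -opt$value
}
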