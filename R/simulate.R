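# Generators for the four simulation scenarios (SimI-SimIV) with ground
# truth, and the packaged default generating parameters.

#' Default generating parameters for the simulation scenarios
#'
#' The mixture parameters estimated from a discovery cohort of 847 miRNAs
#' measured on hepatocellular-carcinoma tumor tissues (60 invasive cases vs
#' 60 noninvasive controls), used as the true values throughout the
#' simulation study: mixing proportions (0.31, 0.58, 0.11) for (OV, EV, UV)
#' and per-cluster (mean, variance, exchangeable correlation) per group.
#'
#' @param m_c,m_n Group sizes the model is declared for (defaults 50/50, the
#'   simulated design).
#'
#' @return A [mixture_model()] with clusters (OV, EV, UV).
#' @examples
#' default_params()$pi
#' @export
default_params <- function(m_c = 50L, m_n = 50L) {
  mixture_model(
    pi = c(0.31, 0.58, 0.11),
    clusters = list(
      cluster_params("OV", mu_c = -0.14, sigma2_c = 1.49, rho_c = 0.08,
                     mu_n = 0.14, sigma2_n = 0.45, rho_n = 0.32,
                     m_c = m_c, m_n = m_n),
      cluster_params("EV", mu_c = 0.03, sigma2_c = 1.01, rho_c = 0.04,
                     mu_n = -0.03, sigma2_n = 1.01, rho_n = 0.11,
                     m_c = m_c, m_n = m_n),
      cluster_params("UV", mu_c = 0.13, sigma2_c = 0.28, rho_c = 0.04,
                     mu_n = -0.13, sigma2_n = 1.69, rho_n = -0.01,
                     m_c = m_c, m_n = m_n)
    ),
    m_c = m_c, m_n = m_n
  )
}

#' Simulation scenario configuration
#'
#' SimI draws each probe's expression vector from its cluster's
#' block-exchangeable multivariate normal; SimII replaces the normal by a
#' multivariate t with `df` degrees of freedom (heavy tails); SimIII and
#' SimIV repeat SimI and SimII with all exchangeable correlations forced to
#' zero.
#'
#' @param scenario One of `"SimI"`, `"SimII"`, `"SimIII"`, `"SimIV"`.
#' @param G Number of probes (>= 3).
#' @param m_c,m_n Group sizes.
#' @param params Generating [mixture_model()]; defaults to
#'   [default_params()].
#' @param df Degrees of freedom for the t scenarios (default 3).
#' @param seed Random seed.
#' @param t_match For t scenarios, whether the normal covariance is used as
#'   the t's scale matrix (`"scale"`, default; the t's covariance is then
#'   `df/(df-2)` times larger) or matched as the t's covariance
#'   (`"covariance"`).
#'
#' @return An object of class `ScenarioConfig`.
#' @export
scenario_config <- function(scenario = c("SimI", "SimII", "SimIII", "SimIV"),
                            G = 1000L, m_c = 50L, m_n = 50L,
                            params = default_params(m_c, m_n),
                            df = 3, seed = 1L,
                            t_match = c("scale", "covariance")) {
  scenario <- match.arg(scenario)
  t_match <- match.arg(t_match)
  G <- as.integer(G)
  if (G < 3L) stop("G must be at least 3")
  if (scenario %in% c("SimII", "SimIV") && df <= 0)
    stop("df must be positive for t scenarios")
  if (scenario %in% c("SimIII", "SimIV")) {
    for (k in 1:3) {
      params$clusters[[k]]$rho_c <- 0
      params$clusters[[k]]$rho_n <- 0
    }
  }
  structure(
    list(scenario = scenario, G = G, m_c = as.integer(m_c),
         m_n = as.integer(m_n), params = params, df = df,
         seed = as.integer(seed), t_match = t_match),
    class = "ScenarioConfig"
  )
}

# Fixed cluster counts round(pi * G) with largest-remainder correction so
# they always sum to G.
cluster_counts <- function(pi, G) {
  n <- round(pi * G)
  d <- G - sum(n)
  if (d != 0) {
    rem <- pi * G - floor(pi * G)
    ord <- order(rem, decreasing = d > 0)
    for (i in seq_len(abs(d))) n[ord[i]] <- n[ord[i]] + sign(d)
  }
  as.integer(n)
}

cs_cov <- function(n, sigma2, rho) {
  sigma2 * ((1 - rho) * diag(n) + rho * matrix(1, n, n))
}

#' One draw from an exchangeable-covariance multivariate normal
#'
#' @param n Dimension (>= 1).
#' @param mu Common mean.
#' @param sigma2 Common variance, > 0.
#' @param rho Exchangeable correlation in `(-1/(n-1), 1)`; negative values
#'   within the range are supported.
#' @param seed Optional seed for this single draw.
#'
#' @return A numeric vector of length n.
#' @export
sample_exchangeable_block <- function(n, mu, sigma2, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 1L) return(stats::rnorm(1, mu, sqrt(sigma2)))
  check_cs_params(n, sigma2, rho)
  mu + drop(stats::rnorm(n) %*% chol(cs_cov(n, sigma2, rho)))
}

# G_k x (m_c + m_n) matrix of zero-mean block-exchangeable normal rows.
rmvn_block <- function(G_k, p, m_c, m_n) {
  zc <- matrix(stats::rnorm(G_k * m_c), G_k, m_c) %*%
    chol(cs_cov(m_c, p$sigma2_c, p$rho_c))
  zn <- matrix(stats::rnorm(G_k * m_n), G_k, m_n) %*%
    chol(cs_cov(m_n, p$sigma2_n, p$rho_n))
  cbind(zc, zn)
}

#' Simulate an expression dataset with known cluster membership
#'
#' Assigns exactly `round(pi_k * G)` probes to each cluster (largest
#' remainder correction if the rounded counts miss G), draws each probe's
#' case+control expression vector from the cluster's distribution, and
#' shuffles probe order so membership is not positional. For the t
#' scenarios each probe shares one chi-square mixing variable across its
#' whole vector (a classic multivariate t draw); by default the normal
#' covariance serves as the t's scale matrix.
#'
#' @param config A [scenario_config()].
#' @param labels Optional factor/character vector of OV/EV/UV memberships
#'   (length G) to reuse across datasets, e.g., for discovery/validation
#'   pairs sharing one truth; overrides the proportion-based assignment and
#'   disables the shuffle.
#'
#' @return A list with `data` (an [expression_dataset()], columns cases
#'   first) and `truth` (class `SimulationTruth`: `labels`, a factor of
#'   true OV/EV/UV memberships aligned with `data$probe_ids`, and `config`).
#' @examples
#' sim <- simulate_dataset(scenario_config("SimI", G = 100, seed = 1))
#' table(sim$truth$labels)
#' @export
simulate_dataset <- function(config, labels = NULL) {
  stopifnot(inherits(config, "ScenarioConfig"))
  set.seed(config$seed)
  G <- config$G
  m_c <- config$m_c
  m_n <- config$m_n
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != G || !all(labels %in% CLUSTER_KINDS))
      stop("labels must be G OV/EV/UV values")
    fixed_order <- order(factor(labels, levels = CLUSTER_KINDS))
    counts <- as.integer(table(factor(labels, levels = CLUSTER_KINDS)))
  } else {
    fixed_order <- NULL
    counts <- cluster_counts(config$params$pi, G)
    labels <- rep(CLUSTER_KINDS, counts)
  }
  heavy <- config$scenario %in% c("SimII", "SimIV")
  x <- matrix(NA_real_, G, m_c + m_n)
  row0 <- 0L
  for (k in 1:3) {
    if (counts[k] == 0L) next
    p <- config$params$clusters[[k]]
    if (heavy && config$t_match == "covariance") {
      shrink <- (config$df - 2) / config$df
      if (shrink <= 0)
        stop("covariance matching requires df > 2")
      p$sigma2_c <- p$sigma2_c * shrink
      p$sigma2_n <- p$sigma2_n * shrink
    }
    z <- rmvn_block(counts[k], p, m_c, m_n)
    if (heavy) z <- z * sqrt(config$df / stats::rchisq(counts[k], config$df))
    mu <- rep(c(p$mu_c, p$mu_n), times = c(m_c, m_n))
    x[row0 + seq_len(counts[k]), ] <- sweep(z, 2, mu, "+")
    row0 <- row0 + counts[k]
  }
  if (!is.null(fixed_order)) {
    x[fixed_order, ] <- x  # back to the caller's label positions
  } else {
    ord <- sample.int(G)
    x <- x[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  data <- expression_dataset(
    x,
    group = rep(c("case", "control"), times = c(m_c, m_n)),
    probe_ids = sprintf("probe_%04d", seq_len(G))
  )
  colnames(data$values) <- c(paste0("case_", seq_len(m_c)),
                             paste0("control_", seq_len(m_n)))
  truth <- structure(
    list(labels = factor(labels, levels = CLUSTER_KINDS), config = config),
    class = "SimulationTruth"
  )
  list(data = data, truth = truth)
}
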