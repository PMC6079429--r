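# Core data containers and exact evaluation of the structured
# multivariate-normal cluster densities and mixture posteriors.

CLUSTER_KINDS <- c("OV", "EV", "UV")

#' Expression dataset with two-group design
#'
#' Bundles a probe-by-sample expression matrix with a two-level group label
#' (case/control) per sample. Rows are probes (e.g., miRNAs), columns are
#' subjects. This is the input container for the mixture clustering and the
#' probe-wise baselines.
#'
#' @param values Numeric matrix, G probes x m samples; all entries finite.
#' @param group Character or factor of length `ncol(values)` with values
#'   `"case"` or `"control"`. Each group needs at least 2 samples.
#' @param probe_ids Unique probe identifiers; defaults to `rownames(values)`
#'   or `probe_1 ... probe_G`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `group` (factor with levels case, control), `probe_ids`,
#'   `m_c`, `m_n`.
#' @examples
#' x <- matrix(rnorm(40), nrow = 4)
#' d <- expression_dataset(x, rep(c("case", "control"), each = 5))
#' d$m_c
#' @export
expression_dataset <- function(values, group, probe_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("expression values must be a finite numeric matrix")
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("length(group) must equal ncol(values)")
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  group <- factor(group, levels = c("case", "control"))
  m_c <- sum(group == "case")
  m_n <- sum(group == "control")
  if (m_c < 2L || m_n < 2L)
    stop("each group needs at least 2 samples (got ", m_c, " cases, ",
         m_n, " controls)")
  if (is.null(probe_ids)) probe_ids <- rownames(values)
  if (is.null(probe_ids)) probe_ids <- paste0("probe_", seq_len(nrow(values)))
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) != nrow(values))
    stop("probe_ids length must equal nrow(values)")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  rownames(values) <- probe_ids
  structure(
    list(values = values, group = group, probe_ids = probe_ids,
         m_c = m_c, m_n = m_n),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "probes x",
      ncol(x$values), "samples (", x$m_c, "cases,", x$m_n, "controls )\n")
  invisible(x)
}

# Column indices of the case / control blocks.
group_index <- function(data) {
  list(case = which(data$group == "case"),
       control = which(data$group == "control"))
}

# rho must keep sigma2 * [(1-rho) I + rho J] positive definite:
# -1/(n-1) < rho < 1 (any rho for n = 1, where it is irrelevant).
rho_lower <- function(n) if (n <= 1L) -Inf else -1 / (n - 1)

check_cs_params <- function(n, sigma2, rho) {
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("sigma2 must be a positive finite number")
  if (n > 1L && (!is.finite(rho) || rho <= rho_lower(n) || rho >= 1))
    stop("rho = ", rho, " outside the positive-definite range (",
         signif(rho_lower(n), 4), ", 1) for n = ", n)
  invisible(TRUE)
}

#' Per-cluster parameters with a variance-order constraint
#'
#' One cluster of the mixture is parameterized by a mean, variance, and
#' exchangeable (compound-symmetry) correlation per group. The `kind` tag
#' encodes the variance relation between cases and controls: `"OV"` requires
#' `sigma2_c > sigma2_n`, `"UV"` requires `sigma2_c < sigma2_n`, and `"EV"`
#' requires equality (means and correlations stay free in all three).
#'
#' @param kind One of `"OV"`, `"EV"`, `"UV"`.
#' @param mu_c,sigma2_c,rho_c Case mean, variance (> 0), and exchangeable
#'   correlation.
#' @param mu_n,sigma2_n,rho_n Control counterparts.
#' @param m_c,m_n Optional group sizes; when supplied, the correlations are
#'   checked against the positive-definiteness bound `-1/(m-1) < rho < 1`.
#'
#' @return An object of class `ClusterParams`.
#' @export
cluster_params <- function(kind, mu_c, sigma2_c, rho_c, mu_n, sigma2_n, rho_n,
                           m_c = NULL, m_n = NULL) {
  kind <- match.arg(kind, CLUSTER_KINDS)
  if (sigma2_c <= 0 || sigma2_n <= 0)
    stop("variances must be positive")
  if (!is.null(m_c)) check_cs_params(m_c, sigma2_c, rho_c)
  if (!is.null(m_n)) check_cs_params(m_n, sigma2_n, rho_n)
  if (kind == "OV" && !(sigma2_c > sigma2_n))
    stop("OV cluster requires sigma2_c > sigma2_n")
  if (kind == "UV" && !(sigma2_c < sigma2_n))
    stop("UV cluster requires sigma2_c < sigma2_n")
  if (kind == "EV" && abs(sigma2_c - sigma2_n) > 1e-8 * max(sigma2_c, sigma2_n))
    stop("EV cluster requires sigma2_c == sigma2_n")
  structure(
    list(kind = kind, mu_c = mu_c, sigma2_c = sigma2_c, rho_c = rho_c,
         mu_n = mu_n, sigma2_n = sigma2_n, rho_n = rho_n),
    class = "ClusterParams"
  )
}

#' Three-component mixture model for OV/EV/UV clustering
#'
#' Mixing proportions plus the three cluster parameter sets, in the fixed
#' order (OV, EV, UV) so that component 1 always means over-variability in
#' cases.
#'
#' @param pi Numeric 3-vector of mixing proportions; non-negative, summing
#'   to 1.
#' @param clusters List of three `ClusterParams` with kinds OV, EV, UV in
#'   that order.
#' @param m_c,m_n Group sizes the model is defined for.
#'
#' @return An object of class `MixtureModel`.
#' @export
mixture_model <- function(pi, clusters, m_c, m_n) {
  pi <- as.numeric(pi)
  if (length(pi) != 3L || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be 3 non-negative proportions summing to 1")
  if (length(clusters) != 3L ||
      !all(vapply(clusters, inherits, logical(1), "ClusterParams")))
    stop("clusters must be a list of three ClusterParams")
  kinds <- vapply(clusters, `[[`, character(1), "kind")
  if (!identical(kinds, CLUSTER_KINDS))
    stop("cluster kinds must be (OV, EV, UV) in that order")
  structure(
    list(pi = pi, clusters = clusters, m_c = m_c, m_n = m_n),
    class = "MixtureModel"
  )
}

#' @export
print.MixtureModel <- function(x, ...) {
  cat("MixtureModel (OV/EV/UV), m_c =", x$m_c, ", m_n =", x$m_n, "\n")
  for (k in 1:3) {
    p <- x$clusters[[k]]
    cat(sprintf(
      "  %s: pi=%.3f  case(mu=%.3f, s2=%.3f, rho=%.3f)  control(mu=%.3f, s2=%.3f, rho=%.3f)\n",
      p$kind, x$pi[k], p$mu_c, p$sigma2_c, p$rho_c, p$mu_n, p$sigma2_n, p$rho_n))
  }
  invisible(x)
}

#' Log density of an exchangeable-covariance multivariate normal
#'
#' Evaluates the log density of \eqn{N(\mu 1, \sigma^2[(1-\rho)I + \rho J])}
#' at a vector `x` in O(n) using the two distinct eigenvalues of the
#' compound-symmetry covariance, \eqn{\lambda_1 = \sigma^2(1-\rho)}
#' (multiplicity n-1) and \eqn{\lambda_2 = \sigma^2(1+(n-1)\rho)}:
#' with \eqn{W = \sum_j (x_j - \bar x)^2} and \eqn{B = n(\bar x - \mu)^2},
#' \deqn{\log f = -\tfrac12[n\log(2\pi) + (n-1)\log\lambda_1 + \log\lambda_2
#'   + W/\lambda_1 + B/\lambda_2].}
#'
#' @param x Numeric vector (length n >= 1), finite.
#' @param mu Common mean.
#' @param sigma2 Common variance, > 0.
#' @param rho Exchangeable correlation, `-1/(n-1) < rho < 1`; ignored for
#'   n = 1.
#'
#' @return The log density (scalar).
#' @examples
#' cs_mvn_logpdf(c(0.3, -0.7, 1.1), mu = 0.1, sigma2 = 2, rho = 0.5)
#' @export
cs_mvn_logpdf <- function(x, mu, sigma2, rho) {
  if (!is.numeric(x) || length(x) < 1L || !all(is.finite(x)))
    stop("x must be a finite numeric vector")
  n <- length(x)
  if (n == 1L) rho <- 0
  check_cs_params(n, sigma2, rho)
  xbar <- mean(x)
  W <- sum((x - xbar)^2)
  cs_logpdf_stats(n, xbar, W, mu, sigma2, rho)
}

# Vectorized over probes: xbar and W are vectors of per-probe group means
# and within-group sums of squares. lambda floors guard degenerate M-step
# outputs without affecting well-conditioned inputs.
cs_logpdf_stats <- function(n, xbar, W, mu, sigma2, rho) {
  if (n == 1L) rho <- 0
  lam1 <- max(sigma2 * (1 - rho), 1e-12)
  lam2 <- max(sigma2 * (1 + (n - 1) * rho), 1e-12)
  B <- n * (xbar - mu)^2
  -0.5 * (n * log(2 * pi) + (n - 1) * log(lam1) + log(lam2) +
            W / lam1 + B / lam2)
}

#' Per-cluster log density of a probe's expression vector
#'
#' Cases and controls are independent, so the cluster log density is the sum
#' of two exchangeable-normal log densities, one per group block.
#'
#' @param x Numeric vector of length `m_c + m_n`: the case block first, then
#'   the control block.
#' @param params A [cluster_params()] object.
#' @param m_c,m_n Number of case / control entries in `x`.
#'
#' @return The cluster log density \eqn{\log f_k(x)}.
#' @export
cluster_logpdf <- function(x, params, m_c, m_n) {
  if (length(x) != m_c + m_n)
    stop("x has length ", length(x), " but m_c + m_n = ", m_c + m_n)
  cs_mvn_logpdf(x[seq_len(m_c)], params$mu_c, params$sigma2_c, params$rho_c) +
    cs_mvn_logpdf(x[m_c + seq_len(m_n)], params$mu_n, params$sigma2_n,
                  params$rho_n)
}

# Per-probe sufficient statistics for the compound-symmetry likelihood:
# group means and within-group sums of squares. The whole likelihood
# depends on the data only through these, so they are computed once per
# dataset and reused across EM iterations.
suff_stats <- function(data) {
  idx <- group_index(data)
  xc <- data$values[, idx$case, drop = FALSE]
  xn <- data$values[, idx$control, drop = FALSE]
  mean_c <- rowMeans(xc)
  mean_n <- rowMeans(xn)
  list(
    mean_c = mean_c, W_c = rowSums((xc - mean_c)^2),
    mean_n = mean_n, W_n = rowSums((xn - mean_n)^2),
    m_c = data$m_c, m_n = data$m_n, G = nrow(data$values)
  )
}

# G x 3 matrix of per-cluster log densities from precomputed stats.
cluster_logdens_matrix <- function(ss, model) {
  ld <- vapply(1:3, function(k) {
    p <- model$clusters[[k]]
    cs_logpdf_stats(ss$m_c, ss$mean_c, ss$W_c, p$mu_c, p$sigma2_c, p$rho_c) +
      cs_logpdf_stats(ss$m_n, ss$mean_n, ss$W_n, p$mu_n, p$sigma2_n, p$rho_n)
  }, numeric(ss$G))
  matrix(ld, nrow = ss$G, ncol = 3L)
}

#' Posterior cluster membership probabilities
#'
#' For probe g and cluster k, the responsibility is
#' \eqn{p_{gk} = \pi_k f_k(x_g) / \sum_j \pi_j f_j(x_g)}, computed in log
#' space with log-sum-exp so that small densities do not underflow.
#'
#' @param data An [expression_dataset()].
#' @param model A [mixture_model()] whose `m_c`, `m_n` match the data.
#'
#' @return A G x 3 matrix with rows summing to 1, columns OV, EV, UV.
#' @export
posterior_probs <- function(data, model) {
  if (model$m_c != data$m_c || model$m_n != data$m_n)
    stop("model group sizes do not match the dataset")
  ss <- suff_stats(data)
  posterior_from_logdens(cluster_logdens_matrix(ss, model), model$pi,
                         data$probe_ids)$resp
}

posterior_from_logdens <- function(logdens, pi, probe_ids = NULL) {
  logw <- sweep(logdens, 2, log(pmax(pi, 0)), "+")  # -Inf where pi = 0
  mx <- apply(logw, 1, max)
  if (any(!is.finite(mx))) {
    bad <- which(!is.finite(mx))[1]
    id <- if (is.null(probe_ids)) bad else probe_ids[bad]
    stop("all cluster densities vanished for probe ", id)
  }
  se <- exp(logw - mx)
  rs <- rowSums(se)
  list(resp = se / rs, loglik = sum(mx + log(rs)))
}
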