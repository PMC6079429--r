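# Constrained EM estimation of the three-component mixture and
# posterior-probability cluster assignment (the "gs" detector).

# Internal non-validating ClusterParams constructor: during EM the OV/UV
# inequality constraints may be transiently violated; they are restored by
# the end-of-run repair step.
cp_raw <- function(kind, mu_c, sigma2_c, rho_c, mu_n, sigma2_n, rho_n) {
  structure(
    list(kind = kind, mu_c = mu_c, sigma2_c = sigma2_c, rho_c = rho_c,
         mu_n = mu_n, sigma2_n = sigma2_n, rho_n = rho_n),
    class = "ClusterParams"
  )
}

#' EM fitting configuration
#'
#' @param tol Relative log-likelihood convergence tolerance
#'   (`|delta ll| / (|ll| + 1) < tol` stops the iteration).
#' @param max_iter Iteration cap per start.
#' @param n_starts Number of initializations; the first is the deterministic
#'   variance-ratio start, the rest perturb its variances.
#' @param seed Base random seed (start s uses `seed + s - 1`).
#' @param init_method `"variance-ratio"` (default) or `"random"`; `"random"`
#'   perturbs even the first start.
#'
#' @return An object of class `FitConfig`.
#' @export
fit_config <- function(tol = 1e-8, max_iter = 2000L, n_starts = 5L,
                       seed = 1L, init_method = c("variance-ratio", "random")) {
  init_method <- match.arg(init_method)
  stopifnot(tol > 0, max_iter >= 1, n_starts >= 1)
  structure(
    list(tol = tol, max_iter = as.integer(max_iter),
         n_starts = as.integer(n_starts), seed = as.integer(seed),
         init_method = init_method),
    class = "FitConfig"
  )
}

# Feasible correlation interval, pulled a relative 1e-6 inside the
# positive-definite range: the likelihood diverges as the exchangeable
# covariance becomes singular at either end, so the boundary itself is
# excluded from the parameter space.
rho_bounds <- function(n) {
  lo <- max(rho_lower(n), -1)
  eps <- 1e-6 * (1 - lo)
  c(lo + eps, 1 - eps)
}

clamp_rho <- function(rho, n) {
  b <- rho_bounds(n)
  min(max(rho, b[1]), b[2])
}

# Weighted closed-form update for one group block of one cluster, from the
# two-eigenvalue decomposition of the exchangeable covariance:
#   lam1-hat = sum p W / ((n-1) sum p),  lam2-hat = sum p B / sum p,
#   sigma2 = ((n-1) lam1 + lam2)/n,     rho = 1 - lam1/sigma2.
# When the interior rho estimate falls outside the positive-definite range
# (common at small n), rho is pinned to the boundary and sigma2 recomputed
# as the conditional maximizer given that rho, so the M step still
# maximizes the expected log-likelihood over the feasible region.
group_update <- function(p, xbar, W, n) {
  P <- sum(p)
  mu <- sum(p * xbar) / P
  SW <- sum(p * W)
  SB <- sum(p * n * (xbar - mu)^2)
  lam1 <- max(SW / ((n - 1) * P), 1e-12)
  lam2 <- max(SB / P, 1e-12)
  sigma2 <- ((n - 1) * lam1 + lam2) / n
  rho <- 1 - lam1 / sigma2
  rho_b <- clamp_rho(rho, n)
  if (rho_b != rho) {
    rho <- rho_b
    sigma2 <- max((SW / (1 - rho) + SB / (1 + (n - 1) * rho)) / (n * P),
                  1e-12)
  }
  list(mu = mu, sigma2 = sigma2, rho = rho, SW = SW, SB = SB, P = P)
}

# Expected log-likelihood contribution of one group block, as a function of
# (sigma2, rho), given the weighted sufficient statistics.
group_Q <- function(P, SW, SB, n, sigma2, rho) {
  lam1 <- max(sigma2 * (1 - rho), 1e-12)
  lam2 <- max(sigma2 * (1 + (n - 1) * rho), 1e-12)
  -0.5 * (P * n * log(2 * pi) + P * (n - 1) * log(lam1) + P * log(lam2) +
            SW / lam1 + SB / lam2)
}

# EV cluster update: one shared sigma2 across groups, free rho per group.
# Means are profiled out in closed form (the GLS mean under compound
# symmetry is the plain group mean, so the weighted mean is exact). For a
# trial sigma2 each rho is maximized on its bounded interval, and the
# profiled objective is maximized over log sigma2 by bounded 1-D search
# bracketing the pooled closed-form start. Nested bounded searches avoid
# the likelihood ridge (sigma2 -> Inf, rho -> 1 with lambda1 fixed) that an
# unconstrained multivariate search can wander onto.
profile_rho <- function(P, SW, SB, n, sigma2) {
  stats::optimize(function(r) group_Q(P, SW, SB, n, sigma2, r),
                  rho_bounds(n), maximum = TRUE, tol = 1e-10)
}

ev_update <- function(uc, un, m_c, m_n) {
  s2_0 <- (m_c * uc$sigma2 + m_n * un$sigma2) / (m_c + m_n)
  prof <- function(ls2) {
    s2 <- exp(ls2)
    profile_rho(uc$P, uc$SW, uc$SB, m_c, s2)$objective +
      profile_rho(un$P, un$SW, un$SB, m_n, s2)$objective
  }
  ls2 <- stats::optimize(prof, log(s2_0) + c(-6, 6), maximum = TRUE,
                         tol = 1e-9)$maximum
  s2 <- exp(ls2)
  list(sigma2 = s2,
       rho_c = clamp_rho(profile_rho(uc$P, uc$SW, uc$SB, m_c, s2)$maximum, m_c),
       rho_n = clamp_rho(profile_rho(un$P, un$SW, un$SB, m_n, s2)$maximum, m_n))
}

m_step_ss <- function(ss, resp, prev = NULL) {
  G <- ss$G
  if (!is.matrix(resp) || nrow(resp) != G || ncol(resp) != 3L)
    stop("responsibilities must be a ", G, " x 3 matrix")
  pi_new <- colSums(resp) / G
  clusters <- vector("list", 3L)
  for (k in 1:3) {
    p <- resp[, k]
    if (sum(p) < 1e-8) {
      if (is.null(prev))
        stop("cluster ", CLUSTER_KINDS[k],
             " has vanishing total responsibility and no previous parameters")
      warning("cluster ", CLUSTER_KINDS[k],
              " starved (total responsibility < 1e-8); keeping previous parameters")
      clusters[[k]] <- prev$clusters[[k]]
      next
    }
    uc <- group_update(p, ss$mean_c, ss$W_c, ss$m_c)
    un <- group_update(p, ss$mean_n, ss$W_n, ss$m_n)
    if (k == 2L) {
      ev <- ev_update(uc, un, ss$m_c, ss$m_n)
      clusters[[k]] <- cp_raw("EV", uc$mu, ev$sigma2, ev$rho_c,
                              un$mu, ev$sigma2, ev$rho_n)
    } else {
      clusters[[k]] <- cp_raw(CLUSTER_KINDS[k], uc$mu, uc$sigma2, uc$rho,
                              un$mu, un$sigma2, un$rho)
    }
  }
  structure(list(pi = pi_new, clusters = clusters, m_c = ss$m_c, m_n = ss$m_n),
            class = "MixtureModel")
}

#' One M step of the constrained EM
#'
#' Given responsibilities, re-estimates mixing proportions and all cluster
#' parameters. OV and UV use the exact weighted closed forms from the
#' two-eigenvalue decomposition; the EV cluster is refit under the shared
#' variance constraint by numerical maximization. OV/UV inequality
#' constraints are not projected here (see [fit_mixture()] for the
#' end-of-run repair).
#'
#' @param data An [expression_dataset()].
#' @param responsibilities G x 3 matrix, rows summing to 1.
#' @param prev Previous `MixtureModel`, used to carry a starved cluster.
#'
#' @return A `MixtureModel` (constraints possibly transiently violated).
#' @export
m_step <- function(data, responsibilities, prev = NULL) {
  m_step_ss(suff_stats(data), responsibilities, prev)
}

#' One E step: responsibilities and observed-data log-likelihood
#'
#' @param data An [expression_dataset()].
#' @param model A `MixtureModel` for the same group sizes.
#'
#' @return A list with `responsibilities` (G x 3) and `loglik`
#'   (\eqn{\sum_g \log \sum_k \pi_k f_k(x_g)}).
#' @export
e_step <- function(data, model) {
  ss <- suff_stats(data)
  out <- posterior_from_logdens(cluster_logdens_matrix(ss, model), model$pi,
                                data$probe_ids)
  list(responsibilities = out$resp, loglik = out$loglik)
}

# Hard-label moment start from per-probe log variance ratios: top quartile
# OV, bottom quartile UV, middle EV.
init_from_ratio <- function(ss) {
  s2c <- ss$W_c / (ss$m_c - 1)
  s2n <- ss$W_n / (ss$m_n - 1)
  r <- log(pmax(s2c, 1e-12) / pmax(s2n, 1e-12))
  if (diff(range(r)) < 1e-10 || ss$G < 12L) return(init_fallback(ss))
  qs <- stats::quantile(r, c(0.25, 0.75), names = FALSE)
  lab <- ifelse(r >= qs[2], 1L, ifelse(r <= qs[1], 3L, 2L))
  if (any(tabulate(lab, 3L) < 1L)) return(init_fallback(ss))
  resp <- matrix(0, ss$G, 3L)
  resp[cbind(seq_len(ss$G), lab)] <- 1
  m_step_ss(ss, resp)
}

# Degenerate-input fallback: global moments with case variances scaled by
# (1.5, 1, 0.67) for (OV, EV, UV) and an EV-dominant prior.
init_fallback <- function(ss) {
  uc <- group_update(rep(1, ss$G), ss$mean_c, ss$W_c, ss$m_c)
  un <- group_update(rep(1, ss$G), ss$mean_n, ss$W_n, ss$m_n)
  s2 <- (ss$m_c * uc$sigma2 + ss$m_n * un$sigma2) / (ss$m_c + ss$m_n)
  mk <- function(kind, f) cp_raw(kind, uc$mu, f * s2, uc$rho,
                                 un$mu, s2, un$rho)
  structure(
    list(pi = c(0.05, 0.90, 0.05),
         clusters = list(mk("OV", 1.5), mk("EV", 1.0), mk("UV", 0.67)),
         m_c = ss$m_c, m_n = ss$m_n),
    class = "MixtureModel"
  )
}

perturb_variances <- function(model) {
  for (k in 1:3) {
    f <- exp(stats::runif(2, -0.2, 0.2))
    model$clusters[[k]]$sigma2_c <- model$clusters[[k]]$sigma2_c * f[1]
    model$clusters[[k]]$sigma2_n <- model$clusters[[k]]$sigma2_n *
      if (k == 2L) f[1] else f[2]
  }
  model
}

#' Initialize the mixture from per-probe variance ratios
#'
#' Labels the top quartile of per-probe log variance ratios
#' \eqn{\log(s_c^2/s_n^2)} as OV, the bottom quartile as UV, and the middle
#' half as EV, then sets each cluster's parameters by the weighted moment
#' closed forms over its labeled probes. Degenerate inputs (all ratios
#' equal, or too few probes) fall back to global moments with case
#' variances scaled by (1.5, 1, 0.67) and an EV-dominant prior.
#'
#' @param data An [expression_dataset()] with at least 3 probes.
#' @param config A [fit_config()]; `init_method = "random"` multiplies the
#'   variances by `exp(U(-0.2, 0.2))` after the moment start.
#'
#' @return A `MixtureModel` start value.
#' @export
init_mixture <- function(data, config = fit_config()) {
  if (nrow(data$values) < 3L) stop("need at least 3 probes to initialize")
  ss <- suff_stats(data)
  model <- init_from_ratio(ss)
  if (config$init_method == "random") {
    set.seed(config$seed)
    model <- perturb_variances(model)
  }
  model
}

# Order clusters by case/control variance ratio (largest -> OV, smallest ->
# UV); if a reorder happened, refit the middle cluster under the EV equality
# constraint using the (permuted) responsibilities; finally nudge any
# still-degenerate OV/UV inequality by a 1e-6 relative margin so the
# returned parameters satisfy their declared constraints.
repair_model <- function(model, ss, resp) {
  ratio <- vapply(model$clusters, function(p) p$sigma2_c / p$sigma2_n,
                  numeric(1))
  ord <- order(ratio, decreasing = TRUE)
  relabeled <- !identical(ord, 1:3)
  if (relabeled) {
    model$clusters <- model$clusters[ord]
    model$pi <- model$pi[ord]
    resp <- resp[, ord, drop = FALSE]
    for (k in 1:3) model$clusters[[k]]$kind <- CLUSTER_KINDS[k]
    if (sum(resp[, 2]) >= 1e-8) {
      uc <- group_update(resp[, 2], ss$mean_c, ss$W_c, ss$m_c)
      un <- group_update(resp[, 2], ss$mean_n, ss$W_n, ss$m_n)
      ev <- ev_update(uc, un, ss$m_c, ss$m_n)
      model$clusters[[2]] <- cp_raw("EV", uc$mu, ev$sigma2, ev$rho_c,
                                    un$mu, ev$sigma2, ev$rho_n)
    }
  }
  ov <- model$clusters[[1]]; uv <- model$clusters[[3]]
  if (ov$sigma2_c <= ov$sigma2_n)
    model$clusters[[1]]$sigma2_c <- ov$sigma2_n * (1 + 1e-6)
  if (uv$sigma2_c >= uv$sigma2_n)
    model$clusters[[3]]$sigma2_c <- uv$sigma2_n / (1 + 1e-6)
  ev <- model$clusters[[2]]
  model$clusters[[2]]$sigma2_n <- ev$sigma2_c
  attr(model, "relabeled") <- relabeled
  model
}

em_run <- function(ss, model, tol, max_iter, probe_ids) {
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    out <- posterior_from_logdens(cluster_logdens_matrix(ss, model), model$pi,
                                  probe_ids)
    resp <- out$resp
    trace <- c(trace, out$loglik)
    if (abs(out$loglik - prev_ll) / (abs(out$loglik) + 1) < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- out$loglik
    model <- m_step_ss(ss, resp, model)
  }
  list(model = model, resp = resp, trace = trace, converged = converged,
       n_iter = length(trace))
}

#' Fit the OV/EV/UV mixture by EM ("gs")
#'
#' Alternates E and M steps from one or more initializations until the
#' relative log-likelihood change drops below `tol`, keeps the restart with
#' the highest final log-likelihood, repairs the variance-order constraints
#' (relabeling by variance ratio if needed), and recomputes posteriors under
#' the repaired model.
#'
#' @param data An [expression_dataset()].
#' @param config A [fit_config()].
#'
#' @return An object of class `dv_fit`: `model` (constraint-satisfying
#'   `MixtureModel`), `responsibilities` (G x 3), `assignments` (factor
#'   OV/EV/UV), `loglik` (final), `loglik_trace` (per EM iteration of the
#'   winning start; non-decreasing), `converged`, `n_iter`, `relabeled`
#'   (whether the end-of-run repair had to reorder clusters), `seed`.
#' @examples
#' sim <- simulate_dataset(scenario_config("SimI", G = 120, seed = 7))
#' fit <- fit_mixture(sim$data, fit_config(n_starts = 2, seed = 7))
#' table(fit$assignments)
#' @export
fit_mixture <- function(data, config = fit_config()) {
  ss <- suff_stats(data)
  base <- init_from_ratio(ss)
  best <- NULL
  for (s in seq_len(config$n_starts)) {
    model0 <- base
    if (s > 1L || config$init_method == "random") {
      set.seed(config$seed + s - 1L)
      model0 <- perturb_variances(model0)
    }
    run <- em_run(ss, model0, config$tol, config$max_iter, data$probe_ids)
    if (is.null(best) || run$trace[run$n_iter] > best$trace[best$n_iter])
      best <- run
  }
  if (!best$converged)
    warning("EM did not converge in ", config$max_iter, " iterations")
  model <- repair_model(best$model, ss, best$resp)
  out <- posterior_from_logdens(cluster_logdens_matrix(ss, model), model$pi,
                                data$probe_ids)
  resp <- out$resp
  dimnames(resp) <- list(data$probe_ids, CLUSTER_KINDS)
  structure(
    list(model = model, responsibilities = resp,
         assignments = assign_clusters(resp),
         loglik = out$loglik, loglik_trace = best$trace,
         converged = best$converged, n_iter = best$n_iter,
         relabeled = isTRUE(attr(model, "relabeled")),
         seed = config$seed),
    class = "dv_fit"
  )
}

#' @export
print.dv_fit <- function(x, ...) {
  cat("dvmix EM fit:", nrow(x$responsibilities), "probes; loglik",
      format(x$loglik), if (x$converged) "(converged" else "(NOT converged",
      "in", x$n_iter, "iterations)\n")
  print(table(x$assignments))
  invisible(x)
}

#' Assign probes to clusters by maximum posterior probability
#'
#' Ties are broken toward the lowest cluster index (OV before EV before UV).
#'
#' @param responsibilities G x 3 matrix of posterior probabilities.
#'
#' @return Factor of length G with levels OV, EV, UV.
#' @export
assign_clusters <- function(responsibilities) {
  responsibilities <- as.matrix(responsibilities)
  if (ncol(responsibilities) != 3L)
    stop("responsibilities must have 3 columns")
  k <- max.col(responsibilities, ties.method = "first")
  factor(CLUSTER_KINDS[k], levels = CLUSTER_KINDS)
}

#' Detect differentially variable probes with the mixture ("gs") method
#'
#' Fits the mixture, assigns each probe to OV/EV/UV by maximum posterior
#' probability, flags OV and UV probes as differentially variable (DV), and
#' records the direction of the sample-variance difference.
#'
#' @param data An [expression_dataset()].
#' @param config A [fit_config()].
#'
#' @return A `dv_calls` data frame with columns `probe_id`, `label`
#'   (OV/EV/UV), `dv` (logical), `direction` (sign of \eqn{s_c^2 - s_n^2});
#'   the fit is attached as attribute `"fit"` and the method name as
#'   `"method"`.
#' @export
detect_dv <- function(data, config = fit_config()) {
  fit <- fit_mixture(data, config)
  ss <- suff_stats(data)
  s2c <- ss$W_c / (ss$m_c - 1)
  s2n <- ss$W_n / (ss$m_n - 1)
  out <- data.frame(
    probe_id = data$probe_ids,
    label = fit$assignments,
    dv = fit$assignments != "EV",
    direction = sign(s2c - s2n),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("dv_calls", "data.frame")
  attr(out, "fit") <- fit
  attr(out, "method") <- "gs"
  out
}
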