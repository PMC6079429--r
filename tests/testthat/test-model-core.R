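# Exchangeable-normal densities and mixture posteriors.

test_that("cs_mvn_logpdf reduces to the univariate and independent cases", {
  expect_equal(cs_mvn_logpdf(0, mu = 0, sigma2 = 1, rho = 0.7),
               dnorm(0, log = TRUE))
  expect_equal(cs_mvn_logpdf(c(1, -1), mu = 0, sigma2 = 1, rho = 0),
               sum(dnorm(c(1, -1), log = TRUE)))
  expect_equal(cs_mvn_logpdf(c(1, -1), mu = 0, sigma2 = 1, rho = 0),
               -(log(2 * pi) + 1))
})

test_that("cs_mvn_logpdf matches the dense-covariance density", {
  x <- c(0.3, -0.7, 1.1)
  expect_equal(
    cs_mvn_logpdf(x, mu = 0.1, sigma2 = 2, rho = 0.5),
    dense_mvn_logpdf(x, rep(0.1, 3), cs_cov_dense(3, 2, 0.5)),
    tolerance = 1e-12
  )
  set.seed(42)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    mu <- rnorm(1)
    s2 <- exp(rnorm(1))
    lo <- if (n == 1) -0.9 else -1 / (n - 1)
    rho <- runif(1, lo + 0.02, 0.95)
    x <- rnorm(n, mu, sqrt(s2))
    got <- cs_mvn_logpdf(x, mu, s2, if (n == 1) 0 else rho)
    want <- dense_mvn_logpdf(x, rep(mu, n),
                             cs_cov_dense(n, s2, if (n == 1) 0 else rho))
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("the n = 2 density integrates to 1", {
  g <- seq(-8, 8, length.out = 201)
  h <- diff(g)[1]
  f <- outer(g, g, Vectorize(function(a, b)
    exp(cs_mvn_logpdf(c(a, b), mu = 0.2, sigma2 = 1.3, rho = -0.4))))
  expect_equal(sum(f) * h^2, 1, tolerance = 1e-4)
})

test_that("cs_mvn_logpdf enforces its parameter contracts", {
  expect_error(cs_mvn_logpdf(c(1, 2, 3), 0, 1, rho = -0.6),
               "positive-definite")
  expect_error(cs_mvn_logpdf(c(1, 2), 0, 1, rho = 1), "positive-definite")
  expect_error(cs_mvn_logpdf(c(1, NA), 0, 1, 0), "finite")
  expect_error(cs_mvn_logpdf(c(1, 2), 0, -1, 0), "positive")
})

test_that("cluster_logpdf is the independent sum of group blocks", {
  p_eq <- cluster_params("EV", mu_c = 0.3, sigma2_c = 1.2, rho_c = 0,
                         mu_n = 0.3, sigma2_n = 1.2, rho_n = 0)
  x <- rnorm(7)
  expect_equal(cluster_logpdf(x, p_eq, 4, 3),
               sum(dnorm(x, 0.3, sqrt(1.2), log = TRUE)))

  p <- cluster_params("OV", mu_c = -0.2, sigma2_c = 2.0, rho_c = 0.3,
                      mu_n = 0.1, sigma2_n = 0.7, rho_n = 0.1)
  set.seed(7)
  x <- rnorm(7)
  expect_equal(cluster_logpdf(x, p, 4, 3),
               dense_cluster_logpdf(x[1:4], x[5:7], p),
               tolerance = 1e-10)
  # exchangeability: permuting within the case block changes nothing
  xp <- c(x[c(3, 1, 4, 2)], x[5:7])
  expect_equal(cluster_logpdf(xp, p, 4, 3), cluster_logpdf(x, p, 4, 3))
  expect_error(cluster_logpdf(x, p, 4, 4), "length")
})

test_that("posterior probabilities follow the mixture formula", {
  mk <- function(kind, s2c, s2n)
    cluster_params(kind, mu_c = 0, sigma2_c = s2c, rho_c = 0.1,
                   mu_n = 0, sigma2_n = s2n, rho_n = 0.1)
  model <- mixture_model(c(1, 0, 0),
                         list(mk("OV", 2, 1), mk("EV", 1, 1), mk("UV", 1, 2)),
                         m_c = 3, m_n = 3)
  d <- make_noise_dataset(5, 3, 3, seed = 1)
  pp <- posterior_probs(d, model)
  expect_equal(unname(pp), matrix(rep(c(1, 0, 0), each = 5), 5))

  same <- mixture_model(rep(1 / 3, 3),
                        list(mk("OV", 2, 1.999999999), mk("EV", 2, 2),
                             mk("UV", 1.999999999, 2)),
                        m_c = 3, m_n = 3)
  pp <- posterior_probs(d, same)
  expect_equal(unname(pp), matrix(1 / 3, 5, 3), tolerance = 1e-6)
})

test_that("posterior probabilities match the dense brute-force oracle", {
  mk <- function(kind, s2c, s2n, rc, rn)
    cluster_params(kind, mu_c = -0.1, sigma2_c = s2c, rho_c = rc,
                   mu_n = 0.2, sigma2_n = s2n, rho_n = rn)
  model <- mixture_model(c(0.3, 0.5, 0.2),
                         list(mk("OV", 1.8, 0.5, 0.1, 0.3),
                              mk("EV", 1.0, 1.0, 0.05, 0.1),
                              mk("UV", 0.4, 1.6, 0.02, -0.05)),
                         m_c = 4, m_n = 3)
  d <- make_noise_dataset(2, 4, 3, seed = 3)
  want <- dense_mixture(d$values, 4, model)$resp
  expect_equal(unname(posterior_probs(d, model)), want, tolerance = 1e-10)
})

test_that("posterior rows sum to 1 for random models and data", {
  set.seed(9)
  for (i in 1:10) {
    m_c <- sample(3:6, 1); m_n <- sample(3:6, 1)
    mk <- function(kind, s2c, s2n)
      cluster_params(kind, rnorm(1), s2c, runif(1, 0, 0.3),
                     rnorm(1), s2n, runif(1, 0, 0.3))
    model <- mixture_model(prop.table(runif(3) + 0.05),
                           list(mk("OV", exp(rnorm(1)) + 1, 0.5),
                                mk("EV", 1, 1),
                                mk("UV", 0.3, exp(rnorm(1)) + 1)),
                           m_c = m_c, m_n = m_n)
    pp <- posterior_probs(make_noise_dataset(30, m_c, m_n, seed = i), model)
    expect_true(all(abs(rowSums(pp) - 1) < 1e-10))
  }
})

test_that("container constructors enforce their invariants", {
  expect_error(expression_dataset(matrix(1:6, 2), c("case", "control", "x")),
               "unknown group")
  expect_error(expression_dataset(matrix(rnorm(6), 2),
                                  c("case", "case", "control")),
               "at least 2")
  expect_error(expression_dataset(matrix(rnorm(8), 2),
                                  rep(c("case", "control"), each = 2),
                                  probe_ids = c("a", "a")),
               "duplicate")
  expect_error(cluster_params("OV", 0, 1, 0, 0, 2, 0), "OV cluster")
  expect_error(cluster_params("UV", 0, 2, 0, 0, 1, 0), "UV cluster")
  expect_error(cluster_params("EV", 0, 1, 0, 0, 2, 0), "EV cluster")
  expect_error(cluster_params("OV", 0, 2, 0.9, 0, 1, 0, m_c = 50, m_n = 50),
               NA)
  expect_error(cluster_params("OV", 0, 2, -0.5, 0, 1, 0, m_c = 50, m_n = 50),
               "positive-definite")
  p <- cluster_params("EV", 0, 1, 0, 0, 1, 0)
  expect_error(mixture_model(c(0.5, 0.5, 0.5), list(p, p, p), 3, 3),
               "summing to 1")
})
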