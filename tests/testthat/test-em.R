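counts1 <- function(n, m) list(n = n, m = m)

test_that("multinomial log-likelihood kernels follow the 0*log0 rule", {
  a1 <- c(0.8, 0.15, 0.05)
  b1 <- c(0.7, 0.2, 0.1)
  expect_equal(causal_loglik(counts1(c(5, 0, 0), c(3, 0, 0)), a1, b1),
               log(0.8^5 * 0.7^3))
  u <- rep(1 / 3, 3)
  for (i in 1:5) {
    n <- drop(rmultinom(1, 5, c(0.5, 0.3, 0.2)))
    m <- drop(rmultinom(1, 3, c(0.5, 0.3, 0.2)))
    expect_equal(causal_loglik(counts1(n, m), u, u), 8 * log(1 / 3))
  }
  expect_identical(causal_loglik(counts1(c(4, 1, 0), c(3, 0, 0)),
                                 c(1, 0, 0), c(1, 0, 0)), -Inf)
  # zero-probability cell with zero count contributes nothing
  expect_equal(causal_loglik(counts1(c(5, 0, 0), c(3, 0, 0)),
                             c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(null_loglik(counts1(c(5, 0, 0), c(3, 0, 0)), a1, b1),
               causal_loglik(counts1(c(5, 0, 0), c(3, 0, 0)), a1, b1))
})

test_that("E-step matches the two-term enumeration on one gene", {
  cc <- matrix(c(5, 0, 0, 3, 0, 0), 1, 6)
  data <- make_model_data(cc, cc, p = 1)
  params <- list(a1 = c(0.8, 0.15, 0.05), b1 = c(0.7, 0.2, 0.1),
                 a0 = rep(1 / 3, 3), b0 = rep(1 / 3, 3),
                 gamma = 0.5, theta = 1)
  resp <- estep(data, params)
  direct <- 0.5 * (0.8^5 * 0.7^3) /
    (0.5 * (0.8^5 * 0.7^3) + 0.5 * (1 / 3)^8)
  expect_equal(resp$v_hat, direct, tolerance = 1e-12)
  expect_equal(round(resp$v_hat, 4), 0.9986)
  expect_equal(unname(resp$w[1] + resp$w_null[1]), 1)
})

test_that("E-step handles degenerate mixtures", {
  cc <- matrix(c(5, 0, 0, 3, 0, 0), 2, 6, byrow = TRUE)
  data <- make_model_data(cc, cc[1, , drop = FALSE], p = 2)
  params <- list(a1 = c(0.8, 0.15, 0.05), b1 = c(0.7, 0.2, 0.1),
                 a0 = rep(1 / 3, 3), b0 = rep(1 / 3, 3),
                 gamma = 0, theta = c(0.5, 0.5))
  # gamma = 0 forces the null state
  resp <- estep(data, params)
  expect_equal(resp$w_null, 1)
  # identical candidates share responsibility symmetrically
  params$gamma <- 0.7
  resp <- estep(data, params)
  expect_equal(resp$w[1], resp$w[2])
})

test_that("M-step reproduces pseudocount-only and pure-count estimates", {
  # fully null responsibilities: causal sums are pseudocounts alone and the
  # total-candidate factor cancels -> a1 = (0.1, 0.01, 0) / 0.11
  cc <- matrix(c(3, 1, 1, 1, 1, 1), 4, 6, byrow = TRUE)
  nc <- matrix(c(5, 0, 0, 3, 0, 0), 2, 6, byrow = TRUE)
  data <- make_model_data(cc, nc, p = c(2, 2))
  resp <- structure(list(w = rep(0, 4), w_null = c(1, 1), v_hat = c(0, 0)),
                    class = "responsibilities")
  # a flat prior with fully-null responsibilities degenerates the MAP
  # denominator: theta falls back to uniform with a warning
  expect_warning(
    params <- mstep(data, resp, pi = rep(1, 4), lambda = c(0.1, 0.01, 0)),
    "degenerate MAP")
  expect_equal(params$a1, c(0.1, 0.01, 0) / 0.11, tolerance = 1e-12)
  expect_equal(params$b1, c(0.1, 0.01, 0) / 0.11, tolerance = 1e-12)
  expect_equal(params$a0, c(5 * 2 + 0.4, 0.04, 0) / (10.44),
               tolerance = 1e-12)
  # hard responsibilities on one gene, no pseudocounts -> pure counts
  data1 <- make_model_data(matrix(c(5, 0, 0, 3, 0, 0), 1, 6),
                           matrix(c(2, 2, 1, 1, 1, 1), 1, 6), p = 1)
  resp1 <- structure(list(w = 1, w_null = 0, v_hat = 1),
                     class = "responsibilities")
  p1 <- mstep(data1, resp1, pi = 2, lambda = c(0, 0, 0))
  expect_equal(p1$a1, c(1, 0, 0))
  expect_equal(p1$b1, c(1, 0, 0))
})

test_that("MAP theta update matches the Dirichlet grid-search maximizer", {
  # worked example: pi = (2, 1.5), hard w = (1, 0)
  data <- make_model_data(matrix(c(5, 0, 0, 3, 0, 0), 2, 6, byrow = TRUE),
                          matrix(c(5, 0, 0, 3, 0, 0), 1, 6), p = 2)
  resp <- structure(list(w = c(1, 0), w_null = 0, v_hat = 1),
                    class = "responsibilities")
  params <- mstep(data, resp, pi = c(2, 1.5), lambda = c(0.1, 0.01, 0))
  expect_equal(params$theta, c(0.8, 0.2))
  expect_equal(params$theta[1],
               grid_map_dirichlet2(c(2, 1.5) + c(1, 0)), tolerance = 1e-6)
  # soft responsibilities, several cases
  for (w1 in c(0.3, 0.6, 0.9)) {
    respw <- structure(list(w = c(w1, 0.1), w_null = 1 - w1 - 0.1,
                            v_hat = w1 + 0.1),
                       class = "responsibilities")
    pw <- mstep(data, respw, pi = c(1.8, 1.2), lambda = c(0.1, 0.01, 0))
    expect_equal(pw$theta[1],
                 grid_map_dirichlet2(c(1.8, 1.2) + c(w1, 0.1)),
                 tolerance = 1e-6)
    expect_equal(sum(pw$theta), 1)
  }
})

test_that("EM fixed-point posteriors match exhaustive enumeration", {
  set.seed(31)
  # two genes, at most three candidates, explicit counts
  counts <- rbind(c(5, 0, 0, 3, 0, 0),
                  c(4, 1, 0, 2, 1, 0),
                  c(2, 2, 1, 1, 1, 1),
                  c(3, 2, 0, 3, 0, 0),
                  c(5, 0, 0, 2, 1, 0))
  nullc <- rbind(c(4, 1, 0, 3, 0, 0),
                 c(2, 3, 0, 1, 2, 0))
  data <- make_model_data(counts, nullc, p = c(3, 2))
  pi <- c(2.5, 1.3, 1.9, 3.0, 1.2)
  fit <- fit_model(data, priors = NULL,
                   control = fit_control(restarts = 2, max_iter = 300,
                                         tol = 1e-12, seed = 4))
  # override the flat prior with explicit weights through mstep/estep cycle
  fitp <- local({
    params <- fit$params
    for (i in 1:200) {
      resp <- estep(data, params)
      params <- mstep(data, resp, pi, c(0.1, 0.01, 0))
    }
    list(params = params, resp = estep(data, params))
  })
  pars <- fitp$params
  gi <- data$gene_index
  for (g in 1:2) {
    rows <- which(gi == g)
    post <- enumerate_posterior(counts[rows, , drop = FALSE], nullc[g, ],
                                pars$theta[rows], pars$gamma,
                                pars$a0, pars$a1, pars$b0, pars$b1)
    expect_equal(unname(fitp$resp$w[rows]), unname(post[seq_along(rows)]),
                 tolerance = 1e-8)
    expect_equal(unname(fitp$resp$w_null[g]),
                 unname(post[length(post)]), tolerance = 1e-8)
  }
})

test_that("objective is non-decreasing and order-invariant", {
  set.seed(13)
  cfg <- sim_config(G = 40, p_mu = 4, p_max = 8, seed = 13)
  sim <- simulate_from_plate(generate_fixture(cfg))
  data <- build_model_data(sim$instances, sim$expr)
  fit <- fit_model(data, sim$priors,
                   fit_control(restarts = 3, max_iter = 100, tol = 1e-10,
                               seed = 8))
  for (trace in fit$restart_traces) {
    expect_true(all(diff(trace) >= -1e-9 * (abs(trace[-length(trace)]) +
                                              1e-12)))
  }
  # permuting genes leaves the objective unchanged
  pi <- fit$pi
  obj1 <- model_objective(data, fit$params, pi)
  perm <- sample(length(data$p))
  rows <- unlist(lapply(perm, function(g) which(data$gene_index == g)))
  data2 <- data
  data2$p <- data$p[perm]
  data2$gene_index <- rep(seq_along(perm), data2$p)
  data2$counts <- data$counts[rows, ]
  data2$null_counts <- data$null_counts[perm, ]
  params2 <- fit$params
  params2$theta <- fit$params$theta[rows]
  obj2 <- model_objective(data2, params2, pi[rows])
  expect_equal(obj2, obj1, tolerance = 1e-10)
})

test_that("fit is deterministic and invariant to gene duplication", {
  cfg <- sim_config(G = 25, p_mu = 4, p_max = 8, seed = 21)
  sim <- simulate_from_plate(generate_fixture(cfg))
  data <- build_model_data(sim$instances, sim$expr)
  ctrl <- fit_control(restarts = 2, max_iter = 150, tol = 1e-9, seed = 77)
  f1 <- fit_model(data, sim$priors, ctrl)
  f2 <- fit_model(data, sim$priors, ctrl)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective, f2$objective)
  # duplicating every gene scales the sufficient statistics but leaves the
  # parameter estimates unchanged
  dup <- build_model_data(c(sim$instances, sim$instances),
                          sim$expr)
  fdup <- fit_model(dup, c(sim$priors, sim$priors), ctrl)
  expect_equal(fdup$params$a1, f1$params$a1, tolerance = 1e-6)
  expect_equal(fdup$params$a0, f1$params$a0, tolerance = 1e-6)
  expect_equal(fdup$params$gamma, f1$params$gamma, tolerance = 1e-6)
})

test_that("pseudocount ordering is preserved on null-only data", {
  cfg <- sim_config(G = 120, p_mu = 4, p_max = 8, seed = 17, gamma = 0.01)
  sim <- simulate_from_plate(generate_fixture(cfg))
  data <- build_model_data(sim$instances, sim$expr)
  fit <- fit_model(data, sim$priors,
                   fit_control(restarts = 2, max_iter = 200, tol = 1e-8,
                               seed = 3, lambda = c(0.1, 0.01, 0)))
  expect_true(fit$params$a1[1] >= fit$params$a1[2])
  expect_true(fit$params$a1[2] >= fit$params$a1[3])
})

test_that("simplex invariants hold after every M-step", {
  cfg <- sim_config(G = 30, p_mu = 4, p_max = 8, seed = 19)
  sim <- simulate_from_plate(generate_fixture(cfg))
  data <- build_model_data(sim$instances, sim$expr)
  pi <- unlist(lapply(sim$priors, `[[`, "pi"), use.names = FALSE)
  params <- list(a1 = c(0.7, 0.2, 0.1), b1 = c(0.7, 0.2, 0.1),
                 a0 = rep(1 / 3, 3), b0 = rep(1 / 3, 3), gamma = 0.5,
                 theta = unlist(lapply(sim$priors, function(x)
                   x$pi / sum(x$pi)), use.names = FALSE))
  for (i in 1:10) {
    resp <- estep(data, params)
    expect_equal(drop(rowsum(resp$w, data$gene_index)) + resp$w_null,
                 rep(1, length(data$p)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    params <- mstep(data, resp, pi)
    for (v in list(params$a0, params$a1, params$b0, params$b1)) {
      expect_equal(sum(v), 1, tolerance = 1e-12)
      expect_true(all(v >= 0))
    }
    expect_equal(drop(rowsum(params$theta, data$gene_index)),
                 rep(1, length(data$p)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("hard EM mode imputes a single state per gene", {
  cfg <- sim_config(G = 20, p_mu = 4, p_max = 6, seed = 23)
  sim <- simulate_from_plate(generate_fixture(cfg))
  data <- build_model_data(sim$instances, sim$expr)
  fit <- fit_model(data, sim$priors,
                   fit_control(restarts = 1, max_iter = 50, tol = 1e-8,
                               seed = 2, em_mode = "hard"))
  expect_true(all(fit$resp$w %in% c(0, 1)))
  expect_true(all(fit$resp$v_hat %in% c(0, 1)))
})
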