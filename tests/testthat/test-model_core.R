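test_that("donor allele means look up theta by genotype category", {
  G <- make_gm(rbind(c(0L, 1L, 2L), c(1L, 1L, 1L)))
  mu <- donor_allele_means(G, theta = c(0.01, 0.5, 0.99))
  expect_equal(unname(mu[1, ]), c(0.01, 0.5, 0.99))
  expect_equal(unname(mu[2, ]), rep(0.5, 3))   # uninformative constant row
  expect_error(donor_allele_means(make_gm(matrix(c(0L, NA), 1))), "missing")
  expect_error(check_theta(c(0.5, 0.5, 0.9)), "strictly increasing")
})

test_that("pooled log-likelihood matches direct evaluation and a per-read oracle", {
  # K = 1, mu = 0.5, a = 1, d = 2 -> log(0.25)
  G1 <- genotype_matrix(tiny_variants(1), "d1", matrix(1L))
  cts1 <- make_counts(1L, 2L)
  mu1 <- donor_allele_means(G1)
  expect_equal(pool_loglik(cts1, mu1, 1), log(0.25), tolerance = 1e-12)

  # zero-depth rows contribute nothing
  cts0 <- make_counts(c(1L, 0L), c(2L, 0L))
  G2 <- genotype_matrix(tiny_variants(2), "d1", matrix(c(1L, 1L), 2))
  expect_equal(pool_loglik(cts0, donor_allele_means(G2), 1), log(0.25))

  # random small instances: per-read product oracle (one log term per read)
  for (s in 1:5) {
    set.seed(s)
    K <- sample(2:4, 1); N <- sample(3:8, 1)
    cfg <- sim_config(K = K, N = N, phi = random_simplex(K),
                      depth_mean = 15, seed = s)
    G <- simulate_genotypes(cfg)
    sim <- simulate_bulk(cfg, G, seed = s + 50L)
    mu <- donor_allele_means(G, cfg$theta)
    oracle <- 0
    for (i in seq_len(N)) {
      p_alt <- sum(mu[i, ] * cfg$phi)
      for (j in seq_len(sim$counts$a[i])) oracle <- oracle + log(p_alt)
      for (j in seq_len(sim$counts$d[i] - sim$counts$a[i]))
        oracle <- oracle + log(1 - p_alt)
    }
    expect_equal(pool_loglik(sim$counts, mu, cfg$phi), oracle,
                 tolerance = 1e-10)
  }
})

test_that("EM recovers the closed-form solution for a single K=2 SNP", {
  # genotypes (0, 2), a/d = 0.7, theta (0.01, 0.5, 0.99):
  # phi2 = (a/d - theta0) / (theta2 - theta0)
  G <- make_gm(matrix(c(0L, 2L), 1))
  cts <- make_counts(70L, 100L)
  fit <- em_fit(cts, G, tol = 1e-12, max_iter = 50000)
  phi2 <- (0.7 - 0.01) / (0.99 - 0.01)
  expect_equal(unname(fit$phi), c(1 - phi2, phi2), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("a single donor yields phi = 1 without iteration", {
  G <- genotype_matrix(tiny_variants(2), "only",
                       matrix(c(1L, 2L), 2))
  cts <- make_counts(c(5L, 9L), c(10L, 10L))
  fit <- em_fit(cts, G)
  expect_equal(unname(fit$phi), 1)
  expect_equal(fit$n_iter, 0L)
})

test_that("EM log-likelihood is monotone and phi stays on the simplex", {
  for (s in 1:4) {
    inst <- bulk_instance(100 + s, N = 300)
    fit <- em_fit(inst$counts, inst$G)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(sum(fit$phi), 1, tolerance = 1e-9)
    expect_true(all(fit$phi >= 0))
  }
})

test_that("permuting donor columns permutes phi identically", {
  inst <- bulk_instance(7, N = 400)
  fit <- em_fit(inst$counts, inst$G)
  perm <- c(3L, 1L, 4L, 2L)
  Gp <- genotype_matrix(inst$G$variants, inst$G$donors[perm],
                        inst$G$G[, perm])
  fitp <- em_fit(inst$counts, Gp)
  expect_equal(unname(fitp$phi), unname(fit$phi[perm]), tolerance = 1e-9)
})

test_that("flipping REF/ALT labels leaves phi unchanged under symmetric theta", {
  inst <- bulk_instance(8, N = 400)
  theta <- c(0.01, 0.5, 0.99)             # theta0 = 1 - theta2
  fit <- em_fit(inst$counts, inst$G, theta0 = theta)
  flip <- seq(1, 400, by = 3)
  Gf <- inst$G
  Gf$G[flip, ] <- 2L - Gf$G[flip, ]
  af <- inst$counts$a
  af[flip] <- inst$counts$d[flip] - af[flip]
  ctsf <- allelic_counts(inst$counts$variants, af, inst$counts$d)
  fitf <- em_fit(ctsf, Gf, theta0 = theta)
  expect_equal(unname(fitf$phi), unname(fit$phi), tolerance = 1e-9)
})

test_that("scaling all counts by a constant leaves the estimate unchanged", {
  inst <- bulk_instance(9, N = 300)
  fit <- em_fit(inst$counts, inst$G, tol = 1e-10)
  cts10 <- allelic_counts(inst$counts$variants, inst$counts$a * 10L,
                          inst$counts$d * 10L)
  fit10 <- em_fit(cts10, inst$G, tol = 1e-10)
  expect_equal(unname(fit10$phi), unname(fit$phi), tolerance = 1e-5)
})

test_that("adaptive theta is learned, ordered, and clipped", {
  cfg <- sim_config(K = 4, N = 1500, phi = c(0.4, 0.3, 0.2, 0.1),
                    theta = c(0.05, 0.45, 0.92), depth_mean = 80, seed = 21)
  G <- simulate_genotypes(cfg)
  sim <- simulate_bulk(cfg, G, seed = 22)
  fit <- em_fit(sim$counts, G, theta_mode = "adaptive")
  expect_true(all(diff(fit$theta) > 0))
  expect_true(all(fit$theta >= 1e-4 & fit$theta <= 1 - 1e-4))
  expect_lt(max(abs(fit$theta - cfg$theta)), 0.05)
  expect_lt(max(abs(fit$phi - cfg$phi)), 0.03)
})

test_that("EM matches the simplex grid search on small instances", {
  for (s in 1:3) {
    set.seed(s)
    K <- 2L + (s %% 2L)
    cfg <- sim_config(K = K, N = 30, phi = random_simplex(K),
                      depth_mean = 60, seed = 300 + s)
    G <- simulate_genotypes(cfg)
    sim <- simulate_bulk(cfg, G, seed = 400 + s)
    fit <- em_fit(sim$counts, G, tol = 1e-12, max_iter = 1e5)
    gs <- grid_search_phi(sim$counts, G)
    expect_lt(max(abs(fit$phi - gs$phi)), 1e-3)
  }
})
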