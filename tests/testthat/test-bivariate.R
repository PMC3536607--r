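test_that("block relationship zeroes between-group entries only", {
  cfg <- sim_config(n_founders = 20, n_generations = 2, n_markers = 5,
                    n_qtl = 1, seed = 71)
  ped <- simulate_pedigree(cfg)
  A <- build_nrm(ped)
  ids <- rownames(A)
  set.seed(1)
  grp <- setNames(sample(1:3, length(ids), replace = TRUE), ids)
  G <- build_block_relationship(A, grp)
  M <- as_matrix_block(G)
  # double-loop oracle
  for (i in ids) for (j in ids) {
    expected <- if (grp[i] == grp[j]) A[i, j] else 0
    expect_identical(M[i, j], expected)
  }
  # K = 1 keeps A intact
  one <- setNames(rep(1L, length(ids)), ids)
  expect_equal(as_matrix_block(build_block_relationship(A, one))[ids, ids],
               A[ids, ids])
  # all-singleton groups give a diagonal matrix
  singles <- setNames(seq_along(ids), ids)
  Ms <- as_matrix_block(build_block_relationship(A, singles))
  Dexp <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(Dexp) <- diag(A)[ids]
  expect_equal(Ms[ids, ids], Dexp, tolerance = 1e-15)
})

# shared generator: data simulated from the bivariate model itself
simulate_bivar <- function(seed, n_founders = 60, K = 2, S0, s2e1 = 2,
                           s2e2 = 0.1, w_range = c(0.5, 1.5)) {
  set.seed(seed)
  cfg <- sim_config(n_founders = n_founders, n_generations = 3,
                    n_markers = 5, n_qtl = 1, seed = seed)
  ped <- simulate_pedigree(cfg)
  ids <- as.character(ped$animal[ped$generation >= 1])
  A <- build_nrm(ped, ids = ids)
  grp <- if (K == 1) setNames(rep(1L, length(ids)), ids) else
    kmeans_groups(difference_matrix(A), K = K, restarts = 10, seed = seed)$group
  G <- build_block_relationship(A, grp)
  Gm <- as_matrix_block(G)
  n <- nrow(Gm)
  L <- chol(Gm + diag(1e-8, n))
  alpha <- t(L) %*% matrix(rnorm(2 * n), n, 2) %*% chol(S0)
  w <- runif(n, w_range[1], w_range[2])
  y1 <- 1 + alpha[, 1] + rnorm(n, 0, sqrt(s2e1 / w))
  y2 <- 0.3 * as.integer(G$group) + alpha[, 2] + rnorm(n, 0, sqrt(s2e2))
  list(debv = data.frame(animal = G$ids, debv = y1, weight = w),
       dgv = data.frame(animal = G$ids, dgv = y2), G = G, A = A, grp = grp)
}

test_that("REML matches a dense restricted-likelihood oracle on a small case", {
  S0 <- matrix(c(3, 1.2, 1.2, 1.5), 2)
  d <- simulate_bivar(81, n_founders = 20, K = 1, S0 = S0)
  # keep n <= 40
  expect_lte(nrow(d$debv), 40)
  est <- fit_bivariate_reml(d$debv, d$dgv, d$G, se = FALSE)
  # independent dense maximization (no block factorization, natural scale,
  # different optimizer path)
  ids <- d$G$ids
  y1 <- d$debv$debv[match(ids, d$debv$animal)]
  y2 <- d$dgv$dgv[match(ids, d$dgv$animal)]
  w <- d$debv$weight[match(ids, d$debv$animal)]
  A <- d$A[ids, ids]
  n <- length(ids)
  X <- rbind(cbind(rep(1, n), 0), cbind(0, rep(1, n)))
  obj <- function(par) {
    phi <- c(exp(par[1]), tanh(par[2]) * sqrt(exp(par[1]) * exp(par[3])),
             exp(par[3]), exp(par[4]), exp(par[5]))
    oracle_neg2reml(phi, y1, y2, w, A, X)
  }
  opt <- optim(c(log(var(y1) / 2), 0.5, log(var(y2) / 2), log(var(y1) / 2),
                 log(var(y2) / 10)), obj,
               method = "Nelder-Mead", control = list(maxit = 5000,
                                                      reltol = 1e-13))
  opt <- optim(opt$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-13))
  phi_orc <- c(exp(opt$par[1]),
               tanh(opt$par[2]) * sqrt(exp(opt$par[1]) * exp(opt$par[3])),
               exp(opt$par[3]), exp(opt$par[4]), exp(opt$par[5]))
  expect_equal(unname(est$components), phi_orc, tolerance = 2e-3)
  rg_orc <- phi_orc[2] / sqrt(phi_orc[1] * phi_orc[3])
  expect_equal(est$r_g, rg_orc, tolerance = 1e-3)
})

test_that("a noiseless duplicate of the genetic signal drives r_g and h2 to 1", {
  set.seed(91)
  cfg <- sim_config(n_founders = 80, n_generations = 3, n_markers = 200,
                    n_qtl = 20, trait_heritability = 0.4, seed = 91)
  herd <- simulate_herd(cfg)
  ped <- herd$pedigree
  ids <- as.character(ped$animal[ped$generation >= 1])
  A <- build_nrm(ped, ids = ids)
  cl <- kmeans_groups(difference_matrix(A), K = 3, restarts = 10, seed = 91)
  G <- build_block_relationship(A, cl)
  debv <- build_debv_table(herd$evaluation[herd$evaluation$animal %in%
                                             as.integer(ids), ],
                           ped, h2 = 0.4)
  # DGV is exactly the true genetic value: a noiseless heritable variable
  dgv <- data.frame(animal = ids, dgv = herd$truth$tbv[ids])
  est <- fit_bivariate_reml(debv, dgv, G, se = FALSE)
  expect_gt(est$r_g, 0.95)
  expect_gt(est$h2_dgv, 0.90)
})

test_that("zeroed between-group blocks make the likelihood separable", {
  S0 <- matrix(c(2, 0.8, 0.8, 1), 2)
  d <- simulate_bivar(101, n_founders = 30, K = 2, S0 = S0)
  est <- fit_bivariate_reml(d$debv, d$dgv, d$G, se = FALSE)
  phi <- unname(est$components)
  ids <- d$G$ids
  # full-model -2logLik at the optimum
  y1 <- d$debv$debv[match(ids, d$debv$animal)]
  y2 <- d$dgv$dgv[match(ids, d$dgv$animal)]
  w <- d$debv$weight[match(ids, d$debv$animal)]
  n <- length(ids)
  grp <- d$G$group
  Gm <- as_matrix_block(d$G)
  # per-group fixed effects on both variables so the projections factorize
  # the same way the covariance does
  X <- matrix(0, 2 * n, 4)
  for (k in 1:2) {
    X[which(grp == k), k] <- 1
    X[n + which(grp == k), 2 + k] <- 1
  }
  full <- oracle_neg2reml(phi, y1, y2, w, Gm, X)
  # sum of per-group -2logLik at the same parameter values
  parts <- sapply(unique(grp), function(g) {
    i <- which(grp == g)
    Xg <- rbind(cbind(rep(1, length(i)), 0), cbind(0, rep(1, length(i))))
    oracle_neg2reml(phi, y1[i], y2[i], w[i], Gm[i, i], Xg)
  })
  expect_equal(full, sum(parts), tolerance = 1e-6)
})

test_that("genetic correlation reproduces the published variance-table algebra", {
  expect_equal(round_half_up(genetic_correlation(
    c(sigma2_trait = 2.80, sigma2_dgv = 0.93, cov_trait_dgv = 0.93)), 2), 0.58)
  expect_equal(round_half_up(genetic_correlation(
    c(sigma2_trait = 111.76, sigma2_dgv = 22.82, cov_trait_dgv = 38.44)), 2),
    0.76)
  expect_equal(genetic_correlation(
    c(sigma2_trait = 5, sigma2_dgv = 2, cov_trait_dgv = 0)), 0)
  expect_error(genetic_correlation(
    c(sigma2_trait = 0, sigma2_dgv = 2, cov_trait_dgv = 0)), "undefined")
  expect_message(genetic_correlation(
    c(sigma2_trait = 1, sigma2_dgv = 1, cov_trait_dgv = 1.01)), "clamped")
})

test_that("standard errors are finite and sane away from boundaries", {
  S0 <- matrix(c(4, 1.7, 1.7, 2), 2)
  d <- simulate_bivar(111, n_founders = 80, K = 3, S0 = S0, s2e2 = 0.3)
  est <- fit_bivariate_reml(d$debv, d$dgv, d$G, se = TRUE)
  expect_true(all(is.finite(est$se)))
  expect_true(is.finite(est$se_r_g))
  expect_gt(est$se_r_g, 0)
  expect_lt(est$se_r_g, 0.5)
})
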