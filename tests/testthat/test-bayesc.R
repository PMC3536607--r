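train_frame <- function(y, w = rep(1, length(y))) {
  data.frame(animal = paste0("a", seq_along(y)), debv = y, weight = w)
}

test_that("no-signal data shrinks all effects toward zero", {
  set.seed(1)
  n <- 40; k <- 25
  Z <- matrix(rbinom(n * k, 2, 0.4), n, k)
  gm <- geno_matrix(Z, animals = paste0("a", 1:n))
  cfg <- bayesc_config(pi = 0.95, chain_length = 1500, burn_in = 300,
                       scale_u = 0.01, scale_e = 1, seed = 2)
  fit <- train_bayesc(train_frame(rep(0, n)), gm, cfg)
  expect_true(all(abs(fit$effect) < 0.05))
  expect_lt(mean(fit$inclusion_freq), 0.2)
})

test_that("pi = 0 with fixed variances reproduces the SNP-BLUP solution", {
  set.seed(9)
  n <- 50; k <- 30
  Z <- matrix(rbinom(n * k, 2, 0.4), n, k)
  u <- rnorm(k, 0, 0.3)
  y <- drop(Z %*% u) + rnorm(n)
  s2u <- 0.09; s2e <- 1
  gm <- geno_matrix(Z, animals = paste0("a", 1:n))
  cfg <- bayesc_config(pi = 0, chain_length = 6000, burn_in = 1000,
                       scale_u = s2u, scale_e = s2e, fixed_variances = TRUE,
                       seed = 4)
  fit <- train_bayesc(train_frame(y), gm, cfg)
  # ridge oracle (intercept unpenalized)
  X <- cbind(1, Z)
  sol <- solve(crossprod(X) + diag(c(0, rep(s2e / s2u, k))), crossprod(X, y))
  # Monte-Carlo error from batch means of an independent replicate chain
  cfg2 <- cfg; cfg2$seed <- 5
  fit2 <- train_bayesc(train_frame(y), gm, cfg2)
  mc_se <- sd(fit$effect - fit2$effect) / sqrt(2)
  expect_lt(max(abs(fit$effect - sol[-1])), max(6 * mc_se, 0.03))
  expect_gt(cor(fit$effect, sol[-1]), 0.995)
})

test_that("sampler finds simulated QTL more often than chance", {
  set.seed(13)
  cfg_sim <- sim_config(n_founders = 200, n_generations = 2, n_markers = 500,
                        n_qtl = 10, trait_heritability = 0.6, seed = 13)
  ped <- simulate_pedigree(cfg_sim)
  G <- gene_drop(ped, cfg_sim)
  tr <- simulate_trait(G, cfg_sim)
  y <- tr$tbv + rnorm(length(tr$tbv), 0, sqrt(tr$var_residual))
  debv <- data.frame(animal = G$animals, debv = y, weight = 1)
  cfg <- bayesc_config(pi = 0.95, chain_length = 2500, burn_in = 500, seed = 3)
  fit <- train_bayesc(debv, G, cfg, h2 = 0.6)
  top10 <- order(fit$inclusion_freq, decreasing = TRUE)[1:10]
  hits <- length(intersect(top10, tr$qtl))
  # P(X >= hits) under hypergeometric draw of 10 from 500 with 10 special
  pval <- phyper(hits - 1, 10, 490, 10, lower.tail = FALSE)
  expect_lt(pval, 0.01)
})

test_that("posterior means are deterministic under seed", {
  set.seed(21)
  n <- 30; k <- 20
  Z <- matrix(rbinom(n * k, 2, 0.3), n, k)
  y <- rnorm(n)
  gm <- geno_matrix(Z, animals = paste0("a", 1:n))
  cfg <- bayesc_config(chain_length = 800, burn_in = 100, seed = 77)
  f1 <- train_bayesc(train_frame(y), gm, cfg, h2 = 0.4)
  f2 <- train_bayesc(train_frame(y), gm, cfg, h2 = 0.4)
  expect_identical(f1$effect, f2$effect)
  expect_identical(f1$sigma2_u, f2$sigma2_u)
})

test_that("a weight-2 record is equivalent to two unit-weight copies", {
  set.seed(33)
  n <- 25; k <- 12
  Z <- matrix(rbinom(n * k, 2, 0.4), n, k)
  y <- rnorm(n)
  # weighted version: first animal has weight 2
  w <- c(2, rep(1, n - 1))
  gmw <- geno_matrix(Z, animals = paste0("a", 1:n))
  # duplicated version: first row appears twice with weight 1
  Zd <- rbind(Z[1, , drop = FALSE], Z)
  gmd <- geno_matrix(Zd, animals = paste0("a", 0:n))
  cfgw <- bayesc_config(pi = 0.5, chain_length = 1200, burn_in = 200,
                        scale_u = 0.05, scale_e = 1, fixed_variances = TRUE,
                        seed = 11)
  fw <- train_bayesc(train_frame(y, w), gmw, cfgw)
  fd <- train_bayesc(data.frame(animal = paste0("a", 0:n),
                                debv = c(y[1], y), weight = 1), gmd, cfgw)
  # with fixed variances the full conditionals coincide, and so does the
  # RNG stream, making the chains identical
  expect_equal(fw$effect, fd$effect, tolerance = 1e-12)
  expect_equal(fw$mu, fd$mu, tolerance = 1e-12)
})

test_that("prior initialization partitions variance and guards edge cases", {
  set.seed(41)
  cfg_sim <- sim_config(n_founders = 300, n_generations = 2, n_markers = 300,
                        n_qtl = 30, trait_heritability = 0.4, seed = 41)
  ped <- simulate_pedigree(cfg_sim)
  G <- gene_drop(ped, cfg_sim)
  tr <- simulate_trait(G, cfg_sim)
  y <- tr$tbv + rnorm(length(tr$tbv), 0, sqrt(tr$var_residual))
  debv <- data.frame(animal = G$animals, debv = y, weight = 1)
  cfg <- initialize_priors(debv, G, bayesc_config(), h2 = 0.4)
  # implied total genetic scale within a factor 2 of the truth
  implied_g <- cfg$scale_u * (1 - cfg$pi) *
    sum(2 * (colMeans(G$geno) / 2) * (1 - colMeans(G$geno) / 2))
  expect_gt(implied_g / tr$var_genetic, 0.5)
  expect_lt(implied_g / tr$var_genetic, 2)
  expect_gt(cfg$scale_e / tr$var_residual, 0.5)
  expect_lt(cfg$scale_e / tr$var_residual, 2)
  # pi -> 1 guard
  cfg_hi <- initialize_priors(debv, G, bayesc_config(pi = 1 - 1e-9), h2 = 0.4)
  expect_true(is.finite(cfg_hi$scale_u))
  # degenerate response
  expect_error(initialize_priors(train_frame(rep(1, 10)),
                                 subset_geno(G, animals = G$animals[1:10]),
                                 bayesc_config(), h2 = 0.4),
               "degenerate")
  # determinism
  expect_identical(cfg, initialize_priors(debv, G, bayesc_config(), h2 = 0.4))
})

test_that("DGV prediction is the dosage-effect product", {
  set.seed(51)
  Z <- matrix(rbinom(1000, 2, 0.5), 20, 50)
  gm <- geno_matrix(Z, animals = paste0("a", 1:20))
  eff <- structure(list(marker = gm$markers$marker,
                        effect = rep(0, 50), inclusion_freq = rep(0, 50),
                        mu = 0, sigma2_u = 1, sigma2_e = 1, n_train = 0,
                        config = bayesc_config()), class = "marker_effects")
  expect_true(all(predict_dgv(gm, eff)$dgv == 0))
  eff$effect[7] <- 0.5
  expect_equal(predict_dgv(gm, eff)$dgv, 0.5 * Z[, 7])
  # loop oracle on a random effect vector
  eff$effect <- rnorm(50)
  loop <- sapply(1:20, function(i) sum(Z[i, ] * eff$effect))
  expect_equal(predict_dgv(gm, eff)$dgv, loop)
  # marker mismatch is an alignment error
  gm2 <- subset_geno(gm, markers = 1:49)
  expect_error(predict_dgv(gm2, eff), "alignment")
})

test_that("held-out accuracy is positive and grows with training-set size", {
  cfg_sim <- sim_config(n_founders = 500, n_generations = 2, n_markers = 300,
                        n_qtl = 20, trait_heritability = 0.5, seed = 61)
  ped <- simulate_pedigree(cfg_sim)
  G <- gene_drop(ped, cfg_sim)
  tr <- simulate_trait(G, cfg_sim)
  set.seed(62)
  y <- tr$tbv + rnorm(length(tr$tbv), 0, sqrt(tr$var_residual))
  holdout <- G$animals[1:200]
  pool <- setdiff(G$animals, holdout)
  acc <- sapply(c(100, 300, 700), function(sz) {
    train_ids <- pool[1:sz]
    debv <- data.frame(animal = train_ids,
                       debv = y[match(train_ids, G$animals)], weight = 1)
    fit <- train_bayesc(debv, subset_geno(G, animals = train_ids),
                        bayesc_config(chain_length = 1500, burn_in = 300,
                                      seed = 63), h2 = 0.5)
    pred <- predict_dgv(subset_geno(G, animals = holdout), fit)
    cor(pred$dgv, tr$tbv[holdout])
  })
  expect_true(all(acc > 0))
  expect_gt(acc[3], acc[1])
})
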