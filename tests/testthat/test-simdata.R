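test_that("pedigree simulation respects structure and determinism", {
  # founders only
  cfg <- sim_config(n_founders = 10, n_generations = 1, n_markers = 5,
                    n_qtl = 1, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10)
  expect_true(all(ped$sire == 0 & ped$dam == 0))

  # determinism under seed
  cfg <- sim_config(n_founders = 20, n_generations = 3, n_markers = 5,
                    n_qtl = 1, seed = 42)
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))

  # structural invariants: parents older, correct sexes, acyclic
  cfg <- sim_config(n_founders = 30, n_generations = 4, n_markers = 5,
                    n_qtl = 1, seed = 7)
  ped <- simulate_pedigree(cfg)
  expect_silent(sort_pedigree(ped))
  nf <- ped[ped$sire != 0, ]
  yr <- setNames(ped$birth_year, ped$animal)
  sex <- setNames(ped$sex, ped$animal)
  expect_true(all(yr[as.character(nf$sire)] < nf$birth_year))
  expect_true(all(yr[as.character(nf$dam)] < nf$birth_year))
  expect_true(all(sex[as.character(nf$sire)] == "M"))
  expect_true(all(sex[as.character(nf$dam)] == "F"))
})

test_that("later generations accumulate inbreeding", {
  cfg <- sim_config(n_founders = 50, n_generations = 5, n_sires = 4,
                    n_clans = 2, n_markers = 5, n_qtl = 1, seed = 11)
  ped <- simulate_pedigree(cfg)
  A <- build_nrm(ped)
  f_last <- inbreeding(A)[as.character(ped$animal[ped$generation == 4])]
  expect_gt(mean(f_last), 0)
  # spot-check against the independent recursive definition on a sub-pedigree
  sub <- ped[ped$animal %in% c(ped$animal[1:10],
                               ped$animal[ped$generation >= 1][1:5]), ]
  keep <- sub$sire %in% c(0, sub$animal) & sub$dam %in% c(0, sub$animal)
  sub$sire[!keep] <- 0L; sub$dam[!keep] <- 0L
  expect_equal(diag(build_nrm(sub)), diag(oracle_nrm(sub)), tolerance = 1e-12)
})

test_that("gene drop obeys Mendelian transmission", {
  cfg <- sim_config(n_founders = 10, n_generations = 3, n_markers = 4,
                    n_qtl = 1, seed = 2)
  ped <- simulate_pedigree(cfg)
  # fixed alleles propagate unchanged
  G0 <- gene_drop(ped, cfg, founder_freq = c(0, 0, 1, 1))
  expect_true(all(G0$geno[, 1:2] == 0))
  expect_true(all(G0$geno[, 3:4] == 2))

  # (1,1) x (1,1) mating: offspring dosages ~ (1/4, 1/2, 1/4)
  ped2 <- data.frame(animal = 1:2002, sire = c(0, 0, rep(1, 2000)),
                     dam = c(0, 0, rep(2, 2000)), birth_year = c(1, 1, rep(2, 2000)))
  cfg2 <- sim_config(n_founders = 2, n_generations = 1, n_markers = 1,
                     n_qtl = 1, seed = 3)
  # force both parents heterozygous by redrawing until so
  repeat {
    G2 <- gene_drop(ped2, cfg2, founder_freq = 0.5)
    if (all(G2$geno[1:2, 1] == 1)) break
    cfg2$seed <- cfg2$seed + 1L
  }
  counts <- tabulate(G2$geno[-(1:2), 1] + 1L, 3L)
  expect_gt(stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 1e-4)

  # determinism
  expect_identical(gene_drop(ped, cfg), gene_drop(ped, cfg))
})

test_that("allele frequencies are preserved in expectation through generations", {
  freqs <- numeric(20)
  for (r in 1:20) {
    cfg <- sim_config(n_founders = 60, n_generations = 3, n_sires = 10,
                      n_markers = 1, n_qtl = 1, seed = 500 + r)
    ped <- simulate_pedigree(cfg)
    G <- gene_drop(ped, cfg, founder_freq = 0.3)
    last <- as.character(ped$animal[ped$generation == 2])
    freqs[r] <- mean(G$geno[match(last, G$animals), 1]) / 2
  }
  expect_lt(abs(mean(freqs) - 0.3), 0.05)
})

test_that("trait simulation hits the target architecture and heritability", {
  cfg <- sim_config(n_founders = 100, n_generations = 2, n_markers = 50,
                    n_qtl = 0, seed = 4)
  ped <- simulate_pedigree(cfg)
  G <- gene_drop(ped, cfg)
  expect_true(all(simulate_trait(G, cfg)$tbv == 0))

  # single QTL with known effect: TBV is the centered dosage
  cfg1 <- sim_config(n_founders = 100, n_generations = 2, n_markers = 50,
                     n_qtl = 1, seed = 5)
  G1 <- gene_drop(ped, cfg1)
  tr1 <- simulate_trait(G1, cfg1)
  z <- G1$geno[, tr1$qtl]
  expect_equal(unname(tr1$tbv), unname((z - mean(z)) * tr1$qtl_effects),
               tolerance = 1e-12)

  # realized heritability close to target given the residual-variance rule
  cfg2 <- sim_config(n_founders = 500, n_generations = 2, n_markers = 200,
                     n_qtl = 30, trait_heritability = 0.4, seed = 6)
  ped2 <- simulate_pedigree(cfg2)
  G2 <- gene_drop(ped2, cfg2)
  tr2 <- simulate_trait(G2, cfg2)
  h2_real <- tr2$var_genetic / (tr2$var_genetic + tr2$var_residual)
  expect_equal(h2_real, 0.4, tolerance = 1e-10) # exact by construction
})

test_that("emulated evaluations recover assigned reliabilities", {
  cfg <- sim_config(n_founders = 1000, n_generations = 2, n_markers = 100,
                    n_qtl = 20, seed = 8)
  ped <- simulate_pedigree(cfg)
  G <- gene_drop(ped, cfg)
  tr <- simulate_trait(G, cfg)
  r2 <- setNames(rep(0.64, nrow(ped)), ped$animal)
  ev <- emulate_evaluation(tr, ped, cfg, reliability = r2)
  r2_emp <- cor(2 * ev$epd, tr$tbv[as.character(ev$animal)])^2
  expect_gt(r2_emp, 0.58)
  expect_lt(r2_emp, 0.70)
  # BIF accuracy round-trips to the assigned reliability exactly
  expect_equal(bif_to_reliability(ev$bif_acc), unname(r2[as.character(ev$animal)]),
               tolerance = 1e-12)
  # r2 = 0: the evaluation carries no information about TBV (degenerate
  # limit of the variance rule: both signal and noise variance vanish)
  ev0 <- emulate_evaluation(tr, ped, cfg, reliability = setNames(rep(0, nrow(ped)), ped$animal))
  expect_true(all(ev0$epd == 0))
  # invalid reliability rejected
  expect_error(emulate_evaluation(tr, ped, cfg,
                                  reliability = setNames(rep(1, nrow(ped)), ped$animal)),
               "configuration")
})

test_that("whole-herd simulation is byte-deterministic under seed", {
  cfg <- sim_config(n_founders = 30, n_generations = 3, n_markers = 40,
                    n_qtl = 5, seed = 99)
  expect_identical(simulate_herd(cfg), simulate_herd(cfg))
})
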