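make_gm <- function(mat, markers = NULL, animals = NULL) {
  geno_matrix(mat, animals = animals %||% paste0("a", seq_len(nrow(mat))),
              markers = markers)
}

test_that("panel harmonization intersects markers and stacks animals", {
  m1 <- make_gm(matrix(c(0, 1, 2, 1), 2, 2),
                markers = data.frame(marker = c("m1", "m2")))
  expect_identical(harmonize_panels(list(m1)), m1)

  m2 <- make_gm(matrix(0, 2, 5),
                markers = data.frame(marker = paste0("m", 1:5)),
                animals = c("b1", "b2"))
  m3 <- make_gm(matrix(1, 2, 3),
                markers = data.frame(marker = c("m2", "m4", "m9")),
                animals = c("c1", "c2"))
  merged <- harmonize_panels(list(m2, m3))
  expect_equal(merged$markers$marker, c("m2", "m4"))
  expect_equal(merged$animals, c("b1", "b2", "c1", "c2"))

  # hand-built three-panel overlap
  mk <- function(names) data.frame(marker = names)
  pA <- make_gm(matrix(0:1, 1, 10, byrow = TRUE)[, 1:10, drop = FALSE],
                markers = mk(paste0("s", 1:10)), animals = "x1")
  pB <- make_gm(matrix(2, 1, 8), markers = mk(paste0("s", 2:9)), animals = "x2")
  pC <- make_gm(matrix(1, 1, 9), markers = mk(paste0("s", c(1:7, 9, 11))),
                animals = "x3")
  out <- harmonize_panels(list(pA, pB, pC))
  expect_equal(out$markers$marker, paste0("s", c(2:7, 9))) # 7 shared markers
  expect_equal(dim(out$geno), c(3L, 7L))
  expect_equal(unname(out$geno["x2", ]), rep(2, 7))

  # duplicate animals and empty intersections are errors
  expect_error(harmonize_panels(list(m2, m2)), "duplicated animal")
  pD <- make_gm(matrix(0, 1, 1), markers = mk("zz"), animals = "y1")
  expect_error(harmonize_panels(list(m2, pD)), "no markers shared")
})

test_that("marker statistics match closed-form values", {
  # exact HWE at p = 0.5: counts (25, 50, 25)
  Z <- matrix(rep(c(0, 1, 2), times = c(25, 50, 25)), ncol = 1)
  st <- compute_marker_stats(make_gm(Z))
  expect_equal(st$maf, 0.5)
  expect_equal(st$hwe_chisq, 0)
  expect_equal(st$hwe_p, 1)

  # call rate with 5 missing of 100
  Z2 <- matrix(c(rep(0, 95), rep(NA, 5)), ncol = 1)
  expect_equal(compute_marker_stats(make_gm(Z2))$call_rate, 0.95)

  # counts (50, 0, 50): chi-square exactly 100, analytic tail
  Z3 <- matrix(rep(c(0, 2), each = 50), ncol = 1)
  st3 <- compute_marker_stats(make_gm(Z3))
  expect_equal(st3$hwe_chisq, 100)
  expect_equal(st3$hwe_p, pchisq(100, df = 1, lower.tail = FALSE))

  # all-missing marker: call rate 0, NA stats
  Z4 <- matrix(NA_real_, 10, 1)
  st4 <- compute_marker_stats(make_gm(Z4))
  expect_equal(st4$call_rate, 0)
  expect_true(is.na(st4$maf) && is.na(st4$hwe_p))
})

test_that("threshold filtering applies the three predicates exactly", {
  st <- data.frame(marker = paste0("m", 1:5),
                   call_rate = c(1, 0.9, 1, 1, 1),
                   maf = c(0.3, 0.3, 0.001, 0.3, 0.05),
                   hwe_chisq = 0,
                   hwe_p = c(1, 1, 1, 1e-40, 0.5))
  G <- make_gm(matrix(0, 2, 5), markers = data.frame(marker = paste0("m", 1:5)))
  kept <- filter_markers(G, st)
  expect_equal(kept$markers$marker, c("m1", "m5"))
  expect_error(filter_markers(G, st, min_maf = 2), "configuration")

  # monomorphic markers all removed by the MAF rule
  Gmono <- make_gm(matrix(2, 5, 3))
  expect_equal(ncol(filter_markers(Gmono)$geno), 0L)
})

test_that("QC on simulated data equals independent predicate re-application", {
  set.seed(31)
  n <- 120; m <- 400
  Z <- matrix(rbinom(n * m, 2, runif(m, 0.01, 0.5)[rep(1:m, each = n)]), n, m)
  Z[sample(length(Z), 0.03 * length(Z))] <- NA       # sprinkle missingness
  Z[, sample(m, 20)] <- 0                            # spiked monomorphic
  hi_miss <- sample(m, 25)
  Z[sample(n, 30), hi_miss] <- NA                    # spiked low call rate
  G <- make_gm(Z)
  st <- compute_marker_stats(G)
  kept <- filter_markers(G, st)
  # independent re-application of the three predicates
  cr <- colMeans(!is.na(Z))
  p <- colMeans(Z, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe <- sapply(seq_len(m), function(j) {
    z <- Z[!is.na(Z[, j]), j]
    pj <- mean(z) / 2
    if (pj <= 0 || pj >= 1) return(1)
    obs <- tabulate(z + 1L, 3L)
    exp <- length(z) * c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    pchisq(sum((obs - exp)^2 / exp), 1, lower.tail = FALSE)
  })
  manual <- unname(which(cr >= 0.95 & maf >= 0.005 & hwe > 1e-30))
  expect_equal(kept$markers$marker, G$markers$marker[manual])

  # idempotence: re-running QC on the filtered set removes nothing
  again <- filter_markers(kept, compute_marker_stats(kept))
  expect_equal(again$markers$marker, kept$markers$marker)
})

test_that("mean imputation preserves observed calls and column means", {
  Z <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2)
  G <- impute_missing(make_gm(Z))
  expect_equal(G$geno[3, 1], 1.0) # mean of {0,2}
  expect_equal(G$geno[, 2], c(a1 = 1, a2 = 1, a3 = 1))

  set.seed(7)
  Z2 <- matrix(rbinom(500, 2, 0.3), 50, 10)
  miss <- sample(length(Z2), 50)
  Z2m <- Z2; Z2m[miss] <- NA
  G2 <- impute_missing(make_gm(Z2m))
  expect_equal(unname(colMeans(G2$geno)), colMeans(Z2m, na.rm = TRUE))
  expect_equal(G2$geno[-miss], Z2m[-miss]) # observed untouched
  expect_false(anyNA(G2$geno))

  # no-missing identity
  G3 <- make_gm(Z2)
  expect_equal(impute_missing(G3)$geno, G3$geno + 0.0)
  # all-missing marker is an error
  expect_error(impute_missing(make_gm(matrix(NA_real_, 3, 1))), "all entries")
})
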