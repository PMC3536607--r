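# Independent oracles used across the suite.  These deliberately use
# different algorithms from the package implementations they check.

# Recursive kinship (coancestry) on the pedigree definition:
# f(i,j) for i == j is 0.5 (1 + f(s_i, d_i)); for j older, f(i,j) =
# 0.5 (f(s_i, j) + f(d_i, j)).  Additive relationship a_ij = 2 f(i,j).
oracle_nrm <- function(ped) {
  ped <- dgvacc::sort_pedigree(ped)
  ids <- ped$animal
  n <- length(ids)
  si <- match(ped$sire, ids, nomatch = 0L)
  di <- match(ped$dam, ids, nomatch = 0L)
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp } # i is the younger (larger index)
    key <- paste(i, j)
    if (!is.null(v <- memo[[key]])) return(v)
    v <- if (i == j) {
      0.5 * (1 + f(si[i], di[i]))
    } else {
      0.5 * (f(si[i], j) + f(di[i], j))
    }
    memo[[key]] <- v
    v
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * f(i, j)
  }
  A
}

# Exhaustive double-loop a_max computation.
oracle_amax <- function(A, group) {
  ids <- rownames(A)
  n <- nrow(A)
  res <- data.frame(animal = ids, group = group[ids],
                    amax_within = NA_real_, amax_between = NA_real_)
  for (i in seq_len(n)) {
    w <- b <- NA_real_
    for (j in seq_len(n)) {
      if (i == j) next
      if (group[ids[i]] == group[ids[j]]) {
        w <- max(w, A[i, j], na.rm = TRUE)
      } else {
        b <- max(b, A[i, j], na.rm = TRUE)
      }
    }
    res$amax_within[i] <- w
    res$amax_between[i] <- b
  }
  res
}

# All partitions of n points into at most K non-empty labelled-irrelevant
# clusters; returns the minimum within-cluster sum of squares.
oracle_best_partition <- function(X, K) {
  n <- nrow(X)
  best <- Inf
  # enumerate assignments via restricted growth strings
  rec <- function(assign, next_label) {
    i <- length(assign) + 1L
    if (i > n) {
      if (max(assign) == K) {
        ss <- dgvacc::partition_withinss(X, assign)
        if (ss < best) best <<- ss
      }
      return(invisible())
    }
    for (lab in seq_len(min(next_label, K))) {
      rec(c(assign, lab), next_label + (lab == next_label))
    }
  }
  rec(integer(0), 1L)
  best
}

# Dense restricted log-likelihood of the bivariate model (no block
# factorization), for the REML oracle.  phi = (s2a1, cov, s2a2, s2e1, s2e2).
oracle_neg2reml <- function(phi, y1, y2, w, A, X) {
  n <- length(y1)
  V <- rbind(cbind(phi[1] * A + diag(phi[4] / w, n), phi[2] * A),
             cbind(phi[2] * A, phi[3] * A + diag(phi[5], n)))
  y <- c(y1, y2)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Vi <- chol2inv(ch)
  XtViX <- t(X) %*% Vi %*% X
  XtViy <- t(X) %*% Vi %*% y
  beta_term <- tryCatch(drop(t(XtViy) %*% solve(XtViX, XtViy)),
                        error = function(e) NULL)
  if (is.null(beta_term)) return(1e10)
  2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
    drop(t(y) %*% Vi %*% y) - beta_term
}

# Garrick-style deregression solved numerically from the 2x2 mixed-model
# system: find (ZpZ_pa, ZpZ_i) reproducing the stated reliabilities, then
# deregress via the right-hand sides.
oracle_deregress <- function(ebv, r2, ebv_pa, r2_pa, h2) {
  lambda <- (1 - h2) / h2
  Ginv <- lambda * matrix(c(4, -2, -2, 2), 2)
  resid <- function(z) {
    C <- solve(matrix(c(z[1], 0, 0, z[2]), 2) + Ginv)
    c(C[1, 1] - (0.5 - r2_pa) / lambda,
      C[2, 2] - (1 - r2) / lambda)
  }
  # solve the two nonlinear equations by damped Newton on log-ish scale
  z <- c(1, 1)
  for (it in 1:200) {
    r <- resid(z)
    if (max(abs(r)) < 1e-12) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      dz <- z; h <- max(1e-6, abs(z[j]) * 1e-6); dz[j] <- dz[j] + h
      J[, j] <- (resid(dz) - r) / h
    }
    step <- solve(J, r)
    z <- z - pmin(pmax(step, -5), 5)
  }
  lhs <- matrix(c(z[1], 0, 0, z[2]), 2) + Ginv
  rhs <- lhs %*% c(ebv_pa, ebv)
  debv <- rhs[2] / z[2]
  r2_debv <- z[2] / (z[2] + lambda)
  list(debv = debv, r2_debv = r2_debv, zpz_pa = z[1], zpz_i = z[2])
}
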