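#' Weighted bivariate animal-model REML for trait-DGV genetic correlation
#'
#' Two-trait model on the stacked vector (DEBV, DGV) of the cross-validated
#' animals: fixed effects are the trait mean for the DEBV side and the five
#' cluster-group class effects for the DGV side; random additive effects for
#' the two variables share the block-diagonal relationship matrix G (pedigree
#' relationships within each cross-validation group, zero between groups),
#' with a 2x2 genetic covariance matrix Sigma0; residuals are uncorrelated
#' between the two variables, with the DEBV residual variance heterogeneous
#' (sigma2_e1 / w_i, the same information weights as in training) and the
#' DGV residual homoscedastic.  Zeroing between-group relationships makes
#' the likelihood separable over groups, pooling the per-group information.
#'
#' The restricted likelihood is maximized directly on a log-Cholesky
#' parameterization of Sigma0 (which keeps it positive semidefinite) plus
#' log residual variances, exploiting the per-group factorization of V.
#' Standard errors come from the numerically differentiated observed
#' information at the optimum, and the r_g standard error from the delta
#' method.
#'
#' @name bivariate
NULL

#' Block-diagonal relationship matrix over cross-validation groups
#'
#' Orders animals by group and keeps the pedigree relationships within each
#' group, zeroing everything between groups (diagonal untouched).
#'
#' @param A relationship matrix over the genotyped animals (computed from
#'   the full pedigree before zeroing, so ancestors inform within-group
#'   relationships).
#' @param assignment a `cluster_assignment` covering `rownames(A)`.
#' @return object of class `block_relationship`: `ids` (group-ordered),
#'   `group` (aligned labels), `blocks` (named list of within-group
#'   relationship matrices).
#' @export
build_block_relationship <- function(A, assignment) {
  grp <- assignment_groups(assignment)
  ids <- rownames(A)
  if (!all(ids %in% names(grp))) {
    stop("alignment error: assignment does not cover all animals in A")
  }
  grp <- grp[ids]
  ord <- order(grp, match(ids, ids))
  ids <- ids[ord]
  grp <- grp[ord]
  blocks <- lapply(split(ids, grp), function(g_ids) {
    A[g_ids, g_ids, drop = FALSE]
  })
  structure(list(ids = ids, group = grp, blocks = blocks),
            class = "block_relationship")
}

#' Dense matrix form of a block relationship
#'
#' @param G a `block_relationship`.
#' @return dense matrix with zeros between groups.
#' @export
as_matrix_block <- function(G) {
  n <- length(G$ids)
  M <- matrix(0, n, n, dimnames = list(G$ids, G$ids))
  for (b in G$blocks) M[rownames(b), colnames(b)] <- b
  M
}

# -2 * restricted log-likelihood (up to an additive constant) of the
# bivariate model, factorized over groups.  `data` is the prepared per-group
# list; `phi` = (s2a1, s2a12_cov, s2a2, s2e1, s2e2) on the natural scale.
#
# Within a group, everything is expressed in the eigenbasis of the group's
# relationship block A = U diag(lambda) U' (computed once).  The variable
# with the homoscedastic residual ("side 2") then has a diagonal
# covariance block d2 = a2 lambda + e2, and the whole 2n-dimensional solve
# reduces to one n-dimensional Cholesky of the Schur complement
# S = a1 Lambda + e1 M - c^2 Lambda^2 / d2, where M = U' diag(1/w) U is
# precomputed.  This is what makes REML at a few thousand animals cheap.
neg2reml_bivar <- function(phi, data) {
  s2a1 <- phi[1]; cov12 <- phi[2]; s2a2 <- phi[3]
  s2e1 <- phi[4]; s2e2 <- phi[5]
  if (s2a1 <= 0 || s2a2 <= 0 || s2e1 <= 0 || s2e2 <= 0) return(1e10)
  if (cov12^2 >= s2a1 * s2a2 * (1 - 1e-12)) return(1e10)
  # map (weighted, unweighted) onto (side 1, side 2)
  if (data$weight_side == "debv") {
    a1 <- s2a1; a2 <- s2a2; e1 <- s2e1; e2 <- s2e2
  } else {
    a1 <- s2a2; a2 <- s2a1; e1 <- s2e2; e2 <- s2e1
  }
  p <- data$p
  logdet <- 0
  BtVB <- matrix(0, p + 1L, p + 1L)
  for (blk in data$groups) {
    lam <- blk$lambda
    d2 <- a2 * lam + e2
    if (any(d2 <= 0)) return(1e10)
    f <- cov12 * lam / d2
    S <- e1 * blk$M
    diag(S) <- diag(S) + a1 * lam - cov12 * lam * f
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- logdet + sum(log(d2)) + 2 * sum(log(diag(ch)))
    # solve V [u; v] = B for all columns of B = [X, y] at once
    B1 <- blk$B1; B2 <- blk$B2
    rhs <- B1 - f * B2
    u <- backsolve(ch, forwardsolve(t(ch), rhs))
    v <- (B2 - (cov12 * lam) * u) / d2
    BtVB <- BtVB + crossprod(B1, u) + crossprod(B2, v)
  }
  XtVX <- BtVB[seq_len(p), seq_len(p), drop = FALSE]
  XtVy <- BtVB[seq_len(p), p + 1L]
  ytVy <- BtVB[p + 1L, p + 1L]
  chx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chx)) return(1e10)
  beta_term <- drop(crossprod(backsolve(chx, XtVy, transpose = TRUE)))
  logdet + 2 * sum(log(diag(chx))) + ytVy - beta_term
}

# Prepare the per-group data structure for the likelihood: eigenbasis of
# each relationship block, transformed responses and design columns, and the
# transformed weight matrix.  Side 1 is the variable whose residual carries
# the information weights, side 2 the homoscedastic one.
prepare_bivar_data <- function(debv, dgv, G, weight_side) {
  ids <- intersect(intersect(as.character(debv$animal),
                             as.character(dgv$animal)), G$ids)
  if (length(ids) < 10L) stop("too few animals with both DEBV and DGV")
  grp_levels <- sort(unique(G$group[G$ids %in% ids]))
  p <- 1L + length(grp_levels)
  groups <- list()
  for (g in grp_levels) {
    g_ids <- ids[G$group[match(ids, G$ids)] == g]
    ng <- length(g_ids)
    j1 <- match(g_ids, as.character(debv$animal))
    j2 <- match(g_ids, as.character(dgv$animal))
    w <- debv$weight[j1]
    if (is.null(w)) w <- rep(1, ng)
    Ag <- G$blocks[[as.character(g)]][g_ids, g_ids, drop = FALSE]
    eg <- eigen(Ag, symmetric = TRUE)
    U <- eg$vectors
    lam <- pmax(eg$values, 0)
    y1 <- debv$debv[j1]
    y2 <- dgv$dgv[j2]
    # design in original space: trait mean on DEBV rows (column 1), group
    # class effect on DGV rows (column 1 + index of g)
    o <- drop(crossprod(U, rep(1, ng)))
    X1t <- matrix(0, ng, p); X1t[, 1L] <- o
    X2t <- matrix(0, ng, p); X2t[, 1L + match(g, grp_levels)] <- o
    if (weight_side == "debv") {
      wt1 <- w
      B1 <- cbind(X1t, drop(crossprod(U, y1)))
      B2 <- cbind(X2t, drop(crossprod(U, y2)))
    } else {
      # weights sit on the DGV residual: DGV becomes side 1
      wt1 <- w
      B1 <- cbind(X2t, drop(crossprod(U, y2)))
      B2 <- cbind(X1t, drop(crossprod(U, y1)))
    }
    M <- crossprod(U, (1 / wt1) * U)
    M <- (M + t(M)) / 2
    groups[[as.character(g)]] <- list(n = ng, ids = g_ids, lambda = lam,
                                      M = M, B1 = B1, B2 = B2)
  }
  list(groups = groups, p = p, weight_side = weight_side,
       n = length(ids), ids = ids)
}

#' Fit the weighted bivariate animal model by REML
#'
#' @param debv deregressed-record table (`animal, debv, weight`).
#' @param dgv DGV table (`animal, dgv`), typically the pooled validation
#'   predictions from [run_crossval()].
#' @param G a `block_relationship` from [build_block_relationship()].
#' @param weight_side which residual carries the information weights:
#'   `"debv"` (default; heterogeneous DEBV residual, consistent with
#'   training) or `"dgv"`.
#' @param se compute standard errors (numerical observed information plus
#'   delta method); set `FALSE` to skip.
#' @param start optional starting values `(s2a1, cov12, s2a2, s2e1, s2e2)`.
#' @return object of class `bivariate_estimates`: the five (co)variance
#'   components with standard errors, `r_g` (genetic correlation, clamped to
#'   [-1, 1]), `h2_dgv`, `h2_trait` with SEs, the restricted log-likelihood,
#'   convergence and boundary diagnostics, and the problem size.
#' @export
fit_bivariate_reml <- function(debv, dgv, G, weight_side = c("debv", "dgv"),
                               se = TRUE, start = NULL) {
  weight_side <- match.arg(weight_side)
  data <- prepare_bivar_data(debv, dgv, G, weight_side)
  y1 <- debv$debv[match(data$ids, as.character(debv$animal))]
  y2 <- dgv$dgv[match(data$ids, as.character(dgv$animal))]
  v1 <- stats::var(y1); v2 <- stats::var(y2)
  floor_e1 <- 1e-8 * v1
  floor_e2 <- 1e-8 * v2
  if (is.null(start)) {
    c0 <- 0.4 * sqrt(0.5 * v1 * 0.9 * v2) * sign(stats::cov(y1, y2) + 1e-300)
    start <- c(0.5 * v1, c0, 0.9 * v2, 0.5 * v1, 0.1 * v2)
  }
  # log-Cholesky parameterization of Sigma0 + log residual variances
  to_phi <- function(th) {
    L11 <- exp(th[1]); L21 <- th[2]; L22 <- exp(th[3])
    c(L11^2, L11 * L21, L21^2 + L22^2,
      max(exp(th[4]), floor_e1), max(exp(th[5]), floor_e2))
  }
  to_theta <- function(phi) {
    L11 <- sqrt(phi[1]); L21 <- phi[2] / L11
    L22sq <- max(phi[3] - L21^2, 1e-10 * phi[3])
    c(log(L11), L21, 0.5 * log(L22sq), log(max(phi[4], floor_e1)),
      log(max(phi[5], floor_e2)))
  }
  obj <- function(th) neg2reml_bivar(to_phi(th), data)
  th0 <- to_theta(start)
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  phi <- to_phi(opt$par)
  names(phi) <- c("sigma2_trait", "cov_trait_dgv", "sigma2_dgv",
                  "sigma2_e_debv", "sigma2_e_dgv")
  boundary <- c(sigma2_e_debv = unname(phi[4] <= floor_e1 * 1.01),
                sigma2_e_dgv = unname(phi[5] <= floor_e2 * 1.01))
  r_g <- phi[2] / sqrt(phi[1] * phi[3])
  clamped <- FALSE
  if (abs(r_g) > 1) {
    clamped <- TRUE
    r_g <- sign(r_g)
  }
  h2_dgv <- phi[3] / (phi[3] + phi[5])
  h2_trait <- phi[1] / (phi[1] + phi[4])
  se_phi <- rep(NA_real_, 5)
  se_rg <- se_h2dgv <- se_h2trait <- NA_real_
  if (se) {
    H <- tryCatch(pracma::hessian(function(p) neg2reml_bivar(p, data), phi),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Cov <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(Cov) && all(is.finite(Cov))) {
        dC <- diag(Cov)
        se_phi <- ifelse(dC > 0, sqrt(pmax(dC, 0)), NA_real_)
        # delta method for r_g
        gr <- c(-r_g / (2 * phi[1]), 1 / sqrt(phi[1] * phi[3]),
                -r_g / (2 * phi[3]), 0, 0)
        v_rg <- drop(t(gr) %*% Cov %*% gr)
        if (is.finite(v_rg) && v_rg >= 0) se_rg <- sqrt(v_rg)
        gh <- c(0, 0, phi[5] / (phi[3] + phi[5])^2, 0,
                -phi[3] / (phi[3] + phi[5])^2)
        v_h <- drop(t(gh) %*% Cov %*% gh)
        if (is.finite(v_h) && v_h >= 0) se_h2dgv <- sqrt(v_h)
        gt <- c(phi[4] / (phi[1] + phi[4])^2, 0, 0,
                -phi[1] / (phi[1] + phi[4])^2, 0)
        v_t <- drop(t(gt) %*% Cov %*% gt)
        if (is.finite(v_t) && v_t >= 0) se_h2trait <- sqrt(v_t)
      }
    }
  }
  structure(list(components = phi, se = stats::setNames(se_phi, names(phi)),
                 r_g = unname(r_g), se_r_g = se_rg, r_g_clamped = clamped,
                 h2_dgv = unname(h2_dgv), se_h2_dgv = se_h2dgv,
                 h2_trait = unname(h2_trait), se_h2_trait = se_h2trait,
                 logLik = -0.5 * opt$value,
                 convergence = opt$convergence,
                 boundary = boundary, weight_side = weight_side,
                 n = data$n),
            class = "bivariate_estimates")
}

#' @export
print.bivariate_estimates <- function(x, ...) {
  cat("bivariate_estimates (n =", x$n, "):\n")
  comp <- data.frame(estimate = x$components, se = x$se)
  print(round(comp, 4))
  cat(sprintf("r_g = %.3f (SE %.3f), h2_dgv = %.3f, h2_trait = %.3f\n",
              x$r_g, x$se_r_g, x$h2_dgv, x$h2_trait))
  if (any(x$boundary)) {
    cat("converged at boundary:",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genetic correlation from (co)variance components
#'
#' r_g = cov / sqrt(var1 * var2), clamped to [-1, 1] (a message is emitted
#' when clamping occurs; REML estimates at the boundary can overshoot by
#' rounding).
#'
#' @param est a `bivariate_estimates` object, or a numeric vector/list with
#'   `sigma2_trait`, `sigma2_dgv`, `cov_trait_dgv`.
#' @return the genetic correlation.
#' @export
genetic_correlation <- function(est) {
  if (inherits(est, "bivariate_estimates")) {
    v1 <- est$components[["sigma2_trait"]]
    v2 <- est$components[["sigma2_dgv"]]
    cv <- est$components[["cov_trait_dgv"]]
  } else {
    v1 <- est[["sigma2_trait"]]; v2 <- est[["sigma2_dgv"]]
    cv <- est[["cov_trait_dgv"]]
  }
  if (!is.finite(v1) || !is.finite(v2) || v1 <= 0 || v2 <= 0) {
    stop("undefined-correlation error: genetic variances must be positive")
  }
  r <- cv / sqrt(v1 * v2)
  if (abs(r) > 1) {
    message("genetic correlation ", format(r, digits = 4),
            " clamped to [-1, 1]")
    r <- sign(r)
  }
  r
}
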