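#' Weighted BayesC for marker effects and DGV prediction
#'
#' Single-site Gibbs sampler for the mixture model
#' y_i = mu + sum_j z_ij u_j + e_i with u_j = 0 with probability pi and
#' u_j ~ N(0, sigma2_u) otherwise, and heterogeneous residual variance
#' sigma2_e / w_i driven by the DEBV information weights.  Direct genomic
#' breeding values are the dosage-weighted sums of posterior-mean effects.
#'
#' @name bayesc
NULL

#' BayesC sampler configuration
#'
#' @param pi prior probability that a marker has zero effect (default 0.95).
#' @param chain_length total Gibbs sweeps (default 41000).
#' @param burn_in discarded initial sweeps (default 1000).
#' @param nu_u,nu_e prior degrees of freedom of the scaled-inverse-chi-square
#'   priors on the marker-effect and residual variances (default 4).
#' @param scale_u,scale_e prior scale parameters; `NA` means "set by
#'   [initialize_priors()] before training".
#' @param fixed_variances if `TRUE`, sigma2_u and sigma2_e stay fixed at
#'   their scales (used by the SNP-BLUP equivalence checks).
#' @param seed integer seed.
#' @return a `bayesc_config` list.
#' @export
bayesc_config <- function(pi = 0.95, chain_length = 41000, burn_in = 1000,
                          nu_u = 4, nu_e = 4, scale_u = NA_real_,
                          scale_e = NA_real_, fixed_variances = FALSE,
                          seed = 1L) {
  if (pi < 0 || pi >= 1) stop("config error: pi must lie in [0, 1)")
  if (burn_in >= chain_length) {
    stop("config error: burn_in must be smaller than chain_length")
  }
  structure(list(pi = pi, chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), nu_u = nu_u, nu_e = nu_e,
                 scale_u = scale_u, scale_e = scale_e,
                 fixed_variances = isTRUE(fixed_variances),
                 seed = as.integer(seed)),
            class = "bayesc_config")
}

#' Set prior scales from the full training data
#'
#' Partitions the weighted phenotypic variance of the DEBV by the trait
#' heritability: genetic scale = h2 * Var(y), residual scale =
#' (1 - h2) * Var(y).  The per-marker effect-variance scale divides the
#' genetic scale by (1 - pi) * sum_j 2 p_j (1 - p_j) (expected genetic
#' variance contributed by the included markers at the observed allele
#' frequencies), with the (1 - pi) divisor floored at 1e-6.
#'
#' @param debv deregressed-record table (`debv`, `weight` columns), usually
#'   from [build_debv_table()].
#' @param genotypes imputed [geno_matrix()] covering the training animals.
#' @param config a [bayesc_config()].
#' @param h2 trait heritability used for the partition.
#' @return the config with `scale_u` and `scale_e` filled in.
#' @export
initialize_priors <- function(debv, genotypes, config, h2) {
  stopifnot(inherits(config, "bayesc_config"))
  vy <- stats::var(debv$debv)
  if (!is.finite(vy) || vy <= 0) {
    stop("degenerate variance: DEBV have zero phenotypic variance")
  }
  var_g <- h2 * vy
  var_e <- (1 - h2) * vy
  Z <- genotypes$geno[match(as.character(debv$animal), genotypes$animals), ,
                      drop = FALSE]
  p <- colMeans(Z) / 2
  het <- sum(2 * p * (1 - p))
  config$scale_u <- var_g / (max(1 - config$pi, 1e-6) * max(het, 1e-12))
  config$scale_e <- var_e
  config
}

#' Train weighted BayesC on deregressed records
#'
#' @param debv deregressed-record table with columns `animal`, `debv`,
#'   `weight` (see [build_debv_table()]).
#' @param genotypes imputed [geno_matrix()] (no missing entries) containing
#'   every training animal.
#' @param config a [bayesc_config()]; if its scales are `NA`,
#'   [initialize_priors()] is run first with `h2`.
#' @param h2 trait heritability (needed only when priors are unset).
#' @return object of class `marker_effects`: list with `marker`, `effect`
#'   (posterior means), `inclusion_freq`, `mu`, `sigma2_u`, `sigma2_e`,
#'   `n_train`, `config`.
#' @export
train_bayesc <- function(debv, genotypes, config = bayesc_config(), h2 = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "bayesc_config"))
  idx <- match(as.character(debv$animal), genotypes$animals)
  if (anyNA(idx)) {
    stop("training animal(s) missing from genotypes: ",
         paste(debv$animal[is.na(idx)][1:5], collapse = ", "))
  }
  Z <- genotypes$geno[idx, , drop = FALSE]
  if (anyNA(Z)) stop("genotypes must be imputed before training")
  w <- debv$weight
  if (is.null(w)) w <- rep(1, nrow(debv))
  if (any(!is.finite(w) | w <= 0)) stop("input error: weights must be positive")
  if (is.na(config$scale_u) || is.na(config$scale_e)) {
    if (is.null(h2)) stop("h2 is required to initialize prior scales")
    config <- initialize_priors(debv, genotypes, config, h2 = h2)
  }
  set.seed(config$seed)
  fit <- .bayesc_gibbs(as.numeric(debv$debv), Z, as.numeric(w),
                       config$pi, config$chain_length, config$burn_in,
                       config$nu_u, config$nu_e,
                       config$scale_u, config$scale_e,
                       config$fixed_variances)
  structure(list(marker = genotypes$markers$marker,
                 effect = as.numeric(fit$effect),
                 inclusion_freq = as.numeric(fit$inclusion_freq),
                 mu = fit$mu, sigma2_u = fit$sigma2_u,
                 sigma2_e = fit$sigma2_e, n_train = nrow(Z),
                 config = config),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat("marker_effects:", length(x$effect), "markers, trained on", x$n_train,
      "records; mean inclusion", format(mean(x$inclusion_freq), digits = 3),
      "\n")
  invisible(x)
}

#' Predict direct genomic breeding values
#'
#' DGV_i = sum_j z_ij * effect_j over the posterior-mean marker effects.
#' The intercept is excluded: it is a constant shift, irrelevant to the
#' correlations and (co)variances evaluated downstream, and group-mean
#' differences are absorbed by the bivariate model's group fixed effects.
#'
#' @param genotypes imputed [geno_matrix()] of the animals to predict.
#' @param effects a `marker_effects` fit whose marker set matches
#'   `genotypes` exactly and in order.
#' @return data frame `animal, dgv`.
#' @export
predict_dgv <- function(genotypes, effects) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(effects, "marker_effects"))
  if (!identical(as.character(genotypes$markers$marker),
                 as.character(effects$marker))) {
    bad <- union(setdiff(genotypes$markers$marker, effects$marker),
                 setdiff(effects$marker, genotypes$markers$marker))
    stop("alignment error: marker sets differ",
         if (length(bad)) paste0(" (e.g. ", paste(utils::head(bad, 5),
                                                  collapse = ", "), ")"))
  }
  dgv <- drop(genotypes$geno %*% effects$effect)
  data.frame(animal = genotypes$animals, dgv = dgv,
             row.names = NULL, stringsAsFactors = FALSE)
}
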