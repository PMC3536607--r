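#' K-fold cross-validation over relatedness-clustered groups
#'
#' Each fold trains the BayesC model on the deregressed records of the
#' animals outside one cluster group and predicts DGV for every genotyped
#' animal inside it, so each animal's DGV never sees its own DEBV.
#'
#' @name crossval
NULL

#' Deterministic per-fold seed from a master seed
#'
#' @param seed master integer seed.
#' @param fold fold number.
#' @return integer seed below 2^31.
#' @export
fold_seed <- function(seed, fold) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(fold) * 7919) %%
               2147483647)
}

#' Run grouped cross-validation
#'
#' @param debv deregressed-record table (`animal, debv, weight`); animals
#'   lacking a record are still predicted but never trained on.
#' @param genotypes imputed [geno_matrix()] covering all clustered animals.
#' @param assignment a `cluster_assignment` over the genotyped animals.
#' @param config a [bayesc_config()]; its seed is the master seed from which
#'   per-fold seeds are derived, so folds are reproducible in isolation and
#'   independent of execution order.
#' @param h2 trait heritability for prior initialization (priors are set
#'   once from the full data so all folds share them, mirroring the
#'   preliminary full-data variance estimation).
#' @return object of class `crossval_result`: `dgv` (data frame
#'   `animal, dgv, group`, one row per genotyped animal), `folds` (per-fold
#'   list with `group`, `n_train`, `n_validate`, `train_animals`, `effects`).
#' @export
run_crossval <- function(debv, genotypes, assignment, config = bayesc_config(),
                         h2 = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  grp <- assignment$group
  if (!all(genotypes$animals %in% names(grp))) {
    stop("assignment does not cover all genotyped animals")
  }
  if (assignment$K < 2) stop("configuration error: need at least 2 groups")
  debv <- debv[as.character(debv$animal) %in% genotypes$animals, , drop = FALSE]
  if (is.na(config$scale_u) || is.na(config$scale_e)) {
    if (is.null(h2)) stop("h2 is required to initialize prior scales")
    config <- initialize_priors(debv, genotypes, config, h2 = h2)
  }
  folds <- list()
  preds <- list()
  for (g in sort(unique(grp[genotypes$animals]))) {
    val_ids <- genotypes$animals[grp[genotypes$animals] == g]
    train <- debv[!(as.character(debv$animal) %in% val_ids), , drop = FALSE]
    if (nrow(train) == 0L) {
      warning("fold ", g, " skipped: no training records")
      next
    }
    fold_cfg <- config
    fold_cfg$seed <- fold_seed(config$seed, g)
    fit <- train_bayesc(train, genotypes, fold_cfg)
    pred <- predict_dgv(subset_geno(genotypes, animals = val_ids), fit)
    pred$group <- g
    preds[[as.character(g)]] <- pred
    folds[[as.character(g)]] <- list(group = g, n_train = nrow(train),
                                     n_validate = length(val_ids),
                                     train_animals = as.character(train$animal),
                                     effects = fit)
  }
  dgv <- do.call(rbind, preds)
  rownames(dgv) <- NULL
  stopifnot(!anyDuplicated(dgv$animal))
  structure(list(dgv = dgv, folds = folds, config = config),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("crossval_result:", nrow(x$dgv), "animals predicted over",
      length(x$folds), "folds\n")
  invisible(x)
}
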