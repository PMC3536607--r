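#' K-means cross-validation groups from pedigree relationships
#'
#' Genotyped animals are partitioned into K (default 5) mutually exclusive
#' groups by Hartigan-Wong K-means on the rows of a difference matrix derived
#' from the numerator relationship matrix, so relatedness is high within and
#' low between groups.  Each row of the difference matrix (an animal's
#' dissimilarity profile to every other animal) is treated as a Euclidean
#' coordinate vector.
#'
#' @name clustering
NULL

#' Difference matrix from a relationship matrix
#'
#' d_ij = max(A) - a_ij with the diagonal zeroed; symmetric and
#' non-negative even for inbred pedigrees (max over the whole matrix,
#' including diagonals).
#'
#' @param A symmetric relationship matrix.
#' @return dissimilarity matrix of the same dimension.
#' @export
difference_matrix <- function(A) {
  stopifnot(is.matrix(A), isTRUE(all.equal(A, t(A), tolerance = 1e-8)))
  D <- max(A) - A
  diag(D) <- 0
  D
}

#' K-means clustering of animals into cross-validation groups
#'
#' Runs Hartigan-Wong K-means on the rows of `D`, keeping the best of
#' `restarts` seeded random initializations (lowest within-cluster sum of
#' squares; ties broken by first found).  Deterministic under `seed`.  An
#' initialization that collapses to an empty cluster is repaired by
#' `stats::kmeans`'s restart or skipped.
#'
#' @param D dissimilarity matrix from [difference_matrix()]; rows are the
#'   clustering coordinates.
#' @param K number of groups (default 5).
#' @param restarts random initializations (default 50).
#' @param seed integer seed.
#' @return object of class `cluster_assignment`: list with `group` (named
#'   integer vector of labels 1..K), `sizes`, `K`, `tot_withinss`.
#' @export
kmeans_groups <- function(D, K = 5, restarts = 50, seed = 1L) {
  n <- nrow(D)
  if (K < 2) stop("configuration error: K must be >= 2")
  if (K > n) stop("configuration error: K exceeds the number of animals")
  if (restarts < 1) stop("configuration error: restarts must be >= 1")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- D[sample.int(n, K), , drop = FALSE]
    fit <- tryCatch(
      stats::kmeans(D, centers = centers, algorithm = "Hartigan-Wong",
                    iter.max = 100),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (any(fit$size == 0)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12) {
      best <- fit
    }
  }
  if (is.null(best)) stop("k-means failed for every initialization")
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  grp <- stats::setNames(as.integer(best$cluster), ids)
  if (any(tabulate(grp, K) == 1L)) {
    warning("singleton cluster group(s); within-group a_max will be ",
            "undefined for their members")
  }
  structure(list(group = grp, sizes = tabulate(grp, K), K = K,
                 tot_withinss = best$tot.withinss),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: K =", x$K, "; sizes:",
      paste(x$sizes, collapse = ", "),
      "; within-SS =", format(x$tot_withinss, digits = 6), "\n")
  invisible(x)
}

#' Random fold assignment (contrast baseline)
#'
#' Random, roughly equal-sized folds ignoring relatedness; used to contrast
#' relationship-aware clustering with conventional random cross-validation.
#'
#' @param ids animal identifiers.
#' @param K number of folds.
#' @param seed integer seed.
#' @return a `cluster_assignment`.
#' @export
random_folds <- function(ids, K = 5, seed = 1L) {
  set.seed(seed)
  n <- length(ids)
  grp <- sample(rep_len(seq_len(K), n))
  grp <- stats::setNames(as.integer(grp), as.character(ids))
  structure(list(group = grp, sizes = tabulate(grp, K), K = K,
                 tot_withinss = NA_real_),
            class = "cluster_assignment")
}

#' Clustering quality as an a_max report
#'
#' Delegates to [amax_report()]: per-group mean and SD of within-group and
#' between-group maximum relationships.  Successful relatedness clustering
#' shows within > between in every group.
#'
#' @param assignment a `cluster_assignment`.
#' @param A relationship matrix over the clustered animals.
#' @return see [amax_report()].
#' @export
clustering_quality <- function(assignment, A) {
  amax_report(A, assignment)
}

#' Within-cluster sum of squares of a partition (direct computation)
#'
#' Used as the comparison objective for the brute-force partition oracle and
#' for 1-swap optimality checks.
#'
#' @param X coordinate matrix (rows = points).
#' @param labels integer cluster labels.
#' @return total within-cluster sum of squared Euclidean distances to
#'   cluster centroids.
#' @export
partition_withinss <- function(X, labels) {
  sum(vapply(split(seq_len(nrow(X)), labels), function(idx) {
    xc <- X[idx, , drop = FALSE]
    sum(sweep(xc, 2, colMeans(xc))^2)
  }, numeric(1)))
}
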