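#' Marker quality control and mean imputation
#'
#' Panel harmonization by marker-name intersection, per-marker call rate,
#' minor allele frequency and Hardy-Weinberg test statistics, threshold
#' filtering (defaults: call rate >= 0.95, MAF >= 0.005, HWE p > 1e-30), and
#' replacement of missing dosages by the marker mean on the 0-2 scale.
#'
#' @name genotype-qc
NULL

#' Merge genotype panels on their common markers
#'
#' Intersects marker names across panels (preserving the first panel's
#' order) and stacks the animals.  Allele orientation is assumed consistent
#' across panels (the writers in this package guarantee it).
#'
#' @param panels list of [geno_matrix()] objects.
#' @return a single `geno_matrix` over the shared markers.
#' @export
harmonize_panels <- function(panels) {
  stopifnot(length(panels) >= 1, all(vapply(panels, inherits, TRUE, "geno_matrix")))
  if (length(panels) == 1L) return(panels[[1L]])
  common <- Reduce(intersect, lapply(panels, function(p) p$markers$marker))
  if (!length(common)) stop("empty-result error: no markers shared across panels")
  ids <- unlist(lapply(panels, function(p) p$animals))
  if (anyDuplicated(ids)) {
    stop("conflict error: duplicated animal id(s) across panels: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  geno <- do.call(rbind, lapply(panels, function(p) {
    p$geno[, common, drop = FALSE]
  }))
  mk <- panels[[1L]]$markers
  mk <- mk[match(common, mk$marker), , drop = FALSE]
  geno_matrix(geno, ids, mk)
}

#' Per-marker QC statistics
#'
#' Call rate = non-missing fraction; MAF = min(p, 1-p) with p the mean dosage
#' over non-missing calls divided by 2; HWE p-value from the Pearson
#' chi-square (1 df, no continuity correction) comparing observed genotype
#' counts to Hardy-Weinberg expectations at the observed allele frequency.
#' Monomorphic markers (p = 0 or 1) get hwe_p = 1: they are removed by the
#' MAF rule, not the HWE rule.  All-missing markers get call_rate 0 and `NA`
#' statistics.
#'
#' @param G a [geno_matrix()] (pre-imputation).
#' @return data frame `marker, call_rate, maf, hwe_chisq, hwe_p`.
#' @export
compute_marker_stats <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  Z <- G$geno
  n <- nrow(Z)
  n_obs <- colSums(!is.na(Z))
  call_rate <- n_obs / n
  n0 <- colSums(Z == 0, na.rm = TRUE)
  n1 <- colSums(Z == 1, na.rm = TRUE)
  n2 <- colSums(Z == 2, na.rm = TRUE)
  p <- ifelse(n_obs > 0, (n1 + 2 * n2) / (2 * n_obs), NA_real_)
  maf <- pmin(p, 1 - p)
  # HWE Pearson chi-square against expected counts n*(q^2, 2pq, p^2)
  e0 <- n_obs * (1 - p)^2
  e1 <- n_obs * 2 * p * (1 - p)
  e2 <- n_obs * p^2
  chisq <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p > 0 & p < 1
  chisq[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  hwe_p <- rep(NA_real_, length(p))
  hwe_p[ok] <- stats::pchisq(chisq[ok], df = 1, lower.tail = FALSE)
  hwe_p[!is.na(p) & !ok] <- 1 # monomorphic: fails on MAF instead
  data.frame(marker = G$markers$marker, call_rate = call_rate, maf = maf,
             hwe_chisq = chisq, hwe_p = hwe_p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter markers on QC thresholds
#'
#' Keeps markers with call_rate >= `min_call_rate` AND maf >= `min_maf` AND
#' hwe_p > `min_hwe_p`, in their original order.  Markers with `NA`
#' statistics (all-missing or monomorphic) fail the corresponding predicate.
#'
#' @param G a [geno_matrix()].
#' @param stats QC table from [compute_marker_stats()] aligned to `G`.
#' @param min_call_rate,min_maf,min_hwe_p thresholds, all in [0, 1].
#' @return the filtered `geno_matrix`, with a `qc` attribute carrying the
#'   per-marker pass flags.
#' @export
filter_markers <- function(G, stats = compute_marker_stats(G),
                           min_call_rate = 0.95, min_maf = 0.005,
                           min_hwe_p = 1e-30) {
  stopifnot(inherits(G, "geno_matrix"),
            identical(stats$marker, G$markers$marker))
  thr <- c(min_call_rate, min_maf, min_hwe_p)
  if (any(thr < 0 | thr > 1)) {
    stop("configuration error: QC thresholds must lie in [0, 1]")
  }
  pass_call <- !is.na(stats$call_rate) & stats$call_rate >= min_call_rate
  pass_maf <- !is.na(stats$maf) & stats$maf >= min_maf
  pass_hwe <- !is.na(stats$hwe_p) & stats$hwe_p > min_hwe_p
  pass <- pass_call & pass_maf & pass_hwe
  out <- subset_geno(G, markers = which(pass))
  attr(out, "qc") <- cbind(stats,
                           pass_call_rate = pass_call, pass_maf = pass_maf,
                           pass_hwe = pass_hwe, pass = pass)
  out
}

#' Mean-impute missing dosages
#'
#' Replaces each missing entry by the marker's mean dosage over the
#' non-missing calls of the same dataset (0-2 scale; imputed values may be
#' fractional).  Observed calls are untouched, so per-marker means are
#' preserved exactly.
#'
#' @param G a [geno_matrix()] that has passed [filter_markers()].
#' @return a `geno_matrix` with no missing entries (storage becomes double).
#' @export
impute_missing <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  Z <- G$geno
  storage.mode(Z) <- "double"
  miss <- is.na(Z)
  if (any(miss)) {
    mu <- colMeans(Z, na.rm = TRUE)
    if (anyNA(mu)) {
      stop("marker(s) with all entries missing: ",
           paste(G$markers$marker[is.na(mu)], collapse = ", "),
           " (should have been removed by filter_markers)")
    }
    for (j in which(colSums(miss) > 0)) Z[miss[, j], j] <- mu[j]
  }
  out <- G
  out$geno <- Z
  out
}
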