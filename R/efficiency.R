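#' Efficiency of selection on DGV versus parent average
#'
#' The relative selection response from using DGV instead of parent-average
#' information, assuming identical selection intensity and generation
#' interval: Efficiency = accuracy of DGV / accuracy of PA =
#' r_g(T, DGV) / sqrt(R2_PA).
#'
#' @name efficiency
NULL

#' Selection efficiency ratio
#'
#' @param r_g genetic correlation between trait and DGV (the DGV accuracy);
#'   non-negative.
#' @param r2_pa parent-average reliability in (0, 1]; `0` yields `NA` with a
#'   warning (efficiency undefined, not infinite).
#' @return efficiency ratio, vectorized.
#' @export
selection_efficiency <- function(r_g, r2_pa) {
  if (any(r_g < 0, na.rm = TRUE)) {
    stop("domain error: r_g must be non-negative")
  }
  if (any(r2_pa < 0 | r2_pa > 1, na.rm = TRUE)) {
    stop("domain error: r2_pa must lie in [0, 1]")
  }
  out <- ifelse(r2_pa > 0, r_g / sqrt(r2_pa), NA_real_)
  if (any(r2_pa == 0, na.rm = TRUE)) {
    warning("r2_pa = 0: efficiency undefined, reported as missing")
  }
  out
}

#' Parent-average reliabilities for a cohort
#'
#' Per-animal R2_PA = (R2_sire + R2_dam) / 4 from BIF-converted parental
#' reliabilities taken from the evaluation table; unknown or unevaluated
#' parents contribute reliability 0.
#'
#' @param evaluation data frame `animal, bif_acc` (one trait).
#' @param pedigree pedigree covering the cohort.
#' @param cohort animal identifiers of interest.
#' @return list with `animals` (data frame `animal, r2_sire, r2_dam, r2_pa`)
#'   and `mean_r2_pa`.
#' @export
cohort_pa_reliability <- function(evaluation, pedigree, cohort) {
  if (!length(cohort)) stop("empty cohort")
  pi_ <- match(cohort, pedigree$animal)
  if (anyNA(pi_)) {
    stop("cohort animal(s) missing from pedigree: ",
         paste(cohort[is.na(pi_)][1:5], collapse = ", "))
  }
  parent_r2 <- function(pid) {
    out <- rep(0, length(pid))
    known <- !is.na(pid) & pid != 0
    j <- match(pid[known], evaluation$animal)
    r2 <- ifelse(is.na(j), 0, bif_to_reliability(evaluation$bif_acc[j]))
    out[known] <- r2
    out
  }
  r2s <- parent_r2(pedigree$sire[pi_])
  r2d <- parent_r2(pedigree$dam[pi_])
  r2pa <- parent_average_reliability(r2s, r2d)
  list(animals = data.frame(animal = cohort, r2_sire = r2s, r2_dam = r2d,
                            r2_pa = r2pa, stringsAsFactors = FALSE),
       mean_r2_pa = mean(r2pa))
}

#' Per-trait efficiency report
#'
#' Combines per-trait bivariate estimates with cohort parent-average
#' reliabilities into a table of trait-level efficiencies (using the cohort
#' mean R2_PA), optionally attaching per-animal efficiency distributions.
#'
#' @param estimates named list of `bivariate_estimates` (or of lists with an
#'   `r_g` element), one per trait.
#' @param pa result of [cohort_pa_reliability()], or a named list of them
#'   (one per trait).
#' @param cohort_label label written into the output.
#' @param per_animal attach per-animal efficiencies?
#' @return data frame `trait, r_g, r2_pa, efficiency, cohort`; when
#'   `per_animal`, an attribute `"per_animal"` holds the per-animal table.
#' @export
efficiency_report <- function(estimates, pa, cohort_label = "genotyped",
                              per_animal = FALSE) {
  traits <- names(estimates)
  get_pa <- function(tr) if (!is.null(pa$mean_r2_pa)) pa else pa[[tr]]
  rows <- list()
  per <- list()
  for (tr in traits) {
    est <- estimates[[tr]]
    if (is.null(est) || is.null(est$r_g) || !is.finite(est$r_g)) {
      warning("trait '", tr, "' skipped: no genetic-correlation estimate")
      next
    }
    pa_tr <- get_pa(tr)
    eff <- selection_efficiency(max(est$r_g, 0), pa_tr$mean_r2_pa)
    rows[[tr]] <- data.frame(trait = tr, r_g = est$r_g,
                             r2_pa = pa_tr$mean_r2_pa, efficiency = eff,
                             cohort = cohort_label, stringsAsFactors = FALSE)
    if (per_animal) {
      an <- pa_tr$animals
      an$trait <- tr
      an$efficiency <- ifelse(an$r2_pa > 0,
                              max(est$r_g, 0) / sqrt(an$r2_pa), NA_real_)
      per[[tr]] <- an
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (per_animal) attr(out, "per_animal") <- do.call(rbind, per)
  out
}
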