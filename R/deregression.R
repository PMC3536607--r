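#' Deregression of estimated breeding values
#'
#' Converts association-evaluation output (EPD with BIF accuracies) into
#' deregressed EBV (DEBV) free of parent-average effects, with the
#' information weights used both as BayesC residual weights and as bivariate
#' animal-model weights.
#'
#' The parent-average removal solves the 2x2 mixed-model information system
#' in the unknowns (parent average, individual) with genetic covariance
#' structure [[1/2, 1/2], [1/2, 1]] sigma2_g.  With lambda = (1 - h2) / h2,
#' alpha = 1 / (0.5 - r2_PA) and delta = (0.5 - r2_PA) / (1 - r2), the
#' effective own-information content and the parent-average information are
#'
#'   Z'Z_PA = lambda (0.5 alpha - 4) + 0.5 lambda sqrt(alpha^2 + 16 / delta)
#'   Z'Z_i  = delta Z'Z_PA + 2 lambda (2 delta - 1)
#'
#' and the DEBV is the individual's right-hand side divided by its own
#' information, DEBV = (-2 lambda PA + (Z'Z_i + 2 lambda) EBV) / Z'Z_i, with
#' reliability r2_DEBV = Z'Z_i / (Z'Z_i + lambda).
#'
#' @name deregression
NULL

#' BIF accuracy to reliability
#'
#' R2 = 1 - (1 - BIF)^2; monotone increasing on [0, 1].
#'
#' @param bif_accuracy BIF accuracy in [0, 1] (vectorized).
#' @return reliability in [0, 1].
#' @export
bif_to_reliability <- function(bif_accuracy) {
  if (any(bif_accuracy < 0 | bif_accuracy > 1, na.rm = TRUE)) {
    stop("domain error: BIF accuracy must lie in [0, 1]")
  }
  1 - (1 - bif_accuracy)^2
}

#' Reliability to BIF accuracy (inverse conversion)
#'
#' @param r2 reliability in [0, 1].
#' @return BIF accuracy 1 - sqrt(1 - r2).
#' @export
reliability_to_bif <- function(r2) {
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) {
    stop("domain error: reliability must lie in [0, 1]")
  }
  1 - sqrt(1 - r2)
}

#' EPD to EBV
#'
#' @param epd expected progeny difference (trait units).
#' @return EBV = 2 * EPD.
#' @export
epd_to_ebv <- function(epd) 2 * epd

#' Parent-average reliability
#'
#' Reliability of the parent-average prediction of an animal's breeding
#' value under the additive model: (r2_sire + r2_dam) / 4, with a missing
#' parent contributing 0.  Maximum 0.5 when both parents are known exactly.
#'
#' @param r2_sire,r2_dam parental reliabilities in [0, 1]; `NA` = unknown.
#' @return parent-average reliability in [0, 0.5].
#' @export
parent_average_reliability <- function(r2_sire, r2_dam) {
  r2_sire[is.na(r2_sire)] <- 0
  r2_dam[is.na(r2_dam)] <- 0
  if (any(r2_sire < 0 | r2_sire > 1 | r2_dam < 0 | r2_dam > 1)) {
    stop("domain error: parental reliabilities must lie in [0, 1]")
  }
  (r2_sire + r2_dam) / 4
}

#' Deregress one EBV, removing the parent-average contribution
#'
#' Vectorized over animals.  Records whose reliability does not exceed the
#' parent-average reliability carry no own/progeny information and are
#' flagged uninformative (`NA` outputs); callers drop them from training.
#' With `r2_pa = 0` (unknown or information-less parents) the computation
#' reduces to simple deregression: debv = ebv / r2, r2_debv = r2.
#'
#' @param ebv estimated breeding value (2 * EPD).
#' @param r2 reliability of the EBV, in (0, 1).
#' @param ebv_pa parent-average EBV, (EBV_sire + EBV_dam) / 2.
#' @param r2_pa parent-average reliability, in [0, 0.5).
#' @param h2 trait heritability in (0, 1).
#' @return data frame `debv, r2_debv, informative`.
#' @export
deregress <- function(ebv, r2, ebv_pa = 0, r2_pa = 0, h2) {
  n <- max(length(ebv), length(r2), length(ebv_pa), length(r2_pa))
  ebv <- rep_len(ebv, n); r2 <- rep_len(r2, n)
  ebv_pa <- rep_len(ebv_pa, n); r2_pa <- rep_len(r2_pa, n)
  if (any(r2 <= 0 | r2 >= 1)) stop("domain error: r2 must lie in (0, 1)")
  if (any(r2_pa < 0 | r2_pa >= 0.5)) {
    stop("domain error: r2_pa must lie in [0, 0.5)")
  }
  if (h2 <= 0 || h2 >= 1) stop("domain error: h2 must lie in (0, 1)")
  lambda <- (1 - h2) / h2
  debv <- r2_debv <- rep(NA_real_, n)
  informative <- r2 > r2_pa + 1e-9
  simple <- informative & r2_pa <= 0
  debv[simple] <- ebv[simple] / r2[simple]
  r2_debv[simple] <- r2[simple]
  g <- informative & r2_pa > 0
  if (any(g)) {
    alpha <- 1 / (0.5 - r2_pa[g])
    delta <- (0.5 - r2_pa[g]) / (1 - r2[g])
    zpz_pa <- lambda * (0.5 * alpha - 4) +
      0.5 * lambda * sqrt(alpha^2 + 16 / delta)
    zpz_i <- delta * zpz_pa + 2 * lambda * (2 * delta - 1)
    rhs_i <- -2 * lambda * ebv_pa[g] + (zpz_i + 2 * lambda) * ebv[g]
    debv[g] <- rhs_i / zpz_i
    r2_debv[g] <- zpz_i / (zpz_i + lambda)
  }
  data.frame(debv = debv, r2_debv = r2_debv, informative = informative)
}

#' Information weight for a deregressed record
#'
#' w = (1 - h2) / ((c + (1 - r2_debv) / r2_debv) * h2), the weight used for
#' the heterogeneous residual variance in both BayesC training and the
#' bivariate model; `c` is the proportion of genetic variance not explained
#' by markers (default 0.40).  Strictly increasing in `r2_debv`.
#'
#' @param r2_debv DEBV reliability in (0, 1].
#' @param c proportion of genetic variance not captured by markers, [0, 1).
#' @param h2 trait heritability in (0, 1).
#' @return positive weight; `Inf` (with a warning) in the unbounded
#'   r2_debv = 1, c = 0 corner.
#' @export
debv_weight <- function(r2_debv, c = 0.40, h2) {
  if (any(r2_debv <= 0 | r2_debv > 1)) {
    stop("domain error: r2_debv must lie in (0, 1]")
  }
  if (c < 0 || c >= 1) stop("domain error: c must lie in [0, 1)")
  if (h2 <= 0 || h2 >= 1) stop("domain error: h2 must lie in (0, 1)")
  denom <- (c + (1 - r2_debv) / r2_debv) * h2
  w <- (1 - h2) / denom
  if (any(!is.finite(w))) {
    warning("unbounded weight at r2_debv = 1 with c = 0; returning Inf")
  }
  w
}

#' Build a deregressed training table from evaluation output and a pedigree
#'
#' Converts EPD to EBV, BIF accuracies to reliabilities, forms each animal's
#' parent average (current parental EBVs and reliabilities; missing parents
#' contribute zero information), deregresses, and attaches information
#' weights.  Uninformative records and animals lacking an evaluation are
#' dropped.
#'
#' @param evaluation data frame `animal, trait, epd, bif_acc` (one trait).
#' @param pedigree pedigree data frame covering the evaluated animals.
#' @param h2 trait heritability.
#' @param c proportion of genetic variance not explained by markers.
#' @return data frame `animal, trait, debv, r2_debv, weight` (informative
#'   records only).
#' @export
build_debv_table <- function(evaluation, pedigree, h2, c = 0.40) {
  stopifnot(all(c("animal", "epd", "bif_acc") %in% names(evaluation)))
  ev <- evaluation[!is.na(evaluation$epd) & !is.na(evaluation$bif_acc), ]
  ebv <- epd_to_ebv(ev$epd)
  r2 <- bif_to_reliability(ev$bif_acc)
  # guard the open-interval requirement of deregress()
  r2 <- pmin(pmax(r2, 1e-6), 1 - 1e-6)
  pi_ <- match(ev$animal, pedigree$animal)
  si <- pedigree$sire[pi_]
  di <- pedigree$dam[pi_]
  parent_stats <- function(pid) {
    j <- match(pid, ev$animal)
    list(ebv = ifelse(is.na(j), 0, ebv[j]),
         r2 = ifelse(is.na(j), 0, r2[j]))
  }
  s <- parent_stats(ifelse(is.na(si) | si == 0, NA, si))
  d <- parent_stats(ifelse(is.na(di) | di == 0, NA, di))
  ebv_pa <- (s$ebv + d$ebv) / 2
  r2_pa <- pmin(parent_average_reliability(s$r2, d$r2), 0.5 - 1e-9)
  dr <- deregress(ebv, r2, ebv_pa, r2_pa, h2 = h2)
  keep <- dr$informative & !is.na(dr$debv)
  out <- data.frame(animal = ev$animal[keep],
                    trait = if (!is.null(ev$trait)) ev$trait[keep] else "trait",
                    debv = dr$debv[keep], r2_debv = dr$r2_debv[keep],
                    stringsAsFactors = FALSE)
  out$weight <- debv_weight(out$r2_debv, c = c, h2 = h2)
  out
}
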