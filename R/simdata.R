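#' Synthetic herd simulation
#'
#' Generates multi-generation beef-cattle-like herds with known truth:
#' a pedigree with strong half-sib family structure (few widely used sires per
#' generation), unlinked biallelic SNPs gene-dropped through the pedigree,
#' a quantitative trait controlled by a sparse subset of loci at a target
#' heritability, and an emulated national-evaluation output (EPD with BIF
#' accuracies) whose reliabilities are recovered as squared EBV-TBV
#' correlations.
#'
#' @name simdata
NULL

#' Simulation configuration
#'
#' @param n_founders founder animals in generation 0 (also the size of each
#'   subsequent generation).
#' @param n_generations number of generations bred after the founders.
#' @param n_sires breeding sires selected per generation; few sires with many
#'   matings gives the half-sib family structure that K-means clustering keys
#'   on.
#' @param natural_mating_frac fraction of matings sired by natural-mating
#'   bulls (each used for only a few matings) rather than the heavily used
#'   AI-like sires; drives the bimodal parent-average reliability pattern.
#' @param n_clans semi-closed herd lines: founders are split into this many
#'   clans and matings stay within clan except for a `migration` fraction of
#'   dams, emulating the subdivided seed-stock structure that makes
#'   relatedness clustering meaningful.
#' @param migration probability that a mating uses a dam from another clan.
#' @param offspring_sd spread of family sizes: matings are assigned to sires
#'   with probabilities drawn from a Dirichlet-like gamma weighting with this
#'   shape; smaller = more unequal families.
#' @param n_markers unlinked biallelic SNPs.
#' @param n_qtl markers with non-zero trait effects.
#' @param founder_allele_freq_range range the founder B-allele frequencies are
#'   drawn from, within (0, 1).
#' @param trait_heritability narrow-sense h2 of the simulated trait.
#' @param target_reliability_mean mean EBV reliability assigned to ordinary
#'   (natural-mating-like) animals; widely used sires get a high-reliability
#'   (AI-sire-like) component, producing the bimodal parent-average pattern.
#' @param seed integer seed; the same configuration and seed reproduce every
#'   downstream artifact bit for bit.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_founders = 100, n_generations = 4, n_sires = 8,
                       n_clans = 8, migration = 0.05,
                       natural_mating_frac = 0.4,
                       offspring_sd = 1, n_markers = 1000, n_qtl = 50,
                       founder_allele_freq_range = c(0.05, 0.95),
                       trait_heritability = 0.4,
                       target_reliability_mean = 0.45, seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_sires = as.integer(n_sires),
              n_clans = as.integer(n_clans),
              migration = migration,
              natural_mating_frac = natural_mating_frac,
              offspring_sd = offspring_sd,
              n_markers = as.integer(n_markers),
              n_qtl = as.integer(n_qtl),
              founder_allele_freq_range = founder_allele_freq_range,
              trait_heritability = trait_heritability,
              target_reliability_mean = target_reliability_mean,
              seed = as.integer(seed))
  check <- function(ok, field, msg) {
    if (!ok) stop("configuration error in '", field, "': ", msg, call. = FALSE)
  }
  check(cfg$n_founders >= 2, "n_founders", "need at least 2 founders")
  check(cfg$n_generations >= 1, "n_generations", "need at least 1 generation")
  check(cfg$n_sires >= 1, "n_sires", "need at least 1 sire")
  check(cfg$n_clans >= 1, "n_clans", "need at least 1 clan")
  check(cfg$migration >= 0 && cfg$migration <= 1, "migration",
        "must be a probability")
  check(cfg$natural_mating_frac >= 0 && cfg$natural_mating_frac <= 1,
        "natural_mating_frac", "must be a proportion")
  check(cfg$n_markers >= 1, "n_markers", "need at least 1 marker")
  check(cfg$n_qtl >= 0 && cfg$n_qtl <= cfg$n_markers, "n_qtl",
        "must satisfy 0 <= n_qtl <= n_markers")
  fr <- cfg$founder_allele_freq_range
  check(length(fr) == 2 && all(fr > 0) && all(fr < 1) && fr[1] <= fr[2],
        "founder_allele_freq_range", "must be an increasing pair in (0,1)")
  check(cfg$trait_heritability > 0 && cfg$trait_heritability < 1,
        "trait_heritability", "must be in (0,1)")
  check(cfg$target_reliability_mean >= 0 && cfg$target_reliability_mean < 1,
        "target_reliability_mean", "must be in [0,1)")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents and alternating sexes.  Each
#' later generation has `n_founders` animals; sires are a small set of males
#' reused across many matings (half-sib families), dams are sampled from the
#' previous generation's females.  Birth year increases by generation.
#'
#' @param config a [sim_config()].
#' @return data frame `animal, sire, dam, birth_year, sex, generation, clan`
#'   (0 = unknown parent), parents-first.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_founders
  n_clans <- min(config$n_clans, n %/% 2)
  base_year <- 2000L
  ped <- data.frame(animal = seq_len(n), sire = 0L, dam = 0L,
                    birth_year = base_year,
                    sex = rep(c("M", "F"), length.out = n),
                    generation = 0L,
                    clan = rep_len(seq_len(n_clans), n),
                    stringsAsFactors = FALSE)
  sires_per_clan <- max(1L, round(config$n_sires / n_clans))
  if (config$n_generations >= 2) {
    next_id <- n + 1L
    for (g in seq_len(config$n_generations - 1L)) {
      prev <- ped[ped$generation == g - 1L, ]
      if (!any(prev$sex == "M") || !any(prev$sex == "F")) {
        stop("configuration error in 'n_founders': a generation has no ",
             "animals of one sex; increase n_founders")
      }
      # clan sizes add up to n
      clan_n <- diff(round(seq(0, n, length.out = n_clans + 1L)))
      kids_list <- list()
      for (cl in seq_len(n_clans)) {
        males <- prev$animal[prev$sex == "M" & prev$clan == cl]
        if (!length(males)) males <- prev$animal[prev$sex == "M"]
        females <- prev$animal[prev$sex == "F" & prev$clan == cl]
        if (!length(females)) females <- prev$animal[prev$sex == "F"]
        other_females <- prev$animal[prev$sex == "F" & prev$clan != cl]
        sires <- if (length(males) <= sires_per_clan) males else
          males[sample.int(length(males), sires_per_clan)]
        # unequal half-sib family sizes: gamma weights ~ Dirichlet
        wts <- stats::rgamma(length(sires),
                             shape = max(config$offspring_sd, 0.1))
        wts <- wts / sum(wts)
        nk <- clan_n[cl]
        if (nk == 0L) next
        off_sire <- sires[sample.int(length(sires), nk, replace = TRUE,
                                     prob = wts)]
        # a fraction of matings use natural-mating bulls, each covering only
        # a few matings, instead of the heavily used AI-like sires
        nat <- which(stats::runif(nk) < config$natural_mating_frac)
        nat_pool <- setdiff(males, sires)
        if (length(nat) && length(nat_pool)) {
          off_sire[nat] <- nat_pool[sample.int(length(nat_pool), length(nat),
                                               replace = TRUE)]
        }
        off_dam <- females[sample.int(length(females), nk, replace = TRUE)]
        if (length(other_females)) {
          migrate <- stats::runif(nk) < config$migration
          if (any(migrate)) {
            off_dam[migrate] <- other_females[
              sample.int(length(other_females), sum(migrate), replace = TRUE)]
          }
        }
        kids_list[[cl]] <- data.frame(
          animal = 0L, sire = off_sire, dam = off_dam,
          birth_year = base_year + g,
          sex = sample(c("M", "F"), nk, replace = TRUE),
          generation = g, clan = cl, stringsAsFactors = FALSE)
      }
      kids <- do.call(rbind, kids_list)
      kids$animal <- seq.int(next_id, next_id + nrow(kids) - 1L)
      ped <- rbind(ped, kids)
      next_id <- next_id + nrow(kids)
    }
  }
  rownames(ped) <- NULL
  ped
}

#' Gene-drop unlinked SNP genotypes through a pedigree
#'
#' Founders are drawn from Hardy-Weinberg proportions at per-marker B-allele
#' frequencies sampled uniformly within the configured range.  Each offspring
#' receives, independently per marker, one allele from each parent; for an
#' unlinked locus a gamete carries the B allele with probability dosage/2.
#'
#' @param pedigree pedigree data frame (parents-first, as from
#'   [simulate_pedigree()]).
#' @param config a [sim_config()].
#' @param founder_freq optional vector of founder B-allele frequencies
#'   (length `n_markers`) overriding the random draw; values 0 or 1 are
#'   allowed here and fix the locus.
#' @return a [geno_matrix()] with dosages in 0/1/2 and no missingness.
#' @export
gene_drop <- function(pedigree, config, founder_freq = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ped <- sort_pedigree(pedigree)
  set.seed(config$seed + 1L)
  m <- config$n_markers
  if (is.null(founder_freq)) {
    fr <- config$founder_allele_freq_range
    founder_freq <- stats::runif(m, fr[1], fr[2])
  }
  stopifnot(length(founder_freq) == m)
  n <- nrow(ped)
  ids <- ped$animal
  si <- match(ped$sire, ids, nomatch = 0L)
  di <- match(ped$dam, ids, nomatch = 0L)
  G <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    pat <- if (s > 0L) stats::rbinom(m, 1L, G[s, ] / 2) else
      stats::rbinom(m, 1L, founder_freq)
    mat <- if (d > 0L) stats::rbinom(m, 1L, G[d, ] / 2) else
      stats::rbinom(m, 1L, founder_freq)
    G[i, ] <- pat + mat
  }
  geno_matrix(G, animals = ids,
              markers = data.frame(marker = paste0("snp", seq_len(m)),
                                   chromosome = "1",
                                   position = seq_len(m) * 1000L,
                                   panel = "sim",
                                   stringsAsFactors = FALSE))
}

#' Simulate a quantitative trait from genotypes
#'
#' Selects `n_qtl` polymorphic markers without replacement, draws their allele
#' substitution effects from a zero-mean normal, and sets
#' TBV_i = sum_j z_ij * effect_j (centered).  The residual variance is chosen
#' so Var(TBV) / (Var(TBV) + Var(residual)) equals the configured
#' heritability.
#'
#' @param genotypes a [geno_matrix()] (no missing entries).
#' @param config a [sim_config()].
#' @return a `truth_set` list: `tbv` (named per animal), `qtl` (marker
#'   indices), `qtl_effects`, `var_genetic`, `var_residual`, `h2`.
#' @export
simulate_trait <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  Z <- genotypes$geno
  m <- ncol(Z)
  n_qtl <- config$n_qtl
  if (n_qtl == 0L) {
    tbv <- stats::setNames(rep(0, nrow(Z)), genotypes$animals)
    out <- list(tbv = tbv, qtl = integer(0), qtl_effects = numeric(0),
                var_genetic = 0, var_residual = 1,
                h2 = config$trait_heritability)
    class(out) <- "truth_set"
    return(out)
  }
  poly <- which(apply(Z, 2L, function(z) stats::var(z) > 0))
  if (length(poly) < n_qtl) {
    warning("fewer polymorphic markers than requested QTL; resampling among ",
            length(poly), " polymorphic loci with replacement not allowed - ",
            "using all of them")
    qtl <- poly
  } else {
    qtl <- sort(sample(poly, n_qtl))
  }
  eff <- stats::rnorm(length(qtl))
  tbv <- drop(Z[, qtl, drop = FALSE] %*% eff)
  tbv <- tbv - mean(tbv)
  vg <- stats::var(tbv)
  h2 <- config$trait_heritability
  ve <- vg * (1 - h2) / h2
  out <- list(tbv = stats::setNames(tbv, genotypes$animals),
              qtl = qtl, qtl_effects = eff,
              var_genetic = vg, var_residual = ve, h2 = h2)
  class(out) <- "truth_set"
  out
}

#' Emulate national-evaluation output (EPD and BIF accuracies)
#'
#' Assigns each animal a target reliability r2 from a two-component mixture
#' (high, AI-sire-like, for sires with several recorded offspring; lower,
#' natural-mating-like, for everyone else), then builds EBV recursively in
#' pedigree order so each one genuinely contains its parent average, the way
#' national evaluations blend pedigree and own information:
#'
#'   EBV_i = (1 - b) PA_i + b TBV_i + e_i,  b = (r2 - r2_PA) / (1 - r2_PA)
#'
#' with PA_i the mean of the parents' emulated EBVs, r2_PA = (r2_s + r2_d)/4,
#' and Var(e) = b (1 - b) (1 - r2_PA) Var(TBV).  This keeps the regression
#' property Var(EBV) = Cov(EBV, TBV) = r2 Var(TBV), so the squared EBV-TBV
#' correlation equals r2 in expectation, while sibling EBVs correlate through
#' the shared parent average (the component deregression later removes).
#' Animals whose target r2 falls below their r2_PA get a shrunken parent
#' average (EBV = (r2/r2_PA) PA + e); they carry no own information and are
#' the records deregression flags as uninformative.  Founders with unknown
#' parents reduce to EBV = r2 TBV + noise.  EPD = EBV / 2 and BIF accuracy
#' = 1 - sqrt(1 - r2).
#'
#' @param truth a `truth_set` from [simulate_trait()].
#' @param pedigree the pedigree the truth set was simulated on.
#' @param config a [sim_config()].
#' @param trait trait label written into the table.
#' @param reliability optional per-animal reliability vector (named by animal
#'   id) overriding the mixture draw; values must lie in [0, 1).
#' @return data frame `animal, trait, epd, bif_acc, r2_true` (the last column
#'   is simulation truth, not part of the emulated association output).
#' @export
emulate_evaluation <- function(truth, pedigree, config, trait = "trait",
                               reliability = NULL) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  ped <- sort_pedigree(pedigree)
  ids <- ped$animal
  tbv <- truth$tbv[as.character(ids)]
  n <- length(ids)
  if (is.null(reliability)) {
    n_off <- table(factor(ped$sire, levels = ids))
    heavy_sire <- as.integer(n_off) >= 5L
    lo <- config$target_reliability_mean
    r2 <- ifelse(heavy_sire,
                 stats::runif(n, 0.80, 0.95),
                 pmin(pmax(stats::rnorm(n, lo, 0.08), 0.05), 0.75))
  } else {
    r2 <- reliability[as.character(ids)]
  }
  if (any(r2 < 0 | r2 >= 1)) {
    stop("configuration error: reliabilities must lie in [0, 1)")
  }
  vg <- max(stats::var(tbv), .Machine$double.eps)
  si <- match(ped$sire, ids, nomatch = 0L)
  di <- match(ped$dam, ids, nomatch = 0L)
  ebv <- numeric(n)
  eps <- stats::rnorm(n)
  for (i in seq_len(n)) {
    pa <- 0
    r2_pa <- 0
    if (si[i] > 0L) { pa <- pa + ebv[si[i]] / 2; r2_pa <- r2_pa + r2[si[i]] / 4 }
    if (di[i] > 0L) { pa <- pa + ebv[di[i]] / 2; r2_pa <- r2_pa + r2[di[i]] / 4 }
    if (r2[i] >= r2_pa) {
      b <- if (r2_pa < 1) (r2[i] - r2_pa) / (1 - r2_pa) else 0
      ve <- b * (1 - b) * (1 - r2_pa) * vg
      ebv[i] <- (1 - b) * pa + b * tbv[i] + eps[i] * sqrt(max(ve, 0))
    } else {
      # less information than the parent average carries: shrink it
      shrink <- r2[i] / r2_pa
      ve <- r2[i] * vg * (1 - shrink)
      ebv[i] <- shrink * pa + eps[i] * sqrt(max(ve, 0))
    }
  }
  out <- data.frame(animal = ids, trait = trait, epd = ebv / 2,
                    bif_acc = 1 - sqrt(1 - r2), r2_true = r2,
                    stringsAsFactors = FALSE)
  out[match(pedigree$animal, out$animal), , drop = FALSE]
}

#' Simulate a complete synthetic herd
#'
#' Convenience wrapper running pedigree simulation, gene drop, trait
#' simulation and evaluation emulation under one configuration.
#'
#' @param config a [sim_config()].
#' @param trait trait label.
#' @return list `pedigree`, `genotypes`, `truth`, `evaluation`, `config`.
#' @export
simulate_herd <- function(config, trait = "trait") {
  ped <- simulate_pedigree(config)
  geno <- gene_drop(ped, config)
  truth <- simulate_trait(geno, config)
  eval_tab <- emulate_evaluation(truth, ped, config, trait = trait)
  list(pedigree = ped, genotypes = geno, truth = truth,
       evaluation = eval_tab, config = config)
}
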