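# Shared configuration for the synthetic-herd analysis run.
# Sourced by every numbered script; all state passes through scratch/ (bulky
# intermediates) and results/ (small tables a reader would look at).

library(dgvacc)

MASTER_SEED <- 20120938L

RESULTS <- "results"
SCRATCH <- "scratch"
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

# herd scale: ~2000 genotyped animals (generations 1+) x 2000 SNPs
HERD_CONFIG <- sim_config(
  n_founders = 500, n_generations = 5, n_sires = 16, n_clans = 8,
  n_markers = 2000, n_qtl = 100,
  trait_heritability = 0.42,       # birth-weight-like trait
  target_reliability_mean = 0.5,
  seed = MASTER_SEED)

# second trait on the same herd: lowly heritable, stayability-like
TRAITS <- list(
  birth_weight = list(h2 = 0.42, seed_offset = 0L),
  stayability  = list(h2 = 0.21, seed_offset = 1000L))

QC <- list(min_call_rate = 0.95, min_maf = 0.005, min_hwe_p = 1e-30)
K_GROUPS <- 5L
KMEANS_RESTARTS <- 20L
CHAIN <- list(length = 2500L, burn_in = 500L)  # reduced from 41000/1000
C_PARAM <- 0.40                                 # genetic variance not in markers

herd_path <- function(name) file.path(SCRATCH, paste0(name, ".rds"))
res_path <- function(name) file.path(RESULTS, name)
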