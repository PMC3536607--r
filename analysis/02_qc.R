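# Marker quality control on the genotyped cohort: call rate, MAF and
# Hardy-Weinberg filters, then mean imputation of the surviving missing
# calls.  Mirrors panel harmonization by splitting the cohort across two
# array "versions" sharing most markers.

source("analysis/00_config.R")

herd <- readRDS(herd_path("herd"))
ped <- herd$pedigree
genotyped_ids <- as.character(ped$animal[ped$generation >= 1])
G <- subset_geno(herd$genotypes, animals = genotyped_ids)

# emulate two array versions: most animals on the full panel, a subset on a
# re-synthesized version missing 3% of the markers; merging keeps the
# intersection
set.seed(MASTER_SEED + 11L)
vB_animals <- sample(genotyped_ids, round(0.85 * length(genotyped_ids)))
vC_animals <- setdiff(genotyped_ids, vB_animals)
vC_markers <- sort(sample(nrow(G$markers), round(0.97 * nrow(G$markers))))
panels <- list(subset_geno(G, animals = vB_animals),
               subset_geno(G, animals = vC_animals, markers = vC_markers))
G <- harmonize_panels(panels)
message("panel intersection: ", nrow(G$markers), " markers across ",
        length(G$animals), " animals")

stats <- compute_marker_stats(G)
G_qc <- filter_markers(G, stats, min_call_rate = QC$min_call_rate,
                       min_maf = QC$min_maf, min_hwe_p = QC$min_hwe_p)
qc_tab <- attr(G_qc, "qc")
utils::write.table(qc_tab, res_path("qc_report.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
message("markers passing QC: ", nrow(G_qc$markers), " of ", nrow(G$markers),
        sprintf(" (%.1f%% missing calls imputed)",
                100 * mean(is.na(G_qc$geno))))

G_imp <- impute_missing(G_qc)
saveRDS(G_imp, herd_path("genotypes_qc"))
message("wrote ", res_path("qc_report.tsv"))
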