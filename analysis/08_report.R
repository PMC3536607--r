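# Final report: replay the published tables' internal algebra (correlations
# from variance components, efficiencies from correlations and PA
# reliabilities) and assemble the synthetic run's table analogs plus a
# manifest into one Markdown document.

source("analysis/00_config.R")

verify <- verify_table_algebra()
utils::write.table(verify$correlations,
                   res_path("verify_correlations.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(verify$efficiencies,
                   res_path("verify_efficiencies.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
message("published-table algebra: ",
        sum(verify$correlations$status == "consistent"), "/",
        nrow(verify$correlations), " correlations consistent at 2 dp, ",
        sum(verify$correlations$status == "rounding-sensitive"),
        " rounding-sensitive, ",
        sum(verify$correlations$status == "fail"), " inconsistent")

read_res <- function(name) {
  p <- res_path(name)
  if (file.exists(p)) utils::read.delim(p, check.names = FALSE) else NULL
}
outputs <- c("pedigree.csv", "qc_report.tsv", "groups.tsv",
             "table2_analog.tsv", "table3_analog.tsv", "table4_analog.tsv",
             "table5_analog.tsv", "table6_analog.tsv")
manifest <- run_manifest(
  seeds = list(master = MASTER_SEED),
  counts = list(
    pedigree_records = nrow(utils::read.csv(res_path("pedigree.csv"))),
    markers_post_qc = sum(read_res("qc_report.tsv")$pass == "TRUE" |
                            read_res("qc_report.tsv")$pass == TRUE),
    cv_groups = K_GROUPS),
  files = file.path(RESULTS, outputs[file.exists(file.path(RESULTS, outputs))]))
write_estimates_json(manifest, res_path("manifest.json"))

build_report(manifest,
             list("Training counts (Table 2 analog)" = read_res("table2_analog.tsv"),
                  "Clustering quality (Table 3 analog)" = read_res("table3_analog.tsv"),
                  "Variance components (Table 4 analog)" = read_res("table4_analog.tsv"),
                  "DGV heritability and accuracy (Table 5 analog)" = read_res("table5_analog.tsv"),
                  "Selection efficiency (Table 6 analog)" = read_res("table6_analog.tsv"),
                  "Published-table verification: correlations" = verify$correlations,
                  "Published-table verification: efficiencies" = verify$efficiencies),
             path = res_path("report.md"))
message("wrote ", res_path("report.md"))
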