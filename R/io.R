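#' Readers and writers for the pipeline's plain-text formats
#'
#' Pedigree CSV (`animal,sire,dam,birth_year`, 0 = unknown parent),
#' genotype matrix TSV and PLINK-style .ped/.map, evaluation CSV, DEBV TSV,
#' relationship-matrix TSV, cluster-assignment TSV, and JSON for estimate
#' objects.
#'
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @param pedigree pedigree data frame.
#' @param path output file.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree[, intersect(c("animal", "sire", "dam",
                                          "birth_year"), names(pedigree))],
                   path, row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline-io
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  ped
}

#' @rdname pipeline-io
#' @param G a [geno_matrix()].
#' @export
write_genotypes_tsv <- function(G, path) {
  df <- data.frame(animal = G$animals, G$geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline-io
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -1, drop = FALSE])
  geno_matrix(geno, animals = df[[1]])
}

#' Write PLINK-style .ped/.map files
#'
#' Alleles are coded A (reference) / B; dosage is the B-allele count.
#' Missing dosages become `0 0`.  Heterozygotes are written `A B`.
#'
#' @param G a [geno_matrix()] with integer dosages.
#' @param prefix path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param pedigree optional pedigree supplying sire/dam/sex columns.
#' @export
write_ped_map <- function(G, prefix, pedigree = NULL) {
  n <- length(G$animals)
  sire <- dam <- rep(0L, n)
  sex <- rep(0L, n)
  if (!is.null(pedigree)) {
    j <- match(G$animals, as.character(pedigree$animal))
    sire <- ifelse(is.na(j), 0L, pedigree$sire[j])
    dam <- ifelse(is.na(j), 0L, pedigree$dam[j])
    if (!is.null(pedigree$sex)) {
      sex <- ifelse(is.na(j), 0L, ifelse(pedigree$sex[j] == "M", 1L, 2L))
    }
  }
  code <- function(d) {
    if (is.na(d)) "0 0" else c("A A", "A B", "B B")[d + 1L]
  }
  lines <- vapply(seq_len(n), function(i) {
    paste(c("FAM", G$animals[i], sire[i], dam[i], sex[i], -9,
            vapply(G$geno[i, ], code, character(1))), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  map <- G$markers
  writeLines(paste(map$chromosome, map$marker, 0, map$position),
             paste0(prefix, ".map"))
}

#' Read PLINK-style .ped/.map files written by [write_ped_map()]
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return a [geno_matrix()] (B-allele dosage; `0 0` becomes missing).
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), stringsAsFactors = FALSE,
                           col.names = c("chromosome", "marker", "cm",
                                         "position"))
  ped_lines <- strsplit(readLines(paste0(prefix, ".ped")), " ", fixed = TRUE)
  m <- nrow(map)
  geno <- matrix(NA_integer_, length(ped_lines), m)
  ids <- character(length(ped_lines))
  for (i in seq_along(ped_lines)) {
    f <- ped_lines[[i]]
    ids[i] <- f[2]
    al <- f[-(1:6)]
    a1 <- al[seq(1, 2 * m, by = 2)]
    a2 <- al[seq(2, 2 * m, by = 2)]
    d <- (a1 == "B") + (a2 == "B")
    d[a1 == "0" | a2 == "0"] <- NA_integer_
    geno[i, ] <- d
  }
  geno_matrix(geno, animals = ids,
              markers = data.frame(marker = map$marker,
                                   chromosome = map$chromosome,
                                   position = map$position, panel = "plink",
                                   stringsAsFactors = FALSE))
}

#' @rdname pipeline-io
#' @param evaluation evaluation data frame (`animal, trait, epd, bif_acc`).
#' @export
write_evaluation <- function(evaluation, path) {
  utils::write.csv(evaluation, path, row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline-io
#' @export
read_evaluation <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline-io
#' @param debv DEBV table from [build_debv_table()].
#' @export
write_debv_table <- function(debv, path) {
  utils::write.table(debv, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline-io
#' @export
read_debv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline-io
#' @param A relationship matrix with identifier dimnames.
#' @export
write_relationship_tsv <- function(A, path) {
  df <- data.frame(animal = rownames(A), A, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline-io
#' @export
read_relationship_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  colnames(A) <- df[[1]]
  A
}

#' @rdname pipeline-io
#' @param assignment a `cluster_assignment`.
#' @export
write_assignment_tsv <- function(assignment, path) {
  grp <- assignment_groups(assignment)
  utils::write.table(data.frame(animal = names(grp), group = grp),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline-io
#' @export
read_assignment_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  grp <- stats::setNames(as.integer(df$group), as.character(df$animal))
  structure(list(group = grp, sizes = tabulate(grp, max(grp)),
                 K = max(grp), tot_withinss = NA_real_),
            class = "cluster_assignment")
}

#' @rdname pipeline-io
#' @param x any list-like object (e.g. `bivariate_estimates`,
#'   `run_manifest`).
#' @export
write_estimates_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
}
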