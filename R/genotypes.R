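#' Genotype matrix container
#'
#' Dosage matrix (animals x markers, number of B alleles 0/1/2, `NA` =
#' missing) plus marker metadata.  Kept as a plain list with a class so the
#' matrix stays a base matrix that linear algebra can use directly.
#'
#' @param geno numeric/integer matrix, animals in rows, markers in columns.
#' @param animals animal identifiers (defaults to rownames).
#' @param markers data frame with at least a `marker` column; `chromosome`,
#'   `position` and `panel` are filled with placeholders when absent.
#' @return object of class `geno_matrix` with elements `geno` (matrix with
#'   dimnames), `animals`, `markers`.
#' @export
geno_matrix <- function(geno, animals = rownames(geno), markers = NULL) {
  geno <- as.matrix(geno)
  if (is.null(animals)) animals <- paste0("a", seq_len(nrow(geno)))
  animals <- as.character(animals)
  if (is.null(markers)) {
    mk <- colnames(geno)
    if (is.null(mk)) mk <- paste0("snp", seq_len(ncol(geno)))
    markers <- data.frame(marker = mk, stringsAsFactors = FALSE)
  }
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (is.null(markers$marker)) stop("markers needs a 'marker' column")
  for (col in c("chromosome", "position", "panel")) {
    if (is.null(markers[[col]])) {
      markers[[col]] <- if (col == "position") seq_len(nrow(markers)) else "0"
    }
  }
  stopifnot(nrow(geno) == length(animals), ncol(geno) == nrow(markers))
  # raw calls are 0/1/2/missing; mean-imputed matrices carry fractional
  # dosages, still bounded by the 0-2 scale
  bad <- !is.na(geno) & (geno < 0 | geno > 2)
  if (any(bad)) {
    stop("genotype entries must lie on the 0-2 dosage scale or be missing; ",
         "found ", paste(unique(geno[bad])[1:min(3, sum(bad))],
                         collapse = ", "))
  }
  dimnames(geno) <- list(animals, markers$marker)
  structure(list(geno = geno, animals = animals, markers = markers),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$animals), "animals x", nrow(x$markers),
      "markers;", sum(is.na(x$geno)), "missing calls\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`.
#' @param animals animal ids or indices to keep (default all).
#' @param markers marker names or indices to keep (default all).
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(x, animals = NULL, markers = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  ai <- if (is.null(animals)) seq_along(x$animals) else {
    if (is.character(animals)) match(animals, x$animals) else animals
  }
  mi <- if (is.null(markers)) seq_len(nrow(x$markers)) else {
    if (is.character(markers)) match(markers, x$markers$marker) else markers
  }
  if (anyNA(ai)) stop("unknown animal id(s)")
  if (anyNA(mi)) stop("unknown marker name(s)")
  geno_matrix(x$geno[ai, mi, drop = FALSE], x$animals[ai],
              x$markers[mi, , drop = FALSE])
}
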