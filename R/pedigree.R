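#' Pedigree algebra: numerator relationship matrix, inbreeding, a_max
#'
#' A pedigree is a data frame with columns `animal`, `sire`, `dam` and
#' `birth_year`, where `0` denotes an unknown parent and every parent row
#' precedes (or is sortable before) its offspring.  These functions implement
#' the tabular method for the additive (numerator) relationship matrix A,
#' principal-submatrix extraction, and the within/between-group maximum
#' relationship (a_max) diagnostics used to judge the quality of
#' cross-validation groups.
#'
#' @name pedigree-algebra
NULL

#' Validate and topologically sort a pedigree
#'
#' Checks identifier uniqueness, that no animal is its own ancestor, and
#' returns the pedigree ordered so every parent precedes its offspring.
#' Unknown parents are coded `0`.
#'
#' @param ped data frame with columns `animal`, `sire`, `dam` and optionally
#'   `birth_year`.
#' @return the pedigree, reordered parents-first, with an integer `order`
#'   attribute mapping back to the input rows.
#' @export
sort_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  ids <- ped$animal
  if (anyDuplicated(ids)) {
    stop("pedigree error: duplicated animal id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n <- nrow(ped)
  idx <- function(x) match(x, ids, nomatch = 0L) # 0 = unknown / not in pedigree
  si <- idx(ped$sire)
  di <- idx(ped$dam)
  # Kahn's algorithm on the parent -> offspring DAG
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree error: cycle involving animal(s): ",
         paste(ids[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "order") <- ord
  out
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the dense additive relationship matrix A over the full pedigree,
#' with the textbook recursion a_ii = 1 + 0.5 a(sire,dam) and
#' a_ij = 0.5 (a_j,sire(i) + a_j,dam(i)); unknown parents are treated as
#' unrelated, non-inbred founders.
#'
#' @param ped pedigree data frame (see [sort_pedigree()]).
#' @param ids optional identifiers to which the returned matrix is restricted
#'   (ancestors still inform the recursion through the full pedigree).
#' @return symmetric numeric matrix with dimnames set to animal identifiers.
#' @export
build_nrm <- function(ped, ids = NULL) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  all_ids <- ped$animal
  si <- match(ped$sire, all_ids, nomatch = 0L)
  di <- match(ped$dam, all_ids, nomatch = 0L)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (s > 0L) rel <- rel + A[j, s]
      if (d > 0L) rel <- rel + A[j, d]
      rel <- 0.5 * rel
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(all_ids, all_ids)
  if (!is.null(ids)) A <- subset_relationships(A, ids)
  A
}

#' Inbreeding coefficients from a relationship matrix
#'
#' @param A numerator relationship matrix.
#' @return named vector of F = a_ii - 1.
#' @export
inbreeding <- function(A) {
  diag(A) - 1
}

#' Principal submatrix of a relationship matrix
#'
#' @param A relationship matrix with identifier dimnames.
#' @param ids identifiers to keep, in the requested order.
#' @return the principal submatrix `A[ids, ids]`.
#' @export
subset_relationships <- function(A, ids) {
  ids <- as.character(ids)
  missing <- setdiff(ids, rownames(A))
  if (length(missing)) {
    stop("lookup error: id(s) not in relationship matrix: ",
         paste(missing, collapse = ", "))
  }
  A[ids, ids, drop = FALSE]
}

#' Within/between-group maximum relationship (a_max) report
#'
#' For each animal, the maximum off-diagonal additive relationship to animals
#' in its own cross-validation group and to animals in all other groups, plus
#' per-group means and standard deviations of both.  Members of singleton
#' groups have no within-group partner; their within a_max is `NA` and is
#' excluded from the group mean.
#'
#' @param A relationship matrix over the clustered animals.
#' @param assignment cluster assignment as returned by [kmeans_groups()], or
#'   any named vector/list with `$group` labels aligned to `rownames(A)`.
#' @return list with `animals` (per-animal data frame) and `groups`
#'   (per-group mean and SD of within and between a_max, plus sizes).
#' @export
amax_report <- function(A, assignment) {
  grp <- assignment_groups(assignment)
  ids <- rownames(A)
  if (is.null(names(grp))) names(grp) <- ids
  if (!all(ids %in% names(grp))) {
    stop("assignment does not cover all animals in A")
  }
  grp <- grp[ids]
  n <- nrow(A)
  Aoff <- A
  diag(Aoff) <- NA_real_
  within <- between <- rep(NA_real_, n)
  for (g in unique(grp)) {
    in_g <- grp == g
    if (sum(in_g) > 1L) {
      within[in_g] <- apply(Aoff[in_g, in_g, drop = FALSE], 1L, max, na.rm = TRUE)
    }
    if (any(!in_g)) {
      between[in_g] <- apply(A[in_g, !in_g, drop = FALSE], 1L, max)
    }
  }
  animals <- data.frame(animal = ids, group = grp,
                        amax_within = within, amax_between = between,
                        row.names = NULL, stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    w <- within[grp == g]; b <- between[grp == g]
    data.frame(group = g, n = sum(grp == g),
               amax_within_mean = mean(w, na.rm = TRUE),
               amax_within_sd = stats::sd(w[!is.na(w)]),
               amax_between_mean = mean(b, na.rm = TRUE),
               amax_between_sd = stats::sd(b[!is.na(b)]),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(animals = animals, groups = groups)
}

# Accept either a cluster_assignment object or a bare named vector of labels.
assignment_groups <- function(assignment) {
  if (inherits(assignment, "cluster_assignment")) return(assignment$group)
  if (is.list(assignment) && !is.null(assignment$group)) return(assignment$group)
  assignment
}
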