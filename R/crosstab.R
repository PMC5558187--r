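#' Cross-tabulate amino-acid substitution classes
#'
#' Builds the 4x4 table of wild-type class (rows) by mutant class (columns)
#' over a set of missense mutations, the summary used to ask how often a
#' substitution preserves the physicochemical character of the residue.
#'
#' @param mutations A tibble of parsed mutations (see [parse_hgvs_p()]); all
#'   rows must be `MISSENSE`.
#' @param scheme Amino-acid class scheme, see [default_aa_scheme()].
#' @return An object of class `class_crosstab`: a 4x4 integer matrix with
#'   classes as dimnames and attributes `row_totals`, `col_totals`,
#'   `grand_total`.
#' @examples
#' m <- parse_hgvs_p(c("p.Leu10Ser", "p.Leu20Ile"))
#' build_crosstab(m)
#' @export
build_crosstab <- function(mutations, scheme = default_aa_scheme()) {
  if (nrow(mutations) > 0 && any(mutations$consequence != "MISSENSE")) {
    abort("build_crosstab() requires missense mutations only.")
  }
  if (nrow(mutations) == 0) {
    counts <- matrix(0L, 4, 4, dimnames = list(AA_CLASSES, AA_CLASSES))
  } else {
    wt_class <- classify_residue(mutations$wild_type, scheme)
    mut_class <- classify_residue(mutations$mutant, scheme)
    counts <- unclass(table(wt_class, mut_class))
    dimnames(counts) <- list(AA_CLASSES, AA_CLASSES)
    storage.mode(counts) <- "integer"
  }
  new_crosstab(counts)
}

new_crosstab <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(4, 4)),
            all(counts >= 0))
  dimnames(counts) <- list(AA_CLASSES, AA_CLASSES)
  structure(counts,
            row_totals = rowSums(counts),
            col_totals = colSums(counts),
            grand_total = sum(counts),
            class = c("class_crosstab", "matrix", "array"))
}

#' Construct a cross-tab directly from cell counts
#'
#' Used when the per-cell counts are known (e.g. from a published table) but
#' the underlying mutation list is not.
#'
#' @param counts 4x4 non-negative integer matrix, rows = wild-type class,
#'   columns = mutant class, in the order hydrophobic, polar, positive,
#'   negative.
#' @return A `class_crosstab`.
#' @export
as_crosstab <- function(counts) new_crosstab(counts)

#' @export
print.class_crosstab <- function(x, ...) {
  cat("Amino-acid substitution class cross-tabulation",
      sprintf("(n = %d)\n", attr(x, "grand_total")))
  m <- cbind(unclass(x), Total = attr(x, "row_totals"))
  m <- rbind(m, Total = c(attr(x, "col_totals"), attr(x, "grand_total")))
  print(m)
  invisible(x)
}

#' Number of class-preserving substitutions
#'
#' The diagonal sum of a substitution-class cross-tab: mutations whose mutant
#' residue stays in the wild type's physicochemical class.
#'
#' @param tab A `class_crosstab`.
#' @return Integer count.
#' @examples
#' m <- parse_hgvs_p(c("p.Leu10Ile", "p.Leu20Ser"))
#' class_conservation_count(build_crosstab(m))  # 1
#' @export
class_conservation_count <- function(tab) {
  stopifnot(inherits(tab, "class_crosstab"))
  as.integer(sum(diag(unclass(tab))))
}

#' Distinct mutated positions from multiplicity structure
#'
#' Given the number of unique protein variants and, for positions carrying
#' more than one variant amino acid, how many positions carry each
#' multiplicity, returns the number of distinct mutated positions.
#'
#' @param n_variants Total number of unique variants.
#' @param multiplicities Named integer vector: names are variants-per-position
#'   (>= 2), values the number of positions with that multiplicity. Positions
#'   with a single variant are implied.
#' @return Integer number of distinct positions.
#' @examples
#' distinct_positions(94, c(`2` = 10, `4` = 1))  # 81
#' distinct_positions(58, c(`2` = 3))            # 55
#' @export
distinct_positions <- function(n_variants, multiplicities = integer()) {
  stopifnot(length(n_variants) == 1, n_variants >= 0)
  if (length(multiplicities) == 0) return(as.integer(n_variants))
  k <- as.integer(names(multiplicities))
  cnt <- as.integer(multiplicities)
  if (anyNA(k) || any(k < 2) || any(cnt < 0)) {
    abort("`multiplicities` must map integer multiplicities >= 2 to non-negative position counts.")
  }
  if (sum(k * cnt) > n_variants) {
    abort("Inconsistent counts: multiplicities account for more variants than `n_variants`.")
  }
  as.integer(n_variants - sum((k - 1L) * cnt))
}

#' Expected number of affected individuals in a cohort
#'
#' Nearest integer to cohort size times disease prevalence; e.g. a population
#' panel of just over 60,000 exomes at a prevalence of 1 in 7000 is expected
#' to contain about nine affected individuals.
#'
#' @param cohort_size Number of individuals (>= 0).
#' @param prevalence Disease prevalence, a fraction in `[0, 1]`.
#' @return Integer expected count.
#' @examples
#' expected_affected(60000, 1 / 7000)  # 9
#' @export
expected_affected <- function(cohort_size, prevalence) {
  stopifnot(cohort_size >= 0, prevalence >= 0, prevalence <= 1)
  as.integer(round(cohort_size * prevalence))
}
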