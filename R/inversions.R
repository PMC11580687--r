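#' Tabulate inversion presence by comparison class
#'
#' Builds the 2x2 contingency table of pairwise synteny comparisons: rows
#' are the comparison classes (`autosome_pair` = autosomes compared among
#' species; `sex_involved` = comparisons involving at least one sex-linked
#' region), columns are inversion presence (at least one inversion between
#' the pair) vs absence.
#'
#' @param records Data frame with columns `class` (one of the two labels)
#'   and `inversion_present` (logical).
#' @return A 2x2 integer matrix with dimnames
#'   `(autosome_pair, sex_involved) x (has_inversion, no_inversion)`; an
#'   all-zero table (empty input) carries attribute `empty = TRUE`.
#' @export
tabulate_inversions <- function(records) {
  stopifnot(all(c("class", "inversion_present") %in% names(records)))
  valid <- c("autosome_pair", "sex_involved")
  bad <- setdiff(unique(records$class), valid)
  if (length(bad))
    stop("unknown comparison class(es): ", paste(bad, collapse = ", "))
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(class = valid,
                                inversion = c("has_inversion",
                                              "no_inversion")))
  for (cl in valid) {
    sub <- records$inversion_present[records$class == cl]
    tab[cl, ] <- c(sum(sub), sum(!sub))
  }
  if (nrow(records) == 0) attr(tab, "empty") <- TRUE
  tab
}

#' Two-sided Fisher exact test of inversion-sex-linkage association
#'
#' Exact hypergeometric test on a 2x2 table, two-sided in the standard
#' convention: the p-value sums the probabilities of all tables with the
#' observed margins whose point probability does not exceed that of the
#' observed table (up to a 1e-7 relative tolerance against floating-point
#' ties). The odds ratio reported is the sample odds ratio, with an `Inf`
#' sentinel when a zero cell puts it out of range. A table with a zero
#' margin carries no information and returns p = 1 with a warning.
#'
#' @param table A 2x2 matrix of non-negative counts (e.g. from
#'   [tabulate_inversions()]).
#' @return List with `p_two_sided`, `odds_ratio` and `observed_table`.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (tab[1, 2] * tab[2, 1] == 0)
    or <- if (tab[1, 1] * tab[2, 2] == 0) NaN else Inf
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: association test is uninformative, p = 1")
    return(list(p_two_sided = 1, odds_ratio = or, observed_table = tab))
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(p_two_sided = min(p, 1), odds_ratio = or, observed_table = tab)
}
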