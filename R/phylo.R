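#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise JC69 distances `d = -(3/4) * log(1 - (4/3) p)` with `p` the
#' mismatch proportion over columns where both sequences carry an unambiguous
#' base (gaps and N skipped pairwise). Saturated pairs (`p >= 3/4`, outside
#' the formula's domain) are reported as `Inf`.
#'
#' @param alignment A `DNAbin` matrix/list (see [ape::as.DNAbin]) or a named
#'   character matrix of aligned equal-length sequences.
#' @return A symmetric numeric matrix of distances with `Inf` sentinels.
#' @export
jc_distance <- function(alignment) {
  dna <- if (inherits(alignment, "DNAbin")) alignment
         else ape::as.DNAbin(alignment)
  dna <- as.matrix(dna)
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  p <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(p[upper.tri(p)])))
    stop("a sequence pair shares zero comparable columns")
  d[p >= 0.75] <- Inf
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); recovers additive trees
#' exactly and is deterministic. Input must be a square symmetric matrix
#' with zero diagonal, at least three taxa and no `NaN`, negative-infinite
#' or (saturated) infinite entries.
#'
#' @param D Distance matrix (rows/columns named by taxa).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (any(is.na(D)) || any(!is.finite(D)))
    stop("distance matrix contains NaN or non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
  ape::nj(D)
}

#' Root a tree with a monophyletic outgroup
#'
#' Places the root on the branch separating the outgroup from the ingroup.
#' Errors (listing the offending leaves) when the outgroup is not
#' monophyletic in the unrooted tree.
#'
#' @param tree A `phylo` or [labeled_tree()].
#' @param outgroup Character vector of outgroup leaf names.
#' @return A rooted tree of the same class as the input.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  ltree <- NULL
  if (inherits(tree, "labeled_tree")) { ltree <- tree; tree <- tree$tree }
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "))
  ingroup <- setdiff(tree$tip.label, outgroup)
  # in an unrooted tree a group is a clade iff it or its complement is one
  # under the arbitrary stored rooting
  if (length(outgroup) > 1 && length(ingroup) > 1 &&
      !ape::is.monophyletic(tree, outgroup) &&
      !ape::is.monophyletic(tree, ingroup))
    stop("outgroup is not monophyletic: ",
         paste(outgroup, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (is.null(ltree)) rooted else labeled_tree(rooted, ltree$labels)
}

#' Classify a rooted gametolog tree into a turnover scenario
#'
#' Given a rooted tree in which every ingroup species contributes exactly one
#' X/W and one Y/Z leaf (X and W are one pole, Y and Z the other, matching
#' the 15X->15W / 15Y->15Z transitions), applies the decision order:
#' \enumerate{
#'   \item both the X/W leaf set and the Y/Z leaf set are monophyletic ->
#'     `GAMETOLOG_CLUSTERING` (recombination stopped before the species
#'     splits, so gametologs cluster by haplotype);
#'   \item every species' two leaves are sisters -> `SPECIES_CLUSTERING`
#'     (recombination continued past the species splits);
#'   \item exactly one species' Y/Z leaf is the earliest-branching ingroup
#'     lineage, and within the remaining clade the other species' X and Y
#'     sets each cluster -> `NEO_FROM_X` with that species focal (its old Y
#'     is an outgroup to X-derived sequences, the signature of a neo-Y
#'     arising from the ancestral X);
#'   \item otherwise `UNRESOLVED`.
#' }
#' The classification uses topology only; it is invariant to leaf order and
#' branch-length rescaling.
#'
#' @param tree A rooted `phylo` or [labeled_tree()]; leaves named
#'   `"<species>_<haplotype>"` unless a label table is attached. Outgroup
#'   leaves (haplotype `A`) are dropped before classification.
#' @param outgroup Optional outgroup leaf names; if the tree is unrooted they
#'   are used to root it first.
#' @return List with `class` (one of the four labels) and `focal_species`
#'   (non-`NA` only for `NEO_FROM_X`).
#' @export
classify_gametolog_topology <- function(tree, outgroup = NULL) {
  lt <- if (inherits(tree, "labeled_tree")) tree else labeled_tree(tree)
  labels <- lt$labels
  tr <- lt$tree
  auto <- union(labels$leaf[labels$haplotype == "A"], outgroup)
  if (!ape::is.rooted(tr)) {
    if (!length(auto)) stop("unrooted tree and no outgroup given")
    tr <- root_with_outgroup(tr, auto)
  }
  if (length(auto)) {
    if (length(auto) >= length(tr$tip.label) - 2)
      stop("too few ingroup leaves after dropping the outgroup")
    tr <- ape::drop.tip(tr, auto)
  }
  labels <- labels[labels$leaf %in% tr$tip.label, , drop = FALSE]
  pole <- ifelse(labels$haplotype %in% c("X", "W"), "XW", "YZ")
  species <- labels$species
  tab <- table(species, pole)
  if (!all(dim(tab) == c(length(unique(species)), 2L)) || !all(tab == 1L))
    stop("each ingroup species must contribute exactly one X/W and one ",
         "Y/Z leaf")
  xw <- labels$leaf[pole == "XW"]
  yz <- labels$leaf[pole == "YZ"]
  sp <- unique(species)
  mono <- function(leaves) length(leaves) == 1L ||
    ape::is.monophyletic(tr, leaves)

  if (mono(xw) && mono(yz))
    return(list(class = "GAMETOLOG_CLUSTERING",
                focal_species = NA_character_))

  pairs_sister <- all(vapply(sp, function(s)
    mono(labels$leaf[species == s]), logical(1)))
  if (pairs_sister)
    return(list(class = "SPECIES_CLUSTERING", focal_species = NA_character_))

  # neo-Y-from-X: one species' Y/Z branches first; the rest (including that
  # species' X/W) form a clade in which the other species' poles each cluster
  root_node <- length(tr$tip.label) + 1L
  kids <- tr$edge[tr$edge[, 1] == root_node, 2]
  basal_tips <- kids[kids <= length(tr$tip.label)]
  for (tip in basal_tips) {
    leaf <- tr$tip.label[tip]
    row <- match(leaf, labels$leaf)
    if (pole[row] != "YZ") next
    s <- species[row]
    others <- setdiff(sp, s)
    if (!length(others)) next
    ox <- labels$leaf[species %in% others & pole == "XW"]
    oy <- labels$leaf[species %in% others & pole == "YZ"]
    if (mono(ox) && mono(oy))
      return(list(class = "NEO_FROM_X", focal_species = s))
  }
  list(class = "UNRESOLVED", focal_species = NA_character_)
}

#' Tally topology classes across single-copy orthologs
#'
#' Applies [classify_gametolog_topology()] to each gene tree and reports the
#' per-class counts, the per-class SCO identifier lists and the majority
#' class among resolved trees (ties yield an `UNRESOLVED` majority).
#'
#' @param trees Named list of rooted trees (`phylo` or [labeled_tree()]);
#'   names are the SCO identifiers.
#' @param outgroup Optional outgroup leaf names passed to the classifier.
#' @return An object of class `topology_report`: list with `per_sco` (named
#'   character vector), `counts`, `majority` and `sco_by_class`.
#' @export
tally_topologies <- function(trees, outgroup = NULL) {
  if (!length(trees)) stop("need at least one tree")
  if (is.null(names(trees)))
    names(trees) <- paste0("SCO", seq_along(trees))
  cls <- vapply(trees, function(tr)
    classify_gametolog_topology(tr, outgroup)$class, character(1))
  levels <- c("GAMETOLOG_CLUSTERING", "SPECIES_CLUSTERING", "NEO_FROM_X",
              "UNRESOLVED")
  counts <- table(factor(cls, levels = levels))
  resolved <- counts[setdiff(levels, "UNRESOLVED")]
  majority <- if (sum(resolved) == 0 ||
                  sum(resolved == max(resolved)) > 1L) "UNRESOLVED"
              else names(resolved)[which.max(resolved)]
  structure(list(per_sco = cls, counts = counts, majority = majority,
                 sco_by_class = split(names(cls), factor(cls,
                                                         levels = levels))),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report> ", length(x$per_sco), " SCOs; majority: ",
      x$majority, "\n", sep = "")
  print(x$counts)
  invisible(x)
}
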