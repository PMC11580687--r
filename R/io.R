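#' Read genotypes and sex labels from a VCF file
#'
#' Reads a VCF v4.x file (plain or gzipped) into a [genotype_matrix()].
#' All records are kept, including multiallelic ones (flagged through
#' `n_alleles` so that [filter_snps()] can remove them); genotype codes count
#' non-reference alleles, `./.` and `.|.` become `NA`, and both phased and
#' unphased separators are accepted. Per-site depth is taken from FORMAT/DP
#' when present.
#'
#' @param path Path to a VCF file.
#' @param sex_map Named character vector mapping sample name to
#'   `"female"`/`"male"`/`"unknown"`. Every name in `sex_map` must occur in
#'   the VCF; VCF samples absent from `sex_map` are labelled `"unknown"`.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sex_map = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample columns")
  samples <- colnames(vcf@gt)[-1L]
  if (!is.null(sex_map)) {
    missing <- setdiff(names(sex_map), samples)
    if (length(missing))
      stop("samples in sex_map absent from VCF: ",
           paste(missing, collapse = ", "))
  }
  sex <- rep("unknown", length(samples))
  names(sex) <- samples
  if (!is.null(sex_map)) sex[names(sex_map)] <- as.character(sex_map)

  gt <- vcfR::extract.gt(vcf, element = "GT")   # sites x samples
  obs <- gt[!is.na(gt) & gt != "."]
  if (length(obs) && any(!grepl("[/|]", obs)))
    stop("haploid-looking genotypes (single allele) are not supported")
  code_gt <- function(g) {
    al <- strsplit(g, "[/|]")
    vapply(al, function(x) {
      if (length(x) == 0L || anyNA(x) || any(x == ".")) return(NA_integer_)
      sum(x != "0")
    }, integer(1))
  }
  geno <- do.call(rbind, lapply(seq_along(samples),
                                function(j) code_gt(gt[, j])))

  depth <- NULL
  fmt <- vcf@gt[, "FORMAT"]
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    depth <- t(dp)
  } else {
    message("no FORMAT/DP field in ", basename(path),
            "; depth-based filtering will be skipped")
  }

  genotype_matrix(
    sample_ids = samples, sex = unname(sex),
    chrom = vcf@fix[, "CHROM"], pos = as.integer(vcf@fix[, "POS"]),
    ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"],
    geno = geno, depth = depth)
}

#' Write a genotype matrix to VCF
#'
#' Writes a minimal VCF v4.2 representation through \pkg{vcfR}. The output is
#' gzip-compressed (`.vcf.gz`), the format `vcfR::write.vcf()` produces.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path (conventionally ending in `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_sites <- length(gm$pos)
  fix <- cbind(CHROM = gm$chrom, POS = as.character(gm$pos),
               ID = rep(".", n_sites), REF = gm$ref, ALT = gm$alt,
               QUAL = rep(".", n_sites), FILTER = rep("PASS", n_sites),
               INFO = rep(".", n_sites))
  code2gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt_body <- matrix("./.", nrow = n_sites, ncol = length(gm$sample_ids),
                    dimnames = list(NULL, gm$sample_ids))
  ok <- !is.na(gm$geno)
  gt_body[t(ok)] <- code2gt[as.character(t(gm$geno)[t(ok)])]
  if (!is.null(gm$depth)) {
    dp <- t(gm$depth)
    dp_chr <- ifelse(is.na(dp), ".", as.character(dp))
    gt_body[] <- paste(gt_body, dp_chr, sep = ":")
    fmt <- "GT:DP"
  } else fmt <- "GT"
  gt <- cbind(FORMAT = rep(fmt, n_sites), gt_body)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            if (!is.null(gm$depth))
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  cls <- methods::getClass("vcfR", where = asNamespace("vcfR"))
  obj <- methods::new(cls, meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read genomic features from BED, GFF3 or TSV
#'
#' Returns a data frame of feature records on 0-based half-open coordinates.
#' BED input is already 0-based half-open; GFF3 (1-based inclusive) is shifted
#' by `start - 1`; TSV input must carry a header with at least
#' `chrom, start, end` (taken as 0-based half-open) and optionally
#' `kind, name, strand`.
#'
#' @param path Input file path.
#' @param dialect One of `"auto"`, `"bed"`, `"gff3"`, `"tsv"`; `"auto"` picks
#'   by file extension.
#' @param kind Default `kind` label for dialects that do not carry one (BED).
#' @return A data frame with columns `chrom, start, end, kind, name, strand`.
#' @export
read_features <- function(path, dialect = c("auto", "bed", "gff3", "tsv"),
                          kind = "feature") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("feature file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    dialect <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                      tsv = "tsv", txt = "tsv",
                      stop("cannot guess dialect from extension: ", ext))
  }
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), kind = character(),
                      name = character(), strand = character(),
                      stringsAsFactors = FALSE)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty)
  out <- switch(dialect,
    bed = {
      gr <- rtracklayer::import(path, format = "BED")
      if (length(gr) == 0) return(empty)
      nm <- if (!is.null(gr$name)) as.character(gr$name)
            else rep(NA_character_, length(gr))
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = GenomicRanges::end(gr),
                 kind = rep(kind, length(gr)), name = nm,
                 strand = as.character(GenomicRanges::strand(gr)),
                 stringsAsFactors = FALSE)
    },
    gff3 = {
      gr <- rtracklayer::import(path, format = "GFF3")
      if (length(gr) == 0) return(empty)
      nm <- if (!is.null(gr$ID)) as.character(gr$ID)
            else rep(NA_character_, length(gr))
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = GenomicRanges::end(gr),
                 kind = as.character(gr$type), name = nm,
                 strand = as.character(GenomicRanges::strand(gr)),
                 stringsAsFactors = FALSE)
    },
    tsv = {
      df <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      if (nrow(df) == 0) return(empty)
      need <- c("chrom", "start", "end")
      if (!all(need %in% names(df)))
        stop("TSV features need columns: ", paste(need, collapse = ", "))
      data.frame(chrom = as.character(df$chrom), start = df$start,
                 end = df$end,
                 kind = if ("kind" %in% names(df)) df$kind
                        else rep(kind, nrow(df)),
                 name = if ("name" %in% names(df)) df$name
                        else rep(NA_character_, nrow(df)),
                 strand = if ("strand" %in% names(df)) df$strand
                          else rep(".", nrow(df)),
                 stringsAsFactors = FALSE)
    })
  if (any(out$start < 0) || any(out$end < 0))
    stop("negative feature coordinates in ", path)
  if (any(out$start >= out$end))
    stop("feature with start >= end in ", path)
  out
}

#' Labeled phylogenetic tree
#'
#' Wraps an \pkg{ape} `phylo` tree with a `(species, haplotype)` label per
#' leaf, where the haplotype is one of `X, Y, Z, W` or `A` (outgroup /
#' autosomal copy).
#'
#' @param tree An `ape::phylo` object.
#' @param labels Data frame with columns `leaf, species, haplotype`, one row
#'   per tip. If `NULL`, labels are parsed from tip names of the form
#'   `"<species>_<haplotype>"`.
#' @return An object of class `labeled_tree`.
#' @export
labeled_tree <- function(tree, labels = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("leaf names must be unique")
  if (is.null(labels)) labels <- parse_leaf_labels(tree$tip.label)
  if (!all(c("leaf", "species", "haplotype") %in% names(labels)))
    stop("labels need columns leaf, species, haplotype")
  if (!setequal(labels$leaf, tree$tip.label))
    stop("label table and tree leaves do not match")
  bad <- setdiff(labels$haplotype, c("X", "Y", "Z", "W", "A"))
  if (length(bad)) stop("invalid haplotype label(s): ",
                        paste(bad, collapse = ", "))
  structure(list(tree = tree, labels = labels), class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("<labeled_tree> ", length(x$tree$tip.label), " leaves, ",
      length(unique(x$labels$species)), " species; rooted: ",
      ape::is.rooted(x$tree), "\n", sep = "")
  invisible(x)
}

# Parse "<species>_<haplotype>" tip names into a label table.
parse_leaf_labels <- function(leaves) {
  m <- regmatches(leaves, regexec("^(.*)_([XYZWA])$", leaves))
  bad <- leaves[lengths(m) != 3L]
  if (length(bad))
    stop("unparseable leaf label(s) (expected '<species>_<X|Y|Z|W|A>'): ",
         paste(bad, collapse = ", "))
  data.frame(leaf = leaves,
             species = vapply(m, `[`, "", 2L),
             haplotype = vapply(m, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Read a newick tree with gametolog leaf labels
#'
#' @param path Path to a newick file.
#' @param labels Optional label table (see [labeled_tree()]); if absent, tip
#'   names must follow the `"<species>_<haplotype>"` convention.
#' @return A [labeled_tree()].
#' @export
read_newick <- function(path, labels = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  labeled_tree(tree, labels)
}

#' Write a labeled tree to newick
#' @param ltree A [labeled_tree()] or `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(ltree, path) {
  tree <- if (inherits(ltree, "labeled_tree")) ltree$tree else ltree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a window track to bedGraph or TSV
#'
#' bedGraph output requires non-overlapping windows (`step_bp == window_bp`);
#' overlapping scans (e.g. the 100-kb/10-kb FST profile) are written as TSV
#' with columns `chrom, start, end, value, n_items`.
#'
#' @param track A [window_track()].
#' @param path Output path.
#' @param dialect `"bedgraph"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, dialect = c("bedgraph", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(track, "window_track"))
  ends <- window_ends(track)
  if (dialect == "bedgraph") {
    if (track$step_bp < track$window_bp)
      stop("overlapping windows cannot be written as bedGraph; use TSV")
    gr <- GenomicRanges::GRanges(
      track$chrom,
      IRanges::IRanges(start = track$starts + 1, end = ends),
      score = track$values)
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    df <- data.frame(chrom = track$chrom, start = track$starts, end = ends,
                     value = track$values,
                     n_items = if (is.null(track$n_items)) NA
                               else track$n_items)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a window track written by [write_track()]
#'
#' @param path Input path.
#' @param dialect `"bedgraph"` or `"tsv"` (`"auto"` picks by extension).
#' @param step_bp Step size; defaults to the window size inferred from the
#'   first record (bedGraph) or from consecutive starts (TSV).
#' @return A [window_track()].
#' @export
read_track <- function(path, dialect = c("auto", "bedgraph", "tsv"),
                       step_bp = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("bedgraph", "bg")) "bedgraph" else "tsv"
  }
  if (dialect == "bedgraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    starts <- GenomicRanges::start(gr) - 1
    window_bp <- max(GenomicRanges::end(gr) - starts)
    window_track(as.character(GenomicRanges::seqnames(gr))[1L], starts,
                 gr$score, window_bp,
                 step_bp = if (is.null(step_bp)) window_bp else step_bp)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    window_bp <- max(df$end - df$start)
    if (is.null(step_bp))
      step_bp <- if (nrow(df) > 1) min(diff(df$start)) else window_bp
    window_track(as.character(df$chrom[1L]), df$start, df$value, window_bp,
                 step_bp = step_bp,
                 n_items = if ("n_items" %in% names(df) &&
                               !all(is.na(df$n_items))) df$n_items)
  }
}
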