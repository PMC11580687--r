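#' Classify SLR-specific genes as losses or insertions
#'
#' Applies the ancestral-outgroup rule to homology presence flags: a gene
#' present in both SLRs is `SHARED`; a gene specific to one SLR that has a
#' homolog on the inferred ancestral (autosomal) chromosome was lost from
#' the other haplotype (`LOSS_FROM_Y` / `LOSS_FROM_X`); with no ancestral
#' hit it is an insertion into the haplotype that carries it
#' (`INSERTION_IN_X` / `INSERTION_IN_Y`). A gene found only on the
#' ancestral chromosome was lost from both SLR haplotypes
#' (`LOSS_FROM_BOTH`). All three flags `FALSE` is an error. Vectorised over
#' rows.
#'
#' @param in_x,in_y,in_ancestor Logical vectors: presence in the X-SLR,
#'   Y-SLR and ancestral chromosome.
#' @return Character vector of calls.
#' @export
classify_slr_specific_gene <- function(in_x, in_y, in_ancestor) {
  n <- length(in_x)
  stopifnot(length(in_y) == n, length(in_ancestor) == n,
            is.logical(in_x), is.logical(in_y), is.logical(in_ancestor))
  if (any(!in_x & !in_y & !in_ancestor))
    stop("gene with all presence flags FALSE")
  ifelse(in_x & in_y, "SHARED",
  ifelse(in_x & !in_y, ifelse(in_ancestor, "LOSS_FROM_Y", "INSERTION_IN_X"),
  ifelse(!in_x & in_y, ifelse(in_ancestor, "LOSS_FROM_X", "INSERTION_IN_Y"),
         "LOSS_FROM_BOTH")))
}

#' Degeneration fractions of the X and Y SLR haplotypes
#'
#' Gene losses from each haplotype expressed as percentages of the number of
#' genes shared between the X and Y haplotypes in the SLR.
#'
#' @param calls Character vector of calls from
#'   [classify_slr_specific_gene()].
#' @param shared_count Number of X/Y-shared SLR genes (> 0; defaults to the
#'   `SHARED` count in `calls`).
#' @return Named numeric vector `c(loss_fraction_X, loss_fraction_Y)`, in
#'   percent.
#' @export
degeneration_fraction <- function(calls, shared_count = sum(calls ==
                                                              "SHARED")) {
  if (shared_count <= 0)
    stop("degeneration fraction undefined: shared_count must be > 0")
  c(loss_fraction_X = 100 * sum(calls == "LOSS_FROM_X") / shared_count,
    loss_fraction_Y = 100 * sum(calls == "LOSS_FROM_Y") / shared_count)
}

#' Classify a duplicate copy by exon presence
#'
#' A copy carrying all `1..required_exons` exons is `INTACT`; a non-empty
#' proper subset is `PARTIAL`; no exons is `ABSENT`. `has_exon1` flags the
#' male-determining configuration in which a partial duplicate retains
#' exon 1 (the ARR17-like silencing trigger). The intact ARR17-like gene has
#' 5 exons; the intact MSF progenitor has 14, of which the Y-linked
#' duplicates carry 5.
#'
#' @param exons_present Integer vector of exon indices present (may be
#'   empty).
#' @param required_exons Number of exons in the intact gene (>= 1).
#' @return List with `exons_present`, `call` and `has_exon1`.
#' @export
classify_duplicate <- function(exons_present, required_exons) {
  stopifnot(required_exons >= 1)
  exons_present <- sort(unique(as.integer(exons_present)))
  if (length(exons_present) &&
      (any(exons_present < 1L) || any(exons_present > required_exons)))
    stop("exon index outside 1..required_exons")
  call <- if (length(exons_present) == 0L) "ABSENT"
          else if (length(exons_present) == required_exons) "INTACT"
          else "PARTIAL"
  list(exons_present = exons_present, call = call,
       has_exon1 = 1L %in% exons_present)
}

#' Detect co-localised ARR17-like + MSF cassettes
#'
#' Reports every pair of an ARR17-like partial duplicate retaining exon 1
#' and an MSF partial duplicate lying within `max_sep_bp` of each other on
#' one haplotype - the configuration of the mobile male-determining unit.
#'
#' @param copies Data frame with columns `copy_id, gene` (`"ARR17"` or
#'   `"MSF"`), `pos` (bp), `call` (from [classify_duplicate()]) and
#'   `has_exon1`.
#' @param slr Length-2 numeric SLR interval in bp (0-based half-open), used
#'   to flag cassette membership.
#' @param max_sep_bp Maximum separation (default 1 Mb).
#' @return Data frame `arr17_copy, msf_copy, arr17_pos, msf_pos,
#'   separation_bp, within_slr` (zero rows when no pair qualifies).
#' @export
detect_cassette <- function(copies, slr, max_sep_bp = 1e6) {
  need <- c("copy_id", "gene", "pos", "call", "has_exon1")
  stopifnot(all(need %in% names(copies)))
  arr <- copies[copies$gene == "ARR17" & copies$call == "PARTIAL" &
                  copies$has_exon1, , drop = FALSE]
  msf <- copies[copies$gene == "MSF" & copies$call == "PARTIAL", ,
                drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(arr))) for (j in seq_len(nrow(msf))) {
    sep <- abs(arr$pos[i] - msf$pos[j])
    if (sep <= max_sep_bp)
      out[[length(out) + 1L]] <- data.frame(
        arr17_copy = arr$copy_id[i], msf_copy = msf$copy_id[j],
        arr17_pos = arr$pos[i], msf_pos = msf$pos[j], separation_bp = sep,
        within_slr = arr$pos[i] >= slr[1] && arr$pos[i] < slr[2] &&
          msf$pos[j] >= slr[1] && msf$pos[j] < slr[2],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(arr17_copy = character(0), msf_copy = character(0),
                      arr17_pos = numeric(0), msf_pos = numeric(0),
                      separation_bp = numeric(0), within_slr = logical(0)))
  do.call(rbind, out)
}
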