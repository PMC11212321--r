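#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet translate
#'   pairwiseAlignment nucleotideSubstitutionMatrix pattern subject
#'   alignedPattern alignedSubject nindel insertion deletion
#' @importFrom BiocGenerics score start end width
NULL

CLONOTYPE_COLUMNS <- c("cdr3_nt", "cdr3_aa", "v_call", "j_call",
                       "count", "fraction", "productive")

#' GermlineReference: a mini V/J germline segment library
#'
#' Holds TRB V and J germline segments together with the 0-based position of
#' the conserved CDR3 anchor codon on each segment: the second conserved
#' cysteine (2nd-CYS) for V segments and the J-phenylalanine/tryptophan
#' (J-PHE/J-TRP) for J segments.  The CDR3 junction runs from the first base
#' of the V anchor codon through the last base of the J anchor codon.
#'
#' @slot sequences \code{DNAStringSet} of segment sequences, named by segment.
#' @slot kind character, \code{"V"} or \code{"J"} per segment.
#' @slot anchor integer, 0-based index of the first base of the anchor codon.
#' @slot family character, segment family (name truncated at the first
#'   \code{"-"} or \code{"*"}).
#' @seealso \code{\link{loadReference}}, \code{\link{referenceSegment}}
#' @exportClass GermlineReference
setClass("GermlineReference",
  representation(
    sequences = "DNAStringSet",
    kind = "character",
    anchor = "integer",
    family = "character"
  )
)

setValidity("GermlineReference", function(object) {
  n <- length(object@sequences)
  msg <- character(0)
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msg <- c(msg, "segment names must be present and unique")
  if (length(object@kind) != n || length(object@anchor) != n ||
      length(object@family) != n)
    msg <- c(msg, "kind, anchor and family must parallel the sequences")
  if (!all(object@kind %in% c("V", "J")))
    msg <- c(msg, "kind must be 'V' or 'J'")
  if (n > 0) {
    w <- width(object@sequences)
    if (any(object@anchor < 0L) || any(object@anchor + 3L > w))
      msg <- c(msg, "anchor codon must lie within the segment sequence")
    codons <- substr(as.character(object@sequences),
                     object@anchor + 1L, object@anchor + 3L)
    aa <- vapply(codons,
                 function(cd) as.character(translate(DNAString(cd))),
                 character(1), USE.NAMES = FALSE)
    bad_v <- object@kind == "V" & aa != "C"
    bad_j <- object@kind == "J" & !(aa %in% c("F", "W"))
    if (any(bad_v | bad_j))
      msg <- c(msg, paste0("anchor codon does not translate to the conserved ",
                           "residue for: ",
                           paste(names(object@sequences)[bad_v | bad_j],
                                 collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Repertoire: one sample's clonotype table plus metadata
#'
#' A clonotype is the set of UMI-corrected molecules sharing one CDR3
#' nucleotide sequence (including both anchor codons).  The table is kept in
#' canonical order (count descending, ties broken by \code{cdr3_nt}) with
#' fractions normalised over the retained clonotypes.
#'
#' @slot sampleId sample identifier.
#' @slot donorId donor identifier.
#' @slot group \code{"treated"}, \code{"untreated"} or \code{"unspecified"}.
#' @slot clonotypes \code{data.frame} with columns \code{cdr3_nt},
#'   \code{cdr3_aa}, \code{v_call}, \code{j_call}, \code{count},
#'   \code{fraction}, \code{productive}.
#' @seealso \code{\link{Repertoire}} (constructor), \code{\link{readAirr}}
#' @exportClass Repertoire
setClass("Repertoire",
  representation(
    sampleId = "character",
    donorId = "character",
    group = "character",
    clonotypes = "data.frame"
  )
)

setValidity("Repertoire", function(object) {
  msg <- character(0)
  ct <- object@clonotypes
  if (!all(CLONOTYPE_COLUMNS %in% names(ct)))
    msg <- c(msg, paste("clonotypes must have columns:",
                        paste(CLONOTYPE_COLUMNS, collapse = ", ")))
  if (!(object@group %in% c("treated", "untreated", "unspecified")))
    msg <- c(msg, "group must be 'treated', 'untreated' or 'unspecified'")
  if (length(msg) == 0 && nrow(ct) > 0) {
    if (anyDuplicated(ct$cdr3_nt))
      msg <- c(msg, "cdr3_nt values must be unique within a repertoire")
    if (any(ct$count < 0))
      msg <- c(msg, "counts must be non-negative")
    if (abs(sum(ct$fraction) - 1) > 1e-9)
      msg <- c(msg, "fractions must sum to 1 (within 1e-9)")
    ord <- orderDesc(ct$count, ct$cdr3_nt)
    if (!identical(ord, seq_len(nrow(ct))))
      msg <- c(msg, "clonotypes must be ordered by descending count, ties by cdr3_nt")
    if (any(ct$productive & ct$cdr3_aa == "") ||
        any(!ct$productive & ct$cdr3_aa != ""))
      msg <- c(msg, "cdr3_aa must be non-empty exactly for productive clonotypes")
    if (any(ct$productive & nchar(ct$cdr3_nt) %% 3L != 0L))
      msg <- c(msg, "productive clonotypes must have in-frame cdr3_nt")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Repertoire
#'
#' Builds a validated \linkS4class{Repertoire} from a clonotype table.
#' Fractions are (re)computed from \code{count} and the table is put into
#' canonical order.  Missing \code{cdr3_aa}/\code{productive} columns are
#' filled by translating the junctions.
#'
#' @param clonotypes data.frame with at least \code{cdr3_nt}, \code{v_call},
#'   \code{j_call}, \code{count}.
#' @param sampleId,donorId,group sample metadata.
#' @return A \linkS4class{Repertoire}.
#' @examples
#' rep <- Repertoire(data.frame(
#'   cdr3_nt = c("TGTGCCAGCAGCGAGCAGTTCTTC", "TGTGCCACCAGCGAGCAGTTCTTC"),
#'   v_call = c("TRBV9*01", "TRBV15*01"), j_call = "TRBJ2-1*01",
#'   count = c(3L, 1L)))
#' clonotypes(rep)$fraction
#' @export
Repertoire <- function(clonotypes, sampleId = "sample", donorId = "donor",
                       group = c("unspecified", "treated", "untreated")) {
  group <- match.arg(group)
  ct <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  stopifnot(all(c("cdr3_nt", "v_call", "j_call", "count") %in% names(ct)))
  if (is.null(ct$cdr3_aa) || is.null(ct$productive)) {
    tr <- translateJunction(ct$cdr3_nt)
    ct$cdr3_aa <- tr$cdr3_aa
    ct$productive <- tr$productive
  }
  ct$count <- as.integer(ct$count)
  total <- sum(ct$count)
  ct$fraction <- if (total > 0) ct$count / total else numeric(nrow(ct))
  ct <- ct[orderDesc(ct$count, ct$cdr3_nt), CLONOTYPE_COLUMNS, drop = FALSE]
  rownames(ct) <- NULL
  new("Repertoire", sampleId = sampleId, donorId = donorId, group = group,
      clonotypes = ct)
}

setMethod("show", "GermlineReference", function(object) {
  cat("GermlineReference with", sum(object@kind == "V"), "V and",
      sum(object@kind == "J"), "J segments\n")
  if (length(object@sequences))
    cat("  segments:", paste(head(names(object@sequences), 6), collapse = ", "),
        if (length(object@sequences) > 6) "..." else "", "\n")
})

setMethod("show", "Repertoire", function(object) {
  ct <- object@clonotypes
  cat(sprintf("Repertoire '%s' (donor %s, %s): %d clonotypes, %d molecules\n",
              object@sampleId, object@donorId, object@group,
              nrow(ct), sum(ct$count)))
  if (nrow(ct) > 0) {
    top <- head(ct, 3)
    cat(sprintf("  top clonotype: %s (%s) fraction %.4g\n",
                top$cdr3_nt[1],
                ifelse(top$cdr3_aa[1] == "", "unproductive", top$cdr3_aa[1]),
                top$fraction[1]))
  }
})

setMethod("length", "GermlineReference", function(x) length(x@sequences))

#' @describeIn GermlineReference-class subset by segment name or index
#' @param x,i object and index
#' @export
setMethod("[", "GermlineReference", function(x, i) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("GermlineReference", sequences = x@sequences[i], kind = x@kind[i],
      anchor = x@anchor[i], family = x@family[i])
})
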