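#' @importFrom utils head
NULL

#' Accessors for Repertoire and GermlineReference objects
#'
#' @param x a \linkS4class{Repertoire} or \linkS4class{GermlineReference}.
#' @return \code{clonotypes} returns the clonotype \code{data.frame};
#'   \code{sampleId}, \code{donorId}, \code{sampleGroup} return metadata
#'   strings; \code{totalCount} the summed molecule count; \code{uniqueCdr3}
#'   the number of distinct CDR3 nucleotide sequences; \code{segmentKind},
#'   \code{anchorPos}, \code{segmentFamily} the per-segment annotations.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))
#' @rdname accessors
#' @export
setMethod("clonotypes", "Repertoire", function(x) x@clonotypes)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "Repertoire", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("donorId", function(x) standardGeneric("donorId"))
#' @rdname accessors
#' @export
setMethod("donorId", "Repertoire", function(x) x@donorId)

#' @rdname accessors
#' @export
setGeneric("sampleGroup", function(x) standardGeneric("sampleGroup"))
#' @rdname accessors
#' @export
setMethod("sampleGroup", "Repertoire", function(x) x@group)

#' @rdname accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))
#' @rdname accessors
#' @export
setMethod("totalCount", "Repertoire", function(x) sum(x@clonotypes$count))

#' @rdname accessors
#' @export
setGeneric("uniqueCdr3", function(x) standardGeneric("uniqueCdr3"))
#' @rdname accessors
#' @export
setMethod("uniqueCdr3", "Repertoire", function(x) nrow(x@clonotypes))

#' @rdname accessors
#' @export
setGeneric("segmentKind", function(x) standardGeneric("segmentKind"))
#' @rdname accessors
#' @export
setMethod("segmentKind", "GermlineReference",
          function(x) setNames(x@kind, names(x@sequences)))

#' @rdname accessors
#' @export
setGeneric("anchorPos", function(x) standardGeneric("anchorPos"))
#' @rdname accessors
#' @export
setMethod("anchorPos", "GermlineReference",
          function(x) setNames(x@anchor, names(x@sequences)))

#' @rdname accessors
#' @export
setGeneric("segmentFamily", function(x) standardGeneric("segmentFamily"))
#' @rdname accessors
#' @export
setMethod("segmentFamily", "GermlineReference",
          function(x) setNames(x@family, names(x@sequences)))

#' @rdname accessors
#' @export
setMethod("names", "GermlineReference", function(x) names(x@sequences))

#' Extract one reference segment as a plain record
#'
#' @param ref a \linkS4class{GermlineReference}.
#' @param name segment name.
#' @return list with \code{name}, \code{kind}, \code{sequence} (character),
#'   \code{anchor} (0-based first base of the anchor codon) and \code{family}.
#' @export
referenceSegment <- function(ref, name) {
  i <- match(name, names(ref@sequences))
  if (is.na(i)) stop("unknown reference segment: ", name)
  list(name = names(ref@sequences)[i], kind = ref@kind[i],
       sequence = as.character(ref@sequences[[i]]), anchor = ref@anchor[i],
       family = ref@family[i])
}

#' Restrict a repertoire to productive clonotypes
#'
#' Drops out-of-frame and stop-codon clonotypes and renormalises fractions
#' over the productive remainder, mirroring the productivity filter the
#' assembly pipeline applies.
#'
#' @param rep a \linkS4class{Repertoire}.
#' @return A \linkS4class{Repertoire} with only productive clonotypes.
#' @export
productiveOnly <- function(rep) {
  ct <- clonotypes(rep)[clonotypes(rep)$productive, , drop = FALSE]
  Repertoire(ct, sampleId = sampleId(rep), donorId = donorId(rep),
             group = sampleGroup(rep))
}
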