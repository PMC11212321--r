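AIRR_COLUMNS <- c("sequence_id", "v_call", "j_call", "junction",
                  "junction_aa", "productive", "duplicate_count")

#' Read a UMI-prefixed FASTQ file
#'
#' Parses a 4-line-per-record FASTQ (Phred+33) in which the unique molecular
#' identifier (UMI) occupies the first \code{umiLength} bases of every read,
#' as produced during 5'-RACE cDNA synthesis.  The UMI is stripped into its
#' own field; \code{sequence}/\code{quality} exclude it.
#'
#' @param path FASTQ file path.
#' @param umiLength number of leading bases to strip as the UMI.
#' @return data.frame with columns \code{read_id}, \code{umi},
#'   \code{sequence}, \code{quality}, in file order.
#' @export
readUmiFastq <- function(path, umiLength = 12L) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': line count ", length(lines),
         " is not divisible by 4")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(read_id = character(0), umi = character(0),
                      sequence = character(0), quality = character(0)))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in '", path, "'")
  short <- which(nchar(seq) <= umiLength)
  if (length(short))
    stop("FASTQ record ", short[1], " shorter than the UMI length (",
         umiLength, ")")
  data.frame(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
    umi = substr(seq, 1L, umiLength),
    sequence = substr(seq, umiLength + 1L, nchar(seq)),
    quality = substr(qual, umiLength + 1L, nchar(qual))
  )
}

#' Write reads as a UMI-prefixed FASTQ file
#'
#' Inverse of \code{\link{readUmiFastq}}: the UMI is re-attached as the read
#' prefix (with matching quality characters) so the round trip is lossless.
#'
#' @param reads data.frame as returned by \code{\link{readUmiFastq}} or
#'   \code{\link{simulateReads}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeUmiFastq <- function(reads, path) {
  umi_qual <- vapply(nchar(reads$umi),
                     function(n) strrep("I", n), character(1))
  out <- rbind(paste0("@", reads$read_id),
               paste0(reads$umi, reads$sequence),
               rep("+", nrow(reads)),
               paste0(umi_qual, reads$quality))
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read an AIRR Rearrangement TSV into a Repertoire
#'
#' Reads a tab-separated clonotype table in the AIRR Community Rearrangement
#' dialect (junction includes both anchor codons).  Rows sharing a junction
#' are merged by summing \code{duplicate_count}; fractions are recomputed
#' from the merged counts.
#'
#' @param path TSV path.
#' @param sampleId,donorId,group sample metadata attached to the result.
#' @return A \linkS4class{Repertoire}.
#' @export
readAirr <- function(path, sampleId = basename(path), donorId = "donor",
                     group = c("unspecified", "treated", "untreated")) {
  group <- match.arg(group)
  tab <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE)
  missing_cols <- setdiff(AIRR_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("AIRR file '", path, "' is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) {
    ct <- data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
                     v_call = character(0), j_call = character(0),
                     count = integer(0), fraction = numeric(0),
                     productive = logical(0))
    return(new("Repertoire", sampleId = sampleId, donorId = donorId,
               group = group, clonotypes = ct))
  }
  count <- as.integer(tab$duplicate_count)
  agg <- rowsum(count, tab$junction, reorder = FALSE)
  first <- !duplicated(tab$junction)
  ct <- data.frame(
    cdr3_nt = tab$junction[first],
    cdr3_aa = tab$junction_aa[first],
    v_call = tab$v_call[first],
    j_call = tab$j_call[first],
    count = as.integer(agg[match(tab$junction[first], rownames(agg)), 1]),
    productive = tab$productive[first] %in% c("T", "TRUE", "true")
  )
  ct$cdr3_aa[!ct$productive] <- ""
  Repertoire(ct, sampleId = sampleId, donorId = donorId, group = group)
}

#' Write a Repertoire as an AIRR Rearrangement TSV
#'
#' Columns are emitted in the fixed order \code{sequence_id}, \code{v_call},
#' \code{j_call}, \code{junction}, \code{junction_aa}, \code{productive},
#' \code{duplicate_count}; \code{productive} is encoded \code{"T"}/\code{"F"}.
#' \code{\link{readAirr}} on the result reproduces junctions, calls and
#' counts exactly.
#'
#' @param rep a \linkS4class{Repertoire}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeAirr <- function(rep, path) {
  ct <- clonotypes(rep)
  out <- data.frame(
    sequence_id = if (nrow(ct)) sprintf("%s_c%05d", sampleId(rep),
                                        seq_len(nrow(ct))) else character(0),
    v_call = ct$v_call,
    j_call = ct$j_call,
    junction = ct$cdr3_nt,
    junction_aa = ct$cdr3_aa,
    productive = ifelse(ct$productive, "T", "F"),
    duplicate_count = ct$count
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a germline V/J reference from FASTA
#'
#' Headers follow the piped dialect \code{>name|kind|anchor} where
#' \code{kind} is \code{V} or \code{J} and \code{anchor} is the 0-based
#' position of the conserved anchor codon (2nd-CYS for V, J-PHE/J-TRP for J).
#' Anchors are validated at load time: a V anchor codon must translate to C
#' and a J anchor codon to F or W.  Families are derived by truncating the
#' segment name at the first \code{"-"} or \code{"*"}.
#'
#' The package ships a small synthetic reference at
#' \code{system.file("extdata", "trb_synthetic_reference.fasta",
#' package = "ClonoTRB")}.
#'
#' @param path FASTA path (defaults to the bundled synthetic reference).
#' @return A \linkS4class{GermlineReference}.
#' @export
loadReference <- function(path = system.file("extdata",
                                             "trb_synthetic_reference.fasta",
                                             package = "ClonoTRB")) {
  seqs <- readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("reference header not in name|kind|anchor form: ",
         names(seqs)[bad[1]])
  nm <- vapply(parts, `[`, character(1), 1L)
  kind <- vapply(parts, `[`, character(1), 2L)
  anchor <- as.integer(vapply(parts, `[`, character(1), 3L))
  names(seqs) <- nm
  family <- sub("[-*].*$", "", nm)
  ref <- new("GermlineReference", sequences = seqs, kind = kind,
             anchor = anchor, family = family)
  validObject(ref)
  ref
}
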