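#' Assembly configuration
#'
#' Thresholds for the read-to-clonotype pipeline: UMI grouping, local
#' alignment scoring and the segment-assignment score floor.  The default
#' scoring (+2 match, -2 mismatch, -3 per gap base, minimum reported score
#' 30) is chosen so that random sequences fail assignment against the
#' bundled reference while true reads pass with wide margin.
#'
#' @param umiLength UMI prefix length in the FASTQ.
#' @param maxHamming maximum UMI Hamming distance for directional merging.
#' @param ratio directional-merge count ratio: a smaller UMI group is folded
#'   into a larger one only when \code{count_large >= ratio * count_small}.
#' @param minScore minimum local alignment score for a V or J assignment.
#' @param match,mismatch,gap alignment scores (gap is per gap base).
#' @param minMeanPhred optional mean-quality cutoff applied to reads before
#'   grouping (\code{NULL} disables quality filtering).
#' @return A list of class \code{AssemblyConfig}.
#' @export
assemblyConfig <- function(umiLength = 12L, maxHamming = 1L, ratio = 2,
                           minScore = 30, match = 2, mismatch = -2, gap = -3,
                           minMeanPhred = NULL) {
  structure(list(umiLength = as.integer(umiLength),
                 maxHamming = as.integer(maxHamming), ratio = ratio,
                 minScore = minScore, match = match, mismatch = mismatch,
                 gap = gap, minMeanPhred = minMeanPhred),
            class = "AssemblyConfig")
}

#' Group reads into UMI families
#'
#' Reads are first grouped by exact UMI.  With \code{maxHamming > 0},
#' smaller groups are then merged into larger ones by the directional rule:
#' group B folds into group A when \code{Hamming(umi_A, umi_B) <= maxHamming}
#' and \code{count_A >= ratio * count_B}.  Candidate parents are considered
#' in deterministic order (descending read count, ties by UMI), and merges
#' chain to the final root, so the result does not depend on input order.
#'
#' @param reads data.frame from \code{\link{readUmiFastq}}.
#' @param maxHamming maximum UMI distance for a merge (0 = exact only).
#' @param ratio directional count ratio.
#' @return List of UMI families, each a list with \code{umi} (the root UMI),
#'   \code{reads} (the member rows) and \code{size}; ordered by descending
#'   family size, ties by UMI.
#' @export
groupByUmi <- function(reads, maxHamming = 1L, ratio = 2) {
  fam <- .groupUmiIndices(reads$umi, maxHamming, ratio)
  lapply(seq_along(fam$members), function(k) {
    rows <- fam$members[[k]]
    list(umi = fam$root[k], reads = reads[rows, , drop = FALSE],
         size = length(rows))
  })
}

# core directional grouping on the UMI vector; returns root UMIs and member
# read-row indices per family, ordered by descending size then UMI
.groupUmiIndices <- function(read_umis, maxHamming = 1L, ratio = 2) {
  if (length(read_umis) == 0L)
    return(list(root = character(0), members = list()))
  cnt <- table(read_umis)
  umis <- names(cnt)
  counts <- as.integer(cnt)
  ord <- orderDesc(counts, umis)
  umis <- umis[ord]; counts <- counts[ord]
  n <- length(umis)
  root <- seq_len(n)

  if (maxHamming > 0L && n > 1L) {
    pos <- new.env(parent = emptyenv())
    for (k in seq_len(n)) assign(umis[k], k, envir = pos)
    findRoot <- function(k) { while (root[k] != k) k <- root[k]; k }
    for (k in seq(2L, n)) {
      if (counts[1] < ratio * counts[k]) next  # no group is large enough
      if (maxHamming == 1L) {
        # enumerate the 3L Hamming-1 neighbours and look them up
        u <- strsplit(umis[k], "", fixed = TRUE)[[1]]
        cand <- integer(0)
        for (p in seq_along(u)) for (b in DNA_BASES4) {
          if (b == u[p]) next
          v <- u; v[p] <- b
          key <- paste(v, collapse = "")
          if (exists(key, envir = pos, inherits = FALSE))
            cand <- c(cand, get(key, envir = pos))
        }
      } else {
        a <- utf8ToInt(umis[k])
        dist <- vapply(umis, function(x) sum(utf8ToInt(x) != a), integer(1))
        cand <- which(dist > 0L & dist <= maxHamming)
      }
      cand <- cand[cand < k & counts[cand] >= ratio * counts[k]]
      if (length(cand))
        root[k] <- findRoot(cand[which.min(cand)])  # earlier = larger/lex-first
    }
    root <- vapply(seq_len(n), findRoot, integer(1))
  }

  idx_by_umi <- split(seq_along(read_umis), read_umis)
  fam_members <- split(seq_len(n), root)
  members <- lapply(fam_members, function(m)
    sort(unlist(idx_by_umi[umis[m]], use.names = FALSE)))
  roots <- vapply(fam_members, function(m) umis[m[1]], character(1))
  sizes <- lengths(members)
  keep <- orderDesc(sizes, roots)
  list(root = unname(roots[keep]), members = unname(members[keep]))
}

#' Consensus sequence of a UMI family
#'
#' Takes the per-position plurality base over the family's reads of the
#' modal length (ties in the modal length resolved towards the shorter
#' length; base ties broken in the fixed order A < C < G < T).
#'
#' @param family a family from \code{\link{groupByUmi}}, or a character
#'   vector of read sequences.
#' @return The consensus DNA string.
#' @export
umiConsensus <- function(family) {
  seqs <- if (is.character(family)) family else family$reads$sequence
  if (length(seqs) == 0L) stop("cannot take the consensus of an empty family")
  lens <- nchar(seqs)
  tab <- table(lens)
  modal <- as.integer(names(tab)[tab == max(tab)][1])  # tie -> shortest
  seqs <- seqs[lens == modal]
  if (length(unique(seqs)) == 1L) return(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  cons <- apply(mat, 2, function(col) {
    counts <- tabulate(match(col, DNA_BASES4), nbins = 4L)
    DNA_BASES4[which.max(counts)]  # first max = A < C < G < T
  })
  paste(cons, collapse = "")
}

.substMatrix <- function(match, mismatch) {
  nucleotideSubstitutionMatrix(match = match, mismatch = mismatch)
}

# walk one gapped alignment to project subject position a1 (1-based) onto
# the pattern; NA when a1 maps to a pattern gap
.projectThroughGaps <- function(pa_i, a1) {
  pch <- strsplit(as.character(alignedPattern(pa_i)), "", fixed = TRUE)[[1]]
  sch <- strsplit(as.character(alignedSubject(pa_i)), "", fixed = TRUE)[[1]]
  pcoord <- cumsum(pch != "-") + start(pattern(pa_i)) - 1L
  scoord <- cumsum(sch != "-") + start(subject(pa_i)) - 1L
  hit <- which(scoord == a1 & sch != "-")[1]
  if (is.na(hit) || pch[hit] == "-") return(NA_integer_)
  pcoord[hit] - 1L
}

# vectorised local alignment of several queries against one segment.
# Anchor projection is lazy: gapless alignments (the overwhelming case for
# substitution-only data) get the arithmetic projection up front; rows with
# indels are marked and resolved per element by .anchorAt, so the expensive
# gapped walk runs only for winning hits.
.alignInfo <- function(queries, segment_seq, anchor0, match, mismatch, gap) {
  pa <- pairwiseAlignment(DNAStringSet(queries), DNAString(segment_seq),
                          type = "local",
                          substitutionMatrix = .substMatrix(match, mismatch),
                          gapOpening = 0, gapExtension = abs(gap))
  p1 <- start(pattern(pa)); p2 <- end(pattern(pa))
  s1 <- start(subject(pa)); s2 <- end(subject(pa))
  ni <- nindel(pa)
  has_indel <- insertion(ni)[, "Length"] > 0L | deletion(ni)[, "Length"] > 0L
  a1 <- anchor0 + 1L
  in_span <- a1 >= s1 & a1 <= s2
  anchorq <- ifelse(in_span & !has_indel, p1 + (a1 - s1) - 1L, NA_integer_)
  list(score = score(pa), qstart = p1 - 1L, qend = p2,
       anchorq = as.integer(anchorq),
       needs_walk = has_indel & in_span, pa = pa, a1 = a1)
}

# anchor position (0-based) of query i from an .alignInfo result
.anchorAt <- function(info, i) {
  if (info$needs_walk[i]) .projectThroughGaps(info$pa[i], info$a1)
  else info$anchorq[i]
}

#' Locally align a query against one reference segment
#'
#' Smith-Waterman local alignment under a linear gap scheme (+2 match, -2
#' mismatch, -3 per gap base by default), with the segment's anchor codon
#' position projected through the alignment onto the query.
#'
#' @param query DNA string.
#' @param segment a record from \code{\link{referenceSegment}}.
#' @param match,mismatch,gap alignment scores.
#' @return List with \code{segment} (name), \code{score},
#'   \code{query_start}/\code{query_end} (0-based half-open) and
#'   \code{anchor_on_query} (0-based, \code{NA} if the anchor is unaligned).
#' @export
alignSegment <- function(query, segment, match = 2, mismatch = -2, gap = -3) {
  stopifnot(nchar(query) > 0)
  info <- .alignInfo(query, segment$sequence, segment$anchor,
                     match, mismatch, gap)
  list(segment = segment$name,
       score = info$score,
       query_start = info$qstart,
       query_end = info$qend,
       anchor_on_query = .anchorAt(info, 1L))
}

# batch V/J assignment over a set of (deduplicated) consensus sequences.
# Returns one row per query: calls, anchors, scores, assignable flag.
.assignVJSet <- function(queries, reference, minScore = 30, match = 2,
                         mismatch = -2, gap = -3) {
  n <- length(queries)
  kinds <- segmentKind(reference)
  anchors <- anchorPos(reference)
  seqs <- as.character(reference@sequences)
  v_names <- sort(names(kinds)[kinds == "V"], method = "radix")
  j_names <- sort(names(kinds)[kinds == "J"], method = "radix")

  out <- data.frame(v_call = NA_character_, j_call = NA_character_,
                    v_anchor = NA_integer_, j_anchor = NA_integer_,
                    v_score = NA_real_, j_score = NA_real_,
                    assignable = rep(FALSE, n))
  if (n == 0L) return(out)

  v_info <- lapply(v_names, function(nm)
    .alignInfo(queries, seqs[nm], anchors[nm], match, mismatch, gap))
  v_scores <- vapply(v_info, `[[`, numeric(n), "score")
  v_scores <- matrix(v_scores, nrow = n)
  best_v <- max.col(v_scores, ties.method = "first")  # lexicographic tie-break
  out$v_call <- v_names[best_v]
  out$v_score <- v_scores[cbind(seq_len(n), best_v)]
  for (i in seq_len(n)) {
    if (out$v_score[i] >= minScore)
      out$v_anchor[i] <- .anchorAt(v_info[[best_v[i]]], i)
  }

  # restrict the J search to the region downstream of the V anchor codon
  idx <- which(!is.na(out$v_anchor) & nchar(queries) > out$v_anchor + 3L)
  if (length(idx)) {
    offs <- out$v_anchor[idx] + 3L
    regions <- substr(queries[idx], offs + 1L, nchar(queries[idx]))
    j_info <- lapply(j_names, function(nm)
      .alignInfo(regions, seqs[nm], anchors[nm], match, mismatch, gap))
    j_scores <- vapply(j_info, `[[`, numeric(length(idx)), "score")
    j_scores <- matrix(j_scores, nrow = length(idx))
    best_j <- max.col(j_scores, ties.method = "first")
    out$j_call[idx] <- j_names[best_j]
    out$j_score[idx] <- j_scores[cbind(seq_along(idx), best_j)]
    for (k in seq_along(idx)) {
      if (j_scores[k, best_j[k]] >= minScore) {
        pj <- .anchorAt(j_info[[best_j[k]]], k)
        if (!is.na(pj)) out$j_anchor[idx[k]] <- pj + offs[k]
      }
    }
  }
  out$assignable <- !is.na(out$v_anchor) & !is.na(out$j_anchor) &
    out$v_score >= minScore & !is.na(out$j_score) & out$j_score >= minScore &
    out$v_anchor < out$j_anchor
  out
}

#' Assign the best V and J segments to a query
#'
#' Picks the best-scoring V and J local alignments at or above
#' \code{minScore}; score ties are broken by segment name.  The J search is
#' restricted to the query region downstream of the projected V anchor
#' codon.  Queries with no qualifying V or J hit are flagged unassignable.
#'
#' @param query DNA string.
#' @param reference a \linkS4class{GermlineReference}.
#' @param minScore,match,mismatch,gap see \code{\link{assemblyConfig}}.
#' @return List with \code{v_call}, \code{j_call}, \code{v_anchor},
#'   \code{j_anchor} (0-based anchor positions on the query), scores, and
#'   \code{assignable}.
#' @export
assignVJ <- function(query, reference, minScore = 30, match = 2,
                     mismatch = -2, gap = -3) {
  as.list(.assignVJSet(query, reference, minScore, match, mismatch, gap)[1, ])
}

#' Extract the CDR3 junction given anchor positions
#'
#' Returns the query substring from the first base of the V anchor codon
#' (2nd-CYS) through the last base of the J anchor codon (J-PHE/J-TRP),
#' inclusive — the junction convention in which productive CDR3s start with
#' C and end with F or W.
#'
#' @param query DNA string.
#' @param vHit,jHit assignment results carrying \code{anchor_on_query} /
#'   \code{v_anchor}/\code{j_anchor} 0-based positions, or bare integers.
#' @return The CDR3 nucleotide string, or \code{NA_character_} when either
#'   anchor is undefined or the anchors are out of order.
#' @export
extractCdr3 <- function(query, vHit, jHit) {
  v0 <- if (is.list(vHit)) {
    if (!is.null(vHit$anchor_on_query)) vHit$anchor_on_query else vHit$v_anchor
  } else vHit
  j0 <- if (is.list(jHit)) {
    if (!is.null(jHit$anchor_on_query)) jHit$anchor_on_query else jHit$j_anchor
  } else jHit
  if (is.na(v0) || is.na(j0) || v0 >= j0) return(NA_character_)
  substr(query, v0 + 1L, j0 + 3L)
}

#' Translate a CDR3 junction and decide productivity
#'
#' A junction is productive iff its length is divisible by 3 and its
#' standard-genetic-code translation contains no stop codon; unproductive
#' junctions get an empty amino-acid string, mirroring the removal of
#' out-of-frame and stop-codon rearrangements from the repertoire.
#'
#' @param cdr3_nt character vector of DNA junctions.
#' @return data.frame with \code{cdr3_aa} and \code{productive}.
#' @export
translateJunction <- function(cdr3_nt) {
  if (length(cdr3_nt) == 0L)
    return(data.frame(cdr3_aa = character(0), productive = logical(0)))
  if (any(!isDna(cdr3_nt)))
    stop("junction contains non-ACGT characters: ",
         cdr3_nt[!isDna(cdr3_nt)][1])
  inframe <- nchar(cdr3_nt) %% 3L == 0L & nchar(cdr3_nt) > 0L
  aa <- character(length(cdr3_nt))
  if (any(inframe)) {
    aa[inframe] <- as.character(translate(DNAStringSet(cdr3_nt[inframe])))
  }
  productive <- inframe & !grepl("*", aa, fixed = TRUE)
  aa[!productive] <- ""
  data.frame(cdr3_aa = aa, productive = productive)
}

# plurality vote with lexicographic tie-break
.plurality <- function(x) {
  ux <- sort(unique(x), method = "radix")
  ux[which.max(tabulate(match(x, ux)))]
}

#' Aggregate per-molecule records into a Repertoire
#'
#' One clonotype per distinct CDR3 nucleotide sequence; the molecule count is
#' the number of UMI families carrying that junction, V/J calls are the
#' plurality vote within the clonotype (ties broken lexicographically), and
#' fractions are normalised over the productive clonotypes retained after
#' the productivity filter.
#'
#' @param records data.frame with one row per molecule: \code{cdr3_nt},
#'   \code{cdr3_aa}, \code{v_call}, \code{j_call}.
#' @param sampleId,donorId,group sample metadata.
#' @return A \linkS4class{Repertoire} of productive clonotypes.
#' @export
aggregateClonotypes <- function(records, sampleId = "sample",
                                donorId = "donor", group = "unspecified") {
  tr <- translateJunction(records$cdr3_nt)
  keep <- tr$productive
  if (!any(keep))
    stop("empty repertoire: no productive records to aggregate")
  records <- records[keep, , drop = FALSE]
  aa <- tr$cdr3_aa[keep]
  by_junction <- split(seq_len(nrow(records)), records$cdr3_nt)
  ct <- data.frame(
    cdr3_nt = names(by_junction),
    cdr3_aa = vapply(by_junction, function(i) aa[i[1]], character(1)),
    v_call = vapply(by_junction,
                    function(i) .plurality(records$v_call[i]), character(1)),
    j_call = vapply(by_junction, function(i) .plurality(records$j_call[i]),
                    character(1)),
    count = lengths(by_junction),
    productive = TRUE,
    row.names = NULL
  )
  Repertoire(ct, sampleId = sampleId, donorId = donorId, group = group)
}

#' Run the full read-to-clonotype assembly
#'
#' Composition of the pipeline: FASTQ parsing with UMI stripping, optional
#' mean-quality filtering, directional UMI grouping, per-family consensus,
#' V/J assignment, CDR3 extraction, productivity filtering and clonotype
#' aggregation.  Molecule counts are UMI families, not raw reads.
#'
#' @param fastqPath path to a UMI-prefixed FASTQ.
#' @param reference a \linkS4class{GermlineReference}.
#' @param config an \code{\link{assemblyConfig}}.
#' @param sampleId,donorId,group sample metadata.
#' @return List with \code{repertoire} (a \linkS4class{Repertoire}) and
#'   \code{qc}, a list of tallies: \code{reads_in}, \code{reads_kept},
#'   \code{umi_families}, \code{unassignable}, \code{unproductive},
#'   \code{clonotypes}.
#' @export
runAssembly <- function(fastqPath, reference, config = assemblyConfig(),
                        sampleId = "sample", donorId = "donor",
                        group = "unspecified") {
  reads <- readUmiFastq(fastqPath, config$umiLength)
  if (nrow(reads) == 0L)
    stop("empty repertoire: no reads in '", fastqPath, "'")
  reads_in <- nrow(reads)
  if (!is.null(config$minMeanPhred)) {
    mean_q <- vapply(reads$quality,
                     function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                     USE.NAMES = FALSE)
    reads <- reads[mean_q >= config$minMeanPhred, , drop = FALSE]
    if (nrow(reads) == 0L)
      stop("empty repertoire: all reads removed by the quality filter")
  }
  fams <- .groupUmiIndices(reads$umi, config$maxHamming, config$ratio)
  cons <- vapply(fams$members,
                 function(rows) umiConsensus(reads$sequence[rows]),
                 character(1))
  uq <- unique(cons)
  asn <- .assignVJSet(uq, reference, config$minScore, config$match,
                      config$mismatch, config$gap)
  cdr3 <- rep(NA_character_, length(uq))
  ok <- asn$assignable
  cdr3[ok] <- substr(uq[ok], asn$v_anchor[ok] + 1L, asn$j_anchor[ok] + 3L)
  tr <- translateJunction(ifelse(is.na(cdr3), "", cdr3))

  map <- match(cons, uq)
  assignable_fam <- ok[map]
  productive_fam <- assignable_fam & tr$productive[map]
  if (!any(productive_fam))
    stop("empty repertoire: no productive molecules after assembly")
  records <- data.frame(
    cdr3_nt = cdr3[map][productive_fam],
    cdr3_aa = tr$cdr3_aa[map][productive_fam],
    v_call = asn$v_call[map][productive_fam],
    j_call = asn$j_call[map][productive_fam]
  )
  rep <- aggregateClonotypes(records, sampleId, donorId, group)
  qc <- list(reads_in = reads_in, reads_kept = nrow(reads),
             umi_families = length(fams$members),
             unassignable = sum(!assignable_fam),
             unproductive = sum(assignable_fam & !productive_fam),
             clonotypes = uniqueCdr3(rep))
  list(repertoire = rep, qc = qc)
}
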