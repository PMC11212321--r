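#' Clonal diversity and dominance indices
#'
#' Plug-in estimators on clonotype fractions \eqn{p_i}: Simpson
#' \eqn{\sum p_i^2}, inverse Simpson (the clonality index)
#' \eqn{1/\sum p_i^2}, Shannon-Weaver \eqn{-\sum p_i \ln p_i} (natural log)
#' and Berger-Parker \eqn{\max p_i}.  No bias correction is applied.
#'
#' @param rep a \linkS4class{Repertoire} with at least one clonotype.
#' @return List with \code{total_count}, \code{unique_cdr3}, \code{simpson},
#'   \code{inv_simpson}, \code{shannon}, \code{berger_parker}.
#' @examples
#' rep <- Repertoire(data.frame(
#'   cdr3_nt = c("TGTGCCAGCAGCGAGCAGTTCTTC", "TGTGCCACCAGCGAGCAGTTCTTC"),
#'   v_call = "TRBV9*01", j_call = "TRBJ2-1*01", count = c(1L, 1L)))
#' clonalDiversity(rep)$inv_simpson  # 2: two equally abundant clones
#' @export
clonalDiversity <- function(rep) {
  ct <- clonotypes(rep)
  if (nrow(ct) == 0L) stop("diversity of an empty repertoire is undefined")
  p <- ct$fraction
  simpson <- sum(p^2)
  list(total_count = sum(ct$count),
       unique_cdr3 = nrow(ct),
       simpson = simpson,
       inv_simpson = 1 / simpson,
       shannon = -sum(p * log(p)),
       berger_parker = max(p))
}

#' V/J/V-J segment usage
#'
#' Fraction of the repertoire attributed to each V segment, J segment or
#' V-J pair, weighted either by molecule count (\code{count_weighted}) or by
#' unique clonotype (\code{clonotype_weighted}).  Clonotypes with a missing
#' call on the requested axis are tallied under \code{"unresolved"}.
#'
#' @param rep a \linkS4class{Repertoire}.
#' @param axis \code{"V"}, \code{"J"} or \code{"VJ"}.
#' @param weighting \code{"count_weighted"} or \code{"clonotype_weighted"}.
#' @return List of class \code{UsageTable} with \code{axis},
#'   \code{weighting} and \code{entries}, a named numeric vector of
#'   fractions sorted descending (ties by name).
#' @export
segmentUsage <- function(rep, axis = c("V", "J", "VJ"),
                         weighting = c("count_weighted",
                                       "clonotype_weighted")) {
  axis <- match.arg(axis)
  weighting <- match.arg(weighting)
  ct <- clonotypes(rep)
  if (nrow(ct) == 0L) stop("usage of an empty repertoire is undefined")
  key <- switch(axis,
                V = ct$v_call,
                J = ct$j_call,
                VJ = paste(ct$v_call, ct$j_call, sep = "|"))
  unresolved <- is.na(ct$v_call) | ct$v_call == "" |
    (axis != "V" & (is.na(ct$j_call) | ct$j_call == ""))
  key[unresolved] <- "unresolved"
  w <- if (weighting == "count_weighted") ct$count else rep(1L, nrow(ct))
  totals <- rowsum(as.numeric(w), key)
  entries <- setNames(totals[, 1] / sum(w), rownames(totals))
  entries <- entries[orderDesc(entries, names(entries))]
  structure(list(axis = axis, weighting = weighting, entries = entries),
            class = "UsageTable")
}

#' Top segments of a usage table
#'
#' @param table a \code{UsageTable} from \code{\link{segmentUsage}}, or a
#'   named numeric vector of fractions.
#' @param n number of top entries (ties broken by name).
#' @return List with \code{segments}, \code{fractions} and \code{combined},
#'   the summed fraction of the top \code{n}.
#' @export
topSegments <- function(table, n) {
  entries <- if (inherits(table, "UsageTable")) table$entries else table
  entries <- entries[orderDesc(entries, names(entries))]
  top <- head(entries, n)
  list(segments = names(top), fractions = unname(top),
       combined = sum(top))
}

#' CDR3 length distribution
#'
#' Count-weighted histogram of CDR3 lengths in nucleotides or amino acids.
#' With \code{unit = "aa"} only productive clonotypes contribute (their aa
#' length is nt length / 3).
#'
#' @param rep a \linkS4class{Repertoire}.
#' @param unit \code{"nt"} or \code{"aa"}.
#' @param productiveOnly drop unproductive clonotypes first (default TRUE;
#'   forced for \code{unit = "aa"}).
#' @return List of class \code{LengthDistribution} with \code{unit},
#'   \code{histogram} (named fractions keyed by length, ascending) and
#'   \code{mode} (smallest length at the maximum, if tied).
#' @export
lengthDistribution <- function(rep, unit = c("nt", "aa"),
                               productiveOnly = TRUE) {
  unit <- match.arg(unit)
  ct <- clonotypes(rep)
  if (unit == "aa") productiveOnly <- TRUE
  if (productiveOnly) ct <- ct[ct$productive, , drop = FALSE]
  if (nrow(ct) == 0L)
    stop("no clonotypes left for the length distribution")
  len <- if (unit == "nt") nchar(ct$cdr3_nt) else nchar(ct$cdr3_aa)
  totals <- rowsum(as.numeric(ct$count), len)
  hist <- setNames(totals[, 1] / sum(ct$count), rownames(totals))
  hist <- hist[order(as.integer(names(hist)))]
  structure(list(unit = unit, histogram = hist,
                 mode = as.integer(names(hist)[which.max(hist)])),
            class = "LengthDistribution")
}

#' Positional amino-acid motif matrix (sequence logo data)
#'
#' Count-weighted positional amino-acid frequencies over the productive
#' clonotypes of exactly one CDR3 amino-acid length, with per-position
#' information content \eqn{\log_2 20 - H_j} in bits (\eqn{H_j} the Shannon
#' entropy of column \eqn{j}).  Letter heights in a logo are
#' \code{freq * info}, so invariant positions reach \eqn{\log_2 20 \approx
#' 4.32} bits and uniform positions carry none.
#'
#' @param rep a \linkS4class{Repertoire}.
#' @param length CDR3 amino-acid length to profile; default is the modal
#'   (count-weighted) aa length.
#' @return List of class \code{MotifMatrix} with \code{length}, \code{freq}
#'   (20 x length matrix, columns summing to 1), \code{info} (bits per
#'   position) and \code{heights} (\code{freq} scaled by \code{info}).
#' @export
motifMatrix <- function(rep, length = NULL) {
  ct <- clonotypes(rep)
  ct <- ct[ct$productive, , drop = FALSE]
  if (nrow(ct) == 0L) stop("no productive clonotypes for the motif matrix")
  aalen <- nchar(ct$cdr3_aa)
  if (is.null(length)) {
    totals <- rowsum(as.numeric(ct$count), aalen)
    length <- as.integer(rownames(totals)[which.max(totals[, 1])])
  }
  sel <- ct[aalen == length, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no productive clonotype of aa length ", length,
         "; available lengths: ",
         paste(sort(unique(aalen)), collapse = ", "))
  freq <- matrix(0, nrow = 20L, ncol = length,
                 dimnames = list(AA_ALPHABET20, seq_len(length)))
  chars <- matrix(unlist(strsplit(sel$cdr3_aa, "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = nrow(sel), byrow = TRUE)
  for (jx in seq_len(length)) {
    totals <- rowsum(as.numeric(sel$count), chars[, jx])
    freq[rownames(totals), jx] <- totals[, 1] / sum(sel$count)
  }
  info <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  structure(list(length = length, freq = freq, info = info,
                 heights = sweep(freq, 2, info, `*`)),
            class = "MotifMatrix")
}

#' Clonal expansion profile (donut-chart summaries)
#'
#' Summarises clonal expansion three ways: (i) summed fractions of
#' clonotypes seen with 1, 2, and 3-or-more molecules (the disjoint classes
#' \code{"1"}, \code{"2"}, \code{"3+"}; the overlapping \code{"2+"} of the
#' donut legend is also reported as \code{"2" + "3+"}); (ii) quintile sums:
#' clonotypes ranked by count, split into 5 equal-size rank blocks Q1-Q5
#' (high to low, remainder clonotypes going to the earlier blocks); (iii)
#' the five most frequent CDR3 amino-acid sequences.
#'
#' @param rep a \linkS4class{Repertoire}.
#' @return List of class \code{ExpansionProfile} with \code{class_freq}
#'   (named "1", "2", "3+"), \code{two_plus}, \code{quintiles} (Q1..Q5) and
#'   \code{top5_aa} (named fractions).
#' @export
expansionProfile <- function(rep) {
  ct <- clonotypes(rep)
  if (nrow(ct) == 0L) stop("expansion profile of an empty repertoire")
  class_freq <- c(
    "1" = sum(ct$fraction[ct$count == 1L]),
    "2" = sum(ct$fraction[ct$count == 2L]),
    "3+" = sum(ct$fraction[ct$count >= 3L])
  )
  n <- nrow(ct)
  base <- n %/% 5L
  extra <- n %% 5L
  sizes <- rep(base, 5L) + c(rep(1L, extra), rep(0L, 5L - extra))
  block <- rep(seq_len(5L), sizes)
  quintiles <- setNames(vapply(seq_len(5L), function(q)
    sum(ct$fraction[block == q]), numeric(1)),
    paste0("Q", seq_len(5L)))
  prod <- ct[ct$productive, , drop = FALSE]
  top5 <- numeric(0)
  if (nrow(prod)) {
    byaa <- rowsum(prod$fraction, prod$cdr3_aa)
    v <- setNames(byaa[, 1], rownames(byaa))
    v <- v[orderDesc(v, names(v))]
    top5 <- head(v, 5L)
  }
  structure(list(class_freq = class_freq,
                 two_plus = unname(class_freq["2"] + class_freq["3+"]),
                 quintiles = quintiles, top5_aa = top5),
            class = "ExpansionProfile")
}

#' Cumulative fraction of the top clonotypes
#'
#' Sum of the \code{n} largest clonotype fractions (the "top-10 account for
#' more than 50 percent" style dominance statistic).
#'
#' @param rep a \linkS4class{Repertoire}.
#' @param n number of top clonotypes.
#' @return A single number in [0, 1].
#' @export
topCumulative <- function(rep, n) {
  if (n <= 0) return(0)
  sum(head(clonotypes(rep)$fraction, n))
}
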