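#' Pairwise repertoire overlap
#'
#' Clonotype sets are keyed by CDR3 nucleotide sequence; the shared
#' percentage uses the pairwise-union denominator,
#' \eqn{100 \cdot |A \cap B| / |A \cup B|}.
#'
#' @param repA,repB \linkS4class{Repertoire} objects.
#' @return List of class \code{OverlapResult} with \code{sample_ids},
#'   \code{shared_clonotypes}, \code{shared_count}, \code{union_count},
#'   \code{percent_shared} (exact) and \code{percent_shared_report} (3
#'   significant figures, the reporting convention).
#' @examples
#' # 55 shared clonotypes out of a union of 608 -> 9.05%
#' @export
repertoireOverlap <- function(repA, repB) {
  a <- clonotypes(repA)$cdr3_nt
  b <- clonotypes(repB)$cdr3_nt
  shared <- intersect(a, b)
  uni <- union(a, b)
  pct <- if (length(uni)) 100 * length(shared) / length(uni) else 0
  structure(list(
    sample_ids = c(sampleId(repA), sampleId(repB)),
    shared_clonotypes = sort(shared, method = "radix"),
    shared_count = length(shared),
    union_count = length(uni),
    percent_shared = pct,
    percent_shared_report = signif3(pct)
  ), class = "OverlapResult")
}

#' Venn-region decomposition of three or more repertoires
#'
#' For every non-empty subset of samples, counts the clonotypes present in
#' exactly that subset.  Also reports the clonotypes shared by all samples
#' and their total molecule count summed across samples (the "total clones"
#' of the all-shared region).
#'
#' @param reps list of \linkS4class{Repertoire} objects (length >= 2).
#' @return List with \code{regions} (named counts, subset labels joined by
#'   \code{"&"}), \code{all_shared} (clonotype set) and
#'   \code{all_shared_total_count}.
#' @export
multiOverlap <- function(reps) {
  stopifnot(length(reps) >= 2)
  ids <- vapply(reps, sampleId, character(1))
  stopifnot(!anyDuplicated(ids))
  sets <- lapply(reps, function(r) clonotypes(r)$cdr3_nt)
  uni <- sort(unique(unlist(sets)), method = "radix")
  member <- vapply(sets, function(s) uni %in% s, logical(length(uni)))
  member <- matrix(member, nrow = length(uni))
  label <- apply(member, 1, function(m) paste(ids[m], collapse = "&"))
  n <- length(ids)
  subsets <- unlist(lapply(seq_len(n), function(k)
    combn(seq_len(n), k, function(ix) paste(ids[ix], collapse = "&"),
          simplify = FALSE)), recursive = FALSE)
  regions <- setNames(integer(length(subsets)), unlist(subsets))
  tab <- table(label)
  regions[names(tab)] <- as.integer(tab)
  all_shared <- uni[rowSums(member) == n]
  total <- sum(vapply(reps, function(r) {
    ct <- clonotypes(r)
    sum(ct$count[ct$cdr3_nt %in% all_shared])
  }, numeric(1)))
  list(regions = regions, all_shared = all_shared,
       all_shared_total_count = total)
}

#' Baroni-Urbani & Buser similarity
#'
#' Presence/absence similarity that credits shared absences within a defined
#' clonotype universe: with \eqn{a} shared presences, \eqn{b}/\eqn{c}
#' clonotypes exclusive to each sample and \eqn{d} universe members absent
#' from both, \deqn{BUB = (\sqrt{ad} + a) / (\sqrt{ad} + a + b + c).}
#' Abundances are ignored.  The universe defaults to the pair's union (all
#' \eqn{d = 0}); supply the union over the full analysis set to credit
#' shared absences, as \code{\link{similarityMatrix}} does.
#'
#' @param repA,repB \linkS4class{Repertoire} objects.
#' @param universe character vector of CDR3 nucleotide sequences; must
#'   contain every clonotype of both samples.
#' @return BUB similarity in [0, 1].
#' @export
bubSimilarity <- function(repA, repB,
                          universe = union(clonotypes(repA)$cdr3_nt,
                                           clonotypes(repB)$cdr3_nt)) {
  sa <- clonotypes(repA)$cdr3_nt
  sb <- clonotypes(repB)$cdr3_nt
  if (!all(sa %in% universe) || !all(sb %in% universe))
    stop("universe must contain every clonotype of both repertoires")
  a <- length(intersect(sa, sb))
  b <- length(setdiff(sa, sb))
  cc <- length(setdiff(sb, sa))
  d <- length(universe) - a - b - cc
  num <- sqrt(a * d) + a
  den <- num + b + cc
  if (den == 0) return(0)
  num / den
}

#' BUB similarity matrix over an analysis set
#'
#' Symmetric matrix of pairwise Baroni-Urbani & Buser similarities with the
#' clonotype universe fixed to the union across all input repertoires, so
#' "shared absence" is defined consistently for every pair; the diagonal
#' is 1.
#'
#' @param reps list of \linkS4class{Repertoire} objects.
#' @return Numeric matrix with sample ids as dimnames.
#' @export
similarityMatrix <- function(reps) {
  ids <- vapply(reps, sampleId, character(1))
  universe <- unique(unlist(lapply(reps, function(r) clonotypes(r)$cdr3_nt)))
  n <- length(reps)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (jx in seq(i + 1, n)) {
      m[i, jx] <- m[jx, i] <- bubSimilarity(reps[[i]], reps[[jx]], universe)
    }
  }
  m
}

#' Track top clonotypes across samples
#'
#' Selects the top \code{n} clonotypes of a focal repertoire by fraction
#' (ties broken by CDR3 sequence) and looks their fractions up in the other
#' samples by CDR3 nucleotide sequence.  Absence is reported as \code{NA},
#' explicitly distinguished from a small non-zero fraction.
#'
#' @param focal the focal \linkS4class{Repertoire}.
#' @param others list of other \linkS4class{Repertoire} objects.
#' @param n number of top clonotypes to track (default 50).
#' @return List of class \code{TrackingMatrix} with \code{cdr3_nt},
#'   \code{cdr3_aa} and \code{fractions}, a clonotype x sample matrix whose
#'   first column is the focal sample.
#' @export
trackClones <- function(focal, others, n = 50L) {
  ct <- clonotypes(focal)
  top <- head(ct[orderDesc(ct$fraction, ct$cdr3_nt), , drop = FALSE], n)
  samples <- c(list(focal), others)
  ids <- vapply(samples, sampleId, character(1))
  fr <- vapply(samples, function(r) {
    oc <- clonotypes(r)
    oc$fraction[match(top$cdr3_nt, oc$cdr3_nt)]
  }, numeric(nrow(top)))
  fr <- matrix(fr, nrow = nrow(top), dimnames = list(top$cdr3_nt, ids))
  structure(list(cdr3_nt = top$cdr3_nt, cdr3_aa = top$cdr3_aa,
                 fractions = fr),
            class = "TrackingMatrix")
}

#' Newly emerging clonotypes
#'
#' Clonotypes detected in the treated repertoire (fraction > 0) and absent
#' from the matched untreated repertoire, keyed by CDR3 nucleotide sequence.
#'
#' @param treated,untreated \linkS4class{Repertoire} objects.
#' @return List with \code{clonotypes} (sorted CDR3 set) and \code{count}.
#' @export
emergingClones <- function(treated, untreated) {
  em <- setdiff(clonotypes(treated)$cdr3_nt, clonotypes(untreated)$cdr3_nt)
  list(clonotypes = sort(em, method = "radix"), count = length(em))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' \eqn{D = \sup_x |\hat F_a(x) - \hat F_b(x)|} between the empirical CDFs,
#' with the p-value from the asymptotic Kolmogorov distribution evaluated at
#' \eqn{\sqrt{n_e} D}, \eqn{n_e = n_a n_b / (n_a + n_b)}.  Intended inputs
#' are the per-clonotype fractions (or cumulative counts) of the dominant
#' clonotypes of two groups.
#'
#' @param valuesA,valuesB non-empty numeric vectors.
#' @return List with \code{statistic} (D), \code{p_value} and \code{n_eff}.
#' @export
ksCompare <- function(valuesA, valuesB) {
  stopifnot(length(valuesA) > 0, length(valuesB) > 0,
            is.numeric(valuesA), is.numeric(valuesB))
  pts <- sort(unique(c(valuesA, valuesB)))
  fa <- vapply(pts, function(x) mean(valuesA <= x), numeric(1))
  fb <- vapply(pts, function(x) mean(valuesB <= x), numeric(1))
  d <- max(abs(fa - fb))
  ne <- length(valuesA) * length(valuesB) /
    (length(valuesA) + length(valuesB))
  lambda <- sqrt(ne) * d
  p <- if (lambda == 0) 1 else {
    k <- seq_len(100)
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  list(statistic = d, p_value = p, n_eff = ne)
}
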