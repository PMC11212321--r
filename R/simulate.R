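#' Simulation configuration for synthetic TRB repertoires
#'
#' Collects every knob of the synthetic-data generator: clone number, clonal
#' abundance model, emerging-clone parameters, sequencing depth, UMI length
#' and the per-base substitution error rate.  All randomness downstream flows
#' from \code{seed}; no global RNG state is consumed.
#'
#' @param nClones number of true clones.
#' @param abundanceModel \code{"power_law"} (rank weight \eqn{i^{-\alpha}})
#'   or \code{"geometric"} (rank weight \eqn{q^i}).
#' @param abundanceParam the exponent \eqn{\alpha > 0} (power_law) or ratio
#'   \eqn{q \in (0,1)} (geometric).
#' @param nEmerging number of clones flagged as newly emerging (treatment
#'   induced); must not exceed \code{nClones}.
#' @param emergingBoost multiplicative factor (\eqn{\ge 1}) applied to the
#'   base weight of emerging clones, modelling preferential expansion.
#' @param readsPerMolecule reads sequenced per cDNA molecule.
#' @param moleculesPerCloneScale total molecules =
#'   \code{nClones * moleculesPerCloneScale}, split multinomially.
#' @param umiLength UMI length in bases.
#' @param subErrorRate per-base substitution probability in [0, 1).
#' @param unproductiveFraction probability that a simulated rearrangement is
#'   frame-shifted (junction length not divisible by 3).
#' @param cdr3LengthMean,cdr3LengthSd target CDR3 nucleotide length
#'   distribution (before frame adjustment), matching the unimodal 35-45 bp
#'   range typical of TRB junctions.
#' @param seed integer seed.
#' @return A list of class \code{SimulationConfig}.
#' @seealso \code{\link{presetConfig}} for the study presets.
#' @export
simulationConfig <- function(nClones = 100L,
                             abundanceModel = c("power_law", "geometric"),
                             abundanceParam = 1.1,
                             nEmerging = 0L,
                             emergingBoost = 1,
                             readsPerMolecule = 3L,
                             moleculesPerCloneScale = 20L,
                             umiLength = 12L,
                             subErrorRate = 0.002,
                             unproductiveFraction = 0.08,
                             cdr3LengthMean = 42,
                             cdr3LengthSd = 2.5,
                             seed = 1L) {
  abundanceModel <- match.arg(abundanceModel)
  stopifnot(nClones >= 1, nEmerging >= 0, nEmerging <= nClones,
            emergingBoost >= 1, readsPerMolecule >= 1,
            moleculesPerCloneScale >= 1, umiLength >= 1,
            subErrorRate >= 0, subErrorRate < 1,
            unproductiveFraction >= 0, unproductiveFraction < 1)
  if (abundanceModel == "geometric")
    stopifnot(abundanceParam > 0, abundanceParam < 1)
  else
    stopifnot(abundanceParam > 0)
  structure(list(
    nClones = as.integer(nClones), abundanceModel = abundanceModel,
    abundanceParam = abundanceParam, nEmerging = as.integer(nEmerging),
    emergingBoost = emergingBoost, readsPerMolecule = as.integer(readsPerMolecule),
    moleculesPerCloneScale = as.integer(moleculesPerCloneScale),
    umiLength = as.integer(umiLength), subErrorRate = subErrorRate,
    unproductiveFraction = unproductiveFraction,
    cdr3LengthMean = cdr3LengthMean, cdr3LengthSd = cdr3LengthSd,
    seed = as.integer(seed)
  ), class = "SimulationConfig")
}

#' Study presets for untreated and treated repertoires
#'
#' \code{"untreated"} emulates a polyclonal baseline repertoire (400 clones,
#' power-law exponent 1.1, no emerging clones, ~8400 molecules);
#' \code{"treated"} emulates the post-stimulation state: fewer clones (150),
#' steeper decay (exponent 1.6), ~1650 molecules and 50 newly emerging
#' clones whose base weights are boosted 20-fold, so they dominate the
#' repertoire.  Both are deterministic in \code{donorSeed}.
#'
#' @param name \code{"untreated"} or \code{"treated"}.
#' @param donorSeed integer donor seed.
#' @param ... overrides passed on to \code{\link{simulationConfig}}.
#' @return A \code{SimulationConfig}.
#' @export
presetConfig <- function(name = c("untreated", "treated"), donorSeed = 1L, ...) {
  name <- match.arg(name)
  defaults <- if (name == "untreated") {
    list(nClones = 400L, abundanceModel = "power_law", abundanceParam = 1.1,
         nEmerging = 0L, emergingBoost = 1, moleculesPerCloneScale = 21L)
  } else {
    list(nClones = 150L, abundanceModel = "power_law", abundanceParam = 1.6,
         nEmerging = 50L, emergingBoost = 20, moleculesPerCloneScale = 11L)
  }
  args <- utils::modifyList(
    c(defaults, list(seed = childSeed(donorSeed, name))),
    list(...))
  do.call(simulationConfig, args)
}

#' Simulate one V(D)J rearrangement junction
#'
#' Builds a CDR3 nucleotide junction as the V segment's suffix from its
#' anchor codon, \code{nInsert} uniformly random bases, and the J segment's
#' prefix through its anchor codon.  D segments are not modelled separately;
#' junction variability is carried by the random inserts.  Uses the current
#' RNG state: wrap in a seeded context for determinism.
#'
#' @param v,j reference segment records from \code{\link{referenceSegment}}.
#' @param nInsert number of untemplated bases (\eqn{\ge 0}).
#' @return The CDR3 nucleotide string (both anchor codons included).
#' @export
simulateRearrangement <- function(v, j, nInsert) {
  stopifnot(v$kind == "V", j$kind == "J", nInsert >= 0)
  vs <- substr(v$sequence, v$anchor + 1L, nchar(v$sequence))
  jp <- substr(j$sequence, 1L, j$anchor + 3L)
  ins <- if (nInsert > 0) randomDna(nInsert) else ""
  paste0(vs, ins, jp)
}

# draw one junction aiming at the configured CDR3 length; frame-adjusted to
# productive (length % 3 == 0) or frame-shifted according to `frameShift`
.drawJunction <- function(v, j, cfg, frameShift) {
  vs_len <- nchar(v$sequence) - v$anchor
  jp_len <- j$anchor + 3L
  target <- max(vs_len + jp_len,
                round(rnorm(1, cfg$cdr3LengthMean, cfg$cdr3LengthSd)))
  ni <- max(0L, as.integer(target) - vs_len - jp_len)
  tot <- vs_len + ni + jp_len
  rem <- tot %% 3L
  if (!frameShift) {
    ni <- if (rem == 0L) ni
          else if (rem <= 1L && ni >= rem) ni - rem  # prefer the smaller shift
          else ni + (3L - rem)
  } else if (rem == 0L) {
    ni <- ni + 1L
  }
  list(cdr3 = simulateRearrangement(v, j, ni), n_insert = ni)
}

#' Simulate a ground-truth repertoire
#'
#' Draws clone abundances from the configured rank-abundance model (clone
#' \eqn{i} gets base weight \eqn{q^i} or \eqn{i^{-\alpha}}; emerging clones
#' get their weight multiplied by \code{emergingBoost}), assigns each clone a
#' simulated rearrangement, and splits
#' \code{nClones * moleculesPerCloneScale} molecules multinomially across
#' clones.  A fraction \code{unproductiveFraction} of rearrangements is
#' frame-shifted; emerging clones are always productive.
#'
#' When \code{baseline} (the matched untreated ground truth of the same
#' donor) is supplied, non-emerging clones are drawn without replacement from
#' the baseline's observed productive clonotypes, so that the only clones
#' absent from the baseline are the flagged emerging ones — the paired
#' treated/untreated design under which emerging-clone detection is exact.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param reference a \linkS4class{GermlineReference}.
#' @param baseline optional ground truth of the matched untreated sample.
#' @param sampleId,donorId,group metadata for the resulting repertoire.
#' @return A list of class \code{GroundTruth} with elements
#'   \code{repertoire} (a \linkS4class{Repertoire} of the clones that
#'   received at least one molecule) and \code{provenance} (a data.frame over
#'   all \code{nClones} true clones: junction, calls, insert count, emerging
#'   flag, productivity, expected fraction (\code{weight}), molecule count
#'   and the full-length read sequence).
#' @export
simulateRepertoire <- function(cfg, reference, baseline = NULL,
                               sampleId = "sim", donorId = "donor",
                               group = "unspecified") {
  v_names <- names(reference)[segmentKind(reference) == "V"]
  j_names <- names(reference)[segmentKind(reference) == "J"]
  stopifnot(length(v_names) >= 1, length(j_names) >= 1)
  withSeed(cfg$seed, {
    n <- cfg$nClones
    ranks <- seq_len(n)
    w <- switch(cfg$abundanceModel,
                geometric = cfg$abundanceParam^ranks,
                power_law = ranks^(-cfg$abundanceParam))
    emerging <- rep(FALSE, n)
    if (cfg$nEmerging > 0) {
      emerging[sample.int(n, cfg$nEmerging)] <- TRUE
      w[emerging] <- w[emerging] * cfg$emergingBoost
    }

    seen <- new.env(parent = emptyenv())
    baseline_junctions <- character(0)
    prov <- data.frame(cdr3_nt = character(n), cdr3_aa = character(n),
                       v_call = character(n), j_call = character(n),
                       n_insert = integer(n), emerging = emerging,
                       productive = logical(n), count = integer(n),
                       full_seq = character(n))

    if (!is.null(baseline)) {
      cand <- baseline$provenance
      cand <- cand[cand$count > 0 & cand$productive, , drop = FALSE]
      baseline_junctions <- baseline$provenance$cdr3_nt
      n_non <- n - cfg$nEmerging
      if (nrow(cand) < n_non)
        stop("simulation error: baseline has only ", nrow(cand),
             " observed productive clones; ", n_non, " needed")
      pick <- cand[sample.int(nrow(cand), n_non), , drop = FALSE]
      idx_non <- which(!emerging)
      for (col in c("cdr3_nt", "cdr3_aa", "v_call", "j_call", "n_insert",
                    "productive", "full_seq"))
        prov[[col]][idx_non] <- pick[[col]]
      for (key in pick$cdr3_nt) assign(key, TRUE, envir = seen)
    }

    todo <- if (is.null(baseline)) seq_len(n) else which(emerging)
    for (i in todo) {
      ok <- FALSE
      shift <- !emerging[i] && runif(1) < cfg$unproductiveFraction
      for (attempt in seq_len(1000L)) {
        v <- referenceSegment(reference, sample(v_names, 1))
        j <- referenceSegment(reference, sample(j_names, 1))
        dr <- .drawJunction(v, j, cfg, frameShift = shift)
        tr <- translateJunction(dr$cdr3)
        # selected clonotypes carry no stop codons: unproductiveFraction is
        # the sole unproductive channel
        if (!shift && !tr$productive) next
        if (exists(dr$cdr3, envir = seen, inherits = FALSE)) next
        if (emerging[i] && dr$cdr3 %in% baseline_junctions) next
        assign(dr$cdr3, TRUE, envir = seen)
        prov$cdr3_nt[i] <- dr$cdr3
        prov$cdr3_aa[i] <- tr$cdr3_aa
        prov$v_call[i] <- v$name
        prov$j_call[i] <- j$name
        prov$n_insert[i] <- dr$n_insert
        prov$productive[i] <- tr$productive
        ins <- substr(dr$cdr3, nchar(v$sequence) - v$anchor + 1L,
                      nchar(dr$cdr3) - j$anchor - 3L)
        prov$full_seq[i] <- paste0(v$sequence, ins, j$sequence)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("simulation error: could not draw a distinct rearrangement for ",
             "clone ", i, " within 1000 attempts")
    }

    prov$weight <- w / sum(w)  # expected fraction of each clone
    prov$count <- as.integer(
      rmultinom(1, n * cfg$moleculesPerCloneScale, w)[, 1])
    obs <- prov[prov$count > 0,
                c("cdr3_nt", "cdr3_aa", "v_call", "j_call", "count",
                  "productive"), drop = FALSE]
    rep <- Repertoire(obs, sampleId = sampleId, donorId = donorId,
                      group = group)
    structure(list(repertoire = rep, provenance = prov, config = cfg),
              class = "GroundTruth")
  })
}

#' Simulate UMI-tagged sequencing reads from a ground truth
#'
#' Each true molecule receives a distinct random UMI of the configured
#' length and emits \code{readsPerMolecule} reads of the full rearrangement
#' (entire V segment + junction inserts + entire J segment).  Each read base
#' is substituted by a uniformly chosen different base with probability
#' \code{subErrorRate}; UMI bases are written error-free.
#'
#' @param gt a \code{GroundTruth} from \code{\link{simulateRepertoire}}.
#' @param cfg the same \code{\link{simulationConfig}} (depth/error fields are
#'   read from it).
#' @return data.frame of reads (\code{read_id}, \code{umi}, \code{sequence},
#'   \code{quality}), suitable for \code{\link{writeUmiFastq}}.
#' @export
simulateReads <- function(gt, cfg) {
  prov <- gt$provenance[gt$provenance$count > 0, , drop = FALSE]
  withSeed(cfg$seed + 1L, {
    n_mol <- sum(prov$count)
    umi_mat <- matrix(sample(DNA_BASES4, n_mol * cfg$umiLength,
                             replace = TRUE), nrow = n_mol)
    umis <- do.call(paste0, as.data.frame(umi_mat))
    while (anyDuplicated(umis)) {  # per-molecule UMIs are distinct
      dup <- which(duplicated(umis))
      umis[dup] <- vapply(dup, function(i) randomDna(cfg$umiLength),
                          character(1))
    }
    mol_seq <- rep(prov$full_seq, prov$count)
    rpm <- cfg$readsPerMolecule
    seqs <- rep(mol_seq, each = rpm)
    umi_out <- rep(umis, each = rpm)
    if (cfg$subErrorRate > 0) {
      lens <- nchar(seqs)
      nerr <- rbinom(length(seqs), lens, cfg$subErrorRate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(lens[i], nerr[i])
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        for (p in pos)
          ch[p] <- sample(setdiff(DNA_BASES4, ch[p]), 1)
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    data.frame(
      read_id = sprintf("r%07d", seq_along(seqs)),
      umi = umi_out,
      sequence = seqs,
      quality = strrep("I", nchar(seqs))
    )
  })
}
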