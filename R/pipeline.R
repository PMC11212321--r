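#' @importFrom jsonlite write_json read_json
#' @importFrom tools md5sum
#' @importFrom utils combn modifyList
NULL

#' Pipeline run configuration
#'
#' Describes one reproducible end-to-end run: which samples to simulate
#' (donor, group and preset overrides per group), which treated/untreated
#' pairs to compare, the assembly thresholds and the single master seed.
#' The master seed is fanned out to per-sample child seeds through a stable
#' hash of the sample id, so adding a sample never perturbs the others.
#'
#' @param seed master integer seed.
#' @param samples data.frame with columns \code{sample_id}, \code{donor_id},
#'   \code{group} (\code{"treated"}/\code{"untreated"}).
#' @param outDir output directory.
#' @param comparisons list of \code{c(treated_id, untreated_id)} pairs;
#'   defaults to every donor that has both groups.
#' @param assembly an \code{\link{assemblyConfig}}.
#' @param presetOverrides named list (\code{untreated}/\code{treated}) of
#'   \code{\link{simulationConfig}} overrides applied to each group preset.
#' @param trackTop number of clonotypes for clone tracking and the KS
#'   comparison of dominant clonotypes.
#' @return List of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed, samples, outDir,
                           comparisons = NULL,
                           assembly = assemblyConfig(),
                           presetOverrides = list(),
                           trackTop = 20L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "donor_id", "group") %in% names(samples)),
            all(samples$group %in% c("treated", "untreated")))
  if (anyDuplicated(samples$sample_id))
    stop("sample_ids must be unique")
  if (is.null(comparisons)) {
    comparisons <- list()
    for (d in unique(samples$donor_id)) {
      tr <- samples$sample_id[samples$donor_id == d &
                                samples$group == "treated"]
      un <- samples$sample_id[samples$donor_id == d &
                                samples$group == "untreated"]
      if (length(tr) == 1 && length(un) == 1)
        comparisons[[length(comparisons) + 1L]] <- c(tr, un)
    }
  }
  for (cmp in comparisons) {
    missing <- setdiff(cmp, samples$sample_id)
    if (length(missing))
      stop("comparison references undeclared sample(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), samples = samples,
                 outDir = outDir, comparisons = comparisons,
                 assembly = assembly, presetOverrides = presetOverrides,
                 trackTop = as.integer(trackTop)),
            class = "PipelineConfig")
}

#' Demonstration configuration
#'
#' Two donors, each with an untreated and a treated sample, at reduced
#' problem size (60/30 clones, ~480 molecules per sample) so the whole
#' pipeline runs in seconds while exercising every stage.
#'
#' @param outDir output directory.
#' @param seed master seed.
#' @return A \code{PipelineConfig}.
#' @export
demoPipelineConfig <- function(outDir, seed = 42L) {
  samples <- data.frame(
    sample_id = c("d1_untreated", "d1_treated", "d2_untreated", "d2_treated"),
    donor_id = c("d1", "d1", "d2", "d2"),
    group = c("untreated", "treated", "untreated", "treated")
  )
  pipelineConfig(
    seed = seed, samples = samples, outDir = outDir,
    presetOverrides = list(
      untreated = list(nClones = 60L, moleculesPerCloneScale = 8L),
      treated = list(nClones = 30L, nEmerging = 8L,
                     moleculesPerCloneScale = 8L)
    )
  )
}

.writeJson <- function(x, path) {
  write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
             na = "null")
  path
}

.sampleStats <- function(rep, trackTop) {
  div <- clonalDiversity(rep)
  exp <- expansionProfile(rep)
  usage_v <- segmentUsage(rep, "V")
  top5 <- topSegments(usage_v, 5L)
  list(
    sample_id = sampleId(rep), donor_id = donorId(rep),
    group = sampleGroup(rep),
    diversity = div,
    top10_cumulative = topCumulative(rep, 10L),
    topN_cumulative = topCumulative(rep, trackTop),
    expansion = list(class_freq = as.list(exp$class_freq),
                     two_plus = exp$two_plus,
                     quintiles = as.list(exp$quintiles),
                     top5_aa = as.list(exp$top5_aa)),
    v_usage_top5 = list(segments = top5$segments,
                        combined = signif3(100 * top5$combined)),
    nt_length_mode = lengthDistribution(rep, "nt")$mode,
    aa_length_mode = lengthDistribution(rep, "aa")$mode
  )
}

#' Run the simulate-assemble-analyse pipeline
#'
#' For every configured sample: simulate a ground-truth repertoire from its
#' group preset (treated samples are paired to their donor's untreated
#' ground truth so emerging clones are well defined), simulate UMI-tagged
#' reads, write the FASTQ, run the assembler, and write the AIRR clonotype
#' table, the ground-truth table, a QC JSON and a stats JSON.  For every
#' treated/untreated comparison: overlap, BUB similarity (universe = union
#' over all samples), emerging clones, top-clonotype tracking (TSV, absent
#' entries as NA) and the KS comparison of dominant-clonotype fractions.
#' Finishes with a manifest of seeds and file checksums; identical
#' config + seed reproduce bit-identical outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param reference a \linkS4class{GermlineReference} (default: bundled).
#' @return Invisibly, the report bundle: repertoires, ground truths, stats,
#'   comparison results and the manifest.
#' @export
runPipeline <- function(config, reference = loadReference()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  samples <- config$samples
  # untreated first within each donor: treated simulations need the baseline
  samples <- samples[order(samples$donor_id,
                           samples$group != "untreated",
                           method = "radix"), , drop = FALSE]
  truths <- list()
  reps <- list()
  stats <- list()
  seeds <- list()
  files <- character(0)

  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    donor <- samples$donor_id[i]
    grp <- samples$group[i]
    seed_i <- childSeed(config$seed, sid)
    seeds[[sid]] <- seed_i
    overrides <- config$presetOverrides[[grp]]
    cfg <- do.call(presetConfig,
                   c(list(name = grp, donorSeed = seed_i),
                     if (is.null(overrides)) list() else overrides))
    baseline <- if (grp == "treated") truths[[paste0(donor, ".untreated")]]
    if (grp == "treated" && is.null(baseline))
      stop("pipeline stage 'simulate' failed for ", sid,
           ": no untreated baseline for donor ", donor)
    gt <- simulateRepertoire(cfg, reference, baseline = baseline,
                             sampleId = sid, donorId = donor, group = grp)
    if (grp == "untreated") truths[[paste0(donor, ".untreated")]] <- gt
    reads <- simulateReads(gt, cfg)
    fq <- file.path(config$outDir, paste0(sid, ".fastq"))
    writeUmiFastq(reads, fq)
    truth_tsv <- file.path(config$outDir, paste0(sid, "_truth.tsv"))
    writeAirr(gt$repertoire, truth_tsv)
    prov_json <- file.path(config$outDir, paste0(sid, "_provenance.json"))
    .writeJson(list(sample_id = sid, seed = seed_i,
                    emerging = gt$provenance$cdr3_nt[gt$provenance$emerging]),
               prov_json)

    asm_cfg <- config$assembly
    asm_cfg$umiLength <- cfg$umiLength
    asm <- runAssembly(fq, reference, asm_cfg,
                       sampleId = sid, donorId = donor, group = grp)
    airr_tsv <- file.path(config$outDir, paste0(sid, ".tsv"))
    writeAirr(asm$repertoire, airr_tsv)
    qc_json <- file.path(config$outDir, paste0(sid, "_qc.json"))
    .writeJson(asm$qc, qc_json)
    st <- .sampleStats(asm$repertoire, config$trackTop)
    stats_json <- file.path(config$outDir, paste0(sid, "_stats.json"))
    .writeJson(st, stats_json)

    truths[[sid]] <- gt
    reps[[sid]] <- asm$repertoire
    stats[[sid]] <- st
    files <- c(files, fq, truth_tsv, prov_json, airr_tsv, qc_json, stats_json)
  }

  bub <- similarityMatrix(reps[samples$sample_id])
  comparisons <- list()
  for (cmp in config$comparisons) {
    tr <- reps[[cmp[1]]]
    un <- reps[[cmp[2]]]
    ov <- repertoireOverlap(tr, un)
    em <- emergingClones(tr, un)
    ntop <- config$trackTop
    ks <- ksCompare(head(clonotypes(tr)$fraction, ntop),
                    head(clonotypes(un)$fraction, ntop))
    track <- trackClones(tr, list(un), n = ntop)
    key <- paste(cmp[1], cmp[2], sep = "_vs_")
    track_tsv <- file.path(config$outDir, paste0(key, "_tracking.tsv"))
    track_df <- data.frame(cdr3_nt = track$cdr3_nt, cdr3_aa = track$cdr3_aa,
                           track$fractions, check.names = FALSE)
    write.table(track_df, track_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    res <- list(treated = cmp[1], untreated = cmp[2],
                shared_count = ov$shared_count,
                union_count = ov$union_count,
                percent_shared = ov$percent_shared_report,
                bub = bub[cmp[1], cmp[2]],
                emerging_count = em$count,
                ks_d = ks$statistic, ks_p = ks$p_value)
    cmp_json <- file.path(config$outDir, paste0(key, "_compare.json"))
    .writeJson(res, cmp_json)
    comparisons[[key]] <- c(res, list(emerging = em$clonotypes))
    files <- c(files, track_tsv, cmp_json)
  }

  heat_tsv <- file.path(config$outDir, "bub_heatmap.tsv")
  write.table(data.frame(sample_id = rownames(bub), bub,
                         check.names = FALSE),
              heat_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, heat_tsv)

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ClonoTRB")),
    sample_seeds = seeds,
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(md5sum(f)))
  )
  manifest_json <- file.path(config$outDir, "manifest.json")
  .writeJson(manifest, manifest_json)

  invisible(list(config = config, repertoires = reps, truths = truths,
                 stats = stats, similarity = bub,
                 comparisons = comparisons, manifest = manifest,
                 dir = config$outDir))
}

#' Summarise a pipeline report bundle
#'
#' One row per sample (molecule count, unique CDR3, inverse Simpson,
#' Berger-Parker, top-10 cumulative fraction) and one per comparison
#' (shared percent, BUB, emerging-clone count).
#'
#' @param bundle the value of \code{\link{runPipeline}}, or the path of a
#'   pipeline output directory (the JSON reports are then re-read).
#' @return data.frame with a \code{type} column (\code{"sample"} or
#'   \code{"comparison"}).
#' @export
summarizeBundle <- function(bundle) {
  if (is.character(bundle)) bundle <- .readBundle(bundle)
  srows <- lapply(bundle$stats, function(st) data.frame(
    type = "sample", id = st$sample_id, group = st$group,
    total_count = st$diversity$total_count,
    unique_cdr3 = st$diversity$unique_cdr3,
    inv_simpson = st$diversity$inv_simpson,
    berger_parker = st$diversity$berger_parker,
    top10_cumulative = st$top10_cumulative,
    percent_shared = NA_real_, bub = NA_real_, emerging = NA_integer_))
  crows <- lapply(bundle$comparisons, function(cm) data.frame(
    type = "comparison", id = paste(cm$treated, "vs", cm$untreated),
    group = NA_character_, total_count = NA_integer_,
    unique_cdr3 = NA_integer_, inv_simpson = NA_real_,
    berger_parker = NA_real_, top10_cumulative = NA_real_,
    percent_shared = cm$percent_shared, bub = cm$bub,
    emerging = cm$emerging_count))
  out <- do.call(rbind, c(srows, crows))
  if (is.null(out))
    warning("empty bundle: nothing to summarise")
  rownames(out) <- NULL
  out
}

.readBundle <- function(dir) {
  readJson <- function(f) {
    tryCatch(read_json(f, simplifyVector = TRUE),
             error = function(e) stop("malformed report JSON '", f, "': ",
                                      conditionMessage(e)))
  }
  stat_files <- list.files(dir, pattern = "_stats\\.json$",
                           full.names = TRUE)
  cmp_files <- list.files(dir, pattern = "_compare\\.json$",
                          full.names = TRUE)
  list(stats = lapply(stat_files, readJson),
       comparisons = lapply(cmp_files, readJson))
}
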