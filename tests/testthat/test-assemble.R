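readsWithUmis <- function(umis, seq = "ACGTACGT") {
  data.frame(read_id = sprintf("r%03d", seq_along(umis)), umi = umis,
             sequence = rep(seq, length.out = length(umis)),
             quality = rep(strrep("I", nchar(seq)),
                           length.out = length(umis)))
}

test_that("directional UMI grouping merges small near-neighbour groups", {
  fams <- groupByUmi(readsWithUmis(c(rep("AAAA", 5), "AAAT")),
                     maxHamming = 1L, ratio = 2)
  expect_length(fams, 1L)
  expect_equal(fams[[1]]$umi, "AAAA")
  expect_equal(fams[[1]]$size, 6L)

  fams2 <- groupByUmi(readsWithUmis(c(rep("AAAA", 3), rep("TTTT", 3))))
  expect_length(fams2, 2L)

  # exact grouping only at maxHamming = 0
  fams3 <- groupByUmi(readsWithUmis(c(rep("AAAA", 5), "AAAT")),
                      maxHamming = 0L)
  expect_length(fams3, 2L)

  # the count-ratio guard blocks merging between similar-sized groups
  fams4 <- groupByUmi(readsWithUmis(c(rep("AAAA", 3), rep("AAAT", 2))),
                      maxHamming = 1L, ratio = 2)
  expect_length(fams4, 2L)
  expect_length(groupByUmi(readsWithUmis(character(0))), 0L)
})

test_that("UMI grouping is invariant to read order and supports wider radii", {
  umis <- c(rep("AAAA", 6), rep("AATA", 2), "AATT")
  reads <- readsWithUmis(umis)
  shuffled <- reads[ClonoTRB:::withSeed(1, sample(nrow(reads))), ]
  f1 <- groupByUmi(reads)
  f2 <- groupByUmi(shuffled)
  expect_equal(vapply(f1, `[[`, character(1), "umi"),
               vapply(f2, `[[`, character(1), "umi"))
  expect_equal(vapply(f1, `[[`, integer(1), "size"),
               vapply(f2, `[[`, integer(1), "size"))

  # Hamming radius 2 folds AATT (distance 2 from AAAA) in as well
  f3 <- groupByUmi(reads, maxHamming = 2L)
  expect_length(f3, 1L)
  expect_equal(f3[[1]]$size, 9L)
})

test_that("family consensus takes the per-position plurality with A<C<G<T ties", {
  expect_equal(umiConsensus(c("ACGT", "ACGT", "ACGA")), "ACGT")
  expect_equal(umiConsensus("ACGT"), "ACGT")
  expect_equal(umiConsensus(c("ACGT", "ACGA")), "ACGA")  # tie at 4: A < T
  # off-modal-length reads are excluded before voting
  expect_equal(umiConsensus(c("ACGT", "ACGT", "ACG")), "ACGT")
  expect_error(umiConsensus(character(0)), "empty")
})

test_that("local alignment scores and anchor projection behave as specified", {
  ref <- refFixture()
  seg <- referenceSegment(ref, "TRBV9*01")
  L <- nchar(seg$sequence)

  hit <- alignSegment(seg$sequence, seg)
  expect_equal(hit$score, 2 * L)
  expect_equal(hit$anchor_on_query, seg$anchor)
  expect_equal(c(hit$query_start, hit$query_end), c(0L, L))

  # one internal mismatch costs one match plus one mismatch: 2L - 4
  mut <- seg$sequence
  substr(mut, 30, 30) <- if (substr(mut, 30, 30) == "A") "C" else "A"
  expect_equal(alignSegment(mut, seg)$score, 2 * L - 4)

  # the projection survives a prefix shift
  hit2 <- alignSegment(paste0("TTTT", seg$sequence), seg)
  expect_equal(hit2$anchor_on_query, seg$anchor + 4L)
})

test_that("V/J assignment recovers generating segments and flags noise", {
  ref <- refFixture()
  v <- referenceSegment(ref, "TRBV12-3*01")
  j <- referenceSegment(ref, "TRBJ2-7*01")
  read <- paste0(v$sequence, "GTAGCA", j$sequence)
  asn <- assignVJ(read, ref)
  expect_true(asn$assignable)
  expect_equal(asn$v_call, "TRBV12-3*01")
  expect_equal(asn$j_call, "TRBJ2-7*01")
  expect_equal(asn$v_anchor, v$anchor)

  # identical-scoring alleles resolve to the lexicographically first name
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(sprintf(">TRBV9B*01|V|%d", v$anchor), v$sequence,
               sprintf(">TRBV9A*01|V|%d", v$anchor), v$sequence,
               sprintf(">TRBJX*01|J|%d", j$anchor), j$sequence), dup)
  ref2 <- loadReference(dup)
  expect_equal(assignVJ(read, ref2)$v_call, "TRBV9A*01")

  # random 50-mers fall below the reporting threshold
  rand <- ClonoTRB:::withSeed(99, replicate(5, ClonoTRB:::randomDna(50)))
  for (q in rand) expect_false(assignVJ(q, ref)$assignable)
})

test_that("CDR3 extraction spans anchor codon to anchor codon inclusive", {
  ref <- refFixture()
  v <- referenceSegment(ref, "TRBV9*01")
  j <- referenceSegment(ref, "TRBJ2-1*01")
  read <- paste0(v$sequence, "GTAGAA", j$sequence)
  asn <- assignVJ(read, ref)
  cdr3 <- extractCdr3(read, asn$v_anchor, asn$j_anchor)
  expect_true(startsWith(cdr3, "TGTGCC"))
  expect_true(endsWith(cdr3, "TTC"))

  # the junction printed for the dominant expanded clone decomposes as
  # TRBV9 suffix + 18 inserted bases + TRBJ2-1 prefix and is recovered exactly
  read2 <- paste0(v$sequence, "GTAGAAGGGGTTCGGGAT", j$sequence)
  asn2 <- assignVJ(read2, ref)
  expect_equal(extractCdr3(read2, asn2$v_anchor, asn2$j_anchor), PRINTED_CDR3)

  expect_true(is.na(extractCdr3(read, 50L, 10L)))   # anchors out of order
  expect_true(is.na(extractCdr3(read, NA_integer_, 10L)))
})

test_that("translation and productivity follow the frame/stop rule", {
  tr <- translateJunction(PRINTED_CDR3)
  expect_equal(tr$cdr3_aa, "CASSVEGVRDEQFF")
  expect_equal(nchar(tr$cdr3_aa), 14L)
  expect_true(tr$productive)
  expect_equal(tr$cdr3_aa, oracleTranslate(PRINTED_CDR3))

  expect_equal(translateJunction("TGTGCCAGCA"),
               data.frame(cdr3_aa = "", productive = FALSE))
  expect_equal(translateJunction("TGTTGAAGCTTC"),
               data.frame(cdr3_aa = "", productive = FALSE))
  expect_error(translateJunction("TGTNCC"), "non-ACGT")
})

test_that("productivity filtering matches a brute-force translation oracle", {
  juncs <- ClonoTRB:::withSeed(17, replicate(60, {
    ClonoTRB:::randomDna(sample(30:45, 1))
  }))
  got <- translateJunction(juncs)
  for (i in seq_along(juncs)) {
    inframe <- nchar(juncs[i]) %% 3 == 0
    oracle_ok <- inframe && !grepl("*", oracleTranslate(juncs[i]), fixed = TRUE)
    expect_equal(got$productive[i], oracle_ok)
    if (oracle_ok) expect_equal(got$cdr3_aa[i], oracleTranslate(juncs[i]))
  }
})

test_that("aggregation counts molecules per junction with plurality calls", {
  x <- junctionFor(1); y <- junctionFor(2)
  rec <- data.frame(cdr3_nt = c(x, x, y),
                    cdr3_aa = translateJunction(c(x, x, y))$cdr3_aa,
                    v_call = c("TRBV9*01", "TRBV9*01", "TRBV15*01"),
                    j_call = "TRBJ2-1*01")
  rep <- aggregateClonotypes(rec)
  ct <- clonotypes(rep)
  expect_equal(ct$count[ct$cdr3_nt == x], 2L)
  expect_equal(ct$fraction, c(2 / 3, 1 / 3))

  rec2 <- data.frame(cdr3_nt = x, cdr3_aa = "",
                     v_call = c("TRBV9*01", "TRBV9*01", "TRBV15*01"),
                     j_call = "TRBJ2-1*01")
  rep2 <- aggregateClonotypes(rec2)
  expect_equal(clonotypes(rep2)$v_call, "TRBV9*01")

  # permutation invariance
  perm <- rec[c(3, 1, 2), ]
  expect_equal(clonotypes(aggregateClonotypes(perm)), ct)

  unprod <- data.frame(cdr3_nt = "TGTTGAAGCTTC", cdr3_aa = "",
                       v_call = "TRBV9*01", j_call = "TRBJ2-1*01")
  expect_error(aggregateClonotypes(unprod), "empty repertoire")
})

test_that("the assembler tolerates sequencing errors through UMI consensus", {
  ref <- refFixture()
  cfg <- simulationConfig(nClones = 40L, moleculesPerCloneScale = 8L,
                          readsPerMolecule = 5L, subErrorRate = 0.005,
                          seed = 31L)
  gt <- simulateRepertoire(cfg, ref)
  reads <- simulateReads(gt, cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeUmiFastq(reads, fq)
  asm <- runAssembly(fq, ref, assemblyConfig(umiLength = cfg$umiLength))
  want <- clonotypes(productiveOnly(gt$repertoire))
  got <- clonotypes(asm$repertoire)
  m <- merge(want, got, by = "cdr3_nt", all = TRUE)
  agree <- mean(!is.na(m$count.x) & !is.na(m$count.y) &
                  m$count.x == m$count.y)
  expect_gte(agree, 0.99)
})

test_that("empty input fails with an empty-repertoire error", {
  ref <- refFixture()
  fq <- withr::local_tempfile(fileext = ".fastq")
  file.create(fq)
  expect_error(runAssembly(fq, ref), "empty repertoire")
})
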