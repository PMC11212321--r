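test_that("diversity indices match hand-computed values", {
  rep <- makeRep(c(5, 3, 2))  # fractions 0.5, 0.3, 0.2
  d <- clonalDiversity(rep)
  expect_equal(d$simpson, 0.38, tolerance = 1e-12)
  expect_equal(d$inv_simpson, 2.6316, tolerance = 1e-4)
  expect_equal(d$shannon, 1.0297, tolerance = 1e-4)
  expect_equal(d$berger_parker, 0.5)
  expect_equal(d$total_count, 10L)
  expect_equal(d$unique_cdr3, 3L)
})

test_that("diversity closed forms hold for uniform and single-clone cases", {
  for (K in c(2L, 7L, 50L)) {
    d <- clonalDiversity(makeRep(rep(4L, K)))
    expect_equal(d$inv_simpson, K, tolerance = 1e-9)
    expect_equal(d$shannon, log(K), tolerance = 1e-12)
  }
  d1 <- clonalDiversity(makeRep(9L))
  expect_equal(d1$inv_simpson, 1)
  expect_equal(d1$shannon, 0)
  expect_equal(d1$berger_parker, 1)
})

test_that("diversity inequalities hold on random repertoires", {
  for (s in 1:8) {
    counts <- ClonoTRB:::withSeed(s, sample(1:50, sample(2:30, 1), TRUE))
    d <- clonalDiversity(makeRep(counts))
    expect_gte(d$berger_parker, 1 / d$unique_cdr3)
    expect_lte(d$inv_simpson, d$unique_cdr3 + 1e-9)
    expect_gte(d$inv_simpson, 1)
    expect_lte(d$shannon, log(d$unique_cdr3) + 1e-12)
    expect_equal(d$inv_simpson, 1 / d$simpson)
  }
})

test_that("segment usage is weighted, normalized and sorted", {
  rep <- makeRep(c(3, 1, 1), v_call = c("TRBV9*01", "TRBV9*01", "TRBV15*01"))
  u <- segmentUsage(rep, "V")
  expect_equal(unname(u$entries), c(0.8, 0.2))
  expect_equal(names(u$entries), c("TRBV9*01", "TRBV15*01"))
  uc <- segmentUsage(rep, "V", weighting = "clonotype_weighted")
  expect_equal(unname(uc$entries), c(2 / 3, 1 / 3))
  expect_equal(sum(u$entries), 1, tolerance = 1e-9)
  single <- segmentUsage(makeRep(4L), "V")
  expect_equal(unname(single$entries), 1)
  vj <- segmentUsage(rep, "VJ")
  expect_equal(sum(vj$entries), 1, tolerance = 1e-9)
  expect_true(all(grepl("\\|", names(vj$entries))))
})

test_that("top segments sum the printed usage shares correctly", {
  top5 <- c("TRBV20-1" = 0.409, "TRBV12-3" = 0.169, "TRBV9" = 0.0550,
            "TRBV10-3" = 0.0461, "TRBV7-6" = 0.0447)
  rest <- setNames(rep((1 - sum(top5)) / 8, 8), paste0("TRBVX", 1:8))
  res <- topSegments(c(rest, top5), 5)
  expect_equal(res$segments, names(top5))
  expect_equal(ClonoTRB:::signif3(100 * res$combined), 72.4)
  expect_equal(topSegments(c(A = 0.6, B = 0.4), 1)$combined, 0.6)
  expect_equal(topSegments(c(A = 0.6, B = 0.4), 5)$combined, 1)
})

test_that("length distributions are count-weighted in nt and aa", {
  j42 <- paste0("TGTGCCAGCAGC", strrep("GCA", 6), "GAGCAGTTCTTC")  # 42 nt
  j36 <- paste0("TGTGCCAGCAGC", strrep("GCA", 4), "GAGCAGTTCTTC")  # 36 nt
  rep <- makeRep(c(3, 1), junctions = c(j42, j36))
  nt <- lengthDistribution(rep, "nt")
  expect_equal(unname(nt$histogram[c("42", "36")]), c(0.75, 0.25))
  expect_equal(nt$mode, 42L)
  aa <- lengthDistribution(rep, "aa")
  expect_equal(names(aa$histogram), c("12", "14"))
  expect_equal(aa$mode, 14L)

  unprod <- Repertoire(data.frame(cdr3_nt = "TGTGCCAGCA",
                                  v_call = "V", j_call = "J", count = 1L))
  expect_error(lengthDistribution(unprod, "nt"), "no clonotypes")
})

test_that("motif matrices carry logo frequencies and information content", {
  # 20 junctions TGT-<codon>-TTC covering every amino acid at position 2
  codons <- c(A = "GCA", C = "TGC", D = "GAC", E = "GAA", F = "TTT",
              G = "GGA", H = "CAC", I = "ATC", K = "AAA", L = "CTG",
              M = "ATG", N = "AAC", P = "CCA", Q = "CAA", R = "AGA",
              S = "AGC", T = "ACA", V = "GTA", W = "TGG", Y = "TAC")
  rep <- makeRep(rep(1L, 20), junctions = paste0("TGT", codons, "TTC"))
  m <- motifMatrix(rep, length = 3L)
  expect_equal(colSums(m$freq), c("1" = 1, "2" = 1, "3" = 1))
  expect_equal(m$freq["C", 1], 1)
  expect_equal(m$info[[1]], log2(20), tolerance = 1e-12)  # invariant column
  expect_equal(m$info[[2]], 0, tolerance = 1e-12)         # uniform column
  expect_equal(m$info[[3]], log2(20), tolerance = 1e-12)

  # a 50/50 column carries log2(20) - 1 bits
  rep2 <- makeRep(c(1L, 1L), junctions = c("TGTGCATTC", "TGTGGATTC"))
  m2 <- motifMatrix(rep2, length = 3L)
  expect_equal(m2$info[[2]], log2(20) - 1, tolerance = 1e-12)

  # column frequencies are invariant under count scaling
  m3 <- motifMatrix(makeRep(c(7L, 7L),
                            junctions = c("TGTGCATTC", "TGTGGATTC")),
                    length = 3L)
  expect_equal(m3$freq, m2$freq)

  expect_error(motifMatrix(rep2, length = 12L), "available lengths")
})

test_that("expansion profiles split read classes, quintiles and top clones", {
  prof <- expansionProfile(makeRep(c(3, 2, 1, 1)))
  expect_equal(unname(prof$class_freq),
               c(2 / 7, 2 / 7, 3 / 7))
  expect_equal(prof$two_plus, 5 / 7)
  expect_equal(sum(prof$class_freq), 1, tolerance = 1e-9)
  expect_equal(sum(prof$quintiles), 1, tolerance = 1e-9)

  eq <- expansionProfile(makeRep(rep(2L, 5)))
  expect_equal(unname(eq$quintiles), rep(0.2, 5))

  one <- expansionProfile(makeRep(6L))
  expect_equal(unname(one$quintiles), c(1, 0, 0, 0, 0))
  expect_length(one$top5_aa, 1L)
})

test_that("top-N cumulative fractions behave at the boundaries", {
  rep <- makeRep(c(5, 3, 2))
  expect_equal(topCumulative(rep, 2), 0.8)
  expect_equal(topCumulative(rep, 0), 0)
  expect_equal(topCumulative(rep, 99), 1)
})

test_that("treated presets are smaller and less even than untreated ones", {
  ref <- refFixture()
  lower_count <- 0L
  inv_u <- inv_t <- numeric(0)
  for (s in 1:6) {
    gu <- simulateRepertoire(presetConfig("untreated", s), ref)
    gtg <- simulateRepertoire(presetConfig("treated", s), ref, baseline = gu)
    if (totalCount(gtg$repertoire) < totalCount(gu$repertoire))
      lower_count <- lower_count + 1L
    inv_u <- c(inv_u, clonalDiversity(gu$repertoire)$inv_simpson)
    inv_t <- c(inv_t, clonalDiversity(gtg$repertoire)$inv_simpson)
  }
  expect_equal(lower_count, 6L)
  # the steeper treated decay concentrates the repertoire
  expect_true(all(inv_t < inv_u))
})
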