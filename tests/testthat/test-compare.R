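test_that("pairwise overlap uses the union denominator", {
  a <- makeSetRep(c(1, 2, 3), "A")
  b <- makeSetRep(c(1, 4), "B")
  ov <- repertoireOverlap(a, b)
  expect_equal(ov$shared_count, 1L)
  expect_equal(ov$union_count, 4L)
  expect_equal(ov$percent_shared_report, 25.0)

  expect_equal(repertoireOverlap(a, a)$percent_shared, 100)
  expect_equal(repertoireOverlap(a, makeSetRep(c(8, 9), "C"))$shared_count, 0L)
  ba <- repertoireOverlap(b, a)
  expect_equal(ba$shared_count, ov$shared_count)
  expect_equal(ba$union_count, ov$union_count)
})

test_that("multi-way overlap decomposes Venn regions and all-shared totals", {
  r1 <- makeSetRep(1, "A"); r2 <- makeSetRep(1, "B"); r3 <- makeSetRep(1, "C")
  m <- multiOverlap(list(r1, r2, r3))
  expect_equal(unname(m$regions["A&B&C"]), 1L)
  expect_equal(sum(m$regions), 1L)
  expect_equal(m$all_shared_total_count, 3)

  d1 <- makeSetRep(1, "A"); d2 <- makeSetRep(2, "B"); d3 <- makeSetRep(3, "C")
  md <- multiOverlap(list(d1, d2, d3))
  expect_equal(unname(md$regions[c("A", "B", "C")]), c(1L, 1L, 1L))
  expect_equal(sum(md$regions), 3L)
  expect_length(md$all_shared, 0L)

  e1 <- makeSetRep(c(1, 2), "A"); e2 <- makeSetRep(1, "B")
  e3 <- makeSetRep(2, "C")
  me <- multiOverlap(list(e1, e2, e3))
  expect_equal(unname(me$regions[c("A&B", "A&C")]), c(1L, 1L))
  expect_equal(unname(me$regions["A&B&C"]), 0L)

  # all-shared molecule totals sum counts across samples
  s1 <- makeSetRep(c(1, 2), "A", counts = c(10L, 1L))
  s2 <- makeSetRep(1, "B", counts = 5L)
  s3 <- makeSetRep(c(1, 3), "C", counts = c(2L, 1L))
  expect_equal(multiOverlap(list(s1, s2, s3))$all_shared_total_count, 17)
})

test_that("BUB similarity follows the shared-absence formula", {
  universe <- vapply(1:4, junctionFor, character(1))  # {W, X, Y, Z}
  a <- makeSetRep(c(1, 2), "A")
  b <- makeSetRep(c(1, 3), "B")
  expect_equal(bubSimilarity(a, b, universe), 0.5)  # a=b=c=d=1
  expect_equal(bubSimilarity(a, a, universe), 1)
  expect_equal(bubSimilarity(a, a), 1)              # default pair universe

  # a = 0, d = 0: numerator vanishes
  dis_a <- makeSetRep(c(1, 2), "A"); dis_b <- makeSetRep(c(3, 4), "B")
  expect_equal(bubSimilarity(dis_a, dis_b, universe), 0)

  expect_error(bubSimilarity(a, makeSetRep(99, "Z"), universe), "universe")

  # symmetric, and monotone non-decreasing in shared absences d
  vals <- vapply(0:30, function(extra) {
    uni <- vapply(seq_len(4 + extra), junctionFor, character(1))
    bubSimilarity(a, b, uni)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(bubSimilarity(a, b, universe), bubSimilarity(b, a, universe))
})

test_that("similarity matrices are symmetric with unit diagonal", {
  reps <- list(makeSetRep(c(1, 2, 3), "A"), makeSetRep(c(2, 3, 4), "B"),
               makeSetRep(c(9, 10), "C"))
  m <- similarityMatrix(reps)
  expect_equal(diag(m), c(A = 1, B = 1, C = 1))
  expect_equal(m, t(m))

  same <- similarityMatrix(list(makeSetRep(1:3, "A"), makeSetRep(1:3, "B")))
  expect_equal(unname(same), matrix(1, 2, 2))

  # disjoint pair inside a larger universe: independent set-count oracle
  uni_n <- length(unique(unlist(lapply(reps, function(r)
    clonotypes(r)$cdr3_nt))))
  a_ <- 0; b_ <- 2; c_ <- 3; d_ <- uni_n - a_ - b_ - c_
  oracle <- (sqrt(a_ * d_) + a_) / (sqrt(a_ * d_) + a_ + b_ + c_)
  expect_equal(m["C", "A"], oracle)
})

test_that("clone tracking reports fractions with explicit absences", {
  focal <- makeSetRep(c(1, 2), "T", counts = c(3L, 2L))   # 0.6, 0.4
  other <- makeSetRep(c(1, 9), "U", counts = c(1L, 9L))   # clone 1 at 0.1
  tm <- trackClones(focal, list(other), n = 2L)
  expect_equal(dim(tm$fractions), c(2L, 2L))
  expect_equal(unname(tm$fractions[, "T"]), c(0.6, 0.4))
  expect_equal(unname(tm$fractions[1, "U"]), 0.1)
  expect_true(is.na(tm$fractions[2, "U"]))

  one <- trackClones(focal, list(other), n = 1L)
  expect_equal(rownames(one$fractions), junctionFor(1))

  solo <- trackClones(focal, list(), n = 2L)
  expect_equal(ncol(solo$fractions), 1L)
})

test_that("emerging clones are treated-only clonotypes", {
  treated <- makeSetRep(c(1, 2, 3), "T")
  untreated <- makeSetRep(1, "U")
  em <- emergingClones(treated, untreated)
  expect_equal(em$count, 2L)
  expect_setequal(em$clonotypes, vapply(c(2, 3), junctionFor, character(1)))
  expect_length(intersect(em$clonotypes, clonotypes(untreated)$cdr3_nt), 0L)

  expect_equal(emergingClones(treated, treated)$count, 0L)
  empty <- new("Repertoire", sampleId = "e", donorId = "d",
               group = "unspecified", clonotypes = clonotypes(treated)[0, ])
  expect_equal(emergingClones(treated, empty)$count, 3L)
})

test_that("simulated emerging clones are recovered exactly at zero error", {
  ref <- refFixture()
  ucfg <- presetConfig("untreated", 8L, nClones = 60L,
                       moleculesPerCloneScale = 10L, subErrorRate = 0)
  tcfg <- presetConfig("treated", 8L, nClones = 30L, nEmerging = 8L,
                       moleculesPerCloneScale = 30L, subErrorRate = 0)
  gu <- simulateRepertoire(ucfg, ref, sampleId = "u", group = "untreated")
  gt <- simulateRepertoire(tcfg, ref, baseline = gu, sampleId = "t",
                           group = "treated")
  em <- emergingClones(gt$repertoire, gu$repertoire)
  flagged <- gt$provenance$cdr3_nt[gt$provenance$emerging &
                                     gt$provenance$count > 0]
  expect_setequal(em$clonotypes, flagged)
})

test_that("the KS statistic matches empirical-CDF gaps and stats::ks.test", {
  expect_equal(ksCompare(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ksCompare(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  expect_equal(ksCompare(c(1, 2), c(1, 3))$statistic, 0.5)
  expect_equal(ksCompare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  xa <- ClonoTRB:::withSeed(5, rnorm(40))
  xb <- ClonoTRB:::withSeed(6, rnorm(35, mean = 0.5))
  ours <- ksCompare(xa, xb)
  base <- suppressWarnings(stats::ks.test(xa, xb, exact = FALSE))
  expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, base$p.value, tolerance = 0.02)
})
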