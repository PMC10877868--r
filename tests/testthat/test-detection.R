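test_that("marker genes are degradative CAZymes, sulfatases and transporters", {
  gt <- make_table(
    families = c("GH16", "GT2,CBM6", "", "", "AA3", "GT2,GH5"),
    roles = c("", "", "SULFATASE", "TBDT_OTHER", "", ""))
  expect_equal(isMarker(gt), c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("degradative classes are exactly GH, PL and CE", {
  expect_true(isDegradative("PL7"))
  expect_true(isDegradative("GH13_8"))
  expect_false(isDegradative("GT4"))
  expect_equal(isDegradative(c("GH1", "CE2", "CBM3", "AA9")),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(isDegradative("XYZ12"), "malformed")
  # prefix parse agrees with a naive substring check over the packaged map
  fams <- mappedFamilies(readSubstrateMap())
  expect_equal(isDegradative(fams), substr(fams, 1, 2) %in% c("GH", "PL", "CE"))
})

test_that("a window with three spread markers yields one trimmed locus", {
  fams <- rep("", 10)
  fams[c(3, 6, 9)] <- c("GH16", "GH3", "PL7")  # indices 2, 5, 8 (0-based)
  loci <- findCandidateLoci(make_table(fams), DetectionParams())
  expect_equal(nrow(loci), 1)
  expect_equal(loci$first_index, 2)
  expect_equal(loci$last_index, 8)
})

test_that("contigs with fewer markers than the threshold yield nothing", {
  fams <- rep("", 30)
  fams[c(5, 20)] <- "GH16"
  expect_equal(nrow(findCandidateLoci(make_table(fams), DetectionParams())), 0)
  empty <- GeneTable("e", data.frame(gene_id = character(0),
                                     contig_id = character(0),
                                     start = integer(0), end = integer(0),
                                     strand = character(0)))
  expect_equal(nrow(findCandidateLoci(empty, DetectionParams())), 0)
})

test_that("short contigs are assessed as one whole-contig window", {
  fams <- c("GH16", "", "GH3", "", "PL7")  # 5 genes < window of 10
  loci <- findCandidateLoci(make_table(fams), DetectionParams())
  expect_equal(nrow(loci), 1)
  expect_equal(c(loci$first_index, loci$last_index), c(0, 4))
  # same 5 genes but only 2 markers: below threshold
  fams2 <- c("GH16", "", "", "", "PL7")
  expect_equal(nrow(findCandidateLoci(make_table(fams2), DetectionParams())), 0)
})

test_that("sliding-window output equals brute-force enumeration on random contigs", {
  params <- DetectionParams()
  for (seed in 1:50) {
    n <- sample(c(30, 120, 200), 1)
    fx <- random_marker_table(seed, n)
    loci <- findCandidateLoci(fx$table, params)
    expected <- brute_force_loci(fx$marker, params@windowLength,
                                 params@minMarkers)
    expect_equal(nrow(loci), length(expected), info = paste("seed", seed))
    if (length(expected) > 0) {
      exp_mat <- do.call(rbind, expected)
      expect_equal(loci$first_index, unname(exp_mat[, "first"]),
                   info = paste("seed", seed))
      expect_equal(loci$last_index, unname(exp_mat[, "last"]),
                   info = paste("seed", seed))
    }
  }
})

test_that("emitted loci begin and end on marker genes", {
  for (seed in 101:110) {
    fx <- random_marker_table(seed, 150)
    loci <- findCandidateLoci(fx$table, DetectionParams())
    for (i in seq_len(nrow(loci))) {
      expect_true(fx$marker[loci$first_index[i] + 1])
      expect_true(fx$marker[loci$last_index[i] + 1])
    }
  }
})

test_that("lowering min_markers never removes a locus", {
  for (seed in 201:210) {
    fx <- random_marker_table(seed, 150)
    hi <- findCandidateLoci(fx$table, DetectionParams(minMarkers = 4))
    lo <- findCandidateLoci(fx$table, DetectionParams(minMarkers = 3))
    # every gene covered at the stricter threshold stays covered
    cover <- function(loci) {
      unlist(lapply(seq_len(nrow(loci)), function(i) {
        loci$first_index[i]:loci$last_index[i]
      }))
    }
    expect_true(all(cover(hi) %in% cover(lo)))
  }
})

test_that("detection is invariant to input row order", {
  fx <- random_marker_table(77, 150)
  g <- geneData(fx$table)
  set.seed(1)
  shuffled <- GeneTable(assemblyId(fx$table), g[sample(nrow(g)), ])
  a <- findCandidateLoci(fx$table, DetectionParams())
  b <- findCandidateLoci(shuffled, DetectionParams())
  expect_equal(a, b)
})

test_that("susCD tandem detection honors adjacency, order and strand policy", {
  # adjacent susC-susD on the same strand
  gt <- make_table(c("", "", "GH16"), c("SUSC", "SUSD", ""))
  expect_true(detectSusCDTandem(geneData(gt))$found)
  # either gene order
  gt2 <- make_table(c("", "", "GH16"), c("SUSD", "SUSC", ""))
  expect_true(detectSusCDTandem(geneData(gt2))$found)
  # not adjacent
  gt3 <- make_table(c("", "GH16", ""), c("SUSC", "", "SUSD"))
  expect_false(detectSusCDTandem(geneData(gt3))$found)
  # opposite strands: policy switch
  gt4 <- make_table(c("", ""), c("SUSC", "SUSD"), strand = c("+", "-"))
  expect_false(detectSusCDTandem(geneData(gt4), "same_strand_adjacent")$found)
  expect_true(detectSusCDTandem(geneData(gt4), "adjacent_any_strand")$found)
})

test_that("imputed strand disqualifies tandems under the same-strand policy", {
  g <- data.frame(gene_id = c("g1", "g2"), contig_id = "c",
                  start = c(1, 100), end = c(90, 190),
                  strand = c(NA, "+"), stringsAsFactors = FALSE)
  g$families <- list(character(0), character(0))
  g$roles <- list("SUSC", "SUSD")
  expect_warning(gt <- GeneTable("a", g), "strand")
  expect_false(detectSusCDTandem(geneData(gt), "same_strand_adjacent")$found)
  expect_true(detectSusCDTandem(geneData(gt), "adjacent_any_strand")$found)
})

test_that("example loci classify into the documented tiers", {
  cl <- function(fams, roles) {
    gt <- make_table(fams, roles)
    cs <- detectClusters(gt, DetectionParams(windowLength = length(fams),
                                             minMarkers = 1))
    tiers(cs)
  }
  expect_equal(cl(c("", "", "GH16", "GH17"), c("SUSC", "SUSD", "", "")), "PUL")
  expect_equal(cl(c("", "GH16", "", "GH3"), c("SUSD", "", "SULFATASE", "")),
               "PUL_LIKE")
  expect_equal(cl(c("GH13", "GH65", "GH31"), c("", "", "")), "CAZYME_RICH")
  expect_equal(cl(c("", "", ""), c("SULFATASE", "SULFATASE", "SULFATASE")),
               "UNCLASSIFIED")
})

test_that("tier assignment matches the truth-table oracle over enumerated loci", {
  # every gene is one of: susC, susD, other TBDT, sulfatase, one degradative
  # CAZyme, or a two-domain degradative gene; all loci up to 4 genes, each
  # combo planted on its own contig of one batch table
  res <- enumerate_tier_combos(max_genes = 4)
  expect_gt(nrow(res), 1500)
  expect_equal(res$got, res$want)
})

test_that("multi-domain genes count per domain by default, per gene on request", {
  # one gene with three degradative domains: rich under domain counting
  gt <- make_table(c("GH13,GH65,GH31", "", "GH16"), c("", "", ""))
  p_dom <- DetectionParams(windowLength = 3, minMarkers = 1)
  p_gene <- DetectionParams(windowLength = 3, minMarkers = 1,
                            countGenesNotDomains = TRUE)
  expect_equal(tiers(detectClusters(gt, p_dom)), "CAZYME_RICH")
  expect_equal(clusterData(detectClusters(gt, p_dom))$degradative_count, 4)
  expect_equal(tiers(detectClusters(gt, p_gene)), "UNCLASSIFIED")
  expect_equal(clusterData(detectClusters(gt, p_gene))$degradative_count, 2)
})

test_that("classifyCluster rejects out-of-range locus indices", {
  gt <- make_table(c("GH16", "GH3", "PL7"))
  locus <- list(contig_id = "c1", first_index = 0, last_index = 9)
  expect_error(classifyCluster(locus, gt), "out of range")
})

test_that("every emitted cluster satisfies its tier invariant", {
  for (seed in 301:305) {
    fx <- random_marker_table(seed, 200)
    cs <- detectClusters(fx$table, DetectionParams())
    expect_true(validObject(cs))
    cl <- clusterData(cs)
    for (i in seq_len(nrow(cl))) {
      switch(cl$tier[i],
        PUL = expect_true(cl$has_susCD_tandem[i] && cl$degradative_count[i] >= 1),
        PUL_LIKE = expect_true(!cl$has_susCD_tandem[i] &&
                                 cl$tbdt_like_count[i] >= 1 &&
                                 cl$degradative_count[i] >= 1),
        CAZYME_RICH = expect_true(cl$degradative_count[i] >= 3 &&
                                    cl$tbdt_like_count[i] == 0),
        UNCLASSIFIED = succeed())
    }
  }
})
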