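test_that("diversity estimators match their closed forms", {
  expect_equal(shannonIndex(c(0, 7, 0)), 0)
  expect_equal(shannonIndex(c(5, 5, 5, 5)), log(4))
  expect_equal(shannonIndex(c(5, 5, 5, 5), base = 2), 2)
  expect_equal(simpsonIndex(10), 0)
  expect_equal(simpsonIndex(c(3, 3)), 0.5)
  expect_equal(simpsonIndex(c(3, 3), form = "dominance"), 0.5)
  expect_equal(chao1Richness(c(1, 1, 2)), 3.5)
  expect_equal(chao1Richness(c(4, 5, 2)), 3)  # no singletons -> S_obs
  expect_equal(chao1Richness(c(1, 1, 2), bias_corrected = FALSE), 3 + 4 / 2)
  expect_equal(goodsCoverage(c(1, 1, 2)), 0.5)
  expect_equal(goodsCoverage(c(4, 5, 2)), 1)
})

test_that("estimators validate their inputs", {
  expect_error(shannonIndex(c(0, 0)), "zero")
  expect_error(simpsonIndex(numeric(0)), "empty")
  expect_error(chao1Richness(c(1.5, 2)), "integers")
  expect_error(goodsCoverage(c(-1, 2)), "non-negative")
})

test_that("random vectors agree with vegan and with direct formulas", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:20) {
    x <- rpois(50, lambda = sample(c(0.5, 2, 20), 1))
    if (sum(x) == 0) next
    expect_equal(shannonIndex(x), unname(vegan::diversity(x, "shannon")),
                 tolerance = 1e-12)
    expect_equal(simpsonIndex(x), unname(vegan::diversity(x, "simpson")),
                 tolerance = 1e-12)
    expect_equal(chao1Richness(x), unname(vegan::estimateR(x)["S.chao1"]),
                 tolerance = 1e-10)
    p <- x[x > 0] / sum(x)
    expect_equal(shannonIndex(x), -sum(p * log(p)), tolerance = 1e-12)
    expect_equal(simpsonIndex(x), 1 - sum(p^2), tolerance = 1e-12)
    expect_equal(goodsCoverage(x), 1 - sum(x == 1) / sum(x), tolerance = 1e-12)
  }
})

test_that("shannon is permutation-invariant and maximal for uniform vectors", {
  set.seed(6)
  x <- rpois(30, 5) + 1
  expect_equal(shannonIndex(sample(x)), shannonIndex(x))
  expect_lte(shannonIndex(x), log(length(x)))
  expect_equal(shannonIndex(rep(7, 30)), log(30))
})

test_that("chao1 never falls below observed richness; goods tracks singletons", {
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(40, 1.2)
    if (sum(x) == 0) next
    expect_gte(chao1Richness(x), sum(x > 0))
    g0 <- goodsCoverage(x)
    if (any(x == 1)) {
      # promoting every singleton to a doubleton strictly raises coverage
      x2 <- x
      x2[x2 == 1] <- 2
      expect_gt(goodsCoverage(x2), g0)
      expect_lt(g0, 1)
    } else {
      expect_equal(g0, 1)
    }
  }
})

test_that("rarefaction draws the requested depth deterministically under seed", {
  x <- c(10, 0, 5, 25)
  r1 <- rarefyCounts(x, 20, seed = 9)
  r2 <- rarefyCounts(x, 20, seed = 9)
  expect_equal(r1, r2)
  expect_equal(sum(r1), 20)
  expect_equal(r1[2], 0)
  expect_error(rarefyCounts(x, 100), "exceeds")
})

test_that("exact 16S containment links on either strand, never with mismatches", {
  sim <- simulateCommunityFixture(17)
  links <- linkAsvToMags(sim$asv_sequences, sim$mag_16s_sequences)
  truth <- sim$truth$exact_links
  got <- links[order(links$asv_id), c("asv_id", "mag_id")]
  want <- truth[order(truth$asv_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # one-mismatch decoys never link
  expect_false(any(links$asv_id %in% sim$truth$decoy_asv_ids))
  expect_true(all(links$evidence == "EXACT_16S"))
  expect_true(all(is.na(links$via_mag_id)))
})

test_that("linking equals a brute-force two-strand substring scan", {
  sim <- simulateCommunityFixture(23, n_asvs = 100, n_mags = 20)
  links <- linkAsvToMags(sim$asv_sequences, sim$mag_16s_sequences)
  bf <- brute_force_links(as.list(sim$asv_sequences),
                          as.list(sim$mag_16s_sequences))
  key <- function(d) sort(paste(d$asv_id, d$mag_id))
  expect_equal(key(links), key(bf))
})

test_that("linking is invariant under reverse-complementing the 16S pool", {
  sim <- simulateCommunityFixture(29, n_asvs = 40, n_mags = 10)
  links <- linkAsvToMags(sim$asv_sequences, sim$mag_16s_sequences)
  rc <- vapply(sim$mag_16s_sequences, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  links_rc <- linkAsvToMags(sim$asv_sequences, rc)
  key <- function(d) sort(paste(d$asv_id, d$mag_id))
  expect_equal(key(links_rc), key(links))
})

test_that("ASVs with ambiguous bases never link; invalid characters error", {
  mags <- c(M1 = paste(rep("ACGT", 100), collapse = ""))
  asv_n <- c(A1 = paste0("ACGT", "N", "CGTA"))
  expect_equal(nrow(linkAsvToMags(asv_n, mags)), 0)
  # U is accepted and treated as T
  asv_u <- c(A2 = "ACGUACGUACGU")
  expect_equal(nrow(linkAsvToMags(asv_u, mags)), 1)
  expect_error(linkAsvToMags(c(A3 = "ACGX"), mags), "invalid characters")
})

test_that("ANI extension is inclusive at the threshold and does not chain", {
  links <- data.frame(asv_id = "a1", mag_id = "A", evidence = "EXACT_16S",
                      via_mag_id = NA_character_, stringsAsFactors = FALSE)
  ani <- data.frame(mag_a = c("A", "A", "B"), mag_b = c("B", "C", "D"),
                    ani = c(95.0, 94.9, 99.0), stringsAsFactors = FALSE)
  out <- extendLinksViaAni(links, ani, threshold = 95)
  ext <- out[out$evidence == "ANI_EXTENSION", ]
  # 95.0 is included, 94.9 is not, and B's own 99% partner D is not reached
  expect_equal(ext$mag_id, "B")
  expect_equal(ext$via_mag_id, "A")
  expect_false("D" %in% out$mag_id)
  expect_false("C" %in% out$mag_id)
})

test_that("ANI extension equals a one-step closure oracle on random inputs", {
  set.seed(31)
  for (rep in 1:10) {
    mags <- sprintf("M%02d", 1:8)
    links <- data.frame(
      asv_id = sample(sprintf("a%d", 1:5), 4, replace = TRUE),
      mag_id = sample(mags, 4, replace = TRUE),
      evidence = "EXACT_16S", via_mag_id = NA_character_,
      stringsAsFactors = FALSE)
    pairs <- t(combn(mags, 2))
    keep <- runif(nrow(pairs)) < 0.3
    ani <- data.frame(mag_a = pairs[keep, 1], mag_b = pairs[keep, 2],
                      ani = round(runif(sum(keep), 90, 100), 2),
                      stringsAsFactors = FALSE)
    out <- extendLinksViaAni(links, ani, threshold = 95)
    # oracle: for every exact link, scan the full table both ways
    expected <- list()
    for (i in seq_len(nrow(links))) {
      for (j in seq_len(nrow(ani))) {
        if (ani$ani[j] < 95) next
        partner <- NULL
        if (ani$mag_a[j] == links$mag_id[i]) partner <- ani$mag_b[j]
        if (ani$mag_b[j] == links$mag_id[i]) partner <- ani$mag_a[j]
        if (!is.null(partner) && partner != links$mag_id[i]) {
          expected[[length(expected) + 1]] <-
            paste(links$asv_id[i], partner, links$mag_id[i])
        }
      }
    }
    got <- out[out$evidence == "ANI_EXTENSION", ]
    expect_setequal(paste(got$asv_id, got$mag_id, got$via_mag_id),
                    unique(unlist(expected)))
  }
})

test_that("asymmetric ANI tables are rejected", {
  links <- data.frame(asv_id = "a1", mag_id = "A", evidence = "EXACT_16S",
                      via_mag_id = NA_character_, stringsAsFactors = FALSE)
  ani <- data.frame(mag_a = c("A", "B"), mag_b = c("B", "A"),
                    ani = c(96, 97), stringsAsFactors = FALSE)
  expect_error(extendLinksViaAni(links, ani), "asymmetric")
  ani_ok <- data.frame(mag_a = c("A", "B"), mag_b = c("B", "A"),
                       ani = c(96, 96), stringsAsFactors = FALSE)
  expect_equal(sum(extendLinksViaAni(links, ani_ok)$evidence == "ANI_EXTENSION"), 1)
})

test_that("alphaDiversity summarizes a count matrix per sample", {
  sim <- simulateCommunityFixture(37, n_samples = 3)
  div <- alphaDiversity(sim$counts, sim$fractions)
  expect_equal(nrow(div), 3)
  for (s in div$sample_id) {
    tr <- sim$truth$diversity[[s]]
    expect_equal(div$shannon[div$sample_id == s], tr$shannon, tolerance = 1e-12)
    expect_equal(div$simpson[div$sample_id == s], tr$simpson, tolerance = 1e-12)
    expect_equal(div$chao1[div$sample_id == s], tr$chao1, tolerance = 1e-12)
    expect_equal(div$goods_coverage[div$sample_id == s], tr$goods,
                 tolerance = 1e-12)
  }
  expect_equal(unname(div$fraction), unname(sim$fractions[div$sample_id]))
})
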