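# run expr under a local RNG state seeded from `seed`, restoring the
# caller's stream afterwards so generators never perturb each other
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# independent sub-streams per generator, split from one master seed, so
# adding a generator never changes existing fixtures
.subseed <- function(seed, stream) {
  (as.integer(seed) * 1009L + stream * 7919L) %% 2147483647L
}

#' Planted-cluster templates
#'
#' Gene-role/family templates the generator plants as ground-truth
#' clusters. Each template is a data.frame of genes in order with
#' `families`, `roles` and `strand`, plus attributes `tier` (the tier the
#' detector must assign) and `substrate` (headline substrate class).
#'
#' @return Named list of templates.
#' @export
#' @examples
#' names(clusterTemplates())
clusterTemplates <- function() {
  tpl <- function(families, roles, strand, tier, substrate) {
    d <- data.frame(families = families, roles = roles, strand = strand,
                    stringsAsFactors = FALSE)
    attr(d, "tier") <- tier
    attr(d, "substrate") <- substrate
    d
  }
  list(
    # laminarin PUL: susCD tandem plus GH16/GH17 laminarinases
    pul_beta_glucan = tpl(
      families = c("", "", "GH16", "GH17", "GH30"),
      roles = c("SUSC", "SUSD", "", "", ""),
      strand = c("+", "+", "+", "+", "+"),
      tier = "PUL", substrate = "beta-1,3-glucan"),
    # alpha-glucan type II PUL: susCD plus GH13/GH65/GH31
    pul_alpha_glucan = tpl(
      families = c("", "", "GH13", "GH65", "GH31"),
      roles = c("SUSC", "SUSD", "", "", ""),
      strand = c("-", "-", "-", "-", "-"),
      tier = "PUL", substrate = "alpha-glucan"),
    # susD-like gene without adjacent susC: PUL-like
    pul_like_beta = tpl(
      families = c("", "GH16", "", "GH3"),
      roles = c("SUSD", "", "SULFATASE", ""),
      strand = c("+", "+", "+", "+"),
      tier = "PUL_LIKE", substrate = "beta-1,3-glucan"),
    # TBDT plus alginate lyases: PUL-like
    pul_like_alginate = tpl(
      families = c("", "PL7", "PL17"),
      roles = c("TBDT_OTHER", "", ""),
      strand = c("+", "+", "-"),
      tier = "PUL_LIKE", substrate = "alginate"),
    # three degradative CAZymes, no transporter: CAZyme-rich
    cazyme_rich_alpha = tpl(
      families = c("GH13", "GH65", "GH31"),
      roles = c("", "", ""),
      strand = c("+", "-", "+"),
      tier = "CAZYME_RICH", substrate = "alpha-glucan"),
    cazyme_rich_pectin = tpl(
      families = c("PL1", "GH28", "CE8", "PL9"),
      roles = c("", "", "", ""),
      strand = c("+", "+", "+", "-"),
      tier = "CAZYME_RICH", substrate = "pectin")
  )
}

.BACKGROUND_FAMILIES <- c("GH16", "GH13", "GH3", "GH29", "GH78", "GH10",
                          "PL7", "PL1", "CE1", "CE8")

#' Generate an annotated gene fixture with planted clusters
#'
#' Builds a synthetic [GeneTable-class] of `n_contigs` contigs with
#' `genes_per_contig` genes each, plants ground-truth clusters from
#' [clusterTemplates()] at given positions, and sprinkles background
#' marker annotations at a Bernoulli rate per non-planted gene. Gene
#' coordinates are 1-based, non-overlapping, with randomized strands
#' except inside planted templates (tandems keep their strands). The
#' output is fully deterministic under `seed`.
#'
#' Planted clusters must not overlap and must keep at least
#' `min_separation` non-planted genes between them and contig edges
#' within the same contig, so that at background rate 0 each planted
#' cluster is recovered as exactly one locus.
#'
#' @param seed Integer master seed.
#' @param n_contigs,genes_per_contig Fixture dimensions.
#' @param planted data.frame with columns `contig` (1-based contig
#'   number), `start_index` (0-based gene index) and `template` (name in
#'   [clusterTemplates()]); NULL plants nothing.
#' @param background_marker_rate Probability that a background gene gets
#'   a random marker annotation.
#' @param min_separation Required gap in genes between planted clusters
#'   (default 10, one detection window).
#' @param taxa Taxon labels sampled per gene.
#' @return List with `gene_table` ([GeneTable-class]) and `truth` (one
#'   row per planted cluster: contig_id, first_index, last_index, tier,
#'   substrate, template, gene_ids).
#' @export
#' @examples
#' fx <- simulateGeneFixture(1, planted = data.frame(
#'   contig = 1, start_index = 10, template = "pul_beta_glucan"))
#' fx$truth
simulateGeneFixture <- function(seed, n_contigs = 5L, genes_per_contig = 60L,
                                planted = NULL, background_marker_rate = 0,
                                min_separation = 10L,
                                taxa = c("Bacteroidota", "Gammaproteobacteria",
                                         "Verrucomicrobiota", "Planctomycetota")) {
  stopifnot(background_marker_rate >= 0, background_marker_rate <= 1)
  templates <- clusterTemplates()
  .with_seed(.subseed(seed, 1L), {
    planted_at <- vector("list", n_contigs)
    if (!is.null(planted) && nrow(planted) > 0) {
      if (!all(planted$template %in% names(templates))) {
        stop("unknown template name(s): ",
             paste(setdiff(planted$template, names(templates)), collapse = ", "))
      }
      for (i in seq_len(nrow(planted))) {
        ct <- planted$contig[i]
        tpl <- templates[[planted$template[i]]]
        lo <- planted$start_index[i]
        hi <- lo + nrow(tpl) - 1L
        if (ct < 1 || ct > n_contigs || lo < 0 || hi >= genes_per_contig) {
          stop("planted cluster ", i, " outside the fixture")
        }
        for (prev in planted_at[[ct]]) {
          if (lo <= prev$hi + min_separation && hi >= prev$lo - min_separation) {
            stop("planted clusters overlap or are closer than min_separation")
          }
        }
        planted_at[[ct]] <- c(planted_at[[ct]],
                              list(list(lo = lo, hi = hi, i = i,
                                        template = planted$template[i])))
      }
    }
    genes <- list()
    truth <- list()
    for (c_i in seq_len(n_contigs)) {
      contig_id <- sprintf("contig_%02d", c_i)
      n <- genes_per_contig
      lens <- sample(300:2400, n, replace = TRUE)
      gaps <- sample(20:200, n, replace = TRUE)
      starts <- cumsum(c(1L, head(lens + gaps, -1)))
      ends <- starts + lens - 1L
      strand <- sample(c("+", "-"), n, replace = TRUE)
      fams <- replicate(n, character(0), simplify = FALSE)
      roles <- replicate(n, character(0), simplify = FALSE)
      is_planted <- rep(FALSE, n)
      for (pl in planted_at[[c_i]]) {
        tpl <- templates[[pl$template]]
        pos <- (pl$lo:pl$hi) + 1L
        is_planted[pos] <- TRUE
        strand[pos] <- tpl$strand
        fams[pos] <- .split_tokens(tpl$families)
        roles[pos] <- .split_tokens(tpl$roles)
      }
      if (background_marker_rate > 0) {
        bg <- which(!is_planted & runif(n) < background_marker_rate)
        for (b in bg) {
          if (runif(1) < 0.8) {
            fams[[b]] <- sample(.BACKGROUND_FAMILIES, 1)
          } else {
            roles[[b]] <- sample(c("SULFATASE", "TBDT_OTHER"), 1)
          }
        }
      }
      gene_ids <- sprintf("%s_g%04d", contig_id, seq_len(n))
      genes[[c_i]] <- data.frame(
        gene_id = gene_ids, contig_id = contig_id, start = starts,
        end = ends, strand = strand, stringsAsFactors = FALSE)
      genes[[c_i]]$families <- fams
      genes[[c_i]]$roles <- roles
      genes[[c_i]]$taxon <- sample(taxa, n, replace = TRUE)
      for (pl in planted_at[[c_i]]) {
        tpl <- templates[[pl$template]]
        truth[[pl$i]] <- data.frame(
          contig_id = contig_id, first_index = pl$lo, last_index = pl$hi,
          tier = attr(tpl, "tier"), substrate = attr(tpl, "substrate"),
          template = pl$template, stringsAsFactors = FALSE)
        truth[[pl$i]]$gene_ids <- list(gene_ids[(pl$lo:pl$hi) + 1L])
      }
    }
    gt <- GeneTable(sprintf("sim_%d", seed), do.call(rbind, genes))
    truth_df <- if (length(truth) > 0) {
      tr <- do.call(rbind, truth)
      rownames(tr) <- NULL
      tr
    } else {
      tr <- data.frame(contig_id = character(0), first_index = integer(0),
                       last_index = integer(0), tier = character(0),
                       substrate = character(0), template = character(0),
                       stringsAsFactors = FALSE)
      tr$gene_ids <- list()
      tr
    }
    list(gene_table = gt, truth = truth_df)
  })
}

#' Generate a per-gene coverage fixture with a planted target fraction
#'
#' Draws log-normal per-gene coverages (heavy-tailed, like real per-gene
#' read depth) and rescales the target set so it holds exactly
#' `planted_fraction` of the total coverage, making the expected
#' [geneFrequency()] of the targets `100 * planted_fraction` by
#' construction.
#'
#' @param gene_table A [GeneTable-class].
#' @param target_gene_ids Genes forming the planted target set.
#' @param planted_fraction Fraction of total coverage held by the
#'   targets, in \[0, 1\] (1 only allowed when the targets are all genes).
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters of the raw draws.
#' @return List with `coverage` (named vector) and `truth`
#'   (`planted_fraction`, `expected_frequency`).
#' @export
simulateCoverageFixture <- function(gene_table, target_gene_ids,
                                    planted_fraction, seed,
                                    meanlog = 2, sdlog = 1) {
  if (planted_fraction > 1 || planted_fraction < 0) {
    stop("planted_fraction must lie in [0, 1]")
  }
  g <- geneData(gene_table)
  if (!all(target_gene_ids %in% g$gene_id)) {
    stop("target gene(s) absent from gene table")
  }
  .with_seed(.subseed(seed, 2L), {
    cov <- rlnorm(nrow(g), meanlog = meanlog, sdlog = sdlog)
    names(cov) <- g$gene_id
    is_t <- g$gene_id %in% target_gene_ids
    if (all(is_t) || all(!is_t)) {
      if (length(target_gene_ids) > 0 && planted_fraction != 1) {
        stop("all genes are targets; planted_fraction must be 1")
      }
    } else if (planted_fraction == 0) {
      cov[is_t] <- 0
    } else if (planted_fraction == 1) {
      stop("planted_fraction 1 requires the target set to be all genes")
    } else {
      s <- planted_fraction * sum(cov[!is_t]) /
        ((1 - planted_fraction) * sum(cov[is_t]))
      cov[is_t] <- cov[is_t] * s
    }
    list(coverage = cov,
         truth = list(planted_fraction = planted_fraction,
                      expected_frequency = 100 * planted_fraction))
  })
}

.random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

#' Generate a community fixture with planted ASV-MAG links
#'
#' Emulates the 16S amplicon side of a bloom time series: per-sample ASV
#' counts from a log-normal abundance model, a pool of MAG-derived 16S
#' sequences (random 1500-mers), ASVs of three kinds — exact substrings
#' of distinct MAG 16S genes (planted links), one-mismatch decoys that
#' must never link, and unrelated random sequences — and a pairwise ANI
#' table with planted pairs at exactly 95.0 (extension boundary) and at
#' 94.9 (below threshold).
#'
#' @param seed Integer master seed.
#' @param n_samples Number of samples (fractions cycle FL, PA3, PA10).
#' @param n_asvs Number of ASVs (must be >= `n_exact_links + n_decoys`).
#' @param n_mags Number of MAG 16S sequences (>= `n_exact_links`).
#' @param n_exact_links Planted exact containments.
#' @param n_decoys Planted one-mismatch near-matches.
#' @param meanlog,sdlog Log-normal abundance parameters.
#' @return List with `counts` (samples x ASV matrix), `fractions`,
#'   `asv_sequences`, `mag_16s_sequences` (named character vectors),
#'   `ani_table`, and `truth` (planted links, expected ANI extensions,
#'   per-sample diversity values computed by direct formula).
#' @export
simulateCommunityFixture <- function(seed, n_samples = 6L, n_asvs = 100L,
                                     n_mags = 20L, n_exact_links = 10L,
                                     n_decoys = 10L, meanlog = 1, sdlog = 1.5) {
  if (n_asvs < n_exact_links + n_decoys) {
    stop("n_asvs must be at least n_exact_links + n_decoys")
  }
  if (n_mags < n_exact_links) stop("need at least one MAG per planted link")
  .with_seed(.subseed(seed, 3L), {
    mag_ids <- sprintf("MAG_%03d", seq_len(n_mags))
    mags <- setNames(vapply(seq_len(n_mags), function(i) .random_dna(1500L),
                            character(1)), mag_ids)
    asv_ids <- sprintf("ASV_%04d", seq_len(n_asvs))
    asv <- character(n_asvs)
    link_truth <- list()
    for (i in seq_len(n_exact_links)) {
      src <- mags[[i]]
      len <- sample(250:400, 1)
      at <- sample(seq_len(1500L - len + 1L), 1)
      frag <- substr(src, at, at + len - 1L)
      # half the planted links are reverse-complemented: both strands count
      if (i %% 2 == 0) {
        frag <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(frag)))
      }
      asv[i] <- frag
      link_truth[[i]] <- data.frame(asv_id = asv_ids[i], mag_id = mag_ids[i],
                                    stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_decoys)) {
      j <- n_exact_links + i
      src <- mags[[(i - 1L) %% n_mags + 1L]]
      len <- sample(250:400, 1)
      at <- sample(seq_len(1500L - len + 1L), 1)
      frag <- substr(src, at, at + len - 1L)
      pos <- sample(len, 1)
      orig <- substr(frag, pos, pos)
      substr(frag, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
      asv[j] <- frag
    }
    for (j in seq(n_exact_links + n_decoys + 1L, length.out = n_asvs - n_exact_links - n_decoys)) {
      asv[j] <- .random_dna(250L)
    }
    names(asv) <- asv_ids
    fractions <- rep(c("FL", "PA3", "PA10"), length.out = n_samples)
    sample_ids <- sprintf("S%02d_%s", seq_len(n_samples), fractions)
    counts <- matrix(0L, n_samples, n_asvs,
                     dimnames = list(sample_ids, asv_ids))
    for (s in seq_len(n_samples)) {
      present <- runif(n_asvs) < 0.7
      x <- numeric(n_asvs)
      x[present] <- floor(rlnorm(sum(present), meanlog, sdlog))
      counts[s, ] <- as.integer(x)
    }
    # direct-formula truth for the sampled vectors
    div <- lapply(seq_len(n_samples), function(s) {
      x <- counts[s, ]
      p <- x[x > 0] / sum(x)
      f1 <- sum(x == 1); f2 <- sum(x == 2)
      list(shannon = -sum(p * log(p)),
           simpson = 1 - sum(p^2),
           chao1 = sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1)),
           goods = 1 - f1 / sum(x))
    })
    names(div) <- sample_ids
    # ANI pairs: MAG_001 pairs with two 16S-less MAGs, one exactly at the
    # species boundary and one just below it
    extra <- sprintf("MAG_X%02d", 1:2)
    ani <- data.frame(
      mag_a = c(mag_ids[1], mag_ids[1], mag_ids[2]),
      mag_b = c(extra[1], extra[2], mag_ids[3]),
      ani = c(95.0, 94.9, 96.5),
      stringsAsFactors = FALSE)
    exact_links <- do.call(rbind, link_truth)
    # complete one-step closure over the planted >= 95% pairs
    ext_truth <- list()
    for (i in seq_len(nrow(exact_links))) {
      anchor <- exact_links$mag_id[i]
      sel <- (ani$mag_a == anchor | ani$mag_b == anchor) & ani$ani >= 95
      partners <- setdiff(unique(c(ani$mag_a[sel], ani$mag_b[sel])), anchor)
      for (b in partners) {
        ext_truth[[length(ext_truth) + 1L]] <- data.frame(
          asv_id = exact_links$asv_id[i], mag_id = b, via_mag_id = anchor,
          stringsAsFactors = FALSE)
      }
    }
    truth <- list(
      exact_links = exact_links,
      decoy_asv_ids = asv_ids[seq(n_exact_links + 1L, length.out = n_decoys)],
      expected_extensions = if (length(ext_truth) > 0) {
        do.call(rbind, ext_truth)
      } else {
        data.frame(asv_id = character(0), mag_id = character(0),
                   via_mag_id = character(0), stringsAsFactors = FALSE)
      },
      boundary_extension = data.frame(
        asv_id = asv_ids[1], mag_id = extra[1], via_mag_id = mag_ids[1],
        stringsAsFactors = FALSE),
      below_threshold_pair = c(mag_ids[1], extra[2]),
      diversity = div)
    list(counts = counts, fractions = setNames(fractions, sample_ids),
         asv_sequences = asv, mag_16s_sequences = mags, ani_table = ani,
         truth = truth)
  })
}

#' Generate random MAG quality statistics
#'
#' Draws completeness/contamination/rRNA/tRNA values spanning all four
#' quality tiers, for exercising [assignQualityTier()].
#'
#' @param seed Integer seed.
#' @param n Number of MAGs.
#' @return data.frame in [readMagStats()] layout (no tier column).
#' @export
simulateMagStats <- function(seed, n = 50L) {
  .with_seed(.subseed(seed, 4L), {
    data.frame(
      mag_id = sprintf("MAG_%04d", seq_len(n)),
      completeness = round(runif(n, 20, 100), 2),
      contamination = round(runif(n, 0, 15), 2),
      rrna_5s = runif(n) < 0.7,
      rrna_16s = runif(n) < 0.7,
      rrna_23s = runif(n) < 0.7,
      trna_count = sample(0:45, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Write a community fixture to disk
#'
#' Emits the ASV count TSV, ASV and MAG-16S FASTA files, ANI TSV and a
#' ground_truth.json; all plain text, byte-identical under a fixed seed.
#'
#' @param sim Result of [simulateCommunityFixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
writeCommunityFixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(dir, "asv_counts.tsv")
  tab <- data.frame(sample_id = rownames(sim$counts),
                    fraction = sim$fractions[rownames(sim$counts)],
                    sim$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  asv_path <- file.path(dir, "asvs.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$asv_sequences), asv_path)
  mag_path <- file.path(dir, "mag_16s.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$mag_16s_sequences), mag_path)
  ani_path <- file.path(dir, "ani.tsv")
  write.table(sim$ani_table, ani_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(counts_path, asv_path, mag_path, ani_path, truth_path))
}
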