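.check_counts <- function(x, integer_only = FALSE) {
  if (length(x) == 0 || all(is.na(x))) stop("empty count vector")
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  if (integer_only && any(x != round(x))) stop("counts must be integers")
  if (sum(x) == 0) stop("all counts are zero")
  invisible(x)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \log p_i} over taxa with positive counts, with
#' \eqn{p_i} the relative abundances. Natural log by default (the usual
#' ecology convention); any base can be supplied.
#'
#' @param counts Non-negative count (or abundance) vector.
#' @param base Logarithm base; default `exp(1)`.
#' @return Non-negative real; 0 for a single-taxon community.
#' @export
#' @examples
#' shannonIndex(c(5, 5, 5, 5))  # log(4)
shannonIndex <- function(counts, base = exp(1)) {
  .check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Simpson diversity index
#'
#' Gini–Simpson form \eqn{1 - \sum p_i^2} by default; set
#' `form = "dominance"` for the plain \eqn{\sum p_i^2}.
#'
#' @inheritParams shannonIndex
#' @param form `"gini"` (default) or `"dominance"`.
#' @return Value in \[0, 1\].
#' @export
#' @examples
#' simpsonIndex(c(10, 10))  # 0.5
simpsonIndex <- function(counts, form = c("gini", "dominance")) {
  form <- match.arg(form)
  .check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  d <- sum(p^2)
  if (form == "gini") 1 - d else d
}

#' Chao1 richness estimator
#'
#' Bias-corrected form (default)
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, with \eqn{F_1}/\eqn{F_2}
#' the singleton/doubleton counts; this form stays finite at
#' \eqn{F_2 = 0}. The classic \eqn{S_{obs} + F_1^2 / (2 F_2)} is available
#' with `bias_corrected = FALSE` (infinite when \eqn{F_2 = 0} and
#' \eqn{F_1 > 0}).
#'
#' @param counts Non-negative integer count vector.
#' @param bias_corrected Use the bias-corrected form (default TRUE).
#' @return Estimated richness, always >= observed richness.
#' @export
#' @examples
#' chao1Richness(c(1, 1, 2))  # 3.5
chao1Richness <- function(counts, bias_corrected = TRUE) {
  .check_counts(counts, integer_only = TRUE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else if (f1 == 0) {
    s_obs
  } else {
    Inf
  }
}

#' Good's coverage estimator
#'
#' \eqn{1 - F_1 / N}: the estimated fraction of the community captured by
#' a sample with \eqn{F_1} singletons among \eqn{N} reads. 1 means no
#' singletons, i.e. sampling depth saturated the observable diversity.
#'
#' @param counts Non-negative integer count vector with positive total.
#' @return Value in \[0, 1\].
#' @export
#' @examples
#' goodsCoverage(c(1, 1, 2))  # 0.5
goodsCoverage <- function(counts) {
  .check_counts(counts, integer_only = TRUE)
  1 - sum(counts == 1) / sum(counts)
}

#' Subsample a count vector without replacement
#'
#' Rarefaction helper for diversity sensitivity checks: draws `size` reads
#' without replacement from the community described by `counts`.
#'
#' @param counts Integer count vector.
#' @param size Number of reads to draw (at most `sum(counts)`).
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of the same length as `counts`.
#' @export
rarefyCounts <- function(counts, size, seed = NULL) {
  .check_counts(counts, integer_only = TRUE)
  if (size > sum(counts)) stop("size exceeds total count")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pool <- rep(seq_along(counts), counts)
  drawn <- sample(pool, size)
  tabulate(drawn, nbins = length(counts))
}

.clean_seq <- function(x, what) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid characters in ", what, " sequence(s): ",
         paste(head(names(x)[bad], 5), collapse = ", "))
  }
  x
}

#' Link ASVs to MAGs by exact 16S containment
#'
#' An amplicon sequence variant (ASV) is linked to a MAG when it occurs as
#' an exact, mismatch-free substring of one of the MAG's 16S rRNA gene
#' sequences on either strand — i.e. a perfect blastn hit with 100%
#' identity over 100% of the ASV length. Ambiguous bases never match: an
#' ASV containing N cannot link. One ASV may link several MAGs and vice
#' versa.
#'
#' @param asv_sequences Named character vector or
#'   [Biostrings::DNAStringSet] of ASV sequences (A/C/G/T/U/N).
#' @param mag_16s_sequences Named character vector or DNAStringSet of
#'   MAG-derived 16S sequences. Multi-copy 16S genes may be supplied as
#'   several entries named `<mag_id>|<copy>`; everything before the first
#'   `|` is the MAG id.
#' @return data.frame with columns `asv_id`, `mag_id`, `evidence`
#'   (`"EXACT_16S"`) and `via_mag_id` (`NA`).
#' @export
linkAsvToMags <- function(asv_sequences, mag_16s_sequences) {
  asv <- .clean_seq(setNames(as.character(asv_sequences),
                             names(asv_sequences)), "ASV")
  mag <- .clean_seq(setNames(as.character(mag_16s_sequences),
                             names(mag_16s_sequences)), "MAG 16S")
  if (is.null(names(asv)) || is.null(names(mag))) {
    stop("ASV and MAG sequences must be named")
  }
  mag_ids <- sub("\\|.*$", "", names(mag))
  subjects <- Biostrings::DNAStringSet(mag)
  links <- list()
  for (a in names(asv)) {
    q <- asv[[a]]
    if (grepl("N", q, fixed = TRUE)) next
    pat <- Biostrings::DNAString(q)
    rc <- Biostrings::reverseComplement(pat)
    hit <- vapply(seq_along(subjects), function(j) {
      s <- subjects[[j]]
      # fixed = TRUE: exact character match only; subject Ns never pair
      Biostrings::countPattern(pat, s, fixed = TRUE) > 0 ||
        Biostrings::countPattern(rc, s, fixed = TRUE) > 0
    }, logical(1))
    for (m in unique(mag_ids[hit])) {
      links[[length(links) + 1L]] <- data.frame(
        asv_id = a, mag_id = m, evidence = "EXACT_16S",
        via_mag_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (length(links) == 0) return(.empty_link_frame())
  out <- do.call(rbind, links)
  rownames(out) <- NULL
  out
}

.empty_link_frame <- function() {
  data.frame(asv_id = character(0), mag_id = character(0),
             evidence = character(0), via_mag_id = character(0),
             stringsAsFactors = FALSE)
}

#' Extend ASV-MAG links across MAGs by ANI
#'
#' MAGs without usable 16S genes inherit links from near-identical
#' relatives: for every exact 16S link (asv, A) and every MAG B with
#' ANI(A, B) >= `threshold` (inclusive, default 95 — the conventional
#' species boundary), an `ANI_EXTENSION` link (asv, B, via = A) is added.
#' Extensions do not chain (no transitive closure) and duplicates are
#' collapsed.
#'
#' @param links data.frame of `EXACT_16S` links from [linkAsvToMags()].
#' @param ani_table data.frame with columns `mag_a`, `mag_b`, `ani`
#'   (percent); must be symmetric where both orientations are present.
#' @param threshold ANI threshold in percent, inclusive.
#' @return The input links plus the extension rows.
#' @export
extendLinksViaAni <- function(links, ani_table, threshold = 95.0) {
  stopifnot(threshold > 0, threshold <= 100)
  if (!all(c("mag_a", "mag_b", "ani") %in% names(ani_table))) {
    stop("ANI table must have columns 'mag_a', 'mag_b', 'ani'")
  }
  key <- paste(ani_table$mag_a, ani_table$mag_b, sep = "\r")
  rev_key <- paste(ani_table$mag_b, ani_table$mag_a, sep = "\r")
  j <- match(rev_key, key)
  both <- !is.na(j)
  if (any(abs(ani_table$ani[both] - ani_table$ani[j[both]]) > 1e-6)) {
    stop("asymmetric ANI entries differ by more than 1e-6")
  }
  exact <- links[links$evidence == "EXACT_16S", , drop = FALSE]
  ext <- list()
  for (i in seq_len(nrow(exact))) {
    a <- exact$mag_id[i]
    hits <- ani_table[(ani_table$mag_a == a | ani_table$mag_b == a) &
                        ani_table$ani >= threshold, , drop = FALSE]
    partners <- setdiff(unique(c(hits$mag_a, hits$mag_b)), a)
    for (b in partners) {
      ext[[length(ext) + 1L]] <- data.frame(
        asv_id = exact$asv_id[i], mag_id = b, evidence = "ANI_EXTENSION",
        via_mag_id = a, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(links, if (length(ext) > 0) do.call(rbind, ext))
  out <- out[!duplicated(out[, c("asv_id", "mag_id", "evidence", "via_mag_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Alpha-diversity summary of an ASV count matrix
#'
#' Computes Shannon, Simpson (Gini form), Chao1 (bias-corrected) and
#' Good's coverage per sample. No rarefaction is applied; use
#' [rarefyCounts()] for sensitivity checks.
#'
#' @param counts Samples x ASV integer matrix (e.g. from
#'   [readAsvCounts()]).
#' @param fractions Optional named fraction labels carried through.
#' @return data.frame, one row per sample.
#' @export
alphaDiversity <- function(counts, fractions = NULL) {
  stopifnot(is.matrix(counts))
  out <- data.frame(
    sample_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    shannon = apply(counts, 1, shannonIndex),
    simpson = apply(counts, 1, simpsonIndex),
    chao1 = apply(counts, 1, chao1Richness),
    goods_coverage = apply(counts, 1, goodsCoverage),
    stringsAsFactors = FALSE)
  if (!is.null(fractions)) out$fraction <- fractions[out$sample_id]
  rownames(out) <- NULL
  out
}
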