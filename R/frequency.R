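#' Coverage-weighted gene frequency (percent)
#'
#' The frequency of a target gene set in a metagenome sample:
#' \deqn{frequency = \frac{\sum \mathrm{avg\ coverage\ of\ target\ genes} \times 100}
#'                        {\sum \mathrm{avg\ coverage\ of\ all\ genes}}}
#' Coverage is the per-gene average read depth as produced by standard
#' read-mapping pipelines; the scale cancels, so frequencies are invariant
#' under rescaling all coverages by a positive constant.
#'
#' @param target_gene_ids Character vector of target gene ids; must all be
#'   present in the coverage table.
#' @param coverage Named numeric vector of per-gene average coverages
#'   (e.g. from [readCoverageTable()]).
#' @return Frequency in percent, a number in \[0, 100\].
#' @export
#' @examples
#' cov <- c(g1 = 25, g2 = 175, g3 = 300)
#' geneFrequency("g1", cov)  # 5
geneFrequency <- function(target_gene_ids, coverage) {
  if (is.null(names(coverage))) stop("coverage must be a named vector")
  total <- sum(coverage)
  if (total <= 0) stop("total coverage is zero; frequency undefined")
  if (length(target_gene_ids) == 0) return(0)
  i <- match(target_gene_ids, names(coverage))
  if (anyNA(i)) {
    stop("target gene id(s) absent from coverage table: ",
         paste(target_gene_ids[is.na(i)], collapse = ", "))
  }
  sum(coverage[i]) * 100 / total
}

#' Per-substrate-class (optionally per-taxon) gene-frequency profile
#'
#' For every substrate class, the target set is the genes carrying at
#' least one degradative family mapping to that class; its frequency is
#' computed by [geneFrequency()]. A multi-substrate gene contributes its
#' full coverage to each of its classes, so class frequencies are not a
#' partition and need not sum to 100. With `group_by_taxon = TRUE` each
#' class frequency is split by the genes' taxon labels (genes without a
#' label aggregate under `"unclassified"`), and the taxon components sum
#' exactly to the class total.
#'
#' @param gene_table A [GeneTable-class].
#' @param coverage Named coverage vector covering every gene in the table.
#' @param substrate_map A [SubstrateMap-class].
#' @param group_by_taxon Split class frequencies by gene taxon.
#' @param sample_id Sample label stored in the output.
#' @return data.frame with columns `sample_id`, `substrate`, `taxon`
#'   (`NA` when not grouping) and `frequency` (percent).
#' @export
substrateFrequencyProfile <- function(gene_table, coverage, substrate_map,
                                      group_by_taxon = FALSE,
                                      sample_id = assemblyId(gene_table)) {
  stopifnot(is(gene_table, "GeneTable"), is(substrate_map, "SubstrateMap"))
  g <- geneData(gene_table)
  miss <- setdiff(g$gene_id, names(coverage))
  if (length(miss) > 0) {
    stop("coverage missing for gene(s): ", paste(head(miss, 5), collapse = ", "))
  }
  gene_classes <- lapply(g$families, function(fams) {
    deg <- fams[.deg_fast(fams)]
    if (length(deg) == 0) return(character(0))
    unique(unlist(lapply(deg, function(f) {
      hit <- substratesFor(substrate_map, f)
      if (length(hit) == 0) "unassigned" else hit
    })))
  })
  classes <- sort(unique(unlist(gene_classes)))
  rows <- list()
  for (cls in classes) {
    in_cls <- vapply(gene_classes, function(x) cls %in% x, logical(1))
    ids <- g$gene_id[in_cls]
    if (!group_by_taxon) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, substrate = cls, taxon = NA_character_,
        frequency = geneFrequency(ids, coverage), stringsAsFactors = FALSE)
    } else {
      tx <- g$taxon[in_cls]
      tx[is.na(tx)] <- "unclassified"
      for (t in sort(unique(tx))) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, substrate = cls, taxon = t,
          frequency = geneFrequency(ids[tx == t], coverage),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sample_id = character(0), substrate = character(0),
                      taxon = character(0), frequency = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble profiles into a long time-series table
#'
#' Binds per-sample frequency profiles into one tidy table with columns
#' `date`, `fraction`, `substrate`, `taxon`, `frequency`, sorted by date
#' (then fraction, substrate, taxon) — the shape stacked time-series bar
#' charts are drawn from.
#'
#' @param profiles List of profiles from [substrateFrequencyProfile()].
#' @param dates Vector of sampling dates (Date or coercible), one per
#'   profile.
#' @param fractions Character vector of fraction labels (e.g. FL, PA3,
#'   PA10), one per profile.
#' @return Sorted long-format data.frame.
#' @export
frequencyTimeseries <- function(profiles, dates, fractions) {
  if (length(profiles) == 0) stop("need at least one profile")
  if (length(dates) != length(profiles) || length(fractions) != length(profiles)) {
    stop("dates and fractions must parallel profiles")
  }
  dates <- as.Date(dates)
  key <- paste(dates, fractions)
  if (anyDuplicated(key)) {
    stop("duplicate (date, fraction) pair: ", key[duplicated(key)][1])
  }
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    if (nrow(p) == 0) return(NULL)
    data.frame(date = dates[i], fraction = fractions[i],
               substrate = p$substrate, taxon = p$taxon,
               frequency = p$frequency, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(date = as.Date(character(0)), fraction = character(0),
                      substrate = character(0), taxon = character(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$date, out$fraction, out$substrate, out$taxon,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
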