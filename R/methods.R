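#' Construct a GeneTable from a per-gene data.frame
#'
#' Sorts genes by start within each contig, assigns 0-based indices, and
#' validates all invariants. This is the low-level constructor used by
#' [readGeneTable()] and the synthetic-data generator.
#'
#' @param assembly_id Assembly name.
#' @param genes data.frame with at least `gene_id`, `contig_id`, `start`,
#'   `end`; optional `strand` (defaulting to "+", flagged in
#'   `strand_imputed`), `families` and `roles` (list columns or
#'   comma-separated strings), and `taxon`.
#' @return A [GeneTable-class].
#' @export
#' @examples
#' gt <- GeneTable("asm", data.frame(
#'   gene_id = c("g1", "g2"), contig_id = "c1",
#'   start = c(1, 500), end = c(300, 900), strand = "+"))
#' nGenes(gt)
GeneTable <- function(assembly_id, genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  n <- nrow(genes)
  if (is.null(genes$strand)) genes$strand <- rep(NA_character_, n)
  if (is.null(genes$strand_imputed)) genes$strand_imputed <- rep(FALSE, n)
  missing_strand <- is.na(genes$strand) | !genes$strand %in% c("+", "-")
  if (any(missing_strand)) {
    warning(sum(missing_strand), " gene(s) lack strand; defaulting to '+' ",
            "(these genes cannot anchor susCD tandems)")
    genes$strand[missing_strand] <- "+"
    genes$strand_imputed <- genes$strand_imputed | missing_strand
  }
  if (is.null(genes$families)) genes$families <- replicate(n, character(0), simplify = FALSE)
  if (is.character(genes$families)) genes$families <- .split_tokens(genes$families)
  if (is.null(genes$roles)) genes$roles <- replicate(n, character(0), simplify = FALSE)
  if (is.character(genes$roles)) genes$roles <- .split_tokens(genes$roles)
  if (is.null(genes$taxon)) genes$taxon <- rep(NA_character_, n)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  .validate_families(genes$families)
  .validate_roles(genes$roles)
  ord <- order(genes$contig_id, genes$start)
  genes <- genes[ord, , drop = FALSE]
  genes$index <- if (nrow(genes) == 0) {
    integer(0)
  } else {
    stats::ave(seq_len(nrow(genes)), genes$contig_id, FUN = seq_along) - 1L
  }
  rownames(genes) <- NULL
  genes <- genes[, .GENE_COLS, drop = FALSE]
  new("GeneTable", assemblyId = as.character(assembly_id), genes = genes)
}

#' @rdname GeneTable-class
#' @export
setMethod("assemblyId", "GeneTable", function(x) x@assemblyId)

#' @rdname GeneTable-class
#' @export
setMethod("geneData", "GeneTable", function(x) x@genes)

#' @rdname GeneTable-class
#' @export
setMethod("contigNames", "GeneTable", function(x) unique(x@genes$contig_id))

#' @rdname GeneTable-class
#' @export
setMethod("nGenes", "GeneTable", function(x) nrow(x@genes))

setMethod("show", "GeneTable", function(object) {
  g <- object@genes
  n_marker <- sum(vapply(seq_len(nrow(g)), function(i) {
    .is_marker_row(g$families[[i]], g$roles[[i]])
  }, logical(1)))
  cat("GeneTable '", object@assemblyId, "': ", nrow(g), " genes on ",
      length(unique(g$contig_id)), " contig(s); ", n_marker,
      " marker gene(s)\n", sep = "")
})

#' @rdname ClusterSet-class
#' @export
setMethod("assemblyId", "ClusterSet", function(x) x@assemblyId)

#' @rdname ClusterSet-class
#' @export
setMethod("clusterData", "ClusterSet", function(x) x@clusters)

#' @rdname ClusterSet-class
#' @export
setMethod("tiers", "ClusterSet", function(x) x@clusters$tier)

#' @rdname ClusterSet-class
#' @export
setMethod("nClusters", "ClusterSet", function(x) nrow(x@clusters))

#' @rdname ClusterSet-class
#' @export
setMethod("detectionParams", "ClusterSet", function(x) x@params)

setMethod("show", "ClusterSet", function(object) {
  cl <- object@clusters
  counts <- table(factor(cl$tier, levels = .TIERS))
  cat("ClusterSet '", object@assemblyId, "': ", nrow(cl), " cluster(s)\n",
      sep = "")
  cat("  PUL: ", counts[["PUL"]], "  PUL_LIKE: ", counts[["PUL_LIKE"]],
      "  CAZYME_RICH: ", counts[["CAZYME_RICH"]], "  UNCLASSIFIED: ",
      counts[["UNCLASSIFIED"]], "\n", sep = "")
})

setMethod("show", "DetectionParams", function(object) {
  cat("DetectionParams: window ", object@windowLength, " genes, >= ",
      object@minMarkers, " markers, tandem policy '", object@tandemPolicy,
      "', count ", if (object@countGenesNotDomains) "genes" else "domains",
      "\n", sep = "")
})

#' Look up the substrate classes of a family
#'
#' A subfamily label (e.g. `"GH13_8"`) is looked up directly first; when
#' absent from the map, the lookup falls back to the base family
#' (`"GH13"`). Unmapped families return `character(0)`.
#'
#' @param x A [SubstrateMap-class].
#' @param family Character vector of family labels.
#' @return For a single label a character vector of substrate classes; for
#'   several labels a named list.
#' @rdname SubstrateMap-class
#' @export
setMethod("substratesFor", "SubstrateMap", function(x, family) {
  one <- function(f) {
    hit <- x@entries[[f]]
    if (is.null(hit)) hit <- x@entries[[baseFamily(f)]]
    if (is.null(hit)) character(0) else hit
  }
  if (length(family) == 1) one(family) else setNames(lapply(family, one), family)
})

#' @rdname SubstrateMap-class
#' @export
setMethod("mappedFamilies", "SubstrateMap", function(x) names(x@entries))

setMethod("show", "SubstrateMap", function(object) {
  cat("SubstrateMap: ", length(object@entries), " family entries over ",
      length(unique(unlist(object@entries))), " substrate classes\n", sep = "")
})
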