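#' GeneTable: ordered, annotated genes of one assembly
#'
#' Container for the per-contig ordered gene models of one genome or
#' metagenome assembly, together with their CAZyme family and functional
#' role annotations. Coordinates are 1-based and inclusive; within each
#' contig genes are sorted by start coordinate and indexed consecutively
#' from 0 (slot column `index`).
#'
#' @slot assemblyId Single string naming the assembly.
#' @slot genes A data.frame with one row per gene and columns `gene_id`,
#'   `contig_id`, `start`, `end`, `strand`, `strand_imputed` (TRUE where
#'   strand was missing in the source and defaulted to "+"),
#'   `families` (list column of CAZyme family labels), `roles` (list column
#'   drawn from SUSC, SUSD, TBDT_OTHER, SULFATASE), `taxon` (character,
#'   NA allowed) and `index` (0-based rank along the contig).
#'
#' @seealso [readGeneTable()], [findCandidateLoci()]
#' @export
setClass("GeneTable",
  representation(assemblyId = "character", genes = "data.frame"))

.GENE_COLS <- c("gene_id", "contig_id", "start", "end", "strand",
                "strand_imputed", "families", "roles", "taxon", "index")

setValidity("GeneTable", function(object) {
  g <- object@genes
  msgs <- character(0)
  if (length(object@assemblyId) != 1) msgs <- c(msgs, "assemblyId must be a single string")
  missing_cols <- setdiff(.GENE_COLS, names(g))
  if (length(missing_cols) > 0) {
    return(paste("genes is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(g) == 0) return(TRUE)
  if (anyDuplicated(g$gene_id)) msgs <- c(msgs, "duplicate gene_id")
  if (any(g$start < 1)) msgs <- c(msgs, "start coordinates must be >= 1")
  if (any(g$end < g$start)) msgs <- c(msgs, "end must be >= start")
  if (!all(g$strand %in% c("+", "-"))) msgs <- c(msgs, "strand must be '+' or '-'")
  fams <- unlist(g$families, use.names = FALSE)
  if (length(fams) > 0 && !all(grepl(.FAMILY_PATTERN, fams))) {
    msgs <- c(msgs, "malformed CAZyme family label")
  }
  roles <- unlist(g$roles, use.names = FALSE)
  if (length(roles) > 0 && !all(roles %in% .ROLE_TOKENS)) {
    msgs <- c(msgs, "unknown role token")
  }
  for (ct in split(g, g$contig_id)) {
    ord <- order(ct$start)
    idx <- sort(ct$index)
    if (!identical(idx, seq(0L, nrow(ct) - 1L))) {
      msgs <- c(msgs, "indices within a contig must be consecutive from 0")
      break
    }
    if (is.unsorted(ct$start[order(ct$index)])) {
      msgs <- c(msgs, "genes must be index-ordered by start coordinate")
      break
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' DetectionParams: sliding-window detection parameters
#'
#' Tunable parameters of the CAZyme-cluster sliding-window detector.
#'
#' @slot windowLength Window length in genes (default 10).
#' @slot minMarkers Minimum marker genes within a window for a hit
#'   (default 3).
#' @slot tandemPolicy Either `"same_strand_adjacent"` (default; a susCD
#'   tandem requires adjacent genes on the same strand) or
#'   `"adjacent_any_strand"`.
#' @slot countGenesNotDomains If TRUE, the CAZyme-rich threshold counts
#'   genes carrying at least one degradative family; if FALSE (default),
#'   every degradative family instance of a multi-domain gene counts.
#'
#' @export
setClass("DetectionParams",
  representation(windowLength = "integer", minMarkers = "integer",
                 tandemPolicy = "character", countGenesNotDomains = "logical"))

setValidity("DetectionParams", function(object) {
  msgs <- character(0)
  if (object@windowLength < 1L) msgs <- c(msgs, "windowLength must be >= 1")
  if (object@minMarkers < 1L || object@minMarkers > object@windowLength) {
    msgs <- c(msgs, "minMarkers must satisfy 1 <= minMarkers <= windowLength")
  }
  if (!object@tandemPolicy %in% c("same_strand_adjacent", "adjacent_any_strand")) {
    msgs <- c(msgs, "tandemPolicy must be 'same_strand_adjacent' or 'adjacent_any_strand'")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct detection parameters
#'
#' @param windowLength Sliding-window length in genes.
#' @param minMarkers Minimum number of marker genes per window.
#' @param tandemPolicy susCD tandem adjacency policy; see
#'   [detectSusCDTandem()].
#' @param countGenesNotDomains Count degradative genes rather than
#'   degradative family instances for the CAZyme-rich threshold.
#' @return A [DetectionParams-class] object.
#' @export
#' @examples
#' DetectionParams()
#' DetectionParams(windowLength = 5, minMarkers = 2)
DetectionParams <- function(windowLength = 10L, minMarkers = 3L,
                            tandemPolicy = c("same_strand_adjacent",
                                             "adjacent_any_strand"),
                            countGenesNotDomains = FALSE) {
  tandemPolicy <- match.arg(tandemPolicy)
  new("DetectionParams", windowLength = as.integer(windowLength),
      minMarkers = as.integer(minMarkers), tandemPolicy = tandemPolicy,
      countGenesNotDomains = isTRUE(countGenesNotDomains))
}

#' SubstrateMap: CAZyme family to substrate-class mapping
#'
#' Maps CAZyme family labels (optionally with subfamily, e.g. `"GH13_8"`)
#' to one or more polysaccharide substrate classes from the controlled
#' vocabulary ([substrateVocabulary()]). Lookups with a subfamily label
#' fall back to the base family when no subfamily-specific entry exists.
#'
#' @slot entries Named list; names are family labels, values character
#'   vectors of substrate classes.
#'
#' @seealso [readSubstrateMap()], [substratesFor()]
#' @export
setClass("SubstrateMap", representation(entries = "list"))

setValidity("SubstrateMap", function(object) {
  e <- object@entries
  msgs <- character(0)
  if (length(e) > 0) {
    if (is.null(names(e)) || any(!nzchar(names(e)))) {
      msgs <- c(msgs, "entries must be a named list keyed by family label")
    } else if (!all(grepl(.FAMILY_PATTERN, names(e)))) {
      msgs <- c(msgs, "malformed family label in map")
    }
    subs <- unlist(e, use.names = FALSE)
    bad <- setdiff(subs, substrateVocabulary())
    if (length(bad) > 0) {
      msgs <- c(msgs, paste("unknown substrate label(s):",
                            paste(unique(bad), collapse = ", ")))
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' ClusterSet: detected CAZyme clusters of one assembly
#'
#' Result container of [detectClusters()]: one row per detected locus with
#' its genomic span, classification tier (PUL, PUL_LIKE, CAZYME_RICH or
#' UNCLASSIFIED), marker bookkeeping and degradative-family content.
#'
#' @slot assemblyId Assembly the clusters were detected in.
#' @slot clusters data.frame with columns `cluster_id`, `contig_id`,
#'   `first_index`, `last_index`, `first_gene_id`, `last_gene_id`, `start`,
#'   `end`, `n_genes`, `tier`, `has_susCD_tandem`, `tbdt_like_count`,
#'   `sulfatase_count`, `degradative_count` and list columns `gene_ids`,
#'   `marker_gene_ids`, `degradative_families`.
#' @slot params The [DetectionParams-class] used for detection.
#'
#' @export
setClass("ClusterSet",
  representation(assemblyId = "character", clusters = "data.frame",
                 params = "DetectionParams"))

.CLUSTER_COLS <- c("cluster_id", "contig_id", "first_index", "last_index",
                   "first_gene_id", "last_gene_id", "start", "end", "n_genes",
                   "tier", "has_susCD_tandem", "tbdt_like_count",
                   "sulfatase_count", "degradative_count", "gene_ids",
                   "marker_gene_ids", "degradative_families")

setValidity("ClusterSet", function(object) {
  cl <- object@clusters
  missing_cols <- setdiff(.CLUSTER_COLS, names(cl))
  if (length(missing_cols) > 0) {
    return(paste("clusters is missing columns:",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cl) == 0) return(TRUE)
  msgs <- character(0)
  if (!all(cl$tier %in% .TIERS)) msgs <- c(msgs, "invalid tier label")
  if (any(cl$last_index < cl$first_index)) msgs <- c(msgs, "last_index < first_index")
  ok_pul <- cl$tier != "PUL" | (cl$has_susCD_tandem & cl$degradative_count >= 1)
  ok_pull <- cl$tier != "PUL_LIKE" |
    (!cl$has_susCD_tandem & cl$tbdt_like_count >= 1 & cl$degradative_count >= 1)
  ok_rich <- cl$tier != "CAZYME_RICH" | (cl$degradative_count >= 3 & cl$tbdt_like_count == 0)
  if (!all(ok_pul)) msgs <- c(msgs, "PUL tier invariant violated")
  if (!all(ok_pull)) msgs <- c(msgs, "PUL_LIKE tier invariant violated")
  if (!all(ok_rich)) msgs <- c(msgs, "CAZYME_RICH tier invariant violated")
  if (length(msgs) == 0) TRUE else msgs
})
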