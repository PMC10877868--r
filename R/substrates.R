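#' Predict target substrate classes of a cluster
#'
#' For each substrate class in the map, counts the cluster genes carrying
#' at least one degradative family (GH/PL/CE) mapping to that class. A
#' multi-substrate gene supports every class its families map to. Genes
#' whose degradative families all lack a map entry are tallied under the
#' reserved class `"unassigned"`. Classes are returned sorted by
#' descending supporting-gene count, ties broken alphabetically.
#'
#' @param cluster One cluster row (as in [clusterData()]), any object with
#'   a `gene_ids` list column resolvable in `gene_table`, or a one-row
#'   data.frame carrying a `degradative_families` list column when
#'   `gene_table` is omitted (per-gene resolution then treats each family
#'   instance as one gene, which is exact for single-domain genes).
#' @param substrate_map A [SubstrateMap-class].
#' @param gene_table Optional [GeneTable-class] to resolve the per-gene
#'   family sets of the cluster.
#' @return data.frame with columns `substrate_class`,
#'   `supporting_gene_count`, and the list column `supporting_families`.
#'   Empty (zero rows) when the cluster has no degradative family.
#' @export
#' @examples
#' gt <- GeneTable("a", data.frame(
#'   gene_id = c("g1", "g2"), contig_id = "c", start = c(1, 100),
#'   end = c(50, 150), strand = "+", families = c("GH16", "GH17")))
#' cs <- detectClusters(gt, DetectionParams(windowLength = 2, minMarkers = 2))
#' predictSubstrates(clusterData(cs)[1, ], readSubstrateMap(), gt)
predictSubstrates <- function(cluster, substrate_map, gene_table = NULL) {
  stopifnot(is(substrate_map, "SubstrateMap"))
  fam_sets <- .cluster_gene_family_sets(cluster, gene_table)
  tallies <- list()
  support <- list()
  for (fams in fam_sets) {
    deg <- fams[.deg_fast(fams)]
    if (length(deg) == 0) next
    classes <- unique(unlist(lapply(deg, function(f) {
      hit <- substratesFor(substrate_map, f)
      if (length(hit) == 0) "unassigned" else hit
    })))
    for (cls in classes) {
      tallies[[cls]] <- (tallies[[cls]] %||% 0L) + 1L
      mapped <- deg[vapply(deg, function(f) {
        hit <- substratesFor(substrate_map, f)
        if (length(hit) == 0) cls == "unassigned" else cls %in% hit
      }, logical(1))]
      support[[cls]] <- union(support[[cls]] %||% character(0), mapped)
    }
  }
  if (length(tallies) == 0) {
    out <- data.frame(substrate_class = character(0),
                      supporting_gene_count = integer(0),
                      stringsAsFactors = FALSE)
    out$supporting_families <- list()
    return(out)
  }
  cls <- names(tallies)
  cnt <- unlist(tallies, use.names = FALSE)
  ord <- order(-cnt, cls)
  out <- data.frame(substrate_class = cls[ord],
                    supporting_gene_count = as.integer(cnt[ord]),
                    stringsAsFactors = FALSE)
  out$supporting_families <- lapply(support[cls[ord]], sort)
  rownames(out) <- NULL
  out
}

.cluster_gene_family_sets <- function(cluster, gene_table) {
  if (!is.null(gene_table)) {
    ids <- if (is.list(cluster$gene_ids)) cluster$gene_ids[[1]] else cluster$gene_ids
    g <- geneData(gene_table)
    sel <- match(ids, g$gene_id)
    if (anyNA(sel)) stop("cluster gene(s) absent from gene table")
    return(g$families[sel])
  }
  fams <- if (is.list(cluster$degradative_families)) {
    cluster$degradative_families[[1]]
  } else {
    cluster$degradative_families
  }
  as.list(fams)
}

#' Type a cluster against the alpha-glucan PUL typology
#'
#' Alpha-glucan PULs fall into four recurrent composition types over the
#' hallmark amylolytic families GH13, GH31, GH57, GH65 and GH77
#' (subfamilies collapsed; families outside this alphabet are accessory
#' and ignored):
#' type I: only GH13; type II: GH13 and GH65, optionally plus GH31;
#' type III: GH13, GH77 and GH57; type IV: only GH13 and GH31. Everything
#' else (including clusters lacking GH13) is `"none"`.
#'
#' @param cluster A cluster row or any object carrying GH families (a
#'   `degradative_families` list column, or a plain character vector of
#'   family labels).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"none"`.
#' @export
#' @examples
#' typeAlphaGlucanPul(c("GH13", "GH65", "GH31"))
typeAlphaGlucanPul <- function(cluster) {
  f <- .restricted_families(cluster, c("GH13", "GH31", "GH57", "GH65", "GH77"))
  if (setequal(f, "GH13")) return("I")
  if (setequal(f, c("GH13", "GH65")) || setequal(f, c("GH13", "GH65", "GH31"))) return("II")
  if (setequal(f, c("GH13", "GH77", "GH57"))) return("III")
  if (setequal(f, c("GH13", "GH31"))) return("IV")
  "none"
}

#' Type a cluster against the beta-glucan (laminarin) PUL typology
#'
#' Beta-glucan PULs are typed over the hallmark laminarinase-related
#' families GH3, GH16, GH17, GH30, GH149 and GH158 (subfamilies
#' collapsed, accessory families ignored), with precedence
#' GH16-only > variant-2 > variant-1:
#' \itemize{
#'   \item `"GH16-only"`: the restricted set is exactly \{GH16\};
#'   \item `"variant-2"`: GH3 together with GH16 or GH17 and nothing
#'     outside \{GH3, GH16, GH17\};
#'   \item `"variant-1"`: at least `min_hallmarks` of the five hallmark
#'     families GH149, GH17, GH16, GH158, GH30 (partial rosters count as
#'     variations of the full cassette);
#'   \item `"none"` otherwise.
#' }
#'
#' @inheritParams typeAlphaGlucanPul
#' @param min_hallmarks Minimum number of the five variant-1 hallmark
#'   families required (default 3).
#' @return One of `"variant-1"`, `"variant-2"`, `"GH16-only"`, `"none"`.
#' @export
#' @examples
#' typeBetaGlucanPul(c("GH149", "GH17", "GH16", "GH158", "GH30"))
#' typeBetaGlucanPul(c("GH17", "GH3"))
typeBetaGlucanPul <- function(cluster, min_hallmarks = 3L) {
  f <- .restricted_families(cluster, c("GH3", "GH16", "GH17", "GH30",
                                       "GH149", "GH158"))
  if (setequal(f, "GH16")) return("GH16-only")
  if ("GH3" %in% f && any(c("GH16", "GH17") %in% f) &&
      all(f %in% c("GH3", "GH16", "GH17"))) {
    return("variant-2")
  }
  hallmark <- c("GH149", "GH17", "GH16", "GH158", "GH30")
  if (sum(hallmark %in% f) >= min_hallmarks) return("variant-1")
  "none"
}

.restricted_families <- function(cluster, alphabet) {
  fams <- if (is.character(cluster)) {
    cluster
  } else if (is.list(cluster$degradative_families)) {
    cluster$degradative_families[[1]]
  } else {
    cluster$degradative_families
  }
  if (length(fams) == 0) return(character(0))
  intersect(unique(baseFamily(fams)), alphabet)
}
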