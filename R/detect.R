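.is_marker_row <- function(families, roles) {
  if (length(roles) > 0 &&
      any(roles %in% c("SULFATASE", "SUSC", "SUSD", "TBDT_OTHER"))) {
    return(TRUE)
  }
  length(families) > 0 && any(.deg_fast(families))
}

#' Is a gene a cluster-detection marker?
#'
#' Marker genes drive the sliding-window locus detection: genes coding for
#' degradative CAZymes (GH, PL or CE families), sulfatases, SusC-like or
#' SusD-like proteins, or other TonB-dependent transporters. GT, CBM and
#' AA families alone do not qualify.
#'
#' @param gene_table A [GeneTable-class].
#' @return Logical vector, one element per gene in table order.
#' @export
#' @examples
#' gt <- GeneTable("a", data.frame(
#'   gene_id = c("g1", "g2"), contig_id = "c", start = c(1, 50),
#'   end = c(30, 90), strand = "+",
#'   families = c("GH16", "GT2"), roles = c("", "")))
#' isMarker(gt)
isMarker <- function(gene_table) {
  stopifnot(is(gene_table, "GeneTable"))
  g <- geneData(gene_table)
  vapply(seq_len(nrow(g)), function(i) {
    .is_marker_row(g$families[[i]], g$roles[[i]])
  }, logical(1))
}

# Window starts for a contig of n genes: step 1, length W; a contig shorter
# than W is covered by a single whole-contig window.
.window_starts <- function(n, w) {
  if (n <= w) return(list(starts = 1L, len = n))
  list(starts = seq_len(n - w + 1L), len = w)
}

#' Find candidate CAZyme-rich loci by sliding window
#'
#' Slides a window of `windowLength` consecutive genes (step one gene)
#' along each contig; every window holding at least `minMarkers` marker
#' genes ([isMarker()]) is a hit. Overlapping or adjacent hit windows on
#' the same contig are merged into maximal runs, and each run is trimmed so
#' that its first and last genes are markers. Windows never span contigs;
#' contigs shorter than the window are assessed as one whole-contig window.
#'
#' @param gene_table A [GeneTable-class].
#' @param params A [DetectionParams-class].
#' @return data.frame with one row per candidate locus: `contig_id`,
#'   `first_index`, `last_index` (0-based inclusive gene indices) and the
#'   list column `marker_gene_ids`.
#' @export
#' @examples
#' gt <- GeneTable("a", data.frame(
#'   gene_id = paste0("g", 1:10), contig_id = "c",
#'   start = seq(1, by = 1000, length.out = 10),
#'   end = seq(900, by = 1000, length.out = 10), strand = "+",
#'   families = c("", "", "GH16", "", "", "GH3", "", "", "PL7", "")))
#' findCandidateLoci(gt, DetectionParams())
findCandidateLoci <- function(gene_table, params = DetectionParams()) {
  stopifnot(is(gene_table, "GeneTable"), is(params, "DetectionParams"))
  g <- geneData(gene_table)
  out <- list()
  if (nrow(g) == 0) return(.empty_locus_frame())
  marker <- isMarker(gene_table)
  w <- params@windowLength
  k <- params@minMarkers
  row_of <- split(seq_len(nrow(g)), g$contig_id)[unique(g$contig_id)]
  for (ct in names(row_of)) {
    sel <- row_of[[ct]]
    sel <- sel[order(g$index[sel])]
    m <- marker[sel]
    n <- length(sel)
    win <- .window_starts(n, w)
    cs <- cumsum(c(0L, as.integer(m)))
    hits <- win$starts[cs[win$starts + win$len] - cs[win$starts] >= k]
    if (length(hits) == 0) next
    # merge overlapping/adjacent hit windows into maximal covered runs
    runs <- .merge_windows(hits, win$len, n)
    for (r in seq_len(nrow(runs))) {
      lo <- runs$lo[r]; hi <- runs$hi[r]
      in_run <- lo:hi
      mk <- in_run[m[in_run]]
      lo2 <- min(mk); hi2 <- max(mk)
      rows <- sel[lo2:hi2]
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ct,
        first_index = g$index[sel[lo2]],
        last_index = g$index[sel[hi2]],
        stringsAsFactors = FALSE)
      out[[length(out)]]$marker_gene_ids <-
        list(g$gene_id[rows][m[lo2:hi2]])
    }
  }
  if (length(out) == 0) return(.empty_locus_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_locus_frame <- function() {
  data.frame(contig_id = character(0), first_index = integer(0),
             last_index = integer(0),
             marker_gene_ids = I(list()))[, c("contig_id", "first_index",
                                             "last_index", "marker_gene_ids")]
}

# hit window start positions (1-based within contig) -> merged covered runs
.merge_windows <- function(hit_starts, len, n) {
  lo <- hit_starts
  hi <- pmin(hit_starts + len - 1L, n)
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  out_lo <- lo[1]; out_hi <- hi[1]
  if (length(lo) > 1) {
    for (i in 2:length(lo)) {
      if (lo[i] <= out_hi[length(out_hi)] + 1L) {
        out_hi[length(out_hi)] <- max(out_hi[length(out_hi)], hi[i])
      } else {
        out_lo <- c(out_lo, lo[i]); out_hi <- c(out_hi, hi[i])
      }
    }
  }
  data.frame(lo = out_lo, hi = out_hi)
}

#' Detect a susCD gene tandem within a locus
#'
#' A susCD tandem is a pair of genes at consecutive positions along the
#' contig, one carrying the SUSC role and the other SUSD (either order).
#' Under the default `same_strand_adjacent` policy the two genes must also
#' lie on the same strand, reflecting co-transcription of the pair; genes
#' whose strand was imputed at read time cannot anchor a tandem under this
#' policy. `adjacent_any_strand` drops the strand requirement.
#'
#' @param genes data.frame of the locus genes ordered by index (as sliced
#'   from [geneData()]).
#' @param tandem_policy `"same_strand_adjacent"` or `"adjacent_any_strand"`.
#' @return List with `found` (logical) and `positions` (integer vector of
#'   the first-gene row offsets of every tandem found, possibly empty).
#' @export
detectSusCDTandem <- function(genes,
                              tandem_policy = c("same_strand_adjacent",
                                                "adjacent_any_strand")) {
  tandem_policy <- match.arg(tandem_policy)
  n <- nrow(genes)
  pos <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      r1 <- genes$roles[[i]]; r2 <- genes$roles[[i + 1L]]
      pair <- ("SUSC" %in% r1 && "SUSD" %in% r2) ||
              ("SUSD" %in% r1 && "SUSC" %in% r2)
      if (!pair) next
      if (tandem_policy == "same_strand_adjacent") {
        if (genes$strand[i] != genes$strand[i + 1L]) next
        if (isTRUE(genes$strand_imputed[i]) || isTRUE(genes$strand_imputed[i + 1L])) next
      }
      pos <- c(pos, i)
    }
  }
  list(found = length(pos) > 0, positions = pos)
}

#' Classify a candidate locus into a cluster tier
#'
#' Applies the three-tier rule with strict precedence
#' PUL > PUL_LIKE > CAZYME_RICH > UNCLASSIFIED:
#' \itemize{
#'   \item PUL: a susCD gene tandem plus at least one degradative CAZyme;
#'   \item PUL_LIKE: at least one susC-like, susD-like or other TBDT gene
#'     plus at least one degradative CAZyme (and no tandem);
#'   \item CAZYME_RICH: at least three degradative CAZymes and no
#'     transporter gene;
#'   \item UNCLASSIFIED: everything else.
#' }
#' By default every degradative family instance of a multi-domain gene
#' counts towards the CAZyme-rich threshold; set
#' `countGenesNotDomains = TRUE` in the params to count genes instead.
#'
#' @param locus One row of the [findCandidateLoci()] result (or any list
#'   with `contig_id`, `first_index`, `last_index`).
#' @param gene_table The [GeneTable-class] the locus was detected in.
#' @param params A [DetectionParams-class].
#' @return One-row data.frame in [ClusterSet-class] column layout.
#' @export
classifyCluster <- function(locus, gene_table, params = DetectionParams()) {
  g <- geneData(gene_table)
  sel <- which(g$contig_id == locus$contig_id &
               g$index >= locus$first_index & g$index <= locus$last_index)
  if (length(sel) != locus$last_index - locus$first_index + 1L) {
    stop("locus indices out of range for contig ", locus$contig_id)
  }
  sel <- sel[order(g$index[sel])]
  .classify_genes(g[sel, , drop = FALSE], locus, params)
}

# classification core on an index-ordered gene slice of one locus
.classify_genes <- function(genes, locus, params) {
  fams <- unlist(genes$families, use.names = FALSE)
  deg_fams <- fams[.deg_fast(fams)]
  deg_per_gene <- vapply(genes$families, function(f) {
    if (length(f) == 0) 0L else sum(.deg_fast(f))
  }, integer(1))
  deg_count <- if (params@countGenesNotDomains) sum(deg_per_gene > 0) else length(deg_fams)
  tandem <- detectSusCDTandem(genes, params@tandemPolicy)
  tbdt_like <- sum(vapply(genes$roles, function(r) {
    any(r %in% c("SUSC", "SUSD", "TBDT_OTHER"))
  }, logical(1)))
  sulf <- sum(vapply(genes$roles, function(r) "SULFATASE" %in% r, logical(1)))
  tier <- if (tandem$found && deg_count >= 1) {
    "PUL"
  } else if (tbdt_like >= 1 && deg_count >= 1) {
    "PUL_LIKE"
  } else if (deg_count >= 3 && tbdt_like == 0) {
    "CAZYME_RICH"
  } else {
    "UNCLASSIFIED"
  }
  marker <- vapply(seq_len(nrow(genes)), function(i) {
    .is_marker_row(genes$families[[i]], genes$roles[[i]])
  }, logical(1))
  out <- data.frame(
    cluster_id = NA_character_,
    contig_id = locus$contig_id,
    first_index = locus$first_index,
    last_index = locus$last_index,
    first_gene_id = genes$gene_id[1],
    last_gene_id = genes$gene_id[nrow(genes)],
    start = min(genes$start),
    end = max(genes$end),
    n_genes = nrow(genes),
    tier = tier,
    has_susCD_tandem = tandem$found,
    tbdt_like_count = tbdt_like,
    sulfatase_count = sulf,
    degradative_count = deg_count,
    stringsAsFactors = FALSE)
  out$gene_ids <- list(genes$gene_id)
  out$marker_gene_ids <- list(genes$gene_id[marker])
  out$degradative_families <- list(deg_fams)
  out
}

#' Detect and classify all CAZyme clusters of an assembly
#'
#' Runs [findCandidateLoci()] followed by [classifyCluster()] on every
#' locus and returns the tiered result as a [ClusterSet-class].
#'
#' @inheritParams findCandidateLoci
#' @return A [ClusterSet-class].
#' @export
#' @examples
#' gt <- GeneTable("a", data.frame(
#'   gene_id = paste0("g", 1:5), contig_id = "c",
#'   start = seq(1, by = 1000, length.out = 5),
#'   end = seq(900, by = 1000, length.out = 5), strand = "+",
#'   families = c("", "", "GH16", "GH17", ""),
#'   roles = c("SUSC", "SUSD", "", "", "")))
#' detectClusters(gt)
detectClusters <- function(gene_table, params = DetectionParams()) {
  loci <- findCandidateLoci(gene_table, params)
  if (nrow(loci) == 0) {
    return(new("ClusterSet", assemblyId = assemblyId(gene_table),
               clusters = .empty_cluster_frame(), params = params))
  }
  g <- geneData(gene_table)
  row_of <- split(seq_len(nrow(g)), g$contig_id)
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    sel <- row_of[[loci$contig_id[i]]]
    sel <- sel[g$index[sel] >= loci$first_index[i] &
                 g$index[sel] <= loci$last_index[i]]
    sel <- sel[order(g$index[sel])]
    .classify_genes(g[sel, , drop = FALSE], loci[i, , drop = FALSE], params)
  })
  cl <- do.call(rbind, rows)
  cl$cluster_id <- sprintf("%s_cluster_%03d", assemblyId(gene_table),
                           seq_len(nrow(cl)))
  rownames(cl) <- NULL
  new("ClusterSet", assemblyId = assemblyId(gene_table), clusters = cl,
      params = params)
}

.empty_cluster_frame <- function() {
  cl <- data.frame(
    cluster_id = character(0), contig_id = character(0),
    first_index = integer(0), last_index = integer(0),
    first_gene_id = character(0), last_gene_id = character(0),
    start = integer(0), end = integer(0), n_genes = integer(0),
    tier = character(0), has_susCD_tandem = logical(0),
    tbdt_like_count = integer(0), sulfatase_count = integer(0),
    degradative_count = integer(0), stringsAsFactors = FALSE)
  cl$gene_ids <- list()
  cl$marker_gene_ids <- list()
  cl$degradative_families <- list()
  cl
}
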