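#' Read a GFF3 file plus sidecar annotation table into a GeneTable
#'
#' CDS features of the GFF3 file define the gene models (1-based inclusive
#' coordinates, as in GFF); the sidecar TSV carries the functional
#' annotation in dbCAN style. Annotation lives in the sidecar rather than
#' in GFF attributes so any GFF dialect with `ID` attributes works.
#'
#' The annotation table must have columns `gene_id`, `cazyme_families`
#' (comma-separated, may be empty), `roles` (comma-separated subset of
#' SUSC, SUSD, TBDT_OTHER, SULFATASE; may be empty) and optionally
#' `taxon`. Genes present in the GFF but absent from the table get empty
#' annotations; annotation rows naming an unknown gene are an error.
#'
#' @param gff_path Path to a GFF3 file with CDS features carrying `ID`
#'   attributes.
#' @param annotation_table_path Path to the annotation TSV, or `NULL` for
#'   no annotation.
#' @param assembly_id Assembly name; defaults to the GFF basename.
#' @return A [GeneTable-class].
#' @export
readGeneTable <- function(gff_path, annotation_table_path = NULL,
                          assembly_id = NULL) {
  if (!file.exists(gff_path)) stop("GFF file not found: ", gff_path)
  .prescan_gff(gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  if (length(gr) == 0) stop("no CDS features in ", gff_path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stop("CDS feature(s) without ID attribute in ", gff_path)
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in GFF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- NA_character_
  genes <- data.frame(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  if (!is.null(annotation_table_path)) {
    ann <- read.delim(annotation_table_path, sep = "\t",
                      colClasses = "character", stringsAsFactors = FALSE)
    req <- c("gene_id", "cazyme_families", "roles")
    missing_cols <- setdiff(req, names(ann))
    if (length(missing_cols) > 0) {
      stop("annotation table missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    if (anyDuplicated(ann$gene_id)) {
      stop("duplicate gene_id in annotation table: ",
           paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
    }
    unknown <- setdiff(ann$gene_id, genes$gene_id)
    if (length(unknown) > 0) {
      stop("annotation rows with unknown gene_id: ",
           paste(unknown, collapse = ", "))
    }
    fams <- .split_tokens(ann$cazyme_families)
    roles <- .split_tokens(ann$roles)
    .validate_families(fams)
    .validate_roles(roles)
    i <- match(genes$gene_id, ann$gene_id)
    genes$families <- replicate(nrow(genes), character(0), simplify = FALSE)
    genes$families[!is.na(i)] <- fams[i[!is.na(i)]]
    genes$roles <- replicate(nrow(genes), character(0), simplify = FALSE)
    genes$roles[!is.na(i)] <- roles[i[!is.na(i)]]
    if (!is.null(ann$taxon)) {
      tx <- ann$taxon[i]
      tx[!is.na(tx) & !nzchar(tx)] <- NA_character_
      genes$taxon <- tx
    }
  }
  if (is.null(assembly_id)) {
    assembly_id <- sub("\\.gff3?$", "", basename(gff_path))
  }
  GeneTable(assembly_id, genes)
}

# cheap structural validation so malformed lines are reported by number;
# full parsing is delegated to rtracklayer
.prescan_gff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield != 9L]
  if (length(bad) > 0) {
    stop("malformed GFF line ", bad[1], ": expected 9 tab-separated fields, got ",
         nfield[match(bad[1], which(body))])
  }
  invisible(TRUE)
}

#' Write a GeneTable as GFF3 plus annotation TSV
#'
#' Inverse of [readGeneTable()]; the pair round-trips all gene fields.
#'
#' @param gene_table A [GeneTable-class].
#' @param gff_path Output GFF3 path.
#' @param annotation_table_path Output annotation TSV path.
#' @return Invisibly, the two paths.
#' @export
writeGeneTable <- function(gene_table, gff_path, annotation_table_path) {
  g <- geneData(gene_table)
  lines <- c("##gff-version 3",
             sprintf("%s\tpulgate\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     g$contig_id, g$start, g$end, g$strand, g$gene_id))
  writeLines(lines, gff_path)
  ann <- data.frame(
    gene_id = g$gene_id,
    cazyme_families = vapply(g$families, paste, character(1), collapse = ","),
    roles = vapply(g$roles, paste, character(1), collapse = ","),
    taxon = ifelse(is.na(g$taxon), "", g$taxon),
    stringsAsFactors = FALSE)
  write.table(ann, annotation_table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(gff_path, annotation_table_path))
}

#' Read (or load the packaged default) substrate map
#'
#' The TSV must have columns `family` and `substrates`
#' (semicolon-separated labels from [substrateVocabulary()]). Duplicate
#' family rows are unioned. When `path` is omitted the map packaged with
#' pulgate is loaded: a curated approximation of dbCAN-sub style
#' family-to-substrate assignments covering the common algal and bacterial
#' polysaccharide classes.
#'
#' @param path Path to a substrate-map TSV, or `NULL` for the packaged
#'   default.
#' @return A [SubstrateMap-class].
#' @export
#' @examples
#' m <- readSubstrateMap()
#' substratesFor(m, "GH16")
readSubstrateMap <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "substrate_map.tsv", package = "pulgate",
                        mustWork = TRUE)
  }
  tab <- read.delim(path, sep = "\t", colClasses = "character",
                    stringsAsFactors = FALSE)
  if (!all(c("family", "substrates") %in% names(tab))) {
    stop("substrate map must have columns 'family' and 'substrates'")
  }
  subs <- .split_tokens(tab$substrates, sep = ";")
  entries <- list()
  for (i in seq_len(nrow(tab))) {
    f <- tab$family[i]
    entries[[f]] <- sort(union(entries[[f]], subs[[i]]))
  }
  new("SubstrateMap", entries = entries)
}

#' Write a cluster report
#'
#' One record per cluster with assembly, contig, gene span (first/last
#' gene and coordinates), tier, marker counts, degradative family list and
#' substrate predictions. TSV and JSON carry identical content; list
#' fields are comma-separated in TSV.
#'
#' @param clusters A [ClusterSet-class].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param substrate_map Optional [SubstrateMap-class]; when given, each
#'   record carries the [predictSubstrates()] headline calls.
#' @return Invisibly, `path`.
#' @export
writeClusterReport <- function(clusters, path, format = c("tsv", "json"),
                               substrate_map = NULL) {
  format <- match.arg(format)
  stopifnot(is(clusters, "ClusterSet"))
  cl <- clusterData(clusters)
  rec <- data.frame(
    assembly_id = rep(assemblyId(clusters), nrow(cl)),
    cluster_id = cl$cluster_id,
    contig_id = cl$contig_id,
    first_gene_id = cl$first_gene_id,
    last_gene_id = cl$last_gene_id,
    start = cl$start,
    end = cl$end,
    first_index = cl$first_index,
    last_index = cl$last_index,
    n_genes = cl$n_genes,
    tier = cl$tier,
    has_susCD_tandem = cl$has_susCD_tandem,
    tbdt_like_count = cl$tbdt_like_count,
    sulfatase_count = cl$sulfatase_count,
    degradative_count = cl$degradative_count,
    stringsAsFactors = FALSE)
  deg <- vapply(cl$degradative_families, paste, character(1), collapse = ",")
  substr_calls <- rep("", nrow(cl))
  if (!is.null(substrate_map) && nrow(cl) > 0) {
    substr_calls <- vapply(seq_len(nrow(cl)), function(i) {
      p <- predictSubstrates(cl[i, , drop = FALSE], substrate_map)
      paste(p$substrate_class, collapse = ",")
    }, character(1))
  }
  if (format == "tsv") {
    rec$degradative_families <- deg
    rec$substrates <- substr_calls
    write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(rec)), function(i) {
      r <- as.list(rec[i, , drop = FALSE])
      r$degradative_families <- cl$degradative_families[[i]]
      r$substrates <- if (nzchar(substr_calls[i])) {
        strsplit(substr_calls[i], ",", fixed = TRUE)[[1]]
      } else {
        character(0)
      }
      r
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a cluster report written by [writeClusterReport()]
#'
#' @param path Report path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame of cluster records (list columns for families and
#'   substrates).
#' @export
readClusterReport <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    rec <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = c(degradative_families = "character",
                                     substrates = "character"))
    rec$degradative_families <- .split_tokens(rec$degradative_families)
    rec$substrates <- .split_tokens(rec$substrates)
    rec
  } else {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (length(recs) == 0) return(.empty_report_frame())
    flat <- lapply(recs, function(r) {
      scalars <- r[!names(r) %in% c("degradative_families", "substrates")]
      as.data.frame(scalars, stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, flat)
    rec$degradative_families <- lapply(recs, function(r) {
      unlist(r$degradative_families) %||% character(0)
    })
    rec$substrates <- lapply(recs, function(r) {
      unlist(r$substrates) %||% character(0)
    })
    rec
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_report_frame <- function() {
  rec <- data.frame(assembly_id = character(0), cluster_id = character(0),
                    contig_id = character(0), stringsAsFactors = FALSE)
  rec$degradative_families <- list()
  rec$substrates <- list()
  rec
}

#' Read a per-gene average-coverage table
#'
#' @param path TSV with columns `gene_id` and `avg_coverage`.
#' @return Named numeric vector of coverages keyed by gene_id.
#' @export
readCoverageTable <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "avg_coverage") %in% names(tab))) {
    stop("coverage table must have columns 'gene_id' and 'avg_coverage'")
  }
  cov <- as.numeric(tab$avg_coverage)
  if (anyNA(cov) || any(cov < 0)) stop("coverages must be non-negative numbers")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in coverage table")
  setNames(cov, tab$gene_id)
}

#' Read a pairwise ANI table
#'
#' @param path TSV with columns `mag_a`, `mag_b`, `ani` (percent).
#' @return data.frame with those columns.
#' @export
readAniTable <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("mag_a", "mag_b", "ani") %in% names(tab))) {
    stop("ANI table must have columns 'mag_a', 'mag_b', 'ani'")
  }
  tab$ani <- as.numeric(tab$ani)
  if (anyNA(tab$ani) || any(tab$ani < 0 | tab$ani > 100)) {
    stop("ANI values must lie in [0, 100]")
  }
  tab
}

#' Read a MAG quality-statistics table
#'
#' @param path TSV with columns `mag_id`, `completeness`, `contamination`,
#'   `rrna_5s`, `rrna_16s`, `rrna_23s` (logical or 0/1), `trna_count`.
#' @return data.frame ready for [assignQualityTier()].
#' @export
readMagStats <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("mag_id", "completeness", "contamination", "rrna_5s", "rrna_16s",
           "rrna_23s", "trna_count")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("MAG stats table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("rrna_5s", "rrna_16s", "rrna_23s")) {
    tab[[col]] <- tab[[col]] %in% c(TRUE, 1, "1", "TRUE", "true", "T")
  }
  tab
}

#' Read an ASV count matrix
#'
#' @param path TSV, first column `sample_id`, second `fraction` (FL, PA3
#'   or PA10), remaining columns one per ASV with integer counts.
#' @return List with `counts` (samples x ASV integer matrix) and
#'   `fractions` (named character vector per sample).
#' @export
readAsvCounts <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!all(c("sample_id", "fraction") %in% names(tab)[1:2])) {
    stop("ASV count table must start with columns 'sample_id', 'fraction'")
  }
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("ASV counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$sample_id
  list(counts = counts, fractions = setNames(tab$fraction, tab$sample_id))
}
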