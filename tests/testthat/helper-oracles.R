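# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (full enumeration, direct formulas) so they cannot
# share bugs with the package implementations they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick gene-table builder: families/roles given as comma strings
make_table <- function(families, roles = rep("", length(families)),
                       strand = rep("+", length(families)),
                       contig = rep("c1", length(families)),
                       assembly = "test_asm") {
  n <- length(families)
  GeneTable(assembly, data.frame(
    gene_id = sprintf("%s_g%03d", contig, seq_len(n)),
    contig_id = contig,
    start = seq(1L, by = 1000L, length.out = n),
    end = seq(900L, by = 1000L, length.out = n),
    strand = strand, families = families, roles = roles,
    stringsAsFactors = FALSE))
}

# brute-force sliding-window enumerator: test every window, mark covered
# genes of hit windows, take maximal covered runs, trim to marker ends
brute_force_loci <- function(marker_flags, window_length, min_markers) {
  n <- length(marker_flags)
  covered <- rep(FALSE, n)
  if (n <= window_length) {
    if (sum(marker_flags) >= min_markers) covered[] <- TRUE
  } else {
    for (s in 1:(n - window_length + 1)) {
      win <- s:(s + window_length - 1)
      if (sum(marker_flags[win]) >= min_markers) covered[win] <- TRUE
    }
  }
  runs <- rle(covered)
  out <- list()
  pos <- cumsum(c(1, runs$lengths))
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    lo <- pos[r]; hi <- pos[r + 1] - 1
    mk <- which(marker_flags[lo:hi]) + lo - 1
    out[[length(out) + 1]] <- c(first = min(mk) - 1L, last = max(mk) - 1L)
  }
  out
}

# truth-table tier oracle: literal restatement of the three definitions
oracle_tier <- function(roles_list, families_list, count_genes = FALSE) {
  n <- length(roles_list)
  deg_per_gene <- vapply(families_list, function(f) {
    if (length(f) == 0) return(0L)
    sum(substr(f, 1, 2) %in% c("GH", "PL", "CE"))
  }, integer(1))
  deg <- if (count_genes) sum(deg_per_gene > 0) else sum(deg_per_gene)
  tandem <- FALSE
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      if (("SUSC" %in% roles_list[[i]] && "SUSD" %in% roles_list[[i + 1]]) ||
          ("SUSD" %in% roles_list[[i]] && "SUSC" %in% roles_list[[i + 1]])) {
        tandem <- TRUE  # same-strand assumed by callers building all-"+" loci
      }
    }
  }
  tbdt <- sum(vapply(roles_list, function(r) {
    any(r %in% c("SUSC", "SUSD", "TBDT_OTHER"))
  }, logical(1)))
  if (tandem && deg >= 1) "PUL"
  else if (tbdt >= 1 && deg >= 1) "PUL_LIKE"
  else if (deg >= 3 && tbdt == 0) "CAZYME_RICH"
  else "UNCLASSIFIED"
}

# hand-built truth table for the alpha-glucan typology over its alphabet
oracle_alpha_label <- function(fset) {
  eq <- function(x) setequal(fset, x)
  if (eq("GH13")) "I"
  else if (eq(c("GH13", "GH65")) || eq(c("GH13", "GH65", "GH31"))) "II"
  else if (eq(c("GH13", "GH77", "GH57"))) "III"
  else if (eq(c("GH13", "GH31"))) "IV"
  else "none"
}

# hand-built truth table for the beta-glucan typology
oracle_beta_label <- function(fset) {
  if (setequal(fset, "GH16")) return("GH16-only")
  if ("GH3" %in% fset && length(intersect(fset, c("GH16", "GH17"))) > 0 &&
      all(fset %in% c("GH3", "GH16", "GH17"))) {
    return("variant-2")
  }
  if (length(intersect(fset, c("GH149", "GH17", "GH16", "GH158", "GH30"))) >= 3) {
    return("variant-1")
  }
  "none"
}

# naive two-strand substring scan over character vectors
brute_force_links <- function(asv, mags) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  out <- list()
  for (a in names(asv)) {
    q <- asv[[a]]
    if (grepl("N", q, fixed = TRUE)) next
    for (m in names(mags)) {
      if (grepl(q, mags[[m]], fixed = TRUE) ||
          grepl(rc(q), mags[[m]], fixed = TRUE)) {
        out[[length(out) + 1]] <- data.frame(asv_id = a, mag_id = m,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(asv_id = character(0), mag_id = character(0)))
  }
  do.call(rbind, out)
}

# Enumerate every role/family combination for loci of up to `max_genes`
# genes, plant each combo on its own contig of one batch table, classify
# them all in one detection pass, and compare with the truth-table oracle.
enumerate_tier_combos <- function(max_genes = 4) {
  kinds <- list(
    susC = list(fam = "", role = "SUSC"),
    susD = list(fam = "", role = "SUSD"),
    tbdt = list(fam = "", role = "TBDT_OTHER"),
    sulf = list(fam = "", role = "SULFATASE"),
    gh = list(fam = "GH16", role = ""),
    gh2 = list(fam = "GH13,GH31", role = ""))
  frames <- list()
  combo_meta <- list()
  ci <- 0L
  for (n in seq_len(max_genes)) {
    combos <- expand.grid(rep(list(names(kinds)), n), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      ks <- unlist(combos[r, ], use.names = FALSE)
      ci <- ci + 1L
      ct <- sprintf("combo_%05d", ci)
      fams <- vapply(ks, function(k) kinds[[k]]$fam, character(1))
      roles <- vapply(ks, function(k) kinds[[k]]$role, character(1))
      frames[[ci]] <- data.frame(
        gene_id = sprintf("%s_g%d", ct, seq_len(n)), contig_id = ct,
        start = seq(1L, by = 1000L, length.out = n),
        end = seq(900L, by = 1000L, length.out = n),
        strand = "+", families = fams, roles = roles,
        stringsAsFactors = FALSE)
      combo_meta[[ci]] <- list(
        contig = ct,
        want = oracle_tier(.split_roles(roles), .split_fams(fams)),
        label = paste(ks, collapse = "+"))
    }
  }
  gt <- GeneTable("enum", do.call(rbind, frames))
  cs <- detectClusters(gt, DetectionParams(windowLength = 10, minMarkers = 1))
  cl <- clusterData(cs)
  got <- setNames(cl$tier, cl$contig_id)
  data.frame(
    label = vapply(combo_meta, `[[`, character(1), "label"),
    # every kind is a marker, so each combo yields exactly one full-span locus
    got = unname(got[vapply(combo_meta, `[[`, character(1), "contig")]),
    want = vapply(combo_meta, `[[`, character(1), "want"),
    stringsAsFactors = FALSE)
}

.split_roles <- function(roles) lapply(strsplit(roles, ","), function(x) x[nzchar(x)])
.split_fams <- function(fams) lapply(strsplit(fams, ","), function(x) x[nzchar(x)])

random_marker_table <- function(seed, n_genes, p_marker = 0.25) {
  set.seed(seed)
  fams <- rep("", n_genes)
  roles <- rep("", n_genes)
  mark <- runif(n_genes) < p_marker
  kind <- sample(c("GH16", "PL7", "CE1", "SULF", "SUSC", "SUSD", "TBDT"),
                 n_genes, replace = TRUE)
  for (i in which(mark)) {
    if (kind[i] %in% c("GH16", "PL7", "CE1")) fams[i] <- kind[i]
    else if (kind[i] == "SULF") roles[i] <- "SULFATASE"
    else if (kind[i] == "TBDT") roles[i] <- "TBDT_OTHER"
    else roles[i] <- kind[i]
  }
  # some non-marker annotation noise
  gt_only <- !mark & runif(n_genes) < 0.1
  fams[gt_only] <- "GT2"
  list(table = make_table(fams, roles), marker = mark)
}
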