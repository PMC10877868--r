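#' @import methods
#' @importFrom stats setNames rlnorm runif
#' @importFrom utils read.delim write.table head tail
NULL

.FAMILY_PATTERN <- "^(GH|PL|CE|GT|CBM|AA)([0-9]+)(_([0-9]+))?$"
.DEGRADATIVE_CLASSES <- c("GH", "PL", "CE")
.ROLE_TOKENS <- c("SUSC", "SUSD", "TBDT_OTHER", "SULFATASE")
.TIERS <- c("PUL", "PUL_LIKE", "CAZYME_RICH", "UNCLASSIFIED")

#' Substrate-class vocabulary of the packaged map
#'
#' The controlled vocabulary of polysaccharide substrate classes that a
#' CAZyme family may be mapped to. "unassigned" is reserved for genes whose
#' degradative families have no map entry and is not itself a valid map
#' target.
#'
#' @return Character vector of valid substrate-class labels.
#' @export
#' @examples
#' substrateVocabulary()
substrateVocabulary <- function() {
  c("beta-1,3-glucan", "alpha-glucan", "alginate", "host-glycan", "xylan",
    "peptidoglycan", "alpha-mannan", "beta-mannan", "pectin", "fucoidan",
    "sialic-acid", "alpha-rhamnoside", "chitin", "arabinan", "cellulose")
}

#' Parse CAZyme family labels
#'
#' Splits dbCAN-style family labels such as `"GH13_8"` into their class
#' prefix (`GH`, `PL`, `CE`, `GT`, `CBM`, `AA`), family number and optional
#' subfamily.
#'
#' @param labels Character vector of family labels.
#' @return A data.frame with columns `label`, `class`, `family` (the base
#'   family, e.g. `"GH13"`), and `subfamily` (integer or `NA`).
#' @export
#' @examples
#' parseFamilyLabel(c("GH13_8", "PL7", "CBM6"))
parseFamilyLabel <- function(labels) {
  labels <- as.character(labels)
  m <- regmatches(labels, regexec(.FAMILY_PATTERN, labels))
  bad <- labels[lengths(m) == 0]
  if (length(bad) > 0) {
    stop("malformed CAZyme family label(s): ", paste(unique(bad), collapse = ", "))
  }
  cls <- vapply(m, `[`, character(1), 2)
  num <- vapply(m, `[`, character(1), 3)
  sub <- vapply(m, `[`, character(1), 5)
  data.frame(
    label = labels,
    class = cls,
    family = paste0(cls, num),
    subfamily = ifelse(sub == "", NA_integer_, suppressWarnings(as.integer(sub))),
    stringsAsFactors = FALSE
  )
}

#' Strip subfamily suffixes from family labels
#'
#' @param labels Character vector of family labels (e.g. `"GH13_8"`).
#' @return Character vector of base families (e.g. `"GH13"`).
#' @export
baseFamily <- function(labels) {
  if (length(labels) == 0) return(character(0))
  parseFamilyLabel(labels)$family
}

#' Is a CAZyme family degradative?
#'
#' Degradative CAZymes are the glycoside hydrolases (GH), polysaccharide
#' lyases (PL) and carbohydrate esterases (CE). Glycosyl transferases (GT),
#' carbohydrate-binding modules (CBM) and auxiliary activities (AA) are not
#' counted as degradative.
#'
#' @param family_label Character vector of family labels.
#' @return Logical vector, `TRUE` where the class prefix is GH, PL or CE.
#' @export
#' @examples
#' isDegradative(c("PL7", "GT4", "GH13_8"))
isDegradative <- function(family_label) {
  if (length(family_label) == 0) return(logical(0))
  bad <- !grepl(.FAMILY_PATTERN, family_label)
  if (any(bad)) {
    stop("malformed CAZyme family label(s): ",
         paste(unique(family_label[bad]), collapse = ", "))
  }
  .deg_fast(family_label)
}

# prefix test on already-validated labels (hot path)
.deg_fast <- function(family_label) {
  substr(family_label, 1, 2) %in% .DEGRADATIVE_CLASSES
}

.validate_roles <- function(roles) {
  roles <- unlist(roles, use.names = FALSE)
  bad <- setdiff(roles, .ROLE_TOKENS)
  if (length(bad) > 0) {
    stop("unknown role token(s): ", paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

.validate_families <- function(families) {
  families <- unlist(families, use.names = FALSE)
  if (length(families) > 0) parseFamilyLabel(families)
  invisible(TRUE)
}

.split_tokens <- function(x, sep = ",") {
  x[is.na(x)] <- ""
  out <- strsplit(trimws(x), sep, fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}
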