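#' Read a samples-by-genes omics matrix from delimited text
#'
#' Reads a continuous (or already binary) omics matrix from a delimited text
#' file with one header row and one leading label column, as produced by the
#' usual sample-by-gene exports of expression or methylation pipelines. The
#' returned matrix is always oriented samples x genes (rownames = sample IDs,
#' colnames = gene IDs) regardless of the on-disk orientation.
#'
#' Empty cells and the token \code{"NA"} (case-insensitive) are read as
#' missing values; use [drop_missing_genes()] to remove affected genes before
#' discretization.
#'
#' @param path Path to the file.
#' @param orientation Either \code{"samples_in_rows"} (default; rows are
#'   patient samples, columns are genes) or \code{"genes_in_rows"} (the
#'   transpose layout).
#' @param delimiter Field delimiter. Defaults to tab for \code{.tsv}/\code{.txt}
#'   files and comma for \code{.csv}; pass explicitly to override.
#' @return A numeric matrix, samples in rows and genes in columns, with
#'   sample IDs as rownames and gene IDs as colnames.
#' @examples
#' path <- system.file("extdata", "toy_matrix.tsv", package = "omicarm")
#' m <- read_omics_matrix(path)
#' dim(m)
#' @export
read_omics_matrix <- function(path,
                              orientation = c("samples_in_rows", "genes_in_rows"),
                              delimiter = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }

  fields <- utils::count.fields(path, sep = delimiter, quote = "\"",
                                blank.lines.skip = TRUE)
  if (length(fields) < 2L) {
    stop("empty input: need at least one header row and one data row in ",
         path, call. = FALSE)
  }
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1L])[1L]
    stop("ragged rows: line ", bad, " of ", path, " has ", fields[bad],
         " fields, expected ", fields[1L], call. = FALSE)
  }

  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          row.names = NULL, check.names = FALSE,
                          na.strings = c("", "NA", "na", "Na", "nA"),
                          colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("empty input: no data columns in ", path, call. = FALSE)
  }

  row_labels <- df[[1L]]
  col_labels <- colnames(df)[-1L]
  if (anyDuplicated(row_labels)) {
    stop("duplicate row labels: ",
         paste(unique(row_labels[duplicated(row_labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(col_labels)) {
    stop("duplicate column labels: ",
         paste(unique(col_labels[duplicated(col_labels)]), collapse = ", "),
         call. = FALSE)
  }

  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(values <- apply(body, c(1L, 2L), as.numeric))
  bad_cell <- !is.na(body) & is.na(values)
  if (any(bad_cell)) {
    idx <- which(bad_cell, arr.ind = TRUE)[1L, ]
    stop("cannot parse cell as a number at data row ", idx[1L],
         ", column '", col_labels[idx[2L]], "': '",
         body[idx[1L], idx[2L]], "'", call. = FALSE)
  }
  dim(values) <- dim(body)
  dimnames(values) <- list(row_labels, col_labels)

  if (orientation == "genes_in_rows") {
    values <- t(values)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty input: zero data rows or columns", call. = FALSE)
  }
  values
}

#' Write a samples-by-genes matrix to delimited text
#'
#' Inverse of [read_omics_matrix()]: writes the matrix with a header row of
#' gene IDs and a leading column of sample IDs. Missing values are written as
#' \code{NA}; numbers are serialized with enough digits for a lossless
#' re-read.
#'
#' @param m Numeric matrix with rownames (sample IDs) and colnames (gene IDs).
#' @param path Output path.
#' @param delimiter Field delimiter; defaults by extension as in
#'   [read_omics_matrix()].
#' @return Invisibly, \code{path}.
#' @export
write_omics_matrix <- function(m, path, delimiter = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  txt <- apply(m, c(1L, 2L), .format_number)
  out <- cbind(sample = rownames(m), txt)
  colnames(out)[1L] <- "sample"
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

## shortest decimal representation that round-trips a double
.format_number <- function(x) {
  if (is.na(x)) return(NA_character_)
  s <- format(x, digits = 15)
  if (as.numeric(s) == x) return(s)
  sprintf("%.17g", x)
}

#' Construct a rule set
#'
#' Internal-facing constructor used by the miner and the tests. A rule set is
#' a data.frame of class \code{"rule_set"} with list columns \code{lhs} and
#' \code{rhs} (sorted character vectors of gene IDs) and numeric columns
#' \code{support}, \code{confidence}, \code{lift}, \code{wcs}, \code{lamda3}.
#'
#' @param lhs,rhs Lists of character vectors (antecedent / consequent items).
#' @param support,confidence,lift,wcs,lamda3 Numeric vectors (recycled NA for
#'   the unscored measures).
#' @return A \code{rule_set} data.frame.
#' @export
rule_set <- function(lhs, rhs, support = numeric(), confidence = numeric(),
                     lift = numeric(), wcs = NA_real_, lamda3 = NA_real_) {
  lhs <- lapply(lhs, function(x) sort(as.character(x)))
  rhs <- lapply(rhs, function(x) sort(as.character(x)))
  n <- length(lhs)
  stopifnot(length(rhs) == n)
  overlap <- mapply(function(x, y) length(intersect(x, y)) > 0, lhs, rhs)
  if (any(overlap)) {
    stop("lhs and rhs overlap in rule(s): ",
         paste(which(overlap), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    support = rep_len(as.numeric(support), n),
    confidence = rep_len(as.numeric(confidence), n),
    lift = rep_len(as.numeric(lift), n),
    wcs = rep_len(as.numeric(wcs), n),
    lamda3 = rep_len(as.numeric(lamda3), n)
  )
  if (n == 0L) {
    df <- data.frame(support = numeric(), confidence = numeric(),
                     lift = numeric(), wcs = numeric(), lamda3 = numeric())
  }
  df$lhs <- lhs
  df$rhs <- rhs
  df <- df[, c("lhs", "rhs", "support", "confidence", "lift", "wcs", "lamda3")]
  class(df) <- c("rule_set", "data.frame")
  df
}

#' @export
print.rule_set <- function(x, ...) {
  cat("Rule set with", nrow(x), "rule(s)\n")
  if (nrow(x) > 0L) {
    lab <- rule_labels(x)
    df <- data.frame(rule = lab,
                     support = round(x$support, 4),
                     confidence = round(x$confidence, 4),
                     lift = round(x$lift, 4),
                     wcs = round(x$wcs, 4),
                     lamda3 = round(x$lamda3, 4))
    print.data.frame(df, row.names = FALSE, ...)
  }
  invisible(x)
}

#' Human-readable rule labels
#'
#' @param rules A \code{rule_set}.
#' @return Character vector like \code{"{A,B} => {C}"}.
#' @export
rule_labels <- function(rules) {
  if (nrow(rules) == 0L) return(character())
  paste0("{", vapply(rules$lhs, paste, "", collapse = ","), "} => {",
         vapply(rules$rhs, paste, "", collapse = ","), "}")
}

#' Write a rule table to TSV
#'
#' Serializes a rule set with the fixed column order
#' \code{lhs, rhs, support, confidence, lift, wcs, lamda3}. Items within
#' \code{lhs}/\code{rhs} are sorted lexicographically and joined by commas;
#' missing measures are written as \code{NA}. [read_rule_table()] restores an
#' equal table.
#'
#' @param rules A \code{rule_set}.
#' @param path Output path (tab-separated).
#' @return Invisibly, \code{path}.
#' @export
write_rule_table <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  df <- data.frame(
    lhs = vapply(rules$lhs, function(x) paste(sort(x), collapse = ","), ""),
    rhs = vapply(rules$rhs, function(x) paste(sort(x), collapse = ","), ""),
    support = vapply(rules$support, .format_number, ""),
    confidence = vapply(rules$confidence, .format_number, ""),
    lift = vapply(rules$lift, .format_number, ""),
    wcs = vapply(rules$wcs, .format_number, ""),
    lamda3 = vapply(rules$lamda3, .format_number, ""),
    stringsAsFactors = FALSE
  )
  if (nrow(rules) == 0L) {
    df <- df[0L, , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a rule table written by [write_rule_table()]
#'
#' @param path Path to the TSV rule table.
#' @return A \code{rule_set}.
#' @export
read_rule_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = "NA", quote = "",
                          stringsAsFactors = FALSE)
  expected <- c("lhs", "rhs", "support", "confidence", "lift", "wcs", "lamda3")
  if (!identical(colnames(df), expected)) {
    stop("rule table must have columns ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  as_items <- function(x) {
    x <- as.character(x)
    if (length(x) == 0L) return(list())
    strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
  }
  rule_set(
    lhs = as_items(df$lhs),
    rhs = as_items(df$rhs),
    support = as.numeric(df$support),
    confidence = as.numeric(df$confidence),
    lift = as.numeric(df$lift),
    wcs = as.numeric(df$wcs),
    lamda3 = as.numeric(df$lamda3)
  )
}
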