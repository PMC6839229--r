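#' Drop genes with missing measurements
#'
#' Removes every gene (column) that has at least one missing value, keeping
#' the sample set unchanged. Run before [discretize()], which requires a
#' complete matrix.
#'
#' @param m Numeric samples x genes matrix.
#' @return The submatrix of complete genes.
#' @export
drop_missing_genes <- function(m) {
  stopifnot(is.matrix(m))
  keep <- colSums(is.na(m)) == 0L
  if (!any(keep)) {
    stop("all ", ncol(m), " genes contain missing values; nothing left",
         call. = FALSE)
  }
  m[, keep, drop = FALSE]
}

#' Keep the top-n genes by variance or an external ranking
#'
#' Selects the \code{n_top} highest-scoring genes, where the score is either
#' supplied externally (e.g. a differential-expression statistic computed
#' upstream) or, by default, the per-gene variance across samples. Columns of
#' the result are ordered by descending score.
#'
#' @param m Numeric samples x genes matrix without missing values.
#' @param n_top Number of genes to keep.
#' @param ranking Optional named numeric vector of scores (larger = better);
#'   must cover every gene in \code{m}. \code{NULL} uses per-gene variance.
#' @return The samples x \code{n_top} submatrix, genes in descending score
#'   order (ties broken alphabetically).
#' @export
select_top_genes <- function(m, n_top, ranking = NULL) {
  stopifnot(is.matrix(m), n_top >= 1L)
  genes <- colnames(m)
  if (is.null(ranking)) {
    score <- apply(m, 2L, stats::var)
  } else {
    missing <- setdiff(genes, names(ranking))
    if (length(missing) > 0L) {
      stop("ranking is missing scores for gene(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    score <- ranking[genes]
  }
  if (n_top > ncol(m)) {
    stop("n_top (", n_top, ") exceeds the number of genes (", ncol(m), ")",
         call. = FALSE)
  }
  ord <- order(-score, genes)
  m[, ord[seq_len(n_top)], drop = FALSE]
}

#' Specify how a continuous matrix is binarized
#'
#' Bundles the discretization method, threshold and direction for
#' [discretize()]. All methods operate per gene (column) across samples, mark
#' a sample 1 when the gene is "dysregulated" there, and interpret
#' \code{direction} as a restriction on the sign of the deviation:
#' \code{"up"} keeps only upward deviations, \code{"down"} only downward, and
#' \code{"both"} is their union.
#'
#' \describe{
#'   \item{zscore}{1 iff |z| > threshold, z the per-gene standard score.
#'     Default threshold 1.96 (two-sided 5\% normal cut).}
#'   \item{quantile}{1 iff the value lies strictly below the threshold-th or
#'     strictly above the (1 - threshold)-th empirical quantile of the gene.
#'     Threshold in (0, 0.5].}
#'   \item{top_fraction}{1 for the ceiling(threshold * m) samples with the
#'     largest |value - median| for the gene. Threshold in (0, 0.5].}
#'   \item{mean_sd}{1 iff |value - mean| > threshold * sd.}
#'   \item{fixed}{1 iff |value| > threshold (an absolute cut on the values
#'     themselves, e.g. a log-fold-change cut).}
#' }
#'
#' @param method One of \code{"zscore"}, \code{"quantile"},
#'   \code{"top_fraction"}, \code{"mean_sd"}, \code{"fixed"}.
#' @param threshold Method-dependent positive cutoff (see Details).
#' @param direction \code{"both"}, \code{"up"} or \code{"down"}.
#' @return A \code{discretization_spec} list.
#' @export
discretization_spec <- function(method = c("zscore", "quantile", "top_fraction",
                                           "mean_sd", "fixed"),
                                threshold = NULL,
                                direction = c("both", "up", "down")) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (is.null(threshold)) {
    threshold <- switch(method,
                        zscore = 1.96, mean_sd = 1.96,
                        quantile = 0.05, top_fraction = 0.05,
                        fixed = 0)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    stop("threshold must be a single number", call. = FALSE)
  }
  if (method %in% c("zscore", "mean_sd") && threshold <= 0) {
    stop("threshold must be positive for method '", method, "'",
         call. = FALSE)
  }
  if (method %in% c("quantile", "top_fraction") &&
      (threshold <= 0 || threshold > 0.5)) {
    stop("threshold must be in (0, 0.5] for method '", method, "'",
         call. = FALSE)
  }
  structure(list(method = method, threshold = threshold,
                 direction = direction),
            class = "discretization_spec")
}

#' Binarize a continuous omics matrix into molecular-event indicators
#'
#' Transforms a continuous matrix into a same-shaped binary matrix in which 1
#' marks a dysregulation event (per the method and threshold in \code{spec})
#' and 0 an insignificant change. This binary matrix doubles as the
#' transaction database for rule mining: each sample row is a transaction and
#' each gene an item.
#'
#' Genes with zero spread (constant columns) under \code{zscore} or
#' \code{mean_sd} produce an all-zero column with a warning. Discretization
#' is column-independent and deterministic.
#'
#' @param m Numeric samples x genes matrix without missing values.
#' @param spec A [discretization_spec()].
#' @return An integer 0/1 matrix with the same dimnames as \code{m}.
#' @examples
#' m <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("s", 1:20), paste0("g", 1:10)))
#' b <- discretize(m, discretization_spec("zscore", 1.96))
#' colMeans(b)
#' @export
discretize <- function(m, spec = discretization_spec()) {
  stopifnot(is.matrix(m), inherits(spec, "discretization_spec"))
  if (anyNA(m)) {
    stop("matrix contains missing values; call drop_missing_genes() first",
         call. = FALSE)
  }
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  constant <- character()
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    dev <- switch(spec$method,
      zscore = {
        s <- stats::sd(x)
        if (s == 0 || is.na(s)) { constant <- c(constant, colnames(m)[j]); next }
        (x - mean(x)) / s
      },
      mean_sd = {
        s <- stats::sd(x)
        if (s == 0 || is.na(s)) { constant <- c(constant, colnames(m)[j]); next }
        (x - mean(x)) / s
      },
      quantile = x,          # handled below on raw values
      top_fraction = x - stats::median(x),
      fixed = x
    )
    hit <- switch(spec$method,
      zscore = abs(dev) > spec$threshold,
      mean_sd = abs(dev) > spec$threshold,
      fixed = abs(dev) > spec$threshold,
      quantile = {
        qs <- stats::quantile(x, c(spec$threshold, 1 - spec$threshold),
                              names = FALSE)
        x < qs[1L] | x > qs[2L]
      },
      top_fraction = {
        k <- min(ceiling(spec$threshold * length(x)), length(x))
        sel <- order(abs(dev), decreasing = TRUE)[seq_len(k)]
        res <- rep(FALSE, length(x)); res[sel] <- TRUE; res
      }
    )
    up_side <- switch(spec$method,
      quantile = x > stats::median(x),
      dev > 0
    )
    hit <- switch(spec$direction,
      both = hit,
      up = hit & up_side,
      down = hit & !up_side
    )
    out[, j] <- as.integer(hit)
  }
  if (length(constant) > 0L) {
    warning("constant gene(s) set to all-zero under method '", spec$method,
            "': ", paste(constant, collapse = ", "), call. = FALSE)
  }
  out
}

#' Assert that a matrix is a valid 0/1 transaction matrix
#'
#' @param b Matrix expected to contain only 0/1 with full dimnames.
#' @return Invisibly, \code{b} coerced to integer storage.
#' @export
as_binary_matrix <- function(b) {
  stopifnot(is.matrix(b))
  if (anyNA(b) || !all(b %in% c(0, 1))) {
    stop("matrix is not binary: entries must all be 0 or 1", call. = FALSE)
  }
  if (is.null(rownames(b)) || is.null(colnames(b))) {
    stop("binary matrix needs sample rownames and gene colnames",
         call. = FALSE)
  }
  storage.mode(b) <- "integer"
  invisible(b)
}
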