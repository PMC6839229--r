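## run code under a fixed RNG seed without disturbing the caller's stream
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a single-omics matrix with planted co-dysregulated gene pairs
#'
#' Generates a continuous samples x genes matrix emulating an expression (or
#' methylation) profile in which a chosen number of gene pairs is
#' co-dysregulated: in a fixed fraction of samples each planted pair is
#' shifted upward and, in all samples, the pair shares a latent factor so its
#' continuous values correlate near \code{target_cor} both inside and outside
#' the dysregulated subset. The remaining genes are independent Gaussian
#' noise. The paired binary matrix marks the dysregulated subset for planted
#' genes and applies the default two-sided z-score cut (1.96) to noise
#' genes, so a planted pair forms a perfect transaction pattern while noise
#' genes fire in about 5\% of samples.
#'
#' Planted genes are named \code{A1, C1, A2, C2, ...} (pair k = Ak => Ck) and
#' noise genes \code{g01, g02, ...}. Output is fully reproducible from
#' \code{seed}; the caller's RNG state is left untouched.
#'
#' @param m Number of samples (>= 10).
#' @param n Total number of genes (>= 2 * planted + 2).
#' @param planted Number of planted pairs (default 1; 0 gives a pure-noise
#'   null matrix).
#' @param fraction Fraction of samples dysregulated (default 0.5).
#' @param target_cor Latent correlation of each planted pair (default 0.95).
#' @param noise_sd Standard deviation of the background noise genes
#'   (default 1).
#' @param shift Upward mean shift of planted genes in dysregulated samples
#'   (default 3).
#' @param seed Integer seed; NULL uses the current RNG state.
#' @return A list: \code{continuous}, \code{binary} (aligned matrices) and
#'   \code{truth}, a \code{synthetic_truth} list recording
#'   \code{planted_pairs} (data.frame gene_a, gene_c, target_cor),
#'   \code{dysregulated_samples}, \code{fraction}, \code{noise_sd} and
#'   \code{seed}.
#' @examples
#' sim <- generate_single_omics(m = 60, n = 20, seed = 7)
#' mine_rules(sim$binary, 0.3, 0.8)
#' @export
generate_single_omics <- function(m = 60, n = 20, planted = 1,
                                  fraction = 0.5, target_cor = 0.95,
                                  noise_sd = 1, shift = 3, seed = NULL) {
  if (m < 10) stop("m must be >= 10", call. = FALSE)
  if (planted < 0) stop("planted must be >= 0", call. = FALSE)
  if (n < 2 * planted + 2) {
    stop("n must be at least 2 * planted + 2 (planted genes plus ",
         "background)", call. = FALSE)
  }
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  if (target_cor <= 0 || target_cor > 1) {
    stop("target_cor must be in (0, 1]", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)

  with_rng_seed(seed, {
    sample_ids <- sprintf("S%03d", seq_len(m))
    pair_genes <- if (planted > 0) {
      as.vector(rbind(paste0("A", seq_len(planted)),
                      paste0("C", seq_len(planted))))
    } else character()
    noise_genes <- sprintf("g%02d", seq_len(n - 2 * planted))
    genes <- c(pair_genes, noise_genes)

    dys <- sort(sample(m, round(fraction * m)))
    cont <- matrix(NA_real_, m, n, dimnames = list(sample_ids, genes))
    bin <- matrix(0L, m, n, dimnames = list(sample_ids, genes))

    # pair noise sd giving cor(z + e1, z + e2) = target_cor for unit-var z
    e_sd <- sqrt((1 - target_cor) / target_cor)
    for (k in seq_len(planted)) {
      z <- stats::rnorm(m)
      base <- ifelse(seq_len(m) %in% dys, shift, 0)
      cont[, paste0("A", k)] <- base + z + stats::rnorm(m, sd = e_sd)
      cont[, paste0("C", k)] <- base + z + stats::rnorm(m, sd = e_sd)
      bin[dys, paste0("A", k)] <- 1L
      bin[dys, paste0("C", k)] <- 1L
    }
    for (g in noise_genes) {
      cont[, g] <- stats::rnorm(m, sd = noise_sd)
    }
    if (length(noise_genes) > 0L) {
      bin[, noise_genes] <- discretize(
        cont[, noise_genes, drop = FALSE],
        discretization_spec("zscore", 1.96, "both")
      )
    }

    truth <- structure(list(
      planted_pairs = data.frame(
        gene_a = if (planted > 0) paste0("A", seq_len(planted)) else character(),
        gene_c = if (planted > 0) paste0("C", seq_len(planted)) else character(),
        target_cor = rep(target_cor, planted),
        stringsAsFactors = FALSE
      ),
      dysregulated_samples = sample_ids[dys],
      fraction = fraction, noise_sd = noise_sd, shift = shift, seed = seed
    ), class = "synthetic_truth")
    list(continuous = cont, binary = bin, truth = truth)
  })
}

#' Simulate two omics layers sharing patients and planted cross-layer pairs
#'
#' Emulates a paired design (e.g. RNA-seq plus DNA methylation on one
#' cohort): two matrices whose sample sets overlap in \code{overlap}
#' patients, with \code{cross_pairs} gene pairs — one gene per layer — that
#' co-dysregulate in a fraction of the shared samples via a shared latent
#' factor, plus independent noise genes in each layer. After
#' [combine_layers()], mining and [filter_cross_omics()], the planted
#' cross-layer rules are recoverable.
#'
#' Cross-pair genes are named \code{X1, X2, ...} (layer 1) and
#' \code{Y1, Y2, ...} (layer 2); noise genes \code{g01...} / \code{h01...}.
#'
#' @param m Samples per layer (>= 10).
#' @param n1,n2 Genes in layer 1 / layer 2 (each >= cross_pairs + 1).
#' @param cross_pairs Number of planted cross-layer pairs (default 1).
#' @param overlap Number of shared samples (default \code{m}; >= 4).
#' @param fraction Fraction of shared samples dysregulated (default 0.5).
#' @param target_cor,noise_sd,shift As in [generate_single_omics()].
#' @param seed Integer seed.
#' @return A list: \code{layer1}, \code{layer2} (each with
#'   \code{continuous} and \code{binary}) and \code{truth} (cross pairs,
#'   shared/dysregulated sample IDs, parameters).
#' @export
generate_paired_omics <- function(m = 60, n1 = 10, n2 = 10, cross_pairs = 1,
                                  overlap = m, fraction = 0.5,
                                  target_cor = 0.95, noise_sd = 1,
                                  shift = 3, seed = NULL) {
  if (m < 10) stop("m must be >= 10", call. = FALSE)
  if (overlap < 4 || overlap > m) {
    stop("overlap must be between 4 and m", call. = FALSE)
  }
  if (n1 < cross_pairs + 1 || n2 < cross_pairs + 1) {
    stop("each layer needs at least cross_pairs + 1 genes", call. = FALSE)
  }

  with_rng_seed(seed, {
    shared <- sprintf("P%03d", seq_len(overlap))
    ids1 <- c(shared, sprintf("L1_%03d", seq_len(m - overlap)))
    ids2 <- c(shared, sprintf("L2_%03d", seq_len(m - overlap)))
    g1 <- c(if (cross_pairs > 0) paste0("X", seq_len(cross_pairs)),
            sprintf("g%02d", seq_len(n1 - cross_pairs)))
    g2 <- c(if (cross_pairs > 0) paste0("Y", seq_len(cross_pairs)),
            sprintf("h%02d", seq_len(n2 - cross_pairs)))

    dys <- sort(sample(overlap, round(fraction * overlap)))
    e_sd <- sqrt((1 - target_cor) / target_cor)

    build_layer <- function(ids, genes, cross_names, latents) {
      cont <- matrix(stats::rnorm(length(ids) * length(genes),
                                  sd = noise_sd),
                     length(ids), length(genes),
                     dimnames = list(ids, genes))
      bin <- matrix(0L, length(ids), length(genes),
                    dimnames = list(ids, genes))
      noise <- setdiff(genes, cross_names)
      if (length(noise) > 0L) {
        bin[, noise] <- discretize(cont[, noise, drop = FALSE],
                                   discretization_spec("zscore", 1.96,
                                                       "both"))
      }
      for (k in seq_along(cross_names)) {
        base <- ifelse(ids %in% shared[dys], shift, 0)
        z <- stats::rnorm(length(ids))   # layer-private samples: own latent
        z[match(shared, ids)] <- latents[[k]]
        cont[, cross_names[k]] <- base + z +
          stats::rnorm(length(ids), sd = e_sd)
        bin[ids %in% shared[dys], cross_names[k]] <- 1L
      }
      list(continuous = cont, binary = bin)
    }

    latents <- lapply(seq_len(max(cross_pairs, 1)),
                      function(k) stats::rnorm(overlap))
    cross1 <- if (cross_pairs > 0) paste0("X", seq_len(cross_pairs)) else character()
    cross2 <- if (cross_pairs > 0) paste0("Y", seq_len(cross_pairs)) else character()
    layer1 <- build_layer(ids1, g1, cross1, latents)
    layer2 <- build_layer(ids2, g2, cross2, latents)

    truth <- structure(list(
      cross_pairs = data.frame(
        layer1_gene = cross1, layer2_gene = cross2,
        target_cor = rep(target_cor, cross_pairs),
        stringsAsFactors = FALSE
      ),
      shared_samples = shared,
      dysregulated_samples = shared[dys],
      fraction = fraction, noise_sd = noise_sd, shift = shift, seed = seed
    ), class = "synthetic_truth")
    list(layer1 = layer1, layer2 = layer2, truth = truth)
  })
}

#' The packaged 5 x 5 worked-example binary matrix
#'
#' A tiny binary expression-alteration matrix of five esophageal-carcinoma
#' patient samples by five cell-cycle genes (NEK2, TPX2, CKS1B, UBE2C,
#' CDKN3), used throughout the documentation and tests as the worked
#' example: at minimum support 0.6 it contains 8 frequent itemsets, and the
#' rule \{NEK2\} => \{CDKN3\} has support 0.6, confidence 1 and lift 5/3.
#' The same matrix ships as a TSV fixture under
#' \code{system.file("extdata", "toy_matrix.tsv", package = "omicarm")}.
#'
#' @return A 5 x 5 integer 0/1 matrix, samples x genes.
#' @examples
#' toy_matrix()
#' @export
toy_matrix <- function() {
  m <- matrix(c(
    1L, 1L, 0L, 1L, 1L,
    0L, 0L, 0L, 0L, 0L,
    1L, 1L, 1L, 1L, 1L,
    1L, 0L, 1L, 1L, 1L,
    0L, 1L, 0L, 0L, 0L
  ), nrow = 5, byrow = TRUE, dimnames = list(
    c("TCGA-2H-A9GF-01", "TCGA-2H-A9GG-01", "TCGA-2H-A9GH-01",
      "TCGA-2H-A9GI-01", "TCGA-2H-A9GJ-01"),
    c("NEK2", "TPX2", "CKS1B", "UBE2C", "CDKN3")
  ))
  m
}

#' Deterministic two-layer toy fixture
#'
#' A fully deterministic (noise-free block design) pair of omics layers for
#' exact-count tests of the multi-omics pipeline: six shared samples (p1-p6)
#' plus two layer-private samples each, one planted cross-layer pair
#' (\code{ga} in layer 1, \code{gb} in layer 2, co-altered in p1-p3) and one
#' noise gene per layer whose alterations never reach pair-level support
#' 0.3 on the shared samples. Mining the combined matrix at support 0.3 /
#' confidence 0.8 yields exactly the two planted cross-layer rules
#' \{ga.1\} => \{gb.2\} and \{gb.2\} => \{ga.1\}.
#'
#' @return A list shaped like [generate_paired_omics()] output.
#' @export
toy_paired_layers <- function() {
  shared <- paste0("p", 1:6)
  ids1 <- c(shared, "p7", "p8")
  ids2 <- c(shared, "p9", "p10")

  cont1 <- matrix(c(
    # ga: high in p1-p3 (altered), low otherwise; gn: unstructured
    5.0, 1.2,
    6.0, 0.4,
    7.0, 0.8,
    1.0, 0.1,
    2.0, 3.5,
    3.0, 0.6,
    1.5, 0.3,
    2.5, 0.9
  ), nrow = 8, byrow = TRUE, dimnames = list(ids1, c("ga", "gn")))
  bin1 <- matrix(c(
    1L, 1L,
    1L, 0L,
    1L, 0L,
    0L, 0L,
    0L, 1L,
    0L, 0L,
    0L, 0L,
    0L, 0L
  ), nrow = 8, byrow = TRUE, dimnames = list(ids1, c("ga", "gn")))

  cont2 <- matrix(c(
    # gb tracks ga on the shared samples; gm unstructured
    5.1, 0.2,
    6.2, 0.5,
    7.3, 4.0,
    0.9, 0.7,
    2.1, 0.4,
    3.2, 3.8,
    1.1, 0.6,
    1.9, 0.2
  ), nrow = 8, byrow = TRUE, dimnames = list(ids2, c("gb", "gm")))
  bin2 <- matrix(c(
    1L, 0L,
    1L, 0L,
    1L, 1L,
    0L, 0L,
    0L, 0L,
    0L, 1L,
    0L, 0L,
    0L, 0L
  ), nrow = 8, byrow = TRUE, dimnames = list(ids2, c("gb", "gm")))

  truth <- structure(list(
    cross_pairs = data.frame(layer1_gene = "ga", layer2_gene = "gb",
                             target_cor = 1, stringsAsFactors = FALSE),
    shared_samples = shared,
    dysregulated_samples = paste0("p", 1:3),
    fraction = 0.5, noise_sd = 0, shift = NA_real_, seed = NULL
  ), class = "synthetic_truth")
  list(layer1 = list(continuous = cont1, binary = bin1),
       layer2 = list(continuous = cont2, binary = bin2),
       truth = truth)
}
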