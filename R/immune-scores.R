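#' Read an expression matrix from TSV
#'
#' Expects a tab-separated table with gene symbols in the first column and
#' one header column per sample.
#'
#' @param path TSV path.
#' @param logScale whether values are already log2-scale.
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path, logScale = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  ExpressionMatrix(m, logScale = logScale)
}

CYTACT_GENES <- c("GZMA", "PRF1")
IFNG_GENES <- c("IDO1", "CXCL9", "CXCL10", "IFNG", "HLA-DRA", "STAT1")

# log2(x + 1) unless already log-scale
log2_values <- function(mat) {
  v <- exprValues(mat)
  if (!mat@logScale) v <- log2(v + 1)
  v
}

# case-insensitive exact symbol match, errors listing what is missing
match_genes <- function(mat, genes) {
  rn <- toupper(rownames(exprValues(mat)))
  idx <- match(toupper(genes), rn)
  if (anyNA(idx))
    stop("gene(s) not found in expression matrix: ",
         paste(genes[is.na(idx)], collapse = ", "))
  idx
}

#' Per-gene z-scores across samples
#'
#' Each requested gene row g is transformed to `(g - mean(g)) / sd(g)` with
#' the sample standard deviation (n - 1 denominator), computed on the
#' log2 scale (raw matrices are transformed `log2(x + 1)` first).
#'
#' @param mat an [ExpressionMatrix-class] with >= 2 samples.
#' @param genes character vector of gene symbols (case-insensitive match).
#' @return matrix of z-scores, genes x samples.
#' @export
zscoreGenes <- function(mat, genes) {
  stopifnot(is(mat, "ExpressionMatrix"))
  v <- log2_values(mat)
  if (ncol(v) < 2L) stop("need at least 2 samples to z-score")
  idx <- match_genes(mat, genes)
  sub <- v[idx, , drop = FALSE]
  rownames(sub) <- genes
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(genes[sds == 0], collapse = ", "))
  (sub - rowMeans(sub)) / sds
}

#' Cytolytic activity score (CytAct)
#'
#' CytAct is the per-sample mean of z-scored log2 GZMA and PRF1
#' expression; the cohort mean of CytAct is 0 by construction.
#'
#' @param mat an [ExpressionMatrix-class] containing GZMA and PRF1.
#' @return named numeric vector of CytAct, one per sample.
#' @export
cytAct <- function(mat) {
  z <- zscoreGenes(mat, CYTACT_GENES)
  colMeans(z)
}

#' Interferon-gamma signature score
#'
#' Mean expression of IDO1, CXCL9, CXCL10, IFNG, HLA-DRA and STAT1.  By
#' default each constituent gene is z-scored (log2 scale) before averaging
#' so the genes contribute comparably, mirroring the CytAct construction;
#' `zscore = FALSE` averages the log2 values directly.
#'
#' @param mat an [ExpressionMatrix-class] containing the 6 genes.
#' @param zscore z-score each gene before averaging (default TRUE).
#' @return named numeric vector of IFNG scores, one per sample.
#' @export
ifngScore <- function(mat, zscore = TRUE) {
  if (zscore) {
    colMeans(zscoreGenes(mat, IFNG_GENES))
  } else {
    idx <- match_genes(mat, IFNG_GENES)
    colMeans(log2_values(mat)[idx, , drop = FALSE])
  }
}

#' Per-sample immune scores table
#'
#' @param mat an [ExpressionMatrix-class].
#' @return data.frame with `sample_id`, `cytact`, `ifng`.
#' @export
immuneScores <- function(mat) {
  data.frame(sample_id = colnames(exprValues(mat)),
             cytact = unname(cytAct(mat)),
             ifng = unname(ifngScore(mat)),
             stringsAsFactors = FALSE)
}
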