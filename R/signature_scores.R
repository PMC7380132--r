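# Single-sample signature z-scores and the stromal contrast.
#
# The data set is first z-score transformed gene-wise; a signature's score for
# a sample is then the unweighted mean of the z-values of its genes.  The
# stromal contrast combines the omental-metastasis and primary-ovarian stromal
# signatures with opposite signs: positive values indicate
# omental-metastasis-like stroma.

#' Gene-wise z-score transformation
#'
#' Standardizes each gene row to mean 0, sd 1 across samples (sample sd,
#' n - 1 denominator).  Zero-variance genes carry no ranking information and
#' are dropped; their ids are recorded in the `dropped_genes` attribute.
#' Transformation is always within one data set, never across merged cohorts.
#'
#' @param mat Expression matrix, genes x samples, at least 2 samples.
#' @return Z-score matrix (same orientation) with attribute `dropped_genes`.
#' @export
ztransform <- function(mat) {
  validate_expression(mat)
  if (ncol(mat) < 2L) stop("z-transform requires at least 2 samples")
  mu <- rowMeans(mat)
  sd <- apply(mat, 1L, stats::sd)
  drop <- sd == 0
  if (any(drop))
    message("ztransform: dropping ", sum(drop), " zero-variance gene(s): ",
            paste(utils::head(rownames(mat)[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "")
  z <- (mat[!drop, , drop = FALSE] - mu[!drop]) / sd[!drop]
  attr(z, "dropped_genes") <- rownames(mat)[drop]
  attr(z, "metadata") <- NULL
  z
}

#' Composite signature z-score
#'
#' Per-sample unweighted mean of the z-values of the signature genes present
#' in the matrix.  Because every retained gene row is mean-zero, the score
#' averages to zero over the samples of the data set.
#'
#' @param z Z-score matrix from [ztransform()].
#' @param sig A [gene_signature()].
#' @return Named numeric vector (one score per sample) with attribute
#'   `missing_genes`.
#' @export
signature_zscore <- function(z, sig) {
  inter <- intersect_signature(sig, z)
  if (is.null(inter$present))
    stop("no genes of signature '", sig$name, "' present in the z-matrix")
  score <- colMeans(z[inter$present$genes, , drop = FALSE])
  attr(score, "missing_genes") <- inter$missing
  score
}

#' Mes 15-gene z-score
#'
#' Named alias of [signature_zscore()] for the 15-gene Mes panel, kept as a
#' distinct output column in score tables.
#'
#' @inheritParams signature_zscore
#' @param mes15 The Mes 15-gene [gene_signature()].
#' @return Named numeric vector of per-sample scores.
#' @export
mes15_zscore <- function(z, mes15) signature_zscore(z, mes15)

#' Signed stromal-signature contrast
#'
#' Combines the omental-metastasis and primary-ovarian-HGSC stromal signature
#' z-scores with opposite signs (omental positive, primary negative).  The
#' default additive contrast is the difference of the two signature z-scores;
#' since z-scores are near zero and signed, a literal quotient is numerically
#' unstable and exists only as a sensitivity-analysis mode.
#'
#' @param z Z-score matrix from [ztransform()].
#' @param omental_sig Omental-metastasis stromal [gene_signature()].
#' @param primary_sig Primary-ovarian stromal [gene_signature()].
#' @param mode `"difference"` (default) or `"quotient"`.
#' @return Named numeric vector of per-sample contrast scores; higher values
#'   indicate omental-metastasis-like stroma.
#' @export
stromal_contrast <- function(z, omental_sig, primary_sig,
                             mode = c("difference", "quotient")) {
  mode <- match.arg(mode)
  om <- signature_zscore(z, omental_sig)
  pr <- signature_zscore(z, primary_sig)
  res <- if (mode == "difference") om - pr else om / pr
  attr(res, "missing_genes") <- NULL
  res
}

#' Per-sample signature score table
#'
#' Scores a set of signatures on one z-matrix and returns a tidy table, with
#' an optional stromal contrast column.
#'
#' @param z Z-score matrix from [ztransform()].
#' @param signatures Named list of [gene_signature()] objects.
#' @param contrast Optional character vector of length 2 naming the omental
#'   and primary stromal signatures (in that order) within `signatures`; adds
#'   a `stromal_contrast` column.
#' @param annotations Optional annotation `data.frame` joined on `sample_id`.
#' @return `data.frame`: `sample_id`, one column per signature, optional
#'   `stromal_contrast`, optional annotation columns.
#' @export
signature_score_table <- function(z, signatures, contrast = NULL,
                                  annotations = NULL) {
  scores <- lapply(signatures, function(s) signature_zscore(z, s))
  out <- data.frame(sample_id = colnames(z), scores, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2L, all(contrast %in% names(signatures)))
    out$stromal_contrast <- stromal_contrast(z, signatures[[contrast[1L]]],
                                             signatures[[contrast[2L]]])
  }
  if (!is.null(annotations))
    out <- merge(out, annotations, by = "sample_id", all.x = TRUE, sort = TRUE)
  out
}
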