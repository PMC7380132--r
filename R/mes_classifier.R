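# The 15-gene binary-threshold Mes classifier.
#
# Each signature gene gets a per-gene threshold: its median expression over a
# reference population (all samples, or a named subset such as primary
# tumors).  A sample scores 1 on a gene when its expression strictly exceeds
# the threshold; the Mes score is the fraction of scored genes at 1, and a
# sample is called Mes only when every gene is above threshold (score == 1).
# Because only the per-gene ranking relative to the median matters, calls are
# invariant under any strictly increasing per-gene transform (e.g. log2).

#' Compute per-gene median thresholds
#'
#' @param mat Expression matrix, genes x samples.
#' @param signature [gene_signature()] defining the gene panel (typically the
#'   15-gene Mes panel).  Genes absent from the matrix are dropped first.
#' @param reference `"all"` (default) to take medians over every sample, or a
#'   character vector of sample ids (e.g. primary tumors only).  The reference
#'   population is always explicit, never inferred.
#' @return Object of class `threshold_set`: named numeric vector of per-gene
#'   thresholds with attributes `reference_description`, `signature_name` and
#'   `missing_genes`.
#' @export
compute_thresholds <- function(mat, signature, reference = "all") {
  validate_expression(mat)
  inter <- intersect_signature(signature, mat)
  if (is.null(inter$present))
    stop("no genes of signature '", signature$name, "' present in the matrix")
  if (identical(reference, "all")) {
    ref_ids <- colnames(mat)
    ref_desc <- sprintf("all %d samples", ncol(mat))
  } else {
    ref_ids <- as.character(reference)
    if (length(ref_ids) == 0L) stop("empty reference sample set")
    absent <- setdiff(ref_ids, colnames(mat))
    if (length(absent))
      stop("reference sample id(s) not in matrix: ",
           paste(absent, collapse = ", "))
    ref_desc <- sprintf("%d named reference samples", length(ref_ids))
  }
  thr <- apply(mat[inter$present$genes, ref_ids, drop = FALSE], 1L,
               stats::median)
  structure(thr,
            reference_description = ref_desc,
            signature_name = signature$name,
            missing_genes = inter$missing,
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %d genes (signature '%s'; reference: %s)\n",
              length(x), attr(x, "signature_name"),
              attr(x, "reference_description")))
  print(unclass(x)[seq_len(min(length(x), 6L))])
  invisible(x)
}

#' Score samples against a threshold set
#'
#' A gene scores 1 when expression strictly exceeds its threshold ("exceeds"
#' is strict: ties score 0).  The Mes score is the mean of the per-gene binary
#' scores over the genes available in the matrix; a sample is called Mes only
#' when the score equals 1.  Genes in the threshold set but absent from the
#' matrix are dropped and the score renormalized, provided at least half the
#' panel remains; below that the classification is deemed unreliable and an
#' error is raised.
#'
#' @param mat Expression matrix on the same scale as the threshold reference.
#' @param thresholds A `threshold_set` from [compute_thresholds()].
#' @param mes_cutoff Mes-call cutoff on the score; the default 1 requires
#'   every gene above threshold.  A relaxed cutoff (< 1) is available for
#'   sensitivity analysis but is not the classifier's definition.
#' @return `data.frame` with one row per sample: `sample_id`, `mes_score`,
#'   `is_mes`, `n_genes_used`, `missing_genes` (comma-separated).  The binary
#'   gene x sample score matrix is attached as attribute `gene_scores`.
#' @export
score_samples <- function(mat, thresholds, mes_cutoff = 1) {
  validate_expression(mat)
  stopifnot(inherits(thresholds, "threshold_set"))
  genes <- names(thresholds)
  used <- genes[genes %in% rownames(mat)]
  missing <- setdiff(genes, used)
  k <- length(genes)
  if (length(used) < ceiling(k / 2))
    stop(sprintf("only %d of %d threshold genes present (< half): %s",
                 length(used), k, "classification unreliable"))
  if (length(missing))
    message("score_samples: ", length(missing), " threshold gene(s) missing, ",
            "score renormalized over ", length(used), " genes")
  scores <- (mat[used, , drop = FALSE] > thresholds[used]) * 1L
  ones <- colSums(scores)
  mes_score <- ones / length(used)
  calls <- data.frame(
    sample_id = colnames(mat),
    mes_score = mes_score,
    is_mes = if (mes_cutoff >= 1) ones == length(used) else mes_score >= mes_cutoff,
    n_genes_used = length(used),
    missing_genes = paste(missing, collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(calls, "gene_scores") <- scores
  calls
}

#' Classify a cohort and summarize Mes fractions by annotation group
#'
#' Convenience wrapper: computes thresholds, scores every sample, joins
#' annotations, and tabulates the count and fraction of Mes calls per group
#' (default: FIGO stage group x dissemination route), in deterministic order.
#'
#' @inheritParams compute_thresholds
#' @inheritParams score_samples
#' @param annotations Optional annotation `data.frame` with `sample_id` plus
#'   the grouping columns.
#' @param group_by Character vector of annotation columns defining the strata.
#' @return List with `calls` (per-sample data frame, annotation columns
#'   joined), `summary` (per-group `n`, `n_mes`, `fraction_mes`; `NULL` when
#'   no annotations are given) and `thresholds`.
#' @export
classify_cohort <- function(mat, signature, reference = "all",
                            annotations = NULL,
                            group_by = c("stage_group", "route"),
                            mes_cutoff = 1) {
  thr <- compute_thresholds(mat, signature, reference)
  calls <- score_samples(mat, thr, mes_cutoff = mes_cutoff)
  summary <- NULL
  if (!is.null(annotations)) {
    if (!"sample_id" %in% names(annotations))
      stop("annotations lack 'sample_id'")
    calls <- merge(calls, annotations, by = "sample_id", all.x = TRUE,
                   sort = TRUE)
    group_by <- intersect(group_by, names(calls))
    if (length(group_by)) {
      key <- interaction(calls[group_by], drop = TRUE, sep = ":", lex.order = TRUE)
      n <- tapply(calls$is_mes, key, length)
      n_mes <- tapply(calls$is_mes, key, sum)
      parts <- do.call(rbind, strsplit(names(n), ":", fixed = TRUE))
      summary <- data.frame(parts, n = as.integer(n),
                            n_mes = as.integer(n_mes),
                            fraction_mes = as.numeric(n_mes / n),
                            row.names = NULL, stringsAsFactors = FALSE)
      names(summary)[seq_along(group_by)] <- group_by
      summary <- summary[do.call(order, summary[group_by]), , drop = FALSE]
      rownames(summary) <- NULL
    }
  } else {
    calls <- calls[order(calls$sample_id), , drop = FALSE]
    rownames(calls) <- NULL
  }
  list(calls = calls, summary = summary, thresholds = thr)
}
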