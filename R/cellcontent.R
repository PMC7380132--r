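# Association between signature scores and annotated cell-type content
# (fibroblast / epithelial cancer cell / immune), as quantified from
# segmented H&E sections.  This module consumes tabular cell counts or areas;
# image analysis itself is out of scope.

#' Cell-type percentages from raw per-class quantities
#'
#' The content of each cell type is its percent of the three annotated cell
#' classes (fibroblast, cancer, immune) — not of all cells.  Scale-invariant:
#' counts and areas give the same percents.
#'
#' @param content `data.frame` (or matrix) with columns `fibroblast`,
#'   `cancer`, `immune` of non-negative quantities, plus an optional
#'   `sample_id` column.
#' @return `data.frame` with `sample_id` (if present) and the three percent
#'   columns summing to 100 per row.
#' @export
cell_percents <- function(content) {
  content <- as.data.frame(content, stringsAsFactors = FALSE)
  classes <- c("fibroblast", "cancer", "immune")
  if (!all(classes %in% names(content)))
    stop("content must have columns: ", paste(classes, collapse = ", "))
  q <- as.matrix(content[, classes])
  if (any(q < 0)) stop("cell quantities must be non-negative")
  tot <- rowSums(q)
  if (any(tot == 0)) {
    bad <- if ("sample_id" %in% names(content))
      content$sample_id[tot == 0] else which(tot == 0)
    stop("all-zero cell record for sample(s): ", paste(bad, collapse = ", "))
  }
  pct <- 100 * q / tot
  out <- as.data.frame(pct, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(content))
    out <- cbind(content["sample_id"], out)
  rownames(out) <- NULL
  out
}

#' Correlate a per-sample score with cell-type content
#'
#' Pairs are joined on sample id; samples missing either value are dropped
#' and counted.  Pearson is the default for continuous z-scores vs percents;
#' Spearman is available (and conventional for percent-of-epithelium
#' analyses).  P-values are two-sided.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param percents Named numeric vector of per-sample percent of one class.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `n`, `method`, `n_dropped`.
#' @export
correlate_score_content <- function(scores, percents,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(names(scores)) || is.null(names(percents)))
    stop("scores and percents must be named by sample id")
  ids <- intersect(names(scores), names(percents))
  x <- as.numeric(scores[ids]); y <- as.numeric(percents[ids])
  keep <- stats::complete.cases(x, y)
  n_dropped <- length(union(names(scores), names(percents))) - sum(keep)
  if (n_dropped > 0)
    message("correlate_score_content: ", n_dropped,
            " sample(s) dropped (unmatched or missing values)")
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired observations, got ", length(x))
  if (stats::sd(x) == 0) stop("score vector is constant; correlation undefined")
  if (stats::sd(y) == 0) stop("percent vector is constant; correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method, n_dropped = n_dropped)
}

#' Score-vs-content association stratified by an annotation column
#'
#' Runs [correlate_score_content()] within each stratum (e.g. matched primary
#' tumors, omental metastases, non-omental metastases).  Strata with fewer
#' than 3 paired samples are reported as untestable rather than erroring.
#'
#' @inheritParams correlate_score_content
#' @param annotations Annotation `data.frame` with `sample_id` and the
#'   stratum column.
#' @param stratum_col Name of the stratifying column.
#' @return `data.frame`: one row per stratum with `stratum`, `r`, `p`, `n`,
#'   `method`, `note` (`"ok"` or `"untestable"`).
#' @export
stratified_association <- function(scores, percents, annotations, stratum_col,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!stratum_col %in% names(annotations))
    stop("unknown stratum column: ", stratum_col)
  strata <- sort(unique(annotations[[stratum_col]]))
  rows <- lapply(strata, function(s) {
    ids <- annotations$sample_id[annotations[[stratum_col]] == s]
    ids <- intersect(ids, intersect(names(scores), names(percents)))
    if (length(ids) < 3L)
      return(data.frame(stratum = s, r = NA_real_, p = NA_real_,
                        n = length(ids), method = method,
                        note = "untestable", stringsAsFactors = FALSE))
    res <- correlate_score_content(scores[ids], percents[ids], method = method)
    data.frame(stratum = s, r = res$r, p = res$p, n = res$n, method = method,
               note = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
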