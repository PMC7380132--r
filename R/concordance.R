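# Agreement between classification schemes and subtype-by-group contingency
# testing.

#' Cross-tabulate two label vectors
#'
#' Labels are matched by sample id; samples labelled `"unclassified"` in
#' either scheme are excluded (and counted in a log message), mirroring the
#' exclusion of samples that do not cluster into any molecular subtype.
#'
#' @param labels_a Named character vector (reference scheme), names = sample ids.
#' @param labels_b Named character vector (comparison scheme).
#' @param exclude Label value(s) to exclude from either vector.
#' @return Integer matrix of counts, rows = reference labels, columns =
#'   comparison labels.
#' @export
cross_tabulate <- function(labels_a, labels_b, exclude = "unclassified") {
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    stop("label vectors must be named by sample id")
  ids <- intersect(names(labels_a), names(labels_b))
  if (length(ids) == 0L) stop("no shared sample ids between label vectors")
  a <- as.character(labels_a[ids]); b <- as.character(labels_b[ids])
  keep <- !(a %in% exclude | b %in% exclude)
  if (any(!keep))
    message("cross_tabulate: excluded ", sum(!keep),
            " sample(s) with label in {", paste(exclude, collapse = ", "), "}")
  tab <- table(a[keep], b[keep])
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = unname(dimnames(tab)))
}

#' Build a confusion table from printed counts
#'
#' Helper for reconstructing a 2x2 agreement table from published summary
#' counts of the form "a of (a+b) reference-positive samples called positive,
#' d of (c+d) reference-negative samples called negative".
#'
#' @param pos_correct,pos_total Correctly called / total reference-positive.
#' @param neg_correct,neg_total Correctly called / total reference-negative.
#' @param labels Length-2 character vector of class labels.
#' @return 2x2 integer matrix, rows = reference, columns = comparison.
#' @export
confusion_from_counts <- function(pos_correct, pos_total,
                                  neg_correct, neg_total,
                                  labels = c("Mes", "non-Mes")) {
  stopifnot(pos_correct <= pos_total, neg_correct <= neg_total)
  matrix(as.integer(c(pos_correct, pos_total - pos_correct,
                      neg_total - neg_correct, neg_correct)),
         nrow = 2L, byrow = TRUE, dimnames = list(labels, labels))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement for a square confusion table:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o = trace/n`
#' and expected agreement `p_e = sum_i row_i * col_i / n^2`.  A degenerate
#' table where both schemes use a single identical category (`p_e = 1`) has
#' kappa defined as 1 when agreement is perfect; otherwise it is an error.
#'
#' @param tab Square numeric matrix of non-negative counts.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("confusion table must be square")
  if (any(tab < 0)) stop("negative counts")
  n <- sum(tab)
  if (n < 1) stop("empty confusion table")
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps * 4) {
    if (p_o == 1) return(1)
    stop("degenerate table: expected agreement 1 with imperfect agreement")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Per-class accuracy
#'
#' Fraction of each reference class (row) that the comparison scheme calls
#' correctly: `counts[i, i] / row_i total`.  Rows with zero total have
#' undefined accuracy, returned as `NA` with a message.
#'
#' @param tab Square numeric matrix of counts.
#' @return Named numeric vector of per-row accuracies.
#' @export
per_class_accuracy <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("confusion table must be square")
  totals <- rowSums(tab)
  acc <- ifelse(totals > 0, diag(tab) / totals, NA_real_)
  if (any(totals == 0))
    message("per_class_accuracy: undefined for empty class(es): ",
            paste(rownames(tab)[totals == 0], collapse = ", "))
  names(acc) <- rownames(tab)
  acc
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the probability of the observed table.  Computed via
#' [stats::fisher.test()], which implements exactly this rule.  A table with
#' any zero margin carries no information about association and returns
#' p = 1 (logged).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("fisher_exact_2x2 requires a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("fisher_exact_2x2: zero margin, p = 1")
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Subtype-by-group contingency tests
#'
#' For each pair of groups, builds the 2x2 table of Mes / non-Mes calls and
#' reports the two-sided Fisher exact p.  Raw p-values are primary; a
#' Benjamini-Hochberg-adjusted column is reported alongside but never used to
#' gate output.
#'
#' @param calls `data.frame` with `sample_id` and logical `is_mes` (as from
#'   [score_samples()]).
#' @param annotations Annotation `data.frame` with `sample_id` and the
#'   grouping column.
#' @param group_col Name of the grouping column (e.g. `"stage_group"`).
#' @param groups Optional character vector restricting/ordering the groups;
#'   defaults to all observed groups in sorted order.  Groups with no samples
#'   are excluded with a message.
#' @return `data.frame` with one row per group pair: group names, the four
#'   cell counts (`a_mes`, `a_nonmes`, `b_mes`, `b_nonmes`), `p`, `p_bh`.
#'   The per-pair 2x2 tables are attached as attribute `tables`.  With fewer
#'   than two groups, returns the per-group count table only.
#' @export
subtype_by_group_test <- function(calls, annotations, group_col,
                                  groups = NULL) {
  if (!group_col %in% names(annotations))
    stop("unknown grouping column: ", group_col)
  df <- merge(calls[, c("sample_id", "is_mes")],
              annotations[, c("sample_id", group_col)], by = "sample_id")
  names(df)[3L] <- "group"
  if (is.null(groups)) groups <- sort(unique(df$group))
  present <- vapply(groups, function(g) sum(df$group == g) > 0, logical(1L))
  if (any(!present))
    message("subtype_by_group_test: excluding empty group(s): ",
            paste(groups[!present], collapse = ", "))
  groups <- groups[present]
  counts <- t(vapply(groups, function(g) {
    sub <- df[df$group == g, ]
    c(n_mes = sum(sub$is_mes), n_nonmes = sum(!sub$is_mes))
  }, c(n_mes = 0, n_nonmes = 0)))
  count_table <- data.frame(group = groups, counts, row.names = NULL,
                            stringsAsFactors = FALSE)
  if (length(groups) < 2L) return(count_table)
  pairs <- utils::combn(groups, 2L)
  tables <- list()
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1L, i]; gb <- pairs[2L, i]
    tab <- matrix(c(counts[ga, "n_mes"], counts[ga, "n_nonmes"],
                    counts[gb, "n_mes"], counts[gb, "n_nonmes"]),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(c(ga, gb), c("Mes", "non-Mes")))
    tables[[paste(ga, gb, sep = " vs ")]] <<- tab
    data.frame(group_a = ga, group_b = gb,
               a_mes = tab[1L, 1L], a_nonmes = tab[1L, 2L],
               b_mes = tab[2L, 1L], b_nonmes = tab[2L, 2L],
               p = fisher_exact_2x2(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  attr(out, "tables") <- tables
  attr(out, "group_counts") <- count_table
  out
}
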