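# Controlled vocabularies shared by loaders, the classifier summaries and the
# synthetic-cohort generator.
.stage_levels    <- c("I", "II", "III", "IV", "unknown")
.primary_sites   <- c("ovary", "peritoneum", "other", "unknown")
.tumor_roles     <- c("primary", "metastatic", "recurrent", "unknown")
.subtype_levels  <- c("Immunoreactive", "Mesenchymal", "Proliferative",
                      "Differentiated", "unclassified")
.signature_roles <- c("mes15", "mes100", "primary_stroma", "omental_stroma",
                      "other")

# Collection sites that count as "peritoneal" for route labelling: the
# extra-pelvic intraperitoneal sites metastatic HGSC is typically sampled from.
.peritoneal_class_sites <- c("peritoneum", "omentum", "colon", "intestine",
                             "abdominal_wall", "diaphragm")

#' Default collection-site normalization table
#'
#' Maps free-text site strings (as found in public annotation tables, where
#' spellings vary across data sets) onto the controlled collection-site
#' vocabulary used by [route_label()].  Users can extend or replace the table
#' when reading annotations.
#'
#' @return Named character vector: names are lower-cased raw strings, values
#'   the normalized vocabulary terms.
#' @export
default_site_table <- function() {
  c(ovary = "ovary", ovarian = "ovary", ovaries = "ovary",
    omentum = "omentum", omental = "omentum",
    peritoneum = "peritoneum", peritoneal = "peritoneum",
    "abdominal wall" = "abdominal_wall", abdominal_wall = "abdominal_wall",
    colon = "colon", intestine = "intestine", bowel = "intestine",
    diaphragm = "diaphragm",
    "lymph node" = "lymph_node", lymph_node = "lymph_node",
    "fallopian tube" = "fallopian_tube", fallopian_tube = "fallopian_tube",
    uterus = "uterus", pelvis = "pelvis",
    unknown = "unknown")
}

#' Normalize collection-site strings
#'
#' @param x Character vector of raw site strings.
#' @param table Normalization table as returned by [default_site_table()].
#' @return Character vector of normalized sites; strings absent from the table
#'   are lower-cased and passed through unchanged.
#' @export
normalize_site <- function(x, table = default_site_table()) {
  key <- tolower(trimws(x))
  out <- unname(table[key])
  out[is.na(out)] <- key[is.na(out)]
  out
}

#' Validate an expression matrix
#'
#' An expression matrix is a base numeric matrix, genes in rows and samples in
#' columns, with unique non-empty row and column names and no missing values.
#' All scoring functions in the package accept matrices in this form.
#'
#' @param values Numeric matrix, genes x samples.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  g <- rownames(values); s <- colnames(values)
  if (is.null(g) || any(!nzchar(g))) stop("gene ids (rownames) missing or empty")
  if (is.null(s) || any(!nzchar(s))) stop("sample ids (colnames) missing or empty")
  if (anyDuplicated(g)) stop("duplicate gene ids: ",
                             paste(unique(g[duplicated(g)]), collapse = ", "))
  if (anyDuplicated(s)) stop("duplicate sample ids: ",
                             paste(unique(s[duplicated(s)]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  invisible(values)
}

#' Read a gene x sample expression matrix from TSV/CSV
#'
#' Expects gene ids in the first column and sample ids in the header row.
#' Duplicate gene rows are collapsed by a configurable rule; missing or
#' non-numeric cells are rejected by default because median thresholds and
#' z-scores are ill-defined under silent missingness.
#'
#' @param path Path to a tab- or comma-separated file.
#' @param sep Field separator; by default inferred from the file extension
#'   (`.csv` comma, otherwise tab).
#' @param duplicate_rule How to collapse duplicate gene rows: `"max-mean"`
#'   (default: keep the row with the highest mean expression), `"first"`, or
#'   `"mean"` (element-wise average).
#' @param missing `"error"` (default) rejects any missing/non-numeric cell;
#'   `"drop"` removes rows containing missing values (logged).  Cells that are
#'   neither numeric nor a recognized NA string are always an error.
#' @param transposed Set `TRUE` if the file stores samples in rows; the matrix
#'   is transposed after reading.  Orientation is never guessed.
#' @return Numeric matrix, genes x samples, with a `metadata` attribute
#'   recording the source path and collapse rule.
#' @export
read_expression <- function(path, sep = NULL,
                            duplicate_rule = c("max-mean", "first", "mean"),
                            missing = c("error", "drop"),
                            transposed = FALSE) {
  duplicate_rule <- match.arg(duplicate_rule)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) == 0L) stop("empty expression matrix: ", path)
  hdr <- names(raw)[-1L]   # data.frame subsetting would uniquify duplicates
  if (!transposed && anyDuplicated(hdr))
    stop("duplicate sample ids: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  ids <- trimws(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  colnames(vals) <- hdr
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = list(NULL, hdr)))
  bad <- is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    cell <- vals[idx[1L], idx[2L]]
    na_like <- is.na(cell) || toupper(trimws(cell)) %in% c("NA", "NAN", "")
    if (missing == "error" || !na_like)
      stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                   cell, ids[idx[1L]], colnames(vals)[idx[2L]]))
    drop_rows <- unique(which(bad, arr.ind = TRUE)[, 1L])
    message("read_expression: dropping ", length(drop_rows),
            " row(s) with missing values")
    num <- num[-drop_rows, , drop = FALSE]
    ids <- ids[-drop_rows]
  }
  rownames(num) <- ids
  if (transposed) num <- t(num)
  if (anyDuplicated(colnames(num)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(num)[duplicated(colnames(num))]), collapse = ", "))
  if (anyDuplicated(rownames(num)))
    num <- collapse_duplicate_genes(num, duplicate_rule)
  validate_expression(num)
  attr(num, "metadata") <- list(source = path, duplicate_rule = duplicate_rule)
  num
}

# Collapse duplicate gene rows; `rule` as documented in read_expression().
collapse_duplicate_genes <- function(mat, rule) {
  dup <- unique(rownames(mat)[duplicated(rownames(mat))])
  warning("collapsing duplicate gene rows (rule '", rule, "'): ",
          paste(dup, collapse = ", "))
  keep_order <- unique(rownames(mat))
  rows <- lapply(keep_order, function(g) {
    block <- mat[rownames(mat) == g, , drop = FALSE]
    if (nrow(block) == 1L) return(block[1L, ])
    switch(rule,
           "max-mean" = block[which.max(rowMeans(block)), ],
           "first"    = block[1L, ],
           "mean"     = colMeans(block))
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(keep_order, colnames(mat))
  out
}

#' Write an expression matrix as TSV
#'
#' Tab-delimited UTF-8 with a `gene_id` header column; round-trips through
#' [read_expression()] exactly for finite decimal values.
#'
#' @param mat Numeric matrix, genes x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  validate_expression(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols (must be unique, non-empty).
#' @param role One of `"mes15"`, `"mes100"`, `"primary_stroma"`,
#'   `"omental_stroma"`, `"other"`.
#' @return Object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, role = "other") {
  role <- match.arg(role, .signature_roles)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene signature '", name, "' is empty")
  if (anyDuplicated(genes)) stop("gene signature '", name, "' has duplicate genes")
  structure(list(name = name, genes = genes, role = role),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s [%s]: %d genes\n", x$name, x$role,
              length(x$genes)))
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' One set per line, tab-separated: name, description, then gene symbols.
#' Duplicate genes within a set are removed with a warning.  Set roles are
#' guessed from the set name when it matches a known role and can be
#' overridden afterwards.
#'
#' @param path GMT file path.
#' @return Named list of [gene_signature()] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sigs <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop("GMT line ", i, ": fewer than 3 fields (name, description, genes...)")
    name <- fields[1L]
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", name, "': duplicate genes removed (",
              paste(unique(genes[duplicated(genes)]), collapse = ", "), ")")
      genes <- unique(genes)
    }
    role <- if (name %in% .signature_roles) name else "other"
    sigs[[name]] <- gene_signature(name, genes, role)
  }
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param sigs List of [gene_signature()] objects.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the signature role).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path, descriptions = NULL) {
  lines <- vapply(seq_along(sigs), function(i) {
    s <- sigs[[i]]
    desc <- if (is.null(descriptions)) s$role else descriptions[[i]]
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Intersect a signature with the genes of an expression matrix
#'
#' Signature genes absent from the matrix are dropped and reported, and the
#' analysis proceeds on the remainder — the convention used when a transcript
#' is missing from a platform (e.g. scoring a 21-gene stromal signature with
#' 20 genes).  An empty intersection is a valid, reportable outcome.
#'
#' @param sig A [gene_signature()].
#' @param mat Expression (or z-score) matrix with gene rownames.
#' @return List with `present` (a `gene_signature` restricted to matrix genes,
#'   order preserved; `NULL` if no gene matches) and `missing` (character
#'   vector of absent genes).
#' @export
intersect_signature <- function(sig, mat) {
  stopifnot(inherits(sig, "gene_signature"))
  hit <- sig$genes %in% rownames(mat)
  present <- if (any(hit))
    gene_signature(sig$name, sig$genes[hit], sig$role) else NULL
  list(present = present, missing = sig$genes[!hit])
}

#' Derive the FIGO stage group
#'
#' @param stage Character vector over `{I, II, III, IV, unknown}`.
#' @return `"I-II"`, `"III-IV"` or `"unknown"`.
#' @export
stage_group <- function(stage) {
  out <- rep("unknown", length(stage))
  out[stage %in% c("I", "II")] <- "I-II"
  out[stage %in% c("III", "IV")] <- "III-IV"
  out
}

#' Route label from presumed origin and collection site
#'
#' The route is a pure function of presumed primary site x collection site:
#' `ov-ov` (ovarian tumor sampled at the ovary), `ov-per` (ovarian tumor
#' sampled at a peritoneal-class site: omentum, peritoneum, colon/intestine,
#' abdominal wall, diaphragm), `per-ov` (presumed peritoneal primary sampled
#' at the ovary), `per-per`.  Combinations outside the vocabulary map to
#' `"other"`.
#'
#' @param primary_site Character vector over `{ovary, peritoneum, other, unknown}`.
#' @param collection_site Character vector of normalized collection sites.
#' @return Character vector of route labels.
#' @export
route_label <- function(primary_site, collection_site) {
  origin <- ifelse(primary_site == "ovary", "ov",
            ifelse(primary_site == "peritoneum", "per", NA_character_))
  coll <- ifelse(collection_site == "ovary", "ov",
          ifelse(collection_site %in% .peritoneal_class_sites, "per",
                 NA_character_))
  ifelse(is.na(origin) | is.na(coll), "other", paste(origin, coll, sep = "-"))
}

#' Read a sample annotation table
#'
#' Tab-delimited with header; requires a `sample_id` column.  Recognized
#' columns (`stage`, `primary_site`, `collection_site`, `tumor_role`,
#' `original_subtype`, and cell-fraction columns `fibroblast`, `cancer`,
#' `immune`) are validated against the controlled vocabularies; `stage_group`
#' and `route` are (re)derived.
#'
#' @param path Annotation TSV path.
#' @param site_table Collection-site normalization table.
#' @return `data.frame` of annotations.
#' @export
read_annotations <- function(path, site_table = default_site_table()) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (!"sample_id" %in% names(ann)) stop("annotation table lacks 'sample_id'")
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotations")
  if ("stage" %in% names(ann)) {
    bad <- setdiff(unique(ann$stage), .stage_levels)
    if (length(bad)) stop("unknown stage value(s): ", paste(bad, collapse = ", "))
    ann$stage_group <- stage_group(ann$stage)
  }
  if ("collection_site" %in% names(ann))
    ann$collection_site <- normalize_site(ann$collection_site, site_table)
  if ("primary_site" %in% names(ann)) {
    bad <- setdiff(unique(ann$primary_site), .primary_sites)
    if (length(bad)) stop("unknown primary_site value(s): ",
                          paste(bad, collapse = ", "))
  }
  if (all(c("primary_site", "collection_site") %in% names(ann)))
    ann$route <- route_label(ann$primary_site, ann$collection_site)
  frac_cols <- c("fibroblast", "cancer", "immune")
  if (all(frac_cols %in% names(ann))) {
    tot <- rowSums(ann[, frac_cols])
    if (any(abs(tot - 100) > 1e-6))
      stop("cell fractions must sum to 100 (sample ",
           ann$sample_id[which(abs(tot - 100) > 1e-6)[1L]], ")")
  }
  ann
}
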