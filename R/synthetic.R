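# Synthetic bulk-tumor cohort generator.
#
# Bulk expression is modelled as a convex mixture of cell-class archetype
# profiles (stroma, cancer epithelium, immune) with multiplicative lognormal
# noise.  The stromal compartment of a sample uses one of two archetypes —
# primary-ovarian stroma or metastatic (upper-abdominal/omental) stroma — and
# the metastatic-stroma archetype carries elevated expression of the 15-gene
# Mes panel and of the omental stromal signature, encoding the premise that
# these signatures originate in the stroma of upper-abdominal/omental lesions.
# Cohorts are structured by dissemination route and FIGO stage group so that
# every downstream analysis (classification, scoring, contingency tests,
# content correlations) has known ground truth.

.archetype_classes <- c("primary_stroma", "metastatic_stroma",
                        "cancer_epithelium", "immune")

#' Default signature set for the generator
#'
#' The 15-gene Mes panel uses the stromal/ECM exemplar genes named in the
#' field (POSTN, COL11A1, LOX, VCAN, TNC, THBS2) completed with canonical
#' activated-CAF genes; the two 21-gene stromal signatures and the 100-gene
#' Mes list are synthetic placeholder identifiers (the published lists live
#' in supplementary material and are supplied as data at analysis time).
#'
#' @return Named list of [gene_signature()] objects: `mes15`, `mes100`,
#'   `primary_stroma`, `omental_stroma`.
#' @export
default_signatures <- function() {
  mes15 <- c("POSTN", "COL11A1", "LOX", "VCAN", "TNC", "THBS2", "FAP",
             "COL1A1", "COL5A1", "COL5A2", "COL10A1", "FN1", "SPARC",
             "INHBA", "FBN1")
  primary21 <- c("GSTA2", sprintf("PSTR%02d", 1:20))
  omental21 <- c("LPREL2", sprintf("OMST%02d", 1:20))
  mes100 <- c(mes15, sprintf("MESX%03d", 1:85))
  list(mes15 = gene_signature("mes15", mes15, "mes15"),
       mes100 = gene_signature("mes100", mes100, "mes100"),
       primary_stroma = gene_signature("primary_stroma", primary21,
                                       "primary_stroma"),
       omental_stroma = gene_signature("omental_stroma", omental21,
                                       "omental_stroma"))
}

#' Default gene universe
#'
#' All signature genes plus anonymous filler genes up to `n_genes`.
#'
#' @param signatures Signature list as from [default_signatures()].
#' @param n_genes Total universe size (default 500).
#' @return Character vector of gene ids.
#' @export
default_gene_universe <- function(signatures = default_signatures(),
                                  n_genes = 500L) {
  sig_genes <- unique(unlist(lapply(signatures, `[[`, "genes")))
  n_fill <- max(0L, n_genes - length(sig_genes))
  c(sig_genes, sprintf("GENE%04d", seq_len(n_fill)))
}

#' Generate cell-class archetype expression profiles
#'
#' Baseline mean expression per gene is drawn log-uniformly over
#' `2^base_log2_range` and shared across classes; each class then gets
#' multiplicative lognormal jitter on non-signature genes (class
#' individuality) and fold elevations on signature genes: the Mes panel and
#' the omental stromal signature in the metastatic-stroma archetype, the
#' primary stromal signature in the primary-stroma archetype.  Keeping
#' signature genes jitter-free makes the elevation ratios exact, so the
#' construction guarantees `metastatic_stroma / cancer_epithelium >= fold_mes`
#' for every Mes-panel gene.
#'
#' @param gene_universe Character vector of gene ids; must contain every
#'   signature gene.
#' @param signatures Named list with `mes15`, `omental_stroma`,
#'   `primary_stroma` [gene_signature()]s (e.g. [default_signatures()]).
#' @param fold_mes Fold elevation of Mes-panel genes in metastatic stroma
#'   (default 10).
#' @param fold_omental Fold elevation of omental-signature genes in
#'   metastatic stroma (default 10).
#' @param fold_primary Fold elevation of primary-signature genes in primary
#'   stroma (default 10).
#' @param base_log2_range Log2 range of baseline means (default `c(4, 10)`,
#'   i.e. linear means 16-1024, typical of normalized intensity data).
#' @param class_jitter_sd Lognormal sd of per-class jitter on non-signature
#'   genes (default 0.1).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Object of class `archetype_profiles`: list with `means` (gene x
#'   class matrix), `signatures`, `folds`, `params`.
#' @export
generate_archetypes <- function(gene_universe = default_gene_universe(),
                                signatures = default_signatures(),
                                fold_mes = 10, fold_omental = 10,
                                fold_primary = 10,
                                base_log2_range = c(4, 10),
                                class_jitter_sd = 0.1,
                                seed = 1L) {
  needed <- c("mes15", "omental_stroma", "primary_stroma")
  if (!all(needed %in% names(signatures)))
    stop("signatures must include: ", paste(needed, collapse = ", "))
  for (nm in needed) {
    absent <- setdiff(signatures[[nm]]$genes, gene_universe)
    if (length(absent))
      stop("signature gene(s) absent from universe (", nm, "): ",
           paste(absent, collapse = ", "))
  }
  n <- length(gene_universe)
  sig_genes <- unique(c(signatures$mes15$genes,
                        signatures$omental_stroma$genes,
                        signatures$primary_stroma$genes))
  means <- withr::with_seed(seed, {
    base <- 2^stats::runif(n, base_log2_range[1L], base_log2_range[2L])
    m <- matrix(base, nrow = n, ncol = length(.archetype_classes),
                dimnames = list(gene_universe, .archetype_classes))
    jit_rows <- !(gene_universe %in% sig_genes)
    for (cl in .archetype_classes)
      m[jit_rows, cl] <- m[jit_rows, cl] *
        exp(stats::rnorm(sum(jit_rows), 0, class_jitter_sd))
    m
  })
  # fold effects combine by max if a gene sits in several elevated signatures
  elev <- function(m, genes, class, fold) {
    m[genes, class] <- pmax(m[genes, class],
                            m[genes, "cancer_epithelium"] * fold)
    m
  }
  means <- elev(means, signatures$mes15$genes, "metastatic_stroma", fold_mes)
  means <- elev(means, signatures$omental_stroma$genes, "metastatic_stroma",
                fold_omental)
  means <- elev(means, signatures$primary_stroma$genes, "primary_stroma",
                fold_primary)
  structure(list(means = means, signatures = signatures,
                 folds = c(mes = fold_mes, omental = fold_omental,
                           primary = fold_primary),
                 params = list(base_log2_range = base_log2_range,
                               class_jitter_sd = class_jitter_sd,
                               seed = seed)),
            class = "archetype_profiles")
}

#' @export
print.archetype_profiles <- function(x, ...) {
  cat(sprintf("<archetype_profiles> %d genes x %d classes (folds: mes %g, omental %g, primary %g)\n",
              nrow(x$means), ncol(x$means), x$folds["mes"], x$folds["omental"],
              x$folds["primary"]))
  invisible(x)
}

#' Default cohort design
#'
#' Route x stage strata emulating a stage-structured HGSC cohort: ovarian
#' tumors sampled at the ovary dominate; early-stage ov-ov samples carry only
#' primary-ovarian stroma; a quarter of late-stage ov-ov samples carry
#' metastatic stroma (re-seeded from upper-abdominal disease); tumors sampled
#' at or presumed to originate from peritoneal sites carry metastatic stroma.
#' `met_fraction` is the fraction of samples in the stratum assigned the
#' metastatic-stroma archetype.  Dirichlet concentrations set the
#' (fibroblast, cancer, immune) fraction distribution; metastatic-site
#' lesions are modelled as more desmoplastic (fibroblast-richer).
#'
#' @param n_total Total cohort size (default 200); strata are scaled
#'   proportionally and rounded.
#' @param noise_sigma Lognormal sd of multiplicative expression noise
#'   (default 0.25, natural-log scale).
#' @param fib_floor Minimum fibroblast fraction for a metastatic-stroma
#'   sample to count as intended-Mes ground truth (default 0.2).
#' @return Object of class `cohort_design`: list with `groups` data frame
#'   (`route`, `stage_group`, `n`, `met_fraction`, `a_fib`, `a_can`,
#'   `a_imm`), `noise_sigma`, `fib_floor`.
#' @export
default_cohort_design <- function(n_total = 200L, noise_sigma = 0.25,
                                  fib_floor = 0.2) {
  groups <- data.frame(
    route        = c("ov-ov", "ov-ov", "ov-per", "per-ov", "per-per"),
    stage_group  = c("I-II", "III-IV", "III-IV", "III-IV", "III-IV"),
    n            = c(40L, 90L, 30L, 15L, 25L),
    met_fraction = c(0, 0.25, 1, 1, 1),
    a_fib        = c(4, 4, 5, 5, 5),
    a_can        = c(5, 5, 4, 4, 4),
    a_imm        = c(1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  if (n_total != 200L) {
    groups$n <- pmax(1L, as.integer(round(groups$n * n_total / 200)))
  }
  structure(list(groups = groups, noise_sigma = noise_sigma,
                 fib_floor = fib_floor),
            class = "cohort_design")
}

# Dirichlet draw via normalized gamma variates.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic cohort
#'
#' Per sample: cell fractions are drawn from the stratum's Dirichlet; the
#' stromal archetype is primary or metastatic according to the stratum's
#' `met_fraction` (an exact count of samples, assigned at random); expression
#' is the fraction-weighted mixture of archetype means times i.i.d. lognormal
#' noise.  Annotations (stage, sites, route, tumor role, an
#' `original_subtype` label consistent with the intended ground truth) and
#' the truth table are populated.  Deterministic for a fixed seed.
#'
#' @param archetypes [generate_archetypes()] output.
#' @param design [default_cohort_design()] output (or a modified copy).
#' @param seed Integer seed.
#' @return Object of class `synthetic_cohort`: list with `matrix` (gene x
#'   sample expression), `annotations`, `truth` (per-sample fractions,
#'   stroma identity, `intended_mes`), `design`, `archetypes`, `seed`.
#' @export
generate_cohort <- function(archetypes, design = default_cohort_design(),
                            seed = 1L) {
  stopifnot(inherits(archetypes, "archetype_profiles"),
            inherits(design, "cohort_design"))
  groups <- design$groups
  if (sum(groups$n) == 0L) stop("cohort design has zero samples")
  means <- archetypes$means
  n_total <- sum(groups$n)
  withr::with_seed(seed, {
    sample_id <- sprintf("S%04d", seq_len(n_total))
    ann_rows <- list(); truth_rows <- list()
    expr <- matrix(NA_real_, nrow = nrow(means), ncol = n_total,
                   dimnames = list(rownames(means), sample_id))
    idx <- 0L
    for (g in seq_len(nrow(groups))) {
      ng <- groups$n[g]
      if (ng == 0L) next
      cols <- idx + seq_len(ng); idx <- idx + ng
      frac <- rdirichlet(ng, c(groups$a_fib[g], groups$a_can[g],
                               groups$a_imm[g]))
      n_met <- round(groups$met_fraction[g] * ng)
      met <- rep(FALSE, ng)
      if (n_met > 0L) met[sample.int(ng, n_met)] <- TRUE
      route <- groups$route[g]
      stg <- groups$stage_group[g]
      stage <- if (stg == "I-II")
        sample(c("I", "II"), ng, replace = TRUE, prob = c(0.3, 0.7))
      else sample(c("III", "IV"), ng, replace = TRUE, prob = c(0.8, 0.2))
      primary_site <- if (startsWith(route, "ov")) "ovary" else "peritoneum"
      collection <- switch(route,
        "ov-ov"  = rep("ovary", ng),
        "per-ov" = rep("ovary", ng),
        "ov-per" = sample(c("omentum", "peritoneum"), ng, replace = TRUE,
                          prob = c(0.6, 0.4)),
        "per-per" = sample(c("peritoneum", "omentum"), ng, replace = TRUE,
                           prob = c(0.6, 0.4)))
      tumor_role <- if (route %in% c("ov-per", "per-ov")) "metastatic" else "primary"
      intended <- met & frac[, 1L] >= design$fib_floor
      other_subtypes <- setdiff(.subtype_levels,
                                c("Mesenchymal", "unclassified"))
      orig <- ifelse(intended, "Mesenchymal",
                     sample(other_subtypes, ng, replace = TRUE))
      stroma_mean <- means[, ifelse(met, "metastatic_stroma",
                                    "primary_stroma"), drop = FALSE]
      # expression = f*stroma + c*cancer + i*immune, per sample
      for (j in seq_len(ng)) {
        m <- frac[j, 1L] * stroma_mean[, j] +
             frac[j, 2L] * means[, "cancer_epithelium"] +
             frac[j, 3L] * means[, "immune"]
        noise <- exp(stats::rnorm(nrow(means), 0, design$noise_sigma))
        expr[, cols[j]] <- m * noise
      }
      ann_rows[[g]] <- data.frame(
        sample_id = sample_id[cols], stage = stage,
        stage_group = stg, primary_site = primary_site,
        collection_site = collection, tumor_role = tumor_role,
        original_subtype = orig,
        fibroblast = 100 * frac[, 1L], cancer = 100 * frac[, 2L],
        immune = 100 * frac[, 3L],
        stringsAsFactors = FALSE)
      truth_rows[[g]] <- data.frame(
        sample_id = sample_id[cols],
        frac_fibroblast = frac[, 1L], frac_cancer = frac[, 2L],
        frac_immune = frac[, 3L],
        stroma_identity = ifelse(met, "metastatic_stroma", "primary_stroma"),
        intended_mes = intended, stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, ann_rows)
    ann$route <- route_label(ann$primary_site, ann$collection_site)
    truth <- do.call(rbind, truth_rows)
    rownames(ann) <- rownames(truth) <- NULL
    structure(list(matrix = expr, annotations = ann, truth = truth,
                   design = design, archetypes = archetypes, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d samples; %d intended Mes (seed %d)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$truth$intended_mes),
              x$seed))
  invisible(x)
}

# Canonical md5 of the generator configuration (design + archetype params).
config_hash <- function(cohort) {
  cfg <- list(groups = cohort$design$groups,
              noise_sigma = cohort$design$noise_sigma,
              fib_floor = cohort$design$fib_floor,
              folds = cohort$archetypes$folds,
              params = cohort$archetypes$params,
              genes = rownames(cohort$archetypes$means))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg, control = c("all", "digits17")), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a synthetic cohort as a plain-text fixture bundle
#'
#' Emits `matrix.tsv`, `annotations.tsv`, `content.tsv` (cell counts =
#' fractions x `cells_per_sample`), `truth.tsv`, `signatures.gmt` and
#' `manifest.json` (seed and configuration hash).  Two runs with the same
#' seed and configuration produce byte-identical files.
#'
#' @param cohort [generate_cohort()] output.
#' @param dir Output directory (created if absent).
#' @param cells_per_sample Cell count scale for `content.tsv` (default 2000).
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(cohort, dir, cells_per_sample = 2000L,
                                 force = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stop("directory exists and is non-empty (use force = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$matrix, file.path(dir, "matrix.tsv"))
  wt <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE,
                                           fileEncoding = "UTF-8")
  wt(cohort$annotations, "annotations.tsv")
  content <- data.frame(
    sample_id = cohort$truth$sample_id,
    fibroblast = round(cohort$truth$frac_fibroblast * cells_per_sample),
    cancer = round(cohort$truth$frac_cancer * cells_per_sample),
    immune = round(cohort$truth$frac_immune * cells_per_sample),
    stringsAsFactors = FALSE)
  wt(content, "content.tsv")
  wt(cohort$truth, "truth.tsv")
  write_gmt(cohort$archetypes$signatures, file.path(dir, "signatures.gmt"))
  manifest <- list(seed = cohort$seed, config_md5 = config_hash(cohort),
                   n_genes = nrow(cohort$matrix),
                   n_samples = ncol(cohort$matrix),
                   cells_per_sample = cells_per_sample)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
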