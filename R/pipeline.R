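#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the end-to-end workflow:
#' QC -> per-trait GWAS -> candidate sets -> wrapper selection ->
#' evaluation (-> annotation, when an eQTL table is supplied).
#'
#' @param qc a [qc_thresholds()]
#' @param thresholds a [threshold_config()]
#' @param search a [search_config()]
#' @param cv a [cv_config()] or NULL to skip repeated CV
#' @param bootstrap a [bootstrap_config()]
#' @param annotation an [annotation_config()]
#' @param classifier name of the selection/evaluation classifier (registry
#'   name); the wrapper search scores subsets with this learner
#' @param eval_classifier name of the final evaluated model (default
#'   random forest, the conventional robustness model for SNP panels)
#' @param seed global seed; every stochastic stage derives from it
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            thresholds = threshold_config(),
                            search = search_config(),
                            cv = cv_config(),
                            bootstrap = bootstrap_config(),
                            annotation = annotation_config(),
                            classifier = "knn",
                            eval_classifier = "random_forest",
                            seed = 1) {
  structure(list(qc = qc, thresholds = thresholds, search = search, cv = cv,
                 bootstrap = bootstrap, annotation = annotation,
                 classifier = classifier, eval_classifier = eval_classifier,
                 seed = as.integer(seed)), class = "pipeline_config")
}

# mean-imputed numeric feature matrix for a set of SNP ids
feature_matrix <- function(G, snp_ids) {
  idx <- match(snp_ids, G$variants$snp_id)
  idx <- idx[!is.na(idx)]
  X <- G$geno[, idx, drop = FALSE]
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  X
}

#' Run the integrated GWAS + marker-selection pipeline
#'
#' Executes QC, per-trait sex-adjusted logistic GWAS with genomic-control
#' diagnostics, stringent/lenient candidate sets, wrapper-based best-first
#' marker selection on the lenient pool, internal evaluation (LOOCV of the
#' selected subset, optional repeated stratified CV of the final model) and
#' -- when an external cohort is supplied -- stratified-bootstrap external
#' validation contrasting the marker-selected panel with the
#' stringent-GWAS-only panel.  All artifacts are written under `out_dir`
#' and a manifest records seeds and versions; re-running the same
#' configuration reproduces all numbers.
#'
#' @param discovery a `genotype_matrix` with trait status columns
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @param external optional external `genotype_matrix` with the same traits;
#'   sample ids must be disjoint from the discovery cohort (leakage guard)
#' @param visits optional visit table for comorbidity mining
#' @param visit_anchor anchor diagnosis code for rule mining
#' @param eqtl optional cis-eQTL table for annotation
#' @return list of class `pipeline_run` with all stage results
#' @export
run_pipeline <- function(discovery, config = pipeline_config(), out_dir,
                         external = NULL, visits = NULL,
                         visit_anchor = NULL, eqtl = NULL) {
  stopifnot(inherits(discovery, "genotype_matrix"),
            inherits(config, "pipeline_config"))
  if (missing(out_dir) || is.null(out_dir))
    stop("configuration error: out_dir is required", call. = FALSE)
  traits <- trait_columns(discovery$samples)
  if (!length(traits)) stop("configuration error: discovery cohort has no trait columns",
                            call. = FALSE)
  if (!is.null(external)) {
    overlap <- intersect(discovery$samples$sample_id, external$samples$sample_id)
    if (length(overlap))
      stop("leakage: ", length(overlap),
           " sample id(s) present in both discovery and external cohorts",
           call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # ---- comorbidity rules (optional, record-level input) ----
  rules <- NULL
  if (!is.null(visits) && !is.null(visit_anchor)) {
    rules <- mine_rules(visits, visit_anchor)
    write_rules(rules, file.path(out_dir, "comorbidity"))
  }
  # ---- QC (discovery only: external samples never enter QC statistics) ----
  qc_res <- apply_qc(discovery, status = discovery$samples[[traits[1]]],
                     thresholds = config$qc)
  G <- qc_res$genotypes
  write_qc_report(qc_res$report, file.path(out_dir, "qc_report"))
  # ---- per-trait GWAS ----
  assoc <- list(); inflation <- list()
  for (trait in traits) {
    y <- trait_status(G, trait)
    a <- logistic_assoc(G, y)
    assoc[[trait]] <- a
    inflation[[trait]] <- lambda_gc(a$p_value[a$status == "ok"])
    write_assoc(a, file.path(out_dir, paste0("assoc_", trait, ".tsv")))
  }
  jsonlite::write_json(
    lapply(inflation, function(x) list(lambda_gc = x$lambda_gc, n_tests = x$n_tests)),
    file.path(out_dir, "lambda_gc.json"), auto_unbox = TRUE, digits = NA)
  # ---- candidate sets at both thresholds ----
  stringent <- candidate_union(assoc, config$thresholds$stringent_p)
  lenient <- candidate_union(assoc, config$thresholds$lenient_p)
  jsonlite::write_json(list(stringent = stringent$per_trait,
                            stringent_union = stringent$union,
                            lenient = lenient$per_trait,
                            lenient_union = lenient$union),
                       file.path(out_dir, "candidates.json"), digits = NA)
  # ---- marker selection + evaluation per trait ----
  clf_sel <- classifier_spec(config$classifier, seed = config$seed)
  markers <- list(); evaluation <- list()
  table1 <- list(); table2 <- list()
  for (trait in traits) {
    y <- trait_status(G, trait)
    pool <- lenient$per_trait[[trait]]
    sel <- NULL
    if (length(pool) >= 1 && length(unique(y[!is.na(y)])) == 2) {
      X <- feature_matrix(G, pool)
      sel <- fixed_subset_workflow(X, y, clf_sel, config$search)
      sel$feature_names <- pool[sel$features]
      markers[[trait]] <- sel
      write_marker_set(sel, trait, file.path(out_dir, paste0("markers_", trait, ".tsv")))
    }
    # final-model evaluation on marker panel vs stringent GWAS panel
    clf_eval <- classifier_spec(config$eval_classifier, seed = config$seed)
    panels <- list(marker = if (!is.null(sel)) sel$feature_names else character(0),
                   gwas_stringent = stringent$per_trait[[trait]])
    ev <- list()
    for (pn in names(panels)) {
      snps <- panels[[pn]]
      Xp <- feature_matrix(G, snps)
      loocv <- loocv_accuracy(Xp, y, clf_eval)
      cv <- NULL
      if (!is.null(config$cv) && min(table(y)) >= config$cv$k)
        cv <- repeated_stratified_cv(Xp, y, clf_eval,
                                     cv_config(config$cv$k, config$cv$repeats,
                                               seed = config$seed))
      ext <- NULL
      if (!is.null(external)) {
        y_ext <- trait_status(external, trait)
        Xe <- feature_matrix(external, snps)
        keep <- !is.na(y_ext)
        model <- fit_classifier(clf_eval, Xp, y)
        ext <- stratified_bootstrap_external(
          model, Xe[keep, , drop = FALSE], y_ext[keep],
          bootstrap_config(config$bootstrap$B, ci_level = config$bootstrap$ci_level,
                           seed = config$seed))
      }
      ev[[pn]] <- list(n_snps = length(snps), loocv_accuracy = loocv,
                       cv = cv, external = ext)
      table1[[length(table1) + 1]] <- data.frame(
        trait = trait, classifier = config$eval_classifier, panel = pn,
        n_snps = length(snps), loocv_accuracy = 100 * loocv,
        cv_accuracy = if (!is.null(cv)) 100 * cv$accuracy$mean else NA_real_,
        external_accuracy = if (!is.null(ext)) 100 * ext$accuracy$mean else NA_real_,
        stringsAsFactors = FALSE)
      if (!is.null(ext))
        table2[[length(table2) + 1]] <- data.frame(
          trait = trait, panel = pn, metric = c("accuracy", "auc"),
          mean = c(ext$accuracy$mean, ext$auc$mean),
          sd = c(ext$accuracy$sd, ext$auc$sd),
          ci_low = c(ext$accuracy$ci_low, ext$auc$ci_low),
          ci_high = c(ext$accuracy$ci_high, ext$auc$ci_high),
          stringsAsFactors = FALSE)
    }
    evaluation[[trait]] <- ev
  }
  table1 <- if (length(table1)) do.call(rbind, table1) else data.frame()
  utils::write.table(table1, file.path(out_dir, "evaluation_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(table2))
    utils::write.table(do.call(rbind, table2),
                       file.path(out_dir, "external_bootstrap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  # ---- annotation (optional) ----
  annotation <- NULL
  if (!is.null(eqtl) && length(markers)) {
    sel_ids <- unique(unlist(lapply(markers, `[[`, "feature_names")))
    v <- G$variants[match(sel_ids, G$variants$snp_id), , drop = FALSE]
    snps <- data.frame(snp_id = v$snp_id, allele1 = v$allele1,
                       allele2 = v$allele2,
                       maf = compute_maf(G)[match(sel_ids, G$variants$snp_id)],
                       stringsAsFactors = FALSE)
    kept <- filter_palindromic(snps, config$annotation)
    annotation <- eqtl_join(kept$retained$snp_id, eqtl, config$annotation)
    write_annotation(annotation, file.path(out_dir, "annotation.tsv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("gwasfunnel")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    traits = traits,
    discovery_samples = discovery$samples$sample_id,
    external_samples = if (!is.null(external)) external$samples$sample_id else character(0),
    qc_surviving_samples = nrow(G$geno),
    qc_surviving_snps = ncol(G$geno))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(qc = qc_res, assoc = assoc, inflation = inflation,
                 stringent = stringent, lenient = lenient, markers = markers,
                 evaluation = evaluation, rules = rules,
                 annotation = annotation, table1 = table1,
                 out_dir = out_dir, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:", length(x$assoc), "trait(s),",
      x$manifest$qc_surviving_samples, "samples x",
      x$manifest$qc_surviving_snps, "SNPs after QC\n")
  for (tr in names(x$inflation))
    cat(sprintf("  %s: lambda_GC %.4f, stringent %d / lenient %d candidates, %d markers\n",
                tr, x$inflation[[tr]]$lambda_gc,
                length(x$stringent$per_trait[[tr]]),
                length(x$lenient$per_trait[[tr]]),
                if (!is.null(x$markers[[tr]])) length(x$markers[[tr]]$features) else 0L))
  invisible(x)
}
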