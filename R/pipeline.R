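# End-to-end orchestration: annotate -> events -> quantify -> test ->
# features -> train/predict -> consensus, with a reproducibility manifest.

#' Pipeline run configuration
#'
#' Defaults are the published study parameters: 50-nt rule threshold, event
#' FDR < 0.01, gene-level alpha 0.05, correlation cutoff 0.75, 3x repeated
#' 5-fold cross-validation, accuracy thresholds 0.95 (EXP) / 0.75 (NOEXP).
#'
#' @param gff3,fasta annotation and genome paths (omit when `simulate` is
#'   given).
#' @param counts optional TSV of event counts (events x libraries).
#' @param alignments optional named vector of SAM/BAM paths per library.
#' @param methylation optional methylation TSV path.
#' @param training_labels optional TSV with columns `event_id`, `label`
#'   (`NMD`/`non-NMD`).
#' @param homology optional TSV with `transcript_id`, `score`.
#' @param simulate optional [simulation_config()]; when given, a synthetic
#'   fixture replaces the file inputs and golden labels supply training
#'   labels via an 80/20 split.
#' @param mode `"EXP"` or `"NOEXP"`.
#' @param rule_50nt_min,fdr_events,alpha_genes,correlation_cutoff,cv_repeats,cv_folds
#'   stage thresholds (study defaults).
#' @param accuracy_exp,accuracy_noexp ensemble retention thresholds.
#' @param seed integer seed for all stochastic stages.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(gff3 = NULL, fasta = NULL, counts = NULL,
                       alignments = NULL, methylation = NULL,
                       training_labels = NULL, homology = NULL,
                       simulate = NULL, mode = c("EXP", "NOEXP"),
                       rule_50nt_min = 50L, fdr_events = 0.01,
                       alpha_genes = 0.05, correlation_cutoff = 0.75,
                       cv_repeats = 3L, cv_folds = 5L,
                       accuracy_exp = 0.95, accuracy_noexp = 0.75,
                       seed = 1L, out_dir = tempfile("asnmd_run_")) {
  mode <- match.arg(mode)
  cfg <- list(gff3 = gff3, fasta = fasta, counts = counts,
              alignments = alignments, methylation = methylation,
              training_labels = training_labels, homology = homology,
              simulate = simulate, mode = mode,
              rule_50nt_min = rule_50nt_min, fdr_events = fdr_events,
              alpha_genes = alpha_genes,
              correlation_cutoff = correlation_cutoff,
              cv_repeats = cv_repeats, cv_folds = cv_folds,
              accuracy_exp = accuracy_exp, accuracy_noexp = accuracy_noexp,
              seed = as.integer(seed), out_dir = out_dir)
  if (is.null(simulate)) {
    for (f in c("gff3", "fasta")) {
      if (is.null(cfg[[f]])) stop(f, " is required unless simulating")
      if (!file.exists(cfg[[f]])) stop(f, " not found: ", cfg[[f]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()] arguments;
#'   `simulate` may be a nested mapping of [simulation_config()] arguments.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate <- do.call(simulation_config, y$simulate)
  }
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order, writing every intermediate as
#' plain TSV/GFF3/JSON under `cfg$out_dir`, plus a manifest recording the
#' package version, seed, configuration hash and input checksums. Reruns
#' with the same configuration and seed are byte-identical.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[asnmd] ", ...)
  homology <- NULL
  training <- NULL

  if (!is.null(cfg$simulate)) {
    log_stage("simulate: generating fixture (", cfg$simulate$n_genes,
              " genes, seed ", cfg$simulate$seed, ")")
    fixture <- generate_fixture(cfg$simulate)
    fdir <- file.path(out, "fixture")
    write_fixture(fixture, fdir)
    models <- fixture$models
    genome <- fixture$genome
    homology <- fixture$homology
  } else {
    log_stage("annotate: loading ", cfg$gff3)
    models <- load_annotation(cfg$gff3, cfg$fasta)
    genome <- attr(models, "genome")
    fixture <- NULL
    if (!is.null(cfg$homology)) {
      h <- utils::read.table(cfg$homology, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
      homology <- stats::setNames(h$score, h$transcript_id)
    }
  }

  log_stage("events: building catalog")
  orfs <- compute_orf_selections(models, genome, homology = homology)
  catalog <- build_event_catalog(models, genome, orf_selections = orfs)
  write_event_catalog(catalog, file.path(out, "events.tsv"))

  log_stage("quant: obtaining event counts")
  if (!is.null(cfg$counts)) {
    cm <- as.matrix(utils::read.table(cfg$counts, header = TRUE, sep = "\t",
                                      row.names = 1L, check.names = FALSE))
    table <- event_count_table(cm)
  } else if (!is.null(cfg$alignments)) {
    table <- count_event_reads(cfg$alignments, catalog)
  } else if (!is.null(fixture)) {
    table <- simulate_counts(fixture$labels, cfg$simulate)
    table$counts <- table$counts[catalog$event_id, , drop = FALSE]
  } else {
    stop("no counts, alignments, or simulation configured")
  }
  utils::write.table(
    data.frame(event_id = rownames(table$counts), table$counts,
               check.names = FALSE),
    file.path(out, "counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  log_stage("test: differential events (FDR < ", cfg$fdr_events, ")")
  results <- differential_events(table, fdr_threshold = cfg$fdr_events)
  utils::write.table(results, file.path(out, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("features: assembling ", cfg$mode, " matrix")
  meth <- if (!is.null(cfg$methylation)) {
    read_methylation_table(cfg$methylation)
  } else NULL
  expr <- expression_feature_block(results)
  feats <- event_feature_matrix(catalog, models, genome,
                                orf_selections = orfs, methylation = meth,
                                expression = expr, mode = cfg$mode)
  write_feature_matrix(feats, file.path(out, "features.tsv"))
  filtered <- filter_features(
    feats, feature_filter_config(correlation_cutoff = cfg$correlation_cutoff))
  write_feature_matrix(filtered, file.path(out, "features_filtered.tsv"))

  if (!is.null(cfg$training_labels)) {
    tl <- utils::read.table(cfg$training_labels, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    training <- stats::setNames(tl$label, tl$event_id)
  } else if (!is.null(fixture)) {
    # golden labels, 80/20 split seeded by cfg$seed
    ev <- fixture$labels$events
    set.seed(cfg$seed)
    train_idx <- sample(nrow(ev), floor(0.8 * nrow(ev)))
    training <- stats::setNames(
      ifelse(ev$is_nmd[train_idx], "NMD", "non-NMD"),
      ev$event_id[train_idx])
  }

  ensemble <- NULL; predictions <- NULL; importance <- NULL
  if (!is.null(training)) {
    training <- training[names(training) %in% rownames(filtered)]
    log_stage("train: ", length(training), " labelled events, ",
              cfg$mode, " mode")
    ecfg <- ensemble_config(
      mode = cfg$mode, repeats = cfg$cv_repeats, folds = cfg$cv_folds,
      accuracy_threshold = if (cfg$mode == "EXP") cfg$accuracy_exp
                           else cfg$accuracy_noexp,
      seed = cfg$seed)
    ensemble <- train_ensemble(
      filtered[names(training), , drop = FALSE], training, ecfg)
    utils::write.table(ensemble$cv_report,
                       file.path(out, "cv_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("predict: voting over ", nrow(filtered), " events with ",
              length(ensemble$retained), " retained models")
    predictions <- predict_ensemble(ensemble, filtered)
    utils::write.table(predictions, file.path(out, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    importance <- rank_importance(ensemble)
    utils::write.table(importance, file.path(out, "importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "asnmd",
    version = as.character(utils::packageVersion("asnmd")),
    seed = cfg$seed,
    mode = cfg$mode,
    config_hash = hash_object(unclass(cfg)),
    inputs = input_checksums(cfg),
    n_events = nrow(catalog),
    n_features = ncol(feats),
    n_features_filtered = ncol(filtered),
    retained_models = if (!is.null(ensemble)) ensemble$retained else NULL)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(models = models, catalog = catalog, counts = table,
                 results = results, features = feats, filtered = filtered,
                 ensemble = ensemble, predictions = predictions,
                 importance = importance, manifest = manifest,
                 fixture = fixture, out_dir = out))
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE, version = 2L)
  unname(tools::md5sum(f))
}

input_checksums <- function(cfg) {
  files <- unlist(cfg[c("gff3", "fasta", "counts", "methylation",
                        "training_labels", "homology")])
  files <- files[!is.null(files) & file.exists(files %||% character(0))]
  if (!length(files)) return(list())
  as.list(tools::md5sum(files))
}
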