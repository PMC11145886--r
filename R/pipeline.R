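#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full analysis run. Exactly
#' one of \code{input} (paths to quantity + metadata TSVs) or
#' \code{simulation} (a \code{\link{simConfig}}) must be supplied.
#'
#' @param input optional \code{list(quant = path, samples = path,
#'   sep = "\t")}.
#' @param simulation optional \code{\link{simConfig}}.
#' @param alpha volcano significance threshold on adjusted p.
#' @param var_equal pooled-variance t-test (TRUE) or Welch.
#' @param absolute_distance use 1 - |rho| dissimilarities.
#' @param thresholds linkage-distance grid.
#' @param families classifier families for the sweep.
#' @param n_iter random-search iterations per cell.
#' @param k_folds CV folds.
#' @param train_fraction training fraction of the stratified split.
#' @param positive positive-class label (NULL = minority).
#' @param n_repeats permutation-importance repeats.
#' @param pi_threshold strict positive-importance cutoff.
#' @param top_k clusters whose members are exported for enrichment.
#' @param seed single global seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @return A validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(input = NULL, simulation = NULL,
                           alpha = 0.01, var_equal = TRUE,
                           absolute_distance = FALSE,
                           thresholds = seq(0, 5, by = 0.25),
                           families = c("GB", "SVC", "RF", "ET", "LR", "KNN"),
                           n_iter = 25L, k_folds = 5L,
                           train_fraction = 0.8, positive = NULL,
                           n_repeats = 10L, pi_threshold = 0,
                           top_k = 10L, seed = 1L, out_dir = tempfile("run")) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of input or simulation must be supplied")
  if (!is.null(input)) {
    for (f in c(input$quant, input$samples))
      if (!file.exists(f)) stop("input file not found: ", f)
  }
  structure(list(
    input = input, simulation = simulation, alpha = alpha,
    var_equal = var_equal, absolute_distance = absolute_distance,
    thresholds = thresholds, families = families, n_iter = as.integer(n_iter),
    k_folds = as.integer(k_folds), train_fraction = train_fraction,
    positive = positive, n_repeats = as.integer(n_repeats),
    pi_threshold = pi_threshold, top_k = as.integer(top_k),
    seed = as.integer(seed), out_dir = out_dir), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{pipelineConfig}}; a
#' \code{simulation} block is passed to \code{\link{simConfig}}.
#'
#' @param path YAML file path.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(simConfig, y$simulation)
  if (!is.null(y$thresholds) && is.character(y$thresholds))
    y$thresholds <- parseThresholdSpec(y$thresholds)
  do.call(pipelineConfig, y)
}

# "0:5:0.25" -> seq(0, 5, 0.25)
parseThresholdSpec <- function(spec) {
  parts <- suppressWarnings(
    as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
  if (length(parts) == 3 && !anyNA(parts))
    seq(parts[1], parts[2], by = parts[3])
  else as.numeric(strsplit(spec, ",", fixed = TRUE)[[1]])
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate or read input; clean (complete-case filter,
#' multi-accession drop, sample filter, log2, batch correction); volcano
#' statistics; stratified split; linkage-distance sweep with cross-validated
#' random search; refit and held-out evaluation; permutation importance with
#' cluster mapping. Writes every intermediate artifact to
#' \code{config$out_dir}: cleaning_report.tsv, volcano.tsv, clusters.tsv,
#' sweep.tsv, test_report.json, importance.tsv, top_proteins.txt, plus a
#' manifest.json of seeds and versions enabling exact re-execution.
#'
#' @param config a \code{PipelineConfig}.
#' @return Invisibly, a list with all in-memory stage results
#'   (\code{quant}, \code{samples}, \code{volcano}, \code{split},
#'   \code{sweep}, \code{evaluation}, \code{importance}, \code{manifest}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(config$simulation)) {
    sim <- stage("simulate", generateDataset(config$simulation))
    quant <- sim$quant; samples <- sim$samples
  } else {
    quant <- stage("read", readQuantTable(config$input$quant,
                                          sep = config$input$sep %||% "\t"))
    samples <- stage("read", readSampleInfo(config$input$samples,
                                            sep = config$input$sep %||% "\t"))
  }

  cleaned <- stage("clean", cleanPipeline(quant, samples))
  m <- cleaned$quant; samples <- cleaned$samples
  write.table(cleaned$report, file.path(config$out_dir, "cleaning_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  case <- if (!is.null(config$positive))
    setdiff(unique(samples$group), config$positive)[1] else NULL
  volcano <- stage("stats", volcanoTable(
    m, samples, case = case, alpha = config$alpha,
    var_equal = config$var_equal))
  write.table(volcano, file.path(config$out_dir, "volcano.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  split <- stage("split", stratifiedSplit(
    samples, fraction = config$train_fraction,
    seed = deriveSeed(seed, 11L)))

  sweep <- stage("sweep", linkageSweep(
    m, samples, split, families = config$families,
    thresholds = config$thresholds, n_iter = config$n_iter,
    k_folds = config$k_folds, seed = deriveSeed(seed, 12L),
    positive = config$positive, absolute = config$absolute_distance))
  sw_tab <- sweepTable(sweep)
  sw_out <- sw_tab[, c("family", "threshold", "n_clusters", "mean_cv_f1")]
  write.table(sw_out, file.path(config$out_dir, "sweep.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeClusterTable(sweep@clusterTree,
                    file.path(config$out_dir, "clusters.tsv"))

  evaluation <- stage("evaluate", refitAndEvaluate(
    sweep, m, samples, split, positive = config$positive,
    seed = deriveSeed(seed, 13L)))
  jsonlite::write_json(
    c(as.list(reportMetrics(evaluation$report)),
      list(positive_class = evaluation$report@positiveClass,
           family = chosenCell(sweep)$family,
           threshold = chosenCell(sweep)$threshold,
           n_clusters = chosenCell(sweep)$n_clusters)),
    file.path(config$out_dir, "test_report.json"),
    auto_unbox = TRUE, digits = NA)

  Xall <- t(quantValues(m))
  X_test <- Xall[split$test_ids, evaluation$sentinels, drop = FALSE]
  grp <- setNames(as.character(samples$group), samples$sample_id)
  pi_rec <- stage("importance", permutationImportance(
    evaluation$fit, X_test, grp[split$test_ids],
    n_repeats = config$n_repeats, seed = deriveSeed(seed, 14L)))
  pi_pos <- filterPositive(pi_rec, threshold = config$pi_threshold)
  pi_pos <- mapToClusters(pi_pos, sweep@clusterTree)
  writeImportanceTable(pi_pos, file.path(config$out_dir, "importance.tsv"))
  top <- if (nrow(pi_pos)) topClusterProteins(
    pi_pos, k = min(config$top_k, nrow(pi_pos))) else character()
  writeLines(top, file.path(config$out_dir, "top_proteins.txt"))
  pi_table <- piVsPvalueTable(pi_pos, volcano)
  write.table(pi_table, file.path(config$out_dir, "pi_vs_pvalue.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ProteoSentinel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    global_seed = seed,
    stage_seeds = list(split = deriveSeed(seed, 11L),
                       sweep = deriveSeed(seed, 12L),
                       refit = deriveSeed(seed, 13L),
                       importance = deriveSeed(seed, 14L)),
    config = config[setdiff(names(config),
                            c("input", "simulation", "out_dir"))],
    n_features_clean = nrow(quantValues(m)),
    n_samples_clean = ncol(quantValues(m)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(quant = m, samples = samples, volcano = volcano,
                 split = split, sweep = sweep, evaluation = evaluation,
                 importance = pi_rec, importance_positive = pi_pos,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
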