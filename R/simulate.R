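#' Simulation configuration
#'
#' Parameters of the synthetic plasma-proteomics generator. The generator
#' emulates the statistical structure the downstream analysis assumes:
#' features organized in correlated blocks through shared latent factors,
#' class effects carried by the latent factors of a few informative blocks,
#' plate-style batch effects, sporadic missing and zero intensities, and a
#' minority of ";"-joined multi-accession feature ids.
#'
#' Defaults mirror a 137-sample two-class cohort (75 vs 62) with 20 blocks of
#' 10 proteins across 3 digestion plates. The default per-cell loss
#' (\code{missing_rate} 0.002 plus \code{zero_rate} 0.001) makes the expected
#' complete-case survival \eqn{(1-r)^{137} \approx 2/3} of features, and
#' \code{multi_id_fraction} (0.17) removes about one in six of the survivors,
#' matching the attrition a real DIA protein matrix shows under the same
#' cleaning rules.
#'
#' @param n_samples total number of samples.
#' @param class_counts integer pair: samples in the disease class (Type B)
#'   and in the control class (DTAA); must sum to \code{n_samples}.
#' @param n_blocks number of correlated feature blocks.
#' @param block_size features per block (scalar or length-\code{n_blocks}).
#' @param within_block_correlation target pairwise Spearman correlation of
#'   features within a block, in [0, 1).
#' @param informative_blocks integer indices of blocks whose latent factor
#'   carries the class effect.
#' @param effect_size standardized mean shift applied to the latent factor of
#'   informative blocks (log2-intensity units on the factor scale).
#' @param n_batches number of batches (digestion plates).
#' @param batch_location_shift additive log2 shift per successive batch.
#' @param batch_scale_factor multiplicative log2-scale factor per successive
#'   batch (> 0).
#' @param missing_rate per-cell missing probability in [0, 1).
#' @param zero_rate per-cell probability of an exact zero intensity, in [0, 1).
#' @param multi_id_fraction fraction of features given ";"-joined ids.
#' @param baseline_mean grand mean log2 intensity.
#' @param noise_sd total per-feature log2 standard deviation.
#' @param seed integer seed; the generator is deterministic given it.
#' @return A validated \code{SimConfig} list.
#' @examples
#' cfg <- simConfig(seed = 1)
#' str(cfg[c("n_samples", "class_counts", "n_blocks")])
#' @export
simConfig <- function(n_samples = 137L,
                      class_counts = c(75L, 62L),
                      n_blocks = 20L,
                      block_size = 10L,
                      within_block_correlation = 0.8,
                      informative_blocks = c(1L, 2L),
                      effect_size = 1.5,
                      n_batches = 3L,
                      batch_location_shift = 0.5,
                      batch_scale_factor = 1.05,
                      missing_rate = 0.002,
                      zero_rate = 0.001,
                      multi_id_fraction = 0.17,
                      baseline_mean = 20,
                      noise_sd = 1,
                      seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    class_counts = as.integer(class_counts),
    n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size),
    within_block_correlation = within_block_correlation,
    informative_blocks = as.integer(informative_blocks),
    effect_size = effect_size,
    n_batches = as.integer(n_batches),
    batch_location_shift = batch_location_shift,
    batch_scale_factor = batch_scale_factor,
    missing_rate = missing_rate,
    zero_rate = zero_rate,
    multi_id_fraction = multi_id_fraction,
    baseline_mean = baseline_mean,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_samples <= 0 || n_blocks <= 0 || any(block_size <= 0) ||
        n_batches <= 0)
      stop("counts must be positive")
    if (length(class_counts) != 2L || sum(class_counts) != n_samples)
      stop("class_counts must be two counts summing to n_samples")
    if (within_block_correlation < 0 || within_block_correlation >= 1)
      stop("within_block_correlation must lie in [0, 1)")
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must lie in [0, 1)")
    if (zero_rate < 0 || zero_rate >= 1)
      stop("zero_rate must lie in [0, 1)")
    if (multi_id_fraction < 0 || multi_id_fraction >= 1)
      stop("multi_id_fraction must lie in [0, 1)")
    if (length(informative_blocks) &&
        !all(informative_blocks %in% seq_len(n_blocks)))
      stop("informative_blocks must be block indices in 1..n_blocks")
    if (batch_scale_factor <= 0) stop("batch_scale_factor must be positive")
  })
  structure(cfg, class = "SimConfig")
}

#' Ground truth of a simulated dataset
#'
#' @slot blockOfFeature integer block index per feature (named by feature id).
#' @slot informativeBlocks integer indices of class-informative blocks.
#' @slot batchOfSample character batch per sample (named by sample id).
#' @export
setClass("SimTruth", slots = c(
  blockOfFeature = "integer",
  informativeBlocks = "integer",
  batchOfSample = "character"
))

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d features in %d blocks (%d informative), %d samples in %d batches\n",
              length(object@blockOfFeature),
              length(unique(object@blockOfFeature)),
              length(object@informativeBlocks),
              length(object@batchOfSample),
              length(unique(object@batchOfSample))))
})

#' Generate a synthetic plasma-proteomics dataset
#'
#' Latent-factor model on the log2 scale: for feature \eqn{f} in block
#' \eqn{b} and sample \eqn{j},
#' \deqn{x_{fj} = \mu_f + \sigma(\sqrt{c}\,F_{bj} + \sqrt{1-c}\,\epsilon_{fj})}
#' with \eqn{c} the within-block correlation, \eqn{F_{bj}} a standard normal
#' latent factor shared by the block, and \eqn{\epsilon_{fj}} independent
#' noise. For informative blocks the latent factor of disease-class samples
#' is shifted by \code{effect_size}, so the class signal is carried at the
#' block level, not by any single feature. Feature baselines \eqn{\mu_f} are
#' spread around \code{baseline_mean} to emulate plasma dynamic range. Batch
#' effects are then injected on the log2 scale, the matrix is exponentiated
#' to raw intensities, and zeros/missing cells are injected.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A list with elements \code{quant} (a raw-scale
#'   \linkS4class{QuantMatrix} with missing cells), \code{samples} (a
#'   sample-metadata data.frame with columns sample_id, group, age, sex,
#'   ethnicity, batch) and \code{truth} (a \linkS4class{SimTruth}).
#' @examples
#' sim <- generateDataset(simConfig(n_blocks = 4, block_size = 3, seed = 7))
#' sim$quant
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_samples
  bs <- if (length(config$block_size) == 1L)
    rep(config$block_size, config$n_blocks) else config$block_size
  if (length(bs) != config$n_blocks)
    stop("block_size must be scalar or one per block")
  p <- sum(bs)
  block_of <- rep(seq_len(config$n_blocks), bs)

  group <- rep(c("TypeB", "DTAA"), config$class_counts)
  sample_ids <- sprintf("S%03d", seq_len(n))

  c_w <- config$within_block_correlation
  # latent factors: blocks x samples
  fac <- matrix(rnorm(config$n_blocks * n), config$n_blocks, n)
  if (config$effect_size != 0 && length(config$informative_blocks))
    fac[config$informative_blocks, group == "TypeB"] <-
      fac[config$informative_blocks, group == "TypeB", drop = FALSE] +
      config$effect_size
  mu_f <- rnorm(p, config$baseline_mean, 2)
  eps <- matrix(rnorm(p * n), p, n)
  log2x <- mu_f + config$noise_sd *
    (sqrt(c_w) * fac[block_of, , drop = FALSE] + sqrt(1 - c_w) * eps)

  # batch structure: balanced random plate assignment
  batches <- sprintf("plate%d", seq_len(config$n_batches))
  batch_of <- sample(rep(batches, length.out = n))
  names(batch_of) <- sample_ids
  shifts <- (seq_len(config$n_batches) - 1) * config$batch_location_shift
  scales <- config$batch_scale_factor^(seq_len(config$n_batches) - 1)
  names(shifts) <- names(scales) <- batches

  # feature ids: Uniprot-like accessions, a fraction ";"-joined
  feature_ids <- sprintf("P%05d", seq_len(p))
  n_multi <- round(config$multi_id_fraction * p)
  if (n_multi > 0) {
    multi <- sample.int(p, n_multi)
    feature_ids[multi] <- paste(feature_ids[multi],
                                sprintf("Q%05d", seq_len(n_multi)), sep = ";")
  }
  dimnames(log2x) <- list(feature_ids, sample_ids)

  qm <- QuantMatrix(log2x, scale = "log2")
  qm <- injectBatchEffects(qm, batch_of, shifts, scales)
  raw <- 2^quantValues(qm)
  if (config$zero_rate > 0) {
    zmask <- matrix(runif(p * n) < config$zero_rate, p, n)
    raw[zmask] <- 0
  }
  qm <- QuantMatrix(raw, scale = "raw")
  qm <- injectMissing(qm, config$missing_rate,
                      seed = deriveSeed(config$seed, 101L))

  # demographics emulating an aortic-disease cohort (older DTAA group)
  age <- ifelse(group == "TypeB",
                round(rnorm(n, 57, 9)), round(rnorm(n, 66, 9)))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4))
  ethnicity <- sample(
    c("Caucasian", "AfricanAmerican", "Hispanic", "Asian", "Other"),
    n, replace = TRUE, prob = c(0.55, 0.25, 0.15, 0.02, 0.03))
  samples <- data.frame(
    sample_id = sample_ids, group = group, age = age, sex = sex,
    ethnicity = ethnicity, batch = unname(batch_of[sample_ids]),
    stringsAsFactors = FALSE)

  truth <- new("SimTruth",
               blockOfFeature = setNames(block_of, feature_ids),
               informativeBlocks = config$informative_blocks,
               batchOfSample = batch_of)
  list(quant = qm, samples = samples, truth = truth)
}

#' Inject missing cells into a quantity matrix
#'
#' Each cell is independently replaced by \code{NA} with probability
#' \code{rate}; deterministic for a fixed seed.
#'
#' @param m a \linkS4class{QuantMatrix}.
#' @param rate missing probability in [0, 1).
#' @param seed integer seed.
#' @return The matrix with missing cells injected.
#' @export
injectMissing <- function(m, rate, seed = 1L) {
  stopifnot(is(m, "QuantMatrix"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(m)
  v <- quantValues(m)
  set.seed(seed)
  mask <- matrix(runif(length(v)) < rate, nrow(v), ncol(v))
  v[mask] <- NA_real_
  setQuantValues(m, v)
}

#' Inject per-batch location/scale effects (log2 scale)
#'
#' On the log2 scale each cell \eqn{x} of a sample in batch \eqn{b} becomes
#' \eqn{shift_b + scale_b \cdot x}. A raw-scale matrix is transformed through
#' log2 and back.
#'
#' @param m a \linkS4class{QuantMatrix}.
#' @param batch_of_sample named character/factor, batch per sample id.
#' @param shifts named numeric, additive log2 shift per batch.
#' @param scales named numeric, multiplicative factor per batch (> 0).
#' @return The matrix with batch effects applied, on its original scale.
#' @export
injectBatchEffects <- function(m, batch_of_sample, shifts, scales) {
  stopifnot(is(m, "QuantMatrix"))
  sid <- sampleIds(m)
  if (!all(sid %in% names(batch_of_sample)))
    stop("every sample must have a batch")
  b <- as.character(batch_of_sample[sid])
  if (!all(b %in% names(shifts)) || !all(b %in% names(scales)))
    stop("unknown batch: missing shift or scale")
  if (any(scales <= 0)) stop("scales must be positive")
  v <- quantValues(m)
  was_raw <- quantScale(m) == "raw"
  if (was_raw) v <- log2(v)
  v <- sweep(sweep(v, 2, scales[b], `*`), 2, shifts[b], `+`)
  if (was_raw) v <- 2^v
  setQuantValues(m, v)
}

#' Write a simulated dataset to disk
#'
#' Writes the quantity matrix and sample metadata as TSV (the formats the
#' cleaning stage reads), the feature-to-block truth as a two-column TSV, and
#' the informative block set as one-line JSON.
#'
#' @param sim result of \code{\link{generateDataset}}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    quant = file.path(dir, "quant.tsv"),
    samples = file.path(dir, "samples.tsv"),
    blocks = file.path(dir, "truth_blocks.tsv"),
    informative = file.path(dir, "truth_informative.json"))
  writeQuantTable(sim$quant, paths[["quant"]])
  write.table(sim$samples, paths[["samples"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(feature_id = names(sim$truth@blockOfFeature),
               block_id = unname(sim$truth@blockOfFeature)),
    paths[["blocks"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(sim$truth@informativeBlocks), paths[["informative"]])
  invisible(paths)
}
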