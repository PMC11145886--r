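#' Keep only features quantified in every sample
#'
#' Removes every feature with at least one missing or exactly-zero value
#' across samples; feature order is preserved. Only exact zeros count as
#' zero — small positive intensities are kept — so the rule stays auditable.
#'
#' @param m a \linkS4class{QuantMatrix}.
#' @return The filtered matrix (possibly with zero features, with a warning).
#' @export
filterCompleteFeatures <- function(m) {
  stopifnot(is(m, "QuantMatrix"))
  v <- quantValues(m)
  keep <- rowSums(is.na(v) | v == 0) == 0L
  if (!any(keep)) warning("no complete features remain")
  setQuantValues(m, v[keep, , drop = FALSE])
}

#' Drop features with multi-accession identifiers
#'
#' Removes every feature whose id contains the accession separator
#' (\code{";"}, the DIA-NN protein-group convention), i.e. protein groups
#' that cannot be attributed to a single Uniprot accession.
#'
#' @param m a \linkS4class{QuantMatrix}.
#' @param sep accession separator, default \code{";"}.
#' @return The filtered matrix.
#' @export
dropMultiIdFeatures <- function(m, sep = ";") {
  stopifnot(is(m, "QuantMatrix"))
  v <- quantValues(m)
  keep <- !grepl(sep, rownames(v), fixed = TRUE)
  if (!any(keep)) warning("all feature ids are multi-accession; empty matrix")
  setQuantValues(m, v[keep, , drop = FALSE])
}

#' Drop samples with incomplete metadata or duplicated quantity columns
#'
#' Removes samples missing any demographic field (group, age, sex,
#' ethnicity, batch) and samples whose entire quantity column exactly
#' duplicates an earlier sample's (first occurrence kept). Matrix and
#' metadata are subset consistently.
#'
#' @param m a \linkS4class{QuantMatrix}.
#' @param info sample metadata data.frame (see \code{\link{readSampleInfo}}).
#' @return \code{list(quant = , samples = )} with filtered matrix and metadata.
#' @export
filterSamples <- function(m, info) {
  stopifnot(is(m, "QuantMatrix"))
  sid <- sampleIds(m)
  missing_meta <- setdiff(sid, info$sample_id)
  if (length(missing_meta))
    stop("sample(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  info <- info[match(sid, info$sample_id), , drop = FALSE]
  complete <- stats::complete.cases(
    info[, c("group", "age", "sex", "ethnicity", "batch")])
  v <- quantValues(m)
  # exact duplicate quantity columns: keep the first occurrence
  keys <- apply(v, 2, paste, collapse = "\r")
  not_dup <- !duplicated(keys)
  keep <- complete & not_dup
  list(quant = setQuantValues(m, v[, keep, drop = FALSE]),
       samples = info[keep, , drop = FALSE])
}

#' Log2-transform raw intensities
#'
#' @param m a raw-scale \linkS4class{QuantMatrix} with strictly positive
#'   values (apply \code{\link{filterCompleteFeatures}} first).
#' @return The matrix on the log2 scale.
#' @export
log2Transform <- function(m) {
  stopifnot(is(m, "QuantMatrix"))
  if (quantScale(m) == "log2")
    stop("matrix is already on the log2 scale")
  v <- quantValues(m)
  if (any(is.na(v)) || any(v <= 0))
    stop("non-positive or missing values present; run the complete-case filter first")
  setQuantValues(m, log2(v), scale = "log2")
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Location/scale batch adjustment with empirical-Bayes shrinkage of the
#' per-batch parameters (parametric ComBat model), applied to the log2
#' matrix with no covariates by default. With a single batch the input is
#' returned unchanged. Delegates to \code{sva::ComBat}.
#'
#' @param m a log2-scale \linkS4class{QuantMatrix}.
#' @param batch_of_sample named vector, batch per sample id.
#' @param mean_only logical; adjust batch locations only (no scale term).
#' @param preserve_group optional group labels (named by sample id) kept as a
#'   covariate so biological class differences are not absorbed into batch
#'   parameters; default none, matching a covariate-free correction.
#' @return The corrected matrix, same dimensions and ordering.
#' @export
combatCorrect <- function(m, batch_of_sample, mean_only = FALSE,
                          preserve_group = NULL) {
  stopifnot(is(m, "QuantMatrix"))
  if (quantScale(m) != "log2") stop("batch correction expects log2 scale")
  sid <- sampleIds(m)
  if (!all(sid %in% names(batch_of_sample)))
    stop("every sample must have a batch")
  batch <- as.character(batch_of_sample[sid])
  if (length(unique(batch)) < 2L) return(m)
  tab <- table(batch)
  if (any(tab < 2L))
    stop("each batch needs at least 2 samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  mod <- NULL
  if (!is.null(preserve_group))
    mod <- model.matrix(~ as.character(preserve_group[sid]))
  v <- quantValues(m)
  # ComBat drops zero-variance features from shrinkage; guard tiny variance
  corrected <- suppressMessages(
    sva::ComBat(dat = v, batch = batch, mod = mod,
                par.prior = TRUE, mean.only = mean_only))
  setQuantValues(m, corrected)
}

#' Run the full data-cleaning stage
#'
#' Applies, in fixed order: complete-case feature filter, multi-accession
#' drop, sample filter (incomplete demographics, duplicated columns), log2
#' transform, batch correction. Returns the cleaned matrix, the filtered
#' metadata and a per-step report of retained counts, in the style of
#' "357 to 238" cleaning summaries.
#'
#' @param m raw-scale \linkS4class{QuantMatrix}.
#' @param info sample metadata data.frame.
#' @param multi_id_sep accession separator.
#' @param mean_only_batch logical, mean-only ComBat.
#' @param preserve_group logical; keep the class label as a ComBat covariate.
#' @return \code{list(quant, samples, report)}; \code{report} is a data.frame
#'   with columns step, n_features, n_samples.
#' @export
cleanPipeline <- function(m, info, multi_id_sep = ";",
                          mean_only_batch = FALSE, preserve_group = FALSE) {
  steps <- list()
  note <- function(step, q) {
    steps[[length(steps) + 1L]] <<-
      data.frame(step = step, n_features = nrow(q), n_samples = ncol(q))
  }
  note("input", m)
  m <- filterCompleteFeatures(m); note("complete_case_filter", m)
  m <- dropMultiIdFeatures(m, sep = multi_id_sep); note("multi_id_drop", m)
  fs <- filterSamples(m, info); m <- fs$quant; info <- fs$samples
  note("sample_filter", m)
  m <- log2Transform(m); note("log2_transform", m)
  batch <- setNames(as.character(info$batch), info$sample_id)
  grp <- if (isTRUE(preserve_group))
    setNames(as.character(info$group), info$sample_id) else NULL
  m <- combatCorrect(m, batch, mean_only = mean_only_batch,
                     preserve_group = grp)
  note("batch_correction", m)
  list(quant = m, samples = info, report = do.call(rbind, steps))
}
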