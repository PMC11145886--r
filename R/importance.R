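#' Permutation importance on the held-out test set
#'
#' For each feature column of the test matrix, shuffles the column
#' \code{n_repeats} times (fresh permutation per repeat, independent across
#' features) and records the decrease in accuracy relative to the unshuffled
#' baseline. Accuracy is the permuted metric. Records are sorted by mean
#' decrease, descending, ties broken by feature id.
#'
#' @param fit a fitted classifier bundle (from the refit step).
#' @param X_test samples x features test matrix (sentinel columns).
#' @param y_test test labels.
#' @param n_repeats shuffles per feature, default 10.
#' @param seed integer seed; fixed seed gives identical repeats.
#' @return data.frame with columns feature_id, mean_pi and a matrix column
#'   \code{repeats} of per-repeat accuracy decreases.
#' @export
permutationImportance <- function(fit, X_test, y_test, n_repeats = 10L,
                                  seed = 1L) {
  if (nrow(X_test) == 0L) stop("empty test set")
  y_test <- as.character(y_test)
  baseline <- mean(predictFit(fit, X_test)$labels == y_test)
  p <- ncol(X_test)
  dec <- matrix(NA_real_, p, n_repeats)
  set.seed(seed)
  perms <- lapply(seq_len(p), function(j)
    replicate(n_repeats, sample.int(nrow(X_test)), simplify = FALSE))
  for (j in seq_len(p)) {
    for (r in seq_len(n_repeats)) {
      Xp <- X_test
      Xp[, j] <- Xp[perms[[j]][[r]], j]
      acc <- mean(predictFit(fit, Xp)$labels == y_test)
      dec[j, r] <- baseline - acc
    }
  }
  out <- data.frame(feature_id = colnames(X_test),
                    mean_pi = rowMeans(dec), stringsAsFactors = FALSE)
  out$repeats <- dec
  out <- out[order(-out$mean_pi, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep features with positive permutation importance
#'
#' @param records output of \code{\link{permutationImportance}}.
#' @param threshold strict lower bound on mean decrease, default 0.
#' @return The filtered records, order preserved.
#' @export
filterPositive <- function(records, threshold = 0) {
  records[records$mean_pi > threshold, , drop = FALSE]
}

#' Map sentinel features back to their full correlated clusters
#'
#' Attaches each sentinel's complete cluster membership, so an important
#' sentinel can be traced back to the correlated protein group it
#' represents.
#'
#' @param records importance records (sentinel feature ids).
#' @param cluster_model the \linkS4class{ClusterModel} the sentinels came from.
#' @return The records with a list column \code{members}.
#' @export
mapToClusters <- function(records, cluster_model) {
  sent <- sentinels(cluster_model)
  missing <- setdiff(records$feature_id, sent)
  if (length(missing))
    stop("sentinel(s) not found in cluster model: ",
         paste(missing, collapse = ", "))
  members <- clusterMembers(cluster_model)
  cluster_of <- setNames(names(sent), sent)
  records$members <- I(unname(members[cluster_of[records$feature_id]]))
  records
}

#' Flatten the members of the top-k importance clusters
#'
#' @param records records with a \code{members} column
#'   (\code{\link{mapToClusters}}), ranked by mean importance.
#' @param k number of top clusters, default 10.
#' @return Character vector of all member feature ids of the k
#'   highest-importance clusters (for export to enrichment tools).
#' @export
topClusterProteins <- function(records, k = 10L) {
  if (k > nrow(records)) {
    warning("k exceeds the number of clusters; using all")
    k <- nrow(records)
  }
  unique(unlist(records$members[seq_len(k)], use.names = FALSE))
}

#' Join permutation importance with differential statistics
#'
#' For positive-importance sentinels, joins mean permutation importance with
#' the volcano-table log2 fold change and adjusted p-value, the comparison
#' of model-based and statistics-based protein ranking.
#'
#' @param records positive-importance records.
#' @param volcano a \code{\link{volcanoTable}} data.frame.
#' @return data.frame (sentinel, mean_pi, log2fc, p_adj, neg_log10_p_adj)
#'   sorted by decreasing mean importance, ties by feature id.
#' @export
piVsPvalueTable <- function(records, volcano) {
  if (nrow(records) == 0L)
    return(data.frame(sentinel = character(), mean_pi = numeric(),
                      log2fc = numeric(), p_adj = numeric(),
                      neg_log10_p_adj = numeric()))
  idx <- match(records$feature_id, volcano$feature_id)
  if (anyNA(idx))
    stop("feature(s) missing from volcano table: ",
         paste(records$feature_id[is.na(idx)], collapse = ", "))
  out <- data.frame(
    sentinel = records$feature_id,
    mean_pi = records$mean_pi,
    log2fc = volcano$log2fc[idx],
    p_adj = volcano$p_adj[idx],
    neg_log10_p_adj = volcano$neg_log10_p_adj[idx],
    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_pi, out$sentinel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write ranked importance records as TSV
#'
#' One row per sentinel cluster: representative protein, mean decrease in
#' accuracy, and the ";"-joined correlated members.
#'
#' @param records records with a \code{members} column.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeImportanceTable <- function(records, path) {
  df <- data.frame(
    sentinel = records$feature_id,
    mean_decrease_accuracy = records$mean_pi,
    n_members = lengths(records$members),
    members = vapply(records$members, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
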