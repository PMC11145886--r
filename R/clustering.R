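#' Spearman correlation matrix on training samples
#'
#' Pairwise Spearman rank correlations between features, computed on the
#' training partition only so the cluster structure never sees held-out
#' samples. Average ranks are used for ties. A constant feature has no rank
#' variance; its correlations are defined as 0 with a warning.
#'
#' @param m a log2-scale \linkS4class{QuantMatrix}.
#' @param train_samples sample ids to use (>= 3).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(m, train_samples = sampleIds(m)) {
  stopifnot(is(m, "QuantMatrix"))
  if (length(train_samples) < 3L) stop("need at least 3 training samples")
  v <- quantValues(m)[, train_samples, drop = FALSE]
  constant <- apply(v, 1, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(cor(t(v), method = "spearman"))
  if (any(constant)) {
    warning("constant feature(s); correlations set to 0: ",
            paste(rownames(v)[constant], collapse = ", "))
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Condensed dissimilarities from a correlation matrix
#'
#' d(i, j) = 1 - rho(i, j) (signed; use \code{absolute = TRUE} for
#' 1 - |rho|), emitted in canonical condensed order: upper-triangle pairs
#' (1,2), (1,3), ..., (1,n), (2,3), ... row-major.
#'
#' @param corr symmetric correlation matrix.
#' @param absolute logical; cluster anti-correlated features together.
#' @return A \code{dist} object of pairwise dissimilarities.
#' @export
correlationToCondensedDistance <- function(corr, absolute = FALSE) {
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8)) stop("asymmetric input")
  d <- if (absolute) 1 - abs(corr) else 1 - corr
  as.dist(d)
}

#' Ward agglomerative linkage on a condensed dissimilarity
#'
#' Nearest-pair agglomeration under the Ward Lance-Williams update
#' \deqn{d(A \cup B, C) = \sqrt{\frac{(n_A+n_C)d_{AC}^2 + (n_B+n_C)d_{BC}^2
#'   - n_C d_{AB}^2}{n_A+n_B+n_C}}}
#' applied directly to the supplied dissimilarities (the pragmatic
#' convention when handed a condensed 1 - rho matrix, with no claim that it
#' embeds in Euclidean space). Ties on the merge distance are broken toward
#' the lexicographically smallest pair of cluster indices, making the tree
#' deterministic.
#'
#' Leaves are nodes \code{1..n}; merge \code{i} creates node \code{n+i}.
#'
#' @param d a \code{dist} object or condensed numeric vector (canonical
#'   order) of non-negative dissimilarities.
#' @param n_items number of items; inferred from \code{d} if absent.
#' @return Numeric matrix with one row per merge and columns \code{left},
#'   \code{right}, \code{height}, \code{size}.
#' @export
wardLinkage <- function(d, n_items = NULL) {
  if (inherits(d, "dist")) {
    n <- attr(d, "Size")
    d <- as.numeric(d)
  } else {
    n <- if (is.null(n_items))
      as.integer(round((1 + sqrt(1 + 8 * length(d))) / 2)) else n_items
  }
  if (length(d) != n * (n - 1) / 2) stop("condensed length inconsistent with n_items")
  if (n < 2L) stop("need at least 2 items")
  if (any(d < 0)) stop("negative dissimilarity")

  D <- matrix(0, n, n)
  D[lower.tri(D)] <- d  # column-major lower triangle == canonical condensed
  D <- D + t(D)
  diag(D) <- Inf

  node <- seq_len(n)       # current node id per active slot
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merges <- matrix(NA_real_, n - 1L, 4L,
                   dimnames = list(NULL, c("left", "right", "height", "size")))
  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    # smallest distance; ties -> lexicographically smallest (i, j) slot pair
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    ord <- order(best[, 1], best[, 2])
    i <- idx[best[ord[1], 1]]
    j <- idx[best[ord[1], 2]]
    h <- D[i, j]
    ni <- size[i]; nj <- size[j]
    merges[s, ] <- c(min(node[i], node[j]), max(node[i], node[j]), h, ni + nj)
    others <- idx[!idx %in% c(i, j)]
    if (length(others)) {
      nk <- size[others]
      D[i, others] <- D[others, i] <-
        sqrt(((ni + nk) * D[i, others]^2 + (nj + nk) * D[j, others]^2 -
                nk * h^2) / (ni + nj + nk))
    }
    active[j] <- FALSE
    size[i] <- ni + nj
    node[i] <- n + s
    D[j, ] <- D[, j] <- Inf
  }
  merges
}

#' Flat clusters from a merge tree at a linkage-distance threshold
#'
#' Undoes every merge whose height exceeds \code{t}; the remaining connected
#' components are the clusters. Labels are contiguous from 1, ordered by
#' each cluster's first member index.
#'
#' @param merges merge matrix from \code{\link{wardLinkage}}.
#' @param t linkage-distance threshold (>= 0).
#' @param n_items number of leaves; inferred from \code{merges} if absent.
#' @return Integer vector of cluster labels, one per leaf.
#' @export
cutAtThreshold <- function(merges, t, n_items = nrow(merges) + 1L) {
  if (t < 0) stop("threshold must be non-negative")
  n <- n_items
  parent <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (s in seq_len(nrow(merges))) {
    if (merges[s, "height"] <= t) {
      ra <- find(merges[s, "left"]); rb <- find(merges[s, "right"])
      parent[ra] <- parent[rb] <- parent[n + s] <- n + s
    }
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  labels <- match(roots, unique(roots))
  as.integer(labels)
}

#' Randomly select one sentinel feature per cluster
#'
#' Chooses, uniformly at random under the given seed, a single
#' representative ("sentinel") feature from each cluster; deterministic per
#' seed.
#'
#' @param labels integer cluster labels, one per feature.
#' @param feature_ids character ids matching \code{labels}.
#' @param seed integer seed.
#' @return Named character vector, one feature id per cluster index.
#' @export
selectSentinels <- function(labels, feature_ids, seed = 1L) {
  stopifnot(length(labels) == length(feature_ids))
  set.seed(seed)
  cl <- sort(unique(labels))
  out <- vapply(cl, function(k) {
    members <- feature_ids[labels == k]
    members[sample.int(length(members), 1L)]
  }, character(1))
  setNames(out, cl)
}

#' Build a full correlation-cluster model on the training partition
#'
#' Spearman correlations, 1 - rho dissimilarities, Ward linkage, a cut at
#' the requested linkage distance and one random sentinel per cluster.
#'
#' @param m log2-scale \linkS4class{QuantMatrix}.
#' @param train_samples sample ids used to estimate correlations.
#' @param threshold linkage-distance cut.
#' @param seed sentinel-selection seed.
#' @param absolute use 1 - |rho| dissimilarities.
#' @return A \linkS4class{ClusterModel}.
#' @export
buildClusterModel <- function(m, train_samples = sampleIds(m), threshold,
                              seed = 1L, absolute = FALSE) {
  rho <- spearmanMatrix(m, train_samples)
  d <- correlationToCondensedDistance(rho, absolute = absolute)
  merges <- wardLinkage(d)
  labels <- cutAtThreshold(merges, threshold)
  fid <- featureIds(m)
  sent <- selectSentinels(labels, fid, seed = seed)
  new("ClusterModel", featureIds = fid, distances = as.numeric(d),
      merges = merges, threshold = threshold,
      labels = setNames(labels, fid), sentinels = sent,
      seed = as.integer(seed))
}

#' Write cluster membership as TSV
#'
#' One row per cluster: the sentinel (representative) protein and the
#' ";"-separated correlated members.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeClusterTable <- function(model, path) {
  members <- clusterMembers(model)
  df <- data.frame(
    cluster = names(model@sentinels),
    sentinel = unname(model@sentinels),
    n_members = lengths(members)[names(model@sentinels)],
    members = vapply(members[names(model@sentinels)],
                     paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
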