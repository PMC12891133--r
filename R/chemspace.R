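# Chemical-space analysis: exact t-SNE embedding of 2048-bit fingerprints,
# Ward.D2 hierarchical clustering of the embedded coordinates, and selection
# of one representative molecule per cluster by maximum average within-cluster
# Tanimoto similarity.

#' t-SNE embedding configuration
#'
#' Defaults follow the chemical-space protocol: three output dimensions,
#' perplexity 40, exact gradients (theta = 0).
#'
#' @param dims Output dimensionality (2 or 3).
#' @param perplexity Target perplexity; must satisfy \code{perplexity < (n-1)/3}.
#' @param theta Only 0 (exact mode) is implemented.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Gradient-descent iterations.
#' @export
embedding_config <- function(dims = 3, perplexity = 40, theta = 0, seed = 42,
                             max_iter = 600) {
  if (!dims %in% c(2, 3)) ls_stop("invalid_config", "dims must be 2 or 3")
  if (theta != 0) ls_stop("invalid_config", "only exact mode (theta = 0) is supported")
  structure(list(dims = dims, perplexity = perplexity, theta = theta,
                 seed = seed, max_iter = max_iter),
            class = "embedding_config")
}

# Conditional probabilities at a given perplexity via binary search on the
# per-point Gaussian bandwidth (standard exact t-SNE calibration).
tsne_p_matrix <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:60) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p); sp <- 1 }
      else H <- log(sp) + beta * sum(di * p) / sp
      diff <- H - target
      if (abs(diff) < 1e-5) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Embed fingerprints into low dimensions with exact t-SNE
#'
#' Exact (non-tree-approximated) t-SNE with early exaggeration and momentum,
#' run on Euclidean distances between fingerprint bit vectors. Deterministic
#' under the configuration seed.
#'
#' @param fingerprints 0/1 matrix (rows = molecules), e.g. from
#'   \code{\link{fingerprint_matrix}} with type \code{extended2048}.
#' @param config An \code{\link{embedding_config}}.
#' @return Numeric n x dims coordinate matrix (rownames preserved).
#' @export
embed_tsne <- function(fingerprints, config = embedding_config()) {
  X <- as.matrix(fingerprints)
  n <- nrow(X)
  if (config$perplexity >= (n - 1) / 3) {
    ls_stop("too_few_points", "need n > 3*perplexity + 1 points (n=%d, perplexity=%g)",
            n, config$perplexity)
  }
  d2 <- as.matrix(stats::dist(X))^2
  P <- tsne_p_matrix(d2, config$perplexity)
  with_stream(config$seed, "embed_tsne", {
    Y <- matrix(stats::rnorm(n * config$dims, sd = 1e-4), n, config$dims)
    G <- matrix(0, n, config$dims)   # momentum buffer
    gains <- matrix(1, n, config$dims)
    eta <- 200
    exag_until <- min(250, config$max_iter %/% 2)
    for (it in seq_len(config$max_iter)) {
      Pe <- if (it <= exag_until) P * 12 else P
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (it < 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      G <- mom * G - eta * gains * grad
      Y <- Y + G
      Y <- sweep(Y, 2, colMeans(Y))
    }
    rownames(Y) <- rownames(X)
    Y
  })
}

#' Hierarchical clustering of embedded coordinates
#'
#' Agglomerative clustering with the Ward.D2 criterion on Euclidean
#' distances, cut at \code{k} clusters. Cluster ids are in order of first
#' appearance in the input.
#'
#' @param coordinates Numeric matrix (rows = molecules).
#' @param k Number of clusters (1 <= k <= n).
#' @return Integer vector of cluster labels in 1..k.
#' @export
cluster_hierarchical <- function(coordinates, k) {
  n <- nrow(coordinates)
  if (k > n || k < 1) ls_stop("invalid_k", "k must lie in 1..n (k=%d, n=%d)", k, n)
  if (k == n) return(seq_len(n))
  hc <- stats::hclust(stats::dist(coordinates), method = "ward.D2")
  unname(stats::cutree(hc, k = k))
}

#' Select one representative molecule per cluster
#'
#' The representative of a cluster is the member with the highest mean
#' Tanimoto similarity to all other members (self-similarity excluded;
#' singleton clusters represent themselves). Ties break toward the lowest
#' input index.
#'
#' @param labels Integer cluster labels.
#' @param fingerprints 0/1 fingerprint matrix aligned with \code{labels};
#'   rownames (or indices) identify molecules.
#' @return Named character vector: cluster id -> molecule id.
#' @export
select_representatives <- function(labels, fingerprints) {
  stopifnot(length(labels) == nrow(fingerprints))
  ids <- rownames(fingerprints) %||% as.character(seq_len(nrow(fingerprints)))
  out <- character(0)
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    if (length(members) == 0) ls_stop("empty_cluster", "cluster %s is empty", cl)
    if (length(members) == 1) {
      out[as.character(cl)] <- ids[members]
      next
    }
    S <- tanimoto_matrix(fingerprints[members, , drop = FALSE])
    mean_sim <- (rowSums(S) - diag(S)) / (length(members) - 1)
    out[as.character(cl)] <- ids[members[which.max(mean_sim)]]
  }
  out
}

#' Run the full chemical-space analysis
#'
#' Embeds extended 2048-bit fingerprints into 3-D, clusters the coordinates
#' (Ward.D2) into \code{k} groups and picks a representative per cluster.
#'
#' @param std_smiles Named character vector (names = molecule ids) of
#'   standardized SMILES.
#' @param k Number of clusters (default 3).
#' @param config An \code{\link{embedding_config}}.
#' @param cluster_on \code{"embedding"} (default) clusters the t-SNE
#'   coordinates; \code{"fingerprints"} clusters the raw bit vectors instead.
#' @return List of class \code{cluster_result}: \code{coordinates},
#'   \code{labels}, \code{k}, \code{representatives}, \code{method}.
#' @export
chemspace_cluster <- function(std_smiles, k = 3, config = embedding_config(),
                              cluster_on = c("embedding", "fingerprints")) {
  cluster_on <- match.arg(cluster_on)
  fp <- fingerprint_matrix(std_smiles, "extended2048")
  rownames(fp) <- names(std_smiles) %||% as.character(seq_along(std_smiles))
  coords <- embed_tsne(fp, config)
  labels <- if (cluster_on == "embedding") {
    cluster_hierarchical(coords, k)
  } else {
    cluster_hierarchical(fp, k)
  }
  reps <- select_representatives(labels, fp)
  structure(list(coordinates = coords, labels = labels, k = k,
                 representatives = reps,
                 method = "ward.D2 on Euclidean distances"),
            class = "cluster_result")
}

#' Write a cluster result as CSV (`id,x,y,z,cluster,is_rep`)
#' @param result A \code{cluster_result}.
#' @param path Output path.
#' @export
write_cluster_csv <- function(result, path) {
  ids <- rownames(result$coordinates)
  df <- data.frame(id = ids,
                   x = result$coordinates[, 1],
                   y = result$coordinates[, 2],
                   z = if (ncol(result$coordinates) >= 3) result$coordinates[, 3] else NA,
                   cluster = result$labels,
                   is_rep = ids %in% result$representatives,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
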