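# independent oracles and small fixture builders, deliberately written as
# plain loops so they share no code path with the implementation

# raw_counts from a dense matrix with auto ids
rc <- function(m, genes = NULL, cells = NULL) {
  genes <- genes %||% paste0("g", seq_len(nrow(m)))
  cells <- cells %||% paste0("c", seq_len(ncol(m)))
  raw_counts(m, genes, cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense triple-loop gf-icf oracle (natural log, clamped negative ICF)
gficf_oracle <- function(counts, allow_negative_icf = FALSE) {
  counts <- as.matrix(counts)
  G <- nrow(counts); N <- ncol(counts)
  gf <- matrix(0, G, N)
  for (j in seq_len(N)) {
    tot <- sum(counts[, j])
    for (i in seq_len(G)) gf[i, j] <- counts[i, j] / tot
  }
  icf <- numeric(G)
  for (i in seq_len(G)) {
    n_i <- sum(counts[i, ] > 0)
    icf[i] <- log(N / (n_i + 1))
    if (!allow_negative_icf && icf[i] < 0) icf[i] <- 0
  }
  w <- matrix(0, G, N)
  for (j in seq_len(N)) {
    for (i in seq_len(G)) w[i, j] <- gf[i, j] * icf[i]
    nrm <- sqrt(sum(w[, j]^2))
    for (i in seq_len(G)) w[i, j] <- w[i, j] / nrm
  }
  w
}

# brute-force pair-counting ARI
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  total <- s11 + s00 + s10 + s01
  expected <- (s11 + s10) * (s11 + s01) / total
  max_term <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_term == expected) return(1)
  (s11 - expected) / (max_term - expected)
}

# all partitions of n elements into at most k blocks, as label vectors
all_partitions <- function(n, k) {
  grow <- function(labels) {
    if (length(labels) == n) return(list(labels))
    nxt <- min(max(labels) + 1, k - 1)
    out <- list()
    for (l in 0:nxt) out <- c(out, grow(c(labels, l)))
    out
  }
  grow(0L)
}

# exhaustive GSEA running-sum oracle, evaluated at every position
es_oracle <- function(ranked, stats, set, p = 1) {
  n <- length(ranked)
  hit <- ranked %in% set
  nh <- sum(hit)
  if (nh == 0) return(NA_real_)
  w <- if (p > 0) abs(stats)^p else rep(1, n)
  denom_hit <- sum(w[hit])
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- if (hit[i]) run + w[i] / denom_hit else run - 1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# O(n^2) brute-force Jaccard k-NN graph oracle on coordinates
knn_jaccard_oracle <- function(coords, k) {
  n <- nrow(coords)
  nnsets <- vector("list", n)
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(coords, 2, coords[i, ])))
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    nnsets[[i]] <- ord[seq_len(k)]
  }
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (i %in% nnsets[[j]] || j %in% nnsets[[i]]) {
        inter <- length(intersect(nnsets[[i]], nnsets[[j]]))
        jac <- inter / length(union(nnsets[[i]], nnsets[[j]]))
        if (jac > 0) out[[length(out) + 1]] <- c(i, j, jac)
      }
    }
  }
  do.call(rbind, out)
}

# weighted-graph modularity recomputed directly from the definition
modularity_oracle <- function(edges_idx, weights, membership) {
  m2 <- 2 * sum(weights)
  n <- length(membership)
  deg <- numeric(n)
  for (e in seq_along(weights)) {
    deg[edges_idx[e, 1]] <- deg[edges_idx[e, 1]] + weights[e]
    deg[edges_idx[e, 2]] <- deg[edges_idx[e, 2]] + weights[e]
  }
  q <- 0
  for (e in seq_along(weights)) {
    if (membership[edges_idx[e, 1]] == membership[edges_idx[e, 2]]) {
      q <- q + 2 * weights[e]
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) q <- q - deg[i] * deg[j] / m2
    }
  }
  q / m2
}

# mean silhouette of a labeling on coordinates (Euclidean)
silhouette_oracle <- function(coords, labels) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per, centers, sd = 0.05, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  coords <- do.call(rbind, lapply(seq_len(k), function(b) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[b, ], n_per, ncol(centers), byrow = TRUE)
  }))
  rownames(coords) <- paste0("c", seq_len(nrow(coords)))
  list(coords = coords, labels = rep(seq_len(k), each = n_per))
}
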