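#' Principal-component meta-genes
#'
#' Projects cells onto the top principal axes of the gf-icf weight matrix
#' (cells are observations, genes are features). The resulting scores act as
#' "meta-genes": a compact feature set fed to the 2-D embedder. Gene-wise
#' mean-centering is applied before projection; no variance scaling (the
#' L2 step already puts cells on a comparable scale). The sign of each
#' component is fixed by forcing its largest-magnitude gene loading to be
#' positive, so results are reproducible across BLAS implementations.
#'
#' @param g A `gficf_matrix` (or any genes x cells numeric matrix).
#' @param n_components Number of components to keep (default 50, capped
#'   explanations in the error message when too large).
#' @param center Gene-wise mean centering (default `TRUE`).
#' @return An object of class `meta_genes`: list with `scores` (cells x
#'   n_components, rownames = cell ids), `explained_variance`,
#'   `n_components`, `rotation`.
#' @export
pca_meta_genes <- function(g, n_components = 50, center = TRUE) {
  x <- if (inherits(g, "gficf_matrix")) g$weights else g
  X <- t(as.matrix(x))                      # cells x genes
  max_comp <- min(dim(X)) - 1
  if (n_components > max_comp) {
    stop("n_components = ", n_components, " exceeds the admissible maximum ",
         max_comp, " (min(genes, cells) - 1)")
  }
  pc <- prcomp(X, center = center, scale. = FALSE, rank. = n_components)
  scores <- pc$x
  rotation <- pc$rotation
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(scores))) {
    i_max <- which.max(abs(rotation[, j]))
    if (rotation[i_max, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(x)
  structure(list(scores = scores,
                 explained_variance = pc$sdev[seq_len(n_components)]^2,
                 n_components = n_components,
                 rotation = rotation),
            class = "meta_genes")
}

#' @export
print.meta_genes <- function(x, ...) {
  pct <- 100 * sum(x$explained_variance) /
    max(sum(x$explained_variance), .Machine$double.eps)
  cat(sprintf("<meta_genes> %d cells x %d components\n",
              nrow(x$scores), x$n_components))
  invisible(x)
}

#' Embed cells in two dimensions
#'
#' Runs exact t-SNE on the meta-gene scores. Defaults follow the standard
#' reproducible setup for droplet scRNA-seq: seed 0 and perplexity 30 on 50
#' principal components. The same seed and input always give identical
#' coordinates. UMAP is accepted as a method name for interface
#' compatibility but no UMAP implementation is available in this build; it
#' raises an informative error.
#'
#' @param mg A `meta_genes` object (or a cells x d numeric matrix).
#' @param method `"tsne"` (implemented) or `"umap"` (errors).
#' @param seed Random seed for the embedding initialization.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (cells - 1) / 3`.
#' @param max_iter Gradient-descent iterations (default 1000).
#' @param eta Learning rate (default 200).
#' @return An object of class `embedding`: list with `coords` (cells x 2,
#'   rownames = cell ids), `method`, `seed`, `perplexity`, `rescaled`.
#' @export
embed_cells <- function(mg, method = c("tsne", "umap"), seed = 0,
                        perplexity = 30, max_iter = 1000, eta = 200) {
  method <- match.arg(method)
  X <- if (inherits(mg, "meta_genes")) mg$scores else as.matrix(mg)
  if (method == "umap") {
    stop("no UMAP implementation is available in this build; ",
         "use method = \"tsne\"")
  }
  n <- nrow(X)
  if (!all(is.finite(X))) stop("embedding input contains non-finite values")
  if (perplexity >= (n - 1) / 3) {
    stop("perplexity = ", perplexity, " too large for ", n,
         " cells (requires perplexity < (cells - 1) / 3)")
  }
  set.seed(seed)
  Y0 <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  Y <- tsne_exact_cpp(X, Y0, perplexity = perplexity, max_iter = max_iter,
                      eta = eta, exaggeration = 12,
                      stop_lying_iter = 250, mom_switch_iter = 250,
                      momentum_init = 0.5, momentum_final = 0.8)
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("x", "y")
  structure(list(coords = Y, method = method, seed = seed,
                 perplexity = perplexity, rescaled = FALSE),
            class = "embedding")
}

#' Rescale embedding coordinates to \[-1, 1\]
#'
#' Each axis is mapped linearly and independently so that its minimum lands
#' on -1 and its maximum on +1; an axis where all cells coincide maps to 0.
#' Distances between cells of the same type are conventionally computed on
#' these rescaled coordinates so that they are comparable across embeddings.
#'
#' @param e An `embedding`.
#' @return The `embedding` with rescaled coordinates and `rescaled = TRUE`.
#' @export
rescale_coords <- function(e) {
  stopifnot(inherits(e, "embedding"))
  if (nrow(e$coords) < 2) stop("need at least 2 cells to rescale")
  coords <- apply(e$coords, 2, function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(0, length(v)))
    2 * (v - r[1]) / (r[2] - r[1]) - 1
  })
  dimnames(coords) <- dimnames(e$coords)
  e$coords <- coords
  e$rescaled <- TRUE
  e
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d cells, method = %s, seed = %d%s\n",
              nrow(x$coords), x$method, x$seed,
              if (x$rescaled) ", rescaled to [-1, 1]" else ""))
  invisible(x)
}

#' @rdname embed_cells
#' @param x An `embedding`.
#' @param ... Unused.
#' @return `tidy()`: tibble with `cell_id`, `x`, `y`.
#' @export
tidy.embedding <- function(x, ...) {
  coords <- x$coords
  tibble::tibble(cell_id = rownames(coords),
                 x = unname(coords[, 1]), y = unname(coords[, 2]))
}

#' Write an embedding as TSV
#'
#' @param e An `embedding`.
#' @param path Output TSV path (`cell_id`, `x`, `y`).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(e, path) {
  readr::write_tsv(tidy(e), path, progress = FALSE)
  invisible(path)
}
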