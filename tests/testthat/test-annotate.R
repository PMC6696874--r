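tiny_gficf <- function() {
  # hand-sized sparse gf-icf matrix for signature tests; sparse enough that
  # every cell keeps at least one positive-ICF gene
  set.seed(15)
  counts <- matrix(rpois(30 * 9, 0.6), 30, 9)
  counts[cbind(1:9, 1:9)] <- counts[cbind(1:9, 1:9)] + 2  # private genes
  gficf_transform(rc(counts))
}

test_that("a single-cell cluster's signature is that cell's weight order", {
  g <- tiny_gficf()
  cl <- tibble::tibble(cell_id = g$cell_ids,
                       cluster = c(0L, rep(1L, 8)))
  sig <- cluster_signature(g, cl, size = 100)
  s0 <- dplyr::filter(sig, cluster == 0)
  w <- as.numeric(g$weights[, 1])
  expect_identical(s0$gene_id,
                   g$gene_ids[order(-w, g$gene_ids)][seq_len(nrow(s0))])
  expect_true(all(diff(s0$score) <= 1e-15))
  expect_true(all(s0$score > 0))   # only positive aggregate scores kept
})

test_that("signature ties break lexicographically and size is honored", {
  w <- Matrix::sparseMatrix(i = c(1, 2, 3, 4), j = c(1, 1, 2, 2),
                            x = c(0.5, 0.5, 1, 0.3), dims = c(4, 2))
  g <- structure(list(weights = w, gene_ids = c("zeta", "alpha", "mid", "low"),
                      cell_ids = c("c1", "c2"), icf = NULL, params = list()),
                 class = "gficf_matrix")
  dimnames(g$weights) <- list(g$gene_ids, g$cell_ids)
  sig <- cluster_signature(g, tibble::tibble(cell_id = c("c1", "c2"),
                                             cluster = c(0L, 0L)), size = 3)
  # aggregates: zeta 0.5, alpha 0.5, mid 1, low 0.3 -> mid, alpha, zeta
  expect_identical(sig$gene_id, c("mid", "alpha", "zeta"))
  expect_error(
    cluster_signature(g, tibble::tibble(cell_id = "nope", cluster = 0L)),
    "absent")
})

test_that("enrichment_score reproduces analytic extremes", {
  ranked <- paste0("g", 1:10)
  stats <- seq(10, 1)
  # set == top 3 of the list, unweighted: ES = 1 (max deviation at rank 3)
  expect_equal(enrichment_score(ranked, stats, ranked[1:3],
                                weight_exponent = 0), 1)
  # set == bottom 3: mirror case, ES = -1
  expect_equal(enrichment_score(ranked, stats, ranked[8:10],
                                weight_exponent = 0), -1)
  # empty intersection is missing, not zero
  expect_identical(enrichment_score(ranked, stats, c("x", "y")), NA_real_)
})

test_that("enrichment_score matches the exhaustive running-sum oracle", {
  set.seed(33)
  for (rep in 1:25) {
    n <- 50
    ranked <- paste0("g", sample(1000, n))
    stats <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    set <- sample(ranked, 8)
    for (p in c(0, 1)) {
      expect_equal(enrichment_score(ranked, stats, set, weight_exponent = p),
                   es_oracle(ranked, stats, set, p = p), tolerance = 1e-12)
    }
  }
})

test_that("enrichment_score ignores identities of genes outside the set", {
  ranked <- paste0("g", 1:30)
  stats <- seq(30, 1) / 10
  set <- c("g3", "g7", "g20")
  relabeled <- ranked
  out <- !ranked %in% set
  relabeled[out] <- paste0("x", seq_len(sum(out)))
  expect_equal(enrichment_score(ranked, stats, set),
               enrichment_score(relabeled, stats, set))
})

test_that("annotate_clusters recovers planted types end-to-end", {
  sim <- simulate_counts(sim_config(n_types = 3, cells_per_type = 60,
                                    n_genes = 400, seed = 5))
  g <- gficf_transform(sim$counts)
  # use the true types as the clustering: assignments must map back
  cl <- tibble::tibble(cell_id = sim$labels$cell_id,
                       cluster = as.integer(factor(sim$labels$cell_type)) - 1L)
  sig <- cluster_signature(g, cl, size = 50)
  panel <- simulate_reference_panel(sim, noise_sd = 0.2, seed = 5)
  ann <- annotate_clusters(sig, panel, n_permutations = 200, seed = 0)
  truth_map <- levels(factor(sim$labels$cell_type))
  expect_identical(ann$assignments$assigned_type,
                   truth_map[ann$assignments$cluster + 1])
  expect_true(all(ann$table$es >= -1 & ann$table$es <= 1))
  # deterministic given seed
  ann2 <- annotate_clusters(sig, panel, n_permutations = 200, seed = 0)
  expect_identical(ann$table, ann2$table)
})

test_that("signatures disjoint from the panel are unassigned", {
  g <- tiny_gficf()
  cl <- tibble::tibble(cell_id = g$cell_ids, cluster = 0L)
  sig <- cluster_signature(g, cl, size = 5)
  expr <- matrix(rexp(40), 20, 2,
                 dimnames = list(paste0("other", 1:20), c("s1", "s2")))
  panel <- suppressWarnings(reference_panel(expr, c("tA", "tA")))
  expect_warning(ann <- annotate_clusters(sig, panel, n_permutations = 10),
                 "shared")
  expect_identical(ann$assignments$assigned_type, "unassigned")
})

test_that("gmt export writes one ranked line per cluster", {
  g <- tiny_gficf()
  cl <- tibble::tibble(cell_id = g$cell_ids,
                       cluster = rep(c(0L, 1L, 2L), each = 3))
  sig <- cluster_signature(g, cl, size = 4)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sig, path)
  lines <- strsplit(readLines(path), "\t")
  expect_length(lines, 3)
  expect_identical(vapply(lines, `[`, "", 1),
                   c("cluster_0", "cluster_1", "cluster_2"))
  expect_identical(lines[[1]][-(1:2)],
                   dplyr::filter(sig, cluster == 0)$gene_id)
})
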