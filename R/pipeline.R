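#' Pipeline configuration
#'
#' Collects every tunable parameter of the full pipeline with the
#' conventional defaults: QC at 500 genes / 1,500 UMI / 10% mitochondrial
#' fraction, 50 principal components, t-SNE with seed 0 and perplexity 30,
#' k = 50 graph neighbors, top-100 gene signatures, 1,000 GSEA
#' permutations. Per-stage seeds are derived deterministically from the
#' single global seed so any stage can be rerun in isolation.
#'
#' @param min_genes,min_umi,max_mito_fraction QC thresholds
#'   (see [qc_thresholds()]).
#' @param icf_smoothing,allow_negative_icf ICF options
#'   (see [gficf_transform()]).
#' @param n_components Number of PCA meta-genes.
#' @param embed_method `"tsne"` (see [embed_cells()]).
#' @param perplexity t-SNE perplexity.
#' @param tsne_max_iter t-SNE gradient-descent iterations.
#' @param k Graph neighborhood size.
#' @param signature_size Genes per cluster signature.
#' @param n_permutations GSEA permutation count.
#' @param weight_exponent GSEA weighting exponent.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_genes = 500, min_umi = 1500,
                            max_mito_fraction = 0.1,
                            icf_smoothing = "add_one_denominator",
                            allow_negative_icf = FALSE,
                            n_components = 50, embed_method = "tsne",
                            perplexity = 30, tsne_max_iter = 1000,
                            k = 50, signature_size = 100,
                            n_permutations = 1000, weight_exponent = 1,
                            seed = 0) {
  structure(as.list(environment()), class = "pipeline_config")
}

# derive a per-stage seed (< 2^31) from the global seed and the stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer(((seed %% 1000003) * 131 + h) %% 2147483647)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full gf-icf pipeline
#'
#' Executes QC filtering, the gf-icf transform, PCA meta-genes, the 2-D
#' t-SNE embedding with \[-1, 1\] rescaling, Jaccard k-NN graph
#' construction, Louvain clustering and signature extraction — and, when a
#' reference panel or truth labels are supplied, GSEA annotation and
#' evaluation metrics. When `out_dir` is given, every stage writes its
#' artifact (`qc_report.tsv`, `gficf/`, `pca.tsv`, `embedding.tsv`,
#' `graph.tsv`, `clusters.tsv`, `signatures.gmt`, `annotation.tsv`,
#' `metrics.json`, `run.log`); identical inputs, config and seed produce
#' byte-identical outputs.
#'
#' @param counts A [raw_counts] object, or a path readable by
#'   [read_counts()].
#' @param config A [pipeline_config].
#' @param panel Optional [reference_panel] (or `NULL`).
#' @param truth Optional tibble with `cell_id`, `cell_type` truth labels.
#' @param group_map Optional label grouping for accuracy computation.
#' @param out_dir Optional output directory for artifacts.
#' @param stop_after Optional stage name (`"qc"`, `"gficf"`, `"pca"`,
#'   `"embedding"`, `"graph"`, `"clusters"`, `"signatures"`): stop the
#'   pipeline after that stage.
#' @param format Count-file format when `counts` is a path.
#' @param verbose Print stage progress messages.
#' @return A list of class `gficf_pipeline` with elements `qc`, `gficf`,
#'   `meta_genes`, `embedding`, `graph`, `clustering`, `signatures`,
#'   `annotation`, `metrics` (later elements `NULL` when not reached or not
#'   requested), plus the effective `config`.
#' @export
run_pipeline <- function(counts, config = pipeline_config(), panel = NULL,
                         truth = NULL, group_map = NULL, out_dir = NULL,
                         stop_after = NULL, format = "mtx_triplet",
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  # no timestamp in the log: reruns with identical inputs must be
  # byte-identical across every artifact, run.log included
  log_lines <- c("scgficf pipeline run",
                 "effective parameters:",
                 sprintf("  %s = %s", names(unclass(config)),
                         vapply(unclass(config), function(v)
                           paste(format(v), collapse = ","), character(1))))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(name, writer) if (!is.null(out_dir)) writer(file.path(out_dir, name))
  done <- function(res, stage) {
    if (!is.null(out_dir)) {
      writeLines(log_lines, file.path(out_dir, "run.log"))
    }
    if (!is.null(stop_after) && identical(stage, stop_after)) res else NULL
  }
  res <- list(config = config)
  class(res) <- "gficf_pipeline"

  if (is.character(counts)) {
    counts <- pipeline_stage("read_counts",
                             read_counts(counts, format = format))
  }
  stopifnot(inherits(counts, "raw_counts"))

  say("QC filtering ", ncol(counts$counts), " cells")
  res$qc <- pipeline_stage("qc_filter", qc_filter(counts, qc_thresholds(
    min_genes = config$min_genes, min_umi = config$min_umi,
    max_mito_fraction = config$max_mito_fraction)))
  log_lines <- c(log_lines, sprintf("qc: %d / %d cells retained",
                                    sum(res$qc$report$pass),
                                    nrow(res$qc$report)))
  emit("qc_report.tsv", function(p) write_qc_report(res$qc, p))
  if (!is.null(done(res, "qc"))) return(res)

  say("gf-icf transform")
  res$gficf <- pipeline_stage("gficf_transform", gficf_transform(
    res$qc$counts, smoothing = config$icf_smoothing,
    allow_negative_icf = config$allow_negative_icf))
  if (!is.null(out_dir)) write_gficf(res$gficf, file.path(out_dir, "gficf"))
  if (!is.null(done(res, "gficf"))) return(res)

  say("PCA meta-genes (", config$n_components, " components)")
  res$meta_genes <- pipeline_stage("pca_meta_genes", pca_meta_genes(
    res$gficf, n_components = config$n_components))
  emit("pca.tsv", function(p) {
    df <- tibble::as_tibble(res$meta_genes$scores, .name_repair = "minimal")
    names(df) <- paste0("PC", seq_len(ncol(df)))
    readr::write_tsv(dplyr::bind_cols(
      tibble::tibble(cell_id = rownames(res$meta_genes$scores)), df), p,
      progress = FALSE)
  })
  if (!is.null(done(res, "pca"))) return(res)

  say("t-SNE embedding")
  res$embedding <- pipeline_stage("embed", rescale_coords(embed_cells(
    res$meta_genes, method = config$embed_method,
    seed = stage_seed(config$seed, "embed"),
    perplexity = config$perplexity, max_iter = config$tsne_max_iter)))
  emit("embedding.tsv", function(p) write_embedding(res$embedding, p))
  if (!is.null(done(res, "embedding"))) return(res)

  say("k-NN Jaccard graph (k = ", config$k, ")")
  res$graph <- pipeline_stage("knn_graph",
                              knn_graph(res$embedding, k = config$k))
  emit("graph.tsv", function(p) write_graph_tsv(res$graph, p))
  if (!is.null(done(res, "graph"))) return(res)

  say("Louvain clustering")
  res$clustering <- pipeline_stage("louvain_cluster", louvain_cluster(
    res$graph, seed = stage_seed(config$seed, "louvain")))
  log_lines <- c(log_lines, sprintf("clustering: %d clusters, modularity %.6f",
                                    res$clustering$n_clusters,
                                    res$clustering$modularity))
  emit("clusters.tsv", function(p) write_clusters(res$clustering, p))
  if (!is.null(done(res, "clusters"))) return(res)

  say("cluster signatures")
  res$signatures <- pipeline_stage("cluster_signature", cluster_signature(
    res$gficf, res$clustering, size = config$signature_size))
  emit("signatures.gmt", function(p) write_gmt(res$signatures, p))
  if (!is.null(done(res, "signatures"))) return(res)

  if (!is.null(panel)) {
    say("GSEA annotation against ", length(panel$cell_types),
        " reference types")
    res$annotation <- pipeline_stage("annotate_clusters", annotate_clusters(
      res$signatures, panel, n_permutations = config$n_permutations,
      seed = stage_seed(config$seed, "gsea"),
      weight_exponent = config$weight_exponent))
    emit("annotation.tsv", function(p) write_annotation(res$annotation, p))
  }

  if (!is.null(truth)) {
    say("evaluation metrics")
    assigned <- NULL
    if (!is.null(res$annotation)) {
      assigned <- res$clustering$labels |>
        dplyr::left_join(res$annotation$assignments, by = "cluster") |>
        dplyr::select("cell_id", "assigned_type")
    }
    res$metrics <- pipeline_stage("evaluate", evaluate_clustering(
      res$clustering, truth, e = res$embedding, assigned = assigned,
      group_map = group_map))
    log_lines <- c(log_lines, sprintf("metrics: ari %.6f purity %.6f",
                                      res$metrics$ari, res$metrics$purity))
    emit("metrics.json", function(p) write_metrics(res$metrics, p))
  }
  if (!is.null(out_dir)) writeLines(log_lines, file.path(out_dir, "run.log"))
  res
}

#' @export
print.gficf_pipeline <- function(x, ...) {
  cat("<gficf_pipeline>\n")
  if (!is.null(x$qc)) print(x$qc)
  if (!is.null(x$gficf)) print(x$gficf)
  if (!is.null(x$clustering)) print(x$clustering)
  if (!is.null(x$annotation)) print(x$annotation)
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
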