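# End-to-end orchestration: QC -> normalize/denoise -> cluster/annotate ->
# pseudotime -> pathology mixed model -> trajectory screen -> enrichment ->
# IF statistics, from one flat configuration, with every stage's output
# persisted as plain TSV/MTX and a YAML manifest.

#' Pipeline configuration
#'
#' A flat list of stage parameters and optional input paths. Either supply
#' `data` (an in-memory dataset with `counts` and `meta`) or `paths$counts`
#' (a directory readable by [read_count_matrix()]).
#'
#' @param data optional in-memory dataset (`synthetic_dataset` or list with
#'   `counts`, `meta`).
#' @param paths named list of input paths: `counts` (dataset directory) and
#'   optionally `signatures`, `homology`, `gmt`, `if_counts`, `tf_list`.
#' @param seed RNG seed for the run.
#' @param min_nuclei,max_genes QC thresholds.
#' @param target_sum normalization target (`NULL` = median depth).
#' @param denoise `"knn"` or `"none"`.
#' @param denoise_k,denoise_n_pcs neighbors and PCA dimensionality of the
#'   expression smoothing used for the per-gene screen. The screen smoother
#'   uses a compact PC space (default 10) because neighbor quality in the
#'   few high-variance components decides how much per-gene trajectory
#'   signal survives the averaging; the pseudotime stage smooths in its own
#'   `dpt_n_pcs`-dimensional space.
#' @param resolutions Leiden resolution sweep.
#' @param graph_k,graph_n_pcs neighbor-graph parameters.
#' @param panels marker panels for annotation (default [marker_panels()]).
#' @param homeo_genes homeostatic panel for the root rule (default: the
#'   canonical homeostatic labels of the synthetic generator).
#' @param dpt_k,dpt_n_pcs,dpt_n_comps diffusion-map parameters.
#' @param screen a [screen_config()].
#' @param lmm_scale pseudotime scale entering the pathology mixed model:
#'   `"raw"` (default) or `"rank"` (rank-uniformized across the astrocyte
#'   nuclei, which undoes the compression of within-population pseudotime
#'   that a dominant between-population diffusion mode can cause).
#' @param datagen optional [simulation_config()] for [simulate_and_run()].
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(data = NULL, paths = list(), seed = 1L,
                            min_nuclei = 30L, max_genes = 2500L,
                            target_sum = NULL,
                            denoise = c("knn", "none"),
                            denoise_k = 30L, denoise_n_pcs = 10L,
                            resolutions = c(0.1, 0.25, 0.5, 1),
                            graph_k = 15L, graph_n_pcs = 30L,
                            panels = marker_panels(),
                            homeo_genes = c("NRXN1", "NRG3", "GPC5", "ERBB4", "NFIA"),
                            dpt_k = 30L, dpt_n_pcs = 30L, dpt_n_comps = 15L,
                            screen = screen_config(),
                            lmm_scale = c("raw", "rank"),
                            datagen = NULL) {
  structure(list(data = data, paths = paths, seed = as.integer(seed),
                 min_nuclei = min_nuclei, max_genes = max_genes,
                 target_sum = target_sum, denoise = match.arg(denoise),
                 denoise_k = denoise_k, denoise_n_pcs = denoise_n_pcs,
                 resolutions = resolutions, graph_k = graph_k,
                 graph_n_pcs = graph_n_pcs, panels = panels,
                 homeo_genes = homeo_genes, dpt_k = dpt_k,
                 dpt_n_pcs = dpt_n_pcs, dpt_n_comps = dpt_n_comps,
                 screen = screen, lmm_scale = match.arg(lmm_scale),
                 datagen = datagen),
            class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  for (p in names(config$paths)) {
    if (!is.null(config$paths[[p]]) && !file.exists(config$paths[[p]])) {
      stop("configured path does not exist: ", p, " = ", config$paths[[p]],
           call. = FALSE)
    }
  }
  if (is.null(config$data) && is.null(config$paths$counts) &&
      is.null(config$datagen)) {
    stop("no input: supply data, paths$counts, or a datagen block", call. = FALSE)
  }
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes QC, normalization (and optional kNN denoising), the clustering
#' resolution sweep with Wilcoxon markers and panel annotation, the
#' cluster-flow table, diffusion pseudotime over the astrocyte populations
#' (root among protoplasmic nuclei), per-population pathology mixed models,
#' the trajectory regression screen with MA tables on protoplasmic nuclei,
#' and (when inputs are configured) signature enrichment and IF statistics.
#' Every stage's table is written under `outdir`; identical config + seed
#' gives identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  res <- list()

  res$input <- run_stage("load", {
    if (!is.null(config$data)) {
      list(counts = as_sparse_counts(config$data$counts), meta = config$data$meta)
    } else {
      list(counts = read_count_matrix(config$paths$counts),
           meta = read_nucleus_meta(config$paths$counts))
    }
  })

  res$qc <- run_stage("qc", {
    m <- filter_genes_min_nuclei(res$input$counts, config$min_nuclei)
    m <- filter_nuclei_gene_count(m, config$max_genes)
    meta <- res$input$meta[match(rownames(m), res$input$meta$nucleus_id), ]
    list(counts = m, meta = meta)
  })

  # Clustering and marker detection run on unsmoothed normalized data;
  # denoising is applied within each analysis population downstream (the
  # cluster-aware analog of model-based denoising), so neighbors from other
  # populations cannot leak expression across cluster boundaries.
  res$expr <- run_stage("normalize", {
    normalize_log(res$qc$counts, config$target_sum)
  })
  denoise <- function(e, n_pcs = config$denoise_n_pcs) {
    if (config$denoise == "knn") {
      knn_smooth(e, k = min(config$denoise_k, nrow(e) - 1L), n_pcs = n_pcs)
    } else {
      e
    }
  }

  res$clusters <- run_stage("cluster", {
    graph <- build_knn_graph(res$expr, n_pcs = config$graph_n_pcs,
                             k = config$graph_k)
    assignments <- cluster_sweep(graph, config$resolutions, seed = config$seed)
    write_tsv(cbind(nucleus_id = rownames(assignments), assignments),
              file.path(outdir, "cluster_assignments.tsv"))
    flow <- cluster_flow_table(assignments)
    write_tsv(flow, file.path(outdir, "cluster_flow.tsv"))
    list(graph = graph, assignments = assignments, flow = flow)
  })

  res$annotation <- run_stage("annotate", {
    assignments <- res$clusters$assignments
    n_cl <- vapply(assignments, function(x) length(unique(x)), integer(1))
    pick <- which(n_cl >= 4)
    col <- if (length(pick) > 0) colnames(assignments)[pick[1]] else
      colnames(assignments)[which.max(n_cl)]
    labels <- assignments[[col]]
    markers <- wilcoxon_markers(res$expr, labels)
    write_tsv(markers, file.path(outdir, "marker_table.tsv"))
    ann <- annotate_clusters(markers, config$panels)
    write_tsv(ann, file.path(outdir, "cluster_labels.tsv"))
    nucleus_label <- ann$label[match(labels, ann$cluster)]
    list(resolution = col, markers = markers, clusters = ann,
         nucleus_label = nucleus_label)
  })

  res$pseudotime <- run_stage("pseudotime", {
    lab <- res$annotation$nucleus_label
    astro <- lab %in% c("protoplasmic", "fibrous")
    if (!any(astro)) stop("no astrocyte clusters found")
    expr_astro <- denoise(res$expr[astro, , drop = FALSE],
                          n_pcs = config$dpt_n_pcs)
    proto_ids <- rownames(res$expr)[lab == "protoplasmic"]
    pt <- compute_pseudotime(expr_astro, homeo_genes = config$homeo_genes,
                             candidates = proto_ids, k = config$dpt_k,
                             n_pcs = config$dpt_n_pcs,
                             n_comps = config$dpt_n_comps)
    write_tsv(pt, file.path(outdir, "pseudotime.tsv"))
    pt
  })

  res$lmm <- run_stage("mixed_model", {
    pt <- res$pseudotime
    if (identical(config$lmm_scale, "rank")) pt$t <- rank_uniform(pt$t)
    lab <- res$annotation$nucleus_label
    fits <- list()
    for (pop in c("protoplasmic", "fibrous")) {
      ids <- rownames(res$expr)[lab == pop]
      rows <- pt$nucleus_id %in% ids
      meta <- res$qc$meta[match(pt$nucleus_id[rows], res$qc$meta$nucleus_id), ]
      fits[[pop]] <- tryCatch(
        fit_random_intercept_lmm(pt$t[rows], meta),
        error = function(e) e$message)
    }
    tabs <- lapply(names(fits), function(pop) {
      f <- fits[[pop]]
      if (!inherits(f, "lmm_fit")) return(NULL)
      cbind(population = pop, f$coefficients)
    })
    write_tsv(do.call(rbind, tabs), file.path(outdir, "lmm_coefficients.tsv"))
    fits
  })

  res$screen <- run_stage("screen", {
    pt <- res$pseudotime
    lab <- res$annotation$nucleus_label
    proto_ids <- rownames(res$expr)[lab == "protoplasmic"]
    rows <- pt$nucleus_id %in% proto_ids
    ranked <- rank_uniform(pt$t[rows], scale = config$screen$rank_scale)
    expr_p <- denoise(res$expr[match(pt$nucleus_id[rows], rownames(res$expr)), ,
                               drop = FALSE])
    records <- gene_trajectory_regression(expr_p, ranked, config$screen)
    write_tsv(records, file.path(outdir, "screen_records.tsv"))
    sig <- classify_dysregulated(records, config$screen)
    write_tsv(data.frame(gene = c(sig$up, sig$down),
                         direction = rep(c("up", "down"),
                                         c(length(sig$up), length(sig$down)))),
              file.path(outdir, "signature.tsv"))
    ma <- ma_table(records, config$screen)
    write_tsv(ma, file.path(outdir, "ma_table.tsv"))
    list(records = records, signature = sig[c("up", "down")], ma = ma)
  })

  res$enrichment <- run_stage("enrichment", {
    out <- list()
    universe <- colnames(res$expr)
    own <- unique(c(res$screen$signature$up, res$screen$signature$down))
    if (!is.null(config$paths$homology) && !is.null(config$paths$signatures)) {
      hmap <- read_homology_map(config$paths$homology)
      sig_tab <- read.delim(config$paths$signatures, stringsAsFactors = FALSE)
      mapped <- map_homologs(sig_tab$gene, hmap, universe,
                             directions = sig_tab$direction)
      out$overlap <- overlap_fisher(mapped$mapped, own, universe)
      write_tsv(data.frame(t(out$overlap$table),
                           p.value = out$overlap$p.value,
                           odds.ratio = out$overlap$odds.ratio),
                file.path(outdir, "signature_overlap.tsv"))
    }
    if (!is.null(config$paths$tf_list) && length(own) > 0) {
      tfs <- readLines(config$paths$tf_list)
      out$tf <- tf_enrichment(res$screen$signature, tfs, universe)
      write_tsv(out$tf, file.path(outdir, "tf_enrichment.tsv"))
    }
    if (!is.null(config$paths$gmt) && length(own) > 0) {
      sets <- read_gmt(config$paths$gmt)
      out$ora <- ora_gene_sets(own, sets, universe)
      write_tsv(out$ora, file.path(outdir, "ora.tsv"))
    }
    out
  })

  res$ifstats <- if (is.null(config$paths$if_counts)) NULL else run_stage("if_stats", {
    tab <- read_if_counts(config$paths$if_counts)
    rows <- lapply(unique(tab$marker), function(mk) {
      cmp <- compare_proportions(pool_counts(tab, mk))
      data.frame(marker = mk,
                 group_1 = rownames(cmp$table)[1],
                 prop_1 = cmp$proportions[1],
                 group_2 = rownames(cmp$table)[2],
                 prop_2 = cmp$proportions[2],
                 odds.ratio = cmp$odds.ratio, p.value = cmp$p.value,
                 stringsAsFactors = FALSE)
    })
    iftab <- do.call(rbind, rows)
    write_tsv(iftab, file.path(outdir, "if_proportions.tsv"))
    iftab
  })

  run_stage("manifest", {
    cfg_for_hash <- config
    cfg_for_hash$data <- NULL
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(yaml::as.yaml(cfg_for_hash[!vapply(cfg_for_hash, is.function, logical(1))]), tmp)
    manifest <- list(seed = config$seed,
                     config_md5 = unname(tools::md5sum(tmp)),
                     r_version = as.character(getRversion()),
                     n_nuclei = nrow(res$expr), n_genes = ncol(res$expr),
                     resolution_used = res$annotation$resolution)
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  })

  invisible(res)
}

#' Simulate a dataset and run the pipeline on it
#'
#' Calls [simulate_dataset()] with the `datagen` block, writes the dataset,
#' runs [run_pipeline()], and appends a machine-readable recovery report
#' comparing the inferred signature to the planted truth (sensitivity per
#' direction and the false-discovery proportion among classified genes).
#'
#' @param config a [pipeline_config()] with a `datagen` block.
#' @param outdir output directory.
#' @return invisible list: pipeline results plus `recovery`.
#' @export
simulate_and_run <- function(config, outdir) {
  if (is.null(config$datagen)) stop("config has no datagen block", call. = FALSE)
  ds <- simulate_dataset(config$datagen)
  write_dataset(ds, file.path(outdir, "data"))
  config$data <- ds
  res <- run_pipeline(config, outdir)
  res$recovery <- signature_recovery(res$screen$signature, ds$truth)
  jsonlite::write_json(res$recovery, file.path(outdir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Score an inferred signature against the planted truth
#'
#' Sensitivity is measured on the planted top programs (the `up`/`down`
#' truth directions). A classified gene counts as a false discovery when its
#' true slope is zero (null or marker gene) or of the opposite sign — genes
#' of the broad weak program called with the correct sign are true, if
#' sub-threshold, associations.
#'
#' @param inferred list with `up` and `down` gene vectors.
#' @param truth the `truth` element of a `synthetic_dataset` (or a list with
#'   `up`/`down` gene vectors, in which case anything outside them is
#'   treated as null).
#' @return list: sensitivity per direction, false-discovery proportion among
#'   classified genes, and the classified counts.
#' @export
signature_recovery <- function(inferred, truth) {
  if (inherits(truth, "synthetic_dataset")) truth <- truth$truth
  if (!is.null(truth$genes)) {
    g <- truth$genes
    top_up <- g$gene[g$direction == "up"]
    top_down <- g$gene[g$direction == "down"]
    pos <- g$gene[g$slope > 0]
    neg <- g$gene[g$slope < 0]
  } else {
    top_up <- pos <- truth$up
    top_down <- neg <- truth$down
  }
  tp_up <- length(intersect(inferred$up, top_up))
  tp_down <- length(intersect(inferred$down, top_down))
  n_called <- length(inferred$up) + length(inferred$down)
  n_false <- sum(!(inferred$up %in% pos)) + sum(!(inferred$down %in% neg))
  list(sensitivity_up = if (length(top_up)) tp_up / length(top_up) else NA,
       sensitivity_down = if (length(top_down)) tp_down / length(top_down) else NA,
       fdp = if (n_called == 0) 0 else n_false / n_called,
       n_up = length(inferred$up), n_down = length(inferred$down))
}
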