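#' Default pipeline configuration
#'
#' Returns the full default configuration for [run_full_pipeline()], with
#' every seed and tunable surfaced. Fields under `synth` feed
#' [synth_config()] when no input files are given; `files` may instead point
#' to `network`, `expression`, `clinical`, `metabolite_sets`,
#' `gene_sets`, `tme` paths.
#'
#' @param ... Overrides, merged recursively.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = tempfile("mpinet_run_"),
    synth = list(),                 # synth_config() overrides
    files = list(),                 # optional real-data inputs
    max_met_degree = 200,
    core_min_degree = 4,
    consensus = list(k = 2, reps = 1000, subsample_fraction = 0.8),
    rf = list(n_trees = 500, top_k = 30),
    classifier = list(alpha = 0.5, nfolds = 10),
    gsea = list(n_permutations = 1000, weight_exponent = 1, min_size = 5),
    link = list(n_trees = 500, cv_folds = 5, threshold = 0.9,
                n_negatives = NULL),
    run_link_prediction = TRUE,
    run_tme = FALSE)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full MPI subtyping and mechanism pipeline
#'
#' Executes the end-to-end analysis on synthetic (default) or user-supplied
#' data: network build/filter, subtype discovery, subtype-relevant gene
#' ranking and GL1 training, C1-vs-C2 differential expression, gene-set
#' GSEA, ImmuP scoring, deltaM with metabolite-set GSEA, MPI link
#' prediction, optional TME sub-clustering, and survival comparison. Every
#' stage writes its outputs under `out_dir` and is logged in the returned
#' manifest. Deterministic: identical configs yield byte-identical label,
#' deltaM and prediction files.
#'
#' @param config A `pipeline_config` (or list of overrides, or a YAML file
#'   path).
#' @return Invisibly, the run manifest (also written as
#'   `run_manifest.json`): config snapshot, per-stage outputs, checksums,
#'   wall times.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  if (is.character(config) && length(config) == 1)
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list(),
                   version = as.character(utils::packageVersion("mpinet")))
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[pipeline] stage: ", name)
    res <- tryCatch(expr, error = function(e)
      stop_mpinet("stage '", name, "' failed: ", conditionMessage(e),
                  class = "mpinet_stage_error"))
    manifest$stages[[name]] <<- list(
      wall_time = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  # --- inputs -------------------------------------------------------------
  scfg <- do.call(synth_config, c(list(seed = config$seed), config$synth))
  inputs <- t_stage("inputs", {
    if (!is.null(config$files$network)) {
      net <- mpi_network(read_mpi_edges(config$files$network, "user"))
      expr <- read_expression(config$files$expression)
      clinical <- read_clinical(config$files$clinical)
      cohort <- expression_cohort(expr, clinical)
      truth <- NULL
      msets <- if (!is.null(config$files$metabolite_sets))
        read_gmt(config$files$metabolite_sets) else NULL
      list(net = net, cohort = cohort, truth = truth, msets = msets,
           acc = NULL)
    } else {
      gn <- gen_mpi_network(scfg)
      gc_ <- gen_cohort(scfg, gn$network)
      acc <- gen_accumulation_scenario(scfg, gn$network)
      list(net = gn$network, cohort = gc_$cohort, truth = gc_$truth,
           msets = acc$sets, acc = acc)
    }
  })
  net <- inputs$net; cohort <- inputs$cohort

  filtered <- t_stage("filter_network", {
    f <- prune_isolated_proteins(
      remove_common_metabolites(net, config$max_met_degree))
    write_mpi_network(f, file.path(out_dir, "network_filtered.tsv"))
    f
  })

  model <- t_stage("subtype", {
    markers <- inputs$truth$markers %||% config$files$markers
    if (is.null(markers))
      stop_mpinet("no marker genes available")
    m <- fit_subtype_model(cohort, filtered, markers,
                           k = config$consensus$k,
                           reps = config$consensus$reps,
                           subsample_fraction =
                             config$consensus$subsample_fraction,
                           seed = config$seed)
    write_tsv_stable(data.frame(sample_id = names(m$labels),
                                subtype = unname(m$labels),
                                discriminant = unname(m$discriminant)),
                     file.path(out_dir, "subtype_labels.tsv"))
    write_tsv_stable(as.data.frame(m$consensus$consensus),
                     file.path(out_dir, "consensus_matrix.tsv"))
    m
  })
  labels <- model$labels

  gl1 <- t_stage("gl1", {
    Z <- zscore_normalize(cohort$expr)
    imp <- rf_gene_importance(Z, labels, n_trees = config$rf$n_trees,
                              seed = config$seed)
    panel <- top_genes(imp, config$rf$top_k)
    write_tsv_stable(head(imp, config$rf$top_k),
                     file.path(out_dir, "subtype_relevant_genes.tsv"))
    cm <- train_classifier(Z[panel, , drop = FALSE], labels,
                           alpha = config$classifier$alpha,
                           nfolds = config$classifier$nfolds,
                           seed = config$seed)
    write_classifier(cm, file.path(out_dir, "gl1.json"))
    cm
  })

  de <- t_stage("differential", {
    d <- unpaired_differential(cohort, "C1", "C2", labels = labels)
    write_tsv_stable(d, file.path(out_dir, "differential_c1_vs_c2.tsv"))
    d
  })

  t_stage("gene_gsea", {
    if (!is.null(config$files$gene_sets)) {
      gs <- read_gmt(config$files$gene_sets)
      r <- gsea(ranked_list(setNames(de$log2FC, de$gene)), gs,
                n_permutations = config$gsea$n_permutations,
                seed = config$seed,
                weight_exponent = config$gsea$weight_exponent,
                min_size = config$gsea$min_size)
      write_tsv_stable(r, file.path(out_dir, "gene_gsea.tsv"))
    } else message("no gene_sets supplied; gene GSEA skipped")
    NULL
  })

  t_stage("immup", {
    immune <- if (!is.null(config$files$immune_sets))
      read_gmt(config$files$immune_sets)
    else {
      # synthetic fallback: treat up-in-C1 informative genes as the
      # immune pathway so the stage exercises the same code path
      up <- inputs$truth$informative[inputs$truth$directions > 0]
      if (length(up) >= 3)
        pathway_collection(list(immune = list(
          name = "immune", category = "synthetic", members = up)))
      else NULL
    }
    if (!is.null(immune)) {
      gl <- suppressWarnings(
        build_immune_gene_list(cohort, labels, immune))
      if (length(gl) >= 3) {
        sc <- sample_set_score(cohort$expr, gl)
        write_tsv_stable(data.frame(sample_id = names(sc),
                                    ImmuP = unname(sc)),
                         file.path(out_dir, "immup.tsv"))
      } else message("immune gene list too small; ImmuP skipped")
    } else message("no immune sets; ImmuP skipped")
    NULL
  })

  acc_table <- t_stage("deltam", {
    fc <- setNames(de$log2FC, de$gene)
    fc <- fc[names(fc) %in% filtered$proteins]
    tab <- delta_m(filtered, fc)
    write_tsv_stable(tab, file.path(out_dir, "deltam.tsv"))
    if (!is.null(inputs$msets)) {
      mg <- metabolite_gsea(tab, inputs$msets,
                            n_permutations = config$gsea$n_permutations,
                            seed = config$seed)
      write_tsv_stable(mg, file.path(out_dir, "metabolite_gsea.tsv"))
    }
    tab
  })

  if (isTRUE(config$run_link_prediction)) {
    link_auroc <- t_stage("link_prediction", {
    li <- gen_link_instance(scfg)
    negs <- sample_negative_pairs(
      li$network,
      config$link$n_negatives %||% nrow(li$positives),
      seed = config$seed)
    lm <- train_link_model(li$positives, negs, li$network,
                           n_trees = config$link$n_trees,
                           cv_folds = config$link$cv_folds,
                           seed = config$seed,
                           min_class = min(50, nrow(li$positives)))
    cand <- li$candidates[, c("metabolite_id", "protein_id")]
    preds <- predict_high_confidence(lm, cand, li$network,
                                     threshold = config$link$threshold)
    write_tsv_stable(preds, file.path(out_dir, "mpi_predictions.tsv"))
    lm$auroc
    })
    manifest$stages$link_prediction$auroc <- link_auroc
  }

  if (isTRUE(config$run_tme)) t_stage("tme", {
    c1 <- names(labels)[labels == "C1"]
    tme <- if (!is.null(config$files$tme)) read_expression(config$files$tme)
      else gen_tme_matrix(scfg, c1)$tme
    sl <- sub_cluster_tme(tme, c1, reps = config$consensus$reps,
                          survival = cohort$clinical, seed = config$seed)
    write_tsv_stable(data.frame(sample_id = names(sl),
                                sub_population = unname(sl)),
                     file.path(out_dir, "s1_s2_labels.tsv"))
    NULL
  }) else message("[pipeline] TME sub-clustering skipped (run_tme = FALSE)")

  t_stage("survival", {
    if (all(c("time", "event") %in% names(cohort$clinical)) &&
        sum(cohort$clinical$event, na.rm = TRUE) >= 2) {
      lr <- logrank_test(cohort, labels)
      jsonlite::write_json(lr, file.path(out_dir, "logrank.json"),
                           auto_unbox = TRUE, digits = NA)
    } else message("no usable survival data; log-rank skipped")
    NULL
  })

  outputs <- list.files(out_dir, full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(
    outputs[!grepl("run_manifest", outputs)]))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
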