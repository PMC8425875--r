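#' PCA projection of an expression matrix onto leading components
#'
#' Samples are the observations, genes the features. Components are ordered
#' by explained variance with a deterministic sign convention: the largest
#' absolute loading of each component is made positive (before any
#' orientation by markers downstream).
#'
#' @param mat Z-scored numeric matrix, genes x samples.
#' @param n_components Number of components (default 2).
#' @return Object of class `pca_projection`: `scores` (samples x k),
#'   `loadings` (genes x k), `explained` (variance fractions).
#' @export
pca_project <- function(mat, n_components = 2) {
  if (nrow(mat) < n_components)
    stop_mpinet("fewer genes (", nrow(mat), ") than components requested",
                class = "mpinet_parameter_error")
  if (ncol(mat) < 3)
    stop_mpinet("need at least 3 samples", class = "mpinet_parameter_error")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE, rank. = n_components)
  k <- min(n_components, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  structure(list(scores = scores, loadings = loadings, explained = expl),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat("pca_projection:", ncol(x$scores), "components;",
      "explained:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Consensus clustering by subsampled partitioning around medoids
#'
#' Repeatedly subsamples items, clusters each subsample with PAM on Euclidean
#' distance, and aggregates the co-clustering frequency of every co-sampled
#' pair into a consensus matrix. Final labels come from an average-linkage
#' hierarchical cut of 1 - consensus at `k_final`.
#'
#' @param points Numeric matrix, samples x features (typically the first two
#'   principal components).
#' @param k_final Number of clusters for the reported labels (default 2).
#' @param k_range Ks for which consensus matrices are computed (default
#'   `k_final`; pass e.g. `2:10` to emulate a maxK = 10 scan).
#' @param reps Subsampling repetitions (default 1000; >= 50 required).
#' @param subsample_fraction Fraction of items per subsample (default 0.8).
#' @param seed RNG seed.
#' @return Object of class `consensus_result`: `labels` (named integer
#'   vector), `consensus` (matrix at `k_final`), `consensus_by_k` (list),
#'   `k`, `params`.
#' @export
consensus_cluster <- function(points, k_final = 2, k_range = NULL,
                              reps = 1000, subsample_fraction = 0.8,
                              seed = 1) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(rownames(points))) rownames(points) <- paste0("item", seq_len(n))
  if (reps < 50)
    stop_mpinet("reps must be >= 50", class = "mpinet_parameter_error")
  if (is.null(k_range)) k_range <- k_final
  if (!k_final %in% k_range) k_range <- sort(unique(c(k_range, k_final)))
  m <- floor(subsample_fraction * n)
  if (m < max(k_range))
    stop_mpinet("subsample size ", m, " smaller than largest K ",
                max(k_range), class = "mpinet_parameter_error")
  D <- as.matrix(dist(points))
  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  cnt <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, m))
      cnt[idx, idx] <- cnt[idx, idx] + 1
      dsub <- D[idx, idx]
      for (k in k_range) {
        cl <- cluster::pam(as.dist(dsub), k = k, diss = TRUE,
                           cluster.only = TRUE)
        for (g in unique(cl)) {
          members <- idx[cl == g]
          conn[[as.character(k)]][members, members] <-
            conn[[as.character(k)]][members, members] + 1
        }
      }
    }
  })
  consensus_by_k <- lapply(conn, function(cc) {
    M <- cc / pmax(cnt, 1)
    M[cnt == 0] <- 0
    diag(M) <- 1
    dimnames(M) <- list(rownames(points), rownames(points))
    M
  })
  M <- consensus_by_k[[as.character(k_final)]]
  hc <- hclust(as.dist(1 - M), method = "average")
  labels <- setNames(cutree(hc, k = k_final), rownames(points))
  structure(list(labels = labels, consensus = M,
                 consensus_by_k = consensus_by_k, k = k_final,
                 params = list(k_range = k_range, reps = reps,
                               subsample_fraction = subsample_fraction,
                               seed = seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result: K =", x$k, "over", length(x$labels), "items (",
      x$params$reps, "reps, subsample", x$params$subsample_fraction, ")\n")
  invisible(x)
}

#' Fit the two-subtype model from core MIPro expression
#'
#' The subtyping pipeline: restrict the z-scored cohort to core
#' metabolite-interacting proteins (degree > 4 on the filtered network),
#' project samples onto the first two principal components, consensus-cluster
#' the projections (PAM, K = 2 by default), then orient labels so that the
#' cluster with LOWER mean marker-gene expression is called C1 (the
#' poor-prognosis, metabolically down-regulated subtype). The PC1 - PC2
#' discriminant is reported as a consistency diagnostic: on well-separated
#' cohorts the two subtypes fall on either side of the PC1 = PC2 line.
#'
#' @param cohort An `expression_cohort` (tumor samples).
#' @param net A filtered `mpi_network` (or a character vector of core protein
#'   ids, bypassing [core_mipros()]).
#' @param marker_genes Genes whose low expression defines C1.
#' @param k Number of subtypes (default 2).
#' @param reps,subsample_fraction,seed Passed to [consensus_cluster()].
#' @param min_core_genes Minimum usable core genes (default 3).
#' @return Object of class `subtype_model`: `labels` (named "C1"/"C2"),
#'   `pca`, `consensus`, `discriminant` (PC1 - PC2 per sample),
#'   `discriminant_agreement`, `core_genes`, `marker_genes`.
#' @export
fit_subtype_model <- function(cohort, net, marker_genes, k = 2,
                              reps = 1000, subsample_fraction = 0.8,
                              seed = 1, min_core_genes = 3) {
  core <- if (inherits(net, "mpi_network")) core_mipros(net) else
    as.character(net)
  genes <- intersect(core, rownames(cohort$expr))
  if (length(genes) < min_core_genes)
    stop_mpinet("only ", length(genes), " core MIPros present in cohort",
                class = "mpinet_parameter_error")
  markers <- intersect(marker_genes, rownames(cohort$expr))
  if (length(markers) == 0)
    stop_mpinet("no marker genes present in the cohort",
                class = "mpinet_parameter_error")
  Z <- zscore_normalize(cohort$expr[genes, , drop = FALSE])
  pca <- pca_project(Z, n_components = 2)
  cons <- consensus_cluster(pca$scores, k_final = k, reps = reps,
                            subsample_fraction = subsample_fraction,
                            seed = seed)
  Zm <- zscore_normalize(cohort$expr)[markers, , drop = FALSE]
  marker_mean <- vapply(seq_len(k), function(g)
    mean(Zm[, cons$labels == g, drop = FALSE]), numeric(1))
  # lower marker expression -> C1; remaining clusters by increasing mean
  ord <- order(marker_mean)
  relabel <- setNames(paste0("C", seq_len(k)), as.character(ord))
  labels <- setNames(relabel[as.character(cons$labels)], names(cons$labels))
  disc <- pca$scores[, 1] - pca$scores[, 2]
  agree <- NA_real_
  if (k == 2) {
    f <- mean((disc < 0) == (labels == "C1"))
    agree <- max(f, 1 - f)  # the line's orientation is arbitrary
  }
  structure(list(labels = labels, pca = pca, consensus = cons,
                 discriminant = disc, discriminant_agreement = agree,
                 core_genes = genes, marker_genes = markers, seed = seed),
            class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("subtype_model:", length(x$labels), "samples;",
      paste(names(table(x$labels)), as.integer(table(x$labels)),
            sep = "=", collapse = ", "),
      "; discriminant agreement",
      format(x$discriminant_agreement, digits = 3), "\n")
  invisible(x)
}

#' Rank genes by random-forest importance for a binary subtype contrast
#'
#' @param mat Z-scored matrix, genes x samples.
#' @param labels Binary labels per sample (named or in column order).
#' @param n_trees Trees (default 500).
#' @param seed RNG seed.
#' @return Data frame `gene`, `importance`, `rank`, sorted by decreasing
#'   importance (ties broken by gene id).
#' @export
rf_gene_importance <- function(mat, labels, n_trees = 500, seed = 1) {
  if (!is.null(names(labels))) labels <- labels[colnames(mat)]
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop_mpinet("labels contain a single class",
                class = "mpinet_parameter_error")
  fit <- rforest(t(mat), labels, n_trees = n_trees, seed = seed)
  imp <- fit$importance
  ord <- order(-imp, names(imp))
  data.frame(gene = names(imp)[ord], importance = unname(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

#' Top-k genes from an importance table
#' @param importance_table Output of [rf_gene_importance()].
#' @param k How many genes (default 30).
#' @return Character vector.
#' @export
top_genes <- function(importance_table, k = 30) {
  head(importance_table$gene, k)
}

#' Train an elastic-net subtype classifier (GL1 / GL2)
#'
#' Penalized logistic regression on a fixed gene panel (typically the top-30
#' subtype-relevant genes), with the penalty strength chosen by seeded
#' cross-validation. The model stores its normalization recipe: target
#' cohorts are row z-scored before prediction, so the classifier transfers
#' across cohorts on the relative-expression scale.
#'
#' @param mat Matrix restricted to the panel genes (genes x samples,
#'   z-scored).
#' @param labels Binary labels per sample (named or in column order); the
#'   alphabetically second level is the "positive" class.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param nfolds CV folds (default 10).
#' @param seed Fold seed.
#' @param min_per_class Minimum samples per class (default 20).
#' @return Object of class `classifier_model`: `genes`, `intercept`,
#'   `coefficients` (named), `levels`, `alpha`, `lambda`, `threshold`,
#'   `recipe`, `seed`.
#' @export
train_classifier <- function(mat, labels, alpha = 0.5, nfolds = 10,
                             seed = 1, min_per_class = 20) {
  if (!is.null(names(labels))) labels <- labels[colnames(mat)]
  y <- factor(labels)
  if (nlevels(y) != 2)
    stop_mpinet("need exactly 2 classes", class = "mpinet_parameter_error")
  if (min(table(y)) < min_per_class)
    stop_mpinet("need >= ", min_per_class, " samples per class",
                class = "mpinet_parameter_error")
  x <- t(mat)
  cvfit <- with_seed(seed,
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                      nfolds = nfolds, standardize = FALSE))
  beta <- as.matrix(coef(cvfit, s = "lambda.min"))
  structure(list(genes = rownames(mat),
                 intercept = unname(beta[1, 1]),
                 coefficients = setNames(beta[-1, 1], rownames(beta)[-1]),
                 levels = levels(y), alpha = alpha,
                 lambda = cvfit$lambda.min, threshold = 0.5,
                 recipe = "row_zscore", seed = seed, version = 1L),
            class = "classifier_model")
}

#' @param object A `classifier_model`.
#' @param cohort An `expression_cohort` or a genes x samples matrix. Rows are
#'   z-scored per the stored recipe before applying the linear predictor;
#'   panel genes absent from the target are set to 0 (the z-score mean).
#' @param type `"class"` (default) or `"prob"` (probability of the second
#'   level).
#' @param ... Unused.
#' @rdname train_classifier
#' @export
predict.classifier_model <- function(object, cohort, type = c("class", "prob"),
                                     ...) {
  type <- match.arg(type)
  mat <- if (inherits(cohort, "expression_cohort")) cohort$expr else
    as.matrix(cohort)
  present <- intersect(object$genes, rownames(mat))
  if (length(present) == 0)
    stop_mpinet("no classifier genes overlap the target cohort",
                class = "mpinet_parameter_error")
  if (identical(object$recipe, "row_zscore")) {
    sub <- mat[present, , drop = FALSE]
    sds <- apply(sub, 1, sd)
    ok <- sds > 0
    sub[ok, ] <- t(scale(t(sub[ok, , drop = FALSE])))
    sub[!ok, ] <- 0
  } else {
    sub <- mat[present, , drop = FALSE]
  }
  X <- matrix(0, nrow = ncol(mat), ncol = length(object$genes),
              dimnames = list(colnames(mat), object$genes))
  X[, present] <- t(sub)
  eta <- object$intercept + drop(X %*% object$coefficients[object$genes])
  prob <- plogis(eta)
  if (type == "prob") return(setNames(prob, colnames(mat)))
  setNames(object$levels[ifelse(prob > object$threshold, 2L, 1L)],
           colnames(mat))
}

#' Serialize / restore a classifier model (versioned JSON)
#' @param model A `classifier_model`.
#' @param path JSON file path.
#' @export
write_classifier <- function(model, path) {
  payload <- unclass(model)
  payload$coefficients <- as.list(model$coefficients)  # keep names in JSON
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  l$coefficients <- unlist(l$coefficients)
  structure(l, class = "classifier_model")
}

#' Two-step three-subtype assignment
#'
#' GL1 separates C1 from C2 on all samples; GL2 is then applied only to
#' predicted-C1 samples to split them into S1 and S2. Every sample receives
#' exactly one of C2/S1/S2.
#'
#' @param gl1 `classifier_model` with levels C1/C2.
#' @param gl2 `classifier_model` with levels S1/S2.
#' @param cohort Matrix or `expression_cohort`.
#' @return Named character vector of labels in `{C2, S1, S2}`.
#' @export
two_step_predict <- function(gl1, gl2, cohort) {
  l1 <- predict(gl1, cohort)
  out <- l1
  c1 <- names(l1)[l1 == "C1"]
  if (length(c1) == 0) {
    warning("no samples predicted C1; returning C2-only labeling")
    return(out)
  }
  mat <- if (inherits(cohort, "expression_cohort")) cohort$expr else
    as.matrix(cohort)
  out[c1] <- predict(gl2, mat[, c1, drop = FALSE])
  out
}

#' Sub-cluster the poor-prognosis subtype on tumor-microenvironment profiles
#'
#' Consensus-clusters the z-scored TME cell-type enrichment profiles of the
#' C1 samples into two sub-populations. When survival data is supplied, S1 is
#' the cluster with the worse outcome (positive Cox log-hazard vs the other);
#' otherwise S1 is the larger cluster.
#'
#' @param tme_matrix Cell types x samples numeric matrix.
#' @param c1_samples Sample ids to sub-cluster (must be covered by the
#'   matrix).
#' @param k Number of sub-populations (default 2).
#' @param survival Optional data frame with `sample_id`, `time`, `event`.
#' @param reps,subsample_fraction,seed Passed to [consensus_cluster()].
#' @return Named character vector of labels "S1"/"S2" plus attribute
#'   `consensus` carrying the `consensus_result`.
#' @export
sub_cluster_tme <- function(tme_matrix, c1_samples, k = 2, survival = NULL,
                            reps = 1000, subsample_fraction = 0.8, seed = 1) {
  c1_samples <- intersect(c1_samples, colnames(tme_matrix))
  if (length(c1_samples) < 10)
    stop_mpinet("need at least 10 C1 samples, found ", length(c1_samples),
                class = "mpinet_parameter_error")
  Z <- zscore_normalize(tme_matrix[, c1_samples, drop = FALSE])
  cons <- consensus_cluster(t(Z), k_final = k, reps = reps,
                            subsample_fraction = subsample_fraction,
                            seed = seed)
  lab <- cons$labels
  s1_cluster <- NULL
  if (!is.null(survival)) {
    sv <- survival[match(c1_samples, survival$sample_id), ]
    ok <- !is.na(sv$time) & sv$time > 0 & !is.na(sv$event)
    if (sum(sv$event[ok]) >= 2 && length(unique(lab[ok])) == 2) {
      fit <- tryCatch(survival::coxph(
        survival::Surv(sv$time[ok], sv$event[ok]) ~ I(lab[ok] == 1)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(coef(fit)[1]))
        s1_cluster <- if (coef(fit)[1] > 0) 1L else 2L
    }
  }
  if (is.null(s1_cluster)) {
    sizes <- table(lab)
    s1_cluster <- as.integer(names(sizes)[which.max(sizes)])
  }
  out <- setNames(ifelse(lab == s1_cluster, "S1", "S2"), names(lab))
  attr(out, "consensus") <- cons
  out
}
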