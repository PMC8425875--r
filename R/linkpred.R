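# Undirected adjacency view of an MPI network for topology features.
mpi_adjacency <- function(net) {
  e <- net$edges
  met_adj <- lapply(split(e$protein_id, e$metabolite_id), unique)
  prot_adj <- lapply(split(e$metabolite_id, e$protein_id), unique)
  for (m in setdiff(net$metabolites, names(met_adj)))
    met_adj[[m]] <- character(0)
  for (p in setdiff(net$proteins, names(prot_adj)))
    prot_adj[[p]] <- character(0)
  list(met = met_adj, prot = prot_adj)
}

#' Uniform negative sampling of non-interacting pairs
#'
#' Samples `n` (metabolite, protein) pairs uniformly without replacement
#' from the complement of the edge set (minus `exclude`), with a fixed seed.
#'
#' @param net An `mpi_network`.
#' @param n Number of pairs.
#' @param seed RNG seed.
#' @param exclude Optional data frame of pairs (`metabolite_id`,
#'   `protein_id`) to exclude in addition to known edges.
#' @return Data frame with columns `metabolite_id`, `protein_id`.
#' @export
sample_negative_pairs <- function(net, n, seed = 1, exclude = NULL) {
  M <- net$metabolites; P <- net$proteins
  total <- length(M) * length(P)
  known <- paste(net$edges$metabolite_id, net$edges$protein_id, sep = "\r")
  if (!is.null(exclude) && nrow(exclude) > 0)
    known <- union(known, paste(exclude$metabolite_id, exclude$protein_id,
                                sep = "\r"))
  n_free <- total - length(known)
  if (n > n_free)
    stop_mpinet("requested ", n, " negatives but only ", n_free,
                " non-edges exist", class = "mpinet_parameter_error")
  if (n == 0)
    return(data.frame(metabolite_id = character(),
                      protein_id = character(), stringsAsFactors = FALSE))
  with_seed(seed, {
    if (total <= 2e6) {
      # enumerate the full grid; index (i, j) -> (i - 1) * |P| + j
      idx <- seq_len(total)
      mi <- (idx - 1L) %/% length(P) + 1L
      pj <- (idx - 1L) %% length(P) + 1L
      key <- paste(M[mi], P[pj], sep = "\r")
      free <- which(!key %in% known)
      pick <- sample(free, n)
      data.frame(metabolite_id = M[(pick - 1L) %/% length(P) + 1L],
                 protein_id = P[(pick - 1L) %% length(P) + 1L],
                 stringsAsFactors = FALSE)
    } else {
      seen <- character(0)
      out_m <- character(0); out_p <- character(0)
      while (length(out_m) < n) {
        cm <- sample(M, n, replace = TRUE)
        cp <- sample(P, n, replace = TRUE)
        k <- paste(cm, cp, sep = "\r")
        ok <- !(k %in% known) & !(k %in% seen) & !duplicated(k)
        out_m <- c(out_m, cm[ok]); out_p <- c(out_p, cp[ok])
        seen <- c(seen, k[ok])
      }
      data.frame(metabolite_id = out_m[seq_len(n)],
                 protein_id = out_p[seq_len(n)], stringsAsFactors = FALSE)
    }
  })
}

# BFS shortest path length between a metabolite and a protein on the
# bipartite adjacency (Inf if disconnected).
bfs_distance <- function(adj, m, p) {
  if (length(adj$met[[m]]) == 0) return(Inf)
  dist <- 1L
  frontier <- adj$met[[m]]   # proteins at distance 1
  seen_m <- m; seen_p <- character(0)
  side <- "prot"
  while (length(frontier) > 0) {
    if (side == "prot") {
      if (p %in% frontier) return(dist)
      seen_p <- c(seen_p, frontier)
      nxt <- setdiff(unique(unlist(adj$prot[frontier], use.names = FALSE)),
                     seen_m)
      side <- "met"
    } else {
      seen_m <- c(seen_m, frontier)
      nxt <- setdiff(unique(unlist(adj$met[frontier], use.names = FALSE)),
                     seen_p)
      side <- "prot"
    }
    frontier <- nxt
    dist <- dist + 1L
  }
  Inf
}

#' Network-topology features for a candidate metabolite-protein pair
#'
#' Six association features computed on the undirected bipartite network,
#' with the candidate edge itself removed when present (leakage control):
#' \describe{
#'   \item{f1}{preferential attachment, deg(m) * deg(p)}
#'   \item{f2}{number of length-3 paths m - p' - m' - p}
#'   \item{f3}{Jaccard of N(m) with the union of protein neighborhoods of
#'     N(p)}
#'   \item{f4}{Jaccard of N(p) with the union of metabolite neighborhoods of
#'     N(m)}
#'   \item{f5}{inverse shortest-path length (0 if disconnected)}
#'   \item{f6}{resource-allocation index over length-3 paths: sum over
#'     intermediate (p', m') of 1 / (deg(p') * deg(m'))}
#' }
#'
#' @param net An `mpi_network`.
#' @param metabolite_id,protein_id Node ids (must exist in the network).
#' @param exclude_candidate_edge Remove the (m, p) edge before computing
#'   (default TRUE).
#' @param adj Optional precomputed adjacency (internal use).
#' @return Named numeric vector `f1..f6`.
#' @export
compute_pair_features <- function(net, metabolite_id, protein_id,
                                  exclude_candidate_edge = TRUE, adj = NULL) {
  if (!metabolite_id %in% net$metabolites)
    stop_mpinet("unknown metabolite: ", metabolite_id,
                class = "mpinet_lookup_error")
  if (!protein_id %in% net$proteins)
    stop_mpinet("unknown protein: ", protein_id,
                class = "mpinet_lookup_error")
  if (is.null(adj)) adj <- mpi_adjacency(net)
  m <- metabolite_id; p <- protein_id
  if (exclude_candidate_edge) {
    adj$met[[m]] <- setdiff(adj$met[[m]], p)
    adj$prot[[p]] <- setdiff(adj$prot[[p]], m)
  }
  Nm <- adj$met[[m]]    # proteins adjacent to m
  Np <- adj$prot[[p]]   # metabolites adjacent to p
  degm <- length(Nm); degp <- length(Np)
  f1 <- degm * degp
  if (degm == 0 || degp == 0)
    return(c(f1 = 0, f2 = 0, f3 = 0, f4 = 0, f5 = 0, f6 = 0))
  # length-3 paths m - p' - m' - p: edges between N(m) proteins and N(p)
  # metabolites, excluding degenerate endpoints
  f2 <- 0; f6 <- 0
  for (pp in Nm) {
    mids <- intersect(adj$prot[[pp]], Np)
    mids <- setdiff(mids, m)
    for (mm in mids) {
      if (identical(pp, p) || identical(mm, m)) next
      f2 <- f2 + 1
      f6 <- f6 + 1 / (length(adj$prot[[pp]]) * length(adj$met[[mm]]))
    }
  }
  union_prot_of_Np <- unique(unlist(adj$met[Np], use.names = FALSE))
  union_met_of_Nm <- unique(unlist(adj$prot[Nm], use.names = FALSE))
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  f3 <- jac(Nm, union_prot_of_Np)
  f4 <- jac(Np, union_met_of_Nm)
  d <- bfs_distance(adj, m, p)
  f5 <- if (is.finite(d)) 1 / d else 0
  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5, f6 = f6)
}

#' Feature matrix for a table of candidate pairs
#'
#' @param net An `mpi_network`.
#' @param pairs Data frame with `metabolite_id`, `protein_id`.
#' @param exclude_candidate_edge Passed to [compute_pair_features()].
#' @return Numeric matrix, one row per pair, columns f1..f6.
#' @export
pair_feature_matrix <- function(net, pairs, exclude_candidate_edge = TRUE) {
  adj <- mpi_adjacency(net)
  X <- t(vapply(seq_len(nrow(pairs)), function(i)
    compute_pair_features(net, pairs$metabolite_id[i], pairs$protein_id[i],
                          exclude_candidate_edge = exclude_candidate_edge,
                          adj = adj),
    numeric(6)))
  rownames(X) <- paste(pairs$metabolite_id, pairs$protein_id, sep = "|")
  X
}

# Rank-based AUROC (equivalent to the Mann-Whitney statistic; ties averaged).
auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC curve points (FPR, TPR) over all score thresholds, descending.
roc_points <- function(scores, labels) {
  ord <- order(-scores)
  tp <- cumsum(labels[ord] == 1); fp <- cumsum(labels[ord] == 0)
  data.frame(fpr = c(0, fp / max(1, sum(labels == 0))),
             tpr = c(0, tp / max(1, sum(labels == 1))))
}

#' Train the MPI link-prediction random forest
#'
#' Computes the six topology features for positive (known-edge) and negative
#' pairs — positives with the candidate edge excluded from the graph —
#' then trains a random forest under seeded stratified cross-validation.
#' The reported ROC and AUROC use out-of-fold probabilities only.
#'
#' @param positives,negatives Data frames with `metabolite_id`,
#'   `protein_id`.
#' @param net An `mpi_network`.
#' @param n_trees Forest size (default 500).
#' @param cv_folds Stratified folds (default 5).
#' @param seed RNG seed.
#' @param min_class Minimum class size (default 50).
#' @return Object of class `link_model`: `forest` (`rforest` fit on all
#'   data), `auroc`, `roc`, `oof_prob`, `feature_names`, `cv_folds`,
#'   `seed`.
#' @export
train_link_model <- function(positives, negatives, net, n_trees = 500,
                             cv_folds = 5, seed = 1, min_class = 50) {
  if (nrow(positives) < min_class || nrow(negatives) < min_class)
    stop_mpinet("need >= ", min_class, " pairs per class",
                class = "mpinet_parameter_error")
  Xp <- pair_feature_matrix(net, positives, exclude_candidate_edge = TRUE)
  Xn <- pair_feature_matrix(net, negatives, exclude_candidate_edge = TRUE)
  X <- rbind(Xp, Xn)
  y <- c(rep(1L, nrow(Xp)), rep(0L, nrow(Xn)))
  n <- length(y)
  oof <- rep(NA_real_, n)
  fold_seed <- seed
  for (attempt in 1:3) {
    folds <- with_seed(fold_seed, {
      f <- integer(n)
      f[y == 1] <- sample(rep_len(seq_len(cv_folds), sum(y == 1)))
      f[y == 0] <- sample(rep_len(seq_len(cv_folds), sum(y == 0)))
      f
    })
    ok <- all(vapply(seq_len(cv_folds), function(k)
      length(unique(y[folds != k])) == 2, logical(1)))
    if (ok) break
    fold_seed <- fold_seed + 1000L
    if (attempt == 3)
      stop_mpinet("could not build folds with both classes",
                  class = "mpinet_parameter_error")
  }
  for (k in seq_len(cv_folds)) {
    fit <- rforest(X[folds != k, , drop = FALSE], y[folds != k],
                   n_trees = n_trees, seed = seed + k)
    oof[folds == k] <- predict(fit, X[folds == k, , drop = FALSE])
  }
  final <- rforest(X, y, n_trees = n_trees, seed = seed)
  structure(list(forest = final, auroc = auroc(oof, y),
                 roc = roc_points(oof, y), oof_prob = oof, labels = y,
                 feature_names = colnames(X), cv_folds = cv_folds,
                 seed = seed),
            class = "link_model")
}

#' @export
print.link_model <- function(x, ...) {
  cat("link_model:", x$forest$n_trees, "trees; cross-validated AUROC",
      format(x$auroc, digits = 3), "\n")
  invisible(x)
}

#' High-confidence MPI predictions
#'
#' Scores candidate pairs with a trained link model and keeps those with
#' predicted probability strictly above `threshold`. Known edges are removed
#' from the candidates unless `include_known = TRUE`.
#'
#' @param model A `link_model`.
#' @param candidates Data frame with `metabolite_id`, `protein_id`.
#' @param net An `mpi_network`.
#' @param threshold Probability cutoff in (0, 1\] (default 0.9, strict ">").
#' @param include_known Keep candidate pairs that are already edges
#'   (default FALSE).
#' @return Data frame `metabolite_id`, `protein_id`, `probability`, sorted
#'   descending.
#' @export
predict_high_confidence <- function(model, candidates, net, threshold = 0.9,
                                    include_known = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop_mpinet("threshold must lie in (0, 1]",
                class = "mpinet_parameter_error")
  known <- paste(net$edges$metabolite_id, net$edges$protein_id, sep = "\r")
  key <- paste(candidates$metabolite_id, candidates$protein_id, sep = "\r")
  if (!include_known) candidates <- candidates[!key %in% known, , drop = FALSE]
  if (nrow(candidates) == 0)
    return(data.frame(metabolite_id = character(), protein_id = character(),
                      probability = numeric(), stringsAsFactors = FALSE))
  X <- pair_feature_matrix(net, candidates, exclude_candidate_edge = TRUE)
  prob <- predict(model$forest, X)
  out <- data.frame(metabolite_id = candidates$metabolite_id,
                    protein_id = candidates$protein_id,
                    probability = prob, stringsAsFactors = FALSE)
  out <- out[out$probability > threshold, , drop = FALSE]
  out <- out[order(-out$probability, out$metabolite_id, out$protein_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein x metabolism-pathway connection map
#'
#' For every protein with predictions, tests whether its predicted
#' interacting metabolites are over-represented in each metabolite pathway
#' (upper-tail hypergeometric within `universe`). Cells below `p_cutoff` are
#' flagged; the per-pathway mean of -log10(p) summarizes column strength.
#'
#' @param predictions Data frame from [predict_high_confidence()].
#' @param metabolite_sets A `pathway_collection` of metabolite sets.
#' @param universe Character vector of testable metabolite ids.
#' @param p_cutoff Significance flag threshold (default 0.05).
#' @return List: `p_matrix` (proteins x pathways), `flags` (logical matrix),
#'   `pathway_summary` (data frame `pathway`, `mean_neg_log10_p`,
#'   `n_significant`).
#' @export
pathway_connection_map <- function(predictions, metabolite_sets, universe,
                                   p_cutoff = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0)
    stop_mpinet("empty universe", class = "mpinet_parameter_error")
  prots <- sort(unique(predictions$protein_id))
  pw <- names(metabolite_sets)
  members <- lapply(metabolite_sets, function(s)
    intersect(s$members, universe))
  keep_pw <- vapply(members, length, integer(1)) > 0
  pw <- pw[keep_pw]; members <- members[keep_pw]
  P <- matrix(NA_real_, length(prots), length(pw),
              dimnames = list(prots, pw))
  for (pr in prots) {
    pred_m <- intersect(
      unique(predictions$metabolite_id[predictions$protein_id == pr]),
      universe)
    if (length(pred_m) == 0) next
    for (w in pw) {
      k <- length(intersect(pred_m, members[[w]]))
      P[pr, w] <- phyper(k - 1, length(members[[w]]),
                         length(universe) - length(members[[w]]),
                         length(pred_m), lower.tail = FALSE)
    }
  }
  keep <- rowSums(!is.na(P)) > 0
  P <- P[keep, , drop = FALSE]
  flags <- !is.na(P) & P < p_cutoff
  summary <- data.frame(
    pathway = pw,
    mean_neg_log10_p = vapply(pw, function(w)
      mean(-log10(pmax(P[, w], 1e-300)), na.rm = TRUE), numeric(1)),
    n_significant = colSums(flags),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(p_matrix = P, flags = flags, pathway_summary = summary)
}
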