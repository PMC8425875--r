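#' Build a ranked list from named scores
#'
#' Sorts descending with the package-wide tie policy: score descending, id
#' ascending.
#'
#' @param scores Named numeric vector (e.g. log2 fold changes or deltaM).
#' @return Named numeric vector of class `ranked_list`, sorted.
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop_mpinet("scores must be uniquely named",
                class = "mpinet_parameter_error")
  ord <- order(-scores, names(scores))
  structure(scores[ord], class = c("ranked_list", "numeric"))
}

#' GSEA enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walks the ranked list; set hits increment the running sum by
#' `|score|^weight_exponent` (normalized over hits), misses decrement by
#' `1/(N - Nh)`. The enrichment score is the running-sum value of maximum
#' absolute deviation (signed).
#'
#' @param ranked A `ranked_list` (or named numeric vector, will be sorted).
#' @param set Character vector of member ids.
#' @param weight_exponent Score weighting exponent (default 1; 0 gives the
#'   classic unweighted KS statistic).
#' @return List with `es` and `running` (the full running sum).
#' @export
gsea_es <- function(ranked, set, weight_exponent = 1) {
  if (!inherits(ranked, "ranked_list")) ranked <- ranked_list(ranked)
  N <- length(ranked)
  hit <- names(ranked) %in% set
  Nh <- sum(hit)
  if (Nh == 0 || Nh == N)
    stop_mpinet("set must hit a strict subset of the ranked list",
                class = "mpinet_parameter_error")
  w <- abs(ranked)^weight_exponent
  w[!hit] <- 0
  sw <- sum(w)
  if (sw == 0) { w[hit] <- 1; sw <- Nh }  # all-zero scores: fall back to unweighted
  step <- ifelse(hit, w / sw, -1 / (N - Nh))
  running <- cumsum(step)
  es_pos <- max(running)
  es_neg <- min(running)
  # signed maximum deviation; exact ties (symmetric profiles) resolve to the
  # positive extremum so the convention is deterministic across platforms
  es <- if (-es_neg > es_pos + 1e-9 * max(abs(es_neg), abs(es_pos), 1))
    es_neg else es_pos
  list(es = unname(es), running = unname(running))
}

# null ES distribution from size-matched random sets
gsea_null <- function(ranked, set_size, n_permutations, weight_exponent) {
  ids <- names(ranked)
  vapply(seq_len(n_permutations), function(i) {
    gsea_es(ranked, sample(ids, set_size), weight_exponent)$es
  }, numeric(1))
}

#' Gene-set enrichment analysis on a ranked list
#'
#' Canonical weighted-KS GSEA with a set-label permutation null: for each set,
#' `n_permutations` random sets of the same size are drawn from the ranked
#' ids (rankings such as per-metabolite deltaM carry no sample-level
#' phenotype to permute). NES is ES divided by the mean |null ES| of matching
#' sign; p is the empirical matching-sign tail; FDR follows the canonical
#' NES-based procedure over the pooled null.
#'
#' @param ranked A `ranked_list` or named numeric vector.
#' @param sets A `pathway_collection`.
#' @param n_permutations Permutations per set (default 1000; < 100 warns,
#'   < 10 errors).
#' @param seed RNG seed.
#' @param weight_exponent Passed to [gsea_es()].
#' @param min_size Minimum set-list intersection (default 5); smaller sets
#'   are skipped with a message.
#' @return Data frame with `set`, `size`, `es`, `nes`, `p`, `fdr`,
#'   `leading_edge` (semicolon-joined), sorted by p.
#' @export
gsea <- function(ranked, sets, n_permutations = 1000, seed = 1,
                 weight_exponent = 1, min_size = 5) {
  if (!inherits(ranked, "ranked_list")) ranked <- ranked_list(ranked)
  if (n_permutations < 10)
    stop_mpinet("n_permutations must be >= 10",
                class = "mpinet_parameter_error")
  if (n_permutations < 100)
    warning("n_permutations < 100 gives a coarse null")
  ids <- names(ranked)
  rows <- list(); null_nes <- list()
  with_seed(seed, {
    for (nm in names(sets)) {
      members <- intersect(sets[[nm]]$members, ids)
      if (length(members) < min_size || length(members) >= length(ids)) {
        message("skipping set ", nm, " (", length(members),
                " usable members)")
        next
      }
      obs <- gsea_es(ranked, members, weight_exponent)
      null <- gsea_null(ranked, length(members), n_permutations,
                        weight_exponent)
      pos <- null[null >= 0]; neg <- null[null < 0]
      mpos <- if (length(pos) > 0) mean(pos) else NA_real_
      mneg <- if (length(neg) > 0) mean(abs(neg)) else NA_real_
      if (obs$es >= 0) {
        nes <- if (is.finite(mpos) && mpos > 0) obs$es / mpos else NA_real_
        p <- if (length(pos) > 0) mean(pos >= obs$es) else 0
      } else {
        nes <- if (is.finite(mneg) && mneg > 0) obs$es / mneg else NA_real_
        p <- if (length(neg) > 0) mean(abs(neg) >= abs(obs$es)) else 0
      }
      if (p == 0) p <- 1 / (n_permutations + 1)
      nnes <- c(if (is.finite(mpos) && mpos > 0) pos / mpos,
                if (is.finite(mneg) && mneg > 0) -abs(neg) / mneg)
      null_nes[[nm]] <- nnes
      hitpos <- which(ids %in% members)
      ext <- if (obs$es >= 0) which.max(obs$running) else
        which.min(obs$running)
      le <- if (obs$es >= 0) ids[intersect(hitpos, seq_len(ext))] else
        ids[hitpos[hitpos >= ext]]
      rows[[nm]] <- data.frame(set = nm, size = length(members),
                               es = obs$es, nes = nes, p = p,
                               leading_edge = paste(le, collapse = ";"),
                               stringsAsFactors = FALSE)
    }
  })
  if (length(rows) == 0)
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), fdr = numeric(),
                      leading_edge = character()))
  out <- do.call(rbind, rows)
  pooled <- unlist(null_nes, use.names = FALSE)
  out$fdr <- vapply(seq_len(nrow(out)), function(i) {
    nes <- out$nes[i]
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(pooled[pooled >= 0] >= nes)
      den <- mean(out$nes[out$nes >= 0] >= nes)
    } else {
      num <- mean(pooled[pooled < 0] <= nes)
      den <- mean(out$nes[out$nes < 0] <= nes)
    }
    if (!is.finite(num) || !is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))
  out <- out[order(out$p, out$set), c("set", "size", "es", "nes", "p",
                                      "fdr", "leading_edge")]
  rownames(out) <- NULL
  out
}

#' Build the immune gene list for the ImmuP score
#'
#' Intersects immune-pathway members with genes significantly up-regulated
#' in C1 vs C2 (unpaired Wilcoxon, BH FDR below `fdr_cutoff`, linear fold
#' change above `fc_cutoff`, i.e. log2FC > log2(fc_cutoff)).
#'
#' @param cohort An `expression_cohort`.
#' @param labels Named subtype labels containing "C1" and "C2".
#' @param immune_pathways A `pathway_collection` of immune gene sets.
#' @param fdr_cutoff Default 0.01.
#' @param fc_cutoff Linear fold-change cutoff, default 1.5.
#' @return Character vector of gene ids (possibly empty, with a warning).
#' @export
build_immune_gene_list <- function(cohort, labels, immune_pathways,
                                   fdr_cutoff = 0.01, fc_cutoff = 1.5) {
  de <- unpaired_differential(cohort, "C1", "C2", labels = labels)
  up <- de$gene[de$p_adjusted < fdr_cutoff & de$log2FC > log2(fc_cutoff)]
  immune <- unique(unlist(lapply(immune_pathways, `[[`, "members")))
  out <- sort(intersect(up, immune))
  if (length(out) == 0)
    warning("immune gene list is empty under the current cutoffs")
  out
}

#' Per-sample gene-set enrichment score (ssGSEA-like)
#'
#' For each sample, genes are ranked by expression (descending; ties broken
#' by gene id) and a weighted running-sum statistic is integrated: hits are
#' weighted by their rank-from-bottom raised to `alpha`, misses by
#' `1/(N - Nh)`. Scores are normalized by their range across samples. The
#' statistic is rank-based, hence invariant to any monotone within-sample
#' transform, and monotone in the set genes' expression.
#'
#' @param mat Genes x samples expression matrix.
#' @param set Character vector of gene ids (>= `min_size` present required).
#' @param method Only `"ssgsea_like"`.
#' @param alpha Rank weighting exponent (default 0.25).
#' @param min_size Minimum usable set size (default 3).
#' @return Named numeric vector, one score per sample.
#' @export
sample_set_score <- function(mat, set, method = "ssgsea_like", alpha = 0.25,
                             min_size = 3) {
  method <- match.arg(method, "ssgsea_like")
  present <- intersect(set, rownames(mat))
  if (length(present) < min_size)
    stop_mpinet("only ", length(present), " set genes present (need >= ",
                min_size, ")", class = "mpinet_parameter_error")
  N <- nrow(mat)
  Nh <- length(present)
  genes <- rownames(mat)
  raw <- vapply(seq_len(ncol(mat)), function(j) {
    ord <- order(-mat[, j], genes)
    hit <- genes[ord] %in% present
    w <- (N:1)^alpha
    w[!hit] <- 0
    phit <- cumsum(w) / sum(w)
    pmiss <- cumsum(!hit) / (N - Nh)
    sum(phit - pmiss)
  }, numeric(1))
  rng <- diff(range(raw))
  out <- if (rng > 0) raw / rng else raw
  setNames(out, colnames(mat))
}
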