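# Independent oracles and fixture builders. Everything here is deliberately
# written in the most naive style available (explicit loops, enumeration)
# and shares no code with the package internals it checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# brute-force deltaM by scanning the raw edge list. Accumulation follows the
# canonical order (per metabolite, producers then consumers, each sorted by
# protein id) so exact floating-point equality is well-defined.
brute_deltam <- function(net, fc) {
  out <- setNames(numeric(length(net$metabolites)), sort(net$metabolites))
  for (m in names(out)) {
    ups <- character(0); downs <- character(0)
    for (i in seq_len(nrow(net$edges))) {
      if (net$edges$metabolite_id[i] != m) next
      p <- net$edges$protein_id[i]
      if (!p %in% names(fc)) next
      r <- net$edges$role[i]
      if (r %in% c("product", "both")) ups <- c(ups, p)
      if (r %in% c("substrate", "both")) downs <- c(downs, p)
    }
    # same ordered reduction as the canonical definition (base sum over
    # sorted protein ids); independence lies in the edge scan above
    out[m] <- sum(fc[sort(ups)]) - sum(fc[sort(downs)])
  }
  out
}

# brute-force weighted-KS running sum, explicit loop
brute_es <- function(scores, set, p = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  N <- length(s)
  hit <- names(s) %in% set
  nh <- sum(hit)
  w <- abs(s)^p
  sw <- sum(w[hit])
  if (sw == 0) { w[] <- 1; sw <- nh }
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + w[i] / sw else cur - 1 / (N - nh)
    run[i] <- cur
  }
  hi <- max(run); lo <- min(run)
  # same tie convention as the implementation: positive extremum on ties
  if (-lo > hi + 1e-9 * max(abs(lo), abs(hi), 1)) lo else hi
}

# exhaustive hypergeometric upper tail: enumerate every draw of size k from
# a universe of size n with K successes
enum_hyper_tail <- function(n, K, k, observed) {
  draws <- utils::combn(n, k)
  succ <- seq_len(K)
  cnt <- 0
  for (j in seq_len(ncol(draws)))
    if (sum(draws[, j] %in% succ) >= observed) cnt <- cnt + 1
  cnt / ncol(draws)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enum_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  EW <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  mean(abs(W_all - EW) >= abs(W_obs - EW) - 1e-12)
}

# exact two-sided rank-sum p by enumerating all group-A labelings
enum_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  W_obs <- sum(r[seq_len(na)])
  EW <- na * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), na)
  W_all <- apply(combos, 2, function(ix) sum(r[ix]))
  mean(abs(W_all - EW) >= abs(W_obs - EW) - 1e-12)
}

# trapezoid AUROC on the empirical ROC curve
auroc_trapezoid <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  fpr <- tpr <- numeric(length(thr) + 2)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  i <- 2
  for (t in thr) {
    tpr[i] <- sum(scores >= t & labels == 1) / np
    fpr[i] <- sum(scores >= t & labels == 0) / nn
    i <- i + 1
  }
  tpr[i] <- 1; fpr[i] <- 1
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# quick random bipartite toy network (plain edge sampling, no generator code)
rand_toy_net <- function(seed, nm = 20, np = 30, n_edges = 80,
                         p_both = 0.15) {
  set.seed(seed)
  mets <- sprintf("m%03d", seq_len(nm))
  prots <- sprintf("p%03d", seq_len(np))
  mi <- sample(mets, n_edges, replace = TRUE)
  pj <- sample(prots, n_edges, replace = TRUE)
  role <- sample(c("substrate", "product", "both"), n_edges, replace = TRUE,
                 prob = c((1 - p_both) / 2, (1 - p_both) / 2, p_both))
  mpi_network(mpi_edges(mi, pj, role, "toy"),
              metabolites = mets, proteins = prots)
}

# small star/chain network builder from an explicit triple list
net_from_triples <- function(...) {
  tr <- list(...)
  mpi_network(mpi_edges(vapply(tr, `[[`, character(1), 1),
                        vapply(tr, `[[`, character(1), 2),
                        vapply(tr, `[[`, character(1), 3), "toy"))
}

wilcox_p_wrap <- function(a, b) mpinet:::wilcox_p(a, b, paired = FALSE)

# cohort fixture with explicit values
toy_cohort <- function(expr, group = NULL, pair_id = NULL, time = NULL,
                       event = NULL, subtype = NULL) {
  cl <- data.frame(sample_id = colnames(expr), stringsAsFactors = FALSE)
  if (!is.null(group)) cl$group <- group
  if (!is.null(pair_id)) cl$pair_id <- pair_id
  if (!is.null(time)) cl$time <- time
  if (!is.null(event)) cl$event <- event
  if (!is.null(subtype)) cl$subtype <- subtype
  expression_cohort(expr, cl)
}
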