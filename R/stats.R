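#' Expression cohort container
#'
#' Couples a genes x samples expression matrix (log2 scale) with a clinical
#' table. Genes with zero variance are dropped with a message; sample ids
#' must be unique and clinical rows must cover the matrix columns.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @param clinical Data frame with a `sample_id` column and optionally
#'   `group`, `subtype`, `pair_id`, `time`, `event` and free covariates.
#' @return Object of class `expression_cohort`.
#' @export
expression_cohort <- function(expr, clinical) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_mpinet("expression matrix must have gene rownames and sample colnames",
                class = "mpinet_format_error")
  if (anyDuplicated(colnames(expr)))
    stop_mpinet("duplicate sample ids", class = "mpinet_format_error")
  if (!all(colnames(expr) %in% clinical$sample_id))
    stop_mpinet("clinical table does not cover all samples",
                class = "mpinet_format_error")
  sds <- apply(expr, 1, sd)
  zv <- rownames(expr)[sds == 0 | is.na(sds)]
  if (length(zv) > 0) {
    message("dropping ", length(zv), " zero-variance gene(s): ",
            paste(head(zv, 5), collapse = ", "),
            if (length(zv) > 5) ", ..." else "")
    expr <- expr[!rownames(expr) %in% zv, , drop = FALSE]
  }
  clinical <- clinical[match(colnames(expr), clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(expr = expr, clinical = clinical, dropped_genes = zv),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("expression_cohort:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  invisible(x)
}

#' Log2 fold change between two groups of log2-scale values
#'
#' Difference of group means computed on log2 values (mean-of-logs
#' convention).
#'
#' @param values_a,values_b Numeric vectors on log2 scale.
#' @return Numeric scalar `mean(values_a) - mean(values_b)`.
#' @export
log2_fold_change <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop_mpinet("empty input to log2_fold_change",
                class = "mpinet_parameter_error")
  mean(values_a) - mean(values_b)
}

#' Multiple-testing adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (step-up false discovery rate) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_mpinet("p-values must lie in [0, 1]", class = "mpinet_parameter_error")
  p.adjust(p, method = method)
}

# Wilcoxon with the package's fixed exact/approximate switch: exact when the
# effective sample size is <= 25 and there are no ties (and, paired, no zero
# differences); otherwise the normal approximation with continuity
# correction. R's wilcox.test implements both branches; we pin the switch.
wilcox_p <- function(a, b, paired) {
  if (paired) {
    d <- a - b
    d <- d[d != 0]
    if (length(d) == 0) return(1.0)
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = exact,
                                 correct = TRUE)$p.value)
  } else {
    exact <- (length(a) + length(b)) <= 25 &&
      !any(duplicated(c(a, b)))
    suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  }
}

#' Paired differential expression (Wilcoxon signed-rank)
#'
#' Tests each gene between two paired sample groups (e.g. tumor vs matched
#' normal) with the Wilcoxon signed-rank test; fold change is the difference
#' of group means on the log2 scale; p-values are BH-adjusted.
#'
#' @param cohort An `expression_cohort` whose clinical table has `group` and
#'   `pair_id` columns.
#' @param group_a,group_b Group labels; every `group_a` sample must have a
#'   `group_b` partner sharing its `pair_id`.
#' @return Data frame with columns `gene`, `log2FC`, `p`, `p_adjusted`,
#'   `direction`.
#' @export
paired_differential <- function(cohort, group_a, group_b) {
  cl <- cohort$clinical
  if (!all(c("group", "pair_id") %in% names(cl)))
    stop_mpinet("clinical table needs group and pair_id columns",
                class = "mpinet_parameter_error")
  sa <- cl[cl$group == group_a, ]
  sb <- cl[cl$group == group_b, ]
  common <- intersect(sa$pair_id, sb$pair_id)
  if (length(common) < 3)
    stop_mpinet("need at least 3 complete pairs, found ", length(common),
                class = "mpinet_parameter_error")
  ia <- sa$sample_id[match(common, sa$pair_id)]
  ib <- sb$sample_id[match(common, sb$pair_id)]
  A <- cohort$expr[, ia, drop = FALSE]
  B <- cohort$expr[, ib, drop = FALSE]
  p <- vapply(seq_len(nrow(A)), function(i) wilcox_p(A[i, ], B[i, ], TRUE),
              numeric(1))
  fc <- rowMeans(A) - rowMeans(B)
  res <- data.frame(gene = rownames(A), log2FC = unname(fc), p = p,
                    p_adjusted = adjust_pvalues(p, "BH"),
                    direction = sign(unname(fc)), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Unpaired differential expression (Wilcoxon rank-sum)
#'
#' @inheritParams paired_differential
#' @param labels Optional per-sample labels (named by sample id) used instead
#'   of the clinical `group` column — convenient for subtype contrasts.
#' @return Data frame as in [paired_differential()].
#' @export
unpaired_differential <- function(cohort, group_a, group_b, labels = NULL) {
  if (is.null(labels)) {
    if (!"group" %in% names(cohort$clinical))
      stop_mpinet("clinical table needs a group column",
                  class = "mpinet_parameter_error")
    labels <- setNames(cohort$clinical$group, cohort$clinical$sample_id)
  }
  labels <- labels[colnames(cohort$expr)]
  ia <- names(labels)[!is.na(labels) & labels == group_a]
  ib <- names(labels)[!is.na(labels) & labels == group_b]
  if (length(ia) < 3 || length(ib) < 3)
    stop_mpinet("both groups need >= 3 samples (", group_a, ": ", length(ia),
                ", ", group_b, ": ", length(ib), ")",
                class = "mpinet_parameter_error")
  A <- cohort$expr[, ia, drop = FALSE]
  B <- cohort$expr[, ib, drop = FALSE]
  p <- vapply(seq_len(nrow(A)), function(i) wilcox_p(A[i, ], B[i, ], FALSE),
              numeric(1))
  fc <- rowMeans(A) - rowMeans(B)
  res <- data.frame(gene = rownames(A), log2FC = unname(fc), p = p,
                    p_adjusted = adjust_pvalues(p, "BH"),
                    direction = sign(unname(fc)), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Univariate Cox proportional-hazards screen
#'
#' Fits one Cox model per gene with expression (z-scored by default) as the
#' sole covariate, Efron tie handling, Wald p-value. Genes on which the model
#' cannot be fit (constant expression, non-convergence) are flagged rather
#' than aborting the screen.
#'
#' @param cohort An `expression_cohort` with `time` and `event` columns.
#' @param zscore Z-score each gene before fitting (default TRUE).
#' @return Data frame with columns `gene`, `coefficient`, `hazard_ratio`,
#'   `p`, `flag` (`"ok"`, `"constant"` or `"failed"`).
#' @export
cox_screen <- function(cohort, zscore = TRUE) {
  cl <- cohort$clinical
  if (!all(c("time", "event") %in% names(cl)))
    stop_mpinet("clinical table needs time and event columns",
                class = "mpinet_parameter_error")
  keep <- !is.na(cl$time) & !is.na(cl$event) & cl$time > 0
  cl <- cl[keep, ]
  if (sum(cl$event) < 10)
    stop_mpinet("need at least 10 events, found ", sum(cl$event),
                class = "mpinet_parameter_error")
  X <- cohort$expr[, cl$sample_id, drop = FALSE]
  surv <- survival::Surv(cl$time, cl$event)
  res <- lapply(rownames(X), function(g) {
    x <- X[g, ]
    if (sd(x) == 0)
      return(data.frame(gene = g, coefficient = NA_real_,
                        hazard_ratio = NA_real_, p = NA_real_,
                        flag = "constant", stringsAsFactors = FALSE))
    if (zscore) x <- (x - mean(x)) / sd(x)
    fit <- tryCatch(
      survival::coxph(surv ~ x, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        tryCatch(suppressWarnings(survival::coxph(surv ~ x, ties = "efron")),
                 error = function(e) NULL)
      })
    if (is.null(fit) || is.na(coef(fit)[1]))
      return(data.frame(gene = g, coefficient = NA_real_,
                        hazard_ratio = NA_real_, p = NA_real_,
                        flag = "failed", stringsAsFactors = FALSE))
    s <- summary(fit)$coefficients
    data.frame(gene = g, coefficient = unname(s[1, "coef"]),
               hazard_ratio = unname(exp(s[1, "coef"])),
               p = unname(s[1, "Pr(>|z|)"]), flag = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' K-group log-rank test
#'
#' @param cohort An `expression_cohort` with `time` and `event`.
#' @param labels Per-sample group labels, named by sample id (or in column
#'   order of the expression matrix).
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(cohort, labels) {
  cl <- cohort$clinical
  if (!all(c("time", "event") %in% names(cl)))
    stop_mpinet("clinical table needs time and event columns",
                class = "mpinet_parameter_error")
  if (is.null(names(labels))) names(labels) <- colnames(cohort$expr)
  lab <- labels[cl$sample_id]
  keep <- !is.na(lab) & !is.na(cl$time) & cl$time > 0
  lab <- factor(lab[keep])
  if (nlevels(lab) < 2)
    stop_mpinet("log-rank needs at least 2 groups",
                class = "mpinet_parameter_error")
  sd_ <- survival::survdiff(
    survival::Surv(cl$time[keep], cl$event[keep]) ~ lab)
  df <- length(sd_$n) - 1
  list(chisq = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' One-sided Fisher enrichment test on a 2x2 table
#'
#' Upper-tail hypergeometric probability that the count in cell \[1,1\] is at
#' least as large as observed, i.e. over-representation in the designated
#' cell.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return P-value.
#' @export
fisher_enrichment_one_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table)) || any(!is.finite(table)))
    stop_mpinet("need a 2x2 table of non-negative integers",
                class = "mpinet_parameter_error")
  a <- table[1, 1]
  # draw column-1 total from row-1 vs row-2 populations
  phyper(a - 1, sum(table[1, ]), sum(table[2, ]), sum(table[, 1]),
         lower.tail = FALSE)
}

#' Row-wise z-score normalization
#'
#' @param mat Numeric matrix (genes x samples).
#' @return Matrix with each row at mean 0, sd 1 (denominator n - 1).
#' @export
zscore_normalize <- function(mat) {
  sds <- apply(mat, 1, sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- rownames(mat)[sds == 0 | is.na(sds)]
    stop_mpinet("zero-variance row(s): ", paste(head(bad, 5), collapse = ", "),
                class = "mpinet_parameter_error")
  }
  t(scale(t(mat)))[, , drop = FALSE]
}
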