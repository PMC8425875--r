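#' Per-metabolite accumulation score (deltaM)
#'
#' For every metabolite in the directed network, deltaM = delta(UpPs) -
#' delta(DownPs): the sum of protein log2 fold changes over its producers
#' minus the sum over its consumers. A positive score means the
#' poor-prognosis subtype up-regulates the metabolite's producers relative
#' to its consumers, i.e. tends to accumulate it. Reversible partners appear
#' in both sets and cancel exactly. Proteins without an entry in `log2fc`
#' are skipped and counted in `n_missing`; summation is in sorted-protein-id
#' order so results are bitwise reproducible.
#'
#' @param net An `mpi_network`.
#' @param log2fc Named numeric vector of per-protein log2 fold changes
#'   (poor- vs well-prognosis subtype, C1 vs C2).
#' @param min_measured Metabolites with fewer measured partners are flagged
#'   `low_confidence` (default 2; a one-protein deltaM is just that
#'   protein's fold change).
#' @return Data frame sorted by metabolite id with columns `metabolite_id`,
#'   `n_up`, `n_down`, `delta_up`, `delta_down`, `deltaM`, `n_missing`,
#'   `low_confidence`.
#' @export
delta_m <- function(net, log2fc, min_measured = 2) {
  mets <- sort(net$metabolites)
  if (length(mets) == 0)
    return(data.frame(metabolite_id = character(), n_up = integer(),
                      n_down = integer(), delta_up = numeric(),
                      delta_down = numeric(), deltaM = numeric(),
                      n_missing = integer(), low_confidence = logical()))
  measured <- names(log2fc)
  rows <- lapply(mets, function(m) {
    nb <- metabolite_neighborhood(net, m)
    up <- sort(intersect(nb$up, measured))
    down <- sort(intersect(nb$down, measured))
    partners <- union(nb$up, nb$down)
    n_missing <- length(setdiff(partners, measured))
    du <- sum(log2fc[up])
    dd <- sum(log2fc[down])
    data.frame(metabolite_id = m, n_up = length(up), n_down = length(down),
               delta_up = du, delta_down = dd, deltaM = du - dd,
               n_missing = n_missing,
               low_confidence = (length(up) + length(down)) < min_measured,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metabolite-set GSEA on the deltaM ranking
#'
#' Ranks metabolites by deltaM (descending) and runs set-permutation GSEA
#' against metabolite sets (e.g. pathway compound lists). Positive NES reads
#' as relative accumulation of the pathway's metabolites in the
#' poor-prognosis subtype, negative NES as consumption.
#'
#' @param acc_table Output of [delta_m()].
#' @param metabolite_sets A `pathway_collection` of metabolite-id sets.
#' @param n_permutations,seed,weight_exponent,min_size Passed to [gsea()].
#' @return Data frame as returned by [gsea()].
#' @export
metabolite_gsea <- function(acc_table, metabolite_sets,
                            n_permutations = 1000, seed = 1,
                            weight_exponent = 1, min_size = 5) {
  if (nrow(acc_table) == 0)
    stop_mpinet("empty accumulation table", class = "mpinet_parameter_error")
  scores <- setNames(acc_table$deltaM, acc_table$metabolite_id)
  gsea(ranked_list(scores), metabolite_sets,
       n_permutations = n_permutations, seed = seed,
       weight_exponent = weight_exponent, min_size = min_size)
}

#' Ranked accumulation report
#'
#' Bar-style table of the top metabolites by deltaM (descending), annotated
#' with the score sign (accumulated / consumed) and, when a pathway
#' collection is supplied, with the pathways each metabolite belongs to.
#'
#' @param acc_table Output of [delta_m()].
#' @param top_k Number of rows (default 20; 0 gives an empty report).
#' @param metabolite_sets Optional `pathway_collection` for annotation.
#' @return Data frame `metabolite_id`, `deltaM`, `direction`, `pathways`.
#' @export
accumulation_report <- function(acc_table, top_k = 20,
                                metabolite_sets = NULL) {
  ord <- order(-acc_table$deltaM, acc_table$metabolite_id)
  out <- acc_table[ord, c("metabolite_id", "deltaM"), drop = FALSE]
  out <- head(out, max(0, top_k))
  out$direction <- ifelse(out$deltaM > 0, "accumulated",
                          ifelse(out$deltaM < 0, "consumed", "neutral"))
  if (!is.null(metabolite_sets)) {
    out$pathways <- vapply(out$metabolite_id, function(m) {
      hits <- names(metabolite_sets)[vapply(metabolite_sets, function(s)
        m %in% s$members, logical(1))]
      paste(hits, collapse = ";")
    }, character(1))
  } else {
    out$pathways <- character(nrow(out))
  }
  rownames(out) <- NULL
  out
}
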