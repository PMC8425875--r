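#' Directed bipartite metabolite-protein interaction network
#'
#' An `mpi_network` holds a deduplicated, role-typed edge list between
#' metabolites and proteins, plus explicit node sets so that proteins that
#' lose all edges during filtering remain indexable until pruned. Direction
#' semantics: `substrate` means the protein consumes the metabolite (edge
#' leaves the metabolite), `product` means the protein produces it (edge
#' points to the metabolite), and `both` marks a reversible interaction.
#'
#' @param edges An `mpi_edges` data frame (or plain data frame with the same
#'   columns). Duplicated (metabolite, protein) pairs are merged: sources are
#'   unioned and conflicting directions collapse to `both`.
#' @param metabolites,proteins Optional node vectors; defaults to the ids
#'   present in `edges`. Must be supersets of the edge endpoints.
#' @return Object of class `mpi_network`: list with `edges`, `metabolites`,
#'   `proteins`.
#' @export
mpi_network <- function(edges, metabolites = NULL, proteins = NULL) {
  edges <- merge_mpi_edges(edges)
  mets <- sort(unique(c(edges$metabolite_id, metabolites)))
  prots <- sort(unique(c(edges$protein_id, proteins)))
  if (length(intersect(mets, prots)) > 0)
    stop_mpinet("bipartiteness violated: ids appear as both metabolite and protein: ",
                paste(head(intersect(mets, prots), 5), collapse = ", "),
                class = "mpinet_format_error")
  structure(list(edges = edges, metabolites = mets, proteins = prots),
            class = "mpi_network")
}

# Deduplicate on (metabolite, protein); union sources; merge roles so that a
# pair seen as substrate in one source and product in another (or as `both`
# anywhere) becomes `both` — reversibility is the conservative merge.
merge_mpi_edges <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    out <- data.frame(metabolite_id = character(), protein_id = character(),
                      role = character(), sources = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("mpi_edges", "data.frame")
    return(out)
  }
  key <- paste(edges$metabolite_id, edges$protein_id, sep = "\r")
  grp <- split(seq_len(nrow(edges)), key)
  idx1 <- vapply(grp, `[[`, integer(1), 1L)
  role <- vapply(grp, function(i) {
    r <- unique(edges$role[i])
    if (length(r) > 1 || "both" %in% r) "both" else r
  }, character(1))
  src <- vapply(grp, function(i) {
    tags <- unlist(strsplit(edges$sources[i], ";", fixed = TRUE))
    paste(sort(unique(tags)), collapse = ";")
  }, character(1))
  out <- data.frame(metabolite_id = edges$metabolite_id[idx1],
                    protein_id = edges$protein_id[idx1],
                    role = role, sources = src, stringsAsFactors = FALSE)
  out <- out[order(out$metabolite_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mpi_edges", "data.frame")
  out
}

#' @export
print.mpi_network <- function(x, ...) {
  cat("mpi_network:", nrow(x$edges), "unique MPIs covering",
      length(x$metabolites), "metabolites and", length(x$proteins),
      "proteins\n")
  invisible(x)
}

#' Integrate MPI edge lists from multiple sources
#'
#' Edges are deduplicated on (metabolite, protein); source tags are unioned
#' and a pair reported as substrate by one source and product by another (or
#' `both` by any) is marked reversible (`both`).
#'
#' @param edge_lists A list of `mpi_edges` data frames.
#' @return An `mpi_network`.
#' @export
integrate_networks <- function(edge_lists) {
  if (inherits(edge_lists, "data.frame")) edge_lists <- list(edge_lists)
  all_edges <- do.call(rbind, lapply(edge_lists, as.data.frame))
  mpi_network(all_edges)
}

#' Node degrees on an MPI network
#'
#' Degree is the number of distinct partners (the network stores at most one
#' edge per pair, so this equals the edge count per node).
#'
#' @param net An `mpi_network`.
#' @param side `"metabolite"` or `"protein"`.
#' @return Named integer vector over all nodes of that side (including
#'   degree-0 nodes kept in the index).
#' @export
mpi_degree <- function(net, side = c("metabolite", "protein")) {
  side <- match.arg(side)
  ids <- if (side == "metabolite") net$metabolites else net$proteins
  col <- if (side == "metabolite") net$edges$metabolite_id else net$edges$protein_id
  d <- setNames(integer(length(ids)), ids)
  if (length(col) > 0) {
    tab <- table(col)
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Remove common (promiscuous) metabolites
#'
#' Metabolites with more than `max_degree` distinct protein partners — water,
#' protons, ADP and the like on real networks — are removed together with
#' their incident edges. The threshold is strict (`degree > max_degree`).
#'
#' @param net An `mpi_network`.
#' @param max_degree Integer, default 200.
#' @return Filtered `mpi_network` (protein index untouched; follow with
#'   [prune_isolated_proteins()]).
#' @export
remove_common_metabolites <- function(net, max_degree = 200) {
  assert_scalar_number(max_degree, "max_degree")
  if (max_degree < 0)
    stop_mpinet("max_degree must be >= 0", class = "mpinet_parameter_error")
  d <- mpi_degree(net, "metabolite")
  drop <- names(d)[d > max_degree]
  keep_edges <- !(net$edges$metabolite_id %in% drop)
  mpi_network(net$edges[keep_edges, , drop = FALSE],
              metabolites = setdiff(net$metabolites, drop),
              proteins = net$proteins)
}

#' Drop proteins left without any metabolite partner
#' @param net An `mpi_network`.
#' @return `mpi_network` whose protein index contains only degree > 0 nodes.
#' @export
prune_isolated_proteins <- function(net) {
  d <- mpi_degree(net, "protein")
  mpi_network(net$edges,
              metabolites = net$metabolites,
              proteins = names(d)[d > 0])
}

#' Core metabolite-interacting proteins
#'
#' Proteins retaining more than `min_degree_exclusive` distinct metabolite
#' partners after filtering (strict inequality). These are the features used
#' for subtype discovery.
#'
#' @param net A filtered `mpi_network`.
#' @param min_degree_exclusive Integer, default 4.
#' @return Sorted character vector of protein ids.
#' @export
core_mipros <- function(net, min_degree_exclusive = 4) {
  assert_scalar_number(min_degree_exclusive, "min_degree_exclusive")
  d <- mpi_degree(net, "protein")
  sort(names(d)[d > min_degree_exclusive])
}

#' Producer and consumer proteins of a metabolite
#'
#' UpPs are proteins with edges pointing to the metabolite (the metabolite is
#' their product); DownPs are proteins with edges leaving it (the metabolite
#' is their substrate). Reversible partners (`both`) appear in both sets, so
#' their fold changes cancel in the accumulation score.
#'
#' @param net An `mpi_network`.
#' @param metabolite_id Metabolite present in the network.
#' @return List with sorted character vectors `up` (UpPs) and `down` (DownPs).
#' @export
metabolite_neighborhood <- function(net, metabolite_id) {
  if (!metabolite_id %in% net$metabolites)
    stop_mpinet("unknown metabolite: ", metabolite_id,
                class = "mpinet_lookup_error")
  e <- net$edges[net$edges$metabolite_id == metabolite_id, , drop = FALSE]
  list(up = sort(e$protein_id[e$role %in% c("product", "both")]),
       down = sort(e$protein_id[e$role %in% c("substrate", "both")]))
}

#' Hypergeometric over-representation of a node set in pathways
#'
#' For each pathway, members are intersected with `universe` and the upper
#' tail P(X >= overlap) of the hypergeometric distribution is computed for
#' the overlap between `node_set` and the pathway. Pathways empty after
#' intersection are skipped.
#'
#' @param node_set Character vector (subset of `universe`).
#' @param pathways A `pathway_collection`.
#' @param universe Character vector of all testable ids.
#' @param correction `"BH"` (Benjamini-Hochberg) or `"bonferroni"`.
#' @return Data frame with columns `pathway`, `name`, `size`, `overlap`, `p`,
#'   `p_adjusted`, sorted by p.
#' @export
node_set_enrichment <- function(node_set, pathways, universe,
                                correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  universe <- unique(universe)
  if (length(universe) == 0)
    stop_mpinet("empty universe", class = "mpinet_parameter_error")
  node_set <- intersect(unique(node_set), universe)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]]$members, universe)
    if (length(members) == 0) return(NULL)
    k <- length(intersect(node_set, members))
    # P(X >= k) drawing |node_set| from universe with |members| successes
    p <- phyper(k - 1, length(members), length(universe) - length(members),
                length(node_set), lower.tail = FALSE)
    data.frame(pathway = pw, name = pathways[[pw]]$name,
               size = length(members), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(pathway = character(), name = character(),
                      size = integer(), overlap = integer(),
                      p = numeric(), p_adjusted = numeric()))
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p, method = correction)
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Community detection on an induced PPI subgraph
#'
#' Induces the subgraph of the PPI network on `node_subset`, drops nodes with
#' no remaining edges, and maximizes modularity with the greedy agglomerative
#' algorithm. Vertices are inserted in lexicographic order so results are
#' deterministic.
#'
#' @param ppi_edges Data frame with columns `protein_a`, `protein_b`.
#' @param node_subset Character vector of nodes to induce on (default: all).
#' @return List of class `community_partition`: `membership` (named integer
#'   vector over retained nodes), `modularity`, `n_modules`.
#' @export
detect_communities <- function(ppi_edges, node_subset = NULL) {
  ea <- as.character(ppi_edges$protein_a)
  eb <- as.character(ppi_edges$protein_b)
  if (!is.null(node_subset)) {
    keep <- ea %in% node_subset & eb %in% node_subset
    ea <- ea[keep]; eb <- eb[keep]
  }
  keep <- ea != eb
  ea <- ea[keep]; eb <- eb[keep]
  if (length(ea) == 0) {
    return(structure(list(membership = setNames(integer(0), character(0)),
                          modularity = 0, n_modules = 0L),
                     class = "community_partition"))
  }
  verts <- sort(unique(c(ea, eb)))
  g <- igraph::graph_from_data_frame(
    unique(data.frame(from = pmin(ea, eb), to = pmax(ea, eb),
                      stringsAsFactors = FALSE)),
    directed = FALSE, vertices = verts)
  comm <- igraph::cluster_fast_greedy(g)
  memb <- as.integer(igraph::membership(comm))
  # never return a partition worse than the trivial connected-component one
  # (greedy agglomeration can leave a clique split at negative modularity)
  comp <- igraph::components(g)$membership
  if (igraph::modularity(g, comp) >= igraph::modularity(g, memb))
    memb <- as.integer(comp)
  structure(list(membership = setNames(memb, igraph::V(g)$name),
                 modularity = igraph::modularity(g, memb),
                 n_modules = length(unique(memb))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", x$n_modules, "modules over",
      length(x$membership), "nodes; modularity",
      format(x$modularity, digits = 4), "\n")
  invisible(x)
}
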