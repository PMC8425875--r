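test_that("read_mpi_edges parses valid files and reports malformed rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite_id\tprotein_id\trole",
               "M1\tP1\tsubstrate", "M1\tP2\tproduct", "M2\tP1\tboth"), f)
  edges <- read_mpi_edges(f, "KEGG")
  expect_equal(nrow(edges), 3)
  expect_true(all(edges$sources == "KEGG"))

  writeLines("metabolite_id\tprotein_id\trole", f)
  expect_equal(nrow(read_mpi_edges(f, "KEGG")), 0)

  writeLines(c("metabolite_id\tprotein_id\trole", "M1\tP1\tcofactor"), f)
  err <- expect_error(read_mpi_edges(f, "KEGG"), class = "mpinet_format_error")
  expect_match(conditionMessage(err), "cofactor")
  expect_match(conditionMessage(err), "2")

  writeLines(c("metabolite_id\trole", "M1\tsubstrate"), f)
  expect_error(read_mpi_edges(f, "KEGG"), class = "mpinet_format_error")
})

test_that("integrate_networks merges directions, sources, and deduplicates", {
  kegg <- mpi_edges("M1", "P1", "substrate", "KEGG")
  brenda <- mpi_edges("M1", "P1", "product", "BRENDA")
  net <- integrate_networks(list(kegg, brenda))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$role, "both")
  expect_equal(net$edges$sources, "BRENDA;KEGG")

  a <- mpi_edges(paste0("Ma", 1:5), paste0("Pa", 1:5), rep("substrate", 5), "A")
  b <- mpi_edges(paste0("Mb", 1:5), paste0("Pb", 1:5), rep("product", 5), "B")
  expect_equal(nrow(integrate_networks(list(a, b))$edges), 10)
})

test_that("integration matches a brute-force pair-set union on overlapping lists", {
  set.seed(42)
  shared <- data.frame(m = sprintf("M%02d", 1:5), p = sprintf("P%02d", 1:5))
  lists <- lapply(1:4, function(i) {
    own <- data.frame(m = sprintf("M%02d", sample(6:40, 5)),
                      p = sprintf("P%02d", sample(6:40, 5)))
    all <- rbind(shared, own)
    mpi_edges(all$m, all$p, sample(c("substrate", "product"), 10,
                                   replace = TRUE), paste0("src", i))
  })
  net <- integrate_networks(lists)
  oracle <- unique(unlist(lapply(lists, function(l)
    paste(l$metabolite_id, l$protein_id))))
  expect_equal(nrow(net$edges), length(oracle))
  expect_setequal(paste(net$edges$metabolite_id, net$edges$protein_id), oracle)
})

test_that("integration is idempotent", {
  net <- rand_toy_net(7)
  again <- integrate_networks(list(net$edges, net$edges))
  expect_equal(again$edges, net$edges)
})

test_that("common-metabolite filter uses a strict degree threshold", {
  # hub: degree 201; near-hub: degree 200 (protein universe of 401)
  prots <- sprintf("P%03d", 1:401)
  edges <- rbind(
    data.frame(metabolite_id = "HUB", protein_id = prots[1:201],
               role = "substrate", sources = "t"),
    data.frame(metabolite_id = "NEAR", protein_id = prots[2:201],
               role = "substrate", sources = "t"))
  net <- mpi_network(edges)
  filt <- remove_common_metabolites(net, 200)
  expect_false("HUB" %in% filt$metabolites)
  expect_true("NEAR" %in% filt$metabolites)
  expect_equal(unname(mpi_degree(filt, "metabolite")["NEAR"]), 200L)

  small <- rand_toy_net(3, nm = 10, np = 10, n_edges = 20)
  expect_equal(remove_common_metabolites(small, 200)$edges, small$edges)
  expect_error(remove_common_metabolites(small, -1),
               class = "mpinet_parameter_error")
})

test_that("filters match a brute-force single pass on random toy nets", {
  for (seed in 1:100) {
    net <- rand_toy_net(seed, nm = 15, np = 20, n_edges = 60)
    maxd <- sample(1:5, 1)
    got <- prune_isolated_proteins(remove_common_metabolites(net, maxd))
    # oracle: count per-metabolite partners from the raw edge list
    mdeg <- table(net$edges$metabolite_id)
    keep_m <- setdiff(net$metabolites, names(mdeg)[mdeg > maxd])
    keep_e <- net$edges[net$edges$metabolite_id %in% keep_m, ]
    expect_setequal(got$metabolites, keep_m)
    expect_setequal(got$proteins, unique(keep_e$protein_id))
    expect_equal(nrow(got$edges), nrow(keep_e))
  }
})

test_that("prune_isolated_proteins drops proteins orphaned by the hub filter", {
  net <- net_from_triples(c("Mhub", "Ponly", "substrate"),
                          c("Mhub", "Pboth", "substrate"),
                          c("Mok", "Pboth", "product"))
  filt <- remove_common_metabolites(net, 1)  # Mhub degree 2 > 1
  expect_true("Ponly" %in% filt$proteins)    # still indexed, degree 0
  pruned <- prune_isolated_proteins(filt)
  expect_false("Ponly" %in% pruned$proteins)
  expect_true("Pboth" %in% pruned$proteins)
})

test_that("core_mipros applies a strict degree-4 default", {
  edges <- rbind(
    data.frame(metabolite_id = sprintf("M%d", 1:5), protein_id = "Pfive",
               role = "substrate", sources = "t"),
    data.frame(metabolite_id = sprintf("M%d", 1:4), protein_id = "Pfour",
               role = "substrate", sources = "t"))
  net <- mpi_network(edges)
  expect_equal(core_mipros(net), "Pfive")
  expect_equal(core_mipros(mpi_network(edges[0, ])), character(0))
  toy <- rand_toy_net(11, nm = 15, np = 12, n_edges = 70)
  pdeg <- table(toy$edges$protein_id)
  expect_equal(core_mipros(toy, 2), sort(names(pdeg)[pdeg > 2]))
})

test_that("metabolite_neighborhood splits producers and consumers", {
  net <- net_from_triples(c("M", "P1", "product"), c("M", "P2", "substrate"),
                          c("M2", "P3", "both"))
  nb <- metabolite_neighborhood(net, "M")
  expect_equal(nb$up, "P1")
  expect_equal(nb$down, "P2")
  nb2 <- metabolite_neighborhood(net, "M2")
  expect_equal(nb2$up, "P3")
  expect_equal(nb2$down, "P3")
  expect_error(metabolite_neighborhood(net, "nope"),
               class = "mpinet_lookup_error")
})

test_that("neighborhoods partition the partner set (up ∪ down = partners, ∩ = both)", {
  for (seed in 1:20) {
    net <- rand_toy_net(seed + 200, nm = 12, np = 15, n_edges = 50)
    for (m in net$metabolites) {
      nb <- metabolite_neighborhood(net, m)
      e <- net$edges[net$edges$metabolite_id == m, ]
      expect_setequal(union(nb$up, nb$down), e$protein_id)
      expect_setequal(intersect(nb$up, nb$down),
                      e$protein_id[e$role == "both"])
    }
  }
})

test_that("node_set_enrichment computes the hypergeometric upper tail", {
  pw <- pathway_collection(list(A = list(name = "A", category = "c",
                                         members = paste0("g", 1:5))))
  universe <- paste0("g", 1:10)
  res <- node_set_enrichment(paste0("g", 1:5), pw, universe)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  # pathway empty after intersection is skipped
  pw2 <- pathway_collection(list(B = list(name = "B", category = "c",
                                          members = "zzz")))
  expect_equal(nrow(node_set_enrichment("g1", pw2, universe)), 0)
  expect_error(node_set_enrichment("g1", pw, character(0)),
               class = "mpinet_parameter_error")
})

test_that("hypergeometric p matches exhaustive enumeration on small universes", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(6:12, 1); K <- sample(2:(n - 1), 1); k <- sample(2:(n - 1), 1)
    universe <- paste0("u", seq_len(n))
    pw <- pathway_collection(list(S = list(name = "S", category = "c",
                                           members = universe[seq_len(K)])))
    node_set <- sample(universe, k)
    res <- node_set_enrichment(node_set, pw, universe)
    oracle <- enum_hyper_tail(n, K, k, res$overlap)
    expect_equal(res$p, oracle, tolerance = 1e-12)
  }
})

test_that("detect_communities splits bridged cliques and labels all retained nodes", {
  cl1 <- t(utils::combn(paste0("a", 1:5), 2))
  cl2 <- t(utils::combn(paste0("b", 1:5), 2))
  ppi <- data.frame(protein_a = c(cl1[, 1], cl2[, 1], "a1"),
                    protein_b = c(cl1[, 2], cl2[, 2], "b1"),
                    stringsAsFactors = FALSE)
  part <- detect_communities(ppi)
  expect_equal(part$n_modules, 2)
  memb <- part$membership
  expect_length(memb, 10)
  expect_equal(length(unique(memb[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(memb[paste0("b", 1:5)])), 1)

  # exhaustive bipartition oracle: the clique split maximizes modularity
  g <- igraph::graph_from_data_frame(ppi, directed = FALSE)
  verts <- igraph::V(g)$name
  best <- -Inf; best_split <- NULL
  for (mask in 0:(2^9 - 1)) {
    side <- c(0, as.integer(intToBits(mask))[1:9])
    q <- igraph::modularity(g, side + 1)
    if (q > best) { best <- q; best_split <- side }
  }
  expect_equal(part$modularity, best, tolerance = 1e-12)

  single <- detect_communities(data.frame(protein_a = cl1[, 1],
                                          protein_b = cl1[, 2]))
  expect_equal(single$n_modules, 1)

  empty <- detect_communities(ppi[0, ])
  expect_equal(empty$n_modules, 0)
  expect_equal(empty$modularity, 0)
})

test_that("bipartiteness is enforced and preserved by every operation", {
  expect_error(mpi_network(mpi_edges("X", "X", "substrate", "t")),
               class = "mpinet_format_error")
  net <- rand_toy_net(9)
  for (op in list(function(n) remove_common_metabolites(n, 3),
                  prune_isolated_proteins,
                  function(n) integrate_networks(list(n$edges)))) {
    out <- op(net)
    expect_length(intersect(out$metabolites, out$proteins), 0)
    expect_true(all(out$edges$metabolite_id %in% out$metabolites))
    expect_true(all(out$edges$protein_id %in% out$proteins))
  }
})

test_that("network TSV round-trips through reader and writer", {
  net <- rand_toy_net(13)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mpi_network(net, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  net2 <- mpi_network(mpi_edges(back$metabolite_id, back$protein_id,
                                back$role, back$source))
  expect_equal(net2$edges, net$edges)
})
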