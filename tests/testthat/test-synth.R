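test_that("gen_mpi_network honors sizes, hubs, roles and determinism", {
  cfg <- synth_config(seed = 2, n_metabolites = 80, n_proteins = 100,
                      hub_fraction = 0.05, hub_degree = 90,
                      max_nonhub_degree = 40)
  gn <- gen_mpi_network(cfg)
  deg <- mpi_degree(gn$network, "metabolite")
  expect_length(gn$truth$hubs, 4)
  expect_true(all(deg[gn$truth$hubs] > 80))
  # deterministic under the same config
  gn2 <- gen_mpi_network(cfg)
  expect_identical(gn$network$edges, gn2$network$edges)
  # hub fraction 0: nothing crosses the common-metabolite filter
  cfg0 <- synth_config(seed = 2, n_metabolites = 80, n_proteins = 100,
                       hub_fraction = 0, max_nonhub_degree = 50)
  deg0 <- mpi_degree(gen_mpi_network(cfg0)$network, "metabolite")
  expect_true(all(deg0 <= 200))
  # edge count close to request (dedup removes only collisions)
  cfgE <- synth_config(seed = 5, n_metabolites = 170, n_proteins = 300,
                       mean_degree = 6, hub_fraction = 0)
  gnE <- gen_mpi_network(cfgE)
  expect_gt(nrow(gnE$network$edges), 0.85 * gnE$truth$requested_edges)
  expect_length(intersect(gnE$network$metabolites, gnE$network$proteins), 0)
})

test_that("synth_config validates its fields", {
  expect_error(synth_config(effect_size = -1),
               class = "mpinet_parameter_error")
  expect_error(synth_config(p_within = 1.5), class = "mpinet_parameter_error")
  expect_error(synth_config(nonsense = 1), class = "mpinet_parameter_error")
})

test_that("gen_cohort plants subtypes, survival and pairing as configured", {
  cfg <- synth_config(seed = 6, n_metabolites = 120, n_proteins = 200,
                      hub_fraction = 0, n_genes = 500, n_samples = 500,
                      effect_size = 1, censoring_fraction = 0.3,
                      paired_normals = 20)
  gn <- gen_mpi_network(cfg)
  co <- gen_cohort(cfg, gn$network)
  cl <- co$cohort$clinical
  tum <- cl[cl$group == "tumor", ]
  # censoring within ±0.05 of target at n=500
  expect_lt(abs(mean(1 - tum$event) - 0.3), 0.05)
  # planted genes live inside the core MIPros
  filt <- prune_isolated_proteins(remove_common_metabolites(gn$network))
  expect_true(all(co$truth$informative %in% core_mipros(filt)))
  # markers are exactly the down-in-C1 informative genes
  expect_setequal(co$truth$markers,
                  names(co$truth$directions)[co$truth$directions < 0])
  # planted shift has the requested magnitude
  X <- co$cohort$expr
  lab <- co$truth$labels
  shift <- rowMeans(X[co$truth$markers, names(lab)[lab == "C1"]]) -
    rowMeans(X[co$truth$markers, names(lab)[lab == "C2"]])
  expect_lt(abs(mean(shift) + 1), 0.15)
  # paired normals carry no subtype shift and complete pairing
  expect_equal(sum(cl$group == "normal"), 20)
  expect_true(all(cl$pair_id[cl$group == "normal"] %in%
                    cl$pair_id[cl$group == "tumor"]))
  expect_error(gen_cohort(synth_config(n_genes = 10, n_informative = 50)),
               class = "mpinet_parameter_error")
})

test_that("cohort_seed varies noise but not the generative structure", {
  cfg_a <- synth_config(seed = 3, n_metabolites = 100, n_proteins = 150,
                        hub_fraction = 0, n_genes = 400, n_samples = 60,
                        n_informative = 25)
  cfg_b <- synth_config(seed = 3, n_metabolites = 100, n_proteins = 150,
                        hub_fraction = 0, n_genes = 400, n_samples = 60,
                        n_informative = 25, cohort_seed = 999)
  net <- gen_mpi_network(cfg_a)$network
  a <- gen_cohort(cfg_a, net)
  b <- gen_cohort(cfg_b, net)
  expect_identical(a$truth$informative, b$truth$informative)
  expect_identical(a$truth$directions, b$truth$directions)
  expect_false(isTRUE(all.equal(a$cohort$expr, b$cohort$expr)))
})

test_that("effect size 0 leaves no recoverable signal; effect 3 is exact", {
  base <- list(seed = 31, n_metabolites = 120, n_proteins = 200,
               hub_fraction = 0, n_genes = 500, n_samples = 100)
  net <- gen_mpi_network(do.call(synth_config, base))$network
  filt <- prune_isolated_proteins(remove_common_metabolites(net))
  co3 <- gen_cohort(do.call(synth_config, c(base, effect_size = 3)), net)
  m3 <- fit_subtype_model(co3$cohort, filt, co3$truth$markers, reps = 100,
                          seed = 1)
  expect_equal(ari(m3$labels, co3$truth$labels[names(m3$labels)]), 1)
  co0 <- gen_cohort(do.call(synth_config, c(base, effect_size = 0)), net)
  m0 <- fit_subtype_model(co0$cohort, filt, co0$truth$markers, reps = 100,
                          seed = 1)
  expect_lt(abs(ari(m0$labels, co0$truth$labels[names(m0$labels)])), 0.15)
})

test_that("accumulation scenario obeys its exact ground-truth contract", {
  cfg <- synth_config(seed = 13, n_metabolites = 70, n_proteins = 90,
                      hub_fraction = 0, acc_sigma = 0, acc_up = 1.5,
                      acc_down = 2)
  gn <- gen_mpi_network(cfg)
  acc <- gen_accumulation_scenario(cfg, gn$network)
  tab <- delta_m(gn$network, acc$log2fc)
  got <- setNames(tab$deltaM, tab$metabolite_id)
  for (i in seq_len(nrow(acc$truth$planted)))
    expect_equal(unname(got[acc$truth$planted$metabolite_id[i]]),
                 acc$truth$planted$deltaM[i], tolerance = 1e-12)
  # the target tops the planted table strictly
  expect_equal(acc$truth$target, acc$truth$planted$metabolite_id[1])
  expect_true(all(acc$truth$planted$deltaM[-1] < acc$truth$target_deltaM))
  # unknown target errors
  expect_error(gen_accumulation_scenario(
    synth_config(seed = 13, target_metabolite = "NOPE"), gn$network),
    class = "mpinet_parameter_error")
})

test_that("gen_link_instance plants blocks and degenerate settings separate classes", {
  cfg <- synth_config(seed = 44, p_within = 1, p_between = 0,
                      link_n_metabolites = 16, link_n_proteins = 20,
                      link_n_positives = 60)
  li <- gen_link_instance(cfg)
  # all positives are within-block
  bm <- li$truth$metabolite_blocks; bp <- li$truth$protein_blocks
  expect_true(all(bm[li$positives$metabolite_id] ==
                    bp[li$positives$protein_id]))
  # with p_within = 1 all candidates are between-block non-edges
  expect_true(all(li$candidates$truth == "between_block"))
  li2 <- gen_link_instance(cfg)
  expect_identical(li$network$edges, li2$network$edges)
  expect_error(gen_link_instance(synth_config(n_blocks = 1)),
               class = "mpinet_parameter_error")
})

test_that("simulate_world writes files that round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 3, n_metabolites = 60, n_proteins = 80,
                      hub_fraction = 0, n_genes = 200, n_samples = 40,
                      n_informative = 15, mean_degree = 8)
  paths <- simulate_world(cfg, dir)
  net <- mpi_network(read_mpi_edges(paths$network, "synthetic"))
  orig <- gen_mpi_network(cfg)$network
  expect_equal(net$edges[, c("metabolite_id", "protein_id", "role")],
               orig$edges[, c("metabolite_id", "protein_id", "role")])
  expr <- read_expression(paths$expression)
  co <- gen_cohort(cfg, orig)
  expect_equal(expr, co$cohort$expr, tolerance = 1e-9)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$accumulation_target,
               gen_accumulation_scenario(cfg, orig)$truth$target)
  sets <- read_gmt(paths$metabolite_sets)
  expect_true("planted_pathway" %in% names(sets))
})
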