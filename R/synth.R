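#' Synthetic-data configuration
#'
#' One seeded configuration object drives every generator, so that a full
#' synthetic world (network, cohort, accumulation scenario, link-prediction
#' instance) is a pure function of the config. Defaults emulate the shape of
#' the real inputs at a desk-testable scale: a heavy-tailed bipartite
#' network of 300 metabolites x 400 proteins, a 2000-gene / 200-sample
#' cohort with 50 informative genes shifted by 1 SD between two subtypes,
#' exponential survival with hazard ratio 3 for the poor-prognosis subtype
#' and 30% censoring, and a 4-block planted-partition instance for link
#' prediction.
#'
#' @param seed Master seed.
#' @param ... Overrides for any default field (see the function body for
#'   the full list).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # network
    n_metabolites = 300, n_proteins = 400, mean_degree = 6,
    hub_fraction = 0.01, hub_degree = 250, max_nonhub_degree = 60,
    role_mix = c(substrate = 0.45, product = 0.45, both = 0.10),
    # cohort
    n_samples = 200, n_genes = 2000, n_informative = 50,
    effect_size = 1.0, frac_down_in_c1 = 0.5, paired_normals = 0,
    cohort_seed = NULL,  # independent cohorts from one generative process
    # survival (time unit: days)
    baseline_hazard = 1 / 1000, hazard_ratio = 3, censoring_fraction = 0.3,
    # accumulation scenario
    acc_up = 1, acc_down = 1, acc_sigma = 0.2, acc_pathway_size = 10,
    acc_n_background_sets = 10, target_metabolite = NULL,
    # link prediction
    n_blocks = 4, p_within = 0.25, p_between = 0.01,
    link_n_metabolites = 60, link_n_proteins = 80, link_n_positives = 200,
    # TME
    n_cell_types = 20)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop_mpinet("unknown config field(s): ", paste(unknown, collapse = ", "),
                class = "mpinet_parameter_error")
  cfg[names(over)] <- over
  probs <- c(cfg$hub_fraction, cfg$p_within, cfg$p_between,
             cfg$censoring_fraction, cfg$frac_down_in_c1)
  if (any(probs < 0 | probs > 1))
    stop_mpinet("probabilities must lie in [0, 1]",
                class = "mpinet_parameter_error")
  if (cfg$effect_size < 0)
    stop_mpinet("effect_size must be >= 0", class = "mpinet_parameter_error")
  if (!isTRUE(all.equal(sum(cfg$role_mix), 1)))
    stop_mpinet("role_mix must sum to 1", class = "mpinet_parameter_error")
  structure(cfg, class = c("synth_config", "list"))
}

#' Generate a heavy-tailed directed bipartite MPI network
#'
#' Metabolite degrees are drawn from a log-normal (heavy-tailed); a
#' `hub_fraction` of metabolites get degree `hub_degree` to exercise the
#' common-metabolite filter; protein partners are sampled with log-normal
#' weights so protein degrees are heavy-tailed too. Edge roles follow
#' `role_mix`.
#'
#' @param cfg A `synth_config`.
#' @return List: `network` (`mpi_network`), `truth` (list with `hubs`,
#'   `requested_edges`).
#' @export
gen_mpi_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  nm <- cfg$n_metabolites; np <- cfg$n_proteins
  if (nm < 1 || np < 1)
    stop_mpinet("network sizes must be >= 1", class = "mpinet_parameter_error")
  if (round(cfg$hub_fraction * nm) > 0 && cfg$hub_degree > np)
    stop_mpinet("hub_degree exceeds the number of proteins",
                class = "mpinet_parameter_error")
  with_seed(cfg$seed, {
    mets <- sprintf("M%04d", seq_len(nm))
    prots <- sprintf("P%04d", seq_len(np))
    deg <- pmax(1, pmin(cfg$max_nonhub_degree, np,
                        round(stats::rlnorm(nm, log(cfg$mean_degree * 0.7),
                                            0.9))))
    n_hub <- round(cfg$hub_fraction * nm)
    if (n_hub > 0) deg[seq_len(n_hub)] <- cfg$hub_degree
    w <- stats::rlnorm(np, 0, 1)
    rows <- vector("list", nm)
    for (i in seq_len(nm)) {
      partners <- sample(prots, deg[i], prob = w)
      role <- sample(names(cfg$role_mix), deg[i], replace = TRUE,
                     prob = cfg$role_mix)
      rows[[i]] <- data.frame(metabolite_id = mets[i], protein_id = partners,
                              role = role, sources = "synthetic",
                              stringsAsFactors = FALSE)
    }
    net <- mpi_network(do.call(rbind, rows), metabolites = mets,
                       proteins = prots)
    list(network = net,
         truth = list(hubs = if (n_hub > 0) mets[seq_len(n_hub)] else
           character(0),
           requested_edges = sum(deg)))
  })
}

# censoring rate mu such that the expected censoring fraction over the
# cohort's per-subject exponential hazards equals the target
censor_rate <- function(lambda, target) {
  if (target <= 0) return(0)
  f <- function(mu) mean(mu / (lambda + mu)) - target
  uniroot(f, c(1e-12, 1e6 * max(lambda)))$root
}

#' Generate an expression cohort with two planted subtypes
#'
#' Gene values are standard normal; `n_informative` genes (sampled from the
#' core MIPros of `net` when a network is given, so subtype recovery
#' exercises the real pipeline) receive a +/- `effect_size` mean shift in
#' subtype C1, with `frac_down_in_c1` of them shifted down — the
#' down-in-C1 genes double as orientation markers. Survival is exponential
#' with the C1 hazard multiplied by `hazard_ratio`; censoring is independent
#' exponential calibrated to `censoring_fraction`. Optional paired normal
#' samples carry no subtype shift.
#'
#' @param cfg A `synth_config`.
#' @param net Optional `mpi_network` whose proteins become gene names.
#' @return List: `cohort` (`expression_cohort`), `truth` (list with
#'   `labels`, `informative`, `directions`, `markers`).
#' @export
gen_cohort <- function(cfg, net = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  # Structural choices (which genes carry signal, in which direction) depend
  # only on cfg$seed; sampling noise additionally honors cfg$cohort_seed so
  # that independent cohorts can share one generative process.
  structural <- with_seed(cfg$seed + 1L, {
    if (!is.null(net)) {
      filtered <- prune_isolated_proteins(remove_common_metabolites(net))
      core <- core_mipros(filtered)
      if (length(core) < cfg$n_informative)
        stop_mpinet("network has only ", length(core),
                    " core MIPros but n_informative = ", cfg$n_informative,
                    class = "mpinet_parameter_error")
      base_genes <- net$proteins
    } else {
      core <- character(0)
      base_genes <- character(0)
    }
    n_fill <- cfg$n_genes - length(base_genes)
    if (n_fill < 0)
      stop_mpinet("n_genes smaller than the network's protein count",
                  class = "mpinet_parameter_error")
    genes <- c(base_genes, sprintf("FILLER%04d", seq_len(n_fill)))
    if (cfg$n_informative > length(genes))
      stop_mpinet("n_informative exceeds gene count",
                  class = "mpinet_parameter_error")
    informative <- if (length(core) >= cfg$n_informative)
      sort(sample(core, cfg$n_informative)) else
      sort(sample(genes, cfg$n_informative))
    n_down <- round(cfg$frac_down_in_c1 * cfg$n_informative)
    dir <- c(rep(-1, n_down), rep(1, cfg$n_informative - n_down))
    list(genes = genes, informative = informative, dir = dir)
  })
  genes <- structural$genes
  informative <- structural$informative
  dir <- structural$dir
  with_seed((cfg$cohort_seed %||% cfg$seed) + 101L, {
    n <- cfg$n_samples
    samples <- sprintf("TUM%04d", seq_len(n))
    subtype <- ifelse(stats::runif(n) < 0.5, "C1", "C2")
    # guarantee both subtypes at small n
    if (length(unique(subtype)) == 1) subtype[1] <- setdiff(c("C1", "C2"),
                                                            subtype[1])
    X <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                dimnames = list(genes, samples))
    is_c1 <- subtype == "C1"
    X[informative, is_c1] <- X[informative, is_c1] +
      dir * cfg$effect_size
    markers <- informative[dir < 0]
    lambda <- cfg$baseline_hazard * ifelse(is_c1, cfg$hazard_ratio, 1)
    T_ <- rexp(n, rate = lambda)
    if (cfg$censoring_fraction > 0) {
      mu <- censor_rate(lambda, cfg$censoring_fraction)
      C_ <- rexp(n, rate = mu)
    } else C_ <- rep(Inf, n)
    time <- pmin(T_, C_)
    event <- as.integer(T_ <= C_)
    clinical <- data.frame(sample_id = samples, group = "tumor",
                           subtype = subtype, pair_id = NA_character_,
                           time = time, event = event,
                           stringsAsFactors = FALSE)
    if (cfg$paired_normals > 0) {
      k <- min(cfg$paired_normals, n)
      nsamp <- sprintf("NOR%04d", seq_len(k))
      Xn <- matrix(rnorm(length(genes) * k), nrow = length(genes),
                   dimnames = list(genes, nsamp))
      X <- cbind(X, Xn)
      clinical$pair_id[seq_len(k)] <- sprintf("PAIR%04d", seq_len(k))
      clinical <- rbind(clinical, data.frame(
        sample_id = nsamp, group = "normal", subtype = NA_character_,
        pair_id = sprintf("PAIR%04d", seq_len(k)), time = NA_real_,
        event = NA_integer_, stringsAsFactors = FALSE))
    }
    cohort <- expression_cohort(X, clinical)
    list(cohort = cohort,
         truth = list(labels = setNames(subtype, samples),
                      informative = informative,
                      directions = setNames(dir, informative),
                      markers = markers))
  })
}

#' Generate a metabolite-accumulation scenario with exact ground truth
#'
#' Plants a pathway of metabolites whose producers are up-regulated (+`acc_up`)
#' and consumers down-regulated (-`acc_down`) in the poor-prognosis subtype;
#' all other proteins get Normal(0, `acc_sigma`) fold changes. Planted
#' metabolites are chosen greedily so no protein receives conflicting
#' assignments, which makes each planted deltaM exactly
#' `acc_up * |up-only| + acc_down * |down-only|` (reversible partners cancel
#' by construction). The target is the planted metabolite with the strictly
#' largest truth score.
#'
#' @param cfg A `synth_config`.
#' @param net An `mpi_network`.
#' @return List: `log2fc` (named vector over all proteins), `truth` (list
#'   with `target`, `target_deltaM`, `planted` data frame, `pathway`
#'   members), `sets` (a `pathway_collection`: the planted pathway plus
#'   `acc_n_background_sets` random background sets).
#' @export
gen_accumulation_scenario <- function(cfg, net) {
  stopifnot(inherits(cfg, "synth_config"), inherits(net, "mpi_network"))
  with_seed(cfg$seed + 2L, {
    a <- cfg$acc_up; b <- cfg$acc_down
    nbs <- lapply(net$metabolites, function(m) metabolite_neighborhood(net, m))
    names(nbs) <- net$metabolites
    up_only <- lapply(nbs, function(nb) setdiff(nb$up, nb$down))
    down_only <- lapply(nbs, function(nb) setdiff(nb$down, nb$up))
    score <- vapply(net$metabolites, function(m)
      a * length(up_only[[m]]) + b * length(down_only[[m]]), numeric(1))
    eligible <- net$metabolites[
      vapply(up_only, length, integer(1)) >= 1 &
      vapply(down_only, length, integer(1)) >= 1]
    if (!is.null(cfg$target_metabolite) &&
        !cfg$target_metabolite %in% eligible)
      stop_mpinet("target metabolite lacks directed partners",
                  class = "mpinet_parameter_error")
    if (length(eligible) == 0)
      stop_mpinet("no metabolite has both a producer and a consumer",
                  class = "mpinet_parameter_error")
    ord <- eligible[order(-score[eligible], eligible)]
    if (!is.null(cfg$target_metabolite))
      ord <- c(cfg$target_metabolite, setdiff(ord, cfg$target_metabolite))
    assigned <- new.env(parent = emptyenv())  # protein -> +a / -b
    planted <- character(0); planted_truth <- numeric(0)
    target_truth <- NA_real_
    for (m in ord) {
      if (length(planted) >= cfg$acc_pathway_size) break
      ups <- up_only[[m]]; downs <- down_only[[m]]
      conflict <- any(vapply(ups, function(p)
        !is.null(assigned[[p]]) && assigned[[p]] != a, logical(1))) ||
        any(vapply(downs, function(p)
          !is.null(assigned[[p]]) && assigned[[p]] != -b, logical(1)))
      if (conflict) next
      truth_m <- a * length(ups) + b * length(downs)
      if (length(planted) > 0 && truth_m >= target_truth) next  # keep target strictly top
      if (length(planted) == 0) target_truth <- truth_m
      for (p in ups) assigned[[p]] <- a
      for (p in downs) assigned[[p]] <- -b
      planted <- c(planted, m)
      planted_truth <- c(planted_truth, truth_m)
    }
    if (length(planted) == 0)
      stop_mpinet("could not plant any metabolite",
                  class = "mpinet_parameter_error")
    log2fc <- setNames(rnorm(length(net$proteins), 0, cfg$acc_sigma),
                       net$proteins)
    for (p in ls(assigned)) log2fc[[p]] <- assigned[[p]]
    # background sets: random metabolites, same size as the planted pathway
    bg <- lapply(seq_len(cfg$acc_n_background_sets), function(i)
      list(name = sprintf("background_%02d", i), category = "background",
           members = sample(net$metabolites,
                            min(length(planted), length(net$metabolites)))))
    sets <- c(list(planted_pathway = list(name = "planted_pathway",
                                          category = "planted",
                                          members = planted)), bg)
    names(sets) <- vapply(sets, `[[`, character(1), "name")
    list(log2fc = log2fc,
         truth = list(target = planted[1], target_deltaM = planted_truth[1],
                      planted = data.frame(metabolite_id = planted,
                                           deltaM = planted_truth,
                                           stringsAsFactors = FALSE),
                      pathway = planted),
         sets = pathway_collection(sets))
  })
}

#' Generate a planted-block link-prediction instance
#'
#' Metabolites and proteins are assigned to `n_blocks` blocks; edges appear
#' with probability `p_within` inside a block and `p_between` across blocks.
#' A sample of existing edges becomes the positive training set; candidates
#' are non-edges labeled by whether they are within-block (positive-like)
#' or between-block.
#'
#' @param cfg A `synth_config`.
#' @return List: `network`, `positives`, `candidates` (with `truth`
#'   column), `truth` (block assignments).
#' @export
gen_link_instance <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_blocks < 2)
    stop_mpinet("need >= 2 blocks", class = "mpinet_parameter_error")
  with_seed(cfg$seed + 3L, {
    nm <- cfg$link_n_metabolites; np <- cfg$link_n_proteins
    mets <- sprintf("LM%03d", seq_len(nm))
    prots <- sprintf("LP%03d", seq_len(np))
    bm <- sample(rep_len(seq_len(cfg$n_blocks), nm))
    bp <- sample(rep_len(seq_len(cfg$n_blocks), np))
    # per-node activity gives the heavy-tailed degrees real MPI networks
    # show; edges concentrate on active nodes, so degree-based features
    # carry genuine signal
    am <- stats::rlnorm(nm, 0, 0.6); am <- am / mean(am)
    ap <- stats::rlnorm(np, 0, 0.6); ap <- ap / mean(ap)
    grid <- expand.grid(mi = seq_len(nm), pj = seq_len(np))
    within <- bm[grid$mi] == bp[grid$pj]
    base <- ifelse(within, cfg$p_within, cfg$p_between)
    # degenerate settings (0 or 1) stay deterministic
    pr <- ifelse(base <= 0, 0,
                 ifelse(base >= 1, 1,
                        pmin(1, base * am[grid$mi] * ap[grid$pj])))
    is_edge <- stats::runif(nrow(grid)) < pr
    edges <- data.frame(metabolite_id = mets[grid$mi[is_edge]],
                        protein_id = prots[grid$pj[is_edge]],
                        role = sample(c("substrate", "product", "both"),
                                      sum(is_edge), replace = TRUE,
                                      prob = c(0.45, 0.45, 0.10)),
                        sources = "synthetic", stringsAsFactors = FALSE)
    net <- mpi_network(edges, metabolites = mets, proteins = prots)
    n_pos <- min(cfg$link_n_positives, nrow(net$edges))
    pos_idx <- sample(nrow(net$edges), n_pos)
    positives <- net$edges[pos_idx, c("metabolite_id", "protein_id")]
    rownames(positives) <- NULL
    non_edge <- !is_edge
    cand_idx <- which(non_edge)
    cand <- data.frame(metabolite_id = mets[grid$mi[cand_idx]],
                       protein_id = prots[grid$pj[cand_idx]],
                       truth = ifelse(within[cand_idx], "within_block",
                                      "between_block"),
                       stringsAsFactors = FALSE)
    list(network = net, positives = positives, candidates = cand,
         truth = list(metabolite_blocks = setNames(bm, mets),
                      protein_blocks = setNames(bp, prots)))
  })
}

#' Generate a TME cell-type enrichment matrix with two planted blocks
#'
#' @param cfg A `synth_config`.
#' @param samples Sample ids (columns).
#' @param effect_size Mean shift of the first half of cell types in the S1
#'   block (default 2).
#' @return List: `tme` (cell types x samples matrix), `truth` (named S1/S2
#'   labels).
#' @export
gen_tme_matrix <- function(cfg, samples, effect_size = 2) {
  with_seed(cfg$seed + 4L, {
    ct <- sprintf("CellType%02d", seq_len(cfg$n_cell_types))
    n <- length(samples)
    lab <- ifelse(seq_len(n) <= n / 2, "S1", "S2")
    X <- matrix(rnorm(length(ct) * n), nrow = length(ct),
                dimnames = list(ct, samples))
    half <- seq_len(ceiling(length(ct) / 2))
    X[half, lab == "S1"] <- X[half, lab == "S1"] + effect_size
    list(tme = X, truth = setNames(lab, samples))
  })
}

#' Write a complete synthetic world to disk
#'
#' Emits expression TSV, clinical TSV, network TSV, GMT sets, a log2FC table
#' and a truth JSON under `out_dir` — every file round-trips through the
#' package readers.
#'
#' @param cfg A `synth_config`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of written paths.
#' @export
simulate_world <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gn <- gen_mpi_network(cfg)
  gc_ <- gen_cohort(cfg, gn$network)
  acc <- gen_accumulation_scenario(cfg, gn$network)
  paths <- list(
    network = file.path(out_dir, "network.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    log2fc = file.path(out_dir, "log2fc.tsv"),
    metabolite_sets = file.path(out_dir, "metabolite_sets.gmt"),
    truth = file.path(out_dir, "truth.json"))
  write_mpi_network(gn$network, paths$network)
  write_expression(gc_$cohort$expr, paths$expression)
  write_tsv_stable(gc_$cohort$clinical, paths$clinical)
  write_tsv_stable(data.frame(protein_id = names(acc$log2fc),
                              log2fc = unname(acc$log2fc)), paths$log2fc)
  write_gmt(acc$sets, paths$metabolite_sets)
  jsonlite::write_json(
    list(seed = cfg$seed,
         subtype_labels = as.list(gc_$truth$labels),
         informative_genes = gc_$truth$informative,
         markers = gc_$truth$markers,
         accumulation_target = acc$truth$target,
         accumulation_target_deltaM = acc$truth$target_deltaM),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
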