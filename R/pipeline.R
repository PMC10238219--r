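#' Run the full synthetic multi-omics pipeline
#'
#' End-to-end orchestration on a simulated study: data generation,
#' per-time-point differential analysis for genes and metabolites,
#' gene co-expression and metabolite correlation networks with Leiden
#' subnetworks, metabolic-subsystem bridging, cross-species concordance
#' against simulated human cohorts, and knockout reversal scoring. All
#' stage outputs are written as TSV under `out_dir` together with a JSON
#' run manifest (configuration snapshot, seed, output file MD5 hashes,
#' stage timings, package version).
#'
#' @param config a [sim_config()] describing the study.
#' @param out_dir output directory (created if needed).
#' @param run_cfg analysis settings from [read_run_config()].
#' @param concordant_fraction sign-concordance rate of the simulated human
#'   cohorts.
#' @param ko_flipped module indices whose dysregulation the simulated
#'   knockout reverses.
#' @return invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_fibrosis_pipeline <- function(config = sim_config(),
                                  out_dir,
                                  run_cfg = read_run_config(NULL),
                                  concordant_fraction = 0.75,
                                  ko_flipped = c(1, 2)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  paths <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    paths <<- c(paths, path)
    path
  }

  ## simulate
  sim <- clock("simulate", {
    s <- simulate_counts(config)
    s$met <- simulate_metabolites(config, s$truth)
    s$phenotypes <- simulate_phenotypes(config, s$truth)
    s
  })
  design <- sim$design
  ref <- design_reference(design)
  emit("counts.tsv", function(p) write_omics_matrix(sim$counts, p))
  emit("metabolites.tsv",
       function(p) write_omics_matrix(sim$met$metabolites, p))
  emit("phenotypes.tsv", function(p) write_omics_matrix(sim$phenotypes, p))
  emit("design.tsv", function(p) write_design(design, p))
  emit("gene_modules.tsv", function(p) write_feature_map(
    data.frame(feature = names(sim$truth$gene_modules),
               target = unname(sim$truth$gene_modules)), p))

  ## differential expression per time point
  timepoints <- setdiff(config$groups, ref)
  sf <- size_factors(sim$counts)
  de <- clock("differential_genes",
              lapply(timepoints, function(tp)
                de_test(sim$counts, design, tp, sf = sf)))
  names(de) <- timepoints
  for (tp in timepoints)
    emit(paste0("de_", tp, ".tsv"),
         function(p) write_differential(de[[tp]], p))
  deg <- consistent_deg_sets(de, alpha = run_cfg$alpha)
  emit("deg0.tsv", function(p) utils::write.table(
    data.frame(feature = deg$deg0), p, sep = "\t", quote = FALSE,
    row.names = FALSE))
  emit("deg1.tsv", function(p) utils::write.table(
    data.frame(feature = deg$deg1), p, sep = "\t", quote = FALSE,
    row.names = FALSE))

  ## metabolomics preprocessing + differential metabolites
  metab <- clock("differential_metabolites", {
    filt <- metabolite_missing_filter(sim$met$metabolites, design,
                                      min_present = run_cfg$min_present)
    imputed <- knn_impute(filt$matrix, design, k = run_cfg$knn_k)
    dm <- lapply(timepoints, function(tp) dm_test(imputed, design, tp))
    names(dm) <- timepoints
    list(filtered = filt, imputed = imputed, dm = dm,
         dm_sets = recurrent_dm_sets(dm, alpha = run_cfg$alpha))
  })
  for (tp in timepoints)
    emit(paste0("dm_", tp, ".tsv"),
         function(p) write_differential(metab$dm[[tp]], p))

  ## gene co-expression network with phenotype nodes
  gcn <- clock("gcn", {
    y <- log2(sweep(as_plain_matrix(sim$counts), 2, sf, "/") + 1)
    aug <- attach_phenotypes(y, sim$phenotypes, base_kind = "gene")
    pairs <- spearman_all_pairs(aug)
    net <- build_gcn(pairs, fdr = run_cfg$fdr,
                     top_fraction = run_cfg$top_fraction)
    part <- leiden_partition(net, resolution = run_cfg$resolution,
                             seed = run_cfg$seed)
    list(network = net, partition = part,
         avg_cc = subnetwork_avg_cc(net, part),
         centrality = phenotype_centrality(net))
  })
  paths <- c(paths, write_network(gcn$network, gcn$partition,
                                  file.path(out_dir, "gcn")))

  ## metabolite correlation network
  mcn <- clock("mcn", {
    pairs <- spearman_all_pairs(log2(metab$imputed),
                                kinds = stats::setNames(
                                  rep("metabolite", nrow(metab$imputed)),
                                  rownames(metab$imputed)))
    net <- build_mcn(pairs, fdr = run_cfg$fdr)
    part <- leiden_partition(net, resolution = run_cfg$resolution,
                             seed = run_cfg$seed)
    list(network = net, partition = part)
  })
  paths <- c(paths, write_network(mcn$network, mcn$partition,
                                  file.path(out_dir, "mcn")))

  ## subsystem bridging
  integ <- clock("integrate", {
    subsys <- simulate_subsystem_map(sim$truth, seed = config$seed)
    gene_part <- gcn$partition[
      gcn$partition$node %in% names(sim$truth$gene_modules), , drop = FALSE]
    gp <- subsystem_profiles(gene_part, subsys, fdr = run_cfg$fdr)
    mp <- subsystem_profiles(mcn$partition, subsys, fdr = run_cfg$fdr)
    list(map = subsys, gene_profiles = gp, metab_profiles = mp,
         bridges = bridge_networks(gp, mp, fdr = run_cfg$fdr))
  })
  emit("bridges.tsv", function(p) utils::write.table(
    integ$bridges, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## cross-species concordance against simulated cohorts
  cross <- clock("crossspecies", {
    mid_tp <- timepoints[ceiling(length(timepoints) / 2)]
    omap <- filter_one_to_one(simulate_ortholog_map(rownames(sim$counts)))
    cohorts <- simulate_cohort_tables(de[[mid_tp]], omap,
                                      concordant_fraction,
                                      seed = config$seed,
                                      alpha = run_cfg$alpha)
    main_labels <- intersect(c(1, 2), unique(gcn$partition$label))
    main_genes <- intersect(
      gcn$partition$node[gcn$partition$label %in% main_labels],
      names(sim$truth$gene_modules))
    if (!length(main_genes)) main_genes <- names(sim$truth$gene_modules)
    list(contrast = mid_tp, map = omap, cohorts = cohorts,
         overlap = overlap_with_cohort(main_genes, cohorts$cohort_a, omap,
                                       alpha = run_cfg$alpha),
         trend_a = same_trend_fraction(de[[mid_tp]], cohorts$cohort_a,
                                       omap, alpha = run_cfg$alpha),
         trend_b = same_trend_fraction(de[[mid_tp]], cohorts$cohort_b,
                                       omap, alpha = run_cfg$alpha),
         validated = validated_set(de[[mid_tp]], cohorts$cohort_a,
                                   cohorts$cohort_b, omap,
                                   alpha = run_cfg$alpha,
                                   partition = gcn$partition))
  })
  emit("validated_genes.tsv", function(p) utils::write.table(
    data.frame(feature = cross$validated$genes), p, sep = "\t",
    quote = FALSE, row.names = FALSE))

  ## knockout reversal on a three-arm companion experiment
  reversal <- clock("reversal", {
    ko <- simulate_ko_experiment(config, flipped = ko_flipped)
    rep_part <- data.frame(
      node = names(sim$truth$gene_modules)[sim$truth$gene_modules > 0],
      label = sim$truth$gene_modules[sim$truth$gene_modules > 0] - 1L,
      stringsAsFactors = FALSE)
    list(disease = ko$disease, perturbation = ko$perturbation,
         report = reversal_analysis(ko$disease, ko$perturbation, rep_part,
                                    alpha = run_cfg$alpha,
                                    fdr = run_cfg$fdr))
  })
  emit("reversal.tsv", function(p) utils::write.table(
    reversal$report, p, sep = "\t", quote = FALSE, row.names = FALSE))

  manifest <- list(
    package = "fibronet",
    version = as.character(utils::packageVersion("fibronet")),
    seed = config$seed,
    run_config = run_cfg,
    sim_config = config[setdiff(names(config),
                                c("module_trajectories",
                                  "phenotype_couplings"))],
    outputs = lapply(stats::setNames(paths, basename(paths)), function(p)
      unname(tools::md5sum(p))),
    timings = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, de = de, deg = deg, metab = metab, gcn = gcn,
                 mcn = mcn, integrate = integ, cross = cross,
                 reversal = reversal, manifest = manifest))
}

#' Simulate a knockout companion experiment
#'
#' Builds a three-arm study (control, disease, perturbed-disease) from a
#' time-course configuration: every planted module keeps its
#' maximum-magnitude disease effect in the disease arm, and modules listed
#' in `flipped` lose it in the perturbed arm (the knockout rescues them)
#' while the others retain it. Returns the two differential tables the
#' reversal analysis consumes.
#'
#' @param config a [sim_config()]; its modules, loadings scale, dispersion
#'   and seed carry over.
#' @param flipped module indices rescued by the perturbation.
#' @return list with `disease` (disease vs control), `perturbation`
#'   (perturbed vs disease), `truth`, and the three-arm `counts`/`design`.
#' @export
simulate_ko_experiment <- function(config, flipped = c(1, 2)) {
  if (length(flipped) && (any(flipped < 1) || any(flipped > config$n_modules)))
    stop("flipped module index out of range")
  peak <- vapply(config$module_trajectories, function(tr)
    tr[which.max(abs(tr))], 0)
  traj <- lapply(seq_len(config$n_modules), function(i)
    c(0, peak[i], if (i %in% flipped) 0 else peak[i]))
  ko_cfg <- sim_config(
    n_genes = config$n_genes, n_metabolites = config$n_metabolites,
    n_modules = config$n_modules,
    groups = c("control", "disease", "ko_disease"),
    replicates = config$replicates,
    module_trajectories = traj,
    gene_module_fraction = config$gene_module_fraction,
    metabolite_module_fraction = config$metabolite_module_fraction,
    loading_sd = config$loading_sd,
    nb_dispersion = config$nb_dispersion,
    baseline_logmean = config$baseline_logmean,
    baseline_logmean_sd = config$baseline_logmean_sd,
    library_size_range = config$library_size_range,
    phenotype_couplings = list(),
    seed = config$seed + 10L)
  sim <- simulate_counts(ko_cfg)
  disease <- de_test(sim$counts, sim$design, "disease")
  design_d <- study_design(sim$design$sample, sim$design$group,
                           reference = "disease",
                           group_levels = ko_cfg$groups)
  perturbation <- de_test(sim$counts, design_d, "ko_disease")
  list(disease = disease, perturbation = perturbation, truth = sim$truth,
       counts = sim$counts, design = sim$design)
}
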