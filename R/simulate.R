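#' Simulation configuration for a multi-omics time course
#'
#' Defines the planted structure of a synthetic bleomycin-style study: gene
#' and metabolite modules following shared group-level trajectories,
#' negative-binomial counts, lognormal metabolite abundances with
#' detection-limit missingness, and phenotype variables coupled to module
#' trajectories.
#'
#' The default design mirrors a five-time-point lung-injury time course
#' (control plus days 7, 14, 21, 28; five animals per group) with five
#' modules whose trajectories follow the canonical fibrosis patterns:
#' sustained down-regulation with a nadir at day 14, early up-regulation
#' with recovery, progressive up-regulation with a plateau, late
#' up-regulation, and a transient early spike.
#'
#' @param n_genes,n_metabolites,n_modules feature and module counts.
#' @param groups ordered group labels; the first is the reference.
#' @param replicates samples per group.
#' @param module_trajectories list of numeric vectors (one per module, one
#'   entry per group, reference entry 0) of standardised effects on the
#'   natural-log scale; defaults to [default_trajectories()].
#' @param gene_module_fraction,metabolite_module_fraction fraction of
#'   features assigned to planted modules (split evenly).
#' @param loading_sd scale of per-feature module loadings (loadings are
#'   drawn uniformly in `loading_sd * [0.5, 1.5]`, strictly positive so a
#'   module is internally positively correlated).
#' @param nb_dispersion negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param baseline_logmean,baseline_logmean_sd natural-log mean count
#'   baseline distribution across genes.
#' @param library_size_range per-sample library-size factor range (uniform).
#' @param metabolite_logmean,metabolite_logmean_sd baseline log-abundance
#'   distribution across metabolites.
#' @param metabolite_noise_sd per-observation lognormal noise sd.
#' @param missing_threshold_quantile abundance quantile (over all entries)
#'   below which a value can go missing.
#' @param missing_prob probability that a value below the threshold is
#'   censored to `NA`.
#' @param phenotype_couplings list of couplings, each a list with elements
#'   `name`, `module` (index), `sign` (+1/-1), `noise_sd`. The default
#'   panel emulates pulmonary-function testing: stiffness index, elastance
#'   and peripheral airway resistance track the progressive module
#'   (stiffness noiselessly, as a positive control), while FEV, FVC and IC
#'   track the down-regulated module.
#' @param seed integer seed; the configuration fully determines all
#'   generated data.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_metabolites = 300, n_modules = 5,
                       groups = c("control", "d7", "d14", "d21", "d28"),
                       replicates = 5,
                       module_trajectories = NULL,
                       gene_module_fraction = 0.5,
                       metabolite_module_fraction = 0.6,
                       loading_sd = 1,
                       nb_dispersion = 0.1,
                       baseline_logmean = 5, baseline_logmean_sd = 1,
                       library_size_range = c(0.7, 1.3),
                       metabolite_logmean = 3, metabolite_logmean_sd = 1,
                       metabolite_noise_sd = 0.3,
                       missing_threshold_quantile = 0.15,
                       missing_prob = 0.8,
                       phenotype_couplings = NULL,
                       seed = 0) {
  if (is.null(module_trajectories))
    module_trajectories <- default_trajectories(n_modules, length(groups))
  if (is.null(phenotype_couplings))
    phenotype_couplings <- default_phenotype_couplings(n_modules)
  cfg <- list(n_genes = as.integer(n_genes),
              n_metabolites = as.integer(n_metabolites),
              n_modules = as.integer(n_modules),
              groups = groups, replicates = as.integer(replicates),
              module_trajectories = module_trajectories,
              gene_module_fraction = gene_module_fraction,
              metabolite_module_fraction = metabolite_module_fraction,
              loading_sd = loading_sd, nb_dispersion = nb_dispersion,
              baseline_logmean = baseline_logmean,
              baseline_logmean_sd = baseline_logmean_sd,
              library_size_range = library_size_range,
              metabolite_logmean = metabolite_logmean,
              metabolite_logmean_sd = metabolite_logmean_sd,
              metabolite_noise_sd = metabolite_noise_sd,
              missing_threshold_quantile = missing_threshold_quantile,
              missing_prob = missing_prob,
              phenotype_couplings = phenotype_couplings,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$module_trajectories) != cfg$n_modules)
    stop("need one trajectory per module")
  for (tr in cfg$module_trajectories) {
    if (length(tr) != length(cfg$groups))
      stop("trajectory vectors need one entry per group")
    if (tr[1] != 0)
      stop("the reference-group trajectory entry must be 0")
  }
  n_mod_genes <- floor(cfg$n_genes * cfg$gene_module_fraction)
  if (n_mod_genes > cfg$n_genes || cfg$gene_module_fraction > 1 ||
      cfg$gene_module_fraction < 0)
    stop("module sizes exceed n_genes")
  if (cfg$metabolite_module_fraction > 1 ||
      cfg$metabolite_module_fraction < 0)
    stop("module sizes exceed n_metabolites")
  if (cfg$n_modules > 0 && n_mod_genes < cfg$n_modules)
    stop("fewer module genes than modules")
  if (cfg$missing_threshold_quantile < 0 ||
      cfg$missing_threshold_quantile > 1)
    stop("missing_threshold_quantile must be in [0, 1]")
  if (cfg$loading_sd < 0 || cfg$nb_dispersion < 0)
    stop("loading_sd and nb_dispersion must be non-negative")
  for (pc in cfg$phenotype_couplings)
    if (pc$module < 1 || pc$module > cfg$n_modules)
      stop("phenotype coupling references unknown module ", pc$module)
  invisible(cfg)
}

#' Default module trajectories
#'
#' Five canonical fibrosis time-course shapes (down/nadir, early-up with
#' recovery, progressive-up plateau, late-up, transient spike), recycled
#' with a sign flip beyond five modules and linearly interpolated to the
#' requested number of groups. The reference entry is always 0.
#'
#' @param n_modules number of modules.
#' @param n_groups number of groups (>= 2).
#' @return list of numeric vectors.
#' @export
default_trajectories <- function(n_modules, n_groups = 5) {
  shapes <- list(c(0, -1.5, -2, -1.5, -1),
                 c(0, 2, 2, 1, 0.5),
                 c(0, 1, 2, 1.5, 1.5),
                 c(0, 0.3, 0.5, 1.5, 1.5),
                 c(0, 1.5, 0.5, -0.5, -1))
  lapply(seq_len(n_modules), function(i) {
    base <- shapes[[(i - 1) %% 5 + 1]]
    if (((i - 1) %/% 5) %% 2 == 1) base <- -base
    tr <- stats::approx(seq_along(base), base,
                        xout = seq(1, length(base),
                                   length.out = n_groups))$y
    tr[1] <- 0
    tr
  })
}

default_phenotype_couplings <- function(n_modules) {
  prog <- min(3, n_modules)
  down <- 1
  list(
    list(name = "stiffness_index", module = prog, sign = 1, noise_sd = 0),
    list(name = "elastance", module = prog, sign = 1, noise_sd = 0.5),
    list(name = "airway_resistance", module = prog, sign = 1,
         noise_sd = 0.7),
    list(name = "FEV", module = down, sign = 1, noise_sd = 0.5),
    list(name = "FVC", module = down, sign = 1, noise_sd = 0.8),
    list(name = "IC", module = down, sign = 1, noise_sd = 1))
}

#' Study design implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return a [study_design()]; samples are named `<group>_<replicate>`.
#' @export
sim_design <- function(config) {
  samples <- unlist(lapply(config$groups, function(g)
    paste0(g, "_", seq_len(config$replicates))))
  groups <- rep(config$groups, each = config$replicates)
  study_design(samples, groups, reference = config$groups[1],
               group_levels = config$groups)
}

#' Planted ground truth implied by a configuration
#'
#' Module assignments are deterministic: the first
#' `floor(n * module_fraction)` features are split as evenly as possible
#' among the modules, in order; remaining features are unplanted
#' (module 0). Gene module i and metabolite module i share trajectory i,
#' which is what makes gene-metabolite subsystem bridges discoverable.
#'
#' @param config a [sim_config()].
#' @return list with `gene_modules`, `metabolite_modules` (named integer
#'   vectors, 0 = no module), `trajectories` (module x group matrix) and
#'   `phenotype_couplings`.
#' @export
sim_ground_truth <- function(config) {
  assign_modules <- function(n, fraction, prefix, width) {
    ids <- sprintf("%s%0*d", prefix, width, seq_len(n))
    n_mod <- floor(n * fraction)
    mod <- rep(0L, n)
    if (config$n_modules > 0 && n_mod > 0)
      mod[seq_len(n_mod)] <-
        rep(seq_len(config$n_modules), length.out = n_mod)[
          order(rep(seq_len(config$n_modules), length.out = n_mod))]
    stats::setNames(mod, ids)
  }
  traj <- do.call(rbind, config$module_trajectories)
  if (!is.null(traj)) dimnames(traj) <- list(NULL, config$groups)
  list(gene_modules = assign_modules(config$n_genes,
                                     config$gene_module_fraction, "gene", 4),
       metabolite_modules = assign_modules(
         config$n_metabolites, config$metabolite_module_fraction, "met", 3),
       trajectories = traj,
       phenotype_couplings = config$phenotype_couplings)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(code)
}

#' Simulate a counts matrix with planted co-expressed modules
#'
#' Counts are negative-binomial with mean
#' `library_size * exp(baseline + loading * trajectory[group])` and
#' variance `mu + alpha * mu^2`; unplanted genes have zero loading.
#' Fully determined by the configuration seed.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (an [omics_matrix()]), `truth`
#'   ([sim_ground_truth()] plus per-gene `loadings`), and `design`.
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  truth <- sim_ground_truth(config)
  design <- sim_design(config)
  with_seed(config$seed, {
    n_g <- config$n_genes
    n_s <- nrow(design)
    base <- stats::rnorm(n_g, config$baseline_logmean,
                         config$baseline_logmean_sd)
    loading <- ifelse(truth$gene_modules > 0,
                      config$loading_sd * stats::runif(n_g, 0.5, 1.5), 0)
    lib <- stats::runif(n_s, config$library_size_range[1],
                        config$library_size_range[2])
    g_idx <- match(design$group, config$groups)
    eff <- matrix(0, n_g, n_s)
    planted <- truth$gene_modules > 0
    if (any(planted))
      eff[planted, ] <- loading[planted] *
        truth$trajectories[truth$gene_modules[planted], g_idx, drop = FALSE]
    mu <- sweep(exp(base + eff), 2, lib, "*")
    counts <- if (config$nb_dispersion > 0)
      matrix(stats::rnbinom(n_g * n_s, mu = mu,
                            size = 1 / config$nb_dispersion), n_g, n_s)
    else
      matrix(stats::rpois(n_g * n_s, mu), n_g, n_s)
    dimnames(counts) <- list(names(truth$gene_modules), design$sample)
    truth$loadings <- stats::setNames(loading, rownames(counts))
    list(counts = omics_matrix(counts, "counts"), truth = truth,
         design = design)
  })
}

#' Simulate metabolite relative peak areas with missing values
#'
#' Lognormal abundances with module shifts sharing the gene-module
#' trajectories; entries below the `missing_threshold_quantile` of all
#' simulated values are censored to `NA` with probability `missing_prob`,
#' mimicking detection-limit missingness.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_counts()] or
#'   [sim_ground_truth()].
#' @return list with `metabolites` (an [omics_matrix()], kind
#'   `relative_peak_area`) and `complete` (the uncensored matrix).
#' @export
simulate_metabolites <- function(config, truth = sim_ground_truth(config)) {
  validate_sim_config(config)
  design <- sim_design(config)
  with_seed(config$seed + 1L, {
    n_m <- config$n_metabolites
    n_s <- nrow(design)
    base <- stats::rnorm(n_m, config$metabolite_logmean,
                         config$metabolite_logmean_sd)
    loading <- ifelse(truth$metabolite_modules > 0,
                      config$loading_sd * stats::runif(n_m, 0.5, 1.5), 0)
    g_idx <- match(design$group, config$groups)
    eff <- matrix(0, n_m, n_s)
    planted <- truth$metabolite_modules > 0
    if (any(planted))
      eff[planted, ] <- loading[planted] *
        truth$trajectories[truth$metabolite_modules[planted], g_idx,
                           drop = FALSE]
    logv <- base + eff +
      matrix(stats::rnorm(n_m * n_s, 0, config$metabolite_noise_sd),
             n_m, n_s)
    vals <- exp(logv)
    dimnames(vals) <- list(names(truth$metabolite_modules), design$sample)
    censored <- vals
    if (config$missing_threshold_quantile > 0) {
      thr <- stats::quantile(vals, config$missing_threshold_quantile)
      low <- vals < thr
      drop <- low & matrix(stats::runif(n_m * n_s) < config$missing_prob,
                           n_m, n_s)
      censored[drop] <- NA
    }
    list(metabolites = omics_matrix(censored, "relative_peak_area"),
         complete = omics_matrix(vals, "relative_peak_area"))
  })
}

#' Simulate phenotype variables coupled to module trajectories
#'
#' Each phenotype is `sign * trajectory[module][group] + N(0, noise_sd)`.
#'
#' @param config a [sim_config()].
#' @param truth ground truth (for the trajectories and couplings).
#' @return an [omics_matrix()] (kind `phenotype`, phenotypes x samples).
#' @export
simulate_phenotypes <- function(config, truth = sim_ground_truth(config)) {
  validate_sim_config(config)
  design <- sim_design(config)
  g_idx <- match(design$group, config$groups)
  with_seed(config$seed + 2L, {
    rows <- lapply(truth$phenotype_couplings, function(pc) {
      if (pc$module < 1 || pc$module > nrow(truth$trajectories))
        stop("phenotype coupling references unknown module ", pc$module)
      pc$sign * truth$trajectories[pc$module, g_idx] +
        stats::rnorm(nrow(design), 0, pc$noise_sd)
    })
    m <- do.call(rbind, rows)
    dimnames(m) <- list(vapply(truth$phenotype_couplings, `[[`, "", "name"),
                        design$sample)
    omics_matrix(m, "phenotype")
  })
}

#' Simulate a one-to-one ortholog map
#'
#' @param genes mouse gene IDs.
#' @return feature map data frame (`feature` = mouse, `target` = human).
#' @export
simulate_ortholog_map <- function(genes) {
  data.frame(feature = genes, target = paste0("HS_", toupper(genes)),
             stringsAsFactors = FALSE)
}

#' Simulate human-cohort differential tables
#'
#' Builds two independent "human cohort" differential tables from a mouse
#' differential table through an ortholog map. A `concordant_fraction` of
#' the mapped mouse-significant genes keeps the mouse fold-change sign in
#' the cohort; the remainder either flips sign (staying significant) or,
#' with probability `nonsig_fraction`, becomes non-significant. Mapped
#' non-significant mouse genes get null cohort statistics.
#'
#' @param mouse_diff mouse differential table.
#' @param ortholog_map one-to-one map (`feature` = mouse, `target` = human).
#' @param concordant_fraction probability a significant gene keeps its sign.
#' @param seed RNG seed.
#' @param alpha significance threshold defining "significant" rows.
#' @param nonsig_fraction probability a discordant gene is rendered
#'   non-significant rather than flipped.
#' @return list with differential tables `cohort_a` and `cohort_b` (human
#'   IDs).
#' @export
simulate_cohort_tables <- function(mouse_diff, ortholog_map,
                                   concordant_fraction, seed = 0,
                                   alpha = 0.05, nonsig_fraction = 0) {
  if (!nrow(ortholog_map)) stop("empty ortholog map")
  if (concordant_fraction < 0 || concordant_fraction > 1)
    stop("concordant_fraction must be in [0, 1]")
  human <- ortholog_map$target[match(mouse_diff$feature,
                                     ortholog_map$feature)]
  keep <- !is.na(human)
  mouse <- mouse_diff[keep, , drop = FALSE]
  human <- human[keep]
  make_cohort <- function(label) {
    n <- nrow(mouse)
    sig <- mouse$padj < alpha
    concord <- stats::runif(n) < concordant_fraction
    gone <- !concord & stats::runif(n) < nonsig_fraction
    s <- ifelse(concord, sign(mouse$log2fc), -sign(mouse$log2fc))
    lfc <- s * abs(stats::rnorm(n, 1.5, 0.4))
    padj <- stats::runif(n, 0.001, 0.049)
    lfc[!sig | gone] <- stats::rnorm(sum(!sig | gone), 0, 0.3)
    padj[!sig | gone] <- stats::runif(sum(!sig | gone), 0.1, 1)
    pval <- padj * stats::runif(n, 0.05, 1)
    new_differential_table(human, lfc, pval, padj, label)
  }
  with_seed(as.integer(seed) + 3L, {
    list(cohort_a = make_cohort("cohort_a"), cohort_b = make_cohort("cohort_b"))
  })
}

#' Simulate a metabolic-subsystem mapping
#'
#' Subsystem `SS<i>` collects a `coverage` fraction of gene module i and of
#' metabolite module i (the shared latent trajectory makes the pair jointly
#' enriched downstream); unplanted features are spread over background
#' subsystems.
#'
#' @param truth ground truth from [sim_ground_truth()].
#' @param coverage fraction of each module mapped to its subsystem.
#' @param n_background number of background subsystems.
#' @param seed RNG seed.
#' @return feature map data frame (`feature`, `target` = subsystem) over
#'   both genes and metabolites.
#' @export
simulate_subsystem_map <- function(truth, coverage = 0.8,
                                   n_background = 5, seed = 0) {
  with_seed(as.integer(seed) + 4L, {
    rows <- list()
    for (v in list(truth$gene_modules, truth$metabolite_modules)) {
      planted <- v[v > 0]
      for (m in sort(unique(planted))) {
        ids <- names(planted)[planted == m]
        take <- sort(sample(ids, ceiling(coverage * length(ids))))
        rows[[length(rows) + 1L]] <- data.frame(
          feature = take, target = paste0("SS", m),
          stringsAsFactors = FALSE)
      }
      bg <- names(v)[v == 0]
      if (length(bg))
        rows[[length(rows) + 1L]] <- data.frame(
          feature = bg,
          target = paste0("BG", sample.int(n_background, length(bg),
                                           replace = TRUE)),
          stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Deterministic miniature fixture dataset
#'
#' A small fully reproducible dataset (30 genes, 12 metabolites, 2
#' phenotypes, 5 groups x 3 samples, seed 1) used in unit tests and
#' documentation examples.
#'
#' @return list with `config`, `design`, `truth`, `counts`, `metabolites`
#'   (censored), `metabolites_complete`, `phenotypes`.
#' @export
sim_fixture <- function() {
  cfg <- sim_config(
    n_genes = 30, n_metabolites = 12, n_modules = 3, replicates = 3,
    gene_module_fraction = 0.6, metabolite_module_fraction = 0.75,
    metabolite_noise_sd = 0.1, missing_threshold_quantile = 0.1,
    missing_prob = 0.5,
    phenotype_couplings = list(
      list(name = "pheno_pos", module = 1, sign = 1, noise_sd = 0),
      list(name = "pheno_neg", module = 2, sign = -1, noise_sd = 0.3)),
    seed = 1)
  sim <- simulate_counts(cfg)
  met <- simulate_metabolites(cfg, sim$truth)
  ph <- simulate_phenotypes(cfg, sim$truth)
  list(config = cfg, design = sim$design, truth = sim$truth,
       counts = sim$counts, metabolites = met$metabolites,
       metabolites_complete = met$complete, phenotypes = ph)
}
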