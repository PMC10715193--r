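#' Derive a stage seed from the master seed
#'
#' Every stochastic stage of the pipeline consumes a seed derived
#' deterministically from the master seed and the stage name, so no stage
#' depends on hidden global randomness or on the order stages run in.
#'
#' @param master Master integer seed.
#' @param stage Stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 1000003
  as.integer((abs(as.numeric(master)) * 1009 + h * 97 + 1) %% (2^31 - 2) + 1)
}

#' Assemble and validate a pipeline configuration
#'
#' Exactly one input mode must be active: either real inputs (`annotations`
#' plus `taxon_map` file paths, optional `trees`) or a `simulation` block.
#'
#' @param annotations Path to a per-protein annotation TSV.
#' @param taxon_map Path to an organism/domain/phylum TSV.
#' @param trees Character vector of newick file paths (optional; real mode).
#' @param simulation A [simulation_spec()], or a list with `n_organisms`,
#'   `total_range`, `laws` (list of `list(category =, exponent =,
#'   log10_norm =, noise_sd =, [slope_large =, break_x =])`), and optional
#'   `phyla` (`list(name =, fraction =)`), `tree_coupling`.
#' @param zero_policy,min_fit_n,n_bins Fit options.
#' @param threshold,min_segment Breakpoint model-selection options.
#' @param z_mode Z-statistic denominator mode.
#' @param n_perm Shuffle-null permutations (0 disables the null stage).
#' @param null_categories Categories for the null stage (default: all).
#' @param assoc_category Category whose per-phylum exponents feed the
#'   distance-divergence stage (default: first category).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotations = NULL, taxon_map = NULL,
                            trees = NULL, simulation = NULL,
                            zero_policy = "drop", min_fit_n = 3L,
                            n_bins = 20L, threshold = 0.05,
                            min_segment = NULL, z_mode = "as_printed",
                            n_perm = 0L, null_categories = NULL,
                            assoc_category = NULL,
                            seed = 1L, out_dir = ".") {
  real <- !is.null(annotations) || !is.null(taxon_map)
  sim <- !is.null(simulation)
  if (real && sim) {
    stop("configuration invalid: both real inputs and a simulation spec given")
  }
  if (!real && !sim) {
    stop("configuration invalid: neither real inputs nor a simulation spec given")
  }
  if (real && (is.null(annotations) || is.null(taxon_map))) {
    stop("real-input mode needs both `annotations` and `taxon_map` paths")
  }
  stopifnot(threshold > 0, threshold < 1, n_perm >= 0)
  structure(list(annotations = annotations, taxon_map = taxon_map,
                 trees = trees, simulation = simulation,
                 zero_policy = zero_policy, min_fit_n = as.integer(min_fit_n),
                 n_bins = as.integer(n_bins), threshold = threshold,
                 min_segment = min_segment, z_mode = z_mode,
                 n_perm = as.integer(n_perm),
                 null_categories = null_categories,
                 assoc_category = assoc_category,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the arguments of [pipeline_config()]; the `simulation`
#' block uses plain lists for laws and phyla (see [pipeline_config()]).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Build a simulation_spec from a plain-list config block
#' @noRd
simulation_from_config <- function(blk, seed) {
  if (inherits(blk, "simulation_spec")) {
    blk$seed <- seed
    return(list(spec = blk, tree_coupling = NULL))
  }
  laws <- list()
  for (l in blk$laws) {
    law <- scaling_law(l$exponent, l$log10_norm %||% 0, l$noise_sd %||% 0)
    if (!is.null(l$break_x)) {
      law <- breakpoint_law(law, l$slope_large, l$break_x)
    }
    laws[[l$category]] <- law
  }
  phyla <- NULL
  if (!is.null(blk$phyla)) {
    phyla <- lapply(blk$phyla, function(p)
      list(name = p$name, fraction = p$fraction,
           offsets = if (is.null(p$offsets)) numeric()
                     else unlist(p$offsets)))
    names(phyla) <- vapply(phyla, `[[`, character(1), "name")
  }
  spec <- simulation_spec(blk$n_organisms, unlist(blk$total_range), laws,
                          phyla = phyla, domain = blk$domain %||% "SimDomain",
                          seed = seed)
  list(spec = spec, tree_coupling = blk$tree_coupling)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full scaling analysis pipeline
#'
#' Orchestrates all stages end-to-end: input (parse or simulate), count
#' matrix, per-domain and per-phylum power-law fits, breakpoint model
#' selection, Z-score tables, breakpoint-span overlay, the shuffle null, and
#' patristic-distance versus exponent-divergence association; writes every
#' table as TSV plus a machine-readable run manifest (JSON) from which the
#' run is reproducible.
#'
#' @param config A [pipeline_config()] or the path to a YAML config file.
#' @return Invisibly, a list with the in-memory results (`matrix`,
#'   `domain_fits`, `phylum_fits`, `models`, `z`, `spans`, `null`, `phylo`,
#'   `manifest`) and the output paths in `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(simulate = stage_seed(config$seed, "simulate"),
                tree = stage_seed(config$seed, "tree"),
                null = stage_seed(config$seed, "null"))
  files <- list()
  truth <- NULL; trees <- list(); tree_mappings <- list()

  if (!is.null(config$simulation)) {
    sb <- simulation_from_config(config$simulation, seeds$simulate)
    spec <- sb$spec
    if (!is.null(sb$tree_coupling) && !is.null(spec$phyla) &&
        length(spec$phyla) >= 3L) {
      st <- simulate_tree(names(spec$phyla), coupling = sb$tree_coupling,
                          seed = seeds$tree)
      trees <- list(simulated = st$tree)
      tree_mappings <- list(simulated = data.frame(
        organism = names(st$offsets), phylum = names(st$offsets),
        stringsAsFactors = FALSE))
      # tree-driven offsets are applied on top of any configured offsets
      for (ph in names(spec$phyla)) {
        base <- spec$phyla[[ph]]$offsets %||% numeric()
        cats <- names(spec$laws)
        add <- stats::setNames(rep(st$offsets[[ph]], length(cats)), cats)
        for (cc in names(base)) add[cc] <- add[cc] + base[[cc]]
        spec$phyla[[ph]]$offsets <- add
      }
      ape::write.tree(st$tree, file.path(out_dir, "tree.nwk"))
      files$tree <- file.path(out_dir, "tree.nwk")
    }
    sim <- simulate_matrix(spec)
    mat <- sim$matrix
    truth <- sim$truth
    records <- if (config$n_perm > 0L) matrix_to_records(mat, compact = TRUE)
               else NULL
    taxon_map <- mat$taxon
    files$truth <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  } else {
    records <- parse_annotation_table(config$annotations)
    taxon_map <- utils::read.table(config$taxon_map, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
    mat <- build_count_matrix(records, taxon_map)
    for (tp in config$trees %||% character()) {
      trees[[basename(tp)]] <- ape::read.tree(tp)
      tree_mappings[[basename(tp)]] <- mat$taxon[, c("organism", "phylum")]
    }
  }

  files$matrix <- write_count_matrix(mat, file.path(out_dir, "count_matrix.tsv"))

  domain_fits <- fit_groups(mat, "domain", zero_policy = config$zero_policy,
                            min_n = config$min_fit_n)
  files$domain_fits <- write_tsv(domain_fits,
                                 file.path(out_dir, "fits_domain.tsv"))
  phylum_fits <- NULL
  has_phyla <- !all(is.na(mat$taxon$phylum))
  if (has_phyla) {
    phylum_fits <- fit_groups(mat, "phylum", zero_policy = config$zero_policy,
                              min_n = config$min_fit_n)
    files$phylum_fits <- write_tsv(phylum_fits,
                                   file.path(out_dir, "fits_phylum.tsv"))
  }

  models <- fit_scaling_models(mat, "domain", threshold = config$threshold,
                               min_segment = config$min_segment,
                               zero_policy = config$zero_policy,
                               min_n = max(config$min_fit_n, 6L))
  msum <- attr(models, "summary")
  if (!is.null(msum)) {
    files$models <- write_tsv(msum, file.path(out_dir, "scaling_models.tsv"))
  }

  ztab <- NULL; spans <- NULL
  if (has_phyla) {
    ztab <- z_table(phylum_fits, domain_fits, mode = config$z_mode)
    files$zscores <- write_tsv(ztab, file.path(out_dir, "zscores.tsv"))
    spans <- breakpoint_spans(mat, models)
    files$spans <- write_tsv(spans, file.path(out_dir, "breakpoint_spans.tsv"))
  }

  nulltab <- NULL
  if (config$n_perm > 0L && !is.null(records) && nrow(records) > 0L) {
    cats <- config$null_categories %||% colnames(mat$counts)
    results <- lapply(cats, function(cc)
      null_distribution(records, cc, taxon_map, n_perm = config$n_perm,
                        seed = stage_seed(seeds$null, cc),
                        zero_policy = config$zero_policy,
                        min_n = config$min_fit_n))
    nulltab <- null_summary(results)
    files$null <- write_tsv(nulltab, file.path(out_dir, "null_summary.tsv"))
  }

  phylo <- NULL
  if (length(trees) > 0L && has_phyla && !is.null(phylum_fits)) {
    acat <- config$assoc_category %||% colnames(mat$counts)[1L]
    sl <- phylum_fits[phylum_fits$category == acat, ]
    slopes <- stats::setNames(sl$slope, sl$group)
    rows <- list()
    for (tn in names(trees)) {
      dmat <- patristic_phylum_matrix(trees[[tn]], tree_mappings[[tn]])
      for (mode in c("abs_diff", "quotient")) {
        vmat <- tryCatch(exponent_divergence(slopes, mode), error = function(e) NULL)
        if (is.null(vmat)) next
        for (method in c("pearson", "spearman")) {
          as <- tryCatch(
            distance_divergence_association(dmat, vmat, method = method),
            error = function(e) NULL)
          if (is.null(as)) next
          rows[[length(rows) + 1L]] <- data.frame(
            tree = tn, category = acat, mode = mode, method = method,
            statistic = as$statistic, n_pairs = as$n_pairs,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) {
      phylo <- do.call(rbind, rows)
      files$phylo <- write_tsv(phylo, file.path(out_dir, "phylo_association.tsv"))
    }
  }

  manifest <- list(
    package = "cogscaling",
    package_version = as.character(utils::packageVersion("cogscaling")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stage_seeds = seeds,
    config = config[setdiff(names(config), "simulation")],
    simulated = !is.null(config$simulation),
    n_organisms = nrow(mat$counts), n_categories = ncol(mat$counts),
    outputs = lapply(files, basename))
  files$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")

  invisible(list(matrix = mat, truth = truth, domain_fits = domain_fits,
                 phylum_fits = phylum_fits, models = models, z = ztab,
                 spans = spans, null = nulltab, phylo = phylo,
                 manifest = manifest, files = files))
}
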