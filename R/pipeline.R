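# Orchestration: named stages driven by a plain-text (YAML or list)
# configuration, each writing its tabular outputs plus a JSON run record
# (inputs, parameters, seed, result files) sufficient to re-execute the
# run; stochastic stages are reproducible from the recorded seed.

stage_keys <- list(
  scan = c("backbones", "polyploid_taxa", "candidate_parents",
           "gene_trees", "leaf_maps", "delta_threshold", "dup_cost",
           "loss_cost", "max_events"),
  reconcile = c("gene_tree", "leaf_map", "network", "dup_cost", "loss_cost"),
  ancestral = c("tree", "traits", "model_class", "n_maps", "seed"),
  ploidy = c("karyotype", "copy_counts", "threshold"),
  mds = c("vcf", "max_missing", "min_maf", "axes", "groups", "seed"),
  simulate = c("what", "network", "n_families", "dup_rate", "loss_rate",
               "tree", "rate", "states", "n_groups", "n_per_group",
               "n_snps", "fst", "missing_rate", "seed")
)

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

# tab-separated leaf->species map: columns leaf_label, species
read_leaf_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("leaf_label", "species") %in% names(m)))
  stats::setNames(m$species, m$leaf_label)
}

read_gene_families <- function(tree_paths, map_paths, names = NULL) {
  tree_paths <- unlist(tree_paths)
  map_paths <- unlist(map_paths)
  if (is.null(names)) names <- sub("\\.[^.]*$", "", basename(tree_paths))
  lapply(seq_along(tree_paths), function(i) {
    gene_family(parse_newick(readLines(tree_paths[i], warn = FALSE)),
                read_leaf_map(map_paths[i]), gene_name = names[i])
  })
}

#' Run a pipeline stage from a configuration
#'
#' Dispatches one of the named stages (`scan`, `reconcile`, `ancestral`,
#' `ploidy`, `mds`, `simulate`) on a configuration given as a list or a
#' YAML file path, with `overrides` taking precedence over file values.
#' Outputs are written under `out_dir` together with a
#' `run_record.json` echoing the inputs, parameters and seed.  Unknown
#' configuration keys fail fast, by name.
#'
#' @param stage Stage name.
#' @param config A named list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param overrides Named list overriding config values.
#' @return The stage's main result object, invisibly; files on disk.
#' @export
run_pipeline <- function(stage, config = list(), out_dir = ".",
                         overrides = list()) {
  stage <- match.arg(stage, names(stage_keys))
  cfg <- utils::modifyList(read_config(config), overrides)
  unknown <- setdiff(names(cfg), stage_keys[[stage]])
  if (length(unknown))
    stop("unknown config key(s) for stage '", stage, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- switch(stage,
    scan = pipeline_scan(cfg, out_dir),
    reconcile = pipeline_reconcile(cfg, out_dir),
    ancestral = pipeline_ancestral(cfg, out_dir),
    ploidy = pipeline_ploidy(cfg, out_dir),
    mds = pipeline_mds(cfg, out_dir),
    simulate = pipeline_simulate(cfg, out_dir))
  record <- list(stage = stage, config = cfg,
                 seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("homeologr")),
                 outputs = result$files)
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(result$value)
}

need <- function(cfg, key) {
  if (is.null(cfg[[key]])) stop("config key '", key, "' is required",
                                call. = FALSE)
  cfg[[key]]
}

pipeline_scan <- function(cfg, out_dir) {
  backbones <- lapply(need(cfg, "backbones"), function(p)
    parse_newick(readLines(p, warn = FALSE)))
  fams <- read_gene_families(need(cfg, "gene_trees"), need(cfg, "leaf_maps"))
  poly <- readLines(need(cfg, "polyploid_taxa"), warn = FALSE)
  cand <- readLines(need(cfg, "candidate_parents"), warn = FALSE)
  costs <- recon_costs(cfg$dup_cost %||% 1, cfg$loss_cost %||% 1)
  rep <- run_scan(backbones, poly[nzchar(poly)], cand[nzchar(cand)], fams,
                  costs, delta_threshold = cfg$delta_threshold %||% 5,
                  max_events = cfg$max_events %||% 2L)
  f1 <- file.path(out_dir, "scan_ranking.csv")
  utils::write.csv(rep$ranking, f1, row.names = FALSE)
  f2 <- file.path(out_dir, "scan_best.json")
  jsonlite::write_json(list(preferred = rep$preferred,
                            min_score = rep$min_score,
                            best_per_events = rep$best_per_events),
                       f2, auto_unbox = TRUE, pretty = TRUE)
  best <- rep$hypotheses[[which(vapply(rep$hypotheses, function(h)
    h$label, character(1)) == rep$preferred)[1]]]
  f3 <- file.path(out_dir, "preferred_multree.nwk")
  writeLines(write_newick(best$mul$tree), f3)
  list(value = rep, files = c(f1, f2, f3))
}

pipeline_reconcile <- function(cfg, out_dir) {
  fam <- read_gene_families(need(cfg, "gene_tree"),
                            need(cfg, "leaf_map"))[[1]]
  net <- parse_enewick(readLines(need(cfg, "network"), warn = FALSE))
  mul <- network_to_multree(net)
  res <- mul_reconcile(fam, mul,
                       recon_costs(cfg$dup_cost %||% 1, cfg$loss_cost %||% 1))
  f1 <- file.path(out_dir, "reconciliation.csv")
  utils::write.csv(tidy(res), f1, row.names = FALSE)
  f2 <- file.path(out_dir, "reconciliation_events.json")
  jsonlite::write_json(list(gene = res$gene_name,
                            n_duplications = res$n_duplications,
                            n_losses = res$n_losses,
                            total_cost = res$total_cost,
                            assignment = as.list(res$assignment)),
                       f2, auto_unbox = TRUE, pretty = TRUE)
  list(value = res, files = c(f1, f2))
}

pipeline_ancestral <- function(cfg, out_dir) {
  tree <- parse_newick(readLines(need(cfg, "tree"), warn = FALSE))
  traits <- utils::read.csv(need(cfg, "traits"), stringsAsFactors = FALSE)
  fit <- fit_mk(tree, traits, model_class = cfg$model_class %||% "ER")
  maps <- stochastic_map(tree, fit$model, traits,
                         n_maps = cfg$n_maps %||% 10, seed = cfg$seed)
  sm <- summarize_maps(maps)
  f1 <- file.path(out_dir, "node_posteriors.csv")
  utils::write.csv(sm$node_freq, f1, row.names = FALSE)
  f2 <- file.path(out_dir, "change_counts.csv")
  utils::write.csv(sm$changes, f2, row.names = FALSE)
  list(value = sm, files = c(f1, f2))
}

pipeline_ploidy <- function(cfg, out_dir) {
  karyo <- if (!is.null(cfg$karyotype))
    utils::read.csv(cfg$karyotype, stringsAsFactors = FALSE) else NULL
  copies <- if (!is.null(cfg$copy_counts))
    utils::read.csv(cfg$copy_counts, stringsAsFactors = FALSE) else NULL
  res <- consensus_ploidy(karyo, copies, threshold = cfg$threshold %||% 0.5)
  f1 <- file.path(out_dir, "ploidy_calls.csv")
  utils::write.csv(res, f1, row.names = FALSE)
  list(value = res, files = f1)
}

pipeline_mds <- function(cfg, out_dir) {
  G <- read_vcf(need(cfg, "vcf"))
  Gf <- filter_variants(G, max_missing = cfg$max_missing %||% 0.10,
                        min_maf = cfg$min_maf %||% 0.01)
  D <- ibs_distance(Gf)
  mds <- classical_mds(D, k = cfg$axes %||% 2)
  files <- character(0)
  f <- file.path(out_dir, "filter_report.csv")
  utils::write.csv(attr(Gf, "filter_report"), f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "distance_matrix.csv")
  utils::write.csv(D, f)
  files <- c(files, f)
  f <- file.path(out_dir, "mds_coordinates.csv")
  coords <- mds$coordinates
  utils::write.csv(coords, f, row.names = FALSE)
  files <- c(files, f)
  value <- list(mds = mds)
  if (!is.null(cfg$groups)) {
    labs <- assign_groups(mds, cfg$groups, seed = cfg$seed)
    f <- file.path(out_dir, "group_labels.csv")
    utils::write.csv(labs, f, row.names = FALSE)
    files <- c(files, f)
    value$groups <- labs
  }
  list(value = value, files = files)
}

pipeline_simulate <- function(cfg, out_dir) {
  what <- match.arg(need(cfg, "what"), c("genefam", "trait", "genotypes"))
  if (what == "genefam") {
    net <- if (is.null(cfg$network)) toy_allopolyploid_network() else
      parse_enewick(readLines(cfg$network, warn = FALSE))
    fams <- simulate_gene_families(net, n_families = cfg$n_families %||% 4,
                                   dup_rate = cfg$dup_rate %||% 0.2,
                                   loss_rate = cfg$loss_rate %||% 0.2,
                                   seed = cfg$seed)
    files <- character(0)
    for (i in seq_along(fams)) {
      f1 <- file.path(out_dir, sprintf("fam%d.nwk", i))
      writeLines(write_newick(fams[[i]]$tree), f1)
      f2 <- file.path(out_dir, sprintf("fam%d.map.tsv", i))
      utils::write.table(
        data.frame(leaf_label = names(fams[[i]]$leaf_to_species),
                   species = unname(fams[[i]]$leaf_to_species)),
        f2, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, f1, f2)
    }
    return(list(value = fams, files = files))
  }
  if (what == "trait") {
    tree <- parse_newick(readLines(need(cfg, "tree"), warn = FALSE))
    model <- mk_model(cfg$states %||% c("0", "1"), rate = cfg$rate %||% 0.5)
    sim <- simulate_trait(tree, model, seed = cfg$seed)
    f1 <- file.path(out_dir, "traits.csv")
    utils::write.csv(sim$data, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "trait_truth.json")
    jsonlite::write_json(list(n_changes = sim$history$n_changes,
                              dwell = as.list(sim$history$dwell)),
                         f2, auto_unbox = TRUE, pretty = TRUE)
    return(list(value = sim, files = c(f1, f2)))
  }
  f1 <- file.path(out_dir, "genotypes.vcf")
  sim <- simulate_genotypes(n_groups = cfg$n_groups %||% 3,
                            n_per_group = cfg$n_per_group %||% 20,
                            n_snps = cfg$n_snps %||% 500,
                            fst = cfg$fst %||% 0.3,
                            missing_rate = cfg$missing_rate %||% 0,
                            vcf_path = f1, seed = cfg$seed)
  f2 <- file.path(out_dir, "group_truth.csv")
  utils::write.csv(sim$labels, f2, row.names = FALSE)
  list(value = sim, files = c(f1, f2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
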