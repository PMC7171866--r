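#' Configuration for an end-to-end pipeline run
#'
#' Collects the inputs (paths to a count table, Newick tree and metadata, or
#' a [simulation_config()] to generate them), preprocessing parameters,
#' null-model thresholds, metric choices and the master seed. Can be read
#' from / written to a flat YAML file.
#'
#' @param table,tree,metadata Input file paths (ignored when `simulation`
#'   is given).
#' @param simulation Optional [simulation_config()]; when present the run
#'   starts from a synthetic metacommunity instead of files.
#' @param rarefaction_depth Reads per sample for [rarefy()]; `NULL` skips
#'   rarefaction.
#' @param min_total_reads Taxon filter threshold for
#'   [filter_low_abundance()]; `NULL` skips filtering.
#' @param thresholds A [process_thresholds()].
#' @param gunifrac_alpha Moderation exponent for [gunifrac()].
#' @param tina_method Association estimator for [taxon_associations()].
#' @param class_width_km Distance-class width for the distance-decay
#'   correlogram.
#' @param sequential_threshold Abrupt-change threshold for
#'   [sequential_beta()].
#' @param signal_var Metadata variable for the phylogenetic-signal check.
#' @param permanova_terms Terms (order matters) for [permanova()]; `NULL`
#'   skips it.
#' @param env_vars,geo_vars Predictor sets for [variance_partition()];
#'   either `NULL` skips it.
#' @param n_perm Permutations for the spatial tests.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param out_dir Output directory; `NULL` disables file output.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(table = NULL, tree = NULL, metadata = NULL,
                            simulation = NULL, rarefaction_depth = NULL,
                            min_total_reads = NULL,
                            thresholds = process_thresholds(),
                            gunifrac_alpha = 0.5,
                            tina_method = "pearson",
                            class_width_km = 1000,
                            sequential_threshold = 0.8,
                            signal_var = "temperature",
                            permanova_terms = c("temperature", "province"),
                            env_vars = c("temperature"),
                            geo_vars = c("province"),
                            n_perm = 999, seed = 1, out_dir = NULL) {
  if (is.null(simulation) && (is.null(table) || is.null(tree) || is.null(metadata)))
    stop_ea("either a simulation config or all three input paths are required")
  structure(as.list(environment()), class = "pipeline_config")
}

# write a result tibble/matrix as TSV with a provenance header
write_stage <- function(obj, path, config_hash, seed) {
  header <- c(
    paste0("ecoassembly ", as.character(utils::packageVersion("ecoassembly"))),
    paste0("config_hash: ", config_hash),
    paste0("seed: ", seed)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  if (is.matrix(obj)) {
    df <- data.frame(id = rownames(obj), obj, check.names = FALSE)
  } else {
    df <- as.data.frame(obj)
  }
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Run the full community-assembly analysis pipeline
#'
#' Stage order mirrors the analysis workflow: preprocessing (rarefaction,
#' low-abundance filter, taxon classes), phylogenetic-signal check, process
#' quantification (beta-NTI + RC-bray + classification), beta-diversity and
#' interaction-adjusted matrices, then spatial statistics (PERMANOVA,
#' variance partitioning, distance-decay correlogram, LCBD, sequential
#' beta-diversity). Stage failures are isolated: a failing stage is
#' recorded in `$errors` and independent downstream stages still run.
#' Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with one element per completed
#'   stage (`table`, `taxon_classes`, `phylo_signal`, `processes`,
#'   `bray_curtis`, `gunifrac`, `tina`, `pina`, `permanova`, `varpart`,
#'   `distance_decay`, `lcbd`, `sequential`), plus `errors` and `warnings`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_ea("config must be a pipeline_config")
  seed <- as.integer(config$seed)
  res <- list(errors = list(), warnings = character())
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  config_hash <- rlang::hash(cfg_for_hash)

  # fail-fast configuration checks before any computation
  if (is.null(config$simulation)) {
    missing <- Filter(function(p) !file.exists(config[[p]]), c("table", "tree", "metadata"))
    if (length(missing) > 0)
      stop_ea(paste0("input file(s) not found: ",
                     paste(unlist(config[missing]), collapse = ", ")))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- simulate_metacommunity(config$simulation)
    x <- sim$counts; tree <- sim$tree; meta <- sim$metadata
    res$simulation <- sim
  } else {
    x <- read_otu_table(config$table)
    tree <- read_tree(config$tree)
    meta <- tibble::as_tibble(utils::read.table(config$metadata, header = TRUE,
                                                sep = "\t", comment.char = "#",
                                                stringsAsFactors = TRUE))
  }

  # --- preprocessing ------------------------------------------------------
  if (!is.null(config$rarefaction_depth)) {
    x <- withCallingHandlers(
      rarefy(x, depth = config$rarefaction_depth, seed = child_seed(seed, 1L)),
      warning = function(w) {
        res$warnings <<- c(res$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    meta <- meta[meta$sample_id %in% rownames(x), ]
  }
  if (!is.null(config$min_total_reads)) x <- filter_low_abundance(x, config$min_total_reads)
  x <- x[, colSums(x) > 0, drop = FALSE] # unobserved taxa carry no signal
  tree_p <- ape::keep.tip(tree, intersect(tree$tip.label, colnames(x)))
  res$table <- x
  res$taxon_classes <- stage("taxon_classes", classify_taxa(x))

  # --- phylogenetic signal ------------------------------------------------
  res$phylo_signal <- stage("phylo_signal",
    phylo_signal_correlogram(x, config$signal_var, tree_p, metadata = meta,
                             n_perm = config$n_perm, seed = child_seed(seed, 2L)))
  if (!is.null(res$phylo_signal)) {
    sig <- res$phylo_signal
    first_ok <- !is.na(sig$p_corrected[1]) && sig$p_corrected[1] < 0.05 && sig$mantel_r[1] > 0
    if (!first_ok) {
      res$warnings <- c(res$warnings,
        "no significant positive phylogenetic signal in the shortest distance class; interpret bNTI-based selection calls with caution")
    }
  }

  # --- process quantification --------------------------------------------
  res$processes <- stage("processes",
    quantify_assembly_processes(x, tree_p, thresholds = config$thresholds,
                                seed = child_seed(seed, 3L)))

  # --- beta diversity -----------------------------------------------------
  res$bray_curtis <- stage("bray_curtis", bray_curtis(x))
  res$gunifrac <- stage("gunifrac", gunifrac(x, tree_p, alpha = config$gunifrac_alpha))
  assoc <- stage("tina", taxon_associations(x, method = config$tina_method))
  res$tina <- if (!is.null(assoc)) stage("tina", tina(x, assoc)) else NULL
  res$pina <- stage("pina", pina(x, tree_p))

  # --- spatial statistics -------------------------------------------------
  d_geo <- stage("geography", haversine_distances(meta))
  if (!is.null(res$bray_curtis)) {
    if (!is.null(config$permanova_terms)) {
      res$permanova <- stage("permanova",
        permanova(res$bray_curtis, meta, config$permanova_terms,
                  n_perm = config$n_perm, seed = child_seed(seed, 4L)))
    }
    if (!is.null(config$env_vars) && !is.null(config$geo_vars)) {
      res$varpart <- stage("varpart",
        variance_partition(res$bray_curtis, meta, config$env_vars, config$geo_vars))
    }
    if (!is.null(d_geo)) {
      res$distance_decay <- stage("distance_decay",
        mantel_correlogram(d_geo, res$bray_curtis,
                           class_width_km = config$class_width_km,
                           n_perm = config$n_perm, seed = child_seed(seed, 5L)))
    }
    res$sequential <- stage("sequential",
      sequential_beta(res$bray_curtis, meta, threshold = config$sequential_threshold))
  }
  res$lcbd <- stage("lcbd", lcbd(x, n_perm = config$n_perm, seed = child_seed(seed, 6L)))

  # --- output bundle ------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(obj, file) {
      if (!is.null(obj)) write_stage(obj, file.path(config$out_dir, file), config_hash, seed)
    }
    w(res$taxon_classes, "taxon_classes.tsv")
    w(res$phylo_signal, "phylo_signal_correlogram.tsv")
    if (!is.null(res$processes)) {
      w(res$processes$calls, "process_calls.tsv")
      w(res$processes$summary, "process_summary.tsv")
    }
    w(if (!is.null(res$bray_curtis)) as.matrix(res$bray_curtis) else NULL, "bray_curtis.tsv")
    w(if (!is.null(res$gunifrac)) as.matrix(res$gunifrac) else NULL, "gunifrac.tsv")
    w(unclass(res$tina), "tina_similarity.tsv")
    w(unclass(res$pina), "pina_similarity.tsv")
    w(res$permanova, "permanova.tsv")
    w(res$varpart, "varpart.tsv")
    w(res$distance_decay, "distance_decay_correlogram.tsv")
    w(res$lcbd, "lcbd.tsv")
    w(res$sequential, "sequential_beta.tsv")
  }
  res$config_hash <- config_hash
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  done <- setdiff(names(x), c("errors", "warnings", "config_hash", "simulation"))
  done <- done[!vapply(x[done], is.null, logical(1))]
  cat("Pipeline run:", length(done), "stages completed\n")
  if (length(x$errors) > 0) {
    cat("Failed stages:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  if (!is.null(x$processes)) print(x$processes)
  invisible(x)
}

#' Read / write pipeline configuration as YAML
#'
#' Flat key-value serialization of a [pipeline_config()] (and nested
#' [simulation_config()] / [process_thresholds()]).
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$thresholds <- unclass(lst$thresholds)
  if (!is.null(lst$simulation)) lst$simulation <- unclass(lst$simulation)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$thresholds)) lst$thresholds <- do.call(process_thresholds, lst$thresholds)
  if (!is.null(lst$simulation)) {
    sim <- lst$simulation
    sim$env_range <- as.numeric(unlist(sim$env_range))
    lst$simulation <- do.call(simulation_config, sim)
  }
  lst <- lst[intersect(names(lst), names(formals(pipeline_config)))]
  do.call(pipeline_config, lst)
}
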