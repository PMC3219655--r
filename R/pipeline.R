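# End-to-end pipeline: simulate-or-load tables, build per-window networks,
# rank nodes, enumerate motifs, optionally test pathway enrichment, and
# write all artifacts plus a machine-readable run manifest.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full network-analysis pipeline
#'
#' Drives every stage from one configuration: obtain the five association
#' tables (either simulated via the synthetic generator or loaded from TSV
#' paths), build one network per requested promoter window, rank all nodes by
#' average stochastic-weight rank, enumerate self-loop and feedback-loop
#' motifs with a participation summary, and optionally run pathway
#' enrichment of loop target genes against the disease-gene background. All
#' outputs are TSV/JSON files under `out_dir`; `manifest.json` records
#' inputs, seeds, thresholds, row counts and the per-window census so a run
#' can be reproduced exactly.
#'
#' @param config a list (or path to a YAML/JSON file encoding one) with
#'   elements:
#'   * `out_dir` (required) output directory;
#'   * exactly one of `simulate` (list of [generator_config()] arguments) or
#'     `tables` (named list of five TSV paths: `mirna_targets`,
#'     `disease_genes`, `tf_hits`, `tcof_pairs`, `ppi_pairs`);
#'   * `windows` promoter windows to build, subset of 1000/5000 (default
#'     both);
#'   * `repetitions` ranking repetitions (default 10000) and `seed`
#'     (default 1);
#'   * `min_core`, `min_matrix` TFBS score thresholds (default 0.9);
#'   * optional `pathways`: path to a two-column TSV (`pathway_id`,
#'     `gene_id`) or a data.frame, enabling the enrichment stage.
#' @return Invisibly, a list with the run `manifest` and the vector of
#'   written `paths`.
#' @export
run_pipeline <- function(config) {
  config <- stage("config", load_pipeline_config(config))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  ledger <- NULL
  tables <- stage("input", {
    if (!is.null(config$simulate)) {
      gen <- generate_tables(do.call(generator_config, config$simulate))
      paths <- c(paths, write_generated(gen, file.path(out_dir, "inputs")))
      ledger <- gen$ledger
      gen$tables
    } else {
      lapply(setNames(nm = names(oc_schemas())), function(nm) {
        read_assoc_table(config$tables[[nm]], nm)
      })
    }
  })

  manifest <- list(
    package_version = as.character(packageVersion("ocmirnet")),
    seed = config$seed,
    repetitions = config$repetitions,
    windows = config$windows,
    min_core = config$min_core, min_matrix = config$min_matrix,
    inputs = if (!is.null(config$simulate)) {
      list(kind = "simulated", generator = config$simulate)
    } else {
      list(kind = "files", paths = config$tables)
    },
    table_rows = vapply(tables, nrow, 0L),
    census = list())

  for (w in config$windows) {
    tag <- paste0("NW", w)
    net <- stage("build", build_from_tables(
      list(tables = tables), promoter_window = w,
      min_core = config$min_core, min_matrix = config$min_matrix))
    np <- file.path(out_dir, paste0("nodes_", tag, ".tsv"))
    ep <- file.path(out_dir, paste0("edges_", tag, ".tsv"))
    write_network(net, np, ep)
    paths <- c(paths, setNames(c(np, ep), paste0(c("nodes_", "edges_"), tag)))

    cts <- census(net)
    manifest$census[[tag]] <- unclass(cts)
    cp <- file.path(out_dir, paste0("census_", tag, ".tsv"))
    write_tsv(as.data.frame(cts), cp)
    paths[paste0("census_", tag)] <- cp

    ranking <- stage("rank", rank_nodes(net, repetitions = config$repetitions,
                                        seed = config$seed))
    rp <- file.path(out_dir, paste0("ranking_", tag, ".tsv"))
    write_ranking(ranking, rp)
    paths[paste0("ranking_", tag)] <- rp

    loops <- stage("motifs", {
      sl <- find_self_loops(net)
      fl <- find_feedback_loops(net)
      sp <- file.path(out_dir, paste0("self_loops_", tag, ".tsv"))
      fp <- file.path(out_dir, paste0("feedback_loops_", tag, ".tsv"))
      write_loops(sl, sp)
      write_loops(fl, fp)
      paths[paste0("self_loops_", tag)] <- sp
      paths[paste0("feedback_loops_", tag)] <- fp
      pp <- file.path(out_dir, paste0("participation_", tag, ".json"))
      jsonlite::write_json(loop_participation(fl), pp, auto_unbox = TRUE)
      paths[paste0("participation_", tag)] <- pp
      fl
    })

    if (!is.null(config$pathways)) {
      stage("enrich", {
        pt <- config$pathways
        if (is.character(pt)) {
          pt <- read_assoc_table(pt, c(pathway_id = "character",
                                       gene_id = "character"))
        }
        background <- net$nodes$id[net$nodes$disease_associated]
        foreground <- unique(loops$target)
        res <- enrich_pathways(foreground, background, pt,
                               adjust = if (length(unique(pt$pathway_id)) > 1)
                                 "BH" else "none")
        epth <- file.path(out_dir, paste0("enrichment_", tag, ".tsv"))
        write_tsv(res, epth)
        paths[paste0("enrichment_", tag)] <- epth
      })
    }
  }

  if (!is.null(ledger)) manifest$ledger <- ledger
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths["manifest"] <- mp
  invisible(list(manifest = manifest, paths = paths))
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the 'yaml' package is required to read YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  if (is.null(config$out_dir)) stop("config requires out_dir")
  if (is.null(config$simulate) == is.null(config$tables)) {
    stop("config requires exactly one of 'simulate' or 'tables'")
  }
  if (!is.null(config$tables)) {
    missing <- setdiff(names(oc_schemas()), names(config$tables))
    if (length(missing)) stop("missing input table path: ", missing[1])
  }
  config$windows <- as.integer(config$windows %||% c(1000L, 5000L))
  if (!length(config$windows) ||
      !all(config$windows %in% c(1000L, 5000L))) {
    stop("windows must be a non-empty subset of {1000, 5000}")
  }
  config$repetitions <- as.integer(config$repetitions %||% 10000L)
  if (config$repetitions < 1L) stop("repetitions must be >= 1")
  config$seed <- as.integer(config$seed %||% 1L)
  config$min_core <- config$min_core %||% 0.9
  config$min_matrix <- config$min_matrix %||% 0.9
  config
}

`%||%` <- function(x, y) if (is.null(x)) y else x
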