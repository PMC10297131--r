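## Config-driven end-to-end pipeline: load -> preprocess -> graph ->
## (grid search) -> compare. Each stage writes a plain-text artifact into
## output_dir and can restart from the previous stage's artifact, so a run
## is resumable and byte-reproducible from its config alone.

`%||%` <- function(a, b) if (is.null(a)) b else a

PIPELINE_STAGES <- c("load", "preprocess", "graph", "gridsearch", "compare")

# per-stage seed: deterministic stage-name hash offset from the master seed
stage_seed <- function(master_seed, stage) {
  # double arithmetic avoids 32-bit overflow; result always fits an integer
  as.integer((as.numeric(master_seed) + sum(utf8ToInt(stage)) * 131) %%
               2147483647)
}

log_msg <- function(level, msg, logfile = NULL) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", sep = "", file = logfile, append = TRUE)
}

#' Assemble and validate a run configuration
#'
#' @param input list with exactly one of `synthetic` (a list of
#'   [synthetic_spec()] arguments), `uci_path`, or `csv_path`.
#' @param preprocess list of [preprocess_config()] arguments.
#' @param graph list with `k`, `metric`, `epsilon`, `use_weights`, `scheme`.
#' @param models per-family architecture lists (see [build_model()]).
#' @param train list of [train_config()] arguments.
#' @param grid optional named candidate lists for [grid_search()]; the
#'   searched family is `grid$family` (default `"fusion"`).
#' @param output_dir artifact directory (created if absent).
#' @param master_seed integer; every stage seed derives from it.
#' @return validated list of class `ckd_run_config`.
#' @export
run_config <- function(input, preprocess = list(), graph = list(),
                       models = list(), train = list(), grid = NULL,
                       output_dir = "ckd_run", master_seed = 1L) {
  sources <- intersect(names(input), c("synthetic", "uci_path", "csv_path"))
  if (length(sources) != 1L)
    stop("config must name exactly one input source (synthetic, uci_path, ",
         "or csv_path); got: ", paste(sources, collapse = ", "))
  if (!is.null(grid) && is.null(grid$family)) grid$family <- "fusion"
  structure(list(input = input, preprocess = preprocess, graph = graph,
                 models = models, train = train, grid = grid,
                 output_dir = output_dir,
                 master_seed = as.integer(master_seed)),
            class = "ckd_run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON file mirroring the [run_config()] fields.
#' @return a `ckd_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

art <- function(config, name) file.path(config$output_dir, name)

#' Load the input dataset (pipeline stage 1)
#' @param config a `ckd_run_config`.
#' @return a [ckd_dataset()]; also written to `output_dir/raw.csv`.
#' @export
pipeline_load <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- config$input
  ds <- if (!is.null(inp$synthetic)) {
    args <- inp$synthetic
    args$seed <- args$seed %||% stage_seed(config$master_seed, "load")
    generate_synthetic(do.call(synthetic_spec, args))
  } else if (!is.null(inp$uci_path)) {
    read_ckd_file(inp$uci_path, provenance = "uci")
  } else {
    read_ckd_file(inp$csv_path, dialect = "csv", provenance = "csv")
  }
  write_ckd_csv(ds, art(config, "raw.csv"))
  ds
}

#' Preprocess (pipeline stage 2)
#' @param config a `ckd_run_config`.
#' @param ds dataset; reloaded from `raw.csv` when NULL.
#' @return the [run_preprocess()] result; written to `processed.csv`.
#' @export
pipeline_preprocess <- function(config, ds = NULL) {
  if (is.null(ds))
    ds <- read_ckd_file(art(config, "raw.csv"), dialect = "csv")
  pargs <- config$preprocess
  pargs$seed <- pargs$seed %||% stage_seed(config$master_seed, "preprocess")
  prep <- run_preprocess(ds, do.call(preprocess_config, pargs))
  df <- as.data.frame(prep$X)
  df$class <- prep$y
  df$role <- as.character(prep$roles)
  df$synthetic <- as.integer(prep$synthetic)
  utils::write.csv(df, art(config, "processed.csv"), row.names = FALSE)
  prep
}

read_processed <- function(config) {
  df <- utils::read.csv(art(config, "processed.csv"), check.names = FALSE)
  list(X = as.matrix(df[, setdiff(names(df), c("class", "role", "synthetic"))]),
       y = as.integer(df$class),
       roles = factor(df$role, levels = c("train", "val", "test")),
       synthetic = as.logical(df$synthetic))
}

#' Build and normalize the patient graph (pipeline stage 3)
#' @param config a `ckd_run_config`.
#' @param prep preprocessed data; reloaded from `processed.csv` when NULL.
#' @return list with `graph` and `adjacency`; graph written to `graph.txt`.
#' @export
pipeline_graph <- function(config, prep = NULL) {
  if (is.null(prep)) prep <- read_processed(config)
  go <- config$graph
  g <- build_knn_graph(prep$X, k = go$k %||% 5L,
                       metric = go$metric %||% "euclidean",
                       epsilon = go$epsilon %||% 1e-8)
  write_graph(g, art(config, "graph.txt"))
  adj <- normalize_adjacency(g, scheme = go$scheme %||% "sym",
                             use_weights = !isFALSE(go$use_weights))
  list(graph = g, adjacency = adj)
}

pipeline_train_config <- function(config) {
  targs <- config$train
  targs$seed <- targs$seed %||% stage_seed(config$master_seed, "compare")
  do.call(train_config, targs)
}

#' Grid search (pipeline stage 4, optional)
#' @param config a `ckd_run_config` with a non-null `grid`.
#' @param prep,adjacency stage inputs; reloaded/rebuilt when NULL.
#' @return the [grid_search()] result; summary written to `gridsearch.json`.
#' @export
pipeline_gridsearch <- function(config, prep = NULL, adjacency = NULL) {
  if (is.null(config$grid)) return(NULL)
  if (is.null(prep)) prep <- read_processed(config)
  if (is.null(adjacency)) adjacency <- pipeline_graph(config, prep)$adjacency
  grid <- config$grid
  family <- grid$family %||% "fusion"
  grid$family <- NULL
  tc <- pipeline_train_config(config)
  tc$seed <- stage_seed(config$master_seed, "gridsearch")
  gs <- grid_search(family, prep$X, prep$y, prep$roles, adjacency,
                    grid = grid, base_train = tc,
                    base_arch = config$models[[family]] %||% list())
  jsonlite::write_json(
    list(family = family, best_config = gs$best_config,
         leaderboard = gs$leaderboard, selection_metric = gs$selection_metric),
    art(config, "gridsearch.json"), auto_unbox = TRUE, digits = NA)
  gs
}

#' Train the four families and write the comparison artifacts (stage 5)
#' @param config a `ckd_run_config`.
#' @param prep,adjacency,gs stage inputs; recomputed when NULL.
#' @return the [compare_models()] result.
#' @export
pipeline_compare <- function(config, prep = NULL, adjacency = NULL, gs = NULL) {
  if (is.null(prep)) prep <- read_processed(config)
  if (is.null(adjacency)) adjacency <- pipeline_graph(config, prep)$adjacency
  tc <- pipeline_train_config(config)
  arch <- config$models %||% list()
  if (!is.null(gs)) {
    fam <- config$grid$family %||% "fusion"
    best <- gs$best_config
    for (nm in intersect(names(best), TRAIN_FIELDS)) tc[[nm]] <- best[[nm]]
    a <- arch[[fam]] %||% list()
    for (nm in intersect(names(best), ARCH_FIELDS)) a[[nm]] <- best[[nm]]
    arch[[fam]] <- a
  }
  cmp <- compare_models(prep$X, prep$y, prep$roles, adjacency,
                        train = tc, arch = arch)
  utils::write.csv(cmp$table, art(config, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(cmp$metrics, function(m) unclass(m)),
    art(config, "metrics.json"), auto_unbox = TRUE, digits = NA)
  for (fam in names(cmp$histories)) {
    utils::write.csv(cmp$histories[[fam]],
                     art(config, paste0("history_", fam, ".csv")),
                     row.names = FALSE)
    save_checkpoint(cmp$models[[fam]],
                    art(config, paste0("checkpoint_", fam, ".json")))
  }
  cmp
}

#' Run the whole pipeline from a configuration
#'
#' Executes load, preprocess, graph construction, optional grid search,
#' and the four-model comparison, writing every artifact plus a run
#' manifest into `output_dir`. Reruns with the same config produce
#' byte-identical metric files.
#'
#' @param config a `ckd_run_config` or path to a JSON config file.
#' @return invisibly, the [compare_models()] result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "ckd_run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- art(config, "run.log")
  stage <- "load"
  result <- tryCatch({
    log_msg("INFO", "stage load", logfile)
    ds <- pipeline_load(config)
    stage <- "preprocess"
    log_msg("INFO", "stage preprocess", logfile)
    prep <- pipeline_preprocess(config, ds)
    stage <- "graph"
    log_msg("INFO", "stage graph", logfile)
    gr <- pipeline_graph(config, prep)
    gs <- NULL
    if (!is.null(config$grid)) {
      stage <- "gridsearch"
      log_msg("INFO", "stage gridsearch", logfile)
      gs <- pipeline_gridsearch(config, prep, gr$adjacency)
    }
    stage <- "compare"
    log_msg("INFO", "stage compare", logfile)
    cmp <- pipeline_compare(config, prep, gr$adjacency, gs)
    for (fam in cmp$table$model)
      log_msg("INFO", sprintf("%s test accuracy %.4f f1 %.4f", fam,
                              cmp$table$accuracy[cmp$table$model == fam],
                              cmp$table$f1[cmp$table$model == fam]), logfile)
    cmp
  }, error = function(e) {
    rec <- list(stage = stage, error = conditionMessage(e))
    jsonlite::write_json(rec, art(config, "error.json"), auto_unbox = TRUE)
    log_msg("ERROR", sprintf("stage %s failed: %s", stage, rec$error), logfile)
    stop("pipeline stage '", stage, "' failed: ", rec$error, call. = FALSE)
  })
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("ckdfusion")),
    r_version = R.version.string,
    stage_seeds = stats::setNames(
      lapply(PIPELINE_STAGES, function(s) stage_seed(config$master_seed, s)),
      PIPELINE_STAGES))
  jsonlite::write_json(manifest, art(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}
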