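# End-to-end pipeline: descriptors -> screening -> BBB prediction ->
# statistics -> report files. Reports are deterministic for a given config
# and seed; wall-clock data goes only to messages, never into reports.

#' Pipeline configuration
#'
#' @param input Path to a descriptor CSV, or `NULL` when `fixture` is used.
#' @param fixture `"table1"` to run on the embedded reference agent table.
#' @param criteria Criteria set names to screen with, from `"cns_a"`,
#'   `"cns_b"`, `"ro5"`.
#' @param summary,correlations,bbb,grubbs_fields,cluster Statistics toggles:
#'   `grubbs_fields` is a character vector of fields to outlier-test
#'   (`character(0)` disables), `cluster` one of `"standardized"`, `"raw"`,
#'   `"off"`.
#' @param regress `NULL` or `list(response =, predictors =)`.
#' @param seed RNG seed (required by stochastic stages).
#' @param out_dir Output directory (created if missing).
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, fixture = NULL,
                       criteria = c("cns_a", "cns_b", "ro5"),
                       summary = TRUE, correlations = TRUE, bbb = TRUE,
                       grubbs_fields = c("log_p", "fw", "volume"),
                       regress = list(response = "fw",
                                      predictors = c("log_p", "psa", "n_atoms", "n_rot")),
                       cluster = "standardized",
                       seed = 1L, out_dir = "nitroscreen-out") {
  cfg <- list(input = input, fixture = fixture, criteria = criteria,
              summary = summary, correlations = correlations, bbb = bbb,
              grubbs_fields = grubbs_fields, regress = regress,
              cluster = cluster, seed = seed, out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (is.null(cfg$input) && is.null(cfg$fixture))
    stop(errorCondition("config needs either 'input' or 'fixture'",
                        class = c("nitroscreen_config_error", "error")))
  if (!is.null(cfg$fixture) && !identical(cfg$fixture, "table1"))
    stop(errorCondition(paste0("unknown fixture: ", cfg$fixture),
                        class = c("nitroscreen_config_error", "error")))
  bad <- setdiff(cfg$criteria, c("cns_a", "cns_b", "ro5"))
  if (length(bad))
    stop(errorCondition(paste0("unknown criteria set(s): ", paste(bad, collapse = ", ")),
                        class = c("nitroscreen_config_error", "error")))
  if (!cfg$cluster %in% c("standardized", "raw", "off"))
    stop(errorCondition("cluster must be 'standardized', 'raw' or 'off'",
                        class = c("nitroscreen_config_error", "error")))
  invisible(cfg)
}

#' Load a pipeline config from JSON or YAML
#'
#' File keys mirror the [run_config()] arguments.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("config file not found: ", path),
                        class = c("nitroscreen_config_error", "error")))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop(errorCondition("the 'yaml' package is required for YAML configs",
                          class = c("nitroscreen_config_error", "error")))
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$regress)) raw$regress <- as.list(raw$regress)
  do.call(run_config, raw)
}

#' Run the screening pipeline
#'
#' Loads the input table (or the embedded reference fixture), screens it
#' against the configured criteria sets, predicts brain/blood partitioning,
#' runs the configured statistics, and writes one report file per stage into
#' `out_dir` (`screening.csv`, `bbb.csv`, `summary.csv`, `correlations.csv`,
#' `grubbs.json`, `regression.json`, `dendrogram.nwk`, `cluster_merges.csv`).
#' Decisions such as dropped zero-variance columns are reported as messages.
#'
#' @param cfg A [run_config()] (or a list of its arguments).
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @examples
#' \donttest{
#' out <- run_pipeline(run_config(fixture = "table1", out_dir = tempfile()))
#' }
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, as.list(cfg))
  tab <- if (!is.null(cfg$fixture)) builtin_table1() else {
    if (!file.exists(cfg$input))
      stop(errorCondition(paste0("input file not found: ", cfg$input),
                          class = c("nitroscreen_data_error", "error")))
    read_descriptor_csv(cfg$input)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  results <- list(table = tab)
  emit <- function(name) {
    paths[[length(paths) + 1]] <<- file.path(cfg$out_dir, name)
    file.path(cfg$out_dir, name)
  }

  sets <- list()
  if ("cns_a" %in% cfg$criteria) sets <- c(sets, list(cns_a()))
  if ("cns_b" %in% cfg$criteria) sets <- c(sets, list(cns_b()))
  if (length(sets) || "ro5" %in% cfg$criteria) {
    ro5_max <- if ("ro5" %in% cfg$criteria) 0L else 4L
    scr <- screen_library(tab, sets = sets, ro5_max = ro5_max)
    results$screening <- scr
    write_report(scr$results, emit("screening.csv"), "csv")
  }
  if (isTRUE(cfg$bbb)) {
    preds <- bbb_table(tab)
    results$bbb <- preds
    results$bbb_summary <- bbb_summary(preds)
    out <- preds
    out$log_bb <- round_out(out$log_bb, 3)
    out$bb <- round_out(out$bb, 3)
    write_report(out, emit("bbb.csv"), "csv")
  }
  if (isTRUE(cfg$summary)) {
    results$summary <- summarize_properties(tab)
    write_report(results$summary, emit("summary.csv"), "csv")
  }
  if (isTRUE(cfg$correlations)) {
    cm <- pearson_matrix(tab)
    results$correlations <- cm
    df <- data.frame(property = rownames(cm), as.data.frame(cm), check.names = FALSE)
    write_report(df, emit("correlations.csv"), "csv")
  }
  if (length(cfg$grubbs_fields)) {
    gr <- lapply(cfg$grubbs_fields, function(f) {
      if (is.null(tab[[f]])) stop(errorCondition(
        paste0("grubbs field not in table: ", f),
        class = c("nitroscreen_data_error", "error")))
      g <- grubbs_test(tab[[f]], alpha = 0.05)
      list(field = f, g_statistic = g$g_statistic, g_critical = g$g_critical,
           alpha = g$alpha, outlier = g$outlier_flag)
    })
    results$grubbs <- gr
    jsonlite::write_json(gr, emit("grubbs.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(cfg$regress)) {
    fit <- ols_fit(tab, cfg$regress$response, cfg$regress$predictors)
    results$regression <- fit
    jsonlite::write_json(list(response = cfg$regress$response,
                              intercept = fit$intercept,
                              coefficients = as.list(fit$coefficients),
                              r_squared = fit$r_squared, n = fit$n),
                         emit("regression.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (cfg$cluster != "off") {
    ct <- cluster_tree(tab, standardize = cfg$cluster == "standardized")
    results$cluster <- ct
    writeLines(as_newick(ct), emit("dendrogram.nwk"))
    write_report(merge_table(ct), emit("cluster_merges.csv"), "csv")
  }
  invisible(list(results = results, paths = unlist(paths), config = cfg))
}
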