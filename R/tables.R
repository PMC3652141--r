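#' Descriptor tables
#'
#' A descriptor table is the pipeline's central exchange object: one row per
#' agent, with the nine molecular-property columns of the reference agent set
#' (`log_p`, `psa`, `n_atoms`, `fw`, `n_on`, `n_ohnh`, `n_ro5_violations`,
#' `n_rot`, and optionally `volume`), plus a character `agent_id`. A
#' `provenance` attribute records whether the values are the embedded fixture,
#' computed from structures, or synthetic.
#'
#' @param df Data frame holding `agent_id` and the descriptor columns.
#' @param provenance One of `"fixture"`, `"computed"`, `"synthetic"`.
#' @return A `descriptor_table` (a validated data frame).
#' @export
descriptor_table <- function(df, provenance = c("computed", "fixture", "synthetic")) {
  provenance <- match.arg(provenance)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$agent_id)) df$agent_id <- as.character(seq_len(nrow(df)))
  df$agent_id <- as.character(df$agent_id)
  validate_descriptor_table(df)
  attr(df, "provenance") <- provenance
  class(df) <- c("descriptor_table", "data.frame")
  df
}

required_descriptor_cols <- function() {
  c("log_p", "psa", "n_atoms", "fw", "n_on", "n_ohnh", "n_rot")
}

validate_descriptor_table <- function(df) {
  req <- required_descriptor_cols()
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop_format("descriptor table is missing required column(s): ",
                paste(missing, collapse = ", "))
  if (anyDuplicated(df$agent_id))
    stop_format("agent_id values must be unique")
  if (nrow(df)) {
    num <- intersect(c(req, "n_ro5_violations", "volume"), names(df))
    for (col in num) {
      if (!is.numeric(df[[col]]))
        stop_format("column '", col, "' is not numeric")
      if (anyNA(df[[col]]))
        stop_format("column '", col, "' contains missing values")
    }
    if (any(df$fw <= 0)) stop_format("fw must be positive")
    if (any(df$psa < 0)) stop_format("psa must be non-negative")
    for (col in intersect(c("n_atoms", "n_on", "n_ohnh", "n_rot"), names(df)))
      if (!is_count_col(df[[col]]))
        stop_format("column '", col, "' must hold non-negative integers")
    if ("n_ro5_violations" %in% names(df) &&
        !all(df$n_ro5_violations %in% 0:4))
      stop_format("n_ro5_violations must be in 0..4")
  }
  invisible(df)
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", nrow(x), " agents, provenance: ",
      attr(x, "provenance") %||% "unknown", "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Reference agent set: molecular properties of the 18 nitrosourea agents
#'
#' The embedded fixture holding the nine tabulated molecular properties of
#' lomustine (agent 1) and its 17 proposed analogs. These tabulated values
#' (from a proprietary property calculator) are the canonical input for all
#' statistics reproduction; descriptors recomputed from structures are a
#' parallel path with documented tolerances and are never substituted silently.
#'
#' @return A `descriptor_table` with 18 rows, `agent_id` `"1"`..`"18"` and
#'   provenance `"fixture"`.
#' @examples
#' t1 <- builtin_table1()
#' t1[t1$agent_id == "1", ]
#' @export
builtin_table1 <- function() {
  df <- data.frame(
    agent_id = as.character(1:18),
    log_p = c(2.965, 2.188, 2.268, 2.034, 2.457, 2.583, 1.975, 2.276, 2.429,
              2.359, 2.476, 1.537, 3.184, 2.498, 2.635, 3.924, 3.182, 2.459),
    psa = c(61.772, 61.771, 61.771, 61.771, 61.771, 61.771, 61.771, 61.771,
            61.771, 61.771, 61.771, 81.999, 61.771, 61.771, 61.771, 61.771,
            61.771, 61.771),
    n_atoms = c(15L, 12L, 13L, 13L, 13L, 16L, 13L, 16L, 14L, 14L, 16L, 15L,
                16L, 13L, 15L, 17L, 16L, 14L),
    fw = c(233.7, 191.6, 207.7, 205.6, 203.6, 268.1, 205.6, 251.7, 217.7,
           219.7, 267.8, 237.7, 312.6, 207.7, 231.7, 261.7, 245.7, 219.7),
    n_on = c(5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 6L, 5L, 5L, 5L, 5L,
             5L, 5L),
    n_ohnh = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L,
               1L, 1L, 1L),
    n_ro5_violations = rep(0L, 18),
    n_rot = c(4L, 4L, 5L, 5L, 5L, 4L, 6L, 4L, 5L, 5L, 8L, 6L, 4L, 6L, 6L, 8L,
              6L, 4L),
    volume = c(208.8, 163.1, 185.5, 179.9, 174.2, 222.3, 180.1, 213.7, 190.5,
               196.1, 236.9, 210.4, 226.7, 185.7, 206.9, 246.5, 223.5, 191.9),
    stringsAsFactors = FALSE)
  descriptor_table(df, provenance = "fixture")
}

#' Reference brain/blood partition values for the 18 agents
#'
#' The tabulated Log BB and BB (= C_brain/C_blood) values printed for the
#' reference agent set. Note the BB column of the source table was derived
#' from the *rounded* Log BB values, so recomputation from the descriptors at
#' full precision agrees within one unit in the third decimal rather than
#' exactly; see the package vignette.
#'
#' @return Data frame with columns `agent_id`, `log_bb`, `bb`.
#' @export
builtin_table3 <- function() {
  data.frame(
    agent_id = c("1, lomustine", as.character(2:18)),
    log_bb = c(-0.325, -0.443, -0.430, -0.466, -0.402, -0.383, -0.475, -0.429,
               -0.406, -0.416, -0.399, -0.841, -0.291, -0.396, -0.375, -0.179,
               -0.292, -0.401),
    bb = c(0.473, 0.361, 0.372, 0.342, 0.396, 0.414, 0.335, 0.372, 0.393,
           0.383, 0.399, 0.144, 0.512, 0.402, 0.422, 0.662, 0.511, 0.397),
    stringsAsFactors = FALSE)
}

# header aliases: normalized header string -> canonical column name
descriptor_aliases <- function() {
  c(agentid = "agent_id", drug = "agent_id", agent = "agent_id", id = "agent_id",
    logp = "log_p",
    polarsurfacearea = "psa", polarsurfaceareaangstroms2 = "psa",
    polarsurfaceareaa2 = "psa", psa = "psa", tpsa = "psa",
    numberofatoms = "n_atoms", natoms = "n_atoms", atoms = "n_atoms",
    molecularweight = "fw", formulaweight = "fw", fw = "fw", mw = "fw",
    numberofon = "n_on", numberofoandn = "n_on", non = "n_on", hba = "n_on",
    numberofohandnhn = "n_ohnh", nohnh = "n_ohnh", hbd = "n_ohnh",
    violationsofruleof5 = "n_ro5_violations", nro5violations = "n_ro5_violations",
    ro5violations = "n_ro5_violations", ro5 = "n_ro5_violations",
    numberofrotatablebonds = "n_rot", nrot = "n_rot", rotatablebonds = "n_rot",
    volume = "volume", molecularvolume = "volume", volumeangstroms3 = "volume",
    volumea3 = "volume", smiles = "smiles")
}

normalize_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a descriptor table from CSV
#'
#' Comma-separated, UTF-8, `.` decimal separator, header row required.
#' Case-insensitive header aliases are accepted (e.g. "Molecular weight" for
#' `fw`, "Number of O & N" for `n_on`). Row order is preserved. A missing
#' `n_ro5_violations` column is filled from [rule_of_five_violations()];
#' `volume` may be absent table-wide.
#'
#' @param path Path to a CSV file.
#' @return A `descriptor_table` with provenance `"computed"`.
#' @export
read_descriptor_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  aliases <- descriptor_aliases()
  canon <- aliases[normalize_header(names(raw))]
  known <- !is.na(canon)
  raw <- raw[, known, drop = FALSE]
  names(raw) <- canon[known]
  missing <- setdiff(required_descriptor_cols(), names(raw))
  if (length(missing))
    stop_format("CSV is missing required column(s): ",
                paste(missing, collapse = ", "))
  numeric_cols <- setdiff(names(raw), c("agent_id", "smiles"))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]])))
    if (anyNA(vals)) {
      row <- if (length(bad)) bad[1] else which(is.na(vals))[1]
      stop_format("non-numeric value in column '", col, "' at data row ", row,
                  ": '", raw[[col]][row], "'")
    }
    raw[[col]] <- vals
  }
  if (nrow(raw) && !"n_ro5_violations" %in% names(raw))
    raw$n_ro5_violations <- rule_of_five_violations(raw)
  if (!nrow(raw)) {
    for (col in setdiff(c(required_descriptor_cols(), "n_ro5_violations"), names(raw)))
      raw[[col]] <- numeric(0)
  }
  descriptor_table(raw, provenance = "computed")
}

#' Write a screening / prediction report
#'
#' Serializes a non-empty result data frame with a deterministic column order
#' and at least six significant digits for floating-point columns.
#'
#' @param results Data frame (e.g. from [screen_library()] or [bbb_table()]).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (nrow(results) == 0L)
    stop_input("refusing to write an empty report")
  results <- results[, order(match(names(results),
                                   c("agent_id", sort(setdiff(names(results), "agent_id"))))),
                     drop = FALSE]
  ok <- tryCatch({
    if (format == "csv") {
      con <- file(path, open = "w", encoding = "UTF-8")
      on.exit(close(con), add = TRUE)
      fmt <- results
      for (col in names(fmt))
        if (is.double(fmt[[col]])) fmt[[col]] <- formatC(fmt[[col]], digits = 8, format = "g")
      utils::write.csv(fmt, con, row.names = FALSE, quote = TRUE)
    } else {
      jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                           auto_unbox = FALSE, pretty = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_input("could not write report to '", path, "': ",
                              conditionMessage(ok))
  invisible(path)
}
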