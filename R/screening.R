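# Drug-likeness screening: Lipinski's Rule of 5 and the two published
# CNS-penetration criteria sets, applied to descriptor tables.

#' Criteria sets
#'
#' A criteria set is data, not code: a named list of bounds
#' `(field, comparator, threshold)` that a descriptor record must satisfy
#' jointly. Comparators are `"<="`, `"<"`, `">="`, `">"`.
#'
#' `cns_a()` is the four-rule CNS-penetration set (formula weight at most 400,
#' Log P at most 5, at most 3 H-bond donors, at most 7 H-bond acceptors);
#' `cns_b()` is the two-rule set (polar surface area at most 90 squared
#' Angstroms, formula weight at most 450).
#'
#' @param name Display name of the set.
#' @param field Character vector of descriptor fields.
#' @param op Comparator per field.
#' @param value Threshold per field.
#' @return A `criteria_set` object.
#' @export
criteria_set <- function(name, field, op, value) {
  stopifnot(length(field) == length(op), length(op) == length(value))
  if (!all(op %in% c("<=", "<", ">=", ">")))
    stop_input("comparators must be one of <=, <, >=, >")
  if (!all(is.finite(value))) stop_input("thresholds must be finite")
  structure(list(name = name,
                 bounds = data.frame(field = field, op = op, value = value,
                                     stringsAsFactors = FALSE)),
            class = "criteria_set")
}

#' @rdname criteria_set
#' @export
cns_a <- function() {
  criteria_set("CNS-A",
               field = c("fw", "log_p", "n_ohnh", "n_on"),
               op = rep("<=", 4),
               value = c(400, 5, 3, 7))
}

#' @rdname criteria_set
#' @export
cns_b <- function() {
  criteria_set("CNS-B",
               field = c("psa", "fw"),
               op = c("<=", "<="),
               value = c(90, 450))
}

#' Load criteria sets from a JSON or YAML config
#'
#' The config maps set names to lists of `{field, op, value}` objects.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return Named list of `criteria_set` objects.
#' @export
read_criteria_config <- function(path) {
  if (!file.exists(path)) stop_input("criteria config not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_input("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  out <- lapply(names(cfg), function(nm) {
    b <- as.data.frame(cfg[[nm]], stringsAsFactors = FALSE)
    criteria_set(nm, b$field, b$op, as.numeric(b$value))
  })
  names(out) <- names(cfg)
  out
}

#' Rule-of-5 violation count
#'
#' Counts violations of the four oral drug-likeness rules: more than 5 H-bond
#' donors, more than 10 H-bond acceptors, molecular mass not less than 500
#' daltons, Log P greater than 5. A compound is conventionally drug-like with
#' at most one violation.
#'
#' @param r A descriptor record / table (any data frame with `log_p`, `fw`,
#'   `n_on`, `n_ohnh` columns).
#' @return Integer vector of violation counts (0-4), one per row.
#' @examples
#' rule_of_five_violations(builtin_table1())
#' @export
rule_of_five_violations <- function(r) {
  for (col in c("log_p", "fw", "n_on", "n_ohnh"))
    if (is.null(r[[col]]))
      stop_input("rule_of_five_violations: missing field '", col, "'")
  as.integer((r$n_ohnh > 5) + (r$n_on > 10) + (r$fw >= 500) + (r$log_p > 5))
}

apply_bound <- function(x, op, value) {
  switch(op,
         "<=" = x <= value, "<" = x < value,
         ">=" = x >= value, ">" = x > value)
}

#' Screen one record against a criteria set
#'
#' @param r A one-row descriptor record (data frame).
#' @param criteria A [criteria_set()].
#' @return A `screen_result`: per-criterion verdicts and their conjunction.
#' @examples
#' cns_pass(builtin_table1()[13, ], cns_a())
#' @export
cns_pass <- function(r, criteria) {
  stopifnot(inherits(criteria, "criteria_set"))
  r <- as.data.frame(r)
  if (nrow(r) != 1L) stop_input("cns_pass expects a single record")
  b <- criteria$bounds
  verdicts <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    f <- b$field[i]
    if (is.null(r[[f]])) stop_input("record lacks field '", f, "' required by ",
                                    criteria$name)
    verdicts[i] <- apply_bound(r[[f]], b$op[i], b$value[i])
  }
  names(verdicts) <- paste0(b$field, b$op, b$value)
  structure(list(agent_id = r$agent_id %||% NA_character_,
                 criteria = criteria$name,
                 verdicts = verdicts,
                 overall_pass = all(verdicts)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", x$agent_id, " vs ", x$criteria, ": ",
      if (x$overall_pass) "PASS" else "FAIL", "\n", sep = "")
  print(x$verdicts)
  invisible(x)
}

#' Screen a descriptor table against criteria sets
#'
#' Applies each criteria set to every record and additionally reports Rule-of-5
#' violation counts. `overall_pass` requires every criteria set to pass and at
#' most `ro5_max` Rule-of-5 violations.
#'
#' @param t A `descriptor_table` (or compatible data frame).
#' @param sets List of [criteria_set()] objects (default: CNS-A and CNS-B).
#' @param ro5_max Maximum allowed Rule-of-5 violations (default 0, the value
#'   all reference agents attain; the classical drug-likeness cut-off is 1).
#' @return A `screen_report`: list with `results` (one row per record:
#'   per-set pass flags, `ro5_violations`, `overall_pass`), `pass_counts` and
#'   `pass_fraction` per criteria set, and `overall_fraction`.
#' @examples
#' screen_library(builtin_table1())$pass_counts
#' @export
screen_library <- function(t, sets = list(cns_a(), cns_b()), ro5_max = 0L) {
  t <- as.data.frame(t)
  if (nrow(t) == 0L) stop_input("screen_library: empty table")
  res <- data.frame(agent_id = t$agent_id %||% as.character(seq_len(nrow(t))),
                    stringsAsFactors = FALSE)
  set_names <- vapply(sets, function(s) s$name, character(1))
  for (s in sets) {
    ok <- rep(TRUE, nrow(t))
    for (i in seq_len(nrow(s$bounds))) {
      f <- s$bounds$field[i]
      if (is.null(t[[f]]))
        stop_input("table lacks field '", f, "' required by ", s$name)
      ok <- ok & apply_bound(t[[f]], s$bounds$op[i], s$bounds$value[i])
    }
    res[[paste0("pass_", gsub("[^A-Za-z0-9]+", "_", tolower(s$name)))]] <- ok
  }
  res$ro5_violations <- rule_of_five_violations(t)
  pass_cols <- grep("^pass_", names(res), value = TRUE)
  res$overall_pass <- Reduce(`&`, c(unname(as.list(res[pass_cols])),
                                    list(res$ro5_violations <= ro5_max)))
  counts <- vapply(pass_cols, function(cl) sum(res[[cl]]), integer(1))
  names(counts) <- set_names
  structure(list(results = res,
                 pass_counts = counts,
                 pass_fraction = counts / nrow(t),
                 n = nrow(t),
                 ro5_max = ro5_max,
                 overall_fraction = mean(res$overall_pass)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", x$n, " compounds\n", sep = "")
  for (nm in names(x$pass_counts))
    cat(sprintf("  %-8s %d/%d pass (%.1f%%)\n", nm, x$pass_counts[[nm]], x$n,
                100 * x$pass_fraction[[nm]]))
  cat(sprintf("  overall (all sets, Ro5 violations <= %d): %d/%d (%.1f%%)\n",
              x$ro5_max, sum(x$results$overall_pass), x$n,
              100 * x$overall_fraction))
  invisible(x)
}
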