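# Brain/blood partition model: the two-descriptor linear Log BB equation in
# polar surface area and Log P, and its library-level summary.

#' Predicted Log BB from polar surface area and Log P
#'
#' Evaluates the linear blood-brain partition model
#' `Log BB = -0.0148 * PSA + 0.152 * LogP + 0.139`, where BB is the
#' brain-to-blood concentration ratio C_brain/C_blood and the logarithm is
#' base 10. Values are computed at full precision; reports round half away
#' from zero to three decimals.
#'
#' @param psa Polar surface area in squared Angstroms (non-negative).
#' @param log_p Octanol-water Log P (finite).
#' @return Log BB (dimensionless), vectorized over inputs.
#' @examples
#' log_bb(61.772, 2.965)  # -0.3245, lomustine
#' @export
log_bb <- function(psa, log_p) {
  if (!is.numeric(psa) || !is.numeric(log_p) || !all(is.finite(psa)) ||
      !all(is.finite(log_p)))
    stop_input("log_bb: psa and log_p must be finite numbers")
  if (any(psa < 0)) stop_input("log_bb: psa must be non-negative")
  -0.0148 * psa + 0.152 * log_p + 0.139
}

#' Brain-to-blood concentration ratio from Log BB
#'
#' @param log_bb Base-10 log of the brain/blood concentration ratio.
#' @return BB = 10^Log BB (always positive).
#' @export
bb_ratio <- function(log_bb) {
  if (!is.numeric(log_bb) || !all(is.finite(log_bb)))
    stop_input("bb_ratio: log_bb must be finite")
  10^log_bb
}

#' Predict Log BB and BB for every record of a descriptor table
#'
#' @param t A `descriptor_table` (or data frame with `psa` and `log_p`).
#' @return Data frame with `agent_id`, `log_bb`, `bb`, in input row order.
#' @examples
#' head(bbb_table(builtin_table1()))
#' @export
bbb_table <- function(t) {
  t <- as.data.frame(t)
  for (col in c("psa", "log_p"))
    if (is.null(t[[col]]))
      stop_input("bbb_table: missing field '", col, "'")
  if (nrow(t) == 0L)
    return(data.frame(agent_id = character(), log_bb = numeric(),
                      bb = numeric(), stringsAsFactors = FALSE))
  bad <- which(!is.finite(t$psa) | !is.finite(t$log_p))
  if (length(bad))
    stop_input("bbb_table: non-finite psa/log_p for agent ",
               (t$agent_id %||% as.character(bad))[bad[1]])
  lbb <- log_bb(t$psa, t$log_p)
  data.frame(agent_id = t$agent_id %||% as.character(seq_len(nrow(t))),
             log_bb = lbb, bb = bb_ratio(lbb), stringsAsFactors = FALSE)
}

#' Summarize brain/blood partition predictions over a library
#'
#' @param preds Data frame from [bbb_table()] (columns `log_bb`, `bb`).
#' @return List with `mean_bb`, `sd_bb` (sample, n-1 denominator), `min_bb`,
#'   `max_bb` and `mean_log_bb`, at full precision.
#' @examples
#' s <- bbb_summary(bbb_table(builtin_table1()))
#' round(s$mean_bb, 3)  # 0.405
#' @export
bbb_summary <- function(preds) {
  preds <- as.data.frame(preds)
  if (nrow(preds) == 0L) stop_input("bbb_summary: empty prediction set")
  if (nrow(preds) < 2L)
    stop_input("bbb_summary: sample standard deviation undefined for n < 2")
  list(mean_bb = mean(preds$bb),
       sd_bb = stats::sd(preds$bb),
       min_bb = min(preds$bb),
       max_bb = max(preds$bb),
       mean_log_bb = mean(preds$log_bb))
}
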