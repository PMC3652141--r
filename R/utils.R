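# internal helpers shared across modules

# Round half away from zero to `digits` decimals (display convention of the
# reference tables; base round() is banker's rounding at ties).
round_out <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(errorCondition(paste0(...), class = c("nitroscreen_input_error", "error")))
stop_format <- function(...) stop(errorCondition(paste0(...), class = c("nitroscreen_format_error", "error")))
stop_structure <- function(...) stop(errorCondition(paste0(...), class = c("nitroscreen_structure_error", "error")))

is_count_col <- function(x) all(is.finite(x) & x >= 0 & x == round(x))
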