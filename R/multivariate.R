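# Multivariate statistics layer: summary statistics, Pearson correlations,
# Grubbs' ESD outlier test, multiple regression, standardized path
# coefficients, and ANOSIM. Clustering lives in cluster.R.

numeric_fields <- function(t) {
  t <- as.data.frame(t)
  names(t)[vapply(t, is.numeric, logical(1))]
}

#' Property summary statistics
#'
#' Mean, minimum, maximum, median and sample standard deviation (n-1
#' denominator) for every numeric property of a descriptor table. The median
#' of an even-sized sample is the mean of the two central order statistics.
#'
#' @param t A `descriptor_table` (or data frame); at least 2 rows.
#' @return Data frame with one row per property.
#' @examples
#' summarize_properties(builtin_table1())
#' @export
summarize_properties <- function(t) {
  t <- as.data.frame(t)
  if (nrow(t) < 2L) stop_input("summarize_properties: need at least 2 records")
  fields <- numeric_fields(t)
  do.call(rbind, lapply(fields, function(f) {
    x <- t[[f]]
    data.frame(property = f, mean = mean(x), minimum = min(x), maximum = max(x),
               median = stats::median(x), sd = stats::sd(x),
               stringsAsFactors = FALSE)
  }))
}

#' Pearson correlation matrix of descriptor properties
#'
#' @param t A `descriptor_table`; at least 3 rows.
#' @param fields Properties to correlate (default: all numeric). Zero-variance
#'   fields are excluded with a message.
#' @return Symmetric correlation matrix with unit diagonal.
#' @examples
#' pearson_matrix(builtin_table1(), c("fw", "n_atoms", "volume"))
#' @export
pearson_matrix <- function(t, fields = NULL) {
  t <- as.data.frame(t)
  if (nrow(t) < 3L) stop_input("pearson_matrix: need at least 3 records")
  fields <- fields %||% numeric_fields(t)
  missing <- setdiff(fields, names(t))
  if (length(missing)) stop_input("unknown field(s): ", paste(missing, collapse = ", "))
  v <- vapply(fields, function(f) stats::var(t[[f]]), numeric(1))
  if (any(v == 0)) {
    message("pearson_matrix: dropping zero-variance field(s): ",
            paste(fields[v == 0], collapse = ", "))
    fields <- fields[v > 0]
  }
  if (length(fields) == 0L)
    stop_input("pearson_matrix: all requested fields have zero variance; correlation undefined")
  stats::cor(as.matrix(t[fields]))
}

#' Grubbs' test for a single outlier (extreme studentized deviate)
#'
#' Tests whether the most extreme value is a significant outlier:
#' `G = max |x_i - mean| / s` with the sample standard deviation `s`, compared
#' with the two-sided critical value
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))`, where `t` is the
#' upper `alpha/(2n)` quantile of Student's t with `n - 2` degrees of freedom.
#'
#' @param values Numeric vector, length at least 3, non-constant.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `grubbs_result`: `g_statistic`, `g_critical`, `alpha`,
#'   `outlier_flag` (`g_statistic > g_critical`) and `outlier_index` (index of
#'   the most extreme value).
#' @examples
#' grubbs_test(builtin_table1()$log_p)
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  if (!is.numeric(values) || length(values) < 3L)
    stop_input("grubbs_test: need at least 3 numeric values")
  s <- stats::sd(values)
  if (s == 0) stop_input("grubbs_test: zero standard deviation")
  n <- length(values)
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  gc <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  structure(list(g_statistic = g, g_critical = gc, alpha = alpha,
                 outlier_flag = g > gc, outlier_index = which.max(dev),
                 n = n),
            class = "grubbs_result")
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("<grubbs_result> n = %d, G = %.4f, critical = %.4f (alpha = %g, two-sided)\n",
              x$n, x$g_statistic, x$g_critical, x$alpha))
  if (x$outlier_flag)
    cat("  significant outlier at index ", x$outlier_index, "\n", sep = "")
  else cat("  no significant outlier\n")
  invisible(x)
}

#' Ordinary least-squares fit of one property on others
#'
#' @param t A `descriptor_table`.
#' @param response Name of the response field.
#' @param predictors Character vector of predictor fields.
#' @return A `regression_fit`: `intercept`, named `coefficients`,
#'   `r_squared`, `n`, `residuals`, `fitted`, and the underlying `lm` object.
#' @examples
#' fit <- ols_fit(builtin_table1(), "fw", c("log_p", "psa", "n_atoms", "n_rot"))
#' fit$r_squared  # 0.7934
#' @export
ols_fit <- function(t, response, predictors) {
  t <- as.data.frame(t)
  fields <- c(response, predictors)
  missing <- setdiff(fields, names(t))
  if (length(missing)) stop_input("unknown field(s): ", paste(missing, collapse = ", "))
  if (nrow(t) <= length(predictors) + 1L)
    stop_input("ols_fit: need more records than predictors + 1")
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = t)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_input("ols_fit: design matrix is rank deficient; collinear predictor(s): ",
               paste(names(cf)[is.na(cf)], collapse = ", "))
  structure(list(intercept = unname(cf[1]),
                 coefficients = cf[-1],
                 r_squared = summary(fit)$r.squared,
                 n = nrow(t),
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(stats::fitted(fit)),
                 lm = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> n = %d, R^2 = %.4f\n", x$n, x$r_squared))
  print(c("(Intercept)" = x$intercept, x$coefficients))
  invisible(x)
}

#' Standardized path coefficients (single-equation path model)
#'
#' Standardized regression weights of the response on the predictors: all
#' variables are z-scored and an ordinary least-squares fit is taken, treating
#' every listed predictor as a direct cause of the response. With a single
#' predictor the path coefficient equals the Pearson correlation.
#'
#' With `method = "ols"` (default) a rank-deficient design is an error, as in
#' [ols_fit()]. `method = "minnorm"` returns the minimum-norm least-squares
#' solution via the SVD pseudoinverse, dropping singular values below
#' `tol` times the largest; exactly or near-collinear predictors then share
#' their weight instead of producing exploding coefficient pairs. See the
#' vignette for why the reference agent table needs this option.
#'
#' @param t A `descriptor_table`.
#' @param response Response field name.
#' @param predictors Predictor field names.
#' @param method `"ols"` or `"minnorm"`.
#' @param tol Relative singular-value cutoff for `method = "minnorm"`.
#' @return A `path_result`: named standardized `coefficients`, `response`,
#'   `method`.
#' @examples
#' path_coefficients(builtin_table1(), "fw", c("log_p", "n_atoms"))
#' @export
path_coefficients <- function(t, response, predictors,
                              method = c("ols", "minnorm"), tol = 1e-4) {
  method <- match.arg(method)
  t <- as.data.frame(t)
  fields <- c(response, predictors)
  missing <- setdiff(fields, names(t))
  if (length(missing)) stop_input("unknown field(s): ", paste(missing, collapse = ", "))
  v <- vapply(fields, function(f) stats::var(t[[f]]), numeric(1))
  if (any(v == 0))
    stop_input("path_coefficients: zero-variance field(s) cannot be standardized: ",
               paste(fields[v == 0], collapse = ", "))
  z <- as.data.frame(scale(as.matrix(t[fields])))
  if (method == "ols") {
    fit <- ols_fit(z, response, predictors)
    cf <- fit$coefficients
  } else {
    X <- as.matrix(z[predictors])
    y <- z[[response]]
    sv <- svd(X)
    keep <- sv$d > tol * sv$d[1]
    cf <- drop(sv$v[, keep, drop = FALSE] %*%
                 ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep]))
    names(cf) <- predictors
  }
  structure(list(coefficients = cf, response = response, method = method),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat("<path_result> standardized direct effects on ", x$response,
      " (", x$method, ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Permutation test comparing mean between-group and within-group rank
#' dissimilarities: `R = (mean_between - mean_within) / (n(n-1)/4)` on
#' mid-ranked Euclidean distances (Clarke's statistic, in [-1, 1]; `R = 1`
#' whenever every between-group distance exceeds every within-group distance).
#' The p-value is the fraction of label permutations (observed labelling
#' included) with `R` at least the observed value.
#'
#' @param x A `descriptor_table` / numeric matrix, or a [stats::dist] object.
#' @param groups Group labels, one per record; at least two groups.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed RNG seed (required: the test is randomization-based).
#' @param standardize Z-score columns (dropping zero-variance ones) before
#'   computing Euclidean distances; ignored when `x` is already a `dist`.
#' @return An `anosim_result`: `r_statistic`, `p_value`, `n_permutations`,
#'   `seed`.
#' @examples
#' t1 <- builtin_table1()
#' anosim_test(t1, groups = t1$psa > 70, n_permutations = 199, seed = 1)
#' @export
anosim_test <- function(x, groups, n_permutations = 999, seed,
                        standardize = TRUE) {
  if (missing(seed)) stop_input("anosim_test: a seed is required")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop_input("anosim_test: need at least two groups")
  d <- if (inherits(x, "dist")) x else {
    m <- as.matrix(as.data.frame(x)[numeric_fields(x)])
    if (standardize) m <- scale_drop_constant(m)$scaled
    stats::dist(m)
  }
  n <- attr(d, "Size")
  if (length(groups) != n)
    stop_input("anosim_test: 'groups' must have one label per record")
  r <- rank(as.vector(d))  # mid-ranks for ties
  within <- as.vector(stats::as.dist(outer(groups, groups, "=="))) > 0
  denom <- n * (n - 1) / 4
  stat <- function(w) (mean(r[!w]) - mean(r[w])) / denom
  observed <- stat(within)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) {
    g <- sample(groups)
    stat(as.vector(stats::as.dist(outer(g, g, "=="))) > 0)
  }, numeric(1))
  p <- (1 + sum(perm >= observed)) / (n_permutations + 1)
  structure(list(r_statistic = observed, p_value = p,
                 n_permutations = n_permutations, seed = seed, n = n),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<anosim_result> R = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$r_statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

# z-score columns, dropping zero-variance ones (returns names dropped)
scale_drop_constant <- function(m) {
  v <- apply(m, 2, stats::var)
  dropped <- colnames(m)[v == 0]
  if (length(dropped))
    message("dropping zero-variance column(s): ", paste(dropped, collapse = ", "))
  list(scaled = scale(m[, v > 0, drop = FALSE]), dropped = dropped)
}
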