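# Chemical-space size extrapolation. The number of stable molecules grows
# exponentially with heavy-atom count, so log10(cumulative count) is close
# to linear in n; a least-squares line fitted over a trusted range is used
# to extrapolate sizes far beyond what can be enumerated explicitly.

#' Fit an exponential growth model to a count table
#'
#' Least-squares fit of `log10(cumulative) = a + b * n_heavy` over the
#' requested range.
#'
#' @param table data.frame with columns `n_heavy` and `cumulative` (a count
#'   table from [enumerate_space()] or [count_table()]).
#' @param fit_range length-2 integer vector (inclusive); default uses all
#'   rows with positive cumulative counts.
#' @return a `growth_model`: list with `intercept`, `slope`, `fit_range`,
#'   `residuals`, `r_squared`, `n_points`.
#' @export
fit_growth_model <- function(table, fit_range = NULL) {
  stopifnot(all(c("n_heavy", "cumulative") %in% names(table)))
  if (is.null(fit_range)) fit_range <- range(table$n_heavy[table$cumulative > 0])
  rows <- table$n_heavy >= fit_range[1] & table$n_heavy <= fit_range[2] &
    table$cumulative > 0
  if (sum(rows) < 2L)
    stop("insufficient data: need at least 2 rows with positive counts in range")
  x <- table$n_heavy[rows]
  y <- log10(table$cumulative[rows])
  fit <- stats::lm(y ~ x)
  res <- unname(stats::residuals(fit))
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else 1
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 fit_range = as.integer(fit_range),
                 residuals = res,
                 r_squared = r2,
                 n_points = sum(rows)),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> log10(N) = %.4f + %.4f * n_heavy  (n = %d, R^2 = %.4f)\n",
              x$intercept, x$slope, x$n_points, x$r_squared))
  invisible(x)
}

#' Extrapolate a growth model to a heavy-atom count
#'
#' @param model a `growth_model`.
#' @param n_heavy heavy-atom count(s) to extrapolate to.
#' @return data.frame with `n_heavy`, `estimate` (10^fit) and
#'   `order_of_magnitude` (nearest power of ten).
#' @export
extrapolate <- function(model, n_heavy) {
  stopifnot(inherits(model, "growth_model"))
  l10 <- model$intercept + model$slope * n_heavy
  data.frame(n_heavy = n_heavy,
             estimate = 10^l10,
             order_of_magnitude = round(l10))
}

#' Coverage of a chemical space by a library
#'
#' @param library_size number of compounds in the screened library.
#' @param space_size size of the full chemical space.
#' @return percentage, `100 * library_size / space_size`.
#' @export
coverage_percent <- function(library_size, space_size) {
  if (any(library_size <= 0) || any(space_size <= 0))
    stop("sizes must be positive")
  100 * library_size / space_size
}
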