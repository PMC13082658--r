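#' Min-range normalisation
#'
#' Maps a vector onto `[0, 1]` by subtracting its minimum and dividing by
#' its range. Used for every predictor and for the response before the
#' importance regression, so that each coefficient reads as the fractional
#' change in the response when that term goes from its minimum to its
#' maximum.
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return A vector in `[0, 1]` attaining both endpoints.
#' @export
#' @examples
#' normalize_range(c(650, 1040, 1300, 1950))
normalize_range <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("cannot min-range normalise a constant vector")
  (x - r[1]) / (r[2] - r[1])
}

# ordered term sets of the 16-term model
importance_main_terms <- c("alpha_d", "c1", "alpha_a", "vmax", "Fmax")
importance_interaction_terms <- c(
  "alpha_d:c1", "alpha_d:alpha_a", "alpha_d:vmax", "alpha_d:Fmax",
  "c1:alpha_a", "c1:vmax", "c1:Fmax", "alpha_a:vmax", "alpha_a:Fmax",
  "vmax:Fmax")

# normalized design matrix (without intercept) for a sweep table
importance_design <- function(table, renormalize_interactions = FALSE) {
  X <- sapply(importance_main_terms, function(nm) normalize_range(table[[nm]]))
  for (tm in importance_interaction_terms) {
    ab <- strsplit(tm, ":", fixed = TRUE)[[1]]
    col <- X[, ab[1]] * X[, ab[2]]
    if (renormalize_interactions) col <- normalize_range(col)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- tm
  }
  X
}

#' Importance regression of sweep performance
#'
#' Ordinary least squares of the (min-range-normalised) performance metric
#' on the five min-range-normalised muscle parameters and their ten
#' pairwise interactions plus an intercept (16 terms). Coefficient
#' magnitudes are the "importance" of each term: the mean fractional
#' change in the response from moving that term across its full range.
#' Interactions are products of the already-normalised main effects (on a
#' full factorial whose ranges include the endpoints these products
#' already span `[0, 1]`).
#'
#' @param table A sweep table from [run_sweep()] (or any tibble with the
#'   five parameter columns and the response).
#' @param variant `"all_terms"` (16 terms), `"first_order_only"`
#'   (intercept, `alpha_a`, `vmax`, `Fmax` and the `alpha_d:c1`
#'   interaction), or `"first_order_independent_only"` (the same without
#'   the interaction).
#' @param response Response column name (default `"J_RMSE"`).
#' @param normalize_response Min-range normalise the response (default
#'   TRUE, as in the importance analysis). Set FALSE to fit the raw
#'   response, e.g. for exact recovery of planted coefficients.
#' @param renormalize_interactions Re-normalise the interaction products
#'   (sensitivity switch; default FALSE).
#' @return An `importance_fit`: coefficients tibble (`term`, `estimate`),
#'   `r_squared`, `variant`, `n`.
#' @export
fit_importance <- function(table,
                           variant = c("all_terms", "first_order_only",
                                       "first_order_independent_only"),
                           response = "J_RMSE",
                           normalize_response = TRUE,
                           renormalize_interactions = FALSE) {
  variant <- match.arg(variant)
  y <- table[[response]]
  if (is.null(y)) stop("response column not found")
  if (normalize_response) y <- normalize_range(y)
  X <- importance_design(table, renormalize_interactions)
  keep <- switch(variant,
    all_terms = colnames(X),
    first_order_only = c("alpha_a", "vmax", "Fmax", "alpha_d:c1"),
    first_order_independent_only = c("alpha_a", "vmax", "Fmax"))
  X <- X[, keep, drop = FALSE]
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) stop("rank-deficient importance design")
  beta <- qr.coef(qrX, y)
  fitted <- drop(Xi %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = tibble::tibble(term = colnames(Xi),
                                  estimate = unname(beta)),
    r_squared = 1 - rss / tss,
    variant = variant, n = length(y),
    response = response, normalize_response = normalize_response
  ), class = "importance_fit")
}

#' @export
print.importance_fit <- function(x, ...) {
  cat(sprintf("<importance_fit> %s, n = %d, R^2 = %.3f\n",
              x$variant, x$n, x$r_squared))
  df <- as.data.frame(x$coefficients)
  df$estimate <- signif(df$estimate, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.importance_fit <- function(x, ...) x$coefficients

#' @export
glance.importance_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n, variant = x$variant)
}

#' Coactivation-performance regression
#'
#' OLS of the max-normalised performance metric `J_RMSE / max(J_RMSE)` on
#' the raw mean coactivation of each solution. A negative slope means that
#' solutions with more coactivation perform better.
#'
#' @param table A sweep table with `J_RMSE` and `a_c_mean` columns.
#' @return A list: `slope`, `intercept`, `r_squared`, `p_value`, and the
#'   underlying `lm` fit.
#' @export
coactivation_regression <- function(table) {
  y <- table$J_RMSE / max(table$J_RMSE)
  if (length(unique(y)) < 2 || length(unique(table$a_c_mean)) < 2)
    stop("degenerate coactivation regression (no variance)")
  fit <- lm(y ~ a_c_mean, data = table)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4], fit = fit)
}
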