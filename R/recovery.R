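# Parameter-recovery indices between generating ("true") and equated
# estimated values, quantile trimming across iterations, and descriptive
# summaries in the layout of factor-by-level tables.

#' Association- and error-based recovery indices
#'
#' Computes the Pearson correlation (association-based) and bias, RMSE, MAE
#' and SEE (error-based) between true and estimated values. SEE is the
#' population SD (n divisor) of the errors `est - true`, which yields the
#' exact decomposition `rmse^2 = bias^2 + see^2`. The correlation is flagged
#' undefined (`NA`) when either vector has zero variance.
#'
#' @param true,est numeric vectors of equal length (>= 2), finite.
#' @param parameter optional label (`"a"`, `"b"`, `"theta"`).
#' @return one-row data.frame with `parameter`, `n_used`, `r`, `bias`,
#'   `rmse`, `mae`, `see`.
#' @export
recovery_indices <- function(true, est, parameter = NA_character_) {
  if (length(true) != length(est))
    stop("validation error: `true` and `est` differ in length", call. = FALSE)
  if (length(true) < 2)
    stop("need at least 2 pairs", call. = FALSE)
  if (any(!is.finite(true)) || any(!is.finite(est)))
    stop("validation error: non-finite values", call. = FALSE)
  e <- est - true
  bias <- mean(e)
  see <- sqrt(mean((e - bias)^2))
  r <- if (sd(true) == 0 || sd(est) == 0) NA_real_ else cor(true, est)
  data.frame(parameter = parameter, n_used = length(e), r = r, bias = bias,
             rmse = sqrt(mean(e^2)), mae = mean(abs(e)), see = see,
             stringsAsFactors = FALSE)
}

#' Trim the outer quantile tails of a set of iteration values
#'
#' Nearest-rank rule: with `k = floor(alpha * n)` finite values per tail, the
#' retained set is every value between the `(k+1)`-th smallest and the
#' `(k+1)`-th largest, inclusive. For 1000 distinct values and
#' `alpha = 0.025` this keeps exactly the central 950; for tiny `n` where a
#' tail rank would not exist (e.g. `n = 3`) nothing is removed. Non-finite
#' values are always dropped and counted as removed. Trimming retained values
#' again with the same thresholds removes nothing.
#'
#' @param values numeric vector of per-iteration index values.
#' @param alpha tail mass per side, in `[0, 0.5)` (default 0.025).
#' @return list with `values` (retained), `mask` (logical, same length as
#'   input), `lower`, `upper` (the retained range), `n_total`, `n_retained`.
#' @export
trim_iterations <- function(values, alpha = 0.025) {
  stopifnot(alpha >= 0, alpha < 0.5)
  fin <- is.finite(values)
  if (!any(fin)) stop("empty-result error: no finite values", call. = FALSE)
  v <- sort(values[fin])
  n <- length(v)
  k <- floor(alpha * n)
  lower <- v[k + 1]
  upper <- v[n - k]
  mask <- fin & values >= lower & values <= upper
  list(values = values[mask], mask = mask, lower = lower, upper = upper,
       n_total = length(values), n_retained = sum(mask))
}

#' Trimmed descriptive summary of recovery records
#'
#' Reproduces the layout of a factor-level descriptive table: for every
#' design factor level (and a marginal `"Total"` row), the mean of each
#' recovery index per IRT parameter, computed after trimming the outer
#' `alpha` tails within each scenario x model x method x parameter x index
#' cell across iterations. Undefined correlations are excluded from cell
#' means (with the exclusion reflected in `n_retained`).
#'
#' @param records long-format records as produced by [run_study()] (one row
#'   per iteration x model x method x parameter, with design columns `tss`,
#'   `aip`, `n`, `c` and index columns `r`, `bias`, `rmse`, `mae`, `see`).
#' @param factors design columns to summarize over.
#' @param alpha trimming tail mass (see [trim_iterations()]); 0 disables.
#' @return data.frame with columns `factor`, `level`, `parameter`, the mean
#'   of each index, and `n_retained`/`n_total` pair counts.
#' @export
summarize_recovery <- function(records,
                               factors = c("method", "model", "c", "aip",
                                           "tss", "n"),
                               alpha = 0.025) {
  stopifnot(nrow(records) >= 1)
  idx_cols <- c("r", "bias", "rmse", "mae", "see")
  dt <- data.table::as.data.table(records)
  long <- data.table::melt(dt,
    measure.vars = idx_cols, variable.name = "index", value.name = "value",
    variable.factor = FALSE)
  cell <- c("scenario_id", "model", "method", "parameter", "index")
  cell <- intersect(cell, names(long))
  long[, keep := {
    if (all(!is.finite(value))) rep(FALSE, .N)
    else trim_iterations(value, alpha)$mask
  }, by = cell]
  kept <- long[keep == TRUE]
  one <- function(fct) {
    g <- kept[, .(mean_value = mean(value), n_retained = .N),
              by = c(fct, "parameter", "index")]
    data.table::setnames(g, fct, "level")
    g[, level := as.character(level)]
    g[, factor := fct]
    g
  }
  tot <- kept[, .(mean_value = mean(value), n_retained = .N),
              by = c("parameter", "index")]
  tot[, `:=`(level = "Total", factor = "Total")]
  all_g <- data.table::rbindlist(c(lapply(intersect(factors, names(kept)), one),
                                   list(tot)), use.names = TRUE, fill = TRUE)
  n_tot <- long[, .(n_total = .N), by = c("parameter", "index")]
  wide <- data.table::dcast(all_g, factor + level + parameter ~ index,
                            value.var = "mean_value")
  nret <- data.table::dcast(all_g, factor + level + parameter ~ index,
                            value.var = "n_retained")
  wide[, n_retained := nret$r]
  data.table::setcolorder(wide, c("factor", "level", "parameter", idx_cols))
  as.data.frame(wide)
}
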