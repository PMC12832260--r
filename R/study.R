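# The factorial simulation engine: builds the scenario grid, runs iterations
# end-to-end (generate -> simulate -> calibrate -> equate -> score), tracks
# convergence and collects long-format recovery records.

ALL_METHODS <- c("MS", "MM", "MGM", "IRF", "TRF")
ALL_MODELS <- c("2PL", "3PL")

# Generating populations for the three samples: sample j takes form j.
SAMPLE_MU <- c(-0.5, 0.0, 0.5)
SAMPLE_SD <- c(0.8, 1.0, 1.2)

#' Anchor items per link for a scenario
#'
#' `max(1, round(aip * tss))` with round-half-up, so even a 5% proportion in a
#' 20-item form yields at least one anchor and equating exists.
#'
#' @param tss items per form.
#' @param aip anchor item proportion.
#' @return integer anchor count per link.
#' @export
n_anchor_for <- function(tss, aip) {
  pmax(1L, as.integer(floor(aip * tss + 0.5)))
}

#' Build the factorial scenario grid
#'
#' Cartesian product of test set size, anchor item proportion, sample size
#' and guessing probability, in a stable deterministic order (the first
#' factor varies fastest). The default levels span 4 x 5 x 5 x 4 = 400
#' scenarios.
#'
#' @param tss test set sizes.
#' @param aip anchor item proportions.
#' @param n sample sizes per form.
#' @param c guessing probabilities.
#' @return data.frame of scenarios with a derived `n_anchor` and a readable
#'   `scenario_id`.
#' @export
scenario_grid <- function(tss = c(20, 40, 60, 80),
                          aip = c(0.05, 0.10, 0.15, 0.20, 0.25),
                          n = c(25, 50, 100, 500, 1000),
                          c = base::c(0.000, 0.125, 0.167, 0.250)) {
  stopifnot(length(tss) >= 1, length(aip) >= 1, length(n) >= 1,
            length(c) >= 1)
  g <- expand.grid(tss = tss, aip = aip, n = n, c = c,
                   KEEP.OUT.ATTRS = FALSE)
  g$n_anchor <- n_anchor_for(g$tss, g$aip)
  g$scenario_id <- sprintf("tss%02d_aip%03.0f_n%04d_c%03.0f",
                           g$tss, g$aip * 1000, g$n, g$c * 1000)
  g
}

#' Study configuration
#'
#' @param tss,aip,n,c design factor levels (defaults: the full grid).
#' @param iterations Monte-Carlo iterations per scenario (default 1000; a
#'   reduced "pilot" count such as 30 is appropriate for desk-scale runs).
#' @param seed master seed; per-iteration seeds are derived deterministically
#'   with [child_seed()], so any execution order gives identical results.
#' @param models IRT models to calibrate (`"2PL"`, `"3PL"`).
#' @param methods equating methods to apply.
#' @param calib calibration settings ([calib_control()]).
#' @param verbose emit one progress line per scenario.
#' @return a `study_config` list.
#' @export
study_config <- function(tss = c(20, 40, 60, 80),
                         aip = c(0.05, 0.10, 0.15, 0.20, 0.25),
                         n = c(25, 50, 100, 500, 1000),
                         c = base::c(0.000, 0.125, 0.167, 0.250),
                         iterations = 1000L, seed = 1L,
                         models = ALL_MODELS, methods = ALL_METHODS,
                         calib = calib_control(), verbose = FALSE) {
  stopifnot(iterations >= 1)
  models <- match.arg(models, ALL_MODELS, several.ok = TRUE)
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  structure(list(tss = tss, aip = aip, n = n, c = c,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), models = models,
                 methods = methods, calib = calib,
                 verbose = isTRUE(verbose)),
            class = "study_config")
}

# empty index row used when a model x method combination is unavailable
na_indices <- function(parameter) {
  data.frame(parameter = parameter, n_used = NA_integer_, r = NA_real_,
             bias = NA_real_, rmse = NA_real_, mae = NA_real_,
             see = NA_real_, stringsAsFactors = FALSE)
}

# true parameter table for the items of one form, plus the true abilities,
# paired against a fit transformed onto the reference scale
pair_form_estimates <- function(truth, est) {
  m <- merge(truth, est, by = "item_id", suffixes = c("_true", "_est"))
  m
}

#' Run one Monte-Carlo iteration of a scenario
#'
#' Executes the full pipeline: item-bank generation, three ability samples
#' from N(-0.5, 0.8^2), N(0, 1) and N(+0.5, 1.2^2), response simulation per
#' form, 2PL/3PL calibration per form, anchor equating of forms 1 and 3 onto
#' the reference scale of form 2 (direct links 1->2 and 3->2; the indirect
#' 1->3 chain is composed and reported for chain-consistency checks), and
#' recovery indices for discrimination, difficulty and ability against the
#' generating values. Items and persons of all three forms are pooled;
#' anchor items contribute one estimate per form they appear in.
#'
#' Randomness is split into deterministic child streams (items, abilities,
#' responses), so the same `seed` reproduces the record bit-identically and
#' both models consume identical response matrices.
#'
#' @param scenario one row of [scenario_grid()] (or a list with `tss`,
#'   `aip`, `n`, `c`, optionally `n_anchor` and `scenario_id`).
#' @param seed iteration seed.
#' @param models,methods,calib see [study_config()].
#' @param keep_data also return the bank, samples, responses and fits
#'   (for testing; heavy).
#' @return list of class `iteration_record` with `indices` (long data.frame),
#'   `convergence` (per model), `coefficients` (per model x method),
#'   `M_aa` (realized mean true anchor discrimination), and optionally
#'   `data`.
#' @export
run_iteration <- function(scenario, seed, models = ALL_MODELS,
                          methods = ALL_METHODS, calib = calib_control(),
                          keep_data = FALSE) {
  tss <- scenario$tss; aip <- scenario$aip
  n <- scenario$n; cc <- scenario$c
  n_anchor <- if (!is.null(scenario$n_anchor)) scenario$n_anchor
              else n_anchor_for(tss, aip)
  sid <- if (!is.null(scenario$scenario_id)) scenario$scenario_id
         else sprintf("tss%02d_aip%03.0f_n%04d_c%03.0f", tss, aip * 1000,
                      n, cc * 1000)

  bank <- generate_item_bank(tss, n_anchor, c = cc,
                             seed = child_seed(seed, 1))
  forms <- lapply(1:3, form_items, bank = bank)
  abil <- lapply(1:3, function(j)
    generate_abilities(n, SAMPLE_MU[j], SAMPLE_SD[j], form = j,
                       seed = child_seed(seed, 10 + j)))
  resp <- lapply(1:3, function(j)
    simulate_responses(abil[[j]], forms[[j]], model = "3PL",
                       seed = child_seed(seed, 20 + j)))

  M_aa <- mean(bank$items$a[bank$items$anchor_block != "none"])
  grid <- quadrature_grid(calib$grid_size, calib$grid_range[1],
                          calib$grid_range[2])

  indices <- list(); conv <- list(); coefs <- list()
  data_out <- if (keep_data) list(bank = bank, abilities = abil,
                                  responses = resp, fits = list()) else NULL

  for (model in models) {
    fits <- lapply(resp, fit_irt, model = model, control = calib)
    if (keep_data) data_out$fits[[model]] <- fits
    ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    conv[[model]] <- data.frame(scenario_id = sid, model = model,
                                converged_forms = sum(ok),
                                all_converged = all(ok),
                                stringsAsFactors = FALSE)
    for (method in methods) {
      row_id <- paste(model, method, sep = ".")
      if (!all(ok)) {
        out <- do.call(rbind, lapply(c("a", "b", "theta"), na_indices))
        out$status <- "not_converged"
        out$model <- model; out$method <- method
        indices[[row_id]] <- out
        next
      }
      res <- tryCatch({
        a12 <- bank$items$item_id[bank$items$anchor_block == "link12"]
        a23 <- bank$items$item_id[bank$items$anchor_block == "link23"]
        coef12 <- equate_anchors(anchor_pairs(fits[[1]], fits[[2]], a12),
                                 method, grid)
        coef12$source_form <- 1L; coef12$target_form <- 2L
        coef32 <- equate_anchors(anchor_pairs(fits[[3]], fits[[2]], a23),
                                 method, grid)
        coef32$source_form <- 3L; coef32$target_form <- 2L
        # indirect 1 -> 3 chain through form 2
        coef13 <- chain_compose(coef12, invert_coef(coef32))
        ident <- new_equating_coef(1, 0, "identity", 0L, 2L, 2L)
        link <- list(coef12, ident, coef32)

        true_a <- c(); true_b <- c(); est_a <- c(); est_b <- c()
        for (j in 1:3) {
          est <- transform_items(fits[[j]]$item_estimates, link[[j]])
          m <- pair_form_estimates(forms[[j]][, c("item_id", "a", "b")], est)
          true_a <- c(true_a, m$a_true); est_a <- c(est_a, m$a_est)
          true_b <- c(true_b, m$b_true); est_b <- c(est_b, m$b_est)
        }
        true_th <- c(); est_th <- c()
        for (j in 1:3) {
          true_th <- c(true_th, abil[[j]]$theta)
          est_th <- c(est_th, transform_theta(fits[[j]]$theta$theta_hat,
                                              link[[j]]))
        }
        out <- rbind(recovery_indices(true_a, est_a, "a"),
                     recovery_indices(true_b, est_b, "b"),
                     recovery_indices(true_th, est_th, "theta"))
        out$status <- "ok"
        coefs[[row_id]] <- data.frame(
          scenario_id = sid, model = model, method = method,
          A12 = coef12$A, B12 = coef12$B, A32 = coef32$A, B32 = coef32$B,
          A13 = coef13$A, B13 = coef13$B, stringsAsFactors = FALSE)
        out
      }, error = function(e) {
        out <- do.call(rbind, lapply(c("a", "b", "theta"), na_indices))
        out$status <- paste0("equating_error: ", conditionMessage(e))
        out
      })
      res$model <- model; res$method <- method
      indices[[row_id]] <- res
    }
  }

  ind <- do.call(rbind, indices)
  ind$scenario_id <- sid; ind$tss <- tss; ind$aip <- aip
  ind$n <- n; ind$c <- cc; ind$M_aa <- M_aa
  rownames(ind) <- NULL
  structure(list(indices = ind,
                 convergence = do.call(rbind, conv),
                 coefficients = if (length(coefs))
                   do.call(rbind, coefs) else NULL,
                 M_aa = M_aa, scenario_id = sid,
                 data = data_out),
            class = "iteration_record")
}

#' Run the full simulation study
#'
#' Loops scenarios and iterations, with per-iteration seeds derived from the
#' master seed so that scenarios are independent and any execution order
#' (or a re-run) yields identical results. Within an iteration the same item
#' bank, samples and responses feed every model and method (common random
#' numbers). Partial failures are recorded in the `status` column of the
#' records, never swallowed.
#'
#' @param config a [study_config()].
#' @return object of class `study_result`: list with `records` (long
#'   data.frame: one row per scenario x iteration x model x method x
#'   parameter), `convergence` (per scenario x iteration x model),
#'   `coefficients`, and the `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  grid <- scenario_grid(config$tss, config$aip, config$n, config$c)
  recs <- list(); convs <- list(); coefs <- list()
  for (s in seq_len(nrow(grid))) {
    scen <- grid[s, ]
    if (config$verbose)
      message(sprintf("[%d/%d] %s", s, nrow(grid), scen$scenario_id))
    n_conv <- 0L
    for (it in seq_len(config$iterations)) {
      iter_seed <- child_seed(config$seed, (s - 1) * 100003 + it)
      rec <- run_iteration(scen, iter_seed, config$models, config$methods,
                           config$calib)
      rec$indices$iteration <- it
      rec$convergence$iteration <- it
      if (!is.null(rec$coefficients)) {
        rec$coefficients$iteration <- it
        coefs[[length(coefs) + 1L]] <- rec$coefficients
      }
      recs[[length(recs) + 1L]] <- rec$indices
      convs[[length(convs) + 1L]] <- rec$convergence
      n_conv <- n_conv + sum(rec$convergence$converged_forms)
    }
    if (config$verbose)
      message(sprintf("    converged form fits: %d / %d", n_conv,
                      config$iterations * 3L * length(config$models)))
  }
  structure(list(
    records = as.data.frame(data.table::rbindlist(recs)),
    convergence = as.data.frame(data.table::rbindlist(convs)),
    coefficients = if (length(coefs))
      as.data.frame(data.table::rbindlist(coefs)) else NULL,
    config = config), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d record rows, %d scenarios, %d iterations\n",
              nrow(x$records), length(unique(x$records$scenario_id)),
              x$config$iterations))
  invisible(x)
}

#' Convergence statistics
#'
#' Per scenario and model: the convergence rate CR (proportion of iterations
#' in which all three form fits converged) and the mean number of converged
#' forms (0-3). The `overall` element reports the grand total-model rate
#' (converged form fits / all form fits) and a CR table by sample size x
#' test set size.
#'
#' @param x a `study_result` or its `convergence` data.frame.
#' @return list with `per_scenario`, `overall` (list with
#'   `total_model_rate`, `mean_converged_forms`, `cr`), and `by_n_tss`
#'   when design columns are recoverable.
#' @export
convergence_stats <- function(x) {
  cv <- if (inherits(x, "study_result")) x$convergence else x
  stopifnot(nrow(cv) >= 1)
  dt <- data.table::as.data.table(cv)
  per <- dt[, .(cr = mean(all_converged),
                mean_forms = mean(converged_forms),
                iterations = .N),
            by = .(scenario_id, model)]
  overall <- list(
    total_model_rate = sum(dt$converged_forms) / (3 * nrow(dt)),
    mean_converged_forms = mean(dt$converged_forms),
    cr = mean(dt$all_converged))
  out <- list(per_scenario = as.data.frame(per), overall = overall)
  if (inherits(x, "study_result")) {
    des <- unique(x$records[, c("scenario_id", "n", "tss")])
    m <- merge(as.data.frame(per), des, by = "scenario_id")
    byn <- data.table::as.data.table(m)[, .(cr = mean(cr)), by = .(n, tss)]
    out$by_n_tss <- as.data.frame(byn[order(n, tss)])
  }
  out
}

#' Desk-scale pilot profile
#'
#' A reduced configuration for directional checks on one CPU: the subgrid
#' test set size {20, 40} x anchor proportion {5%, 25%} x sample size
#' {100, 500} x guessing {0, 0.25}, 30 iterations, 2PL calibration with the
#' mean-mean and Haebara methods. Large enough to reproduce the direction of
#' the main effects, far too small for their magnitudes.
#'
#' @param seed master seed.
#' @param iterations iterations per scenario (default 30).
#' @return a [study_config()].
#' @export
pilot_config <- function(seed = 1L, iterations = 30L) {
  study_config(tss = c(20, 40), aip = c(0.05, 0.25), n = c(100, 500),
               c = base::c(0, 0.25), iterations = iterations, seed = seed,
               models = "2PL", methods = c("MM", "IRF"))
}

#' Analytic sampling error of the mean and variance
#'
#' Closed forms under a normal population: the standard error of the sample
#' mean is `sigma / sqrt(n)`; the standard error of the sample variance is
#' `sigma^2 * sqrt(2 / (n - 1))`.
#'
#' @param n sample size.
#' @param sigma population SD (default 1, the standardized latent trait).
#' @return list with `se_mean` and `se_variance`.
#' @export
sampling_se <- function(n, sigma = 1) {
  stopifnot(n >= 2, sigma > 0)
  list(se_mean = sigma / sqrt(n),
       se_variance = sigma^2 * sqrt(2 / (n - 1)))
}

#' Guessing probability implied by the number of distractors
#'
#' For a multiple-choice item answered at random, `c = 1 / d` where `d` is
#' the number of response options a guesser chooses among (e.g. eight
#' options give `c = 0.125`).
#'
#' @param d number of distractors (>= 1).
#' @return guessing probability.
#' @export
guessing_from_distractors <- function(d) {
  stopifnot(all(d >= 1))
  1 / d
}
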