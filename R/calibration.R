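# Marginal maximum likelihood (EM) calibration of 2PL/3PL item parameters on
# a fixed quadrature grid, and EAP ability scoring. The latent prior is
# standard normal, so every form's estimates live on their own
# sample-standardized scale -- the incomparability that equating resolves.

#' Fixed quadrature grid with standard-normal prior weights
#'
#' Equally spaced nodes with standard-normal density weights renormalized to
#' sum to one. Used both as the latent prior in calibration and as the
#' integration weights of the characteristic-curve equating criteria.
#'
#' @param n_nodes number of nodes (default 61).
#' @param lower,upper grid range (default `[-6, 6]`, wide enough for 3PL tails).
#' @return list with `nodes` (strictly increasing) and `weights`
#'   (nonnegative, summing to 1).
#' @export
quadrature_grid <- function(n_nodes = 61L, lower = -6, upper = 6) {
  stopifnot(n_nodes >= 2, lower < upper)
  nodes <- seq(lower, upper, length.out = n_nodes)
  w <- dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' Calibration settings
#'
#' @param grid_size number of quadrature nodes.
#' @param grid_range latent grid range.
#' @param tol convergence rule: maximum absolute change in any item parameter
#'   between EM cycles must fall below `tol`.
#' @param max_cycles EM cycle budget; exceeding it returns
#'   `converged = FALSE` (the result is still usable downstream, which counts
#'   it as a non-convergence).
#' @param c_max upper box constraint for the estimated guessing parameter
#'   (3PL only).
#' @return list of settings for [fit_irt()].
#' @export
calib_control <- function(grid_size = 61L, grid_range = c(-6, 6),
                          tol = 1e-4, max_cycles = 500L, c_max = 0.5) {
  stopifnot(tol > 0, max_cycles >= 1, c_max > 0, c_max <= 1)
  list(grid_size = as.integer(grid_size), grid_range = grid_range,
       tol = tol, max_cycles = as.integer(max_cycles), c_max = c_max)
}

#' Fit a 2PL or 3PL model by marginal maximum likelihood (EM)
#'
#' EM with a fixed quadrature prior (standard normal). The M-step maximizes
#' each item's expected complete-data log-likelihood by Fisher scoring with
#' step halving, so the marginal log-likelihood is nondecreasing across
#' cycles. Items answered all-correct or all-incorrect are inestimable; they
#' are excluded from the fit and listed in the result. Abilities are scored
#' by EAP ([score_eap()]).
#'
#' Initialization: `a = 1`, `b = qnorm(1 - proportion correct)` clipped to
#' `[-3, 3]`, and `c = 0.1` under the 3PL.
#'
#' @param responses persons x items binary matrix (as from
#'   [simulate_responses()]).
#' @param model `"2PL"` or `"3PL"` (under the 2PL the guessing parameter is
#'   fixed at zero).
#' @param control settings from [calib_control()].
#' @return object of class `calibration_result`: list with `item_estimates`
#'   (data.frame `item_id`, `a`, `b`, `c`), `theta` (data.frame `person_id`,
#'   `theta_hat`), `loglik`, `loglik_trace`, `converged`, `n_cycles`,
#'   `model`, `excluded_items`, `grid`.
#' @export
fit_irt <- function(responses, model = c("2PL", "3PL"),
                    control = calib_control()) {
  model <- match.arg(model)
  x <- as.matrix(responses)
  if (!is.numeric(x) || any(!x %in% c(0, 1)))
    stop("`responses` must be a binary matrix", call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 persons and 2 items", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- sprintf("i%04d", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- sprintf("p%05d", seq_len(nrow(x)))

  pbar <- colMeans(x)
  estimable <- pbar > 0 & pbar < 1
  excluded <- colnames(x)[!estimable]
  grid <- quadrature_grid(control$grid_size, control$grid_range[1],
                          control$grid_range[2])

  if (sum(estimable) < 2) {
    # too few estimable items for a model fit; honor the no-crash contract
    est <- data.frame(item_id = character(0), a = numeric(0),
                      b = numeric(0), c = numeric(0))
    theta <- data.frame(person_id = rownames(x),
                        theta_hat = rep(0, nrow(x)))
    return(structure(list(item_estimates = est, theta = theta,
                          loglik = NA_real_, loglik_trace = numeric(0),
                          converged = FALSE, n_cycles = 0L, model = model,
                          excluded_items = excluded, grid = grid),
                     class = "calibration_result"))
  }

  xf <- x[, estimable, drop = FALSE]
  p0 <- pbar[estimable]
  a0 <- rep(1, ncol(xf))
  b0 <- pmin(pmax(qnorm(1 - p0), -3), 3)
  c0 <- if (model == "3PL") rep(0.1, ncol(xf)) else rep(0, ncol(xf))

  fit <- em_fit_cpp(xf, grid$nodes, grid$weights,
                    if (model == "3PL") 3L else 2L,
                    a0, b0, c0, control$c_max, control$tol,
                    control$max_cycles)

  est <- data.frame(item_id = colnames(xf), a = as.numeric(fit$a),
                    b = as.numeric(fit$b), c = as.numeric(fit$c),
                    stringsAsFactors = FALSE)
  theta_hat <- score_eap(x, est, grid)
  theta <- data.frame(person_id = rownames(x), theta_hat = theta_hat,
                      stringsAsFactors = FALSE)
  structure(list(item_estimates = est, theta = theta,
                 loglik = fit$loglik,
                 loglik_trace = as.numeric(fit$loglik_trace),
                 converged = isTRUE(fit$converged),
                 n_cycles = as.integer(fit$n_cycles), model = model,
                 excluded_items = excluded, grid = grid),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s, %d items (%d excluded), %d persons\n",
              x$model, nrow(x$item_estimates), length(x$excluded_items),
              nrow(x$theta)))
  cat(sprintf("  loglik %.3f after %d EM cycles; converged: %s\n",
              x$loglik, x$n_cycles, x$converged))
  invisible(x)
}

#' EAP ability estimates
#'
#' Expected a posteriori ability: the posterior mean over the quadrature grid
#' under a standard-normal prior. Shrinkage keeps the estimate finite for
#' every response pattern, including all-correct and all-incorrect. With zero
#' scorable items the posterior equals the prior and the estimate is its mean
#' (0 up to grid symmetry).
#'
#' @param responses persons x items binary matrix; columns are matched to
#'   `item_estimates$item_id` by name when dimnames are present, otherwise by
#'   position.
#' @param item_estimates data.frame with `item_id`, `a`, `b`, `c`.
#' @param grid a [quadrature_grid()].
#' @return numeric vector of ability estimates, one per person.
#' @export
score_eap <- function(responses, item_estimates, grid = quadrature_grid()) {
  x <- as.matrix(responses)
  if (nrow(x) == 0) stop("empty response matrix", call. = FALSE)
  if (nrow(item_estimates) == 0) return(rep(0, nrow(x)))
  if (!is.null(colnames(x))) {
    keep <- intersect(colnames(x), item_estimates$item_id)
    if (length(keep) == 0) return(rep(0, nrow(x)))
    x <- x[, keep, drop = FALSE]
    it <- item_estimates[match(keep, item_estimates$item_id), , drop = FALSE]
  } else {
    if (ncol(x) != nrow(item_estimates))
      stop("unnamed responses must have one column per item estimate",
           call. = FALSE)
    it <- item_estimates
  }
  if (any(rowSums(!is.na(x)) == 0))
    stop("validation error: empty response row", call. = FALSE)
  # items x nodes probability matrix
  P <- vapply(grid$nodes, function(th) icc_prob(th, it$a, it$b, it$c, "3PL"),
              numeric(nrow(it)))
  P <- matrix(P, nrow = nrow(it))
  logP <- log(P); log1mP <- log1p(-P)
  logL <- x %*% logP + (1 - x) %*% log1mP       # persons x nodes
  logL <- sweep(logL, 2, log(grid$weights), "+")
  m <- apply(logL, 1, max)
  w <- exp(logL - m)
  as.numeric((w %*% grid$nodes) / rowSums(w))
}
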