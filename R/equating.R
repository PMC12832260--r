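# Anchor-item scale linking. All five methods estimate the same linear map
# from the source form's scale to the target form's scale:
#   b_target = A * b_source + B,  a_target = a_source / A,  c unchanged.
# Moment methods (MS, MM, MGM) use anchor summary statistics; the
# characteristic-curve methods (IRF = Haebara, TRF = Stocking-Lord) minimize
# weighted squared differences of response functions over a quadrature grid.

new_equating_coef <- function(A, B, method, n_anchors,
                              source_form = NA_integer_,
                              target_form = NA_integer_, loss = NA_real_) {
  if (!is.finite(A) || !is.finite(B) || A <= 0)
    stop("equating coefficients must be finite with A > 0", call. = FALSE)
  structure(list(A = A, B = B, method = method,
                 n_anchors = as.integer(n_anchors),
                 source_form = source_form, target_form = target_form,
                 loss = loss),
            class = "equating_coef")
}

#' @export
print.equating_coef <- function(x, ...) {
  cat(sprintf("<equating_coef> %s: A = %.6f, B = %.6f (%d anchors, form %s -> %s)\n",
              x$method, x$A, x$B, x$n_anchors,
              as.character(x$source_form), as.character(x$target_form)))
  invisible(x)
}

#' Pair anchor-item estimates from two forms
#'
#' Joins the two forms' item-parameter estimates on `item_id`, keeping the
#' shared (anchor) items.
#'
#' @param source,target item-parameter data.frames (`item_id`, `a`, `b`, `c`)
#'   or `calibration_result` objects.
#' @param anchor_ids optional restriction to a known anchor block.
#' @return data.frame with columns `item_id`, `a_source`, `b_source`,
#'   `c_source`, `a_target`, `b_target`, `c_target`.
#' @export
anchor_pairs <- function(source, target, anchor_ids = NULL) {
  as_est <- function(x) {
    if (inherits(x, "calibration_result")) x$item_estimates
    else if (inherits(x, "item_bank")) x$items
    else x
  }
  s <- as_est(source); t <- as_est(target)
  need <- c("item_id", "a", "b", "c")
  if (!all(need %in% names(s)) || !all(need %in% names(t)))
    stop("item tables need columns item_id, a, b, c", call. = FALSE)
  m <- merge(s[, need], t[, need], by = "item_id",
             suffixes = c("_source", "_target"), sort = TRUE)
  if (!is.null(anchor_ids)) m <- m[m$item_id %in% anchor_ids, , drop = FALSE]
  if (nrow(m) == 0)
    stop("no shared anchor items between source and target", call. = FALSE)
  rownames(m) <- NULL
  m
}

validate_pairs <- function(pairs) {
  need <- c("a_source", "b_source", "a_target", "b_target")
  if (!all(need %in% names(pairs)))
    stop("anchor pairs need a/b columns for both sides", call. = FALSE)
  if (nrow(pairs) < 1) stop("need at least one anchor pair", call. = FALSE)
  if (any(pairs$a_source <= 0) || any(pairs$a_target <= 0))
    stop("validation error: nonpositive anchor discriminations", call. = FALSE)
  invisible(pairs)
}

#' Mean-sigma equating coefficients
#'
#' `A = sd(b_target) / sd(b_source)`, `B = mean(b_target) - A * mean(b_source)`.
#' Requires at least two anchors (an SD of one value is undefined) and a
#' nonzero source-difficulty SD.
#'
#' @param pairs anchor pairs from [anchor_pairs()].
#' @return an `equating_coef`.
#' @export
ms_coefficients <- function(pairs) {
  validate_pairs(pairs)
  if (nrow(pairs) < 2)
    stop("method-inapplicable: mean-sigma needs >= 2 anchors", call. = FALSE)
  s <- sd(pairs$b_source)
  if (s == 0)
    stop("degenerate-anchor error: zero source-difficulty SD", call. = FALSE)
  A <- sd(pairs$b_target) / s
  if (A <= 0)
    stop("degenerate-anchor error: zero target-difficulty SD", call. = FALSE)
  B <- mean(pairs$b_target) - A * mean(pairs$b_source)
  new_equating_coef(A, B, "MS", nrow(pairs))
}

#' Mean-mean equating coefficients
#'
#' `A = sum(a_source) / sum(a_target)`, `B = mean(b_target) - A * mean(b_source)`.
#'
#' @inheritParams ms_coefficients
#' @return an `equating_coef`.
#' @export
mm_coefficients <- function(pairs) {
  validate_pairs(pairs)
  A <- sum(pairs$a_source) / sum(pairs$a_target)
  B <- mean(pairs$b_target) - A * mean(pairs$b_source)
  new_equating_coef(A, B, "MM", nrow(pairs))
}

#' Mean-geometric-mean equating coefficients
#'
#' `A` is the geometric mean of the per-anchor discrimination ratios
#' `a_source / a_target`; `B` as in the mean-mean method.
#'
#' @inheritParams ms_coefficients
#' @return an `equating_coef`.
#' @export
mgm_coefficients <- function(pairs) {
  validate_pairs(pairs)
  A <- exp(mean(log(pairs$a_source / pairs$a_target)))
  B <- mean(pairs$b_target) - A * mean(pairs$b_source)
  new_equating_coef(A, B, "MGM", nrow(pairs))
}

# Characteristic-curve loss: source anchors mapped onto the target scale
# (a/A, A*b + B; c untransformed) and compared against target-estimated ICCs
# over the grid. level = "item" gives the Haebara criterion, "test" the
# Stocking-Lord criterion.
cc_loss <- function(par, pairs, grid, level) {
  A <- par[1]; B <- par[2]
  if (!is.finite(A) || !is.finite(B) || A <= 1e-3) return(1e10)
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    pt <- icc_prob(grid$nodes, pairs$a_target[i], pairs$b_target[i],
                   pairs$c_target[i], "3PL")
    ps <- icc_prob(grid$nodes, pairs$a_source[i] / A,
                   A * pairs$b_source[i] + B, pairs$c_source[i], "3PL")
    pt - ps
  }, numeric(length(grid$nodes)))
  d <- matrix(d, nrow = length(grid$nodes))
  val <- if (level == "item") sum(grid$weights * rowSums(d^2))
         else sum(grid$weights * rowSums(d)^2)
  0.5 * val
}

cc_coefficients <- function(pairs, grid, init, level, method, tol = 1e-6) {
  validate_pairs(pairs)
  if (!all(c("c_source", "c_target") %in% names(pairs))) {
    pairs$c_source <- 0; pairs$c_target <- 0
  }
  if (is.null(init)) init <- mm_coefficients(pairs)
  p0 <- c(init$A, init$B)
  f <- function(par) cc_loss(par, pairs, grid, level)
  opt <- optim(p0, f, method = "Nelder-Mead",
               control = list(reltol = tol * 1e-4, maxit = 1000))
  # one restart polishes the simplex near the optimum
  opt <- optim(opt$par, f, method = "Nelder-Mead",
               control = list(reltol = tol * 1e-4, maxit = 1000))
  if (!all(is.finite(opt$par)) || !is.finite(opt$value))
    stop("numerical error: characteristic-curve optimizer returned ",
         "non-finite values (method ", method, ")", call. = FALSE)
  best <- if (opt$value <= f(p0)) opt$par else p0
  new_equating_coef(best[1], best[2], method, nrow(pairs),
                    loss = f(best))
}

#' Haebara (item response function) equating coefficients
#'
#' Minimizes the quadrature-weighted sum over anchors of squared differences
#' between target-estimated ICCs and source ICCs mapped onto the target scale.
#' Nelder-Mead, warm-started at the mean-mean solution, with the slope
#' constrained away from zero (`A > 1e-3`).
#'
#' @inheritParams ms_coefficients
#' @param grid integration grid from [quadrature_grid()].
#' @param init optional starting `equating_coef` (default: mean-mean).
#' @return an `equating_coef` (with the achieved loss in `$loss`).
#' @export
irf_coefficients <- function(pairs, grid = quadrature_grid(), init = NULL) {
  cc_coefficients(pairs, grid, init, "item", "IRF")
}

#' Stocking-Lord (test response function) equating coefficients
#'
#' As [irf_coefficients()], but the square sits outside the sum over anchors:
#' the criterion compares test characteristic curves. With a single anchor the
#' two criteria coincide.
#'
#' @inheritParams irf_coefficients
#' @return an `equating_coef`.
#' @export
trf_coefficients <- function(pairs, grid = quadrature_grid(), init = NULL) {
  cc_coefficients(pairs, grid, init, "test", "TRF")
}

#' Compute equating coefficients by a named method
#'
#' @inheritParams irf_coefficients
#' @param method one of `"MS"`, `"MM"`, `"MGM"`, `"IRF"`, `"TRF"`.
#' @return an `equating_coef`.
#' @export
equate_anchors <- function(pairs, method = c("MM", "MS", "MGM", "IRF", "TRF"),
                           grid = quadrature_grid(), init = NULL) {
  method <- match.arg(method)
  switch(method,
         MS = ms_coefficients(pairs),
         MM = mm_coefficients(pairs),
         MGM = mgm_coefficients(pairs),
         IRF = irf_coefficients(pairs, grid, init),
         TRF = trf_coefficients(pairs, grid, init))
}

#' Transform item parameters onto the target scale
#'
#' `b' = A b + B`, `a' = a / A`; the guessing parameter is scale-invariant.
#'
#' @param items data.frame with `a`, `b` (and optionally `c`) columns.
#' @param coef an `equating_coef` (or list with `A`, `B`).
#' @return `items` with transformed `a` and `b`.
#' @export
transform_items <- function(items, coef) {
  stopifnot(is.finite(coef$A), coef$A > 0, is.finite(coef$B))
  items$a <- items$a / coef$A
  items$b <- coef$A * items$b + coef$B
  items
}

#' Transform ability values onto the target scale
#'
#' `theta' = A theta + B`; together with [transform_items()] this leaves the
#' response probability invariant: `icc(theta', item') = icc(theta, item)`.
#'
#' @param theta numeric vector of abilities.
#' @inheritParams transform_items
#' @return transformed abilities.
#' @export
transform_theta <- function(theta, coef) {
  stopifnot(is.finite(coef$A), coef$A > 0, is.finite(coef$B))
  coef$A * theta + coef$B
}

#' Invert an equating transformation
#'
#' @inheritParams transform_items
#' @return the `equating_coef` of the inverse map `(1/A, -B/A)`.
#' @export
invert_coef <- function(coef) {
  new_equating_coef(1 / coef$A, -coef$B / coef$A,
                    paste0(coef$method, "^-1"), coef$n_anchors,
                    coef$target_form, coef$source_form)
}

#' Compose equating coefficients along a chain
#'
#' Functional composition of the linear maps, applied left to right: the
#' target scale of each link must be the source scale of the next. For two
#' links `A_c = A_12 * A_23` and `B_c = A_23 * B_12 + B_23`.
#'
#' @param ... `equating_coef` objects (or a single list of them), in chain
#'   order.
#' @return the composed `equating_coef` (method tag `"chain"`).
#' @export
chain_compose <- function(...) {
  links <- list(...)
  if (length(links) == 1L && !inherits(links[[1]], "equating_coef"))
    links <- links[[1]]
  if (length(links) == 0) stop("empty chain", call. = FALSE)
  if (length(links) == 1L) return(links[[1]])
  A <- 1; B <- 0
  sf <- links[[1]]$source_form
  for (k in seq_along(links)) {
    lk <- links[[k]]
    if (k > 1) {
      prev <- links[[k - 1]]
      if (!is.na(prev$target_form) && !is.na(lk$source_form) &&
          prev$target_form != lk$source_form)
        stop("broken chain: link ", k, " does not start at the previous ",
             "link's target form", call. = FALSE)
    }
    B <- lk$A * B + lk$B
    A <- A * lk$A
  }
  n <- min(vapply(links, function(l) l$n_anchors, integer(1)))
  new_equating_coef(A, B, "chain", n, sf,
                    links[[length(links)]]$target_form)
}
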