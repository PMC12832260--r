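# Item containers, item characteristic curves and Bernoulli response
# simulation for the 1PL/2PL/3PL logistic models.

#' Item characteristic curve probability
#'
#' Probability of a correct response under the logistic IRT models
#' \deqn{p(\theta) = c + (1 - c)\,\frac{\exp[a(\theta - b)]}{1 + \exp[a(\theta - b)]}.}
#' Under `model = "1PL"` the discrimination is forced to 1; under `"1PL"` and
#' `"2PL"` the lower asymptote is forced to 0, so `p` is the plain logistic in
#' those cases.
#'
#' @param theta ability value(s) on the logit scale; must be finite.
#' @param a discrimination (> 0), recycled against `theta`.
#' @param b difficulty on the logit scale.
#' @param c guessing probability in `[0, 1)` (lower asymptote).
#' @param model one of `"2PL"`, `"3PL"`, `"1PL"`.
#' @return numeric vector of probabilities, strictly inside `(c, 1)`.
#' @examples
#' icc_prob(0, a = 1.2, b = 0.5)           # 2PL
#' icc_prob(-4, a = 1, b = 0, c = 0.25, model = "3PL")
#' @export
icc_prob <- function(theta, a = 1, b = 0, c = 0, model = c("2PL", "3PL", "1PL")) {
  model <- match.arg(model)
  if (!is.numeric(theta) || length(theta) == 0L || any(!is.finite(theta)))
    stop("`theta` must be finite numeric", call. = FALSE)
  if (model == "1PL") a <- 1
  if (model != "3PL") c <- 0
  if (any(!is.finite(a)) || any(a <= 0))
    stop("discrimination `a` must be finite and > 0", call. = FALSE)
  if (any(!is.finite(b)))
    stop("difficulty `b` must be finite", call. = FALSE)
  if (any(!is.finite(c)) || any(c < 0) || any(c >= 1))
    stop("guessing `c` must lie in [0, 1)", call. = FALSE)
  c + (1 - c) * plogis(a * (theta - b))
}

# Underlying normal parameters of a log-normal with given mean and sd of the
# variable itself (moment matching). sd = 0 collapses to a point mass.
lognormal_pars <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(list(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a three-form item bank linked by two anchor blocks
#'
#' Draws discriminations from a log-normal distribution parameterized by the
#' mean and SD of the discriminations themselves (moment-matched), and
#' difficulties from a normal distribution. All items share the guessing
#' probability `c` of the scenario. Forms 1 and 2 share `n_anchor` items
#' (block `"link12"`), forms 2 and 3 share `n_anchor` further items
#' (`"link23"`); no item is shared between forms 1 and 3.
#'
#' @param tss items per form (test set size).
#' @param n_anchor anchor items per link; must satisfy
#'   `1 <= n_anchor <= floor(tss / 2)` so form 2 can host both blocks.
#' @param a_mean,a_sd mean and SD of the discrimination distribution.
#' @param b_mean,b_sd mean and SD of the difficulty distribution.
#' @param c common guessing probability in `[0, 1)`.
#' @param seed optional RNG seed; the ambient stream is left untouched.
#' @return an object of class `item_bank`: a list with elements `items`
#'   (data.frame with `item_id`, `a`, `b`, `c`, `anchor_block`, `forms`),
#'   `tss` and `n_anchor`. The bank holds `3 * tss - 2 * n_anchor` distinct
#'   items.
#' @export
generate_item_bank <- function(tss, n_anchor, a_mean = 1, a_sd = 0.2,
                               b_mean = 0, b_sd = 1, c = 0, seed = NULL) {
  stopifnot(length(tss) == 1L, tss >= 2, tss == round(tss),
            length(n_anchor) == 1L, n_anchor == round(n_anchor))
  if (n_anchor < 1 || n_anchor > floor(tss / 2))
    stop("design error: `n_anchor` must lie in [1, floor(tss/2)] ",
         "(form 2 hosts both anchor blocks)", call. = FALSE)
  if (c < 0 || c >= 1) stop("guessing `c` must lie in [0, 1)", call. = FALSE)
  n_items <- 3 * tss - 2 * n_anchor
  lp <- lognormal_pars(a_mean, a_sd)
  draws <- with_seed(seed, {
    list(a = rlnorm(n_items, lp$meanlog, lp$sdlog),
         b = rnorm(n_items, b_mean, b_sd))
  })
  n_u <- tss - n_anchor      # unique items in forms 1 and 3
  n_u2 <- tss - 2 * n_anchor # unique items in form 2
  block <- c(rep("none", n_u), rep("link12", n_anchor), rep("none", n_u2),
             rep("link23", n_anchor), rep("none", n_u))
  # "|" keeps multi-form membership CSV-safe without quoting
  forms <- c(rep("1", n_u), rep("1|2", n_anchor), rep("2", n_u2),
             rep("2|3", n_anchor), rep("3", n_u))
  items <- data.frame(
    item_id = sprintf("i%04d", seq_len(n_items)),
    a = draws$a, b = draws$b, c = c,
    anchor_block = block, forms = forms,
    stringsAsFactors = FALSE
  )
  structure(list(items = items, tss = as.integer(tss),
                 n_anchor = as.integer(n_anchor)),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> 3 forms x %d items, %d anchors per link, %d distinct items\n",
              x$tss, x$n_anchor, nrow(x$items)))
  invisible(x)
}

#' Items administered in one form, in administration order
#'
#' Form 1 is its unique items followed by the `link12` block; form 2 is
#' `link12`, its unique items, then `link23`; form 3 is `link23` followed by
#' its unique items.
#'
#' @param bank an `item_bank`.
#' @param form form index in `{1, 2, 3}`.
#' @return data.frame of item parameters (one row per item).
#' @export
form_items <- function(bank, form) {
  stopifnot(inherits(bank, "item_bank"), form %in% 1:3)
  it <- bank$items
  sel <- vapply(strsplit(it$forms, "|", fixed = TRUE),
                function(f) as.character(form) %in% f, logical(1))
  out <- it[sel, , drop = FALSE]
  stopifnot(nrow(out) == bank$tss)
  rownames(out) <- NULL
  out
}

#' Draw an ability sample for one form
#'
#' @param n sample size (>= 1).
#' @param mu,sigma mean and SD of the generating normal distribution
#'   (`sigma > 0`).
#' @param form form index the sample takes.
#' @param seed optional RNG seed.
#' @return an object of class `ability_sample`: list with `person_id`,
#'   `theta`, `form`, `mu`, `sigma`.
#' @export
generate_abilities <- function(n, mu, sigma, form = 1L, seed = NULL) {
  stopifnot(n >= 1, n == round(n), is.finite(mu), sigma > 0)
  theta <- with_seed(seed, rnorm(n, mu, sigma))
  structure(list(person_id = sprintf("f%d_p%05d", form, seq_len(n)),
                 theta = theta, form = as.integer(form),
                 mu = mu, sigma = sigma),
            class = "ability_sample")
}

#' @export
print.ability_sample <- function(x, ...) {
  cat(sprintf("<ability_sample> form %d, n = %d, generating N(%.2f, %.2f^2)\n",
              x$form, length(x$theta), x$mu, x$sigma))
  invisible(x)
}

#' Simulate binary item responses
#'
#' Independent Bernoulli draws with success probabilities from the item
#' characteristic curves. Generation always honors the items' guessing
#' parameters: requesting `model = "2PL"` for items with `c > 0` is an error
#' (the 2PL-vs-3PL distinction belongs to calibration, not generation).
#'
#' @param abilities an `ability_sample`.
#' @param items data.frame of item parameters (`item_id`, `a`, `b`, `c`),
#'   e.g. from [form_items()].
#' @param model `"2PL"` or `"3PL"`.
#' @param seed optional RNG seed.
#' @return integer matrix persons x items of 0/1 with person/item dimnames.
#' @export
simulate_responses <- function(abilities, items, model = c("3PL", "2PL"),
                               seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(abilities, "ability_sample"), nrow(items) >= 1)
  if (model == "2PL" && any(items$c > 0))
    stop("validation error: items carry c > 0 but model \"2PL\" was requested; ",
         "generation always honors c", call. = FALSE)
  theta <- abilities$theta
  p <- vapply(seq_len(nrow(items)), function(i) {
    icc_prob(theta, items$a[i], items$b[i], items$c[i], model = "3PL")
  }, numeric(length(theta)))
  p <- matrix(p, nrow = length(theta))
  x <- with_seed(seed, {
    matrix(as.integer(runif(length(p)) < p), nrow = nrow(p))
  })
  dimnames(x) <- list(abilities$person_id, items$item_id)
  x
}
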