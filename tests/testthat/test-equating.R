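test_that("mean-sigma coefficients match hand computation", {
  pairs <- data.frame(item_id = c("a1", "a2", "a3"),
                      a_source = c(1, 1, 1), b_source = c(-1, 0, 1),
                      c_source = 0,
                      a_target = c(1, 1, 1), b_target = c(-1, 1, 3),
                      c_target = 0)
  co <- ms_coefficients(pairs) # SDs 1 and 2, means 0 and 1
  expect_equal(co$A, 2)
  expect_equal(co$B, 1)
  expect_equal(co$n_anchors, 3L)

  id <- ms_coefficients(identity_pairs())
  expect_equal(id$A, 1); expect_equal(id$B, 0)

  shift <- identity_pairs()
  shift$b_target <- shift$b_source + 5
  co5 <- ms_coefficients(shift)
  expect_equal(co5$A, 1); expect_equal(co5$B, 5)

  expect_error(ms_coefficients(identity_pairs(1)), "method-inapplicable")
  flat <- identity_pairs(3); flat$b_source <- 0; flat$b_target <- 0
  expect_error(ms_coefficients(flat), "degenerate-anchor")
})

test_that("mean-mean coefficients match the summary formula", {
  pairs <- data.frame(item_id = c("a1", "a2", "a3"),
                      a_source = c(0.8, 1.0, 1.2), b_source = c(-1, 0, 1),
                      c_source = 0,
                      a_target = c(0.4, 0.5, 0.6), b_target = c(-1, 1, 3),
                      c_target = 0)
  co <- mm_coefficients(pairs) # sum ratio 3.0 / 1.5
  expect_equal(co$A, 2)
  expect_equal(co$B, 1)
  expect_equal(co$B, mean(pairs$b_target) - co$A * mean(pairs$b_source))

  one <- data.frame(item_id = "a1", a_source = 2, b_source = 0, c_source = 0,
                    a_target = 1, b_target = 1, c_target = 0)
  co1 <- mm_coefficients(one)
  expect_equal(co1$A, 2); expect_equal(co1$B, 1)

  id <- mm_coefficients(identity_pairs())
  expect_equal(id$A, 1); expect_equal(id$B, 0)

  bad <- identity_pairs(); bad$a_source[1] <- -1
  expect_error(mm_coefficients(bad), "validation error")
})

test_that("mean-geometric-mean slope is the geometric mean of ratios", {
  p <- identity_pairs(3)
  p$a_source <- p$a_target * 2
  expect_equal(mgm_coefficients(p)$A, 2)
  p2 <- identity_pairs(2)
  p2$a_source <- p2$a_target * c(1, 4)
  expect_equal(mgm_coefficients(p2)$A, 2) # sqrt(1 * 4)
  id <- mgm_coefficients(identity_pairs())
  expect_equal(id$A, 1); expect_equal(id$B, 0)
})

test_that("characteristic-curve methods recover planted coefficients", {
  grid <- quadrature_grid()
  for (fn in list(irf_coefficients, trf_coefficients)) {
    pl <- planted_pairs(A = 2, B = 1, c = 0.15)
    co <- fn(pl, grid)
    expect_equal(co$A, 2, tolerance = 1e-4)
    expect_equal(co$B, 1, tolerance = 1e-4)
    expect_lt(co$loss, 1e-10)
    id <- fn(identity_pairs(), grid)
    expect_equal(id$A, 1, tolerance = 1e-4)
    expect_equal(id$B, 0, tolerance = 1e-4)
  }
  # basin of attraction: a perturbed warm start converges back to truth
  pl <- planted_pairs(A = 2, B = 1)
  init <- structure(list(A = 2.1, B = 1.1, method = "init", n_anchors = 5L,
                         source_form = NA, target_form = NA),
                    class = "equating_coef")
  co <- irf_coefficients(pl, quadrature_grid(), init = init)
  expect_equal(co$A, 2, tolerance = 1e-4)
  expect_equal(co$B, 1, tolerance = 1e-4)
})

test_that("IRF and TRF coincide for a single anchor", {
  one <- planted_pairs(A = 1.3, B = -0.4, l = 3, seed = 5)[2, ]
  one$b_target <- one$b_target + 0.3 # make the loss nonzero
  grid <- quadrature_grid()
  a <- irf_coefficients(one, grid)
  b <- trf_coefficients(one, grid)
  expect_equal(a$A, b$A, tolerance = 1e-6)
  expect_equal(a$B, b$B, tolerance = 1e-6)
})

test_that("all five methods are exact on noiseless linear anchor sets", {
  for (seed in 1:5) {
    A <- exp(runif(1, -0.5, 0.5)); B <- runif(1, -1, 1)
    pl <- planted_pairs(A = A, B = B, l = 6, seed = seed)
    for (m in c("MS", "MM", "MGM", "IRF", "TRF")) {
      co <- equate_anchors(pl, m)
      expect_equal(co$A, A, tolerance = 1e-4)
      expect_equal(co$B, B, tolerance = 1e-4)
    }
  }
})

test_that("parameter and ability transforms are consistent inverses", {
  co <- structure(list(A = 2, B = 1, method = "MM", n_anchors = 3L,
                       source_form = 1L, target_form = 2L),
                  class = "equating_coef")
  it <- data.frame(item_id = "i1", a = 1.2, b = 0.5, c = 0.2)
  tr <- transform_items(it, co)
  expect_equal(tr$a, 0.6)
  expect_equal(tr$b, 2.0)
  expect_equal(tr$c, 0.2) # guessing is scale-invariant

  idc <- structure(list(A = 1, B = 0), class = "equating_coef")
  expect_equal(transform_items(it, idc), it)

  back <- transform_items(tr, invert_coef(co))
  expect_equal(back$a, it$a, tolerance = 1e-12)
  expect_equal(back$b, it$b, tolerance = 1e-12)

  expect_equal(transform_theta(0.5, co), 2.0)
  # ICC invariance on a grid
  th <- seq(-3, 3, by = 0.5)
  p0 <- icc_prob(th, it$a, it$b, it$c, "3PL")
  p1 <- icc_prob(transform_theta(th, co), tr$a, tr$b, tr$c, "3PL")
  expect_equal(p0, p1, tolerance = 1e-12)
})

test_that("chain composition equals sequential application", {
  mk <- function(A, B, sf = NA_integer_, tf = NA_integer_)
    structure(list(A = A, B = B, method = "x", n_anchors = 2L,
                   source_form = sf, target_form = tf),
              class = "equating_coef")
  co <- chain_compose(mk(2, 1), mk(0.5, -1))
  expect_equal(co$A, 1)
  expect_equal(co$B, -0.5)

  l1 <- mk(1.7, 0.3); l2 <- mk(0.8, -0.6); l3 <- mk(1.2, 0.15)
  b <- rnorm(5)
  seq_applied <- 1.2 * (0.8 * (1.7 * b + 0.3) - 0.6) + 0.15
  cc <- chain_compose(list(l1, l2, l3))
  expect_equal(cc$A * b + cc$B, seq_applied, tolerance = 1e-12)
  # associativity
  left <- chain_compose(chain_compose(l1, l2), l3)
  right <- chain_compose(l1, chain_compose(l2, l3))
  expect_equal(left$A, right$A, tolerance = 1e-12)
  expect_equal(left$B, right$B, tolerance = 1e-12)

  inv <- chain_compose(l1, invert_coef(l1))
  expect_equal(inv$A, 1, tolerance = 1e-12)
  expect_equal(inv$B, 0, tolerance = 1e-12)

  single <- chain_compose(l1)
  expect_equal(single$A, l1$A); expect_equal(single$B, l1$B)

  expect_error(chain_compose(mk(2, 1, 1L, 2L), mk(1, 0, 3L, 2L)),
               "broken chain")
})

test_that("method slopes agree across iterations on calibrated data", {
  # the five methods track the same transformation under sampling noise
  # the true slope is varied across iterations (source-sample SD 0.6-1.4),
  # so agreement means every method tracks the same transformation
  methods <- c("MS", "MM", "MGM", "IRF", "TRF")
  As <- matrix(NA_real_, 20, length(methods),
               dimnames = list(NULL, methods))
  grid <- quadrature_grid()
  sds <- seq(0.6, 1.4, length.out = nrow(As))
  for (i in seq_len(nrow(As))) {
    bank <- generate_item_bank(40, 10, c = 0, seed = 300 + i)
    anchors <- bank$items$item_id[bank$items$anchor_block == "link12"]
    ab1 <- generate_abilities(300, -0.2, sds[i], 1, seed = 400 + 2 * i)
    ab2 <- generate_abilities(300, 0, 1, 2, seed = 401 + 2 * i)
    fit1 <- fit_irt(simulate_responses(ab1, form_items(bank, 1),
                                       seed = 500 + 2 * i), "2PL")
    fit2 <- fit_irt(simulate_responses(ab2, form_items(bank, 2),
                                       seed = 501 + 2 * i), "2PL")
    pairs <- anchor_pairs(fit1, fit2, anchors)
    for (m in methods)
      As[i, m] <- equate_anchors(pairs, m, grid)$A
  }
  cm <- cor(As)
  expect_gt(min(cm), 0.9)
})
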