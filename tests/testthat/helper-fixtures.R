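# Shared fixtures: all built in code, no files.

# anchor pairs whose two sides are exactly linearly related by (A, B):
# a_target = a_source / A, b_target = A * b_source + B, equal c.
planted_pairs <- function(A = 2, B = 1, l = 5, c = 0, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    a <- exp(rnorm(l, 0, 0.2))
    b <- rnorm(l)
  })
  data.frame(item_id = sprintf("a%02d", seq_len(l)),
             a_source = a, b_source = b, c_source = c,
             a_target = a / A, b_target = A * b + B, c_target = c,
             stringsAsFactors = FALSE)
}

# identical estimates on both sides (identity link)
identity_pairs <- function(l = 4) {
  a <- c(0.8, 1.1, 0.9, 1.3)[seq_len(l)]
  b <- c(-1, 0, 0.5, 1.2)[seq_len(l)]
  data.frame(item_id = sprintf("a%02d", seq_len(l)),
             a_source = a, b_source = b, c_source = 0,
             a_target = a, b_target = b, c_target = 0,
             stringsAsFactors = FALSE)
}

# one calibrated 2PL dataset reused across calibration tests
calibrated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bank <- generate_item_bank(40, 10, c = 0, seed = 42)
      f1 <- form_items(bank, 1)
      ab <- generate_abilities(1000, 0, 1, 1, seed = 7)
      x <- simulate_responses(ab, f1, seed = 8)
      cache <<- list(bank = bank, items = f1, abilities = ab,
                     responses = x, fit = fit_irt(x, "2PL"))
    }
    cache
  }
})
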