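specs <- example_specs()

test_that("same-or-adjacent constraints count disjoint period pairs", {
  expect_equal(nrow(constrain_same_adjacent(specs, include_within = TRUE)), 8L)
  cs <- constrain_same_adjacent(specs, include_within = FALSE)
  expect_equal(nrow(cs), 4L)
  expect_setequal(
    paste(cs$term_a, cs$term_b, sep = "~"),
    c(
      "weight:slope1~map:slope3", "weight:slope1~map:slope4",
      "weight:slope2~map:slope4", "weight:slope3~map:slope1"
    )
  )
  # a single response whose periods are all adjacent yields nothing
  expect_equal(nrow(constrain_same_adjacent(list(spline_spec("z", 0, 5, 10)))), 0L)
  # intercepts are never constrained
  all_cs <- constrain_same_adjacent(specs)
  expect_false(any(grepl("intercept", c(all_cs$term_a, all_cs$term_b))))
})

test_that("precedence constraints target subsequent periods of the other response", {
  expect_equal(nrow(constrain_precedence(specs, "map", "weight")), 3L)
  expect_equal(nrow(constrain_precedence(specs, "weight", "map")), 5L)
  one <- list(spline_spec("z", 0, numeric(), 10))
  expect_equal(nrow(constrain_precedence(one, "z", "z")), 0L)
  expect_error(constrain_precedence(specs, "bmi", "weight"), "bmi")
})

test_that("blocking one effect against a response counts that response's effects", {
  expect_equal(nrow(constrain_block(specs, "map:slope1", "weight")), 4L)
  cs <- constrain_block(specs, "map:slope1", "weight", include_intercept = FALSE)
  expect_equal(nrow(cs), 3L)
  expect_true(all(grepl("^weight:slope", setdiff(c(cs$term_a, cs$term_b), "map:slope1"))))
  # a response always carries at least one slope; with the intercept excluded
  # the count is exactly that response's slope count
  one_slope <- list(
    a = spline_spec("a", 0, 5, 10),
    b = spline_spec("b", 0, numeric(), 10)
  )
  expect_equal(
    nrow(constrain_block(one_slope, "a:slope1", "b", include_intercept = FALSE)),
    n_splines(one_slope$b)
  )
  expect_error(constrain_block(specs, "map:slope1", "map"), "differ")
})

test_that("lagged constraints keep associations beyond the lag free", {
  # saturating lag reduces to full precedence
  expect_warning(sat <- constrain_lag(specs, "weight", "map", 4), "saturates")
  expect_equal(
    tibble::as_tibble(sat)[],
    tibble::as_tibble(constrain_precedence(specs, "weight", "map"))[],
    ignore_attr = TRUE
  )
  cs <- constrain_lag(specs, "weight", "map", 1)
  expect_setequal(
    paste(cs$term_a, cs$term_b, sep = "~"),
    c("weight:slope1~map:slope2", "weight:slope2~map:slope3")
  )
  sym <- list(
    a = spline_spec("a", 0, 5, 10),
    b = spline_spec("b", 0, 5, 10)
  )
  expect_equal(nrow(constrain_lag(sym, "a", "b", 1)), 1L)
  expect_error(constrain_lag(specs, "weight", "map", 0))
})

test_that("constraint-set algebra holds over random spline geometries", {
  withr::with_seed(42, {
    for (rep in 1:15) {
      mk <- function(r) {
        nk <- sample(1:3, 1)
        spline_spec(r, 0, sort(sample(seq(1, 19), nk)), 20)
      }
      ss <- list(a = mk("a"), b = mk("b"))
      prec_ab <- constrain_precedence(ss, "a", "b")
      prec_ba <- constrain_precedence(ss, "b", "a")
      key <- function(cs) paste(cs$term_a, cs$term_b, sep = "~")
      for (d in 1:3) {
        lag_cs <- suppressWarnings(constrain_lag(ss, "a", "b", d))
        expect_true(all(key(lag_cs) %in% key(prec_ab)))
      }
      # each cross-response subsequent pair appears in exactly one direction
      expect_length(intersect(key(prec_ab), key(prec_ba)), 0L)
      # same-or-adjacent is symmetric in response order (pairs are unordered)
      ukey <- function(cs) {
        paste(pmin(cs$term_a, cs$term_b), pmax(cs$term_a, cs$term_b), sep = "~")
      }
      s1 <- constrain_same_adjacent(ss)
      s2 <- constrain_same_adjacent(rev(ss))
      expect_setequal(ukey(s1), ukey(s2))
    }
  })
})

test_that("constraint sets reject variances, unknown terms and duplicates", {
  expect_error(
    constrain_pairs(specs, data.frame(term_a = "map:slope1", term_b = "map:slope1")),
    "may not repeat"
  )
  expect_error(constrain_pairs(specs, "map:slope9~weight:slope1"), "unknown")
  cs <- constrain_pairs(specs, c(
    "weight:slope1~map:slope3", "map:slope3~weight:slope1"
  ))
  expect_equal(nrow(cs), 1L)
})

test_that("hypothesis configuration blocks compile to the same sets", {
  expect_equal(
    nrow(constraints_from_config(specs, list(type = "precedence", from = "map", to = "weight"))),
    3L
  )
  expect_equal(
    nrow(constraints_from_config(specs, list(
      type = "block", effect = "map:slope1", other_response = "weight"
    ))),
    4L
  )
  expect_error(constraints_from_config(specs, list(type = "nope")), "unknown hypothesis")
})

test_that("constraint cardinality equals the LRT degrees of freedom on a fitted pair", {
  sim <- simulate_growth(toy_gspec(n = 60, seed = 21))
  spec <- mlm_spec(toy_specs())
  full <- fit_mlm(sim$data, spec)
  cs <- constrain_precedence(toy_specs(), "y1", "y2")
  expect_gt(nrow(cs), 0L)
  restr <- fit_mlm(sim$data, spec, constraints = cs)
  out <- lrt(full, restr)
  expect_identical(out$df, nrow(cs))
  expect_gte(out$statistic, 0)
})
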