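test_that("round_percent rounds half-up as the published scores do", {
  expect_equal(round_percent(2, 7), 29)
  expect_equal(round_percent(5, 9), 56)
  expect_equal(round_percent(1, 2), 50)
  expect_equal(round_percent(0, 10), 0)
  expect_equal(round_percent(11, 11), 100)
  expect_error(round_percent(1, 0), "denominator")
  expect_error(round_percent(5, 4), "numerator")
})

test_that("engaged categories are those with any present slot", {
  all_on <- make_pattern(default_slots$slot_id)
  a <- assessment_from_pattern(all_on, default_tax)
  expect_equal(engaged_categories(a, default_tax),
               default_tax$categories$id)

  only_dairy <- make_pattern("dairy:nutrient_poor")
  expect_equal(engaged_categories(
    assessment_from_pattern(only_dairy, default_tax), default_tax),
    "dairy")

  two <- make_pattern(c("grain:nutritious", "beverages:nutrient_poor"))
  expect_equal(engaged_categories(
    assessment_from_pattern(two, default_tax), default_tax),
    c("grain", "beverages"))
})

test_that("worst and best cases score 100% and 0%", {
  worst <- make_pattern(
    default_slots$slot_id[default_slots$healthfulness == "nutrient_poor"])
  s <- score_assessment(assessment_from_pattern(worst, default_tax),
                        default_tax)
  expect_equal(c(s$numerator, s$denominator, s$percent), c(11, 11, 100))

  best <- make_pattern(
    default_slots$slot_id[default_slots$healthfulness == "nutritious"])
  s0 <- score_assessment(assessment_from_pattern(best, default_tax),
                         default_tax)
  expect_equal(c(s0$numerator, s0$denominator, s0$percent), c(0, 10, 0))

  sf <- score_assessment(assessment_from_pattern(worst, default_tax),
                         default_tax, mode = "fixed")
  expect_equal(c(sf$numerator, sf$denominator, sf$percent), c(11, 11, 100))
})

test_that("a narrow menu engaging one category is not advantaged", {
  # an ice-cream shop: only the dairy nutrient-poor slot present
  p <- make_pattern("dairy:nutrient_poor")
  s <- score_assessment(assessment_from_pattern(p, default_tax),
                        default_tax)
  expect_equal(c(s$numerator, s$denominator, s$percent), c(2, 2, 100))
  # under the initial fixed scheme the same menu looked mid-range
  sf <- score_assessment(assessment_from_pattern(p, default_tax),
                         default_tax, mode = "fixed")
  expect_equal(c(sf$numerator, sf$denominator), c(6, 11))
})

test_that("a three-paired-plus-beverages pattern scores 2/7 = 29%", {
  p <- make_pattern(c("vegetables:nutritious", "meat:nutritious",
                      "grain:nutritious", "grain:nutrient_poor",
                      "beverages:nutrient_poor"))
  s <- score_assessment(assessment_from_pattern(p, default_tax),
                        default_tax)
  expect_equal(c(s$numerator, s$denominator, s$percent), c(2, 7, 29))
})

test_that("zero engaged categories is an error, not a silent 0%", {
  empty <- make_pattern(character(0))
  a <- assessment_from_pattern(empty, default_tax)
  expect_error(score_assessment(a, default_tax), "engages no")
  # fixed mode still scores (all nutritious slots absent)
  sf <- score_assessment(a, default_tax, mode = "fixed")
  expect_equal(c(sf$numerator, sf$denominator), c(5, 11))
})

test_that("implementation matches the brute-force oracle over every
           pattern in both modes", {
  pats <- all_patterns(default_tax)
  for (mode in c("engaged", "fixed")) {
    got <- matrix(NA_integer_, nrow = length(pats), ncol = 3)
    want <- matrix(NA_integer_, nrow = length(pats), ncol = 3)
    for (i in seq_along(pats)) {
      p <- pats[[i]]
      ref <- oracle_score(p, default_tax, mode)
      a <- assessment_from_pattern(p, default_tax)
      if (mode == "engaged" && ref$denominator == 0) {
        expect_error(score_assessment(a, default_tax, mode))
        next
      }
      s <- score_assessment(a, default_tax, mode)
      got[i, ] <- c(s$numerator, s$denominator, s$percent)
      want[i, ] <- c(ref$numerator, ref$denominator,
                     as.integer(floor(100 * ref$numerator /
                                        ref$denominator + 0.5)))
    }
    expect_identical(got, want, info = mode)
  }
})

test_that("engaged denominator always decomposes as 2k + b", {
  for (p in random_patterns(100, default_tax, seed = 7)) {
    s <- score_assessment(assessment_from_pattern(p, default_tax),
                          default_tax)
    a <- assessment_from_pattern(p, default_tax)
    eng <- engaged_categories(a, default_tax)
    paired <- default_tax$categories$id[default_tax$categories$paired]
    k <- sum(eng %in% paired)
    b <- sum(!eng %in% paired)
    expect_equal(s$denominator, 2 * k + b)
    expect_true(s$denominator >= 1 && s$denominator <= 11)
    expect_true(s$numerator <= s$denominator)
    expect_true(s$percent >= 0 && s$percent <= 100)
  }
})

test_that("engaged-mode percent is monotone under slot changes", {
  pats <- random_patterns(60, default_tax, seed = 11)
  for (p in pats) {
    base <- score_assessment(assessment_from_pattern(p, default_tax),
                             default_tax)$percent
    for (sid in default_slots$slot_id) {
      if (p[[sid]]) next
      q <- p
      q[[sid]] <- TRUE
      alt <- score_assessment(assessment_from_pattern(q, default_tax),
                              default_tax)$percent
      if (default_slots$healthfulness[default_slots$slot_id == sid] ==
            "nutritious") {
        expect_lte(alt, base)
      } else {
        expect_gte(alt, base)
      }
    }
  }
})

test_that("scoring depends only on slot presence, not item multiplicity", {
  m1 <- tiny_menu(c("Cola", "Garlic bread"))
  m2 <- tiny_menu(c("Cola", "Lemonade", "Iced tea", "Garlic bread",
                    "Meat pie"))
  s1 <- score_assessment(assess_menu(m1, default_tax), default_tax)
  s2 <- score_assessment(assess_menu(m2, default_tax), default_tax)
  expect_equal(s1$numerator, s2$numerator)
  expect_equal(s1$denominator, s2$denominator)
  expect_equal(s1$percent, s2$percent)
})
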