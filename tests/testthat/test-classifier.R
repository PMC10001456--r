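test_that("cue rules place canonical items in their published groups", {
  cases <- list(
    list("garlic bread", "grain:nutrient_poor", "rule"),
    list("steamed dim sum", "grain:nutritious", "rule"),
    list("chicken parmigiana", "meat:nutrient_poor", "rule"),
    list("hot chips", "vegetables:nutrient_poor", "rule"),
    list("garden salad", "vegetables:nutritious", "rule"),
    list("fresh fruit salad", "fruit:nutritious", "rule"),
    list("ice cream sundae", "dairy:nutrient_poor", "rule"),
    list("flat white", "dairy:nutritious", "rule"),
    list("soft drink", "beverages:nutrient_poor", "rule"),
    list("grilled fish", "meat:nutritious", "rule")
  )
  for (cs in cases) {
    a <- classify_item(cs[[1]], default_tax)
    expect_equal(a$slot_id, cs[[2]], info = cs[[1]])
    expect_equal(a$basis, cs[[3]], info = cs[[1]])
    expect_gt(length(a$matched_cues), 0)
  }
})

test_that("risk default: a matched category without demonstrated
           healthfulness falls to the nutrient-poor slot", {
  a <- classify_item("beef burger", default_tax)
  expect_equal(a$slot_id, "grain:nutrient_poor")
  expect_equal(a$basis, "risk_default")
  # plain coffee: dairy category cue only
  b <- classify_item("coffee", default_tax)
  expect_equal(b$slot_id, "dairy:nutrient_poor")
  expect_equal(b$basis, "risk_default")
  # an exclude cue vetoes the nutritious group and drops to the default
  c1 <- classify_item("latte with caramel syrup", default_tax)
  expect_equal(c1$slot_id, "dairy:nutrient_poor")
  expect_equal(c1$basis, "risk_default")
  c2 <- classify_item("latte", default_tax)
  expect_equal(c2$slot_id, "dairy:nutritious")
  expect_equal(c2$basis, "rule")
})

test_that("wholly uncued items are unclassified, never guessed", {
  a <- classify_item("chef's surprise", default_tax)
  expect_equal(a$basis, "unclassified")
  expect_true(is.na(a$slot_id))
  expect_equal(length(a$matched_cues), 0)
})

test_that("grain-based mixed dishes take the grain category over their
           meat or vegetable components", {
  for (txt in c("beef burger", "chicken pizza", "pork sandwich",
                "lamb wrap", "salmon sushi", "chicken noodles")) {
    expect_equal(classify_item(txt, default_tax)$category_id, "grain",
                 info = txt)
  }
  # non-grain multi-category: longest matched cue wins
  a <- classify_item("chicken parmigiana with chips", default_tax)
  expect_equal(a$slot_id, "meat:nutrient_poor")
})

test_that("longer phrases suppress cues embedded in their span", {
  # "bread" (nutritious) must not fire inside "garlic bread"
  expect_equal(classify_item("garlic bread", default_tax)$slot_id,
               "grain:nutrient_poor")
  expect_equal(classify_item("sourdough bread", default_tax)$slot_id,
               "grain:nutritious")
  # "frozen yoghurt" (nutrient-poor) vs "yoghurt" (nutritious)
  expect_equal(classify_item("frozen yoghurt", default_tax)$slot_id,
               "dairy:nutrient_poor")
  expect_equal(classify_item("natural yoghurt", default_tax)$slot_id,
               "dairy:nutritious")
  # word boundaries: "cake" must not fire inside "cheesecake"
  expect_equal(classify_item("cheesecake", default_tax)$slot_id,
               "dairy:nutrient_poor")
})

test_that("classification is a pure function of text and taxonomy", {
  texts <- c("garlic bread", "beef burger", "latte", "chef's surprise")
  for (txt in texts) {
    expect_identical(classify_item(txt, default_tax),
                     classify_item(txt, default_tax))
  }
})

test_that("meal deals are one unit and any nutrient-poor component forces
           the nutrient-poor slot", {
  m <- mast_menu("o1", "fast_food_takeaway", items = tibble::tibble(
    name = "Burger meal",
    description = "burger + fries + soft drink",
    is_meal_deal = TRUE
  ))
  a <- classify_item(m$items, default_tax)
  expect_equal(a$slot_id, "grain:nutrient_poor")
  # only one slot engaged by the deal
  asm <- assess_menu(m, default_tax)
  expect_equal(sum(asm$slot_presence), 1)
})

test_that("assess_menu marks slots from eligible items with one evidence
           item each", {
  m <- tiny_menu(c("Garlic bread", "Steamed dim sum"))
  a <- assess_menu(m, default_tax)
  expect_true(a$slot_presence[["grain:nutrient_poor"]])
  expect_true(a$slot_presence[["grain:nutritious"]])
  expect_equal(sum(a$slot_presence), 2)
  expect_equal(sort(names(a$slot_presence)), sort(default_slots$slot_id))

  # duplicates: slot present once, evidence is the first item
  m2 <- tiny_menu(c("Cola", "Lemonade"))
  a2 <- assess_menu(m2, default_tax)
  expect_true(a2$slot_presence[["beverages:nutrient_poor"]])
  expect_equal(unname(a2$evidence[["beverages:nutrient_poor"]]),
               m2$items$item_id[1])

  # ineligible and unclassified items never reach a slot
  m3 <- mast_menu("o3", "restaurant", items = tibble::tibble(
    name = c("Garlic bread", "Mystery special", "Kids cola"),
    on_main_menu = c(TRUE, TRUE, FALSE)
  ))
  a3 <- assess_menu(m3, default_tax)
  expect_equal(sum(a3$slot_presence), 1)
  expect_equal(a3$unclassified_items, m3$items$item_id[2])
  expect_error(assess_menu(
    mast_menu("o4", "restaurant",
              items = tibble::tibble(name = "Kids cola",
                                     on_main_menu = FALSE)),
    default_tax), "eligible")
})

test_that("overrides are applied after rules and logged", {
  m <- tiny_menu(c("Garlic bread", "Mystery special"))
  ov <- tibble::tibble(outlet_id = "t1",
                       item_id = m$items$item_id,
                       slot = c("unclassified", "vegetables:nutritious"),
                       note = c("", ""))
  a <- assess_menu(m, default_tax, overrides = ov)
  expect_false(a$slot_presence[["grain:nutrient_poor"]])
  expect_true(a$slot_presence[["vegetables:nutritious"]])
  expect_equal(length(a$overrides_applied), 2)
  expect_true(m$items$item_id[1] %in% a$unclassified_items)
  expect_equal(a$assignments$basis[2], "override")
  # overrides for other outlets are ignored
  ov2 <- ov; ov2$outlet_id <- "someone-else"
  a2 <- assess_menu(m, default_tax, overrides = ov2)
  expect_true(a2$slot_presence[["grain:nutrient_poor"]])
  expect_error(
    assess_menu(m, default_tax,
                overrides = tibble::tibble(outlet_id = "t1",
                                           item_id = m$items$item_id[1],
                                           slot = "grain:delicious")),
    "unknown slot")
})

test_that("slot presence is invariant to item order and monotone in the
           item set", {
  names <- c("Garlic bread", "Steamed dim sum", "Cola", "Flat white",
             "Garden salad")
  base <- assess_menu(tiny_menu(names), default_tax)
  perm <- assess_menu(tiny_menu(rev(names)), default_tax)
  expect_equal(perm$slot_presence, base$slot_presence)
  # adding items never flips a slot from present to absent
  bigger <- assess_menu(tiny_menu(c(names, "Ice cream", "Fresh fruit")),
                        default_tax)
  expect_true(all(bigger$slot_presence[base$slot_presence]))
})
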