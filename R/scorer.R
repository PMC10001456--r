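#' Round a penalty fraction to an integer percentage
#'
#' Half-up rounding of `100 * numerator / denominator`, matching how the
#' published pilot scores are printed (2/7 -> 29, 5/9 -> 56, 1/2 -> 50).
#'
#' @param numerator Integer penalty points, `0 <= numerator <= denominator`.
#' @param denominator Positive integer.
#' @return Integer percent in 0..100.
#' @export
round_percent <- function(numerator, denominator) {
  if (any(denominator < 1)) {
    stop("denominator must be >= 1", call. = FALSE)
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  as.integer(floor(100 * numerator / denominator + 0.5))
}

#' Categories engaged by an assessment
#'
#' A category is engaged when at least one of its slots (nutrient-poor or
#' nutritious) is marked present on the menu. Only engaged categories
#' contribute penalty points and denominator under the final scoring
#' scheme, so an outlet selling nothing assessable in a category is
#' neither penalised nor credited for it.
#'
#' @param assessment A `mast_assessment`.
#' @param taxonomy A `mast_taxonomy`.
#' @return Character vector of engaged category ids (taxonomy order).
#' @export
engaged_categories <- function(assessment, taxonomy) {
  stopifnot(inherits(assessment, "mast_assessment"),
            inherits(taxonomy, "mast_taxonomy"))
  slots <- mast_slots(taxonomy)
  present <- assessment$slot_presence[slots$slot_id]
  engaged <- unique(slots$category_id[present])
  taxonomy$categories$id[taxonomy$categories$id %in% engaged]
}

#' Score an assessed menu
#'
#' Penalty points: +1 for each nutrient-poor food category available on
#' the menu, and +1 for each paired category whose corresponding
#' nutritious slot is absent. The score is the penalty total divided by a
#' denominator, times 100, rounded half-up to an integer percent. 0% is
#' the best case (only nutritious groups present), 100% the worst (no
#' nutritious groups present).
#'
#' Two denominator schemes are supported:
#' * `"engaged"` (the final scheme, default): both penalties and
#'   denominator run over engaged categories only — the denominator is the
#'   number of available slots among engaged categories (2 per paired
#'   category, 1 for the unpaired beverages category). This removes the
#'   advantage narrow menus (e.g. an ice-cream shop engaging a single
#'   category) would otherwise enjoy over diverse menus.
#' * `"fixed"` (the initial scheme): penalties over all categories with a
#'   constant denominator of 11 (the full slot count).
#'
#' @param assessment A `mast_assessment`.
#' @param taxonomy A `mast_taxonomy`.
#' @param mode `"engaged"` or `"fixed"`.
#' @return A `mast_score`: list with integer `numerator`, `denominator`,
#'   `percent` and the `mode`, plus outlet metadata.
#' @examples
#' tax <- load_taxonomy()
#' slots <- mast_slots(tax)
#' worst <- setNames(slots$healthfulness == "nutrient_poor", slots$slot_id)
#' a <- assessment_from_pattern(worst, tax)
#' score_assessment(a, tax)$percent  # 100
#' @export
score_assessment <- function(assessment, taxonomy,
                             mode = c("engaged", "fixed")) {
  stopifnot(inherits(assessment, "mast_assessment"),
            inherits(taxonomy, "mast_taxonomy"))
  mode <- match.arg(mode)
  slots <- mast_slots(taxonomy)
  present <- assessment$slot_presence[slots$slot_id]

  cat_ids <- taxonomy$categories$id
  np_present <- vapply(cat_ids, function(cid) {
    any(present[slots$category_id == cid &
                  slots$healthfulness == "nutrient_poor"])
  }, logical(1))
  has_nutritious_slot <- vapply(cat_ids, function(cid) {
    any(slots$category_id == cid & slots$healthfulness == "nutritious")
  }, logical(1))
  nu_present <- vapply(cat_ids, function(cid) {
    any(present[slots$category_id == cid &
                  slots$healthfulness == "nutritious"])
  }, logical(1))
  engaged <- np_present | nu_present

  if (mode == "engaged") {
    if (!any(engaged)) {
      stop("menu '", assessment$outlet_id,
           "' engages no food category; it cannot be scored ",
           "(a 0% score means best-case, not unassessable)", call. = FALSE)
    }
    numerator <- sum(np_present[engaged]) +
      sum(has_nutritious_slot[engaged] & !nu_present[engaged])
    denominator <- sum(ifelse(has_nutritious_slot[engaged], 2L, 1L))
  } else {
    numerator <- sum(np_present) +
      sum(has_nutritious_slot & !nu_present)
    denominator <- nrow(slots)
  }

  structure(
    list(outlet_id = assessment$outlet_id,
         outlet_type = assessment$outlet_type,
         numerator = as.integer(numerator),
         denominator = as.integer(denominator),
         percent = round_percent(numerator, denominator),
         mode = mode),
    class = "mast_score"
  )
}

#' @export
print.mast_score <- function(x, ...) {
  cat("<mast_score '", x$outlet_id, "'> ", x$numerator, "/",
      x$denominator, " = ", x$percent, "% (", x$mode, " mode)\n",
      sep = "")
  invisible(x)
}

#' Collect scores into a tibble
#'
#' @param scores A list of `mast_score` objects (or a single one).
#' @return A tibble with columns `outlet_id`, `outlet_type`, `mode`,
#'   `numerator`, `denominator`, `percent` (the fixed column order of the
#'   scores CSV).
#' @export
scores_table <- function(scores) {
  if (inherits(scores, "mast_score")) scores <- list(scores)
  dplyr::bind_rows(lapply(scores, function(s) {
    tibble(outlet_id = s$outlet_id, outlet_type = s$outlet_type,
           mode = s$mode, numerator = s$numerator,
           denominator = s$denominator, percent = s$percent)
  }))
}
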