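#' Classify a single menu item into a taxonomy slot
#'
#' Deterministic cue-lexicon classification implementing the risk-based
#' coding rules:
#'
#' 1. All cue phrases (group `include_cues` plus category-level neutral
#'    cues) are matched case-insensitively on whole words, tolerant of
#'    plural `s`/`es`. Longer phrases win: a shorter cue wholly contained
#'    in the span of a longer match is suppressed (so "garlic bread" never
#'    also counts as "bread").
#' 2. A group's `exclude_cues`, matched anywhere in the text, veto that
#'    group's matches; the vetoed match still counts as evidence for the
#'    category (and thus feeds the risk default).
#' 3. When cues from several categories match, the major-ingredient rule
#'    decides: grain-based mixed dishes (burger, pizza, sandwich, wrap,
#'    sushi, pasta, noodles, ...) take the grain category over their meat
#'    or vegetable components; otherwise the category with the longest
#'    matched cue wins, ties resolved by category order.
#' 4. Within the winning category, a nutrient-poor group match takes
#'    precedence (risk principle); a nutritious group match without any
#'    nutrient-poor match demonstrates the nutritious slot; neutral or
#'    vetoed matches alone fall to the nutrient-poor slot with basis
#'    `risk_default` — items are assumed nutrient-poor unless the text
#'    demonstrates otherwise.
#' 5. No cue at all gives basis `unclassified` and no slot.
#'
#' Meal deals are assessed as one unit: the slot category comes from the
#' major component as above, and any nutrient-poor cue anywhere in the
#' deal text forces the nutrient-poor slot.
#'
#' @param item A one-row item tibble from a `mast_menu` (normalised), or a
#'   character string which is taken as the item text.
#' @param taxonomy A `mast_taxonomy`.
#' @return An assignment: a list with `item_id`, `slot_id` (or `NA`),
#'   `category_id`, `healthfulness`, `group_id` (or `NA`), `matched_cues`
#'   and `basis` (`"rule"`, `"risk_default"` or `"unclassified"`).
#' @examples
#' tax <- load_taxonomy()
#' classify_item("garlic bread", tax)$slot_id       # grain:nutrient_poor
#' classify_item("steamed dim sum", tax)$slot_id    # grain:nutritious
#' classify_item("beef burger", tax)$basis          # risk_default
#' @export
classify_item <- function(item, taxonomy) {
  stopifnot(inherits(taxonomy, "mast_taxonomy"))
  if (is.character(item)) {
    item <- normalise_items(as_menu_items(tibble(name = item)))
  }
  text <- item$class_text[1]
  item_id <- item$item_id[1]
  is_deal <- isTRUE(item$is_meal_deal[1])

  matches <- match_cues(text, taxonomy)
  if (nrow(matches) == 0) {
    return(assignment(item_id, slot_id = NA_character_,
                      category_id = NA_character_,
                      healthfulness = NA_character_,
                      group_id = NA_character_,
                      matched_cues = character(0), basis = "unclassified"))
  }

  kept <- suppress_overlaps(matches)

  # Exclude-cue veto: a vetoed group match is downgraded to neutral
  # category evidence.
  grps <- taxonomy$groups
  vetoed <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    gid <- kept$group_id[i]
    if (is.na(gid)) next
    excl <- grps$exclude_cues[[match(gid, grps$id)]]
    if (length(excl) > 0 && any(vapply(excl, function(e) {
      grepl(cue_regex(e), text, ignore.case = TRUE, perl = TRUE)
    }, logical(1)))) {
      vetoed[i] <- TRUE
    }
  }
  kept$group_id[vetoed] <- NA_character_
  kept$healthfulness[vetoed] <- NA_character_

  category_id <- choose_category(kept, taxonomy)
  in_cat <- kept[kept$category_id == category_id, , drop = FALSE]

  np_rows <- which(!is.na(in_cat$healthfulness) &
                     in_cat$healthfulness == "nutrient_poor")
  nu_rows <- which(!is.na(in_cat$healthfulness) &
                     in_cat$healthfulness == "nutritious")
  any_np_anywhere <- any(!is.na(kept$healthfulness) &
                           kept$healthfulness == "nutrient_poor")

  cat_slots <- mast_slots(taxonomy)
  cat_paired <- any(cat_slots$category_id == category_id &
                      cat_slots$healthfulness == "nutritious")

  pick <- function(rows) {
    r <- rows[order(-nchar(in_cat$cue[rows]))][1]
    in_cat[r, , drop = FALSE]
  }

  if (length(np_rows) > 0) {
    m <- pick(np_rows)
    assignment(item_id, paste0(category_id, ":nutrient_poor"), category_id,
               "nutrient_poor", m$group_id, kept$cue, "rule")
  } else if (is_deal && any_np_anywhere) {
    # risk principle for meal deals: any nutrient-poor component anywhere
    # drags the whole deal to the nutrient-poor slot of its category
    assignment(item_id, paste0(category_id, ":nutrient_poor"), category_id,
               "nutrient_poor", NA_character_, kept$cue, "rule")
  } else if (length(nu_rows) > 0 && cat_paired) {
    m <- pick(nu_rows)
    assignment(item_id, paste0(category_id, ":nutritious"), category_id,
               "nutritious", m$group_id, kept$cue, "rule")
  } else {
    # category matched but healthfulness not demonstrated -> risk default
    assignment(item_id, paste0(category_id, ":nutrient_poor"), category_id,
               "nutrient_poor", NA_character_, kept$cue, "risk_default")
  }
}

assignment <- function(item_id, slot_id, category_id, healthfulness,
                       group_id, matched_cues, basis) {
  list(item_id = item_id, slot_id = slot_id, category_id = category_id,
       healthfulness = healthfulness,
       group_id = if (length(group_id) == 0) NA_character_
                  else as.character(group_id),
       matched_cues = as.character(matched_cues), basis = basis)
}

# Whole-word, case-insensitive, plural-tolerant regex for a cue phrase.
cue_regex <- function(cue) {
  esc <- gsub("([][{}()|^$.*+?\\\\-])", "\\\\\\1", cue, perl = TRUE)
  # allow a plural s/es on the final word of the phrase
  paste0("(?<![A-Za-z])", esc, "(es|s)?(?![A-Za-z])")
}

# All cue matches of a taxonomy in `text`: one row per (cue, position).
match_cues <- function(text, taxonomy) {
  rows <- list()
  add_matches <- function(cue, category_id, group_id, healthfulness) {
    m <- gregexpr(cue_regex(cue), text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1) return()
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      rows[[length(rows) + 1L]] <<- tibble(
        cue = cue, category_id = category_id, group_id = group_id,
        healthfulness = healthfulness,
        start = as.integer(m[k]), end = as.integer(m[k]) + len[k] - 1L
      )
    }
  }
  grps <- taxonomy$groups
  for (i in seq_len(nrow(grps))) {
    for (cue in grps$include_cues[[i]]) {
      add_matches(cue, grps$category_id[i], grps$id[i],
                  grps$healthfulness[i])
    }
  }
  cats <- taxonomy$categories
  for (i in seq_len(nrow(cats))) {
    for (cue in cats$neutral_cues[[i]]) {
      add_matches(cue, cats$id[i], NA_character_, NA_character_)
    }
  }
  if (length(rows) == 0) {
    return(tibble(cue = character(0), category_id = character(0),
                  group_id = character(0), healthfulness = character(0),
                  start = integer(0), end = integer(0)))
  }
  dplyr::bind_rows(rows)
}

# Longest-phrase-first span suppression: keep a match only if its span does
# not overlap a longer match already kept. Ties broken by taxonomy order
# (the order rows were generated in), which is stable.
suppress_overlaps <- function(matches) {
  ord <- order(-(matches$end - matches$start))
  kept_idx <- integer(0)
  for (i in ord) {
    overlap <- FALSE
    for (j in kept_idx) {
      if (matches$start[i] <= matches$end[j] &&
          matches$end[i] >= matches$start[j]) {
        overlap <- TRUE
        break
      }
    }
    if (!overlap) kept_idx <- c(kept_idx, i)
  }
  matches[sort(kept_idx), , drop = FALSE]
}

# Category precedence: grain-major rule, then longest matched cue, then
# category order.
choose_category <- function(kept, taxonomy) {
  cands <- unique(kept$category_id)
  if (length(cands) == 1) return(cands)
  if ("grain" %in% cands) return("grain")
  best_len <- vapply(cands, function(cid) {
    max(nchar(kept$cue[kept$category_id == cid]))
  }, numeric(1))
  cands <- cands[best_len == max(best_len)]
  if (length(cands) > 1) {
    ord <- match(cands, taxonomy$categories$id)
    cands <- cands[which.min(ord)]
  }
  cands[1]
}

#' Assess a menu against a taxonomy
#'
#' Classifies every eligible item and records, for each of the taxonomy's
#' slots, whether at least one item engages it. Only one item per slot is
#' recorded as evidence (the first in menu order) — availability is
#' presence/absence, so additional items meeting the same definition do
#' not change the result. Manual overrides are applied after rule
#' classification and logged.
#'
#' @param menu A `mast_menu` with at least one eligible item.
#' @param taxonomy A `mast_taxonomy`.
#' @param overrides Optional overrides: a data.frame with columns
#'   `item_id`, `slot` (a slot id such as `"vegetables:nutritious"`, or
#'   `"unclassified"`) and optionally `outlet_id` (rows for other outlets
#'   are ignored) and `note`. See [read_overrides()].
#' @return A `mast_assessment`: outlet id/type, `slot_presence` (named
#'   logical over all slots), `evidence` (slot -> item id), `assignments`
#'   tibble, `overrides_applied` and `unclassified_items`.
#' @export
assess_menu <- function(menu, taxonomy, overrides = NULL) {
  stopifnot(inherits(menu, "mast_menu"), inherits(taxonomy, "mast_taxonomy"))
  items <- menu$items[menu$items$eligible, , drop = FALSE]
  if (nrow(items) == 0) {
    stop("menu '", menu$outlet_id, "' has no eligible items to assess",
         call. = FALSE)
  }
  slots <- mast_slots(taxonomy)

  assigns <- lapply(seq_len(nrow(items)), function(i) {
    classify_item(items[i, , drop = FALSE], taxonomy)
  })

  applied <- list()
  if (!is.null(overrides) && nrow(overrides) > 0) {
    ov <- as_tibble(overrides)
    if ("outlet_id" %in% names(ov)) {
      ov <- ov[ov$outlet_id == menu$outlet_id, , drop = FALSE]
    }
    for (i in seq_len(nrow(ov))) {
      idx <- which(items$item_id == ov$item_id[i])
      if (length(idx) == 0) next
      slot <- squish(ov$slot[i])
      if (identical(slot, "unclassified")) {
        assigns[[idx]] <- assignment(items$item_id[idx], NA_character_,
                                     NA_character_, NA_character_,
                                     NA_character_, character(0),
                                     "unclassified")
      } else {
        if (!slot %in% slots$slot_id) {
          stop("override for item '", ov$item_id[i],
               "' names unknown slot '", slot, "'", call. = FALSE)
        }
        parts <- strsplit(slot, ":", fixed = TRUE)[[1]]
        assigns[[idx]] <- assignment(items$item_id[idx], slot, parts[1],
                                     parts[2], NA_character_, character(0),
                                     "override")
      }
      applied[[length(applied) + 1L]] <- list(item_id = items$item_id[idx],
                                              slot = slot)
    }
  }

  slot_presence <- setNames(rep(FALSE, nrow(slots)), slots$slot_id)
  evidence <- setNames(rep(NA_character_, nrow(slots)), slots$slot_id)
  unclassified <- character(0)
  for (a in assigns) {
    if (is.na(a$slot_id)) {
      unclassified <- c(unclassified, a$item_id)
    } else {
      if (!slot_presence[[a$slot_id]]) {
        evidence[[a$slot_id]] <- a$item_id
      }
      slot_presence[[a$slot_id]] <- TRUE
    }
  }

  structure(
    list(
      outlet_id = menu$outlet_id,
      outlet_type = menu$outlet_type,
      slot_presence = slot_presence,
      evidence = evidence,
      assignments = dplyr::bind_rows(lapply(assigns, function(a) {
        tibble(item_id = a$item_id, slot_id = a$slot_id,
               group_id = a$group_id, basis = a$basis,
               matched_cues = paste(a$matched_cues, collapse = "; "))
      })),
      overrides_applied = applied,
      unclassified_items = unclassified
    ),
    class = "mast_assessment"
  )
}

#' Read a manual overrides file
#'
#' CSV with columns `outlet_id, item_id, slot, note`; `slot` is either a
#' slot id (`"category:healthfulness"`) or `"unclassified"`.
#'
#' @param path Path to the CSV.
#' @return A tibble of overrides.
#' @export
read_overrides <- function(path) {
  if (!file.exists(path)) stop("overrides file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("item_id", "slot")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("overrides file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_tibble(df)
}

#' Construct an assessment directly from a slot-presence pattern
#'
#' Used when slot presence is already known (e.g. coded by hand or
#' generated synthetically) and only scoring/reporting is needed.
#'
#' @param pattern Named logical vector over the taxonomy's slot ids.
#' @param taxonomy A `mast_taxonomy`.
#' @param outlet_id,outlet_type Outlet metadata carried into the result.
#' @return A `mast_assessment`.
#' @export
assessment_from_pattern <- function(pattern, taxonomy,
                                    outlet_id = "pattern",
                                    outlet_type = "other") {
  slots <- mast_slots(taxonomy)
  if (is.null(names(pattern)) || !setequal(names(pattern), slots$slot_id)) {
    stop("pattern must be a named logical over all ", nrow(slots),
         " slot ids of the taxonomy", call. = FALSE)
  }
  pattern <- as.logical(pattern[slots$slot_id])
  structure(
    list(outlet_id = outlet_id, outlet_type = outlet_type,
         slot_presence = setNames(pattern, slots$slot_id),
         evidence = setNames(rep(NA_character_, nrow(slots)),
                             slots$slot_id),
         assignments = tibble(item_id = character(0),
                              slot_id = character(0),
                              group_id = character(0),
                              basis = character(0),
                              matched_cues = character(0)),
         overrides_applied = list(),
         unclassified_items = character(0)),
    class = "mast_assessment"
  )
}

#' @export
print.mast_assessment <- function(x, ...) {
  cat("<mast_assessment '", x$outlet_id, "'>\n", sep = "")
  present <- names(x$slot_presence)[x$slot_presence]
  cat("  present slots: ",
      if (length(present)) paste(present, collapse = ", ") else "(none)",
      "\n", sep = "")
  if (length(x$unclassified_items)) {
    cat("  unclassified: ", paste(x$unclassified_items, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Serialise an assessment to JSON
#'
#' @param assessment A `mast_assessment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(assessment, path) {
  stopifnot(inherits(assessment, "mast_assessment"))
  obj <- list(
    outlet_id = assessment$outlet_id,
    outlet_type = assessment$outlet_type,
    slot_presence = as.list(assessment$slot_presence),
    evidence = as.list(assessment$evidence),
    overrides_applied = assessment$overrides_applied,
    unclassified_items = assessment$unclassified_items
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}
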