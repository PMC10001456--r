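#' Published pilot scores
#'
#' The (numerator, denominator, percent) triples and outlet classifications
#' published for the 30 food service outlets scored in the pilot of the
#' instrument (one Local Government Authority in Perth, Western Australia).
#' Used as the reference for end-to-end validation of the scoring pipeline.
#'
#' @return A tibble with columns `outlet`, `outlet_type`, `numerator`,
#'   `denominator`, `percent`.
#' @export
pilot_scores <- function() {
  ff <- "fast_food_takeaway"; cf <- "cafe_coffee_shop"
  rs <- "restaurant"; pb <- "pub_hotel_tavern"
  tibble(
    outlet = 1:30,
    outlet_type = c(ff, cf, ff, rs, cf, ff, ff, cf, pb, rs, rs, cf, pb, rs,
                    cf, pb, pb, ff, ff, ff, ff, ff, ff, ff, ff, ff, ff, ff,
                    ff, ff),
    numerator = c(2L, 4L, 2L, 3L, 5L, 5L, 5L, 4L, 4L, 4L, 4L, 7L, 7L, 6L,
                  7L, 7L, 7L, 4L, 9L, 6L, 6L, 6L, 10L, 10L, 10L, 9L, 9L,
                  11L, 9L, 11L),
    denominator = c(7L, 11L, 5L, 7L, 11L, 11L, 9L, 7L, 7L, 7L, 7L, 11L,
                    11L, 9L, 9L, 9L, 9L, 5L, 11L, 7L, 7L, 7L, 11L, 11L,
                    11L, 9L, 9L, 11L, 9L, 11L),
    percent = c(29L, 36L, 40L, 43L, 45L, 45L, 56L, 57L, 57L, 57L, 57L, 64L,
                64L, 67L, 78L, 78L, 78L, 80L, 82L, 86L, 86L, 86L, 91L, 91L,
                91L, 100L, 100L, 100L, 100L, 100L)
  )
}

#' Construct a slot-presence pattern scoring a given (numerator, denominator)
#'
#' Builds, deterministically for a given seed, a presence/absence pattern
#' over the taxonomy's slots whose engaged-mode score is exactly
#' `numerator / denominator`. Feasibility under the default taxonomy:
#' the denominator must decompose as `2k + b` with `k` engaged paired
#' categories (`k <= 5`) and `b` in `{0, 1}` for the unpaired beverages
#' category; `b <= numerator <= denominator` (an engaged beverages
#' category always contributes its penalty point).
#'
#' Construction is greedy: engage beverages when `b = 1` (+1 penalty),
#' then spread the remaining penalties over `k` paired categories as
#' either +2 (nutrient-poor present, nutritious absent), +1 (both slots
#' present) or +0 (nutritious only). The seed shuffles which categories
#' play which role.
#'
#' @param numerator,denominator Target integer score components.
#' @param seed Integer seed controlling which categories are engaged.
#' @param taxonomy A `mast_taxonomy` (default scheme by default).
#' @return Named logical vector over the taxonomy's slot ids.
#' @export
pattern_for <- function(numerator, denominator, seed = 1L,
                        taxonomy = load_taxonomy()) {
  slots <- mast_slots(taxonomy)
  paired_ids <- unique(slots$category_id[slots$healthfulness ==
                                           "nutritious"])
  unpaired_ids <- setdiff(unique(slots$category_id), paired_ids)

  if (denominator < 1 || numerator < 0) {
    stop("infeasible target: numerator and denominator must be ",
         "non-negative with denominator >= 1", call. = FALSE)
  }
  if (numerator > denominator) {
    stop("infeasible target: numerator ", numerator,
         " exceeds denominator ", denominator, call. = FALSE)
  }
  b <- denominator %% 2L
  k <- (denominator - b) %/% 2L
  if (b > length(unpaired_ids)) {
    stop("infeasible target: denominator ", denominator,
         " requires an unpaired category the taxonomy lacks",
         call. = FALSE)
  }
  if (k > length(paired_ids)) {
    stop("infeasible target: denominator ", denominator,
         " requires ", k, " paired categories but the taxonomy has ",
         length(paired_ids), call. = FALSE)
  }
  if (numerator < b) {
    stop("infeasible target: an engaged unpaired category always ",
         "contributes 1 penalty point, so numerator must be >= ", b,
         call. = FALSE)
  }

  rng <- local_rng(seed)
  engaged_paired <- rng$sample_vec(paired_ids, k)
  rem <- numerator - b
  n2 <- rem %/% 2L          # categories taking both penalties
  n1 <- rem %% 2L           # category taking one penalty
  stopifnot(n2 + n1 <= k)
  roles <- c(rep(2L, n2), rep(1L, n1), rep(0L, k - n2 - n1))

  pattern <- setNames(rep(FALSE, nrow(slots)), slots$slot_id)
  for (i in seq_along(engaged_paired)) {
    cid <- engaged_paired[i]
    if (roles[i] == 2L) {
      pattern[paste0(cid, ":nutrient_poor")] <- TRUE
    } else if (roles[i] == 1L) {
      pattern[paste0(cid, ":nutrient_poor")] <- TRUE
      pattern[paste0(cid, ":nutritious")] <- TRUE
    } else {
      pattern[paste0(cid, ":nutritious")] <- TRUE
    }
  }
  if (b == 1L) {
    pattern[paste0(unpaired_ids[1], ":nutrient_poor")] <- TRUE
  }
  pattern
}

# Seeded RNG scoped away from the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    f()
  }
  list(
    sample_vec = function(x, size = length(x)) {
      with_state(function() x[sample.int(length(x), size)])
    },
    sample_int = function(n, size = 1) {
      with_state(function() sample.int(n, size, replace = TRUE))
    }
  )
}

#' Pilot fixture: 30 outlets reproducing the published pilot scores
#'
#' Constructs one slot-presence pattern per published pilot outlet such
#' that engaged-mode scoring reproduces every printed (numerator,
#' denominator, percent) triple, with the printed outlet classifications.
#' The per-outlet menus were not published, so the patterns are a
#' consistent reconstruction, not the pilot's actual coding.
#'
#' @param taxonomy A `mast_taxonomy` (default scheme by default).
#' @param seed Base seed; outlet `i` uses `seed + i`.
#' @return A list of 30 entries, each a list with `outlet_id`,
#'   `outlet_type`, `numerator`, `denominator`, `percent` (the published
#'   targets) and `pattern` (named logical over the 11 slots).
#' @export
pilot_fixture <- function(taxonomy = load_taxonomy(), seed = 20230L) {
  ref <- pilot_scores()
  lapply(seq_len(nrow(ref)), function(i) {
    list(
      outlet_id = sprintf("outlet-%02d", ref$outlet[i]),
      outlet_type = ref$outlet_type[i],
      numerator = ref$numerator[i],
      denominator = ref$denominator[i],
      percent = ref$percent[i],
      pattern = pattern_for(ref$numerator[i], ref$denominator[i],
                            seed = seed + i, taxonomy = taxonomy)
    )
  })
}

#' Generate a concrete menu realising a slot-presence pattern
#'
#' Emits one menu item per present slot, drawn from that slot's cue
#' lexicon (e.g. "garlic bread" for the nutrient-poor grain slot), such
#' that `assess_menu(generate_menu(pattern))` reproduces the pattern
#' exactly. Only cue phrases that classify back to their own slot are
#' used; the choice among them is seeded and reproducible.
#'
#' @param pattern Named logical over the taxonomy's slot ids.
#' @param taxonomy A `mast_taxonomy`.
#' @param seed Integer seed for phrase choice.
#' @param outlet_id,outlet_type Metadata for the generated menu.
#' @return A `mast_menu`.
#' @export
generate_menu <- function(pattern, taxonomy = load_taxonomy(), seed = 1L,
                          outlet_id = "synthetic",
                          outlet_type = "other") {
  slots <- mast_slots(taxonomy)
  if (is.null(names(pattern)) || !setequal(names(pattern), slots$slot_id)) {
    stop("pattern must be a named logical over all ", nrow(slots),
         " slot ids", call. = FALSE)
  }
  rng <- local_rng(seed)
  vocab <- slot_vocabulary(taxonomy)
  present <- slots$slot_id[as.logical(pattern[slots$slot_id])]
  items <- lapply(present, function(sid) {
    phrases <- vocab[[sid]]
    if (length(phrases) == 0) {
      stop("slot '", sid, "' has no cue phrase that classifies back to ",
           "itself; cannot generate an item for it", call. = FALSE)
    }
    phrases[rng$sample_int(length(phrases))]
  })
  mast_menu(outlet_id, outlet_type,
            items = tibble(
              item_id = sprintf("%s-item-%02d", outlet_id,
                                seq_along(items)),
              section = "menu",
              name = unlist(items, use.names = FALSE) %||% character(0)
            ),
            source = "synthetic")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# Cue phrases per slot that provably classify back to that slot. Cached per
# taxonomy object within a session.
slot_vocabulary <- function(taxonomy) {
  key <- paste0("vocab-", digest_taxonomy(taxonomy))
  cached <- vocab_cache[[key]]
  if (!is.null(cached)) return(cached)
  slots <- mast_slots(taxonomy)
  grps <- taxonomy$groups
  vocab <- setNames(vector("list", nrow(slots)), slots$slot_id)
  for (i in seq_len(nrow(grps))) {
    sid <- paste0(grps$category_id[i], ":", grps$healthfulness[i])
    for (cue in grps$include_cues[[i]]) {
      a <- classify_item(cue, taxonomy)
      if (!is.na(a$slot_id) && a$slot_id == sid) {
        vocab[[sid]] <- c(vocab[[sid]], cue)
      }
    }
  }
  vocab_cache[[key]] <- vocab
  vocab
}

vocab_cache <- new.env(parent = emptyenv())

digest_taxonomy <- function(taxonomy) {
  # cheap structural fingerprint; avoids hashing dependencies
  paste(nrow(taxonomy$groups), nrow(taxonomy$categories),
        sum(nchar(unlist(taxonomy$groups$include_cues))),
        taxonomy$include_water, taxonomy$include_alcohol, sep = "-")
}

#' Random slot-presence patterns
#'
#' Uniformly samples presence/absence over the taxonomy's slots,
#' optionally requiring at least one engaged slot.
#'
#' @param n Number of patterns.
#' @param taxonomy A `mast_taxonomy`.
#' @param seed Integer seed.
#' @param nonempty Require at least one present slot (default `TRUE`).
#' @return A list of named logical vectors.
#' @export
random_patterns <- function(n, taxonomy = load_taxonomy(), seed = 1L,
                            nonempty = TRUE) {
  slots <- mast_slots(taxonomy)
  rng <- local_rng(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      p <- rng$sample_int(2L, nrow(slots)) == 1L
      if (!nonempty || any(p)) break
    }
    out[[i]] <- setNames(p, slots$slot_id)
  }
  out
}

#' Write the pilot fixture to disk
#'
#' Materialises the 30 reconstructed pilot outlets as menu CSVs plus an
#' expected-scores CSV, for end-to-end runs of the command-line pipeline.
#'
#' @param dir Output directory (created if needed).
#' @param taxonomy A `mast_taxonomy`.
#' @param seed Base seed passed to [pilot_fixture()] and
#'   [generate_menu()].
#' @return The directory, invisibly.
#' @export
write_pilot_fixture <- function(dir, taxonomy = load_taxonomy(),
                                seed = 20230L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fixture <- pilot_fixture(taxonomy, seed = seed)
  menus <- lapply(seq_along(fixture), function(i) {
    fx <- fixture[[i]]
    generate_menu(fx$pattern, taxonomy, seed = seed + 1000L + i,
                  outlet_id = fx$outlet_id, outlet_type = fx$outlet_type)
  })
  for (m in menus) {
    write_menu(m, file.path(dir, paste0(m$outlet_id, ".csv")))
  }
  expected <- dplyr::bind_rows(lapply(fixture, function(fx) {
    tibble(outlet_id = fx$outlet_id, outlet_type = fx$outlet_type,
           mode = "engaged", numerator = fx$numerator,
           denominator = fx$denominator, percent = fx$percent)
  }))
  utils::write.csv(expected, file.path(dir, "expected-scores.csv"),
                   row.names = FALSE)
  invisible(dir)
}
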