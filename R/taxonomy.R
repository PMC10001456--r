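#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

HEALTHFULNESS <- c("nutrient_poor", "nutritious")

#' Load a MAST taxonomy
#'
#' Reads a taxonomy configuration (YAML or JSON) describing the food
#' categories, food groups and classification cue lexicons used to assess
#' menus. With `path = NULL` the packaged default is loaded: the Australian
#' scheme of six food categories containing 15 nutrient-poor and 12
#' nutritious food groups (27 in total), yielding 11 assessable
#' (category, healthfulness) slots.
#'
#' Water and alcoholic beverages are excluded from the default scheme: tap
#' water is freely available in Australian food outlets as a cultural norm,
#' and alcohol availability is assessed separately through liquor licensing.
#' Both can be switched on for other settings, which adds a nutritious
#' "water" group and/or a nutrient-poor "alcoholic beverages" group to the
#' beverages and miscellaneous category.
#'
#' @param path Path to a taxonomy configuration file (`.yaml`/`.yml` or
#'   `.json`), or `NULL` for the packaged default.
#' @param include_water Override the configuration's `include_water` flag
#'   (logical, or `NULL` to use the file's value).
#' @param include_alcohol Override the configuration's `include_alcohol`
#'   flag.
#' @return A `mast_taxonomy` object: a list with `categories` and `groups`
#'   tibbles, the water/alcohol flags, `version` and `profile`.
#' @examples
#' tax <- load_taxonomy()
#' nrow(tax$groups)   # 27
#' mast_slots(tax)    # the 11 default slots
#' @export
load_taxonomy <- function(path = NULL, include_water = NULL,
                          include_alcohol = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default-taxonomy.yaml", package = "mast")
  }
  if (!file.exists(path)) {
    stop("taxonomy configuration not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(include_water)) raw$include_water <- isTRUE(include_water)
  if (!is.null(include_alcohol)) raw$include_alcohol <- isTRUE(include_alcohol)
  build_taxonomy(raw, source = path)
}

# Construct and schema-check a mast_taxonomy from a parsed configuration list.
build_taxonomy <- function(raw, source = "<config>") {
  fail <- function(field, why) {
    stop("invalid taxonomy configuration (", source, "): field '", field,
         "' ", why, call. = FALSE)
  }
  if (is.null(raw$categories) || length(raw$categories) == 0) {
    fail("categories", "is missing or empty")
  }
  if (is.null(raw$groups) || length(raw$groups) == 0) {
    fail("groups", "is missing or empty")
  }
  chr1 <- function(entry, field, where) {
    v <- entry[[field]]
    if (is.null(v) || !is.character(as.character(v)) || length(v) != 1 ||
        is.na(v) || !nzchar(as.character(v))) {
      fail(paste0(where, "$", field), "must be a non-empty string")
    }
    as.character(v)
  }
  cues <- function(entry, field) {
    v <- entry[[field]]
    if (is.null(v)) return(character(0))
    as.character(unlist(v, use.names = FALSE))
  }

  categories <- tibble(
    id = vapply(raw$categories, chr1, "", field = "id", where = "categories"),
    name = vapply(raw$categories, chr1, "", field = "name",
                  where = "categories"),
    paired = vapply(raw$categories, function(x) isTRUE(x$paired), logical(1)),
    neutral_cues = lapply(raw$categories, cues, field = "neutral_cues")
  )

  grp_list <- raw$groups
  include_water <- isTRUE(raw$include_water)
  include_alcohol <- isTRUE(raw$include_alcohol)
  if (include_water && !is.null(raw$optional_groups$water)) {
    grp_list <- c(grp_list, list(raw$optional_groups$water))
    wcat <- raw$optional_groups$water$category_id
    categories$paired[categories$id == wcat] <- TRUE
  }
  if (include_alcohol && !is.null(raw$optional_groups$alcohol)) {
    grp_list <- c(grp_list, list(raw$optional_groups$alcohol))
  }

  hf <- vapply(grp_list, chr1, "", field = "healthfulness", where = "groups")
  bad_hf <- setdiff(unique(hf), HEALTHFULNESS)
  if (length(bad_hf) > 0) {
    fail("groups$healthfulness",
         paste0("must be one of {nutrient_poor, nutritious}; got '",
                bad_hf[1], "'"))
  }
  groups <- tibble(
    id = vapply(grp_list, chr1, "", field = "id", where = "groups"),
    name = vapply(grp_list, chr1, "", field = "name", where = "groups"),
    category_id = vapply(grp_list, chr1, "", field = "category_id",
                         where = "groups"),
    healthfulness = hf,
    definition = vapply(grp_list, function(x) {
      if (is.null(x$definition)) "" else as.character(x$definition)
    }, character(1)),
    include_cues = lapply(grp_list, cues, field = "include_cues"),
    exclude_cues = lapply(grp_list, cues, field = "exclude_cues")
  )
  unknown <- setdiff(groups$category_id, categories$id)
  if (length(unknown) > 0) {
    fail("groups$category_id",
         paste0("references unknown category '", unknown[1], "'"))
  }

  structure(
    list(
      version = if (is.null(raw$version)) "" else as.character(raw$version),
      profile = if (is.null(raw$profile)) "" else as.character(raw$profile),
      include_water = include_water,
      include_alcohol = include_alcohol,
      categories = categories,
      groups = groups,
      optional_groups = lapply(raw$optional_groups, function(g) {
        g$include_cues <- as.character(unlist(g$include_cues,
                                              use.names = FALSE))
        g$exclude_cues <- as.character(unlist(g$exclude_cues,
                                              use.names = FALSE))
        g
      })
    ),
    class = "mast_taxonomy"
  )
}

#' Validate a taxonomy against its structural invariants
#'
#' Violations are returned as data, not raised as errors, so configuration
#' problems can be reported in bulk. Structural checks (unique identifiers,
#' resolvable category references, paired categories holding groups of both
#' healthfulness levels, unpaired categories holding only nutrient-poor
#' groups) apply to every taxonomy. When the taxonomy declares the
#' `australian-default` profile, the default scheme's counts are also
#' enforced: 6 categories, 15 nutrient-poor groups, 12 nutritious groups
#' and 11 slots.
#'
#' @param taxonomy A `mast_taxonomy`.
#' @return A tibble with columns `code` and `message`, one row per
#'   violation; zero rows means the taxonomy is valid.
#' @examples
#' nrow(validate_taxonomy(load_taxonomy()))  # 0
#' @export
validate_taxonomy <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "mast_taxonomy"))
  violations <- list()
  flag <- function(code, message) {
    violations[[length(violations) + 1L]] <<- tibble(code = code,
                                                     message = message)
  }
  cats <- taxonomy$categories
  grps <- taxonomy$groups

  dup_cat <- unique(cats$id[duplicated(cats$id)])
  for (d in dup_cat) flag("duplicate_category_id",
                          paste0("category id '", d, "' is not unique"))
  dup_grp <- unique(grps$id[duplicated(grps$id)])
  for (d in dup_grp) flag("duplicate_group_id",
                          paste0("group id '", d, "' is not unique"))
  unknown <- setdiff(grps$category_id, cats$id)
  for (u in unknown) flag("unknown_category",
                          paste0("group references unknown category '", u,
                                 "'"))

  for (i in seq_len(nrow(cats))) {
    cid <- cats$id[i]
    n_np <- sum(grps$category_id == cid &
                  grps$healthfulness == "nutrient_poor")
    n_nu <- sum(grps$category_id == cid & grps$healthfulness == "nutritious")
    if (cats$paired[i]) {
      if (n_np == 0) flag("paired_missing_nutrient_poor",
                          paste0("paired category '", cid,
                                 "' has no nutrient-poor group"))
      if (n_nu == 0) flag("paired_missing_nutritious",
                          paste0("paired category '", cid,
                                 "' has no nutritious group"))
    } else {
      if (n_nu > 0) flag("unpaired_has_nutritious",
                         paste0("unpaired category '", cid,
                                "' has nutritious group"))
      if (n_np == 0) flag("unpaired_missing_nutrient_poor",
                          paste0("unpaired category '", cid,
                                 "' has no nutrient-poor group"))
    }
  }

  if (identical(taxonomy$profile, "australian-default")) {
    base_np <- sum(grps$healthfulness == "nutrient_poor") -
      as.integer(taxonomy$include_alcohol)
    base_nu <- sum(grps$healthfulness == "nutritious") -
      as.integer(taxonomy$include_water)
    if (nrow(cats) != 6) {
      flag("category_count",
           paste0("default profile expects 6 categories, found ",
                  nrow(cats)))
    }
    if (base_np != 15) {
      flag("nutrient_poor_group_count",
           paste0("default profile expects 15 nutrient-poor groups, found ",
                  base_np))
    }
    if (base_nu != 12) {
      flag("nutritious_group_count",
           paste0("default profile expects 12 nutritious groups, found ",
                  base_nu))
    }
    n_unpaired <- sum(!cats$paired)
    if (n_unpaired != 1 - as.integer(taxonomy$include_water)) {
      flag("unpaired_count",
           paste("default profile expects exactly one unpaired category",
                 "unless water is included"))
    }
  }

  if (length(violations) == 0) {
    tibble(code = character(0), message = character(0))
  } else {
    dplyr::bind_rows(violations)
  }
}

#' Enumerate the assessable slots of a taxonomy
#'
#' A slot is a (category, healthfulness) pair for which the taxonomy
#' defines at least one food group. Order is deterministic: categories in
#' configuration order, and within a category the nutrient-poor slot before
#' the nutritious slot. The default taxonomy has 11 slots (6 nutrient-poor
#' + 5 nutritious); enabling water adds a 12th.
#'
#' @param taxonomy A `mast_taxonomy`.
#' @return A tibble with columns `slot_id` (e.g. `"grain:nutritious"`),
#'   `category_id` and `healthfulness`.
#' @export
mast_slots <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "mast_taxonomy"))
  grps <- taxonomy$groups
  cat_ids <- character(0)
  hfs <- character(0)
  for (cid in taxonomy$categories$id) {
    for (hf in HEALTHFULNESS) {
      if (any(grps$category_id == cid & grps$healthfulness == hf)) {
        cat_ids <- c(cat_ids, cid)
        hfs <- c(hfs, hf)
      }
    }
  }
  tibble(slot_id = paste0(cat_ids, ":", hfs), category_id = cat_ids,
         healthfulness = hfs)
}

#' Serialise a taxonomy back to a configuration file
#'
#' Writes YAML (or JSON when the path ends in `.json`) that [load_taxonomy()]
#' reads back to an identical object.
#'
#' @param taxonomy A `mast_taxonomy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "mast_taxonomy"))
  cats <- taxonomy$categories
  grps <- taxonomy$groups
  # Optional water/alcohol groups are re-appended from the flags at load
  # time, so they are stripped from the main group list on write.
  optional_ids <- c(
    if (taxonomy$include_water) taxonomy$optional_groups$water$id,
    if (taxonomy$include_alcohol) taxonomy$optional_groups$alcohol$id
  )
  keep <- !(grps$id %in% optional_ids)
  group_entry <- function(i) {
    list(id = grps$id[i], name = grps$name[i],
         category_id = grps$category_id[i],
         healthfulness = grps$healthfulness[i],
         definition = grps$definition[i],
         include_cues = as.list(grps$include_cues[[i]]),
         exclude_cues = as.list(grps$exclude_cues[[i]]))
  }
  raw <- list(
    version = taxonomy$version,
    profile = taxonomy$profile,
    include_water = taxonomy$include_water,
    include_alcohol = taxonomy$include_alcohol,
    categories = lapply(seq_len(nrow(cats)), function(i) {
      list(id = cats$id[i], name = cats$name[i],
           paired = cats$paired[i],
           neutral_cues = as.list(cats$neutral_cues[[i]]))
    }),
    groups = lapply(which(keep), group_entry),
    optional_groups = taxonomy$optional_groups
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' @export
print.mast_taxonomy <- function(x, ...) {
  n_np <- sum(x$groups$healthfulness == "nutrient_poor")
  n_nu <- sum(x$groups$healthfulness == "nutritious")
  cat("<mast_taxonomy", if (nzchar(x$version)) paste0("v", x$version),
      ">\n")
  cat("  categories: ", nrow(x$categories), " (",
      sum(x$categories$paired), " paired)\n", sep = "")
  cat("  groups:     ", nrow(x$groups), " (", n_np, " nutrient-poor, ",
      n_nu, " nutritious)\n", sep = "")
  cat("  slots:      ", nrow(mast_slots(x)), "\n", sep = "")
  invisible(x)
}
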