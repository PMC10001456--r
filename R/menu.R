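OUTLET_TYPES <- c("restaurant", "cafe_coffee_shop", "pub_hotel_tavern",
                  "fast_food_takeaway", "other")

MENU_COLUMNS <- c("outlet_id", "outlet_type", "section", "item_name",
                  "description", "is_meal_deal", "is_customisable",
                  "default_configuration", "on_main_menu")

#' Construct a menu
#'
#' A menu is one outlet's offer as a list of normalised items. Items are
#' normalised on construction (see [normalise_item()]): customisable items
#' are reduced to their default configuration for classification, meal
#' deals are kept as one unit, and kids'-menu items not listed on the main
#' menu are marked ineligible for assessment.
#'
#' @param outlet_id Outlet identifier.
#' @param outlet_type One of `"restaurant"`, `"cafe_coffee_shop"`,
#'   `"pub_hotel_tavern"`, `"fast_food_takeaway"`, `"other"`. Unknown
#'   values are mapped to `"other"` with a warning.
#' @param items A tibble/data.frame of items with (a subset of) columns
#'   `item_id`, `section`, `name`, `description`, `is_meal_deal`,
#'   `is_customisable`, `default_configuration`, `on_main_menu`. Only
#'   `name` is mandatory.
#' @param source Free-text provenance note (e.g. which delivery platform
#'   the menu was captured from).
#' @return A `mast_menu` object.
#' @export
mast_menu <- function(outlet_id, outlet_type = "other",
                      items = NULL, source = "") {
  outlet_type <- as.character(outlet_type)
  if (!outlet_type %in% OUTLET_TYPES) {
    warning("unknown outlet type '", outlet_type, "' mapped to 'other'",
            call. = FALSE)
    outlet_type <- "other"
  }
  items <- as_menu_items(items)
  if (anyDuplicated(items$item_id)) {
    stop("duplicate item_id in menu '", outlet_id, "': ",
         paste(unique(items$item_id[duplicated(items$item_id)]),
               collapse = ", "), call. = FALSE)
  }
  items <- normalise_items(items)
  structure(
    list(outlet_id = as.character(outlet_id), outlet_type = outlet_type,
         items = items, source = as.character(source)),
    class = "mast_menu"
  )
}

squish <- function(x) {
  x <- gsub("\\s+", " ", as.character(x))
  trimws(x)
}

# Coerce a raw item table to the canonical item tibble, filling defaults.
as_menu_items <- function(items) {
  if (is.null(items) || nrow(as.data.frame(items)) == 0) {
    return(tibble(
      item_id = character(0), section = character(0), name = character(0),
      description = character(0), is_meal_deal = logical(0),
      is_customisable = logical(0), default_configuration = character(0),
      on_main_menu = logical(0)
    ))
  }
  items <- as_tibble(items)
  n <- nrow(items)
  get_chr <- function(col, default) {
    if (col %in% names(items)) squish(items[[col]]) else rep(default, n)
  }
  get_lgl <- function(col, default) {
    if (!col %in% names(items)) return(rep(default, n))
    v <- items[[col]]
    if (is.character(v)) v <- tolower(squish(v)) %in% c("true", "t", "1",
                                                        "yes", "y")
    out <- as.logical(v)
    out[is.na(out)] <- default
    out
  }
  name <- get_chr("name", "")
  if ("item_name" %in% names(items) && !"name" %in% names(items)) {
    name <- squish(items$item_name)
  }
  if (any(!nzchar(name))) {
    stop("menu items must have a non-empty name", call. = FALSE)
  }
  item_id <- if ("item_id" %in% names(items)) {
    squish(items$item_id)
  } else {
    sprintf("item-%03d", seq_len(n))
  }
  section <- get_chr("section", "")
  on_main <- get_lgl("on_main_menu", NA)
  # Section headings like "kids" set the eligibility default when the flag
  # is not supplied; an explicit flag always wins.
  kids <- grepl("\\b(kids?|children('s)?)\\b", section, ignore.case = TRUE)
  on_main[is.na(on_main)] <- !kids[is.na(on_main)]
  tibble(
    item_id = item_id,
    section = section,
    name = name,
    description = get_chr("description", ""),
    is_meal_deal = get_lgl("is_meal_deal", FALSE),
    is_customisable = get_lgl("is_customisable", FALSE),
    default_configuration = get_chr("default_configuration", ""),
    on_main_menu = on_main
  )
}

#' Normalise a menu item for assessment
#'
#' Applies the menu-coding conventions to one item and records the text
#' the classifier will see:
#' * customisable items (e.g. a choice of toppings or sides) are reduced to
#'   their default configuration — the default option is what is assessed;
#'   if the default configuration is empty a warning is raised and the
#'   name/description are used as-is;
#' * meal deals are assessed as one unit, never split into components;
#' * kids'-menu items are eligible only when listed on the main menu
#'   (`on_main_menu = TRUE`); ineligible items are retained but marked
#'   `eligible = FALSE`.
#'
#' The operation is idempotent.
#'
#' @param item A one-row item tibble (as held in a `mast_menu`).
#' @return The item with `class_text` (classification text) and `eligible`
#'   columns filled in.
#' @export
normalise_item <- function(item) {
  normalise_items(as_menu_items(item))
}

normalise_items <- function(items) {
  n <- nrow(items)
  class_text <- squish(paste(items$name, items$description))
  custom <- items$is_customisable
  has_default <- nzchar(items$default_configuration)
  class_text[custom & has_default] <-
    items$default_configuration[custom & has_default]
  if (any(custom & !has_default)) {
    warning("customisable item(s) without a default configuration; ",
            "name/description used as-is: ",
            paste(items$item_id[custom & !has_default], collapse = ", "),
            call. = FALSE)
  }
  items$class_text <- squish(class_text)
  items$eligible <- items$on_main_menu
  items
}

#' Read a menu file
#'
#' Reads one outlet's menu from CSV or JSON. The CSV dialect has mandatory
#' header columns `outlet_id, outlet_type, section, item_name, description,
#' is_meal_deal, is_customisable, default_configuration, on_main_menu`
#' (UTF-8). The JSON dialect is one object per outlet mirroring the menu
#' structure (`outlet_id`, `outlet_type`, `source`, `items`).
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; guessed from the extension when
#'   omitted.
#' @return A `mast_menu` (or a list of them if the CSV holds several
#'   outlet ids).
#' @export
read_menu <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (!file.exists(path)) stop("menu file not found: ", path, call. = FALSE)
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(menu_from_json(raw))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (nrow(df) == 0) stop("empty menu file: ", path, call. = FALSE)
  missing_cols <- setdiff(c("outlet_id", "item_name"), names(df))
  if (length(missing_cols) > 0) {
    stop("menu CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  menus <- lapply(split(df, df$outlet_id), function(sub) {
    mast_menu(
      outlet_id = sub$outlet_id[1],
      outlet_type = if ("outlet_type" %in% names(sub)) sub$outlet_type[1]
                    else "other",
      items = sub[setdiff(names(sub), c("outlet_id", "outlet_type"))],
      source = path
    )
  })
  # keep first-appearance order of outlets
  menus <- menus[unique(df$outlet_id)]
  if (length(menus) == 1) menus[[1]] else menus
}

menu_from_json <- function(raw) {
  if (!is.null(raw$items)) {
    items <- dplyr::bind_rows(lapply(raw$items, function(it) {
      as_tibble(lapply(it, function(v) if (is.null(v)) NA else v))
    }))
    mast_menu(outlet_id = raw$outlet_id,
              outlet_type = if (is.null(raw$outlet_type)) "other"
                            else raw$outlet_type,
              items = items,
              source = if (is.null(raw$source)) "" else raw$source)
  } else {
    lapply(raw, menu_from_json)
  }
}

#' Write a menu file
#'
#' Inverse of [read_menu()] for both dialects:
#' `read_menu(write_menu(m, p), format)` reproduces `m`.
#'
#' @param menu A `mast_menu`.
#' @param path Output path.
#' @param format `"csv"`, `"json"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_menu <- function(menu, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(menu, "mast_menu"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  core <- menu$items[, c("item_id", "section", "name", "description",
                         "is_meal_deal", "is_customisable",
                         "default_configuration", "on_main_menu")]
  if (format == "json") {
    obj <- list(outlet_id = menu$outlet_id, outlet_type = menu$outlet_type,
                source = menu$source,
                items = lapply(seq_len(nrow(core)), function(i) {
                  as.list(core[i, ])
                }))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    out <- cbind(outlet_id = menu$outlet_id, outlet_type = menu$outlet_type,
                 stats::setNames(core, c("item_id", "section", "item_name",
                                         "description", "is_meal_deal",
                                         "is_customisable",
                                         "default_configuration",
                                         "on_main_menu")))
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @export
print.mast_menu <- function(x, ...) {
  cat("<mast_menu '", x$outlet_id, "' (", x$outlet_type, ")>\n", sep = "")
  cat("  ", nrow(x$items), " items (", sum(x$items$eligible),
      " eligible)\n", sep = "")
  invisible(x)
}
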