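#' Summarise a batch of menu scores
#'
#' Per-outlet-type and overall summary statistics over integer percent
#' scores: n, mean (computed over the per-outlet integer percents and then
#' rounded half-up, matching how published batch results are reported),
#' min and max; plus counts of outlets against screening thresholds.
#'
#' @param scores A tibble as produced by [scores_table()] (needs columns
#'   `outlet_type` and `percent`), or a list of `mast_score` objects.
#' @param thresholds A data.frame with columns `comparator`
#'   (`">="`, `"<="`, `">"`, `"<"`, `"=="`) and `threshold`. The default
#'   reproduces the pilot's screening cuts: scores at or above 56%
#'   (high-risk menus), exactly 100% (no nutritious items), and below 30%
#'   (few nutrient-poor items).
#' @return A `mast_summary`: list with `by_type` and `overall` tibbles
#'   (`n`, `mean`, `min`, `max`) and a `threshold_counts` tibble.
#' @export
summarize_scores <- function(scores,
                             thresholds = data.frame(
                               comparator = c(">=", "==", "<"),
                               threshold = c(56, 100, 30))) {
  if (is.list(scores) && !is.data.frame(scores)) {
    if (all(vapply(scores, inherits, logical(1), "mast_score"))) {
      scores <- scores_table(scores)
    }
  }
  scores <- as_tibble(scores)
  if (nrow(scores) == 0) stop("no scores to summarise", call. = FALSE)
  stopifnot(all(c("outlet_type", "percent") %in% names(scores)))

  half_up <- function(x) as.integer(floor(x + 0.5))
  grp_stats <- function(df) {
    tibble(n = nrow(df), mean = half_up(mean(df$percent)),
           min = as.integer(min(df$percent)),
           max = as.integer(max(df$percent)))
  }
  types <- unique(scores$outlet_type)
  by_type <- dplyr::bind_rows(lapply(types, function(tp) {
    cbind(tibble(outlet_type = tp),
          grp_stats(scores[scores$outlet_type == tp, ]))
  }))
  overall <- grp_stats(scores)

  cmp_fun <- list(">=" = `>=`, "<=" = `<=`, ">" = `>`, "<" = `<`,
                  "==" = `==`)
  threshold_counts <- dplyr::bind_rows(lapply(seq_len(nrow(thresholds)),
    function(i) {
      cmp <- as.character(thresholds$comparator[i])
      thr <- thresholds$threshold[i]
      tibble(comparator = cmp, threshold = thr,
             count = sum(cmp_fun[[cmp]](scores$percent, thr)))
    }))

  structure(list(by_type = as_tibble(by_type), overall = overall,
                 threshold_counts = threshold_counts),
            class = "mast_summary")
}

#' @export
print.mast_summary <- function(x, ...) {
  cat("<mast_summary> overall: n=", x$overall$n, " mean=", x$overall$mean,
      "% range=", x$overall$min, "-", x$overall$max, "%\n", sep = "")
  for (i in seq_len(nrow(x$by_type))) {
    cat("  ", format(x$by_type$outlet_type[i], width = 20), " n=",
        x$by_type$n[i], " mean=", x$by_type$mean[i], "% range=",
        x$by_type$min[i], "-", x$by_type$max[i], "%\n", sep = "")
  }
  for (i in seq_len(nrow(x$threshold_counts))) {
    cat("  outlets ", x$threshold_counts$comparator[i], " ",
        x$threshold_counts$threshold[i], "%: ",
        x$threshold_counts$count[i], "\n", sep = "")
  }
  invisible(x)
}

#' Flatten a summary for CSV output
#'
#' @param summary A `mast_summary`.
#' @return A tibble with one row per group (`overall` first, then each
#'   outlet type) and columns `group`, `n`, `mean`, `min`, `max`.
#' @export
summary_table <- function(summary) {
  stopifnot(inherits(summary, "mast_summary"))
  dplyr::bind_rows(
    cbind(tibble(group = "overall"), summary$overall),
    stats::setNames(summary$by_type,
                    c("group", "n", "mean", "min", "max"))
  )
}

#' Improvement signals for one assessed menu
#'
#' Derives the actions the score rewards, in priority order. Because a
#' single nutritious item removes a penalty point while any number of
#' nutrient-poor items incurs only one, the strongest signal to an outlet
#' operator is to *add* nutritious meals; reducing nutrient-poor offerings
#' is also recommended but moves the score less directly.
#'
#' @param assessment A `mast_assessment`.
#' @param taxonomy A `mast_taxonomy`.
#' @return A `mast_signals` list: `outlet_id`; `add_nutritious` — engaged
#'   paired categories whose nutritious slot is absent; and
#'   `reduce_nutrient_poor` — categories whose nutrient-poor slot is
#'   present (with its evidence item where known).
#' @export
improvement_signals <- function(assessment, taxonomy) {
  stopifnot(inherits(assessment, "mast_assessment"),
            inherits(taxonomy, "mast_taxonomy"))
  slots <- mast_slots(taxonomy)
  present <- assessment$slot_presence[slots$slot_id]
  engaged <- engaged_categories(assessment, taxonomy)

  paired_ids <- unique(slots$category_id[slots$healthfulness ==
                                           "nutritious"])
  nu_absent <- vapply(engaged, function(cid) {
    cid %in% paired_ids &&
      !any(present[slots$category_id == cid &
                     slots$healthfulness == "nutritious"])
  }, logical(1))
  np_present <- vapply(engaged, function(cid) {
    any(present[slots$category_id == cid &
                  slots$healthfulness == "nutrient_poor"])
  }, logical(1))

  structure(
    list(outlet_id = assessment$outlet_id,
         add_nutritious = engaged[nu_absent],
         reduce_nutrient_poor = engaged[np_present],
         evidence = assessment$evidence),
    class = "mast_signals"
  )
}

#' Render signals as a text report
#'
#' Additions are listed before reductions: adding a nutritious meal is the
#' strongest signal the score sends.
#'
#' @param signals A `mast_signals`.
#' @param taxonomy A `mast_taxonomy` (for display names).
#' @return Character vector of report lines.
#' @export
render_signals <- function(signals, taxonomy) {
  stopifnot(inherits(signals, "mast_signals"))
  cname <- function(cid) {
    taxonomy$categories$name[match(cid, taxonomy$categories$id)]
  }
  lines <- c(paste0("Improvement signals for outlet ", signals$outlet_id,
                    ":"))
  if (length(signals$add_nutritious) == 0 &&
      length(signals$reduce_nutrient_poor) == 0) {
    return(c(lines, "  Menu already meets the best-case pattern."))
  }
  if (length(signals$add_nutritious) > 0) {
    lines <- c(lines, "  Add nutritious options (strongest signal):")
    for (cid in signals$add_nutritious) {
      lines <- c(lines, paste0("    - ", cname(cid)))
    }
  }
  if (length(signals$reduce_nutrient_poor) > 0) {
    lines <- c(lines, "  Reduce nutrient-poor options:")
    for (cid in signals$reduce_nutrient_poor) {
      ev <- signals$evidence[paste0(cid, ":nutrient_poor")]
      lines <- c(lines, paste0("    - ", cname(cid),
                               if (!is.na(ev)) paste0(" (e.g. item ", ev,
                                                      ")")))
    }
  }
  lines
}

#' Serialise signals to JSON
#'
#' @param signals A `mast_signals`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  stopifnot(inherits(signals, "mast_signals"))
  jsonlite::write_json(
    list(outlet_id = signals$outlet_id,
         add_nutritious = signals$add_nutritious,
         reduce_nutrient_poor = signals$reduce_nutrient_poor),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
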