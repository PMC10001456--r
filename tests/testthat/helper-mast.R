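# Shared fixtures for the suite. The default taxonomy is loaded once; an
# independent brute-force scorer serves as the oracle for the scoring
# arithmetic (a literal per-category enumeration of the penalty rules,
# kept deliberately separate from the package's implementation).

default_tax <- load_taxonomy()
default_slots <- mast_slots(default_tax)

# Enumerate the penalty sums category by category, straight from the rule
# statement: +1 when the category's nutrient-poor slot is present, +1 when
# a corresponding nutritious slot exists but is absent; engaged mode
# restricts both sums and the denominator to categories with any present
# slot, fixed mode uses every category over the full slot count.
oracle_score <- function(pattern, taxonomy = default_tax,
                         mode = c("engaged", "fixed")) {
  mode <- match.arg(mode)
  slots <- mast_slots(taxonomy)
  num <- 0L
  den <- 0L
  for (cid in unique(slots$category_id)) {
    np_id <- paste0(cid, ":nutrient_poor")
    nu_id <- paste0(cid, ":nutritious")
    has_nu <- nu_id %in% slots$slot_id
    np <- np_id %in% slots$slot_id && isTRUE(pattern[[np_id]])
    nu <- has_nu && isTRUE(pattern[[nu_id]])
    if (mode == "engaged") {
      if (np || nu) {
        num <- num + np + (has_nu && !nu)
        den <- den + (if (has_nu) 2L else 1L)
      }
    } else {
      num <- num + np + (has_nu && !nu)
    }
  }
  if (mode == "fixed") den <- nrow(slots)
  list(numerator = as.integer(num), denominator = as.integer(den))
}

# All 2^k presence patterns over the taxonomy's slots.
all_patterns <- function(taxonomy = default_tax) {
  slots <- mast_slots(taxonomy)
  k <- nrow(slots)
  lapply(seq_len(2^k) - 1L, function(code) {
    bits <- as.logical(bitwAnd(bitwShiftR(code, seq_len(k) - 1L), 1L))
    stats::setNames(bits, slots$slot_id)
  })
}

make_pattern <- function(present, taxonomy = default_tax) {
  slots <- mast_slots(taxonomy)
  p <- stats::setNames(rep(FALSE, nrow(slots)), slots$slot_id)
  p[present] <- TRUE
  p
}

tiny_menu <- function(names, outlet_id = "t1", outlet_type = "cafe_coffee_shop",
                      ...) {
  mast_menu(outlet_id, outlet_type,
            items = tibble::tibble(name = names, ...))
}
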