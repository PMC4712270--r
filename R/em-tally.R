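# Fixed vocabulary of the ultrastructure annotation scheme: four features of
# the capillary wall, each scored into a small closed set of categories.
em_vocabulary <- function() {
  list(
    luminal_membrane = c("smooth", "protrusions"),
    tight_junction = c("intact", "discontinuous"),
    basal_membrane = c("intact", "increased_thickness", "detachment"),
    astroglia = c("intact", "edematous")
  )
}

em_groups <- c("control", "1d", "3d", "21d")
em_regions <- c("frontal_cortex", "hippocampus")

#' Validate per-image ultrastructure annotations
#'
#' Checks a data frame (or CSV file) of per-image electron-microscopy
#' annotations: required columns, closed category vocabularies, and
#' uniqueness of the `(region, group, capillary_id, image_id)` key. Rows
#' failing validation raise an error naming the offending rows.
#'
#' @param x A data frame, or path to a CSV file, with columns `region`,
#'   `group`, `capillary_id`, `image_id`, `luminal_membrane`,
#'   `tight_junction`, `basal_membrane`, `astroglia`.
#' @return A validated tibble.
#' @export
validate_annotations <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_csv(x, show_col_types = FALSE)
  }
  x <- tibble::as_tibble(x)
  vocab <- em_vocabulary()
  required <- c("region", "group", "capillary_id", "image_id", names(vocab))
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    tj_abort("validation", paste0("Missing annotation columns: ",
                                  paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) tj_abort("validation", "Annotation table is empty.")
  for (feat in names(vocab)) {
    bad <- which(!(x[[feat]] %in% vocab[[feat]]))
    if (length(bad)) {
      tj_abort("validation", sprintf(
        "Unknown %s value '%s' in row %d (allowed: %s).",
        feat, x[[feat]][bad[1]], bad[1], paste(vocab[[feat]], collapse = ", ")))
    }
  }
  bad_grp <- which(!(x$group %in% em_groups))
  if (length(bad_grp)) {
    tj_abort("validation", sprintf("Unknown group '%s' in row %d.",
                                   x$group[bad_grp[1]], bad_grp[1]))
  }
  bad_reg <- which(!(x$region %in% em_regions))
  if (length(bad_reg)) {
    tj_abort("validation", sprintf("Unknown region '%s' in row %d.",
                                   x$region[bad_reg[1]], bad_reg[1]))
  }
  key <- paste(x$region, x$group, x$capillary_id, x$image_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    tj_abort("validation", sprintf(
      "Duplicate annotation key (region, group, capillary_id, image_id) in row %d.",
      dup[1]))
  }
  x
}

#' Tally ultrastructure annotations into percentage tables
#'
#' Aggregates validated per-image annotations into, for each region x group
#' and each of the four wall features, the percentage of records falling in
#' each category, together with the number of capillaries and images per
#' cell. With `denominator = "image"` (default) each annotated image is one
#' record; with `denominator = "capillary"` images are first collapsed to
#' one record per capillary by majority category (ties go to the first
#' category in vocabulary order). Exact fractions are retained alongside the
#' integer-rounded percentages, and the result is invariant to record order.
#'
#' @param annotations Data frame as accepted by [validate_annotations()].
#' @param denominator `"image"` or `"capillary"`.
#' @return List of class `tj_em_tally` with `percentages` (tibble: region,
#'   group, feature, category, n, fraction, percent) and `counts` (tibble:
#'   region, group, n_capillaries, n_images).
#' @export
tally_ultrastructure <- function(annotations, denominator = c("image", "capillary")) {
  denominator <- match.arg(denominator)
  x <- validate_annotations(annotations)
  vocab <- em_vocabulary()
  counts <- x %>%
    dplyr::group_by(.data$region, .data$group) %>%
    dplyr::summarise(
      n_capillaries = dplyr::n_distinct(.data$capillary_id),
      n_images = dplyr::n(),
      .groups = "drop"
    )
  long <- x %>%
    tidyr::pivot_longer(dplyr::all_of(names(vocab)),
                        names_to = "feature", values_to = "category")
  if (denominator == "capillary") {
    long <- long %>%
      dplyr::group_by(.data$region, .data$group, .data$capillary_id,
                      .data$feature, .data$category) %>%
      dplyr::summarise(n_img = dplyr::n(), .groups = "drop_last") %>%
      dplyr::arrange(dplyr::desc(.data$n_img),
                     match(.data$category, unlist(vocab)), .by_group = TRUE) %>%
      dplyr::slice(1) %>%
      dplyr::ungroup()
  }
  pct <- long %>%
    dplyr::group_by(.data$region, .data$group, .data$feature) %>%
    dplyr::mutate(denom = dplyr::n()) %>%
    dplyr::group_by(.data$region, .data$group, .data$feature,
                    .data$category, .data$denom) %>%
    dplyr::summarise(n = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(fraction = .data$n / .data$denom,
                  percent = round(100 * .data$fraction)) %>%
    dplyr::select(-"denom")
  # include zero-count categories so every table cell is present
  frame <- tidyr::expand_grid(
    counts[, c("region", "group")],
    purrr::imap_dfr(vocab, ~ tibble::tibble(feature = .y, category = .x))
  )
  pct <- frame %>%
    dplyr::left_join(pct, by = c("region", "group", "feature", "category")) %>%
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      fraction = dplyr::coalesce(.data$fraction, 0),
      percent = dplyr::coalesce(.data$percent, 0)
    ) %>%
    dplyr::arrange(.data$region, match(.data$group, em_groups),
                   match(.data$feature, names(vocab)),
                   match(.data$category, unlist(vocab)))
  structure(list(percentages = pct, counts = counts,
                 denominator = denominator),
            class = "tj_em_tally")
}

#' @export
print.tj_em_tally <- function(x, ...) {
  cat("<tj_em_tally> denominator =", x$denominator, "\n")
  print(x$counts)
  print(x$percentages, n = 20)
  invisible(x)
}

#' Wide ultrastructure summary table
#'
#' Reshapes a [tally_ultrastructure()] result into the conventional report
#' layout: one block per region, rows for capillary/image counts and each
#' feature's categories, one column per group, integer percentages.
#'
#' @param tally A `tj_em_tally`.
#' @return Tibble with columns `region`, `feature`, `category` and one
#'   column per group.
#' @export
em_table_wide <- function(tally) {
  stopifnot(inherits(tally, "tj_em_tally"))
  counts_long <- tally$counts %>%
    tidyr::pivot_longer(c("n_capillaries", "n_images"),
                        names_to = "feature", values_to = "value") %>%
    dplyr::mutate(category = "count", value = as.numeric(.data$value))
  pct_long <- tally$percentages %>%
    dplyr::select("region", "group", "feature", "category", value = "percent")
  dplyr::bind_rows(counts_long, pct_long) %>%
    tidyr::pivot_wider(names_from = "group", values_from = "value") %>%
    dplyr::arrange(.data$region)
}
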