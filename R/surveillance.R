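# Surveillance record audit: necropsy completeness classification, the
# record-inclusion filter with a deterministic exclusion log, and the
# representation cross-tabs against orders and vulnerability categories.

#' Classify the examination level of one specimen
#'
#' A necropsy is `complete` when at least five of the six key organs (brain,
#' heart, lungs, liver, spleen, kidneys) were examined macroscopically and
#' histologically on an intact specimen. It is `partial` when two or more key
#' organs were missing or unassessable, when the assessment was macroscopic
#' only, or when essential body parts were absent. Anything else is `other`.
#'
#' @param organs_examined character vector of key organ names examined for
#'   this specimen (subset of the six).
#' @param histology_done logical: histology performed on the examined organs.
#' @param macroscopic_only logical: the specimen was assessed only
#'   macroscopically.
#' @param essential_parts_missing logical: essential body parts (e.g., the
#'   head) were absent.
#' @return `"complete"`, `"partial"`, or `"other"`.
#' @export
#' @examples
#' classify_examination(c("brain", "heart", "lungs", "liver", "spleen",
#'                        "kidneys"), TRUE)          # complete
#' classify_examination(c("heart", "lungs", "liver", "kidneys"), TRUE)  # partial
classify_examination <- function(organs_examined, histology_done,
                                 macroscopic_only = FALSE,
                                 essential_parts_missing = FALSE) {
  unknown <- setdiff(organs_examined, key_organs)
  if (length(unknown) > 0) {
    stop("unknown key organ: ", unknown[1], call. = FALSE)
  }
  n_examined <- length(unique(organs_examined))
  n_missing <- 6L - n_examined
  if (n_examined >= 5 && isTRUE(histology_done) && !isTRUE(macroscopic_only) &&
      !isTRUE(essential_parts_missing)) {
    return("complete")
  }
  if (n_missing >= 2 || isTRUE(macroscopic_only) || !isTRUE(histology_done) ||
      isTRUE(essential_parts_missing)) {
    return("partial")
  }
  "other"
}

#' Filter surveillance records by the inclusion rules
#'
#' A record is included when its examination level is complete or partial,
#' its coordinates are present and finite, it was not collected for a
#' targeted research project, and its date parses and falls inside the study
#' window. Excluded records get exactly one reason code: the first failing
#' rule in the fixed order level -> coords -> targeted -> date (`"level"`,
#' `"coords"`, `"targeted"`, `"bad_date"`, `"date_window"`).
#'
#' @param records data.frame with columns `record_id`, `species`, `date`
#'   (ISO-8601 character), `lat`, `lon`, `examination_level`, `targeted`.
#' @param window length-2 character or Date vector, inclusive date window.
#' @return list with `included` (data.frame) and `excluded` (data.frame with
#'   an extra `reason` column).
#' @export
filter_records <- function(records, window = c("2008-01-01", "2022-08-31")) {
  window <- as.Date(window)
  stopifnot(length(window) == 2, !anyNA(window))
  dates <- suppressWarnings(as.Date(as.character(records$date),
                                    format = "%Y-%m-%d"))
  ok_level <- records$examination_level %in% c("complete", "partial")
  ok_coords <- is.finite(records$lat) & is.finite(records$lon)
  ok_target <- !records$targeted
  bad_date <- is.na(dates)
  ok_window <- !bad_date & dates >= window[1] & dates <= window[2]

  reason <- rep(NA_character_, nrow(records))
  reason[!ok_level] <- "level"
  reason[is.na(reason) & !ok_coords] <- "coords"
  reason[is.na(reason) & !ok_target] <- "targeted"
  reason[is.na(reason) & bad_date] <- "bad_date"
  reason[is.na(reason) & !ok_window] <- "date_window"

  keep <- is.na(reason)
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(included = records[keep, , drop = FALSE], excluded = excluded)
}

#' Cross-tabulate included records against orders and categories
#'
#' Summarizes how species and vulnerability categories are represented in the
#' included surveillance sample: counts per submission year, counts and
#' proportions per taxonomic order, record counts per vulnerability category
#' (through the species-to-category join, with explicit zero rows), species
#' counts per category, and a tally of records for species without an
#' assessment (`unassessed`). Species missing from the order lookup are
#' listed under `unmatched`, never dropped silently.
#'
#' @param included data.frame of included records (see [filter_records()]).
#' @param assignments data.frame with columns `species`, `category` (e.g.,
#'   `categorize_all()$assignments` or the packaged reference table).
#' @param orders data.frame with columns `species`, `order`.
#' @return list of class `"tva_representation"` with elements `per_year`,
#'   `per_order`, `per_category_records`, `per_category_species`,
#'   `unassessed` (record count), `unmatched` (character), `n_included`.
#' @export
representation_summary <- function(included, assignments, orders) {
  n <- nrow(included)
  yr <- substr(as.character(included$date), 1, 4)
  per_year <- as.data.frame(table(year = yr), stringsAsFactors = FALSE)
  names(per_year) <- c("year", "n")

  ord <- orders$order[match(included$species, orders$species)]
  unmatched <- sort(unique(included$species[is.na(ord)]))
  per_order <- as.data.frame(table(order = ord[!is.na(ord)]),
                             stringsAsFactors = FALSE)
  names(per_order) <- c("order", "n")
  per_order$prop <- if (nrow(per_order) > 0) per_order$n / sum(per_order$n)
                    else numeric(0)

  cat <- assignments$category[match(included$species, assignments$species)]
  rec_n <- as.vector(table(factor(cat, levels = 1:8)))
  per_category_records <- data.frame(category = 1:8,
                                     label = category_labels, n = rec_n)
  sp_cat <- assignments$category[assignments$species %in% included$species]
  per_category_species <- data.frame(
    category = 1:8, label = category_labels,
    n_species = as.vector(table(factor(sp_cat, levels = 1:8))))

  structure(list(per_year = per_year, per_order = per_order,
                 per_category_records = per_category_records,
                 per_category_species = per_category_species,
                 unassessed = sum(is.na(cat)),
                 unmatched = unmatched, n_included = n),
            class = "tva_representation")
}

#' @export
print.tva_representation <- function(x, ...) {
  cat("Surveillance representation summary\n")
  cat(sprintf("  included records: %d (%d unassessed)\n",
              x$n_included, x$unassessed))
  cat("  records per order:\n")
  print(x$per_order, row.names = FALSE)
  cat("  records per vulnerability category:\n")
  print(x$per_category_records, row.names = FALSE)
  if (length(x$unmatched) > 0) {
    cat("  unmatched species:", paste(x$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}
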