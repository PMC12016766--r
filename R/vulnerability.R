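# The eight-way vulnerability categorizer: combining the high-exposure,
# high-sensitivity and low-adaptive-capacity flags into categories 1-8, its
# exact inverse, and the per-species assignment with tally.

category_labels <- c("highly vulnerable", "biologically susceptible",
                     "potential adapter", "potential persister",
                     "exposed only", "sensitive only",
                     "low adaptive capacity only", "low vulnerability")

# category -> (exposed, sensitive, low_ac), one row per category 1..8
category_table <- data.frame(
  category = 1:8,
  exposed  = c(TRUE,  FALSE, TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE),
  sensitive = c(TRUE, TRUE,  TRUE,  FALSE, FALSE, TRUE,  FALSE, FALSE),
  low_ac   = c(TRUE,  TRUE,  FALSE, TRUE,  FALSE, FALSE, TRUE,  FALSE),
  label = category_labels
)

#' Assign a vulnerability category from the three dimension flags
#'
#' The eight combinations of (exposed, sensitive, low adaptive capacity) map
#' to: 1 highly vulnerable (T,T,T), 2 biologically susceptible (F,T,T),
#' 3 potential adapter (T,T,F), 4 potential persister (T,F,T), 5 exposed only
#' (T,F,F), 6 sensitive only (F,T,F), 7 low adaptive capacity only (F,F,T),
#' 8 low vulnerability (F,F,F).
#'
#' @param exposed,sensitive,low_ac logical vectors (recycled to a common
#'   length).
#' @return data.frame with columns `category` (integer 1-8) and `label`.
#' @export
#' @examples
#' assign_category(TRUE, TRUE, TRUE)    # 1, highly vulnerable
#' assign_category(FALSE, FALSE, FALSE) # 8, low vulnerability
assign_category <- function(exposed, sensitive, low_ac) {
  n <- max(length(exposed), length(sensitive), length(low_ac))
  exposed <- rep_len(as.logical(exposed), n)
  sensitive <- rep_len(as.logical(sensitive), n)
  low_ac <- rep_len(as.logical(low_ac), n)
  if (anyNA(exposed) || anyNA(sensitive) || anyNA(low_ac)) {
    stop("dimension flags must be TRUE or FALSE", call. = FALSE)
  }
  idx <- match(paste(exposed, sensitive, low_ac),
               paste(category_table$exposed, category_table$sensitive,
                     category_table$low_ac))
  data.frame(category = category_table$category[idx],
             label = category_table$label[idx])
}

#' Invert a vulnerability category into its dimension flags
#'
#' Exact inverse of [assign_category()]:
#' `assign_category(invert_category(c)) == c` for all categories.
#'
#' @param category integer vector with values in 1-8.
#' @return data.frame with logical columns `exposed`, `sensitive`, `low_ac`.
#' @export
#' @examples
#' invert_category(4)  # exposed, not sensitive, low adaptive capacity
invert_category <- function(category) {
  if (any(!category %in% 1:8)) {
    stop("category must be an integer in 1..8", call. = FALSE)
  }
  category_table[match(category, category_table$category),
                 c("exposed", "sensitive", "low_ac"), drop = FALSE]
}

#' Categorize all species and tally the categories
#'
#' Joins the three per-species dimension flags, assigns each species its
#' category, and tallies categories 1-8 (explicit zero rows included).
#'
#' @param flags data.frame with columns `species`, `exposed`, `sensitive`,
#'   `low_ac`; no flag may be missing.
#' @return list with `assignments` (species, exposed, sensitive, low_ac,
#'   category, label) and `tally` (category, label, n, pct).
#' @export
categorize_all <- function(flags) {
  need <- c("species", "exposed", "sensitive", "low_ac")
  stopifnot(all(need %in% names(flags)))
  for (col in c("exposed", "sensitive", "low_ac")) {
    if (anyNA(flags[[col]])) {
      stop(sprintf("species '%s' is missing flag '%s'",
                   flags$species[is.na(flags[[col]])][1], col),
           call. = FALSE)
    }
  }
  cat <- assign_category(flags$exposed, flags$sensitive, flags$low_ac)
  assignments <- cbind(flags[need], cat)
  n <- as.vector(table(factor(assignments$category, levels = 1:8)))
  tally <- data.frame(category = 1:8, label = category_labels, n = n,
                      pct = 100 * n / nrow(assignments))
  list(assignments = assignments, tally = tally)
}
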