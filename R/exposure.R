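# Species exposure: percentage of a species' occupied cells per climate
# tercile class, the weighted exposure value, max-min rescaling, and the
# high-exposure flag.

#' Raw exposure of one species from its occupied cells
#'
#' Computes the percentages `a`, `b`, `c` of the species' occupied cells in
#' tercile classes 0, 1, 2 and the exposure value
#' \eqn{a \times 0 + b \times 1 + c \times 2}. Percentages are on the 0-100
#' scale, so the raw exposure spans \[0, 200\].
#'
#' @param cells integer vector of occupied cell ids.
#' @param classes data.frame with columns `cell_id`, `tercile_class` (e.g.,
#'   from [climate_novelty()]).
#' @return one-row data.frame `a`, `b`, `c`, `raw_exposure`.
#' @export
#' @examples
#' cls <- data.frame(cell_id = 0:9, tercile_class = rep(c(0, 1, 2), c(3, 4, 3)))
#' exposure_raw(0:9, cls)  # a=30 b=40 c=30, raw = 100
exposure_raw <- function(cells, classes) {
  idx <- match(cells, classes$cell_id)
  if (anyNA(idx)) {
    stop(sprintf("occupied cell %s has no tercile class",
                 cells[which(is.na(idx))[1]]), call. = FALSE)
  }
  cl <- classes$tercile_class[idx]
  pct <- 100 * as.vector(table(factor(cl, levels = 0:2))) / length(cl)
  data.frame(a = pct[1], b = pct[2], c = pct[3],
             raw_exposure = pct[2] + 2 * pct[3])
}

#' Max-min linear rescaling
#'
#' \eqn{(x - \min x) / (\max x - \min x)}: the minimum maps to 0, the maximum
#' to 1, rank order is preserved.
#'
#' @param x numeric vector with at least 2 values and `max > min`.
#' @return numeric vector in \[0, 1\].
#' @export
#' @examples
#' minmax_rescale(c(0, 50, 100))  # 0 0.5 1
minmax_rescale <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to rescale", call. = FALSE)
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) stop("max equals min: no spread to rescale", call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Flag highly exposed species
#'
#' Two rules: `"cutoff"` (default) flags species whose rescaled exposure is
#' `>= cutoff` (default 0.5); `"top_quartile"` flags species at or above the
#' 75th percentile of the rescaled values (ties share the flag).
#'
#' @param rescaled numeric vector of rescaled exposures in \[0, 1\].
#' @param rule `"cutoff"` or `"top_quartile"`.
#' @param cutoff numeric threshold for the cutoff rule.
#' @return logical vector; the rule used is recorded in attribute `"rule"`.
#' @export
flag_exposed <- function(rescaled, rule = c("cutoff", "top_quartile"),
                         cutoff = 0.5) {
  rule <- match.arg(rule)
  stopifnot(all(rescaled >= 0 & rescaled <= 1))
  flag <- if (rule == "cutoff") {
    rescaled >= cutoff
  } else {
    rescaled >= stats::quantile(rescaled, 0.75, type = 7)
  }
  structure(flag, rule = rule)
}

#' Exposure scores for all species
#'
#' Runs [exposure_raw()] per species over an occurrence table, rescales the
#' raw exposures across species with [minmax_rescale()], and applies
#' [flag_exposed()].
#'
#' @param occurrences data.frame with columns `species`, `cell_id`.
#' @param classes data.frame with columns `cell_id`, `tercile_class`.
#' @param rule,cutoff passed to [flag_exposed()].
#' @return data.frame with one row per species: `species`, `a`, `b`, `c`,
#'   `raw_exposure`, `rescaled`, `high_exposure`, `rule`.
#' @export
species_exposure <- function(occurrences, classes, rule = "cutoff",
                             cutoff = 0.5) {
  sp <- split(occurrences$cell_id, occurrences$species)
  rows <- lapply(names(sp), function(s) {
    cbind(species = s, exposure_raw(sp[[s]], classes))
  })
  out <- do.call(rbind, rows)
  out$rescaled <- minmax_rescale(out$raw_exposure)
  flag <- flag_exposed(out$rescaled, rule = rule, cutoff = cutoff)
  out$high_exposure <- as.logical(flag)
  out$rule <- attr(flag, "rule")
  out
}
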