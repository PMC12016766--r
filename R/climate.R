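# Climate-novelty metrics: annual bioclimatic variables, period climatologies,
# the standardized Euclidean distance (SED) between periods, tercile
# classification, and the predictor collinearity screen.

#' Compute annual bioclimatic variables from monthly records
#'
#' Aggregates monthly climate records into the six bioclimatic variables used
#' by the assessment, per cell and year: annual mean temperature (`bio01`,
#' mean of monthly means), maximum temperature of the warmest month (`bio05`),
#' minimum temperature of the coldest month (`bio06`), annual precipitation
#' (`bio12`, sum), precipitation of the wettest (`bio13`) and driest (`bio14`)
#' months.
#'
#' @param records data.frame with columns `cell_id`, `year`, `month`, `tmean`,
#'   `tmax`, `tmin`, `prcp`. Every cell-year must have exactly 12 months.
#' @return data.frame with columns `cell_id`, `year`, `bio01`, `bio05`,
#'   `bio06`, `bio12`, `bio13`, `bio14`.
#' @export
#' @examples
#' rec <- data.frame(cell_id = 0, year = 2000, month = 1:12,
#'                   tmean = 10, tmax = 15, tmin = 5, prcp = 50)
#' compute_bioclim(rec)  # bio01 = 10, bio05 = 15, bio12 = 600
compute_bioclim <- function(records) {
  need <- c("cell_id", "year", "month", "tmean", "tmax", "tmin", "prcp")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(records$prcp < 0, na.rm = TRUE)) {
    stop("negative precipitation in records", call. = FALSE)
  }
  key <- paste(records$cell_id, records$year, sep = "\r")
  cnt <- table(key)
  bad <- names(cnt)[cnt != 12]
  if (length(bad) > 0) {
    parts <- strsplit(bad[1], "\r", fixed = TRUE)[[1]]
    stop(sprintf("cell %s year %s has %d months (12 required)",
                 parts[1], parts[2], cnt[[bad[1]]]), call. = FALSE)
  }
  if (anyDuplicated(paste(key, records$month, sep = "\r")) > 0) {
    stop("duplicated cell-year-month records", call. = FALSE)
  }
  ord <- order(records$cell_id, records$year, records$month)
  rec <- records[ord, ]
  ncy <- nrow(rec) / 12L
  as_m <- function(x) matrix(x, nrow = 12L)
  row_max <- function(m) do.call(pmax, asplit(m, 1))
  row_min <- function(m) do.call(pmin, asplit(m, 1))
  first <- seq(1L, nrow(rec), by = 12L)
  data.frame(cell_id = rec$cell_id[first], year = rec$year[first],
             bio01 = colMeans(as_m(rec$tmean)),
             bio05 = row_max(as_m(rec$tmax)),
             bio06 = row_min(as_m(rec$tmin)),
             bio12 = colSums(as_m(rec$prcp)),
             bio13 = row_max(as_m(rec$prcp)),
             bio14 = row_min(as_m(rec$prcp)))
}

#' Summarize bioclimatic variables over a period
#'
#' Per cell and variable, the mean over the period's years and (optionally,
#' for the baseline) the interannual standard deviation with the sample (n-1)
#' denominator.
#'
#' @param bioclim data.frame from [compute_bioclim()].
#' @param years integer vector of years defining the period (>= 2 years per
#'   cell must be present).
#' @param with_sd logical; compute the interannual SD (required for the
#'   baseline period).
#' @param sd_floor optional positive epsilon; SDs of exactly 0 are raised to
#'   this floor instead of raising an error.
#' @return data.frame in long form: `cell_id`, `variable`, `mean`, and `sd`
#'   when `with_sd` is TRUE.
#' @export
summarize_period <- function(bioclim, years, with_sd = FALSE,
                             sd_floor = NULL) {
  sub <- bioclim[bioclim$year %in% years, , drop = FALSE]
  if (nrow(sub) == 0) stop("no bioclim years inside the period", call. = FALSE)
  cnt <- table(sub$cell_id)
  if (any(cnt < 2)) {
    stop(sprintf("cell %s has fewer than 2 years in the period",
                 names(cnt)[cnt < 2][1]), call. = FALSE)
  }
  if (length(unique(cnt)) != 1) {
    stop("cells cover unequal numbers of years in the period", call. = FALSE)
  }
  n_years <- unname(cnt[1])
  ord <- order(sub$cell_id, sub$year)
  sub <- sub[ord, ]
  cells <- sub$cell_id[seq(1L, nrow(sub), by = n_years)]
  out <- lapply(bioclim_vars, function(v) {
    m <- matrix(sub[[v]], nrow = n_years)
    mu <- colMeans(m)
    res <- data.frame(cell_id = cells, variable = v, mean = mu)
    if (with_sd) {
      s <- sqrt(colSums((m - rep(mu, each = n_years))^2) / (n_years - 1))
      if (any(s == 0)) {
        if (is.null(sd_floor)) {
          stop(sprintf("variable %s has zero interannual SD in cell %s",
                       v, cells[which(s == 0)[1]]), call. = FALSE)
        }
        s[s == 0] <- sd_floor
      }
      res$sd <- s
    }
    res
  })
  do.call(rbind, out)
}

#' Standardized Euclidean distance of climate change per grid cell
#'
#' For each cell, the climate dissimilarity between the recent and baseline
#' periods: the sum over the six bioclimatic variables of the squared
#' difference in period means divided by the squared baseline interannual SD,
#'
#' \deqn{SED_i = \sum_{k=1}^{6} (b_{ki} - a_{ki})^2 / s_{ki}^2}
#'
#' where \eqn{a} and \eqn{b} are the baseline and recent period means and
#' \eqn{s} the baseline interannual SD. No outer square root is applied by
#' default; `sqrt = TRUE` gives the square-rooted (distance-metric) variant.
#'
#' @param baseline data.frame from [summarize_period()] with `sd` present.
#' @param recent data.frame from [summarize_period()] for the recent period.
#' @param sqrt logical; apply an outer square root.
#' @return data.frame with columns `cell_id`, `sed`.
#' @export
compute_sed <- function(baseline, recent, sqrt = FALSE) {
  if (is.null(baseline$sd)) {
    stop("baseline summary lacks the interannual SD", call. = FALSE)
  }
  if (any(baseline$sd <= 0)) {
    stop("nonpositive baseline SD", call. = FALSE)
  }
  m <- merge(baseline, recent, by = c("cell_id", "variable"),
             suffixes = c("_base", "_recent"))
  cnt <- table(m$cell_id)
  if (any(cnt != 6)) {
    stop(sprintf("cell %s lacks one of the 6 variables in a period",
                 names(cnt)[cnt != 6][1]), call. = FALSE)
  }
  term <- (m$mean_recent - m$mean_base)^2 / m$sd^2
  sed <- rowsum(term, m$cell_id)
  cell <- rownames(sed)
  sed <- as.vector(sed)
  if (sqrt) sed <- base::sqrt(sed)
  out <- data.frame(cell_id = utils::type.convert(cell, as.is = TRUE),
                    sed = sed)
  out[order(out$cell_id), , drop = FALSE]
}

#' Tercile break points of a set of values
#'
#' Default method `"quantile"` takes the 33.33rd and 66.67th percentiles
#' (linear-interpolation quantile definition, R type 7); `"range_thirds"`
#' splits the value range into three equal-width bands.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @param method `"quantile"` or `"range_thirds"`.
#' @return numeric length-2 vector `c(break1, break2)` with
#'   `break1 <= break2`.
#' @export
#' @examples
#' tercile_breaks(1:9)                       # ~ (3.67, 6.33)
#' tercile_breaks(c(0, 3), "range_thirds")   # (1, 2)
tercile_breaks <- function(values, method = c("quantile", "range_thirds")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2) {
    stop("tercile breaks need non-identical values", call. = FALSE)
  }
  if (method == "quantile") {
    br <- unname(stats::quantile(values, probs = c(1, 2) / 3, type = 7))
  } else {
    r <- range(values)
    br <- r[1] + c(1, 2) * diff(r) / 3
  }
  br
}

#' Classify a value into tercile class 0, 1, or 2
#'
#' Lowest band is class 0, middle 1, upper 2. The upper break is left-closed:
#' a value exactly at `break2` falls in class 2; a value exactly at `break1`
#' falls in class 1.
#'
#' @param value numeric vector.
#' @param breaks length-2 numeric from [tercile_breaks()].
#' @return integer vector of classes in `{0, 1, 2}`.
#' @export
#' @examples
#' classify_tercile(c(2.10, 2.25, 2.33), c(2.20, 2.33))  # 0 1 2
classify_tercile <- function(value, breaks) {
  stopifnot(length(breaks) == 2, breaks[1] <= breaks[2])
  ifelse(value >= breaks[2], 2L, ifelse(value >= breaks[1], 1L, 0L))
}

#' Pairwise collinearity screen of the bioclimatic predictors
#'
#' Pearson correlation for all pairs of the six variables across cells; a
#' pair is flagged collinear when `|r| >= threshold`. The screen is advisory:
#' it reports, it never drops variables.
#'
#' @param cell_table data.frame with one row per cell and one column per
#'   bioclimatic variable (plus an ignored `cell_id` column if present).
#' @param threshold absolute-correlation flag threshold (default 0.7).
#' @return data.frame with columns `var1`, `var2`, `r`, `collinear`. Pairs
#'   involving a zero-variance variable get `r = NA` and `collinear = NA`.
#' @export
collinearity_screen <- function(cell_table, threshold = 0.7) {
  vars <- intersect(bioclim_vars, names(cell_table))
  if (length(vars) < 2) stop("need at least 2 variables", call. = FALSE)
  if (nrow(cell_table) < 3) stop("need at least 3 cells", call. = FALSE)
  pairs <- utils::combn(vars, 2)
  r <- apply(pairs, 2, function(p) {
    x <- cell_table[[p[1]]]; y <- cell_table[[p[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  })
  data.frame(var1 = pairs[1, ], var2 = pairs[2, ], r = r,
             collinear = ifelse(is.na(r), NA, abs(r) >= threshold))
}

#' Map climate novelty across the grid
#'
#' Convenience wrapper running the full climate stage: bioclim aggregation,
#' period summaries, SED, and tercile classification.
#'
#' @param records monthly climate records (see [compute_bioclim()]).
#' @param baseline_years,recent_years integer year vectors of the two periods.
#' @param tercile_method passed to [tercile_breaks()].
#' @param sed_sqrt passed to [compute_sed()].
#' @param sd_floor passed to [summarize_period()].
#' @return data.frame `cell_id`, `sed`, `tercile_class`, with the breaks in
#'   attribute `"breaks"`.
#' @export
climate_novelty <- function(records, baseline_years, recent_years,
                            tercile_method = "quantile", sed_sqrt = FALSE,
                            sd_floor = NULL) {
  if (length(intersect(baseline_years, recent_years)) > 0) {
    stop("baseline and recent periods overlap", call. = FALSE)
  }
  bc <- compute_bioclim(records)
  base <- summarize_period(bc, baseline_years, with_sd = TRUE,
                           sd_floor = sd_floor)
  rec <- summarize_period(bc, recent_years)
  sed <- compute_sed(base, rec, sqrt = sed_sqrt)
  br <- tercile_breaks(sed$sed, method = tercile_method)
  sed$tercile_class <- classify_tercile(sed$sed, br)
  attr(sed, "breaks") <- br
  sed
}
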