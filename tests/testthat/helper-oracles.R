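# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and explicit formulas, never the
# package's own aggregation paths.

# Random monthly climate table for a small grid, two periods.
random_records <- function(n_cells, base_years, rec_years, shift = 0) {
  years <- c(base_years, rec_years)
  grid <- expand.grid(month = 1:12, year = years, cell_id = seq_len(n_cells) - 1L)
  n <- nrow(grid)
  recent <- grid$year %in% rec_years
  tmean <- rnorm(n, 10, 2) + shift * recent
  data.frame(cell_id = grid$cell_id, year = grid$year, month = grid$month,
             tmean = tmean,
             tmax = tmean + abs(rnorm(n, 5, 1)),
             tmin = tmean - abs(rnorm(n, 5, 1)),
             prcp = pmax(0, rnorm(n, 70, 20) + 2 * shift * recent))
}

# Naive per-cell-year bioclim aggregation by looping.
brute_bioclim <- function(records) {
  keys <- unique(records[c("cell_id", "year")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    r <- records[records$cell_id == keys$cell_id[i] &
                   records$year == keys$year[i], ]
    data.frame(cell_id = keys$cell_id[i], year = keys$year[i],
               bio01 = mean(r$tmean), bio05 = max(r$tmax),
               bio06 = min(r$tmin), bio12 = sum(r$prcp),
               bio13 = max(r$prcp), bio14 = min(r$prcp))
  })
  do.call(rbind, out)
}

# Naive SED straight from monthly records.
brute_sed <- function(records, base_years, rec_years, use_sqrt = FALSE) {
  bc <- brute_bioclim(records)
  vars <- c("bio01", "bio05", "bio06", "bio12", "bio13", "bio14")
  cells <- sort(unique(bc$cell_id))
  sed <- vapply(cells, function(cl) {
    b <- bc[bc$cell_id == cl & bc$year %in% base_years, ]
    r <- bc[bc$cell_id == cl & bc$year %in% rec_years, ]
    total <- 0
    for (v in vars) {
      total <- total + (mean(r[[v]]) - mean(b[[v]]))^2 / stats::sd(b[[v]])^2
    }
    total
  }, numeric(1))
  if (use_sqrt) sed <- sqrt(sed)
  data.frame(cell_id = cells, sed = sed)
}

# Linear-interpolation quantile by the explicit h = (n-1)p + 1 formula.
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Pearson correlation from the definition.
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Percentage of cells per tercile class and the weighted exposure, by loop.
brute_exposure <- function(cells, classes) {
  cl <- vapply(cells, function(cc) {
    classes$tercile_class[classes$cell_id == cc]
  }, numeric(1))
  a <- 100 * sum(cl == 0) / length(cl)
  b <- 100 * sum(cl == 1) / length(cl)
  c <- 100 * sum(cl == 2) / length(cl)
  c(a = a, b = b, c = c, raw = a * 0 + b * 1 + c * 2)
}

# Three-point scoring with explicit breaks, by cut-offs written out.
brute_score <- function(values, breaks, low_scores_2) {
  cl <- vapply(values, function(v) {
    if (v >= breaks[2]) 2 else if (v >= breaks[1]) 1 else 0
  }, numeric(1))
  if (low_scores_2) 2 - cl else cl
}
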