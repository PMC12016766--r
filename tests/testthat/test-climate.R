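test_that("bioclim variables aggregate monthly records correctly", {
  rec <- data.frame(cell_id = 0, year = 2000, month = 1:12,
                    tmean = 10, tmax = 15, tmin = 5, prcp = 50)
  bc <- compute_bioclim(rec)
  expect_equal(bc$bio01, 10)
  expect_equal(bc$bio05, 15)
  expect_equal(bc$bio06, 5)
  expect_equal(bc$bio12, 600)
  expect_equal(bc$bio13, 50)
  expect_equal(bc$bio14, 50)

  rec2 <- rec
  rec2$prcp <- c(0, rep(10, 11))
  bc2 <- compute_bioclim(rec2)
  expect_equal(bc2$bio14, 0)
  expect_equal(bc2$bio12, 110)
})

test_that("bioclim aggregation matches a brute-force loop on random tables", {
  set.seed(101)
  for (i in 1:10) {
    rec <- random_records(3, 2000:2002, 2010:2011)
    got <- compute_bioclim(rec)
    want <- brute_bioclim(rec)
    got <- got[order(got$cell_id, got$year), ]
    want <- want[order(want$cell_id, want$year), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("incomplete cell-years are rejected with the offending cell named", {
  rec <- data.frame(cell_id = 7, year = 2000, month = 1:11,
                    tmean = 10, tmax = 15, tmin = 5, prcp = 50)
  expect_error(compute_bioclim(rec), "cell 7 year 2000")
})

test_that("period summaries give the sample mean and n-1 SD", {
  bc <- data.frame(cell_id = 0, year = 1:2,
                   bio01 = c(4, 6), bio05 = c(4, 6), bio06 = c(4, 6),
                   bio12 = c(4, 6), bio13 = c(4, 6), bio14 = c(4, 6))
  s <- summarize_period(bc, 1:2, with_sd = TRUE)
  expect_equal(unique(s$mean), 5)
  expect_equal(unique(s$sd), sqrt(2))

  # degenerate: identical values across years
  bc$bio01 <- 5
  expect_error(summarize_period(bc, 1:2, with_sd = TRUE), "zero interannual SD")
  s2 <- summarize_period(bc, 1:2, with_sd = TRUE, sd_floor = 1e-6)
  expect_equal(s2$sd[s2$variable == "bio01"], 1e-6)
})

test_that("period summaries match direct recomputation over 30 years", {
  set.seed(77)
  rec <- random_records(2, 1961:1990, 1991:2020)
  bc <- compute_bioclim(rec)
  s <- summarize_period(bc, 1961:1990, with_sd = TRUE)
  for (cl in 0:1) {
    sub <- bc[bc$cell_id == cl & bc$year %in% 1961:1990, ]
    for (v in c("bio01", "bio12", "bio14")) {
      row <- s[s$cell_id == cl & s$variable == v, ]
      expect_equal(row$mean, mean(sub[[v]]))
      expect_equal(row$sd, stats::sd(sub[[v]]))
    }
  }
})

test_that("SED is zero at identity, one per unit shift, additive over variables", {
  base <- expand.grid(cell_id = 0, variable = bioclim_vars <-
                        c("bio01", "bio05", "bio06", "bio12", "bio13", "bio14"))
  base$mean <- 10
  base$sd <- 2
  rec <- base[c("cell_id", "variable", "mean")]

  expect_equal(compute_sed(base, rec)$sed, 0)

  one <- rec
  one$mean[one$variable == "bio01"] <- 12  # one baseline SD away
  expect_equal(compute_sed(base, one)$sed, 1)

  all6 <- rec
  all6$mean <- 12
  expect_equal(compute_sed(base, all6)$sed, 6)
  expect_equal(compute_sed(base, all6, sqrt = TRUE)$sed, sqrt(6))

  bad <- base
  bad$sd[1] <- 0
  expect_error(compute_sed(bad, rec), "nonpositive")
})

test_that("SED equals brute-force recomputation from monthly records", {
  set.seed(11)
  for (i in 1:20) {
    rec <- random_records(4, 2000:2004, 2010:2014, shift = runif(1, 0, 3))
    got <- climate_novelty(rec, 2000:2004, 2010:2014)
    want <- brute_sed(rec, 2000:2004, 2010:2014)
    expect_equal(got$sed, want$sed, tolerance = 1e-12)
  }
})

test_that("SED is invariant under affine rescaling of the climate series", {
  set.seed(12)
  rec <- random_records(3, 2000:2003, 2010:2013, shift = 1)
  sed1 <- climate_novelty(rec, 2000:2003, 2010:2013)$sed
  rec2 <- rec
  for (v in c("tmean", "tmax", "tmin")) rec2[[v]] <- 1.8 * rec2[[v]] + 32
  rec2$prcp <- 25.4 * rec2$prcp
  sed2 <- climate_novelty(rec2, 2000:2003, 2010:2013)$sed
  expect_equal(sed1, sed2, tolerance = 1e-9)
})

test_that("tercile breaks match the interpolation oracle and range thirds", {
  br <- tercile_breaks(1:9)
  expect_equal(br, c(brute_quantile(1:9, 1 / 3), brute_quantile(1:9, 2 / 3)))
  expect_equal(br, c(11 / 3, 19 / 3), tolerance = 1e-12)

  expect_equal(tercile_breaks(c(0, 3), method = "range_thirds"), c(1, 2))

  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:50, 1))
    for (m in c("quantile", "range_thirds")) {
      br <- tercile_breaks(x, method = m)
      expect_lte(br[1], br[2])
    }
  }
  expect_error(tercile_breaks(rep(2, 5)), "non-identical")
})

test_that("tercile classes use a left-closed upper break", {
  br <- c(2.20, 2.33)
  expect_equal(classify_tercile(2.10, br), 0L)
  expect_equal(classify_tercile(2.25, br), 1L)
  expect_equal(classify_tercile(2.33, br), 2L)
  expect_equal(classify_tercile(2.20, br), 1L)

  # classes partition the values
  set.seed(6)
  x <- rnorm(200)
  cl <- classify_tercile(x, tercile_breaks(x))
  expect_equal(sum(table(cl)), 200)
  expect_equal(sort(unique(cl)), 0:2)
})

test_that("collinearity screen flags |r| >= 0.7 and reports undefined pairs", {
  set.seed(8)
  tab <- as.data.frame(matrix(rnorm(500 * 6), ncol = 6))
  names(tab) <- c("bio01", "bio05", "bio06", "bio12", "bio13", "bio14")
  rep1 <- collinearity_screen(tab)
  expect_equal(nrow(rep1), 15)
  expect_true(all(!rep1$collinear))  # independent simulated variables

  tab2 <- tab
  tab2$bio05 <- tab2$bio01          # duplicated variable: r = 1
  tab2$bio06 <- -tab2$bio01         # r = -1, absolute-value rule
  rep2 <- collinearity_screen(tab2)
  r15 <- rep2[rep2$var1 == "bio01" & rep2$var2 == "bio05", ]
  r16 <- rep2[rep2$var1 == "bio01" & rep2$var2 == "bio06", ]
  expect_equal(r15$r, 1)
  expect_true(r15$collinear)
  expect_equal(r16$r, -1)
  expect_true(r16$collinear)

  tab3 <- tab
  tab3$bio14 <- 0                   # zero variance: r undefined, reported
  rep3 <- collinearity_screen(tab3)
  expect_true(all(is.na(rep3$r[rep3$var1 == "bio14" | rep3$var2 == "bio14"])))
})
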