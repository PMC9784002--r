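test_that("indicator tables round-trip through CSV at full precision", {
  syn <- synth_indicators(n_units = 7, seed = 42)
  vpath <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_indicator_table(syn$table, vpath, spec_path = spath)
  back <- read_indicator_table(vpath, spath)
  expect_equal(back$values, syn$table$values, tolerance = 1e-12)
  expect_identical(back$units, syn$table$units)
  expect_identical(back$specs$orientation, syn$table$specs$orientation)
})

test_that("invalid tables are rejected with the offending cell named", {
  specs <- data.frame(id = c("X1", "X2"), name = c("a", "b"),
                      dimension = "needs", orientation = "high_quality")
  v <- matrix(1:6, 3, 2, dimnames = list(NULL, c("X1", "X2")))

  bad <- v; bad[2, 2] <- NA
  expect_error(indicator_table(bad, specs, units = c("u1", "u2", "u3")),
               "u2.*X2")
  expect_error(indicator_table(v, specs, units = c("u1", "u1", "u3")),
               "duplicate unit")
  expect_error(indicator_table(v[, 1, drop = FALSE], specs,
                               units = c("u1", "u2", "u3")),
               "missing from table")
  expect_error(
    indicator_table(matrix(1, 3, 3, dimnames = list(NULL, c("X1", "X2", "X9"))),
                    specs, units = c("u1", "u2", "u3")),
    "not in spec")

  # an empty cell in a CSV file is reported with unit and indicator
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit,X1,X2", "u1,1,2", "u2,,4", "u3,5,6"), f)
  sf <- withr::local_tempfile(fileext = ".csv")
  write.csv(specs, sf, row.names = FALSE)
  expect_error(read_indicator_table(f, sf), "u2.*X1")
})

test_that("the maternal panel has 12 indicators split 3/5/4 with one low-quality", {
  p <- maternal_panel()
  expect_equal(nrow(p), 12)
  expect_equal(as.integer(table(p$dimension)[c("needs", "utilization",
                                               "resources")]),
               c(3L, 5L, 4L))
  expect_equal(p$id[p$orientation == "low_quality"], "X1")
  expect_match(p$name[1], "mortality")
})

test_that("fixture tables carry 31 provinces per year and dimension", {
  for (y in years) {
    rsr <- maternal_fixture(y, "rsr")
    prb <- maternal_fixture(y, "probit")
    grd <- maternal_fixture(y, "grading")
    for (d in dimensions) {
      expect_equal(sum(rsr$dimension == d), 31)
      expect_equal(sum(prb$dimension == d), 31)
      expect_equal(sum(grd$dimension == d), 31)
    }
    expect_equal(anyDuplicated(rsr$region[rsr$dimension == "needs"]), 0L)
    expect_true(all(c("Shanxi", "Shaanxi") %in% rsr$region))
  }
})

test_that("published ranks agree with descending order of published RSR except flagged ties", {
  for (y in years) for (d in dimensions) {
    df <- maternal_fixture(y, "rsr")
    df <- df[df$dimension == d, ]
    recomputed <- rank(-df$rsr, ties.method = "min")
    tied <- df$rsr %in% df$rsr[duplicated(df$rsr)]
    # untied provinces: printed rank is exactly the descending rank
    expect_equal(df$rank[!tied], recomputed[!tied])
    # tied provinces keep distinct printed ranks spanning their tie block
    for (v in unique(df$rsr[tied])) {
      blk <- df$rank[df$rsr == v]
      expect_equal(sort(blk), seq(min(blk), length.out = length(blk)))
    }
  }
  # the documented 2009 needs tie carries distinct printed ranks
  df <- maternal_fixture(2009, "rsr")
  im <- df[df$region == "Inner Mongolia" & df$dimension == "needs", ]
  gd <- df[df$region == "Guangdong" & df$dimension == "needs", ]
  expect_equal(im$rsr, gd$rsr)
  expect_equal(sort(c(im$rank, gd$rank)), c(16, 17))
})

test_that("spot values match the published tables", {
  rsr09 <- maternal_fixture(2009, "rsr")
  bj <- rsr09[rsr09$region == "Beijing" & rsr09$dimension == "utilization", ]
  expect_equal(bj$rsr, 0.814)
  expect_equal(bj$rank, 1)
  xz <- rsr09[rsr09$region == "Xizang" & rsr09$dimension == "utilization", ]
  expect_equal(xz$rsr, 0.032)
  expect_equal(xz$rank, 31)
  prb09 <- maternal_fixture(2009, "probit")
  fj <- prb09[prb09$region == "Fujian" & prb09$dimension == "needs", ]
  expect_equal(fj$p, 3.2)
  expect_equal(fj$probit, 3.151)
})
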