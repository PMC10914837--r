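test_that("unit weights are K/Xs with K the reciprocal standard sum", {
  std <- builtin_standards("WHO")
  # single parameter: closed form (1/1.5)/1.5 = 4/9
  w1 <- unit_weights(std, "F")
  expect_equal(w1$K, 1 / 1.5)
  expect_equal(unname(w1$Wn), 4 / 9)

  w3 <- unit_weights(std, c("F", "TDS", "pH"))
  expect_equal(w3$K, 1 / 1010)
  expect_equal(unname(w3$Wn["F"]), (1 / 1010) / 1.5, tolerance = 1e-12)
  expect_equal(unname(w3$Wn["TDS"]), (1 / 1010) / 1000, tolerance = 1e-12)
  expect_equal(unname(w3$Wn["pH"]), (1 / 1010) / 8.5, tolerance = 1e-12)

  # over the full WHO table the tightest standard (fluoride, 1.5 mg/L)
  # takes the largest weight, then potassium (12 mg/L)
  wa <- unit_weights(std)
  ord <- names(sort(wa$Wn, decreasing = TRUE))
  expect_equal(ord[1:3], c("F", "pH", "K"))
  expect_equal(rank(-wa$Wn), rank(std$Xs[match(names(wa$Wn),
                                               std$parameter)]),
               ignore_attr = TRUE)

  expect_error(unit_weights(std, character(0)), "non-empty")
  expect_error(unit_weights(std, "EC"), "not in standards")
})

test_that("quality ratings scale excursions to 100 at the standard", {
  std <- builtin_standards("WHO")
  Q <- quality_rating(who_standard_sample(), std)
  expect_true(all(Q == 100))

  s <- make_samples(F = 3.0, pH = 7.75)
  Q <- quality_rating(s, std, include = c("F", "pH"))
  expect_equal(unname(Q[, "F"]), 200)
  expect_equal(unname(Q[, "pH"]), 50)

  # signed convention reproduces the raw formula below pH 7
  s2 <- make_samples(pH = 6.25)
  expect_equal(unname(quality_rating(s2, std, "pH")[, 1]), 50)
  expect_equal(unname(quality_rating(s2, std, "pH",
                                     ph_rating = "signed")[, 1]), -50)

  expect_error(quality_rating(s, std, include = c("F", "EC")), "EC")
})

test_that("the index is the weighted mean of ratings", {
  std <- builtin_standards("WHO")
  w <- unit_weights(std, c("F", "TDS", "pH"))

  expect_equal(compute_wqi(c(F = 100, TDS = 100, pH = 100), w), 100)
  expect_equal(compute_wqi(c(F = 0, TDS = 0, pH = 0), w), 0)

  # three-parameter toy against an independent spreadsheet-style oracle
  xs <- c(1.5, 1000, 8.5)
  wn <- (1 / sum(xs)) / xs
  qn <- c(100 * 3.0 / 1.5, 100 * 500 / 1000, 100 * 0.75 / 1.5)
  oracle <- sum(qn * wn) / sum(wn)
  expect_equal(oracle, 177.3, tolerance = 1e-3)  # hand value ~177.3
  got <- compute_wqi(c(F = qn[1], TDS = qn[2], pH = qn[3]), w)
  expect_equal(got, oracle, tolerance = 1e-12)

  # invariance to rescaling all weights by a positive constant
  w2 <- w; w2$Wn <- w$Wn * 7.3
  expect_equal(compute_wqi(c(F = 120, TDS = 30, pH = 66), w2),
               compute_wqi(c(F = 120, TDS = 30, pH = 66), w),
               tolerance = 1e-12)

  expect_error(compute_wqi(c(F = 1, Cl = 2, pH = 3), w), "differ")
})

test_that("WQI increases when any one concentration rises above ideal", {
  std <- builtin_standards("WHO")
  base <- make_samples(F = 1, TA = 200, TDS = 800, Cl = 200, Na = 150,
                       K = 10, SO4 = 100, NO3 = 20, Mg = 20, Ca = 80,
                       TH = 250, pH = 7.8)
  w0 <- wqi(base, std)$wqi
  for (p in setdiff(std$parameter, "pH")) {
    up <- as.data.frame(base)
    up[[p]] <- up[[p]] * 1.5
    expect_gt(wqi(water_samples(up), std)$wqi, w0)
  }
})

test_that("reduced parameter sets keep the index inside the rating range", {
  std <- builtin_standards("WHO")
  s <- make_samples(F = 2.2, TA = 400, TDS = 1500, Cl = 500, Na = 350,
                    K = 40, SO4 = 80, NO3 = 9, Mg = 15, Ca = 90,
                    TH = 300, pH = 8.6)
  for (drop in c("F", "K", "TDS")) {
    inc <- setdiff(std$parameter, drop)
    r <- wqi(s, std, include = inc)
    Q <- attr(r, "Qn")
    expect_gte(r$wqi, min(Q))
    expect_lte(r$wqi, max(Q))
  }
})

test_that("quality bands follow the five-class table with closed upper edges", {
  expect_equal(as.character(categorize_wqi(99.323)), "poor")
  expect_equal(as.character(categorize_wqi(185.866)), "unfit")
  expect_equal(as.character(categorize_wqi(c(0, 25, 25.01, 50, 62, 75.5,
                                             100, 100.000001))),
               c("potable", "potable", "palatable", "palatable",
                 "moderately poor", "poor", "poor", "unfit"))
  expect_error(categorize_wqi(-0.1), "non-negative")
})

test_that("village aggregation supports both documented methods", {
  std <- builtin_standards("WHO")
  # five identical samples: both methods collapse to the sample WQI
  vals <- list(F = 2, TA = 300, TDS = 1200, Cl = 400, Na = 300, K = 25,
               SO4 = 60, NO3 = 7, Mg = 14, Ca = 80, TH = 240, pH = 8.4)
  s <- do.call(make_samples, c(lapply(vals, rep, 5),
                               list(village = rep("A", 5))))
  one <- wqi(s[1, ], std)$wqi
  for (m in c("mean-of-wqi", "wqi-of-mean")) {
    v <- village_summary(s, std, method = m)
    expect_equal(v$wqi, one, tolerance = 1e-12)
    expect_equal(v$n_samples, 5L)
  }
  expect_error(village_summary(make_samples(), std), "village")
})

test_that("mean-of-wqi averages per-sample indices", {
  std <- builtin_standards("WHO")
  # scale the standard sample so the per-sample indices are known multiples
  base <- as.data.frame(who_standard_sample())
  mult <- c(1.1, 1.2, 1.3, 1.4, 1.5)
  rows <- do.call(rbind, lapply(seq_along(mult), function(i) {
    r <- base
    for (p in setdiff(names(r), c("sample_id", "pH"))) r[[p]] <- r[[p]] * mult[i]
    r$sample_id <- paste0("s", i)
    r
  }))
  rows$village <- "A"
  rows$pH <- 8.5  # keep the pH rating at 100 throughout
  s <- water_samples(rows)
  per <- wqi(s, std)$wqi
  v <- village_summary(s, std)
  expect_equal(v$wqi, mean(per), tolerance = 1e-12)
  expect_equal(as.character(v$category), "unfit")
})

test_that("aggregate bands match a brute-force check over simulated villages", {
  s <- suppressWarnings(generate_samples(seed = 9))
  v <- village_summary(s)
  expect_equal(as.character(v$category) == "unfit", v$wqi > 100)
})
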