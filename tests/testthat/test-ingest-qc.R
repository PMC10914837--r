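test_that("sample tables round-trip through CSV with schema validation", {
  s <- make_samples(F = c(1.2, 2.1), TDS = c(900, 1500), pH = c(8.008, 8.960),
                    Na = c(200, 400), TA = c(300, 350), Cl = c(250, 500),
                    K = c(20, 30), SO4 = c(50, 70), NO3 = c(6, 8),
                    Mg = c(10, 20), Ca = c(70, 90), TH = c(200, 300))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(s), path, row.names = FALSE)
  back <- read_sample_table(path)
  expect_s3_class(back, "water_samples")
  expect_equal(nrow(back), 2)
  expect_equal(back$pH, c(8.008, 8.960))    # parsed values echo input
  expect_equal(back$sample_id, s$sample_id) # row order preserved

  # missing required column is named in the error
  df <- as.data.frame(s); df$F <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_sample_table(path), "F")

  # non-numeric cell errors with its row index
  df <- as.data.frame(s); df$Na <- c("200", "oops")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_sample_table(path), "row 2")

  # negative concentration rejected
  df <- as.data.frame(s); df$Cl <- c(-1, 500)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_sample_table(path), "negative")
})

test_that("column-name schema mapping renames file headers", {
  s <- make_samples(TDS = 1200)
  df <- as.data.frame(s)
  names(df)[names(df) == "TDS"] <- "TDS (mg/L)"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_sample_table(path), "TDS")
  back <- read_sample_table(path, schema = c(TDS = "TDS (mg/L)"))
  expect_equal(back$TDS, 1200)
})

test_that("meq conversion matches equivalent-weight arithmetic", {
  prof <- to_meq(make_samples(Na = 22.99, Ca = 40.08))
  expect_equal(prof$Na, 1.0)
  expect_equal(prof$Ca, 2.0)

  # survey-mean profile: meq values and cation dominance sequence
  m <- default_marginals()
  vals <- setNames(as.list(m$mean), m$parameter)
  prof <- to_meq(do.call(make_samples, vals))
  expect_equal(prof$Na, 343.4 / 22.99)    # ~14.94
  expect_equal(prof$Ca, 82.42 / 20.04)    # ~4.11
  expect_equal(prof$Mg, 13.464 / 12.15)   # ~1.11
  expect_equal(prof$K, 29.08 / 39.10)     # ~0.74
  dom <- dominance_sequence(prof)[[1]]
  expect_equal(dom$cations, c("Na", "Ca", "Mg", "K"))
})

test_that("bicarbonate comes from TA unless HCO3 is measured", {
  via_ta <- to_meq(make_samples(TA = 100))
  expect_equal(via_ta$HCO3, 100 * (61.02 / 50.04) / 61.02)
  expect_match(attr(via_ta, "hco3_source"), "TA")

  df <- as.data.frame(make_samples(TA = 100))
  df$HCO3 <- 61.02
  via_hco3 <- to_meq(water_samples(df))
  expect_equal(via_hco3$HCO3, 1.0)
  expect_match(attr(via_hco3, "hco3_source"), "measured")

  df$HCO3 <- NULL; df$TA <- NULL
  expect_error(to_meq(water_samples(df)), "HCO3")
})

test_that("meq conversion inverts to mg/L within 1e-9 relative", {
  set.seed(11)
  ions <- c("Ca", "Mg", "Na", "K", "Cl", "SO4", "NO3", "F")
  vals <- setNames(as.list(runif(8, 1, 500)), ions)
  s <- do.call(make_samples, c(vals, list(TA = 0)))
  prof <- to_meq(s)
  for (ion in ions) {
    back <- prof[[ion]] * unname(equivalent_weight(ion))
    expect_equal(back, s[[ion]], tolerance = 1e-9)
  }
})

test_that("charge-balance gate flags imbalance beyond +-5%", {
  # perfectly balanced NaCl water
  bal <- charge_balance(to_meq(make_samples(Na = 22.99, Cl = 35.45)))
  expect_equal(bal$cbe_percent, 0)
  expect_true(bal$pass)

  # cation sum 10 vs anion sum 9 meq/L: +100/19 %, outside the gate
  s <- make_samples(Na = 10 * 22.99, Cl = 9 * 35.45)
  chk <- charge_balance(to_meq(s))
  expect_equal(chk$cbe_percent, 100 / 19, tolerance = 1e-12)
  expect_false(chk$pass)

  # cation 10 vs anion 10.5: -100*0.5/20.5 %, inside
  s <- make_samples(Na = 10 * 22.99, Cl = 10.5 * 35.45)
  chk <- charge_balance(to_meq(s))
  expect_equal(chk$cbe_percent, 100 * (-0.5) / 20.5, tolerance = 1e-12)
  expect_true(chk$pass)

  expect_error(charge_balance(to_meq(make_samples())), "all-zero")
})

test_that("CBE is antisymmetric and scale invariant", {
  set.seed(21)
  for (i in 1:20) {
    na <- runif(1, 10, 500); cl <- runif(1, 10, 500)
    a <- charge_balance(to_meq(make_samples(Na = na, Cl = cl)))
    b <- charge_balance(to_meq(make_samples(Na = cl * 22.99 / 35.45,
                                            Cl = na * 35.45 / 22.99)))
    expect_equal(a$cbe_percent, -b$cbe_percent, tolerance = 1e-9)
    k <- runif(1, 0.1, 10)
    sc <- charge_balance(to_meq(make_samples(Na = k * na, Cl = k * cl)))
    expect_equal(sc$cbe_percent, a$cbe_percent, tolerance = 1e-9)
  }
})

test_that("dominance ordering is descending with catalog-order tie-break", {
  prof <- to_meq(make_samples(TA = 8 * 50.04, Cl = 6 * 35.45,
                              SO4 = 1.2 * 48.03, NO3 = 0.1 * 62,
                              F = 0.08 * 19, Na = 22.99))
  dom <- dominance_sequence(prof)[[1]]
  expect_equal(dom$anions, c("HCO3", "Cl", "SO4", "NO3", "F"))
  expect_false(dom$anion_tie)

  # all cations at equal meq: catalog order, flagged as tied
  eq <- to_meq(make_samples(Ca = 20.04, Mg = 12.15, Na = 22.99, K = 39.10,
                            Cl = 35.45))
  dom <- dominance_sequence(eq)[[1]]
  expect_equal(dom$cations, c("Ca", "Mg", "Na", "K"))
  expect_true(dom$cation_tie)

  # dominance order unchanged under uniform scaling
  s1 <- dominance_sequence(to_meq(make_samples(Na = 100, Ca = 50, Cl = 120)))
  s2 <- dominance_sequence(to_meq(make_samples(Na = 300, Ca = 150, Cl = 360)))
  expect_equal(s1[[1]]$cations, s2[[1]]$cations)
})
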