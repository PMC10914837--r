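test_that("rank correlation handles ties by midranks", {
  df <- data.frame(a = c(1, 2, 2, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  rho <- spearman_matrix(df, c("a", "b", "c"))
  # oracle: midrank both vectors, then the Pearson formula, by hand
  ra <- c(1, 2.5, 2.5, 4); rb <- c(1, 3, 2, 4)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(rho["a", "b"], oracle, tolerance = 1e-12)
  # reversal of a tied vector: the midrank oracle again (|rho| < 1 with ties)
  rc <- c(4, 3, 2, 1)
  oracle_ac <- sum((ra - mean(ra)) * (rc - mean(rc))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rc - mean(rc))^2))
  expect_equal(rho["a", "c"], oracle_ac, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(rho)[, ]))
  expect_equal(unname(diag(rho)), rep(1, 3))
})

test_that("rank correlation is invariant to monotone transforms", {
  set.seed(41)
  df <- data.frame(a = rexp(30), b = rnorm(30), c = runif(30))
  r1 <- spearman_matrix(df, c("a", "b", "c"))
  df2 <- data.frame(a = log(df$a), b = df$b^3 + 5 * df$b, c = exp(df$c))
  r2 <- spearman_matrix(df2, c("a", "b", "c"))
  expect_equal(unclass(r1)[, ], unclass(r2)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # y = 2x: perfect monotone association
  df$d <- 2 * df$a
  expect_equal(spearman_matrix(df, c("a", "d"))["a", "d"], 1)
})

test_that("constant variables are flagged undefined, not zeroed", {
  df <- data.frame(a = 1:10, b = rep(3, 10))
  expect_warning(rho <- spearman_matrix(df, c("a", "b")), "constant")
  expect_true(is.na(rho["a", "b"]))
  expect_equal(attr(rho, "constant"), "b")
  expect_equal(rho["b", "b"], 1)
  expect_error(spearman_matrix(df[1:2, ], c("a", "b")), "3 samples")
})

test_that("correlation PCA satisfies its spectral identities", {
  s <- suppressWarnings(generate_samples(seed = 5))
  p <- pca_correlation(s)
  expect_equal(sum(p$eigenvalues), length(p$variables), tolerance = 1e-8)
  expect_equal(sum(p$pct_variance), 100, tolerance = 1e-8)
  # full loading matrix reconstructs the correlation matrix
  expect_equal(p$loadings %*% t(p$loadings), p$correlation,
               tolerance = 1e-8, ignore_attr = TRUE)
  # deterministic sign convention: top entry of each column positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("degenerate correlation structures give the expected spectra", {
  # two perfectly correlated variables: eigenvalues {2, 0}
  df <- data.frame(a = c(1, 2, 3, 4, 5), b = 2 * c(1, 2, 3, 4, 5) + 1)
  p <- suppressWarnings(pca_correlation(df, c("a", "b")))
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(p$pct_variance[1], 100, tolerance = 1e-9)
  expect_equal(p$n_retained, 1)

  expect_error(pca_correlation(df[1:2, ], c("a", "b")), "at least")
  df$c <- 1
  expect_error(pca_correlation(df, c("a", "c")), "constant")
})

test_that("the Kaiser rule counts eigenvalues strictly above one", {
  expect_equal(kaiser_retain(c(2.5, 1.1, 0.7, 0.4)), 2)
  expect_equal(kaiser_retain(c(1.0, 0.9)), 0)
  expect_equal(kaiser_retain(c(3)), 1)
  expect_error(kaiser_retain(numeric(0)), "empty")
  expect_error(kaiser_retain(c(0.4, 2.5)), "descending")
})

test_that("varimax leaves simple structure fixed and recovers mixed structure", {
  L0 <- cbind(c(0.9, 0.8, 0.7, 0, 0, 0), c(0, 0, 0, 0.85, 0.75, 0.65))
  # already simple structure: unchanged up to sign
  out <- varimax_rotate(L0, tol = 1e-10)
  expect_equal(unclass(out)[, ], L0, tolerance = 1e-6, ignore_attr = TRUE)

  # mix by a known 30 degree rotation, then recover
  M <- L0 %*% rot2(pi / 6)
  rec <- varimax_rotate(M, tol = 1e-12)
  # grid-search oracle over rotation angles
  grid_crit <- sapply(seq(-pi / 4, pi / 4, length.out = 20001), function(th)
    varimax_criterion_oracle(M %*% rot2(th)))
  expect_gte(varimax_criterion_oracle(rec), max(grid_crit) - 1e-8)
  # alignment up to sign/permutation
  perm <- apply(abs(t(rec) %*% L0), 2, which.max)
  aligned <- rec[, perm, drop = FALSE]
  for (j in 1:2) if (sum(aligned[, j] * L0[, j]) < 0) aligned[, j] <- -aligned[, j]
  expect_equal(unclass(aligned)[, ], L0, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("varimax preserves communalities and improves monotonically", {
  set.seed(43)
  for (i in 1:10) {
    L <- matrix(rnorm(12 * 3), 12, 3)
    out <- varimax_rotate(L, tol = 1e-10)
    expect_equal(rowSums(unclass(out)^2), rowSums(L^2), tolerance = 1e-8)
    path <- attr(out, "criterion")
    expect_true(all(diff(path) >= -1e-12))
    # orthogonality of the accumulated rotation
    R <- attr(out, "rotmat")
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(L %*% R, unclass(out), tolerance = 1e-10, ignore_attr = TRUE)
  }
  # single retained component: returned unchanged (up to sign convention)
  one <- matrix(c(0.9, -0.4, 0.2), 3, 1)
  expect_equal(unclass(varimax_rotate(one))[, ], one[, 1], ignore_attr = TRUE)
})

test_that("varimax agrees with the reference implementation", {
  set.seed(44)
  L <- matrix(rnorm(10 * 3), 10, 3)
  for (norm in c(FALSE, TRUE)) {
    mine <- varimax_rotate(L, tol = 1e-12, normalize = norm)
    ref <- stats::varimax(L, normalize = norm, eps = 1e-10)
    expect_equal(varimax_criterion_oracle(unclass(mine)),
                 varimax_criterion_oracle(ref$loadings), tolerance = 1e-7)
  }
})

test_that("loading strength bands follow the 0.75/0.50/0.30 cuts", {
  expect_equal(classify_loading(0.823), "strong")
  expect_equal(classify_loading(-0.435), "weak")
  expect_equal(classify_loading(c(0.75, 0.5, 0.3, 0.2999)),
               c("strong", "moderate", "weak", "negligible"))
  expect_error(classify_loading(1.2), "exceeds 1")
})

test_that("planted block structure is recovered end to end", {
  s <- suppressWarnings(generate_block_structured(n = 500, seed = 42))
  p <- pca_correlation(s)
  expect_equal(p$n_retained, 3)
  blocks <- attr(s, "blocks")
  assign <- apply(abs(p$rotated_loadings), 1, which.max)
  # variables sharing a planted block share a component, blocks differ
  comp_of_block <- vapply(blocks, function(b) unique(assign[b])[1], numeric(1))
  for (b in seq_along(blocks))
    expect_true(all(assign[blocks[[b]]] == comp_of_block[b]))
  expect_equal(sort(comp_of_block), 1:3)
  # block variables load strongly on their own component
  expect_true(all(abs(p$rotated_loadings[blocks[[1]], comp_of_block[1]]) >= 0.75))
})
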