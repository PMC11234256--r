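test_that("bait normalization divides by per-channel bait abundance", {
  lay <- tiny_layout()
  m <- tiny_matrix(list(P1 = c(250, rep(100, 5), 1, 1, 1)))
  norm <- bait_normalize(m, lay)
  expect_equal(unname(norm$values["P1", "WT_1"]), 0.25)
  expect_equal(unname(norm$values["BAIT", ]), rep(1, 6))
  expect_false("CTRL_1" %in% colnames(norm$values))

  # multiplying one whole channel by 7 cancels in the ratio
  vals <- m$values
  vals[, "VAR_2"] <- vals[, "VAR_2"] * 7
  norm2 <- bait_normalize(abundance_matrix(vals, "BAIT"), lay)
  expect_equal(norm2$values, norm$values)

  # missing propagates; missing/zero bait is an error naming the channel
  vals_na <- m$values
  vals_na["P1", "WT_2"] <- NA
  expect_true(is.na(bait_normalize(abundance_matrix(vals_na, "BAIT"),
                                   lay)$values["P1", "WT_2"]))
  vals_bad <- m$values
  vals_bad["BAIT", "VAR_3"] <- 0
  expect_error(bait_normalize(abundance_matrix(vals_bad, "BAIT"), lay),
               "VAR_3", class = "apms_normalization_error")
})

test_that("fold enrichment is the variant/WT ratio of mean normalized abundance", {
  lay <- tiny_layout()
  # bait constant 1000 -> normalized values are value/1000
  m <- tiny_matrix(list(
    P1 = c(100, 100, 100, 200, 250, 150, 1, 1, 1),  # FE = 0.20/0.10 = 2
    P2 = c(rep(120, 6), 1, 1, 1)                    # identical -> FE = 1
  ))
  fe <- fold_enrichment(bait_normalize(m, lay), lay)
  expect_equal(fe$fold_enrichment[fe$protein == "P1"], 2)
  expect_equal(fe$fold_enrichment[fe$protein == "P2"], 1)
  expect_equal(fe$fold_enrichment[fe$protein == "BAIT"], 1)
})

test_that("fold enrichment flags undefined cases but keeps the protein", {
  lay <- tiny_layout()
  vals <- tiny_matrix(list(P1 = c(NA, NA, NA, 100, 110, 90, 1, 1, 1)))$values
  m <- abundance_matrix(vals, "BAIT")
  expect_warning(fe <- fold_enrichment(bait_normalize(m, lay), lay),
                 "undefined")
  row <- fe[fe$protein == "P1", ]
  expect_false(row$defined)
  expect_true(is.na(row$fold_enrichment))
  expect_identical(row$n_wt, 0L)
  expect_identical(nrow(fe), 2L)  # protein retained
})

test_that("fold enrichment is invariant under per-channel rescaling", {
  lay <- tiny_layout()
  set.seed(31)
  for (i in 1:10) {
    vals <- matrix(stats::rlnorm(15 * 9, 3, 1), 15, 9,
                   dimnames = list(c("BAIT", paste0("P", 1:14)), lay$channel))
    m <- abundance_matrix(vals, "BAIT")
    fe1 <- fold_enrichment(bait_normalize(m, lay), lay)
    scales <- stats::rlnorm(9, 0, 1)
    m2 <- abundance_matrix(sweep(vals, 2L, scales, "*"), "BAIT")
    fe2 <- fold_enrichment(bait_normalize(m2, lay), lay)
    expect_equal(fe2$fold_enrichment, fe1$fold_enrichment, tolerance = 1e-12)
  }
})

test_that("ratio of means equals ratio of sums at equal replicate counts", {
  lay <- tiny_layout()
  set.seed(5)
  vals <- matrix(stats::rlnorm(10 * 9, 3, 1), 10, 9,
                 dimnames = list(c("BAIT", paste0("P", 1:9)), lay$channel))
  norm <- bait_normalize(abundance_matrix(vals, "BAIT"), lay)
  fe <- fold_enrichment(norm, lay)
  by_sums <- rowSums(norm$values[, paste0("VAR_", 1:3)]) /
    rowSums(norm$values[, paste0("WT_", 1:3)])
  expect_equal(fe$fold_enrichment, unname(by_sums), tolerance = 1e-12)
})

test_that("pooled t-test matches the closed form and its stated policies", {
  fit <- homoscedastic_t_test(c(2, 4, 6), c(1, 2, 3))
  orc <- oracle_pooled_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(fit$t_statistic, orc$t, tolerance = 1e-10)
  expect_equal(fit$t_statistic, 1.549193338, tolerance = 1e-8)
  expect_identical(fit$df, 4)
  expect_equal(fit$p_value, 0.1962611781, tolerance = 1e-8)

  same <- homoscedastic_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # zero pooled variance: defined, not an error
  expect_message(z1 <- homoscedastic_t_test(c(5, 5, 5), c(7, 7, 7)),
                 "zero variance")
  expect_equal(z1$p_value, 0)
  expect_message(z2 <- homoscedastic_t_test(c(5, 5, 5), c(5, 5, 5)),
                 "zero variance")
  expect_equal(z2$p_value, 1)

  expect_error(homoscedastic_t_test(c(1), c(1, 2, 3)),
               class = "apms_insufficient_replicates")
})

test_that("log2 transform option tests the log-scale means", {
  a <- c(2, 4, 8); b <- c(1, 2, 4)
  fit <- homoscedastic_t_test(a, b, log_transform = TRUE)
  orc <- oracle_pooled_t(log2(a), log2(b))
  expect_equal(fit$t_statistic, orc$t, tolerance = 1e-10)
  expect_equal(fit$p_value, orc$p, tolerance = 1e-10)
  expect_error(homoscedastic_t_test(c(-1, 2, 3), b, log_transform = TRUE),
               class = "apms_validation_error")
})

test_that("Welch test matches the closed form and nears the pooled test", {
  a <- c(0.30, 0.35, 0.40, 0.33); b <- c(0.60, 0.62, 0.66, 0.70)
  fit <- welch_t_test(a, b)
  orc <- oracle_welch_t(a, b)
  expect_equal(fit$t_statistic, orc$t, tolerance = 1e-10)
  expect_equal(fit$df, orc$df, tolerance = 1e-10)
  expect_equal(fit$p_value, orc$p, tolerance = 1e-10)
  expect_lt(fit$p_value, 0.01)

  expect_equal(welch_t_test(a, a)$p_value, 1)

  # with equal sample variances at n1 = n2 the Satterthwaite df collapses
  # to n1 + n2 - 2, so Welch and pooled tests coincide
  set.seed(99)
  for (i in 1:20) {
    x <- stats::rnorm(5)
    y <- x + stats::runif(1, 0.2, 1)  # pure shift: identical variance
    pw <- welch_t_test(x, y)
    pp <- homoscedastic_t_test(x, y)
    expect_equal(pw$df, pp$df, tolerance = 1e-10)
    expect_equal(pw$p_value, pp$p_value, tolerance = 1e-10)
  }
})

test_that("swapping group labels negates t and preserves p", {
  set.seed(12)
  for (i in 1:10) {
    x <- stats::rnorm(4); y <- stats::rnorm(4, 1)
    f1 <- homoscedastic_t_test(x, y); f2 <- homoscedastic_t_test(y, x)
    expect_equal(f1$t_statistic, -f2$t_statistic, tolerance = 1e-12)
    expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
    w1 <- welch_t_test(x, y); w2 <- welch_t_test(y, x)
    expect_equal(w1$t_statistic, -w2$t_statistic, tolerance = 1e-12)
    expect_equal(w1$p_value, w2$p_value, tolerance = 1e-12)
  }
})
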