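make_counts <- function(...) {
  df <- do.call(rbind, lapply(list(...), function(r) {
    data.frame(participant = r[[1]], image = r[[2]], genotype = r[[3]],
               positive = r[[4]], total = r[[5]], stringsAsFactors = FALSE)
  }))
  rater_counts(df$participant, df$image, df$genotype, df$positive, df$total)
}

test_that("rater count tables validate counts", {
  expect_error(rater_counts("p1", "i1", "WT", 11, 10),
               class = "apms_validation_error")
  expect_error(rater_counts("p1", "i1", "WT", -1, 10),
               class = "apms_validation_error")
  expect_error(rater_counts("p1", "i1", "WT", 0, 0),
               class = "apms_validation_error")
})

test_that("per-participant proportions pool counts across images", {
  counts <- make_counts(
    list("p1", "i1", "WT", 3, 10), list("p1", "i2", "WT", 4, 10)
  )
  s <- retention_summary(counts)
  expect_equal(s$participant$proportion, 7 / 20)
  expect_equal(s$genotype$mean_proportion, 0.35)
  expect_equal(s$genotype$sem, 0)  # single participant
})

test_that("genotype summary averages participants with SEM across raters", {
  counts <- make_counts(
    list("p1", "i1", "WT", 30, 100),
    list("p2", "i1", "WT", 35, 100),
    list("p3", "i1", "WT", 40, 100)
  )
  s <- retention_summary(counts)
  expect_equal(s$genotype$mean_proportion, 0.35)
  expect_equal(s$genotype$sem, 0.05 / sqrt(3), tolerance = 1e-12)
  expect_identical(s$genotype$n_participants, 3L)

  zero <- make_counts(list("p1", "i1", "WT", 0, 50), list("p2", "i1", "WT", 0, 50))
  sz <- retention_summary(zero)
  expect_equal(sz$genotype$mean_proportion, 0)
  expect_equal(sz$genotype$sem, 0)
})

test_that("summary requires full participant/genotype coverage", {
  counts <- make_counts(
    list("p1", "i1", "WT", 3, 10), list("p1", "i2", "HET", 5, 10),
    list("p2", "i1", "WT", 4, 10)
  )
  expect_error(retention_summary(counts), "p2", class = "apms_coverage_error")
})

test_that("summary is invariant to record ordering and bounded by image extremes", {
  set.seed(3)
  counts <- simulate_rater_counts(seed = 41)
  s1 <- retention_summary(counts)
  shuffled <- counts[sample(nrow(counts)), ]
  s2 <- retention_summary(rater_counts(shuffled$participant, shuffled$image,
                                       shuffled$genotype, shuffled$positive,
                                       shuffled$total))
  expect_equal(s1$participant, s2$participant)
  expect_equal(s1$genotype, s2$genotype)

  # pooled proportion lies between the per-image extremes
  for (i in seq_len(nrow(s1$participant))) {
    row <- s1$participant[i, ]
    sub <- counts[counts$participant == row$participant &
                    counts$genotype == row$genotype, ]
    props <- sub$positive / sub$total
    expect_gte(row$proportion, min(props))
    expect_lte(row$proportion, max(props))
  }
})

test_that("max-p rule reports the largest per-participant Welch p-value", {
  counts <- simulate_rater_counts(true_proportion = c(WT = 0.3, HET = 0.6),
                                  seed = 10)
  sig <- retention_significance(counts, "WT", "HET")
  expect_identical(nrow(sig$participant), 3L)
  expect_equal(sig$p_reported, max(sig$participant$p_value))
  expect_true(all(sig$p_reported >= sig$participant$p_value))

  # a participant scoring identical proportions in both genotypes forces p = 1
  counts2 <- make_counts(
    list("p1", "a1", "WT", 2, 10), list("p1", "a2", "WT", 4, 10),
    list("p1", "b1", "HET", 2, 10), list("p1", "b2", "HET", 4, 10),
    list("p2", "a1", "WT", 1, 10), list("p2", "a2", "WT", 2, 10),
    list("p2", "b1", "HET", 8, 10), list("p2", "b2", "HET", 9, 10)
  )
  sig2 <- retention_significance(counts2, "WT", "HET")
  expect_equal(sig2$p_reported, 1)

  short <- make_counts(
    list("p1", "a1", "WT", 2, 10),
    list("p1", "b1", "HET", 3, 10), list("p1", "b2", "HET", 4, 10)
  )
  expect_error(retention_significance(short, "WT", "HET"),
               "p1", class = "apms_insufficient_data")
})

test_that("measurement comparison supports both variance modes", {
  x <- seq(1.0, 1.9, by = 0.1)
  expect_equal(compare_measurements(x, x)$p_value, 1)
  expect_lt(compare_measurements(x, x + 5)$p_value, 0.001)
  expect_equal(compare_measurements(x, x + 5)$p_value,
               compare_measurements(x + 5, x)$p_value, tolerance = 1e-12)
  expect_identical(compare_measurements(x, x + 1, "pooled")$method,
                   "homoscedastic")
  expect_identical(compare_measurements(x, x + 1, "welch")$method, "welch")
})

test_that("counts and measurements read back from delimited files", {
  counts <- simulate_rater_counts(images_per_genotype = 3L, seed = 6)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_rater_counts(path)
  expect_equal(as.data.frame(back), as.data.frame(counts))

  mpath <- tempfile(fileext = ".csv")
  writeLines(c("group,value", "WT,1.5", "HOM,0.9"), mpath)
  meas <- read_measurements(mpath)
  expect_identical(meas$group, c("WT", "HOM"))
  expect_equal(meas$value, c(1.5, 0.9))
})
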