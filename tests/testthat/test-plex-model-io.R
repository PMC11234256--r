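test_that("layout construction validates roles, replicates and uniqueness", {
  lay <- tiny_layout(n_unused = 1L)
  expect_s3_class(lay, "plex_layout")
  expect_length(apmsenrich:::.active_channels(lay), 9L)
  expect_identical(experimental_channels(lay),
                   c("WT_1", "WT_2", "WT_3", "VAR_1", "VAR_2", "VAR_3"))
  expect_identical(control_channels(lay), paste0("CTRL_", 1:3))

  expect_error(plex_layout(c("a", "b"), c("WT_BAIT", "WT_BAIT"), c(1, 1)),
               class = "apms_validation_error")
  expect_error(plex_layout("a", "SOME_ROLE", 1),
               class = "apms_validation_error")
  expect_error(plex_layout(character(), character(), integer()),
               class = "apms_validation_error")
  expect_error(plex_layout(c("a", "a"), c("WT_BAIT", "VARIANT_BAIT"), c(1, 1)),
               class = "apms_validation_error")
  # duplicate replicate indices are fine across roles, and for UNUSED channels
  expect_silent(plex_layout(c("a", "b", "c"),
                            c("WT_BAIT", "VARIANT_BAIT", "UNUSED"), c(1, 1, 1)))
})

test_that("layout JSON round-trips and validates on read", {
  lay <- tiny_layout(n_unused = 1L)
  path <- tempfile(fileext = ".json")
  write_layout(lay, path)
  lay2 <- read_layout(path)
  expect_identical(as.data.frame(lay), as.data.frame(lay2))

  bad <- list(channels = data.frame(id = c("a", "b"),
                                    role = c("WT_BAIT", "WT_BAIT"),
                                    replicate = c(1, 1)))
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(read_layout(path2), class = "apms_validation_error")
  path3 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(channels = list()), path3)
  expect_error(read_layout(path3), class = "apms_validation_error")
})

test_that("abundance tables load with missing-value and error handling", {
  lay <- tiny_layout()
  m <- read_abundance_table(write_abundance_fixture(), lay, bait_id = "BAIT")
  expect_identical(dim(m), c(3L, 9L))
  expect_identical(sum(is.na(m$values)), 0L)
  expect_identical(unname(m$gene["P1"]), "G1")

  m2 <- read_abundance_table(write_abundance_fixture(blank_cell = c(2L, 4L)),
                             lay, bait_id = "BAIT")
  expect_identical(sum(is.na(m2$values)), 1L)
  expect_true(is.na(m2$values["P1", "VAR_1"]))

  expect_error(
    read_abundance_table(write_abundance_fixture(drop_channel = "VAR_2"),
                         lay, bait_id = "BAIT"),
    "VAR_2", class = "apms_layout_mismatch")
  expect_error(
    read_abundance_table(write_abundance_fixture(), lay, bait_id = "NOPE"),
    class = "apms_bait_not_found")
  expect_error(
    read_abundance_table(write_abundance_fixture(negative_cell = c(3L, 2L)),
                         lay, bait_id = "BAIT"),
    class = "apms_validation_error")
})

test_that("tab- and comma-delimited dialects produce identical matrices", {
  lay <- tiny_layout()
  m_tab <- read_abundance_table(write_abundance_fixture(sep = "\t"), lay, "BAIT")
  m_csv <- read_abundance_table(write_abundance_fixture(sep = ","), lay, "BAIT")
  expect_identical(m_tab$values, m_csv$values)
})

test_that("contaminant accessions are excluded at load", {
  lay <- tiny_layout()
  m <- read_abundance_table(write_abundance_fixture(), lay, "BAIT",
                            contaminants = "P2")
  expect_identical(rownames(m$values), c("BAIT", "P1"))
  conta_file <- tempfile()
  writeLines("P1", conta_file)
  m2 <- read_abundance_table(write_abundance_fixture(), lay, "BAIT",
                             contaminants = conta_file)
  expect_identical(rownames(m2$values), c("BAIT", "P2"))
})

test_that("abundance matrices round-trip through write/read", {
  lay <- tiny_layout()
  sim <- simulate_apms(apms_sim_config(n_background_binders = 5L,
                                       n_nonspecific = 3L, n_differential = 2L,
                                       seed = 11))
  path <- tempfile(fileext = ".tsv")
  write_abundance_table(sim$abundance, path)
  back <- read_abundance_table(path, sim$layout, bait_id = "BAIT")
  expect_equal(back$values, sim$abundance$values, tolerance = 1e-10)
})

test_that("enrichment tables round-trip and degenerate tables serialize", {
  tab <- data.frame(protein = c("A", "B"), gene = c("a", "b"),
                    fold_enrichment = c(2.5, 0.5),
                    p_value = c(0.001234567, 0.25),
                    q_value = c(0.01, 0.3),
                    significant = c(TRUE, FALSE),
                    high_confidence = c(TRUE, TRUE),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_enrichment_table(tab, path)
  expect_length(readLines(path), 3L)
  back <- read_enrichment_table(path)
  expect_identical(back$protein, tab$protein)
  expect_equal(back$p_value, tab$p_value, tolerance = 1e-7)
  expect_identical(back$significant, tab$significant)

  empty <- tab[0L, ]
  path2 <- tempfile(fileext = ".tsv")
  write_enrichment_table(empty, path2)
  expect_length(readLines(path2), 1L)
  expect_error(write_enrichment_table(tab, file.path(tempdir(), "no", "x.tsv")),
               class = "apms_io_error")
})

test_that("abundance matrix constructor rejects invalid input", {
  v <- matrix(1:4, 2, dimnames = list(c("BAIT", "P1"), c("c1", "c2")))
  expect_error(abundance_matrix(unname(v), "BAIT"), class = "apms_validation_error")
  v2 <- v; v2[2, 1] <- -1
  expect_error(abundance_matrix(v2, "BAIT"), class = "apms_validation_error")
  expect_error(abundance_matrix(v, "ZZZ"), class = "apms_bait_not_found")
})
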