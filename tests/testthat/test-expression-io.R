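test_that("read_expression_tsv builds the tensor and validates input", {
  fx <- write_expression_fixture()
  ds <- read_expression_tsv(fx$expr, fx$manifest)
  expect_s3_class(ds, "coex_dataset")
  expect_equal(dim(ds$values), c(3, 2, 2))
  expect_equal(ds$timepoints, c(0, 4))
  expect_equal(ds$values["p2", "t4", "r2"], 11)

  # duplicated probeset row
  dir <- withr::local_tempdir()
  lines <- readLines(fx$expr)
  writeLines(c(lines, lines[2]), file.path(dir, "dup.tsv"))
  expect_error(read_expression_tsv(file.path(dir, "dup.tsv"), fx$manifest),
               "duplicate")

  # manifest names a column absent from the file
  mf <- utils::read.delim(fx$manifest)
  mf$column[1] <- "t9_r9"
  expect_error(read_expression_tsv(fx$expr, mf), "absent")

  # file column not covered by the manifest
  mf2 <- utils::read.delim(fx$manifest)[-1, ]
  expect_error(read_expression_tsv(fx$expr, mf2), "not described")

  # non-numeric cell is reported with its location
  lines2 <- readLines(fx$expr)
  lines2[3] <- sub("^p2\t2", "p2\toops", lines2[3])
  writeLines(lines2, file.path(dir, "bad.tsv"))
  expect_error(read_expression_tsv(file.path(dir, "bad.tsv"), fx$manifest),
               "non-numeric.*oops")
})

test_that("anova_filter selects extreme separation and skips flat probesets", {
  # p1 constant; p2 has group means 0, 0, 10 with sd 0.01
  set.seed(1)
  vals <- array(NA_real_, c(2, 3, 3),
                dimnames = list(c("p1", "p2"), NULL, NULL))
  vals[1, , ] <- 5
  vals[2, , ] <- rbind(rnorm(3, 0, 0.01), rnorm(3, 0, 0.01),
                       rnorm(3, 10, 0.01))
  ds <- expression_dataset(vals, c(0, 2, 8))
  res <- anova_filter(ds, alpha = 0.05)
  expect_false(res$selected[res$probeset_id == "p1"])
  expect_true(res$selected[res$probeset_id == "p2"])
})

test_that("anova_filter controls the type-I error on null data", {
  set.seed(77)
  n <- 2000
  vals <- array(rnorm(n * 5 * 3), c(n, 5, 3))
  dimnames(vals)[[1]] <- sprintf("p%04d", seq_len(n))
  ds <- expression_dataset(vals, 1:5)
  res <- anova_filter(ds, alpha = 0.05)
  hits <- sum(res$selected)
  ci <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("probesets lacking usable groups are excluded with a warning", {
  vals <- array(NA_real_, c(2, 2, 2), dimnames = list(c("p1", "p2"), NULL,
                                                      NULL))
  vals[1, , ] <- matrix(c(1, 2, 3, 4), 2)
  vals[2, 1, ] <- c(1, 2)  # only one time group has data
  ds <- expression_dataset(vals, c(0, 6))
  expect_warning(res <- anova_filter(ds), "excluded")
  expect_true(is.na(res$p_value[res$probeset_id == "p2"]))
})

test_that("build_gene_map intersects genes and re-maps all probesets", {
  annA <- tibble::tibble(probeset_id = c("a1", "a2", "a3", "a4"),
                         gene_symbol = c("g1", "g2", "g2", "g3"))
  annB <- tibble::tibble(probeset_id = c("b1", "b2", "b3"),
                         gene_symbol = c("G2", "g3", "g4"))
  gm <- build_gene_map(list(A = c("a1", "a2", "a3", "a4"),
                            B = c("b1", "b2", "b3")),
                       list(A = annA, B = annB))
  expect_equal(gm$common_genes, c("G2", "G3"))  # case-insensitive intersect
  a_g2 <- gm$map$probeset_id[gm$map$condition == "A" & gm$map$gene == "G2"]
  expect_setequal(a_g2, c("a2", "a3"))  # both surviving probesets re-mapped
  expect_true(all(dplyr::count(gm$map, .data$condition, .data$gene)$n >= 1))

  expect_warning(
    empty <- build_gene_map(list(A = "a1", B = "b3"),
                            list(A = annA, B = annB)),
    "no genes")
  expect_length(empty$common_genes, 0)
})

test_that("condense_replicates averages, passes through, and weights sanely", {
  vals <- array(NA_real_, c(1, 2, 2))
  vals[1, , ] <- cbind(c(1, 5), c(3, 7))
  ds <- expression_dataset(vals, c(0, 1))
  expect_equal(unname(condense_replicates(ds)[1, ]), c(2, 6))

  # single replicate: passthrough
  one <- expression_dataset(matrix(1:4, 2, dimnames = list(c("p1", "p2"),
                                                           NULL)), c(0, 1))
  expect_equal(unname(condense_replicates(one)), matrix(as.numeric(1:4), 2))

  # equal replicate variances: weighted == mean
  set.seed(3)
  sym <- array(rnorm(10 * 6 * 2), c(10, 6, 2))
  sym[, , 2] <- sym[, , 1] + 0.5  # identical residual structure
  dimnames(sym)[[1]] <- sprintf("p%d", 1:10)
  dss <- expression_dataset(sym, 1:6)
  expect_equal(condense_replicates(dss, "weighted"),
               condense_replicates(dss, "mean"), tolerance = 1e-12)

  # mean condensation commutes with replicate reordering
  perm <- sym[, , c(2, 1)]
  dsp <- expression_dataset(perm, 1:6)
  expect_equal(condense_replicates(dsp, "mean"),
               condense_replicates(dss, "mean"))

  # a noisier replicate channel is down-weighted (needs >= 3 replicates:
  # with two, residuals around the per-time mean are symmetric and the
  # channels are indistinguishable)
  set.seed(4)
  base <- matrix(rep(sin(seq(0, 3, length.out = 8)), each = 20), 20, 8,
                 byrow = FALSE)
  arr <- array(NA_real_, c(20, 8, 3), dimnames = list(sprintf("p%d", 1:20),
                                                      NULL, NULL))
  arr[, , 1] <- base + rnorm(160, 0, 0.01)
  arr[, , 2] <- base + rnorm(160, 0, 0.01)
  arr[, , 3] <- base + rnorm(160, 0, 2)
  dsn <- expression_dataset(arr, 1:8)
  w <- condense_replicates(dsn, "weighted")
  m <- condense_replicates(dsn, "mean")
  expect_lt(mean((w - base)^2), mean((m - base)^2))
})

test_that("an empty time point drops the probeset with a warning", {
  vals <- array(NA_real_, c(2, 2, 2), dimnames = list(c("p1", "p2"), NULL,
                                                      NULL))
  vals[1, , ] <- 1
  vals[2, 1, ] <- 1  # t2 entirely missing for p2
  ds <- expression_dataset(vals, c(0, 1))
  expect_warning(prof <- condense_replicates(ds), "dropping 1")
  expect_equal(rownames(prof), "p1")
})

test_that("the SOFT reader parses tables and subsets", {
  soft <- c(
    "^DATABASE = Geo",
    "^DATASET = GDS_synthetic",
    "!dataset_title = synthetic fixture",
    "^SUBSET = GDS_synthetic_1",
    "!subset_description = 0 hour",
    "!subset_sample_id = GSM1,GSM2",
    "!subset_type = time",
    "^SUBSET = GDS_synthetic_2",
    "!subset_description = 4 hour",
    "!subset_sample_id = GSM3",
    "!subset_type = time",
    "^DATASET = GDS_synthetic",
    "!dataset_table_begin",
    "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3",
    "p1\tGeneA\t1.0\t1.2\t5.0",
    "p2\tGeneB\t2.0\t2.1\t2.2",
    "!dataset_table_end")
  fp <- withr::local_tempfile(fileext = ".soft")
  writeLines(soft, fp)
  gds <- read_geo_soft(fp)
  expect_equal(dim(gds$table), c(2, 5))
  expect_equal(gds$table$GSM3, c(5.0, 2.2))
  expect_equal(nrow(gds$subsets), 3)  # GSM1, GSM2 in one subset + GSM3
  expect_setequal(gds$subsets$sample_id[gds$subsets$description == "0 hour"],
                  c("GSM1", "GSM2"))
})
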