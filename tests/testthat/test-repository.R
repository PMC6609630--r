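# Repository schema, reader/writer round-trip, and the inclusion filter.

make_repo_df <- function() {
  generate_repository_fixture(n_proteins = 2, k_per_protein = 3,
                              cfg = synth_config(seed = 42))
}

test_that("reader/writer round-trips a well-formed repository", {
  df <- make_repo_df()
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_repository(df, path)
  back <- read_abundance_repository(path)
  expect_equal(nrow(back), nrow(df))
  for (col in repository_columns())
    expect_equal(back[[col]], df[[col]], tolerance = 1e-12, label = col)
  # tsv path too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_repository(df, path2)
  expect_equal(read_abundance_repository(path2)$value, df$value)
})

test_that("missing cells load as NA, never zero, and rows keep their index", {
  df <- make_repo_df()
  df$value_sd[2] <- NA
  df$value_cv_pct[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_repository(df, path)
  back <- read_abundance_repository(path)
  expect_true(is.na(back$value_sd[2]))
  expect_true(is.na(back$value_cv_pct[2]))
  expect_identical(attr(back, ".row"), seq_len(nrow(df)))
})

test_that("malformed numeric cells raise a row-level error", {
  df <- make_repo_df()
  path <- withr::local_tempfile(fileext = ".csv")
  df$value <- as.character(df$value)
  df$value[3] <- "12,7"
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_abundance_repository(path), "row\\(s\\) 3")
})

test_that("unknown enums load as 'other' with a warning", {
  df <- make_repo_df()
  df$tissue[1] <- "plasma"
  df$method[2] <- "SRM-ish"
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_repository(df, path)
  expect_warning(expect_warning(back <- read_abundance_repository(path),
                                "tissue"), "method")
  expect_identical(back$tissue[1], "other")
  expect_identical(back$method[2], "other")
})

test_that("reported %CV consistent with SD/mean passes; discrepancy warns", {
  df <- make_repo_df()[1:3, ]
  df$value[1] <- 35; df$value_sd[1] <- 7; df$value_cv_pct[1] <- 20  # 100*7/35
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_repository(df, path)
  expect_silent(read_abundance_repository(path))
  df$value_cv_pct[1] <- 24          # off by 4 percentage points
  write_abundance_repository(df, path)
  expect_warning(read_abundance_repository(path), "disagrees")
})

test_that("unit handling: canonical and rescalable units pass, others fail", {
  expect_equal(unit_scale_factor(c("pmol/mg microsomal protein", "pmol/mg",
                                   "fmol/ug", "pmol/ug", "fmol/mg")),
               c(1, 1, 1, 1000, 0.001))
  expect_true(all(is.na(unit_scale_factor(c("ng/mg", "ratio", "AU")))))
  # a pmol/ug record is rescaled into the study set
  df <- make_repo_df()
  df$unit[1] <- "pmol/ug"
  df$value[1] <- df$value[1] / 1000
  df$value_sd[1] <- df$value_sd[1] / 1000
  sets <- filter_for_meta(df)
  d <- sets[[1]]$data
  ref <- filter_for_meta(make_repo_df())[[1]]$data
  expect_equal(d$x, ref$x, tolerance = 1e-12)
})

test_that("inclusion filter applies the four criteria and accounts for every record", {
  # protein P: 1 pooled, 1 relative, 1 mRNA, 3 eligible from 2 labs -> k = 3
  base <- make_repo_df()[1, ]
  row <- function(...) { r <- base; mods <- list(...)
    for (nm in names(mods)) r[[nm]] <- mods[[nm]]
    r$value_sd <- r$value * 0.2
    r$value_cv_pct <- 20
    r }
  df <- rbind(
    row(protein_name = "P", source = "lab1", pooled = TRUE),
    row(protein_name = "P", source = "lab1", quant_mode = "relative",
        unit = "ratio"),
    row(protein_name = "P", source = "lab2", method = "mRNA"),
    row(protein_name = "P", source = "lab1", value = 30),
    row(protein_name = "P", source = "lab1", value = 40),
    row(protein_name = "P", source = "lab2", value = 35))
  sets <- filter_for_meta(df)
  expect_length(sets, 1)
  expect_equal(sets[[1]]$k, 3)
  counts <- attr(sets, "exclusions")
  expect_equal(unname(counts["retained"]), 3)
  expect_equal(unname(counts["pooled_sample"]), 1)
  expect_equal(unname(counts["relative_quantification"]), 1)
  expect_equal(unname(counts["ineligible_method"]), 1)
  expect_equal(sum(counts), nrow(df))
})

test_that("single-source proteins are excluded entirely (criterion iv)", {
  df <- generate_repository_fixture(n_proteins = 1, k_per_protein = 3,
                                    single_source_protein = TRUE,
                                    cfg = synth_config(seed = 7))
  sets <- filter_for_meta(df)
  expect_length(sets, 1)
  expect_false(grepl("SINGLE", names(sets)[1]))
  expect_equal(unname(attr(sets, "exclusions")["single_source"]), 2)
})

test_that("filter is idempotent and empty input yields empty output", {
  df <- make_repo_df()
  sets1 <- filter_for_meta(df)
  kept <- df[setdiff(seq_len(nrow(df)), attr(sets1, "excluded_rows")$row), ]
  sets2 <- filter_for_meta(kept)
  expect_equal(length(sets2), length(sets1))
  for (nm in names(sets1))
    expect_equal(sets2[[nm]]$data$x, sets1[[nm]]$data$x)
  empty <- filter_for_meta(df[0, ])
  expect_length(empty, 0)
  expect_equal(unname(attr(empty, "exclusions")["retained"]), 0)
})

test_that("records lacking SD pass the filter", {
  df <- make_repo_df()
  df$value_sd[1] <- NA
  df$value_cv_pct[1] <- NA
  sets <- filter_for_meta(df)
  expect_true(any(is.na(sets[[1]]$data$sd)))
})

test_that("study_set validates means, counts and CV consistency", {
  expect_error(study_set("P", label = "a", x = -1, n = 5), "positive")
  expect_error(study_set("P", label = "a", x = 10, n = 0), ">= 1")
  expect_warning(study_set("P", label = c("a", "b"), x = c(10, 20),
                           sd = c(2, 4), n = c(5, 5), cv = c(0.5, 0.2)),
                 "disagrees")
  ss <- study_set("P", label = c("a", "b"), x = c(10, 20), sd = c(2, 4),
                  n = c(5, 7))
  expect_equal(ss$k, 2)
  expect_equal(ss$N, 12)
  expect_equal(ss$data$cv, c(0.2, 0.2))
})
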