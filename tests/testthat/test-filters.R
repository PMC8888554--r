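test_that("QC coefficient of variation matches hand arithmetic", {
  tab <- metabo_table(
    intensity = cbind(matrix(1, 3, 1, dimnames = list(NULL, "S1")),
                      matrix(c(10, 8, 0, 10, 12, 0), 3, 2,
                             dimnames = list(NULL, c("QC_01", "QC_02")))),
    features = data.frame(feature_id = c("A", "B", "C"), rt = c(50, 50, 50),
                          mz = 1:3, annotation = "", pc_group = 1:3,
                          stringsAsFactors = FALSE),
    is_qc = c(FALSE, TRUE, TRUE)
  )
  cv <- qc_cv(tab)
  expect_equal(unname(cv["A"]), 0)                       # constant series
  expect_equal(unname(cv["B"]), sd(c(8, 12)) / 10)       # 2.828/10 = 0.2828
  expect_equal(unname(cv["B"]), 0.28284271, tolerance = 1e-7)
  expect_true(is.na(cv["C"]))                            # zero-mean QC
  cl <- filter_cleaned(tab)
  expect_false("C" %in% cl$report$surviving_ids)
})

test_that("cleaned filter applies the void and CV rules exactly", {
  tab <- make_filter_fixture()
  cv <- qc_cv(tab)
  expect_equal(unname(cv), c(0.10, 0.35, 0.10, 0.20, 0.29), tolerance = 1e-12)
  res <- filter_cleaned(tab)
  expect_identical(res$report$surviving_ids, c("F3", "F4", "F5"))
  expect_equal(unname(res$report$removed_by["void"]), 1)    # F1, RT 30
  expect_equal(unname(res$report$removed_by["qc_cv"]), 1)   # F2, CV 0.35
  expect_equal(res$report$n_input - res$report$n_surviving,
               sum(res$report$removed_by))
})

test_that("a feature at exactly 40 s is retained (void rule is strict)", {
  tab <- make_filter_fixture()
  tab$features$rt[1] <- 40.0
  res <- filter_cleaned(tab)
  expect_true("F1" %in% res$report$surviving_ids)
  # everything violating both rules -> empty but valid
  tab2 <- make_filter_fixture()
  tab2$features$rt[] <- 10
  res2 <- filter_cleaned(tab2)
  expect_equal(res2$report$n_surviving, 0)
  expect_equal(nrow(res2$table$intensity), 0)
})

test_that("pc_group filter keeps the argmax of cumulative study signal", {
  tab <- make_filter_fixture()
  cl <- filter_cleaned(tab)$table      # F3 (grp 2), F4 (grp 2), F5 (grp 3)
  res <- filter_pc_group(cl)
  # F4 row-sum 240 beats F3 row-sum 90; F5 alone in its group
  expect_identical(res$report$surviving_ids, c("F4", "F5"))
  expect_equal(res$report$n_surviving,
               length(unique(cl$features$pc_group)))
  expect_error(filter_pc_group(tab), "cleaned")
})

test_that("pc_group ties break to the lexicographically smaller id", {
  tab <- make_filter_fixture()
  tab$intensity[3, 1:3] <- tab$intensity[4, 1:3]   # F3 ties F4
  cl <- filter_cleaned(tab)$table
  res <- filter_pc_group(cl)
  expect_true("F3" %in% res$report$surviving_ids)
  expect_false("F4" %in% res$report$surviving_ids)
  expect_identical(res$report$ties, "F3")
})

test_that("ion filter matches molecular-ion annotations after normalization", {
  tab <- make_filter_fixture()
  cl <- filter_cleaned(tab)$table
  res <- filter_ion(cl)
  # F3 "[M+H]+" and F5 "[M + H]+" (whitespace-normalized) survive
  expect_identical(res$report$surviving_ids, c("F3", "F5"))
  # negative-mode annotation with unicode minus
  tab2 <- make_filter_fixture()
  tab2$mode$polarity <- "negative"
  tab2$features$annotation <- c("[M-H]-", "x", "[M−H]−", "", "[M+H]+")
  res2 <- filter_ion(filter_cleaned(tab2)$table)
  expect_identical(res2$report$surviving_ids, "F3")  # unicode form, cleaned-surviving
  # positive-mode table containing only deprotonated ions -> empty, no error
  tab3 <- make_filter_fixture()
  tab3$features$annotation[] <- "[M-H]-"
  res3 <- filter_ion(filter_cleaned(tab3)$table)
  expect_equal(res3$report$n_surviving, 0)
  # unknown mode is a precondition error
  tab4 <- make_filter_fixture()
  tab4$mode <- NULL
  expect_error(filter_ion(filter_cleaned(tab4)$table), "mode")
})

test_that("filters are idempotent and nested within the cleaned set", {
  md <- simulate_metadata(10, seed = 11)
  sim <- simulate_metabolome(md, n_features = 120, seed = 12)
  cl <- filter_cleaned(sim$table)
  cl2 <- filter_cleaned(cl$table)
  expect_identical(cl2$report$surviving_ids, cl$report$surviving_ids)
  pg <- filter_pc_group(cl$table)
  pg2 <- filter_pc_group(pg$table)
  expect_identical(pg2$report$surviving_ids, pg$report$surviving_ids)
  io <- filter_ion(cl$table)
  io2 <- filter_ion(io$table)
  expect_identical(io2$report$surviving_ids, io$report$surviving_ids)
  expect_true(all(pg$report$surviving_ids %in% cl$report$surviving_ids))
  expect_true(all(io$report$surviving_ids %in% cl$report$surviving_ids))
})

test_that("on low-noise synthetic data cleaned survivors match the truth ledger", {
  md <- simulate_metadata(10, seed = 13)
  sim <- simulate_metabolome(md, n_features = 150, frac_void = 0.1,
                             frac_high_cv = 0.15, n_qc = 10,
                             qc_cv_base = 0.02, qc_cv_high = 1.0, seed = 14)
  cl <- filter_cleaned(sim$table)
  expected <- setdiff(sim$table$features$feature_id,
                      union(sim$truth$void_ids, sim$truth$high_cv_ids))
  expect_setequal(cl$report$surviving_ids, expected)
})
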