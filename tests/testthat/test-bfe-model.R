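# Feature-table assembly, metrics and cross-validated ddG regression.

test_that("pearson_r matches the textbook formula and handles degeneracy", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  set.seed(14)
  x <- rnorm(100); y <- 0.4 * x + rnorm(100)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), direct, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("rmse follows its closed forms", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1.0)
  set.seed(3)
  obs <- rnorm(50)
  expect_equal(rmse(obs + 0.7, obs), 0.7, tolerance = 1e-12)
})

test_that("withheld structures go to the exclusion report, not silently", {
  tab <- make_ddg_table(n_complexes = 3, muts_per_complex = 4, seed = 8,
                        r2 = 0.5)
  records <- tab$records
  # withhold one complex carrying 2 of its records
  records$complex[c(2, 6)] <- "MISSING"
  ft <- build_feature_table(records[c(1:8), ], tab$structures,
                            reverse = FALSE, include_regions = FALSE)
  expect_equal(nrow(ft$features), 6)
  expect_equal(nrow(ft$exclusions), 2)
  expect_true(all(ft$exclusions$reason == "structure unavailable"))
})

test_that("reverse augmentation mirrors one-hots and negates ddG", {
  tab <- make_ddg_table(n_complexes = 2, muts_per_complex = 3, seed = 9,
                        r2 = 0.5)
  ft <- build_feature_table(tab$records, tab$structures,
                            features = tab$features,
                            reverse = TRUE, include_regions = FALSE)
  expect_equal(nrow(ft$features), 2 * nrow(tab$records))
  d <- ft$meta$direction == "direct"
  r <- ft$meta$direction == "reverse"
  expect_equal(ft$meta$ddg[r], -ft$meta$ddg[d])
  spec_cols <- !grepl("^(wt|mut|region)_", colnames(ft$features))
  expect_equal(ft$features[r, spec_cols], ft$features[d, spec_cols])
  wt_cols <- grepl("^wt_", colnames(ft$features))
  mut_cols <- grepl("^mut_", colnames(ft$features))
  expect_equal(unname(ft$features[r, wt_cols]),
               unname(ft$features[d, mut_cols]))
  expect_equal(unname(ft$features[r, mut_cols]),
               unname(ft$features[d, wt_cols]))
  # reverse of reverse is the identity
  expect_equal(ft$meta$pair_id[r], ft$meta$pair_id[d])
})

test_that("feature tables are deterministic for a fixed seed and config", {
  t1 <- make_ddg_table(n_complexes = 2, muts_per_complex = 3, seed = 5)
  t2 <- make_ddg_table(n_complexes = 2, muts_per_complex = 3, seed = 5)
  expect_identical(t1$features, t2$features)
  expect_identical(t1$records, t2$records)
  f1 <- build_feature_table(t1$records, t1$structures, features = t1$features,
                            include_regions = FALSE)
  f2 <- build_feature_table(t2$records, t2$structures, features = t2$features,
                            include_regions = FALSE)
  expect_identical(f1$features, f2$features)
})

test_that("cross-validation is deterministic and partitions records", {
  tab <- make_ddg_table(n_complexes = 4, muts_per_complex = 8, r2 = 0.9,
                        seed = 16)
  ft <- build_feature_table(tab$records, tab$structures,
                            features = tab$features,
                            reverse = FALSE, include_regions = FALSE)
  cv1 <- crossvalidate(ft, folds = 4, seed = 3, nrounds = 80,
                       early_stopping_rounds = 20, params = list(eta = 0.1))
  cv2 <- crossvalidate(ft, folds = 4, seed = 3, nrounds = 80,
                       early_stopping_rounds = 20, params = list(eta = 0.1))
  expect_identical(cv1$fold, cv2$fold)
  expect_equal(cv1$r_p, cv2$r_p)
  expect_equal(cv1$rmse, cv2$rmse)
  # partition: each record in exactly one test fold
  expect_equal(sort(unique(cv1$fold)), 1:4)
  expect_equal(length(cv1$fold), nrow(ft$features))
  expect_false(any(is.na(cv1$predictions)))
  expect_error(crossvalidate(ft, folds = 64), "folds")

  # direct and reverse records share a fold
  ftr <- build_feature_table(tab$records, tab$structures,
                             features = tab$features,
                             reverse = TRUE, include_regions = FALSE)
  cvr <- crossvalidate(ftr, folds = 4, seed = 3, nrounds = 40,
                       early_stopping_rounds = 10, params = list(eta = 0.2))
  for (p in unique(ftr$meta$pair_id))
    expect_equal(length(unique(cvr$fold[ftr$meta$pair_id == p])), 1L)
})

test_that("complex-grouped folds defeat per-complex leakage", {
  tab <- make_ddg_table(n_complexes = 12, muts_per_complex = 10, r2 = 0,
                        seed = 19)
  # signal that is a pure per-complex offset: learnable only through leakage
  offsets <- setNames(rnorm(12, sd = 2), unique(tab$records$complex))
  records <- tab$records
  records$ddg <- offsets[records$complex]
  ft <- build_feature_table(records, tab$structures, features = tab$features,
                            reverse = FALSE, include_regions = FALSE)
  cv_rec <- crossvalidate(ft, folds = 6, seed = 2, nrounds = 300,
                          early_stopping_rounds = 30, params = list(eta = 0.1))
  cv_grp <- crossvalidate(ft, folds = 6, seed = 2, nrounds = 300,
                          early_stopping_rounds = 30, params = list(eta = 0.1),
                          group_by_complex = TRUE)
  # record-level folds inflate; grouped folds collapse toward zero
  expect_gt(cv_rec$r_p, 0.6)
  expect_lt(abs(cv_grp$r_p), 0.35)
  # grouped folds put all records of a complex in one fold
  for (cid in unique(ft$meta$complex))
    expect_equal(length(unique(cv_grp$fold[ft$meta$complex == cid])), 1L)
})

test_that("generated ddG tables hit their target explained variance", {
  r2s <- vapply(1:6, function(s) {
    tab <- make_ddg_table(n_complexes = 4, muts_per_complex = 10, r2 = 0.8,
                          seed = 30 + s)
    X <- tab$features[, tab$truth$columns, drop = FALSE]
    summary(lm(tab$records$ddg ~ X))$r.squared
  }, 0)
  expect_lt(abs(mean(r2s) - 0.8), 0.05)
})

test_that("mutation tables read from SKEMPI-style CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(complex = c("1ABC", "1ABC"),
                       mutation = c("EA38G", "YB10F"),
                       ddg = c(1.2, -0.4)), path, row.names = FALSE)
  tab <- read_mutation_table(path)
  expect_equal(tab$chain, c("A", "B"))
  expect_equal(tab$wt, c("E", "Y"))
  expect_equal(tab$resno, c(38L, 10L))
  expect_equal(tab$ddg, c(1.2, -0.4))
})
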