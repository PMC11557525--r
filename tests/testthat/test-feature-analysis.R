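test_that("Spearman correlation handles monotone transforms and sparse pairs", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 6)
  a <- data.frame(x = x)
  b <- data.frame(lin = 2 * x + 3, anti = exp(-x))
  rho <- pairwise_spearman(a, b)
  expect_equal(rho["x", "lin"], 1)
  expect_equal(rho["x", "anti"], -1)
  sparse <- data.frame(u = c(1, 2, NA, NA, NA, NA), v = c(2, 1, NA, NA, NA, NA))
  expect_true(is.na(pairwise_spearman(sparse)["u", "v"]))
})

test_that("Spearman equals brute-force rank-then-Pearson", {
  set.seed(4)
  df <- as.data.frame(matrix(rnorm(6 * 5), nrow = 6))
  rho <- pairwise_spearman(df)
  for (i in 1:5) {
    for (j in 1:5) {
      ri <- rank(df[[i]]); rj <- rank(df[[j]])
      brute <- sum((ri - mean(ri)) * (rj - mean(rj))) /
        sqrt(sum((ri - mean(ri))^2) * sum((rj - mean(rj))^2))
      expect_equal(rho[i, j], brute, tolerance = 1e-12)
    }
  }
})

test_that("variance-inflation indices behave at both extremes", {
  set.seed(5)
  indep <- as.data.frame(matrix(rnorm(4000 * 3), ncol = 3))
  v <- multicollinearity(indep)
  expect_true(all(v$vif < 1.05))
  dup <- data.frame(a = rnorm(50), b = rnorm(50))
  dup$c <- dup$a
  vd <- multicollinearity(dup)
  expect_true(any(is.infinite(vd$vif) & vd$collinear))
})

test_that("a planted R-squared of 0.8 yields a VIF near 5", {
  set.seed(6)
  n <- 1e4
  x1 <- rnorm(n); x2 <- rnorm(n)
  # y = x1 + x2 + e with var(e) chosen so R^2 = 0.8 -> VIF = 5
  y <- x1 + x2 + rnorm(n, 0, sqrt(0.5))
  v <- multicollinearity(data.frame(x1 = x1, x2 = x2, y = y))
  expect_equal(v$vif[v$feature == "y"], 5, tolerance = 0.5)
})

test_that("triage drops duplicates for correlation and tames collinear blocks", {
  set.seed(7)
  n <- 300
  base <- matrix(rnorm(n * 9), ncol = 9)
  df <- as.data.frame(base)
  names(df) <- paste0("f", 1:9)
  df$f_dup <- df$f1 # perfectly correlated pair
  # planted 3-feature collinear block
  df$f10 <- df$f2 + df$f3 + rnorm(n, 0, 0.1)
  sel <- select_features(df, r_max = 0.8, vif_max = 5)
  expect_true("f_dup" %in% sel$eliminated$feature)
  expect_equal(
    sel$eliminated$reason[sel$eliminated$feature == "f_dup"], "correlation"
  )
  expect_true(all(sel$vif$vif <= 5))
  # determinism across runs
  sel2 <- select_features(df, r_max = 0.8, vif_max = 5)
  expect_identical(sel$retained, sel2$retained)
  expect_identical(sel$eliminated, sel2$eliminated)
  # independent features survive untouched
  sel3 <- select_features(df[paste0("f", 1:9)])
  expect_equal(nrow(sel3$eliminated), 0)
  # manual drops recorded
  sel4 <- select_features(df[paste0("f", 1:9)], manual_drops = "f4")
  expect_true(all(sel4$eliminated$reason == "manual"))
  expect_false("f4" %in% sel4$retained)
})

test_that("similarity clustering merges duplicates first, blocks at the cut", {
  set.seed(8)
  n <- 500
  a <- rnorm(n); b <- rnorm(n)
  df <- data.frame(
    a1 = a, a2 = a + rnorm(n, 0, 0.1),
    b1 = b, b2 = b + rnorm(n, 0, 0.1)
  )
  df$a_dup <- df$a1
  cl <- similarity_clusters(df)
  expect_equal(min(cl$linkage$height), 0, tolerance = 1e-12)
  groups <- stats::cutree(cl$hclust, h = 0.5)
  expect_equal(groups[["a1"]], groups[["a2"]])
  expect_equal(groups[["b1"]], groups[["b2"]])
  expect_false(groups[["a1"]] == groups[["b1"]])
})

test_that("separable data is classified accurately and reproducibly", {
  tab <- gen_feature_table(n_per_class = 60, n_informative = 2, n_noise = 3,
                           effect = 10, seed = 9)
  fit <- fit_classifier(tab, label = "class", seed = 21)
  expect_gt(fit$test_accuracy, 0.95)
  fit2 <- fit_classifier(tab, label = "class", seed = 21)
  expect_identical(fit$model_name, fit2$model_name)
  expect_identical(fit$test_accuracy, fit2$test_accuracy)
  expect_identical(fit$cv_results, fit2$cv_results)
})

test_that("shuffled labels score near the majority fraction", {
  tab <- gen_feature_table(n_per_class = 60, n_informative = 2, n_noise = 3,
                           effect = 10, seed = 10)
  set.seed(22)
  tab$class <- sample(tab$class)
  fit <- fit_classifier(tab, label = "class", seed = 22)
  expect_lt(fit$test_accuracy, 0.75) # 0.5 majority + sampling noise
})

test_that("stratification errors when a class has too few members", {
  tab <- gen_feature_table(n_per_class = 30, seed = 11)
  tiny <- tab[c(which(tab$class == "A"), which(tab$class == "B")[1:2]), ]
  expect_error(fit_classifier(tiny, label = "class", k_folds = 3, seed = 1),
               "fewer")
})

test_that("majority baseline tracks the class balance", {
  tab90 <- gen_feature_table(n_per_class = 50, seed = 12)[1:100, ]
  tab90$class <- factor(rep(c("A", "B"), times = c(90, 10)))
  mb <- majority_baseline(tab90, label = "class", k_folds = 5, repeats = 5,
                          seed = 2)
  expect_equal(mb$mean, 0.9, tolerance = 0.02)
  tab50 <- gen_feature_table(n_per_class = 50, seed = 13)
  mb50 <- majority_baseline(tab50, label = "class", k_folds = 5, repeats = 5,
                            seed = 2)
  expect_equal(mb50$mean, 0.5, tolerance = 0.05)
})

test_that("majority baseline equals the evaluated-fold majority fraction exactly", {
  y <- factor(rep(c("A", "B"), times = c(8, 4)))
  tab <- data.frame(x = seq_along(y), class = y)
  mb <- majority_baseline(tab, label = "class", k_folds = 4, repeats = 1,
                          seed = 3)
  # every fold holds 2 A and 1 B; training majority is always A
  expect_equal(unique(mb$fold_accuracies$accuracy), 2 / 3)
})

test_that("126 rows at a 93/33 split give the stratified majority accuracy", {
  tab <- gen_feature_table(n_per_class = 63, n_informative = 1, n_noise = 1,
                           seed = 14)
  tab$class <- factor(rep(c("A", "B"), times = c(93, 33)))
  mb <- majority_baseline(tab, label = "class", k_folds = 5, repeats = 10,
                          seed = 4)
  expect_equal(mb$mean, 93 / 126, tolerance = 0.01)
  expect_lt(mb$sd, 0.03)
})

test_that("permutation importance separates signal from noise features", {
  tab <- gen_feature_table(n_per_class = 100, n_informative = 1, n_noise = 5,
                           effect = 10, seed = 15)
  fit <- fit_classifier(tab, label = "class", test_size = 0.3, seed = 30)
  imp <- permutation_importance(fit, repeats = 30, seed = 31)
  expect_equal(nrow(imp$samples), 6 * 30) # count contract
  s <- imp$summary
  expect_gte(s$mean_importance[s$feature == "inf_1"], 0.3)
  noise_means <- s$mean_importance[grepl("^noise_", s$feature)]
  expect_true(all(abs(noise_means) <= 0.05))
  # seeded determinism
  imp2 <- permutation_importance(fit, repeats = 30, seed = 31)
  expect_identical(imp$samples, imp2$samples)
})

test_that("importance of an irrelevant feature shrinks as repeats grow", {
  tab <- gen_feature_table(n_per_class = 100, n_informative = 1, n_noise = 1,
                           effect = 10, seed = 16)
  fit <- fit_classifier(tab, label = "class", test_size = 0.3, seed = 32)
  means <- purrr::map_dbl(c(5, 20, 60), function(r) {
    abs(permutation_importance(fit, repeats = r, seed = 33)$summary |>
          dplyr::filter(feature == "noise_1") |>
          dplyr::pull(mean_importance))
  })
  expect_lt(means[3], 0.05)
  expect_lte(means[3], means[1] + 0.02)
})

test_that("Mann-Whitney comparison matches the enumeration oracle", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- group_compare(a, b)
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1) # 2 * 1/20
  expect_true(res$exact)
  same <- group_compare(c(1, 2, 3), c(1.5, 2.5, 0.5))
  expect_equal(same$p_value, enumerate_mw_p(c(1, 2, 3), c(1.5, 2.5, 0.5)))
  expect_error(group_compare(numeric(0), b), "at least one")
})

test_that("identical groups give p = 1 and ties fall back to the approximation", {
  res <- group_compare(c(5, 7, 7, 9), c(5, 7, 7, 9))
  expect_false(res$exact) # ties present
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  exact_same <- group_compare(c(1, 4, 6), c(2, 3, 7))
  expect_true(exact_same$exact)
})

test_that("p-values fall monotonically with larger group shifts", {
  set.seed(40)
  base <- rnorm(30)
  ps <- purrr::map_dbl(c(0.2, 0.8, 1.6), function(shift) {
    group_compare(base, rnorm(30) + shift)$p_value
  })
  expect_true(all(diff(ps) < 0))
})

test_that("tidiers and plots expose fitted objects in standard forms", {
  lat <- cone_latencies()
  fit <- fit_cone(lat)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "x0", "y0", "c"))
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
  tab <- gen_feature_table(effect = 5, seed = 17)
  cfit <- fit_classifier(tab, label = "class", seed = 18)
  expect_s3_class(tidy(cfit), "tbl_df")
  expect_equal(nrow(glance(cfit)), 1)
  imp <- permutation_importance(cfit, repeats = 3, seed = 19)
  expect_s3_class(autoplot(imp), "ggplot")
  sel <- select_features(gen_feature_table(seed = 20)[1:5])
  expect_s3_class(autoplot(sel), "ggplot")
})
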