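test_that("precision and sensitivity match their definitions, with guards", {
  cc <- confusion_counts(9, 1, 1, 20)
  expect_equal(as.numeric(precision(cc)), 90)
  expect_equal(as.numeric(sensitivity(cc)), 90)
  expect_false(attr(precision(cc), "degenerate"))
  z <- confusion_counts(0, 0, 0, 5)
  expect_equal(as.numeric(precision(z)), 0)
  expect_true(attr(precision(z), "degenerate"))
  expect_true(attr(sensitivity(z), "degenerate"))
  expect_invalid(confusion_counts(-1, 0, 0, 0))
})

test_that("metrics agree with an independent recomputation on random tables", {
  set.seed(17)
  for (i in 1:50) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    fn <- sample(0:50, 1); tn <- sample(0:50, 1)
    cc <- confusion_counts(tp, fp, fn, tn)
    p_ref <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    s_ref <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    f_ref <- if (p_ref + s_ref == 0) 0 else
      2 * p_ref * s_ref / (p_ref + s_ref)
    expect_identical(as.numeric(precision(cc)), p_ref)
    expect_identical(as.numeric(sensitivity(cc)), s_ref)
    expect_equal(f1(p_ref, s_ref), f_ref, tolerance = 1e-12)
  }
})

test_that("F1 reproduces the pathologist worked example and its identities", {
  expect_equal(round(f1(100, 98.90), 2), 99.45)
  for (x in c(0, 13.7, 50, 100)) expect_equal(f1(x, x), x)
  expect_equal(f1(0, 80), 0)
  expect_equal(f1(0, 0), 0)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(1, 1, 100); s <- runif(1, 1, 100)
    v <- f1(p, s)
    expect_gte(v, min(p, s)); expect_lte(v, max(p, s))
    expect_equal(v, f1(s, p))
  }
  expect_invalid(f1(120, 50))
})

test_that("grouped k-fold partitions 24 slides into 4 disjoint folds of 6", {
  slides <- sprintf("slide_%02d", 1:24)
  split <- kfold_by_group(slides, 4, seed = 11)
  expect_equal(split$k, 4)
  expect_setequal(names(split$assignments), slides)
  expect_equal(unname(table(split$assignments)), rep(6L, 4),
               ignore_attr = TRUE)
  # leave-one-group-out
  loo <- kfold_by_group(slides, 24, seed = 1)
  expect_equal(unname(table(loo$assignments)), rep(1L, 24),
               ignore_attr = TRUE)
  expect_invalid(kfold_by_group(slides, 25))
  # no tile-level leakage: every tile follows its slide
  tile_slides <- sample(slides, 500, replace = TRUE)
  folds <- fold_of(split, tile_slides)
  for (sl in slides)
    expect_length(unique(folds[tile_slides == sl]), 1)
  expect_identical(unname(folds),
                   unname(split$assignments[tile_slides]))
})

test_that("imbalance resampling follows the 1-in-10 rule deterministically", {
  pool <- as.list(1:400)
  sub <- resample_imbalance(pool, 3000, 0.1, seed = 2)
  expect_length(sub, 300)
  expect_true(all(unlist(sub) %in% 1:400))
  expect_false(anyDuplicated(unlist(sub)) > 0)
  expect_identical(resample_imbalance(pool, 3000, 0.1, seed = 2), sub)
  expect_identical(resample_imbalance(pool, 400, 1, seed = 9), pool)
  expect_invalid(resample_imbalance(pool, 5000, 0.1))
  expect_invalid(resample_imbalance(pool, 100, 1.5))
})

test_that("fold evaluation aggregates per-fold metrics correctly", {
  # single-class registries make per-fold outcomes fully predictable
  reg <- add_class(model_registry(), tiny_model("tumorlike"))
  all_pos <- generate_tiles(default_texture_specs()$tumorlike, 3, 32)
  rep1 <- evaluate_folds(list(reg, reg), list(all_pos, all_pos))
  expect_equal(rep1$per_fold$precision, c(100, 100))
  expect_equal(rep1$per_fold$sensitivity, c(100, 100))
  expect_equal(rep1$per_fold$f1, c(100, 100))
  expect_equal(rep1$aggregate$f1$mean, 100)
  expect_equal(rep1$aggregate$f1$sd, 0)
  # an all-positive predictor has sensitivity 100, precision = prevalence
  mixed <- c(generate_tiles(default_texture_specs()$tumorlike, 2, 32),
             generate_tiles(default_texture_specs()$stromalike, 2, 32))
  rep2 <- evaluate_folds(list(reg), list(mixed))
  expect_equal(rep2$per_fold$sensitivity, 100)
  expect_equal(rep2$per_fold$precision, 50)
  expect_equal(rep2$per_fold$f1, round(f1(50, 100), 2))
  # aggregate equals a hand computation over the per-fold values
  repm <- evaluate_folds(list(reg, reg), list(all_pos, mixed))
  expect_equal(repm$aggregate$precision$mean,
               round(mean(repm$per_fold$precision), 2))
  expect_equal(repm$aggregate$precision$sd,
               round(stats::sd(repm$per_fold$precision), 2))
  expect_equal(repm$aggregate$precision$median,
               round(stats::median(repm$per_fold$precision), 2))
})
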