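# Standardization, f1 scoring, cross-validated SVM decoding, importance.

make_frm <- function(rfrs, n_rep = 40, rate = 8, seed = 1) {
  u <- make_units(rfrs, base_rate = rate)
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = n_rep)
  spk <- simulate_spike_trains(u, prot, seed = seed)
  build_rate_matrix(spk, prot, unit_ids = u$unit_id)
}

test_that("standard scores use train-only statistics with population SD", {
  X <- matrix(c(0, 2, 10, 10), nrow = 2)
  sc <- standardize(X)
  expect_equal(unname(sc$mu), c(1, 10))
  expect_equal(unname(sc$sigma), c(1, 0))
  expect_equal(unname(sc$Z[, 1]), c(-1, 1))
  expect_true(all(sc$Z[, 2] == 0))  # zero-variance column maps to 0

  set.seed(2)
  Xr <- matrix(stats::rnorm(200), 20, 10)
  Z <- standardize(Xr)$Z
  expect_equal(colMeans(Z), rep(0, 10), tolerance = 1e-12)
  expect_equal(colMeans(Z^2), rep(1, 10), tolerance = 1e-12)

  # no leakage: scaler parameters ignore the apply matrix entirely
  outlier <- matrix(1e6, 3, 10)
  sc2 <- standardize(Xr, outlier)
  expect_identical(sc2$mu, standardize(Xr)$mu)
  expect_identical(sc2$sigma, standardize(Xr)$sigma)
})

test_that("the two algebraic forms of f1 agree", {
  expect_equal(as.numeric(f1_from_confusion(8, 2, 2)), 0.8)
  expect_equal(as.numeric(f1_from_confusion(5, 0, 0)), 1)
  # P = R = 0.5: harmonic mean of equal values is the value
  expect_equal(as.numeric(f1_from_confusion(5, 5, 5)), 0.5)
  expect_identical(attr(f1_from_confusion(0, 0, 0), "flag"), "undefined")

  set.seed(42)
  for (i in 1:1000) {
    cm <- stats::rpois(3, 20) + c(1, 0, 0)
    f_count <- as.numeric(f1_from_confusion(cm[1], cm[2], cm[3]))
    P <- cm[1] / (cm[1] + cm[2]); R <- cm[1] / (cm[1] + cm[3])
    f_pr <- 2 * P * R / (P + R)
    expect_lt(abs(f_count - f_pr), 1e-12)
  }
})

test_that("stratified folds preserve class balance and shuffle by seed", {
  y <- rep(c("phase1", "phase2"), each = 30)
  f <- stratified_folds(y, 10, seed = 3)
  tab <- table(f, y)
  expect_true(all(tab == 3))
  expect_identical(stratified_folds(y, 10, seed = 3), f)
  expect_false(identical(stratified_folds(y, 10, seed = 4), f))
})

test_that("separable data decode perfectly; decoding is deterministic", {
  set.seed(10)
  X <- rbind(matrix(stats::rnorm(60 * 5, 0), ncol = 5),
             matrix(stats::rnorm(60 * 5, 8), ncol = 5))
  y <- rep(c("phase1", "phase2"), each = 60)
  r <- cross_validated_decode(X, y, seed = 1)
  expect_equal(r$f1_mean, 1)
  expect_equal(r$confusion$FP + r$confusion$FN, 0)
  expect_equal(Reduce(`+`, r$confusion), 120)
  r2 <- cross_validated_decode(X, y, seed = 1)
  expect_identical(r$f1_per_fold, r2$f1_per_fold)
  expect_identical(r$confusion, r2$confusion)
})

test_that("permuted labels decode at chance", {
  frm <- make_frm(rep(0.8, 8), n_rep = 20, seed = 2)
  set.seed(7)
  f1s <- replicate(50, {
    y <- sample(frm$phase_labels)
    cross_validated_decode(frm$values, y, folds = 5,
                           seed = sample.int(1e6, 1))$f1_mean
  })
  expect_gt(mean(f1s), 0.4)
  expect_lt(mean(f1s), 0.6)
})

test_that("duplicating every sample leaves a separable decoding unchanged", {
  frm <- make_frm(rep(0.9, 10), n_rep = 30, seed = 4)
  r1 <- cross_validated_decode(frm$values, frm$phase_labels, seed = 5)
  r2 <- cross_validated_decode(rbind(frm$values, frm$values),
                               c(frm$phase_labels, frm$phase_labels), seed = 5)
  expect_equal(r1$f1_mean, r2$f1_mean, tolerance = 1e-12)
})

test_that("degenerate inputs raise the documented errors and warnings", {
  X <- matrix(stats::rnorm(40), 10, 4)
  expect_error(cross_validated_decode(X, rep("phase1", 10)), "both phase classes")
  expect_warning(
    cross_validated_decode(X, rep(c("phase1", "phase2"), each = 5), folds = 10),
    "fold count")
})

test_that("the 80/20 holdout variant evaluates a single stratified split", {
  frm <- make_frm(rep(0.9, 10), n_rep = 30, seed = 6)
  r <- cross_validated_decode(frm$values, frm$phase_labels, seed = 2,
                              holdout_fraction = 0.2)
  expect_length(r$f1_per_fold, 1)
  # 30 repetitions x 2 phases = 60 samples; 20% of them form the test set
  expect_equal(Reduce(`+`, r$confusion), round(0.2 * 60))
})

test_that("a single informative unit is ranked most important", {
  frm <- make_frm(c(0.9, rep(0, 9)), seed = 1)
  imp <- feature_importance(frm, folds = 5, repeats = 3, seed = 2)
  expect_equal(imp$rank[imp$unit_id == "u001"], 1)
  expect_error(feature_importance(frm$values[, 1, drop = FALSE],
                                  frm$phase_labels), "at least 2")
})

test_that("stronger rate separation earns the higher importance rank", {
  wins <- vapply(1:10, function(s) {
    frm <- make_frm(c(0.6, 0.3, rep(0, 8)), seed = s)
    imp <- feature_importance(frm, folds = 5, repeats = 3, seed = s + 100)
    imp$rank[imp$unit_id == "u001"] < imp$rank[imp$unit_id == "u002"]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("uninformative populations have importances near zero", {
  frm <- make_frm(rep(0, 10), seed = 3)
  imp <- feature_importance(frm, folds = 5, repeats = 3, seed = 4)
  expect_lt(max(abs(imp$importance)), 0.1)
})

test_that("contributing-unit fraction behaves at its edge cases", {
  imp1 <- data.frame(unit_id = sprintf("u%02d", 1:50),
                     importance = c(0.5, rep(0, 49)))
  expect_equal(fraction_contributing_units(imp1)$fraction, 0.02)
  imp2 <- data.frame(unit_id = sprintf("u%02d", 1:20),
                     importance = rep(0.3, 20))
  expect_equal(fraction_contributing_units(imp2)$fraction, 1)
})

test_that("a 60%-selective population shows a majority of contributing units", {
  # moderate-signal regime so single-unit contributions stay measurable
  fr <- vapply(1:3, function(s) {
    spec <- population_spec(n_units = 20, mixture_weights = c(0.4, 0.3, 0.3),
                            selectivity = 0.5, base_rate = 6, seed = s)
    u <- generate_population(spec)
    prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 40)
    spk <- simulate_spike_trains(u, prot, seed = s + 10)
    frm <- build_rate_matrix(spk, prot, unit_ids = u$unit_id)
    imp <- feature_importance(frm, folds = 5, repeats = 3, seed = s + 20)
    fraction_contributing_units(imp)$fraction
  }, numeric(1))
  expect_gte(mean(fr), 0.4)
  expect_lte(mean(fr), 0.8)
})

test_that("importance rank tracks true selectivity magnitude", {
  rc <- vapply(1:3, function(s) {
    spec <- population_spec(n_units = 20, mixture_weights = c(0.4, 0.3, 0.3),
                            selectivity = 0.5, base_rate = 6, seed = s)
    u <- generate_population(spec)
    prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 40)
    spk <- simulate_spike_trains(u, prot, seed = s + 30)
    frm <- build_rate_matrix(spk, prot, unit_ids = u$unit_id)
    imp <- feature_importance(frm, folds = 5, repeats = 3, seed = s + 40)
    stats::cor(abs(u$true_rfr), -imp$rank[match(u$unit_id, imp$unit_id)],
               method = "spearman")
  }, numeric(1))
  expect_gt(mean(rc), 0.5)
})
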