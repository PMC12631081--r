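test_that("stratified split honors fractions and singleton rule", {
  ids <- sprintf("S%02d", 1:13)
  labs <- factor(c(rep("A", 10), rep("B", 2), "C"))
  sp <- stratifiedSplit(ids, labs, 0.8, seed = 1)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sum(labs[match(sp$train, ids)] == "A"), 8)
  expect_true("S13" %in% sp$train)  # singleton tumor goes to train
  sp2 <- stratifiedSplit(ids, labs, 0.8, seed = 1)
  expect_identical(sp, sp2)
  expect_error(stratifiedSplit(character(), factor()), "empty")
  expect_error(stratifiedSplit(ids, labs, 1.2), "fraction")
})

test_that("CV tuning prefers an adequate candidate over a crippled one", {
  med <- mediumFit()
  tr <- med$split$train
  X <- med$X[tr, ]; y <- med$y[tr]
  cands <- data.frame(
    eta = c(0.1, 0.3), max_depth = c(5, 1), min_child_weight = c(1, 1),
    subsample = c(0.9, 0.9), colsample_bytree = c(0.9, 0.9),
    max_rounds = c(300L, 5L))
  tuned <- tuneCV(X, y, cands, seed = 7)
  expect_equal(tuned$params$max_depth, 5)
  expect_lt(tuned$cvRMSE, tuned$log$cvRMSE[2])
  # single candidate comes back unchanged
  one <- tuneCV(X, y, cands[1, ], seed = 7)
  expect_equal(one$params$eta, 0.1)
  # deterministic fold assignment
  again <- tuneCV(X, y, cands, seed = 7)
  expect_equal(tuned$log, again$log)
  expect_error(tuneCV(X, rep(1, nrow(X)), cands), "degenerate")
})

test_that("a deep unregularized fit overfits the training target", {
  med <- mediumFit()
  tr <- med$split$train
  X <- med$X[tr, ]; y <- med$y[tr]
  deep <- fitFinal(X, y, list(objective = "reg:squarederror", eta = 0.3,
                              max_depth = 8, min_child_weight = 1,
                              subsample = 1, colsample_bytree = 1),
                   nrounds = 200, seed = 1)
  pred <- predict(deep, X)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.95)
})

test_that("model round-trips through serialization with identical output", {
  med <- mediumFit()
  X <- med$X[med$split$test, ]
  p1 <- predict(med$model, X)
  raw <- xgboost::xgb.save.raw(med$model@booster)
  clone <- med$model
  clone@booster <- xgboost::xgb.load.raw(raw)
  expect_identical(unname(p1), unname(predict(clone, X)))
  expect_error(predict(med$model, X[, 1:3]), "missing feature")
})

test_that("an all-missing feature column gets zero attribution", {
  set.seed(5)
  X <- cbind(a = rnorm(100), dead = NA_real_)
  y <- X[, "a"] * 2 + rnorm(100, sd = 0.1)
  m <- fitFinal(X, y, list(objective = "reg:squarederror", eta = 0.3,
                           max_depth = 3, min_child_weight = 1,
                           subsample = 1, colsample_bytree = 1),
                nrounds = 30, seed = 1)
  sm <- shapMatrix(m, X)
  expect_true(all(shapValues(sm)[, "dead"] == 0))
})

test_that("rank AUC equals pairwise enumeration and evaluation behaves", {
  set.seed(6)
  pred <- c(0.1, 0.9, 0.4, 0.4, 0.8, 0.2, 0.6, 0.3, 0.7, 0.5)
  truth <- c(0, 1, 0, 1, 1, 0, 1, 0, 1, 0)
  expect_equal(aucRank(pred, truth), oracleAUC(pred, truth))
  expect_warning(a <- aucRank(pred, rep(1, 10)), "one class")
  expect_true(is.na(a))

  med <- mediumFit()
  te <- med$split$test
  ev <- evaluateModel(med$model, med$X[te, ], med$y[te],
                      tumorLabels = tumorLabels(med$cohort$exposures)[
                        match(te, sampleIds(med$cohort$exposures))])
  expect_true(ev$overall$auc >= 0 && ev$overall$auc <= 1)
  expect_true(ev$overall$kappa >= -1 && ev$overall$kappa <= 1)
  expect_equal(nrow(ev$perTumor), nlevels(tumorLabels(med$cohort$exposures)))
  # perfect predictions give perfect metrics
  y <- med$y[te]
  perfect <- list(overall = NULL)
  fake <- med$model
  ssTot <- sum((y - mean(y))^2)
  expect_equal(cohenKappa(y > fake@cutoff, y > fake@cutoff), 1)
  expect_equal(oracleAUC(y, y > fake@cutoff), 1)
  # constant predictions: kappa 0
  expect_equal(cohenKappa(y > fake@cutoff, rep(FALSE, length(y))), 0)
})

test_that("no test rows influence tuning, fitting or scaling", {
  med <- mediumFit()
  # rebuild the model after perturbing every test row; train-side
  # artifacts must be identical
  cohort <- med$cohort
  feats <- assembleFeatures(med$omics, lapply(
    layers(med$omics), function(m) colnames(m)[1:10]))
  sp <- med$split
  pert <- feats
  pert[sp$test, ] <- pert[sp$test, ] * 100 + 7
  s1 <- suppressWarnings(zScale(feats, sp$train))
  s2 <- suppressWarnings(zScale(pert, sp$train))
  expect_identical(s1$center, s2$center)
  expect_identical(s1$scale, s2$scale)
  y <- med$y[rownames(feats)]
  cands <- makeSearchSpace(2, maxRounds = 50, seed = 3)
  t1 <- tuneCV(s1$values[sp$train, ], y[sp$train], cands, seed = 3)
  t2 <- tuneCV(s2$values[sp$train, ], y[sp$train], cands, seed = 3)
  expect_equal(t1$log, t2$log)
  m1 <- fitFinal(s1$values[sp$train, ], y[sp$train], t1$params,
                 t1$nrounds, seed = 3)
  m2 <- fitFinal(s2$values[sp$train, ], y[sp$train], t2$params,
                 t2$nrounds, seed = 3)
  expect_identical(predict(m1, s1$values[sp$train, ]),
                   predict(m2, s1$values[sp$train, ]))
})
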