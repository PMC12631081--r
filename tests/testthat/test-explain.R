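test_that("SHAP rows plus base value reproduce raw predictions", {
  med <- mediumFit()
  X <- med$X[med$split$test, ]
  sm <- shapMatrix(med$model, X)
  pred <- predict(med$model, X)
  err <- abs(rowSums(shapValues(sm)) + baseValue(sm) - pred) /
    pmax(abs(pred), 1e-8)
  expect_lt(max(err), 1e-3)
  expect_error(shapMatrix(med$model, X[, 1:2]), "missing feature")
})

test_that("single-tree SHAP equals brute-force Shapley enumeration", {
  # depth-2 tree over 2 informative features + 1 distractor
  set.seed(10)
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- ifelse(X[, "a"] > 0, 2, -1) + ifelse(X[, "b"] > 0.3, 1, 0)
  m <- fitFinal(X, y, list(objective = "reg:squarederror", eta = 1,
                           max_depth = 2, min_child_weight = 1,
                           subsample = 1, colsample_bytree = 1),
                nrounds = 1, seed = 1)
  sm <- shapMatrix(m, X)
  for (i in c(1, 57, 200)) {
    x <- as.list(X[i, ])
    brute <- oracleShapley(m@booster, x, colnames(X))
    expect_equal(unname(shapValues(sm)[i, ]), unname(brute),
                 tolerance = 1e-5)
  }
  # null player: a feature never split on attributes exactly zero
  tree <- as.data.frame(xgboost::xgb.model.dt.tree(model = m@booster))
  unused <- setdiff(colnames(X), tree$Feature)
  for (f in unused) expect_true(all(shapValues(sm)[, f] == 0))
})

test_that("SHAP importance is the mean absolute attribution", {
  sm <- new("ShapMatrix",
            values = cbind(a = c(1, -1, 1), b = c(0, 0, 0)),
            baseValue = 0,
            featureValues = cbind(a = 1:3, b = 4:6) * 1.0)
  imp <- shapImportance(sm)
  expect_equal(unname(imp), c(1, 0))
  sm2 <- sm; sm2@values[, "a"] <- sm2@values[, "a"] * 2
  expect_equal(unname(shapImportance(sm2)["a"]), 2)
})

test_that("per-tumor SHAP/value correlations hit the closed-form cases", {
  v <- cbind(f1 = c(1, 2, 3, 4), f2 = c(1, 2, 3, 4), f3 = c(5, 5, 5, 5))
  sm <- new("ShapMatrix",
            values = cbind(f1 = c(1, 2, 3, 4), f2 = -c(1, 2, 3, 4),
                           f3 = c(0, 0, 0, 0)),
            baseValue = 0, featureValues = v)
  h <- shapFeatureCorrelation(sm, factor(rep("T1", 4)))
  expect_equal(unname(h["T1", "f1"]), 1)
  expect_equal(unname(h["T1", "f2"]), -1)
  expect_true(is.na(h["T1", "f3"]))  # constant column is missing, not 0
  expect_warning(
    h2 <- shapFeatureCorrelation(sm, factor(c("A", "A", "A", "B"))),
    "fewer than")
  expect_true(all(is.na(h2["B", ])))
})

test_that("bootstrap clustering supports clean two-block structure", {
  set.seed(20)
  base1 <- rnorm(40); base2 <- rnorm(40)
  H <- rbind(r1 = base1 + rnorm(40, sd = 0.05),
             r2 = base1 + rnorm(40, sd = 0.05),
             r3 = base2 + rnorm(40, sd = 0.05),
             r4 = base2 + rnorm(40, sd = 0.05))
  hm <- clusterWithBootstrap(H, B = 100, seed = 1)
  sup <- hm@support
  expect_gte(sup[["r1+r2"]], 0.95)
  expect_gte(sup[["r3+r4"]], 0.95)
  expect_true(all(sup >= 0 & sup <= 1))
  # B = 1 gives support in {0, 1}
  hm1 <- clusterWithBootstrap(H, B = 1, seed = 2)
  expect_true(all(hm1@support %in% c(0, 1)))
  # identical rows cluster without error
  hmId <- clusterWithBootstrap(rbind(a = 1:5, b = 1:5, c = 1:5) * 1.0,
                               B = 5, seed = 3)
  expect_length(hmId@support, 2)
  expect_error(clusterWithBootstrap(H, B = 0), "at least 1")
  nw <- dendrogramNewick(hm)
  expect_match(nw, "^\\(.*\\);$")
})

test_that("top-N ablation converges to and reproduces the full model", {
  med <- mediumFit()
  te <- med$split$test
  X <- med$X[te, ]; y <- med$y[te]
  sm <- shapMatrix(med$model, X)
  imp <- shapImportance(sm)
  abl <- topnAblation(med$model, X, y,
                      nGrid = c(0, 1, 5, 10, 20, ncol(X)),
                      importance = imp)
  full <- predict(med$model, X)
  # N = all is bit-identical to the full model
  expect_identical(abl$rmse[abl$n == ncol(X)],
                   sqrt(mean((y - full)^2)))
  # N = 0 collapses to the constant default-path output
  Xna <- X; Xna[] <- NA_real_
  expect_identical(abl$rmse[abl$n == 0],
                   sqrt(mean((y - predict(med$model, Xna))^2)))
  # masking only zero-importance features changes nothing
  zeroImp <- names(imp)[imp == 0]
  if (length(zeroImp)) {
    Xz <- X; Xz[, zeroImp] <- NA_real_
    expect_identical(predict(med$model, Xz), full)
  }
  expect_warning(topnAblation(med$model, X, y,
                              nGrid = c(1, ncol(X) + 50),
                              importance = imp), "clamped")
})

test_that("waterfall rows sum to prediction minus base value", {
  med <- mediumFit()
  X <- med$X[med$split$test, ]
  sm <- shapMatrix(med$model, X)
  pred <- predict(med$model, X)
  wf <- waterfallExport(sm, 1, topK = ncol(X))
  expect_equal(sum(wf$contribution), pred[[1]] - baseValue(sm),
               tolerance = 1e-4)
  wf1 <- waterfallExport(sm, 1, topK = 1)
  expect_equal(nrow(wf1), 2)
  expect_equal(wf1$feature[2], "other")
  expect_equal(sum(wf1$contribution), pred[[1]] - baseValue(sm),
               tolerance = 1e-4)
  smz <- new("ShapMatrix", values = matrix(0, 1, 2,
               dimnames = list("s", c("a", "b"))),
             baseValue = 1,
             featureValues = matrix(1, 1, 2,
               dimnames = list("s", c("a", "b"))))
  expect_equal(nrow(waterfallExport(smz, 1)), 0)
})
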