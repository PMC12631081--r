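test_that("feature ranks combine correlation sign with importance weight", {
  sm <- new("ShapMatrix",
            values = cbind(up = c(1, 2, 3), down = c(3, 2, 1),
                           flat = c(0, 0, 0)),
            baseValue = 0,
            featureValues = cbind(up = c(1, 2, 3), down = c(1, 2, 3),
                                  flat = c(1, 2, 3)))
  expect_warning(rk <- rankFeatures(sm, importance = c(up = 0.3,
                                                       down = 0,
                                                       flat = 0.5)),
                 "dropped")
  # closed forms: corr 1, importance 0.3 -> 10^0.3; corr -1, imp 0 -> -1
  expect_equal(rk$rank[rk$feature == "up"], 1 * 10^0.3)
  expect_equal(rk$rank[rk$feature == "down"], -1)
  expect_false("flat" %in% rk$feature)
  # linear reading: corr * 10 * importance
  rkLin <- suppressWarnings(rankFeatures(sm,
    importance = c(up = 0.3, down = 0.2, flat = 0),
    reading = "linear"))
  expect_equal(rkLin$rank[rkLin$feature == "up"], 1 * 10 * 0.3)
  # zero correlation gives rank 0 regardless of importance
  smz <- new("ShapMatrix",
             values = cbind(z = c(1, -1, 1, -1)), baseValue = 0,
             featureValues = cbind(z = c(1, 1, -1, -1)))
  rkz <- rankFeatures(smz, importance = c(z = 5))
  expect_equal(rkz$rank, 0)
})

test_that("GMT parsing handles sets, duplicates and malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg1\tg4\tg5\tg6\tg7\tg4"), path)
  sets <- loadGMT(path)
  expect_length(sets, 2)
  expect_length(sets$setA, 3)
  expect_length(sets$setB, 5)  # duplicate g4 deduplicated
  writeLines(c("setA\tdesc\tg1", "setA\tdesc\tg2"), path)
  expect_error(loadGMT(path), "duplicate set name at GMT line 2")
  writeLines("setA\tdesc", path)
  expect_error(loadGMT(path), "malformed GMT line 1")
  writeLines("setA\tdesc\t\t", path)
  expect_error(loadGMT(path), "empty gene list")
})

test_that("enrichment score equals the brute-force running sum", {
  ranks <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3),
                    paste0("g", 1:8))
  set3 <- c("g1", "g2", "g3")
  got <- gseaPreranked(ranks, list(top = set3), nPerm = 50,
                       minSize = 3, seed = 1)
  expect_equal(got$es, oracleES(ranks, set3), tolerance = 1e-12)
  bottom <- c("g6", "g7", "g8")
  gotB <- gseaPreranked(ranks, list(bot = bottom), nPerm = 50,
                        minSize = 3, seed = 1)
  expect_gt(got$es, 0)
  expect_gt(got$es, gotB$es)
  expect_equal(gotB$es, oracleES(ranks, bottom), tolerance = 1e-12)
  # unweighted mode is invariant to positive monotone rescaling
  gotU <- gseaPreranked(ranks, list(top = set3), nPerm = 10,
                        minSize = 3, weightExponent = 0, seed = 1)
  gotU2 <- gseaPreranked(setNames(ranks * 3 + sign(ranks),
                                  names(ranks)),
                         list(top = set3), nPerm = 10, minSize = 3,
                         weightExponent = 0, seed = 1)
  expect_equal(gotU$es, gotU2$es, tolerance = 1e-12)
  # whole-universe set: running sum returns to ~0 without error
  gotAll <- gseaPreranked(ranks, list(all = names(ranks)), nPerm = 10,
                          minSize = 3, maxSize = 10, seed = 1)
  expect_equal(gotAll$es, 0)
})

test_that("enrichment agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(33)
  ranks <- setNames(sort(rnorm(40), decreasing = TRUE),
                    paste0("g", 1:40))
  sets <- list(s1 = paste0("g", 1:8), s2 = paste0("g", 30:40))
  ours <- gseaPreranked(ranks, sets, nPerm = 100, minSize = 3, seed = 1)
  for (nm in names(sets)) {
    ref <- fgsea::calcGseaStat(ranks,
                               which(names(ranks) %in% sets[[nm]]),
                               gseaParam = 1)
    expect_equal(ours$es[ours$pathway == nm], ref, tolerance = 1e-10)
  }
})

test_that("permutation p-values respect their floor and BH is monotone", {
  set.seed(12)
  ranks <- setNames(rnorm(60), paste0("g", 1:60))
  ranks[1:6] <- ranks[1:6] + 5
  res <- gseaPreranked(ranks, list(strong = paste0("g", 1:6),
                                   weak = paste0("g", 20:27)),
                       nPerm = 200, minSize = 3, seed = 4)
  expect_true(all(res$pval >= 1 / 201))
  expect_true(all(res$padj >= res$pval - 1e-15))
  ordRaw <- order(res$pval)
  expect_true(all(diff(res$padj[ordRaw]) >= -1e-15))
})

test_that("collection partition buckets and counts form a partition", {
  colls <- list(Hallmarks = list(h1 = c("A", "B")),
                KEGG = list(k1 = c("B", "C")),
                GOBP = list(g1 = c("D")))
  part <- partitionByCollections(c("A", "B", "C", "E"), colls)
  expect_true(part$Hallmarks[part$gene == "A"])
  expect_false(part$KEGG[part$gene == "A"])
  expect_true(part$Complementary[part$gene == "E"])
  expect_false(any(part$Complementary & (part$Hallmarks | part$KEGG |
                                           part$GOBP)))
  expect_equal(sum(attr(part, "intersections")), 4)
})

test_that("mutation association recovers separation and respects BH", {
  scores <- c(6:10, 1:5) / 10
  carrier <- c(rep(1, 5), rep(0, 5))
  res <- mutationAssociation(scores, carrier,
                             factor(rep("BRCA", 10)), minGroup = 3)
  expect_equal(res$U, 25)  # n1 * n0: full separation
  expect_equal(res$padj, res$pval)  # BH identity at m = 1
  # fully separated 10 vs 10 in one tumor
  s2 <- c(21:30, 1:10) / 30
  res2 <- mutationAssociation(s2, rep(c(1, 0), each = 10),
                              factor(rep("OV", 20)))
  expect_equal(res2$U, 100)
  expect_equal(res2$pval, 2 / choose(20, 10), tolerance = 1e-10)
  # groups under the size floor are skipped
  res3 <- mutationAssociation(scores, c(1, rep(0, 9)),
                              factor(rep("X", 10)))
  expect_equal(nrow(res3), 0)
  expect_error(mutationAssociation(scores, carrier[-1],
                                   factor(rep("X", 10))), "aligned")
})
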