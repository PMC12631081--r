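# Independent oracles and small fixture builders shared by the tests.
# Each oracle is a deliberately naive, loop-based transcription of the
# quantity it checks, kept independent of the package's vectorized path.

# random ExposureSet with gamma exposures (no planted structure)
randomExposureSet <- function(n = 200, nTypes = 3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("R%04d", seq_len(n))
  panel <- list(SBS = paste0("SBS", 1:30), ID = paste0("ID", 1:23),
                CN = paste0("CN", 1:21), scarHRD = "scarHRD")
  mats <- lapply(panel, function(bm) {
    m <- matrix(rgamma(n * length(bm), shape = 1.5, scale = 30),
                n, length(bm), dimnames = list(ids, bm))
    # sprinkle some all-zero rows/entries to hit the degenerate paths
    if (runif(1) < 0.3) m[sample(n, 1), ] <- 0
    m
  })
  new("ExposureSet", exposures = mats, sampleIds = ids,
      tumorLabels = factor(sample(paste0("T", seq_len(nTypes)), n,
                                  replace = TRUE)))
}

# straight-line loop transcription of the scoring chain (row
# normalization, max normalization, CN combination, supra-epsilon
# weights, rescaling, weighted sum), one sample at a time
oracleScores <- function(es, epsilon = 0.1) {
  ex <- exposures(es)
  G <- length(sampleIds(es))
  Ehat <- list()
  for (k in c("SBS", "ID", "CN")) {
    m <- ex[[k]]
    out <- m
    for (i in seq_len(G)) {
      s <- sum(m[i, ])
      out[i, ] <- if (s == 0) 0 else m[i, ] / s
    }
    Ehat[[k]] <- out
  }
  mx <- max(ex$scarHRD[, 1])
  e4 <- if (mx == 0) rep(0, G) else ex$scarHRD[, 1] / mx
  E <- cbind(Ehat$SBS[, "SBS3"], Ehat$ID[, "ID6"],
             ((1 - Ehat$CN[, "CN1"]) + Ehat$CN[, "CN17"]) / 2, e4)
  labs <- as.character(tumorLabels(es))
  s <- numeric(G)
  for (tt in unique(labs)) {
    idx <- which(labs == tt)
    w <- numeric(4)
    for (k in 1:4) {
      cnt <- 0
      for (i in idx) if (E[i, k] >= epsilon) cnt <- cnt + 1
      w[k] <- cnt / length(idx)
    }
    if (sum(w) == 0) w <- rep(1, 4)
    w <- w / sum(w)
    for (i in idx) s[i] <- sum(w * E[i, ])
  }
  names(s) <- sampleIds(es)
  s
}

# pairwise-enumeration AUC (ties count half)
oracleAUC <- function(pred, truth) {
  pos <- pred[as.logical(truth)]; neg <- pred[!as.logical(truth)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# expected tree output when only the features in S are known; unknown
# splits average the children weighted by training cover (the tree-path
# conditional expectation TreeSHAP targets)
.treeExpect <- function(tree, x, S) {
  rec <- function(id) {
    row <- tree[tree$ID == id, ]
    if (row$Feature == "Leaf") return(row$Gain)
    if (row$Feature %in% S) {
      v <- x[[row$Feature]]
      nxt <- if (is.na(v)) row$Missing
             else if (v < row$Split) row$Yes else row$No
      return(rec(nxt))
    }
    cy <- tree$Cover[tree$ID == row$Yes]
    cn <- tree$Cover[tree$ID == row$No]
    (cy * rec(row$Yes) + cn * rec(row$No)) / (cy + cn)
  }
  rec(tree$ID[tree$Node == 0])
}

# brute-force Shapley values by coalition enumeration over all features
oracleShapley <- function(booster, x, features) {
  tree <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  tree <- tree[tree$Tree == 0, ]
  vapply(features, function(f) {
    others <- setdiff(features, f)
    phi <- 0
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(character())
                 else asplit(utils::combn(others, k), 2)
      for (S in subsets) {
        S <- as.character(S)
        wgt <- factorial(length(S)) *
          factorial(length(features) - length(S) - 1) /
          factorial(length(features))
        phi <- phi + wgt * (.treeExpect(tree, x, c(S, f)) -
                              .treeExpect(tree, x, S))
      }
    }
    phi
  }, numeric(1))
}

# naive running-sum GSEA enrichment score (weight exponent p)
oracleES <- function(ranks, set, p = 1) {
  ord <- names(sort(ranks, decreasing = TRUE))
  nh <- sum(ord %in% set)
  nm <- length(ord) - nh
  sumW <- sum(abs(ranks[intersect(ord, set)]) ^ p)
  run <- 0; best <- 0
  for (g in ord) {
    if (g %in% set) run <- run + abs(ranks[[g]]) ^ p / sumW
    else run <- run - 1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# shared medium-size fitted pipeline fixture (built once per test run)
.fixtures <- new.env(parent = emptyenv())
mediumFit <- function() {
  if (!is.null(.fixtures$med)) return(.fixtures$med)
  cfg <- syntheticConfig(nSamples = 600,
                         nGenesPerLayer = c(CNV = 60, EXP = 60,
                                            MET = 60, MUT = 60),
                         nInformativePerLayer = c(CNV = 6, EXP = 6,
                                                  MET = 6, MUT = 6),
                         seed = 11)
  cohort <- generateCohort(cfg)
  scores <- discretizeByMedian(panhrdScores(cohort$exposures))
  omics <- transformBundle(cohort$omics)
  split <- stratifiedSplit(sampleIds(cohort$exposures),
                           tumorLabels(cohort$exposures), seed = 11)
  # model tests do not need the selection stage: use the planted genes
  # plus a margin of noise genes as the feature set
  sel <- lapply(names(layers(omics)), function(nm)
    c(cohort$truth@informativeGenes[[nm]],
      setdiff(colnames(layers(omics)[[nm]]), cohort$truth@informativeGenes[[nm]])[1:4]))
  names(sel) <- names(layers(omics))
  feats <- assembleFeatures(omics, sel)
  scaled <- suppressWarnings(zScale(feats, split$train))
  y <- hrdScores(scores)[rownames(scaled$values)]
  tuned <- tuneCV(scaled$values[split$train, ], y[split$train],
                  candidates = makeSearchSpace(2, maxRounds = 300,
                                               seed = 11), seed = 11)
  model <- fitFinal(scaled$values[split$train, ], y[split$train],
                    tuned$params, tuned$nrounds,
                    cutoff = scores@cutoff, seed = 11)
  .fixtures$med <- list(cfg = cfg, cohort = cohort, scores = scores,
                        omics = omics, split = split,
                        X = scaled$values, y = y, model = model)
  .fixtures$med
}
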