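test_that("similarity scores equal a dynamic-programming oracle", {
  # local alignment, match +1 / mismatch -1 / linear gap -2
  swOracle <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    H <- matrix(0, length(av) + 1, length(bv) + 1)
    best <- 0
    for (i in seq_along(av)) for (j in seq_along(bv)) {
      d <- H[i, j] + if (av[i] == bv[j]) 1 else -1
      H[i + 1, j + 1] <- max(0, d, H[i, j + 1] - 2, H[i + 1, j] - 2)
      best <- max(best, H[i + 1, j + 1])
    }
    best
  }
  withr::with_seed(41, seqs <- replicate(5, randomDna(50)))
  got <- similarityScores(seqs)
  for (i in 1:5) {
    ref <- mean(vapply(setdiff(1:5, i), function(j)
      swOracle(seqs[i], seqs[j]), numeric(1)))
    expect_equal(got[i], ref, ignore_attr = TRUE)
  }

  twins <- rep(randomDna(100, seed = 6), 2)
  expect_equal(unname(similarityScores(twins)), c(100, 100))

  odd <- c(randomDna(60, seed = 7, gc = 0.9),
           randomDna(60, seed = 8, gc = 0.9), strrep("A", 60))
  sc <- similarityScores(odd)
  expect_identical(which.min(sc), 3L)
  expect_error(similarityScores(character()), "no sequences")
})

test_that("subset construction sorts, splits and drops deterministically", {
  sub <- buildTrainingSubsets(paste0("p", 1:4), c(9, 7, 5, 3),
                              paste0("n", 1:2), 2)
  expect_identical(sub$subset1, c("p1", "p2", "n1", "n2"))
  expect_identical(sub$subset2, c("p3", "p4", "n1", "n2"))

  # ties broken by record id, so permuting input order changes nothing
  ids <- paste0("p", sprintf("%02d", 1:6))
  sc <- c(5, 5, 5, 5, 1, 1)
  s1 <- suppressWarnings(buildTrainingSubsets(ids, sc, paste0("n", 1:2), 2))
  perm <- c(4, 2, 6, 1, 3, 5)
  s2 <- suppressWarnings(
    buildTrainingSubsets(ids[perm], sc[perm], paste0("n", 1:2), 2))
  expect_identical(s1, s2)

  expect_warning(
    sub3 <- buildTrainingSubsets(paste0("p", 1:5), 5:1, paste0("n", 1:2), 2),
    "dropped")
  expect_identical(sub3$dropped, "p5")
  expect_error(buildTrainingSubsets(paste0("p", 1:3), 3:1,
                                    paste0("n", 1:2), 2), "at least 4")
  expect_error(buildTrainingSubsets(paste0("p", 1:4), 4:1,
                                    paste0("n", 1:3), 2), "group_size")
})

test_that("the published survey composition yields the documented splits", {
  comp <- referenceSurveyComposition()
  train <- comp[comp$dataset == "training", ]
  test <- comp[comp$dataset == "testing", ]
  expect_identical(train$ac + train$ne, 280L)   # ND dropped
  expect_identical(test$ac + test$ne, 48L)
  expect_warning(
    sub <- buildTrainingSubsets(sprintf("p%03d", seq_len(train$ac)),
                                rev(seq_len(train$ac)),
                                sprintf("n%02d", seq_len(train$ne)),
                                train$ne),
    "10 lowest-similarity")
  expect_identical(length(sub$subset1), 180L)
  expect_identical(length(sub$subset2), 180L)
  expect_identical(length(sub$dropped), 10L)
})

test_that("the combo sweep enumerates the 15 feature subsets", {
  combos <- enumerateCombos()
  expect_identical(length(combos), 15L)
  expect_identical(vapply(combos, length, integer(1)),
                   rep(1:4, c(4, 6, 4, 1)))
  labels <- vapply(combos, paste, character(1), collapse = "+")
  expect_identical(anyDuplicated(labels), 0L)
  expect_identical(combos[[15]], c("Ngram", "Motif", "NPC", "CGI"))
})

test_that("the naive-Bayes integrator separates, deduplicates and abstains", {
  withr::with_seed(50, {
    y <- rep(c("Ac", "NAc"), each = 25)
    sep <- c(rnorm(25, 0.9, 0.02), rnorm(25, 0.1, 0.02))
    noise <- runif(50)
  })
  probs <- cbind(`ups1k.ngram` = sep, `ups1k.npc` = noise)
  l2 <- trainLayerTwo(probs, y, c("Ngram", "NPC"))
  pred <- layerTwoPredict(l2, probs)
  expect_equal(ifelse(pred >= 0.5, "Ac", "NAc"), y)

  # duplicated evidence columns keep the symmetric-case ranking
  dup <- cbind(`ups1k.ngram` = sep, `distance.ngram` = sep)
  l2dup <- trainLayerTwo(dup, y, "Ngram")
  l2one <- trainLayerTwo(dup[, 1, drop = FALSE], y, "Ngram")
  expect_identical(layerTwoPredict(l2dup, dup) >= 0.5,
                   layerTwoPredict(l2one, dup[, 1, drop = FALSE]) >= 0.5)

  # constant columns are unusable: falls back to the class prior
  flat <- cbind(`ups1k.cgi` = rep(0.5, 50))
  l2flat <- trainLayerTwo(flat, y, "CGI")
  expect_equal(layerTwoPredict(l2flat, flat), rep(0.5, 50))
  expect_error(trainLayerTwo(probs, rep("Ac", 50), "Ngram"),
               "single class")
})

test_that("layer-1 training produces eight deterministic calibrated models", {
  enc <- smallEncoded()
  ids <- enc$ids
  y <- enc$labels[ids]
  dm <- publishedDistanceModel()
  cfg <- fastConfig()
  maskKeys <- c("ups1k.ngram", "distance.ngram", "middle.ngram",
                "ups1k.motif")
  masks <- lapply(maskKeys, function(k)
    selectPatterns(enc$features[[k]][ids, ], y))
  names(masks) <- maskKeys

  l1 <- trainLayerOne(enc, ids, masks, dm, cfg, seed = 2)
  expect_identical(length(l1), 8L)
  expect_identical(names(l1),
                   pairKeyVec <- paste(
                     tolower(c("UPS1K", "UPS1K", "UPS1K", "UPS1K",
                               "DISTANCE", "DISTANCE", "MIDDLE", "MIDDLE")),
                     tolower(c("Ngram", "Motif", "NPC", "CGI",
                               "Ngram", "NPC", "Ngram", "NPC")),
                     sep = "."))

  l1b <- trainLayerOne(enc, ids, masks, dm, cfg, seed = 2)
  m <- new("TwoLayerModel", layer1 = l1, combo = "Ngram",
           layer2 = trainLayerTwo(
             activTag:::layerOneProbsFromModels(l1, enc, ids, dm,
                                                "multiply"),
             y, "Ngram"),
           distanceModel = dm, masks = masks, motifLibrary = enc$library,
           propertyTable = enc$reduced, config = cfg,
           manifest = list(seed = 2))
  p1 <- layerOneOutputs(m, enc, ids)
  expect_identical(dim(p1), c(length(ids), 8L))
  expect_true(all(p1 >= 0 & p1 <= 1))
  p1b <- activTag:::layerOneProbsFromModels(l1b, enc, ids, dm, "multiply")
  expect_identical(unname(p1), unname(p1b))   # same seed, same model
})

test_that("a linearly separable toy problem is learned perfectly", {
  withr::with_seed(60, {
    X <- rbind(matrix(rnorm(40, 3), 20, 2), matrix(rnorm(40, -3), 20, 2))
    colnames(X) <- c("f1", "f2")
    rownames(X) <- sprintf("r%02d", 1:40)
    y <- rep(c("Ac", "NAc"), each = 20)
  })
  mod <- activTag:::trainOneModel(X, y, rep(1, 40), "UPS1K", "NPC",
                                  fastConfig(), seed = 1)
  p <- activTag:::predictOneModel(mod, X, rep(1, 40), rep(TRUE, 40),
                                  "multiply")
  expect_equal(unname(ifelse(p >= 0.5, "Ac", "NAc")), y)
})

test_that("the end-to-end fit on a strongly planted study is coherent", {
  fit <- smallFit()
  model <- selectedModel(fit)
  expect_s4_class(model, "TwoLayerModel")
  expect_identical(length(model@layer1), 8L)
  proto <- protocolTable(fit)
  expect_identical(nrow(proto), 6L)          # 2 models x 3 protocols
  expect_true(all(c("cross_validation", "self_consistency",
                    "exchange_testing") %in% proto$protocol))
  # self-consistency should not trail cross-validation on accuracy
  for (mnm in c("subset1", "subset2")) {
    slf <- proto$acc[proto$model == mnm &
                     proto$protocol == "self_consistency"]
    cv <- proto$acc[proto$model == mnm &
                    proto$protocol == "cross_validation"]
    expect_gte(slf, cv - 5)
  }
  # strong planted signal is learned
  expect_gt(proto$auc[proto$model == fit@manifest$selected &
                      proto$protocol == "cross_validation"], 0.8)
})

test_that("model bundles round-trip to identical predictions", {
  fit <- smallFit()
  model <- selectedModel(fit)
  enc <- smallEncoded()
  dir <- withr::local_tempdir()
  saveModelBundle(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  loaded <- loadModelBundle(dir)
  expect_identical(predictTwoLayer(loaded, enc, enc$ids),
                   predictTwoLayer(model, enc, enc$ids))
  expect_identical(loaded@combo, model@combo)
  expect_error(loadModelBundle(withr::local_tempdir()), "manifest")
})

test_that("flanking-gene prediction windows and ranks candidate genes", {
  fit <- smallFit()
  model <- selectedModel(fit)
  st <- smallStudy()
  genome <- studyGenome(st)
  genes <- studyGenes(st)
  ins0 <- as.data.frame(studyInsertions(st))[1, ]
  ins <- list(line_id = ins0$line_id, chrom = ins0$chrom,
              position = ins0$position, orientation = ins0$orientation)
  tab <- predictFlankingGenes(model, genome, genes, ins)
  expect_gte(nrow(tab), 1L)
  expect_identical(colnames(tab),
                   c("gene_id", "chrom", "tls", "distance_bp",
                     "location_class", "label", "confidence"))
  expect_true(all(tab$distance_bp <= 30000))
  expect_true(all(tab$confidence >= 0 & tab$confidence <= 1))

  # the gene exactly at the window boundary is included (closed interval)
  d0 <- abs(genes$tls[match(tab$gene_id[1], genes$gene_id)] -
            ins$position)
  atBoundary <- predictFlankingGenes(model, genome, genes, ins,
                                     window_bp = d0)
  expect_true(tab$gene_id[1] %in% atBoundary$gene_id)
  # a window short of every gene is empty
  none <- predictFlankingGenes(model, genome, genes, ins,
                               window_bp = max(1, d0 - 1))
  expect_identical(nrow(none), 0L)
  expect_error(predictFlankingGenes(model, genome, genes, ins, 0),
               "positive")
})
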