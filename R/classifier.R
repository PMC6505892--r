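#' Encode every record of a region set with the four feature families
#'
#' Produces the eight admissible (region, feature) matrices: all four
#' families on the upstream promoter, k-mer and physicochemical
#' encodings on the DISTANCE and MIDDLE regions. Motif scanning and
#' CpG-island detection run on the promoter with the TLS placed just 3'
#' of its last base. Regions shorter than 2 nt yield zero rows and are
#' flagged so downstream classifiers can abstain.
#'
#' @param regions a `RegionSet`.
#' @param library a `MotifLibrary`.
#' @param reduced 16 x k matrix from [reducePropertyTable()].
#' @param config configuration list, see [defaultRunConfig()].
#' @param labels optional label table (`line_id`, `gene_id`, `label`).
#' @return an encoded-study list: `ids`, `labels`, `distance_bp`,
#'   `valid` (record x region logical), `features` (8 named matrices),
#'   `regions`, `library`, `reduced`.
#' @export
encodeStudy <- function(regions, library, reduced,
                        config = defaultRunConfig(), labels = NULL) {
  rec <- regionRecords(regions)
  ids <- recordIds(regions)
  if (anyDuplicated(ids)) stop("duplicate (line_id, gene_id) records")
  n <- length(ids)
  seqs <- list(UPS1K = rec$ups1k, DISTANCE = rec$distance_seq,
               MIDDLE = rec$middle)
  valid <- vapply(seqs, function(s) nchar(s) >= 2, logical(n))
  if (n == 1) valid <- matrix(valid, nrow = 1,
                              dimnames = list(NULL, names(seqs)))
  rownames(valid) <- ids

  feats <- list()
  npcNames <- as.vector(t(outer(rownames(reduced), colnames(reduced),
                                function(d, p) paste0("npc:", d, ":", p))))
  for (rg in REGION_NAMES) {
    m <- t(vapply(seqs[[rg]], countNgrams, numeric(5440),
                  USE.NAMES = FALSE))
    dimnames(m) <- list(ids, ngramNames())
    feats[[pairKey(rg, "Ngram")]] <- m
  }
  nk <- ncol(reduced)
  for (rg in REGION_NAMES) {
    m <- t(vapply(seqs[[rg]], function(s) {
      if (nchar(s) >= 2) encodeNpc(s, reduced) else numeric(16 * nk)
    }, numeric(16 * nk), USE.NAMES = FALSE))
    dimnames(m) <- list(ids, npcNames)
    feats[[pairKey(rg, "NPC")]] <- m
  }
  pthr <- config$motif.p_threshold
  m <- t(vapply(rec$ups1k, function(s) {
    occ <- scanMotifs(s, library, pthr)
    encodeMotifs(occ, library, nchar(s))
  }, numeric(6 * length(library)), USE.NAMES = FALSE))
  dimnames(m) <- list(ids, motifChannelNames(library))
  feats[[pairKey("UPS1K", "Motif")]] <- m

  m <- t(vapply(rec$ups1k, function(s) {
    isl <- detectCpgIslands(s, config$cgi.min_len, config$cgi.gc_min,
                            config$cgi.oe_min, config$cgi.window,
                            config$cgi.shift)
    encodeCgi(isl, s, nchar(s))
  }, numeric(5), USE.NAMES = FALSE))
  dimnames(m) <- list(ids, cgiChannelNames())
  feats[[pairKey("UPS1K", "CGI")]] <- m

  labvec <- setNames(rep(NA_character_, n), ids)
  if (!is.null(labels) && nrow(labels) > 0) {
    lid <- paste(labels$line_id, labels$gene_id, sep = "|")
    hit <- match(ids, lid)
    labvec[!is.na(hit)] <- labels$label[hit[!is.na(hit)]]
  }
  list(ids = ids, labels = labvec,
       distance_bp = setNames(rec$distance_bp, ids),
       valid = valid, features = feats, regions = regions,
       library = library, reduced = reduced)
}

encLabels <- function(enc, ids) unname(enc$labels[ids])

#' Mean pairwise local-alignment similarity scores
#'
#' Each sequence is aligned locally (Smith-Waterman; match +1,
#' mismatch -1, linear gap cost -2 per base, exact scores computed in
#' compiled code) against every other sequence; its score is the mean
#' of those pairwise scores. Used to split positives into two
#' similarity-balanced groups.
#'
#' @param seqs character vector of (promoter) sequences, length >= 2.
#' @return numeric vector of mean pairwise scores, named like `seqs`.
#' @export
similarityScores <- function(seqs) {
  n <- length(seqs)
  if (n == 0) stop("no sequences")
  if (n == 1) stop("need at least 2 sequences")
  out <- .meanPairwiseLocalScores(as.character(seqs))
  names(out) <- names(seqs)
  out
}

#' Split positives into two similarity groups and build training subsets
#'
#' Positives are sorted by similarity score (descending; ties broken by
#' record id). The top `group_size` become subset 1's positives, the
#' next `group_size` subset 2's; extras are dropped with a warning. Each
#' subset is its positives plus all (shared) negatives, giving two
#' balanced training sets of `2 * group_size` records.
#'
#' @param pos_ids positive record ids.
#' @param scores similarity scores aligned with `pos_ids`.
#' @param neg_ids negative record ids; must number exactly `group_size`
#'   (1:1 positive:negative balance).
#' @param group_size positives per subset.
#' @return list with `subset1`, `subset2` (record id vectors) and
#'   `dropped` (positive ids not used).
#' @export
buildTrainingSubsets <- function(pos_ids, scores, neg_ids, group_size) {
  if (length(pos_ids) < 2 * group_size)
    stop("need at least ", 2 * group_size, " positives, got ",
         length(pos_ids))
  if (length(neg_ids) != group_size)
    stop("negatives (", length(neg_ids), ") must equal group_size (",
         group_size, ")")
  ord <- order(-scores, pos_ids)
  sorted <- pos_ids[ord]
  s1 <- sorted[seq_len(group_size)]
  s2 <- sorted[group_size + seq_len(group_size)]
  dropped <- sorted[-seq_len(2 * group_size)]
  if (length(dropped) > 0)
    warning(length(dropped), " lowest-similarity positive(s) dropped: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  list(subset1 = c(s1, neg_ids), subset2 = c(s2, neg_ids),
       dropped = dropped)
}

#' All non-empty feature combinations for the integrator sweep
#'
#' @return list of 15 character vectors: the 4 singletons, 6 pairs,
#'   4 triples and the full quadruple, in deterministic order.
#' @export
enumerateCombos <- function() {
  out <- list()
  for (k in 1:4)
    out <- c(out, utils::combn(FEATURE_NAMES, k, simplify = FALSE))
  out
}

comboLabel <- function(combo) paste(combo, collapse = "+")

# -- layer 1 ---------------------------------------------------------------

# Assemble the design matrix for one (region, feature) model: pattern
# mask (k-mer / motif families only), activation-probability weighting,
# then column standardization with the stored parameters.
prepDesign <- function(X, pi_w, model = NULL, mask_cols = NULL,
                      weighting = "multiply") {
  if (!is.null(mask_cols)) X <- X[, mask_cols, drop = FALSE]
  if (weighting == "multiply") {
    X <- X * pi_w
  } else if (weighting == "append") {
    X <- cbind(X, pi_dist = pi_w)
  }
  X
}

trainOneModel <- function(X, y, pi_w, region, feature, config, seed,
                         mask = NULL, fixed = NULL) {
  degenerate <- function(reason)
    list(region = region, feature = feature,
         key = pairKey(region, feature), degenerate = reason)
  mask_cols <- NULL
  if (!is.null(mask)) {
    mask_cols <- names(mask$mask)[mask$mask]
    if (length(mask_cols) == 0)
      return(degenerate("no pattern passed the significance filter"))
  }
  X <- prepDesign(X, pi_w, mask_cols = mask_cols,
                  weighting = config$distance.weighting)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- which(scl > 0)
  if (length(keep) == 0)
    return(degenerate("all feature columns constant"))
  X <- scale(X[, keep, drop = FALSE], ctr[keep], scl[keep])
  yf <- factor(y, levels = c("Ac", "NAc"))

  folds <- stratifiedFolds(y, config$layer1.inner_folds,
                           childSeed(seed, 11), ids = rownames(X))
  if (is.null(fixed)) {
    grid <- expand.grid(cost = config$layer1.cost_grid,
                        gamma = config$layer1.gamma_grid)
    accs <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in unique(folds)) {
        hold <- folds == f
        m <- e1071::svm(X[!hold, , drop = FALSE], yf[!hold],
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
        correct <- correct +
          sum(predict(m, X[hold, , drop = FALSE]) == yf[hold])
      }
      accs[g] <- correct
    }
    best <- which.max(accs)   # ties: first in grid order
    cost <- grid$cost[best]; gamma <- grid$gamma[best]
  } else {
    cost <- fixed$cost; gamma <- fixed$gamma
  }

  fit <- e1071::svm(X, yf, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  # Platt-style calibration on out-of-fold decision values (seeded and
  # deterministic, unlike libsvm's built-in probability model)
  dv <- numeric(length(y))
  for (f in unique(folds)) {
    hold <- folds == f
    m <- e1071::svm(X[!hold, , drop = FALSE], yf[!hold],
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
    dv[hold] <- attr(predict(m, X[hold, , drop = FALSE],
                             decision.values = TRUE),
                     "decision.values")[, 1]
  }
  cal <- suppressWarnings(glm((y == "Ac") ~ dv, family = binomial()))
  list(region = region, feature = feature,
       key = pairKey(region, feature), degenerate = NULL,
       mask_cols = mask_cols, center = ctr[keep], scale = scl[keep],
       keep = names(ctr)[keep], cost = cost, gamma = gamma, svm = fit,
       platt = unname(coef(cal)), seed = seed)
}

predictOneModel <- function(model, X, pi_w, valid, weighting) {
  n <- nrow(X)
  if (!is.null(model$degenerate)) return(rep(0.5, n))
  Xp <- prepDesign(X, pi_w, mask_cols = model$mask_cols,
                   weighting = weighting)
  Xp <- scale(Xp[, model$keep, drop = FALSE], model$center, model$scale)
  dv <- attr(predict(model$svm, Xp, decision.values = TRUE),
             "decision.values")[, 1]
  p <- plogis(model$platt[1] + model$platt[2] * dv)
  p[!valid] <- 0.5
  p
}

#' Train the eight first-layer classifiers
#'
#' One RBF-kernel margin classifier per admissible (region, feature)
#' pair, with the pattern mask applied to the k-mer and motif families,
#' activation-probability weighting, column standardization, a seeded
#' inner 3-fold grid search over (cost, gamma), and seeded Platt-style
#' probability calibration.
#'
#' @param enc encoded study from [encodeStudy()].
#' @param ids training record ids (balanced subset).
#' @param masks named list of pattern masks (keys `ups1k.ngram`,
#'   `distance.ngram`, `middle.ngram`, `ups1k.motif`).
#' @param distModel a `DistanceLogisticModel` for the weighting.
#' @param config configuration list.
#' @param seed RNG seed.
#' @return named list of 8 layer-1 model objects (fixed pair order).
#' @export
trainLayerOne <- function(enc, ids, masks, distModel,
                          config = defaultRunConfig(), seed = 1L) {
  y <- encLabels(enc, ids)
  pi_w <- activationProbability(distModel, enc$distance_bp[ids])
  pairs <- layerOnePairs()
  models <- list()
  for (i in seq_len(nrow(pairs))) {
    rg <- pairs$region[i]; ft <- pairs$feature[i]
    key <- pairKey(rg, ft)
    mask <- if (ft %in% c("Ngram", "Motif")) masks[[key]] else NULL
    models[[key]] <- trainOneModel(
      enc$features[[key]][ids, , drop = FALSE], y, pi_w, rg, ft,
      config, childSeed(seed, i), mask = mask)
  }
  models
}

layerOneProbsFromModels <- function(models, enc, ids, distModel,
                                    weighting) {
  pi_w <- activationProbability(distModel, enc$distance_bp[ids])
  out <- vapply(models, function(m)
    predictOneModel(m, enc$features[[m$key]][ids, , drop = FALSE], pi_w,
                    enc$valid[ids, m$region], weighting),
    numeric(length(ids)))
  if (length(ids) == 1)
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(models)))
  rownames(out) <- ids
  out
}

#' Calibrated layer-1 probabilities for records of an encoded study
#'
#' One activation probability per first-layer model, in the fixed
#' (region, feature) pair order. Records whose region is missing (for
#' example a DISTANCE interval shorter than 2 nt) receive 0.5 from the
#' models of that region.
#'
#' @param model a `TwoLayerModel`.
#' @param enc encoded study.
#' @param ids record ids (default: all).
#' @return records x 8 matrix of probabilities.
#' @export
layerOneOutputs <- function(model, enc, ids = enc$ids) {
  layerOneProbsFromModels(model@layer1, enc, ids, model@distanceModel,
                          model@config$distance.weighting)
}

# -- layer 2 ---------------------------------------------------------------

#' Train the Gaussian naive-Bayes integrator over a feature combination
#'
#' @param probs records x models matrix of layer-1 probabilities
#'   (columns named by pair key).
#' @param labels `"Ac"`/`"NAc"` labels.
#' @param combo non-empty subset of the four feature names.
#' @return an integrator list usable by [layerTwoPredict()].
#' @export
trainLayerTwo <- function(probs, labels, combo) {
  stopifnot(all(combo %in% FEATURE_NAMES), length(combo) > 0)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  pairs <- layerOnePairs()
  cols <- pairKey(pairs$region, pairs$feature)[pairs$feature %in% combo]
  cols <- intersect(cols, colnames(probs))
  x <- probs[, cols, drop = FALSE]
  varying <- cols[apply(x, 2, sd) > 0]
  if (length(varying) == 0) {
    return(list(combo = combo, cols = character(),
                prior = mean(labels == "Ac"), nb = NULL))
  }
  yf <- factor(labels, levels = c("Ac", "NAc"))
  x <- probs[, varying, drop = FALSE]
  nb <- e1071::naiveBayes(as.data.frame(x), yf)
  # inputs outside the training range are clipped at prediction time:
  # in the Gaussian tails the larger-variance class wins regardless of
  # direction, which inverts rankings under covariate shift
  list(combo = combo, cols = varying, prior = mean(labels == "Ac"),
       nb = nb, lo = apply(x, 2, min), hi = apply(x, 2, max))
}

#' Posterior activation probabilities from the integrator
#' @param l2 integrator from [trainLayerTwo()].
#' @param probs records x models layer-1 probability matrix.
#' @export
layerTwoPredict <- function(l2, probs) {
  if (is.null(l2$nb)) return(rep(l2$prior, nrow(probs)))
  x <- probs[, l2$cols, drop = FALSE]
  for (j in seq_along(l2$cols))
    x[, j] <- pmin(pmax(x[, j], l2$lo[j]), l2$hi[j])
  as.numeric(predict(l2$nb, as.data.frame(x), type = "raw")[, "Ac"])
}

#' Posterior activation probability of the full two-layer model
#' @param model a `TwoLayerModel`.
#' @param enc encoded study.
#' @param ids record ids.
#' @export
predictTwoLayer <- function(model, enc, ids = enc$ids) {
  layerTwoPredict(model@layer2, layerOneOutputs(model, enc, ids))
}

# -- subset training with stacked cross-validation -------------------------

#' Train a two-layer model on one training subset
#'
#' Fits the pattern masks and the eight layer-1 classifiers on the full
#' subset, then runs a seeded stratified 5-fold cross-validation of the
#' whole stack (masks and layer-1 models refit per fold with the
#' hyperparameters found on the full subset) to score all 15 feature
#' combinations on pooled out-of-fold predictions. The combination with
#' the highest cross-validated AUC becomes the model's integrator.
#'
#' @param enc encoded study.
#' @param ids record ids of the (balanced) training subset.
#' @param distModel `DistanceLogisticModel` for weighting.
#' @param config configuration list.
#' @param seed RNG seed.
#' @param subsetName label stored in the manifest.
#' @return list: `model` (a `TwoLayerModel`), `ids`, `comboTable`
#'   (15 x metrics), `cvReport` (selected combo's row).
#' @export
trainSubsetModel <- function(enc, ids, distModel,
                             config = defaultRunConfig(), seed = 1L,
                             subsetName = "subset", verbose = FALSE) {
  t0 <- Sys.time()
  vlog <- function(stage) if (verbose)
    message(sprintf("  [%s] %s: %.1f s elapsed", subsetName, stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
  y <- encLabels(enc, ids)
  alpha <- config$patterns.alpha
  maskKeys <- c(pairKey("UPS1K", "Ngram"), pairKey("DISTANCE", "Ngram"),
                pairKey("MIDDLE", "Ngram"), pairKey("UPS1K", "Motif"))
  fitMasks <- function(use_ids) {
    ms <- lapply(maskKeys, function(k)
      selectPatterns(enc$features[[k]][use_ids, , drop = FALSE],
                     encLabels(enc, use_ids), alpha))
    names(ms) <- maskKeys
    ms
  }
  masks <- fitMasks(ids)
  vlog("pattern masks")
  layer1 <- trainLayerOne(enc, ids, masks, distModel, config, seed)
  vlog("layer-1 grid search")
  hyper <- lapply(layer1, function(m)
    if (is.null(m$degenerate)) list(cost = m$cost, gamma = m$gamma)
    else NULL)

  combos <- enumerateCombos()
  folds <- stratifiedFolds(y, config$cv.folds, childSeed(seed, 77),
                           ids = ids)
  weighting <- config$distance.weighting
  pairs <- layerOnePairs()
  # out-of-fold layer-1 probabilities: masks and layer-1 models refit
  # per fold (hyperparameters reused from the full-subset search)
  oofP <- matrix(NA_real_, length(ids), nrow(pairs),
                 dimnames = list(ids, names(layer1)))
  for (f in unique(folds)) {
    tr <- ids[folds != f]; te <- ids[folds == f]
    mtr <- fitMasks(tr)
    ytr <- encLabels(enc, tr)
    pi_tr <- activationProbability(distModel, enc$distance_bp[tr])
    mods <- list()
    for (i in seq_len(nrow(pairs))) {
      rg <- pairs$region[i]; ft <- pairs$feature[i]
      key <- pairKey(rg, ft)
      mask <- if (ft %in% c("Ngram", "Motif")) mtr[[key]] else NULL
      mods[[key]] <- trainOneModel(
        enc$features[[key]][tr, , drop = FALSE], ytr, pi_tr, rg, ft,
        config, childSeed(seed, 100 + f * 10 + i), mask = mask,
        fixed = hyper[[key]])
    }
    oofP[te, ] <- layerOneProbsFromModels(mods, enc, te, distModel,
                                          weighting)
    vlog(sprintf("cross-validation fold %d", f))
  }
  # the integrator is trained and evaluated on out-of-fold layer-1
  # probabilities (stacked generalization), so its inputs at fit time
  # match what it sees on unseen records
  comboTable <- do.call(rbind, lapply(combos, function(cb) {
    sc <- numeric(length(ids))
    for (f in unique(folds)) {
      hold <- folds == f
      l2 <- trainLayerTwo(oofP[!hold, , drop = FALSE], y[!hold], cb)
      sc[hold] <- layerTwoPredict(l2, oofP[hold, , drop = FALSE])
    }
    rep <- evaluationReport(sc, y)
    data.frame(combo = comboLabel(cb), acc = rep$acc, auc = rep$auc,
               f1 = rep$f1, sn = rep$sn, sp = rep$sp)
  }))
  bestIdx <- which.max(comboTable$auc)
  combo <- combos[[bestIdx]]
  l2 <- trainLayerTwo(oofP, y, combo)
  cvRow <- comboTable[bestIdx, ]
  cvReport <- list(acc = cvRow$acc, auc = cvRow$auc, f1 = cvRow$f1,
                   sn = cvRow$sn, sp = cvRow$sp)
  model <- new("TwoLayerModel", layer1 = layer1, combo = combo,
               layer2 = l2, distanceModel = distModel, masks = masks,
               motifLibrary = enc$library, propertyTable = enc$reduced,
               config = config,
               manifest = list(subset = subsetName, seed = seed,
                               n_train = length(ids),
                               cvReport = cvReport))
  list(model = model, ids = ids, comboTable = comboTable,
       cvReport = cvReport)
}

#' Train the full two-layer activation predictor
#'
#' End-to-end training: region extraction, feature encoding, the
#' distance logistic, similarity-based subset construction, per-subset
#' two-layer models with the feature-combination sweep, the four
#' evaluation protocols, and overfitting-aware final model selection
#' (higher [modelSelectionScore()] total; ties broken by
#' cross-validated AUC).
#'
#' @param study a `TagStudy` with a non-empty label table.
#' @param library a `MotifLibrary`.
#' @param properties 16 x P dinucleotide property matrix (raw; reduced
#'   internally).
#' @param config configuration list.
#' @param seed master RNG seed.
#' @param test_study optional independent `TagStudy` for the
#'   independent-testing protocol.
#' @return a `TwoLayerFit`.
#' @export
trainTwoLayer <- function(study, library, properties,
                          config = defaultRunConfig(), seed = 1L,
                          test_study = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  vlog <- function(stage) if (verbose)
    message(sprintf("[train] %s: %.1f s elapsed", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
  labels <- as.data.frame(studyLabels(study))
  if (nrow(labels) == 0) stop("study has no labelled records")
  regions <- extractRegions(studyGenome(study), studyGenes(study),
                            studyInsertions(study), labels,
                            config$distance.enhancer_offset)
  vlog("region extraction")
  reduced <- reducePropertyTable(properties, config$npc.components)
  enc <- encodeStudy(regions, library, reduced, config, labels)
  vlog("feature encoding")

  y <- enc$labels[enc$ids]
  distModel <- if (identical(config$distance.source, "config")) {
    new("DistanceLogisticModel", beta0 = config$distance.beta0,
        beta1 = config$distance.beta1, n = NA_integer_, converged = TRUE)
  } else {
    fitDistanceLogistic(enc$distance_bp[enc$ids], y)
  }

  pos <- enc$ids[y == "Ac"]
  neg <- enc$ids[y == "NAc"]
  group_size <- min(length(neg), floor(length(pos) / 2))
  if (group_size < 5)
    stop("too few records per class to build training subsets")
  if (length(neg) > group_size)
    neg <- withSeed(childSeed(seed, 3), sample(sort(neg), group_size))
  scores <- similarityScores(
    setNames(regionRecords(regions)$ups1k, enc$ids)[pos])
  vlog("similarity scores")
  subsets <- buildTrainingSubsets(pos, scores, neg, group_size)

  fit1 <- trainSubsetModel(enc, subsets$subset1, distModel, config,
                           childSeed(seed, 1), "subset1", verbose)
  fit2 <- trainSubsetModel(enc, subsets$subset2, distModel, config,
                           childSeed(seed, 2), "subset2", verbose)

  test_enc <- NULL
  if (!is.null(test_study)) {
    tlab <- as.data.frame(studyLabels(test_study))
    tregions <- extractRegions(studyGenome(test_study),
                               studyGenes(test_study),
                               studyInsertions(test_study), tlab,
                               config$distance.enhancer_offset)
    test_enc <- encodeStudy(tregions, library, reduced, config, tlab)
    vlog("independent test encoding")
  }
  proto <- protocolSuite(fit1, fit2, enc, test_enc)
  vlog("evaluation protocols")

  getRow <- function(model, protocol) {
    r <- proto[proto$model == model & proto$protocol == protocol, ]
    list(acc = r$acc, auc = r$auc, f1 = r$f1, sn = r$sn, sp = r$sp)
  }
  scores2 <- lapply(c(subset1 = "subset1", subset2 = "subset2"),
                    function(m)
    tryCatch(
      modelSelectionScore(getRow(m, "cross_validation"),
                          getRow(m, "exchange_testing"),
                          getRow(m, "self_consistency")),
      error = function(e) {
        warning(m, ": quality score undefined (", conditionMessage(e),
                "); model excluded from selection")
        list(components = c(AUC = NA_real_, Sn = NA_real_,
                            Sp = NA_real_), total = -Inf)
      }))
  totals <- vapply(scores2, `[[`, numeric(1), "total")
  cvauc <- c(fit1$cvReport$auc, fit2$cvReport$auc)
  selected <- if (abs(diff(totals)) < 1e-12) {
    if (cvauc[2] > cvauc[1]) "subset2" else "subset1"
  } else names(which.max(totals))
  final <- if (selected == "subset1") fit1 else fit2

  new("TwoLayerFit", model = final$model,
      subsetModels = list(subset1 = fit1, subset2 = fit2),
      protocol = proto, scores = scores2,
      manifest = list(seed = seed, selected = selected,
                      group_size = group_size,
                      dropped_positives = subsets$dropped,
                      n_train = length(enc$ids)))
}

#' Predict activation of genes flanking an insertion
#'
#' Scores every gene whose TLS lies within `window_bp` of the insertion
#' (closed interval, same chromosome): regions are extracted and
#' encoded, the frozen pattern masks and distance weighting applied,
#' and both classifier layers evaluated.
#'
#' @param model a trained `TwoLayerModel` (e.g. from
#'   [selectedModel()] or [loadModelBundle()]).
#' @param genome a `DNAStringSet`.
#' @param genes `GRanges` of gene models (mcols `gene_id`, `tls`).
#' @param insertion one-row insertion record (`line_id`, `chrom`,
#'   `position`).
#' @param window_bp search window either side of the insertion
#'   (default 30000, the model's reliable range).
#' @return data.frame: gene_id, chrom, tls, distance_bp,
#'   location_class, label, confidence -- empty (with a `note`
#'   attribute) when no gene is in the window.
#' @export
predictFlankingGenes <- function(model, genome, genes, insertion,
                                 window_bp = 30000L) {
  if (window_bp <= 0) stop("window_bp must be positive")
  sel <- as.character(seqnames(genes)) == insertion$chrom &
    abs(genes$tls - insertion$position) <= window_bp
  empty <- data.frame(gene_id = character(), chrom = character(),
                      tls = integer(), distance_bp = integer(),
                      location_class = character(), label = character(),
                      confidence = numeric())
  if (!any(sel)) {
    attr(empty, "note") <- "no genes within window"
    return(empty)
  }
  genes <- genes[sel]
  ins <- S4Vectors::DataFrame(line_id = insertion$line_id,
                              chrom = insertion$chrom,
                              position = insertion$position,
                              orientation =
                                insertion$orientation %||% "unknown")
  pairs <- data.frame(line_id = rep(insertion$line_id, length(genes)),
                      gene_id = genes$gene_id)
  regions <- suppressWarnings(
    extractRegions(genome, genes, ins, pairs,
                   model@config$distance.enhancer_offset))
  enc <- encodeStudy(regions, model@motifLibrary, model@propertyTable,
                     model@config)
  post <- predictTwoLayer(model, enc)
  rec <- regionRecords(regions)
  out <- data.frame(gene_id = rec$gene_id,
                    chrom = as.character(seqnames(genes)),
                    tls = genes$tls,
                    distance_bp = rec$distance_bp,
                    location_class = rec$location_class,
                    label = ifelse(post >= 0.5, "Ac", "NAc"),
                    confidence = post)
  out[order(out$distance_bp), , drop = FALSE]
}
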