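# Shared fixtures, all built in code. Expensive objects are memoised for
# the session so several test files can reuse them.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

randomDna <- function(n, seed = NULL, gc = 0.5) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                           (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# A near-indicator PWM for a consensus string (prob p on the consensus
# base), as a valid MotifLibrary matrix.
indicatorPwm <- function(consensus, p = 0.997) {
  v <- strsplit(consensus, "")[[1]]
  pwm <- matrix((1 - p) / 3, 4, length(v),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(match(v, c("A", "C", "G", "T")), seq_along(v))] <- p
  pwm
}

tinyLibrary <- function(consensi = c(m1 = "TATAAT", m2 = "GGGCCCGG")) {
  new("MotifLibrary",
      motifs = lapply(consensi, indicatorPwm),
      background = rep(0.25, 4))
}

# Worked miniature study + its extracted regions (truncation warning of
# one fixture gene is expected).
fixtureRegions <- function() memo("fixtureRegions", {
  st <- workedFixture()
  suppressWarnings(extractRegions(studyGenome(st), studyGenes(st),
                                  studyInsertions(st),
                                  as.data.frame(studyLabels(st))))
})

# Quick configuration for classifier-mechanics tests: single
# hyperparameter point, 3 CV folds.
fastConfig <- function() {
  cfg <- defaultRunConfig()
  cfg$layer1.cost_grid <- 1
  cfg$layer1.gamma_grid <- 0.05
  cfg$cv.folds <- 3
  cfg
}

# Small planted-signal study with strong signal, for fast classifier
# tests (not the acceptance-scale study).
smallSpec <- function(n = 60L)
  syntheticSpec(n_records = n, q_ac = 1, q_nac = 0,
                distance_range = c(100L, 15000L), cassette_bp = 40000L)

smallStudy <- function() memo("smallStudy", generateStudy(smallSpec(), seed = 5))

smallEncoded <- function() memo("smallEncoded", {
  st <- smallStudy()
  labels <- as.data.frame(studyLabels(st))
  rg <- suppressWarnings(extractRegions(studyGenome(st), studyGenes(st),
                                        studyInsertions(st), labels))
  lib <- syntheticMotifLibrary(smallSpec(), n_decoys = 3L, seed = 5)
  red <- reducePropertyTable(syntheticPropertyTable(seed = 5))
  encodeStudy(rg, lib, red, fastConfig(), labels)
})

smallFit <- function() memo("smallFit", {
  st <- smallStudy()
  lib <- syntheticMotifLibrary(smallSpec(), n_decoys = 3L, seed = 5)
  props <- syntheticPropertyTable(seed = 5)
  suppressWarnings(trainTwoLayer(st, lib, props, fastConfig(), seed = 5))
})

# -- acceptance-scale study (seed = the generator default) -----------------

accStudy <- function() memo("accStudy",
  generateStudy(syntheticSpec(), seed = 7))

accTestStudy <- function() memo("accTestStudy",
  generateStudy(syntheticSpec(n_records = 120L), seed = 8))

accFit <- function() memo("accFit", {
  lib <- syntheticMotifLibrary(syntheticSpec(), seed = 7)
  props <- syntheticPropertyTable(seed = 7)
  suppressWarnings(trainTwoLayer(accStudy(), lib, props,
                                 defaultRunConfig(), seed = 7,
                                 test_study = accTestStudy()))
})
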