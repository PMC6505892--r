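#' The frozen default distance-activation logistic model
#'
#' Activation probability as a function of enhancer-to-TLS distance x:
#' `pi(x) = plogis(1.448 - 7.099e-05 * x)`. These coefficients ship as
#' the default so prediction works without refitting.
#'
#' @return a `DistanceLogisticModel`.
#' @export
publishedDistanceModel <- function() {
  new("DistanceLogisticModel", beta0 = 1.448, beta1 = -7.099e-05,
      n = NA_integer_, converged = TRUE)
}

#' Fit the distance-activation logistic model
#'
#' Maximum-likelihood logistic regression of the Ac/NAc label on the
#' enhancer-to-TLS distance in bp.
#'
#' @param distances non-negative distances (bp).
#' @param labels `"Ac"`/`"NAc"` per record.
#' @return a `DistanceLogisticModel`.
#' @export
fitDistanceLogistic <- function(distances, labels) {
  if (length(distances) != length(labels)) stop("length mismatch")
  if (length(distances) < 10) stop("need at least 10 records")
  y <- labels == "Ac"
  if (all(y) || !any(y)) stop("both classes must be present")
  if (sd(distances) == 0) stop("distances are constant; degenerate design")
  fit <- suppressWarnings(glm(y ~ distances, family = binomial()))
  if (!fit$converged)
    warning("logistic fit did not converge; coefficients still returned")
  new("DistanceLogisticModel",
      beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
      n = length(y), converged = fit$converged)
}

#' Activation probability at a given distance
#'
#' @param model a `DistanceLogisticModel`.
#' @param x distance(s) in bp, >= 0.
#' @return probabilities in (0, 1), strictly decreasing in `x` when the
#'   slope is negative.
#' @export
activationProbability <- function(model, x) {
  plogis(model@beta0 + model@beta1 * x)
}

#' Weight a feature vector by an activation probability
#'
#' Elementwise scaling `v * p`. Identical sequences observed at
#' different enhancer distances thereby receive distinct encodings.
#'
#' @param v numeric feature vector (or matrix, scaled row-wise by a
#'   vector `p` of matching length).
#' @param p probability in (0, 1].
#' @export
weightFeatureVector <- function(v, p) {
  if (any(p <= 0 | p > 1)) stop("weight must be in (0, 1]")
  if (is.matrix(v)) v * p else v * p
}

#' Activation ratio per distance bin
#'
#' @param records data.frame with `distance_bp` and `label` columns.
#' @param bin_edges strictly increasing bin edges in bp; bins are
#'   `[e_i, e_{i+1})`, the last closed on the right.
#' @return data.frame: bin_lo, bin_hi, n, n_ac, ac_fraction (NA for
#'   empty bins).
#' @export
activationRatioByDistance <- function(records,
                                      bin_edges = c(0, 2000, 5000, 10000,
                                                    20000, 30000)) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  if (any(records$distance_bp < 0)) stop("negative distance")
  bins <- cut(records$distance_bp, breaks = bin_edges,
              include.lowest = TRUE, right = FALSE)
  n <- as.integer(table(bins))
  nac <- as.integer(table(bins[records$label == "Ac"]))
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1],
             n = n, n_ac = nac,
             ac_fraction = ifelse(n > 0, nac / n, NA_real_))
}

#' Association between a categorical factor and activation
#'
#' Builds the levels x (Ac, NAc) contingency table for one of the
#' insertion-geometry factors and tests independence with a chi-square
#' test (no continuity correction, the textbook statistic).
#'
#' @param records data.frame with a `label` column and the factor column.
#' @param factor one of `"gene_orientation"`, `"tdna_orientation"`,
#'   `"location_class"` (any categorical column name is accepted).
#' @return list with `table`, `statistic`, `p.value`.
#' @export
factorAssociation <- function(records, factor) {
  if (!factor %in% colnames(records)) stop("no column ", factor)
  f <- records[[factor]]
  if (length(unique(f)) < 2)
    stop("factor ", factor, " has a single level")
  tab <- table(f, factor(records$label, levels = c("Ac", "NAc")))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic),
       p.value = unname(ct$p.value))
}
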