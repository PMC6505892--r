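#' S4 classes for activation-tagging data and models
#'
#' @name activTag-classes
#' @aliases MotifLibrary-class RegionSet-class TagStudy-class
#'   DistanceLogisticModel-class TwoLayerModel-class TwoLayerFit-class
NULL

#' @rdname activTag-classes
#' @slot motifs named list of 4 x W probability matrices (rows A,C,G,T;
#'   every column sums to 1); list order fixes the motif index.
#' @slot background 0-order background base frequencies (A,C,G,T).
#' @exportClass MotifLibrary
setClass("MotifLibrary",
  representation(motifs = "list", background = "numeric"))

setValidity("MotifLibrary", function(object) {
  if (length(object@motifs) == 0) return("library contains no motifs")
  if (is.null(names(object@motifs)) || anyDuplicated(names(object@motifs)))
    return("motifs must have unique names")
  for (m in object@motifs) {
    if (!is.matrix(m) || nrow(m) != 4 || ncol(m) < 1)
      return("each motif must be a 4-row matrix with width >= 1")
    if (!identical(rownames(m), c("A", "C", "G", "T")))
      return("motif rows must be named A, C, G, T")
    if (any(abs(colSums(m) - 1) > 1e-9))
      return("every motif column must sum to 1")
  }
  if (length(object@background) != 4 ||
      abs(sum(object@background) - 1) > 1e-6)
    return("background must be 4 frequencies summing to 1")
  TRUE
})

#' Number of motifs in a library
#' @param x a `MotifLibrary`
#' @export
setMethod("length", "MotifLibrary", function(x) length(x@motifs))

#' Motif identifiers, in library order
#' @param library a `MotifLibrary`
#' @return character vector of motif ids
#' @export
motifIds <- function(library) names(library@motifs)

#' Motif widths, in library order
#' @param library a `MotifLibrary`
#' @return integer vector of widths
#' @export
motifWidths <- function(library) vapply(library@motifs, ncol, integer(1))

setMethod("show", "MotifLibrary", function(object) {
  w <- motifWidths(object)
  cat("MotifLibrary with", length(object), "motifs (widths",
      min(w), "-", max(w), ")\n")
  cat("background:", paste(sprintf("%s=%.3f", c("A", "C", "G", "T"),
                                   object@background), collapse = " "), "\n")
})

#' @rdname activTag-classes
#' @slot records a `DataFrame` with one row per (gene, insertion) record:
#'   columns gene_id, line_id, ups1k, distance_seq, middle, distance_bp,
#'   location_class.
#' @exportClass RegionSet
setClass("RegionSet", representation(records = "DFrame"))

REGIONSET_COLS <- c("gene_id", "line_id", "ups1k", "distance_seq",
                    "middle", "distance_bp", "location_class")

setValidity("RegionSet", function(object) {
  r <- object@records
  if (!all(REGIONSET_COLS %in% colnames(r)))
    return(paste("records must have columns",
                 paste(REGIONSET_COLS, collapse = ", ")))
  if (nrow(r) > 0) {
    if (any(r$distance_bp < 0)) return("distance_bp must be >= 0")
    if (!all(r$location_class %in% c("US", "DS", "IG")))
      return("location_class must be US, DS or IG")
  }
  TRUE
})

#' Region records as a DataFrame
#' @param x a `RegionSet`
#' @export
regionRecords <- function(x) x@records

#' Record identifiers of a RegionSet (line_id|gene_id)
#' @param x a `RegionSet`
#' @export
recordIds <- function(x) paste(x@records$line_id, x@records$gene_id, sep = "|")

setMethod("length", "RegionSet", function(x) nrow(x@records))

setMethod("show", "RegionSet", function(object) {
  r <- object@records
  cat("RegionSet with", nrow(r), "records\n")
  if (nrow(r) > 0) {
    cat("  distance_bp:", min(r$distance_bp), "-", max(r$distance_bp), "\n")
    cat("  location:", paste(sprintf("%s=%d", names(table(r$location_class)),
                                     as.integer(table(r$location_class))),
                             collapse = " "), "\n")
  }
})

#' @rdname activTag-classes
#' @slot genome a `DNAStringSet` of chromosome sequences.
#' @slot genes a `GRanges` of gene bodies with mcols gene_id and tls.
#' @slot insertions `DataFrame`: line_id, chrom, position, orientation.
#' @slot labels `DataFrame`: line_id, gene_id, label (Ac/NAc); may be empty.
#' @slot manifest list of generator ground truth (planted positions, true
#'   activation probabilities) or reading provenance.
#' @exportClass TagStudy
setClass("TagStudy",
  representation(genome = "DNAStringSet", genes = "GRanges",
                 insertions = "DFrame", labels = "DFrame",
                 manifest = "list"))

setValidity("TagStudy", function(object) {
  ins <- object@insertions
  if (nrow(ins) > 0) {
    if (!all(c("line_id", "chrom", "position", "orientation") %in%
             colnames(ins)))
      return("insertions need line_id, chrom, position, orientation")
    if (!all(ins$chrom %in% names(object@genome)))
      return("insertion on unknown chromosome")
  }
  if (nrow(object@labels) > 0 &&
      !all(c("line_id", "gene_id", "label") %in% colnames(object@labels)))
    return("labels need line_id, gene_id, label")
  TRUE
})

#' @describeIn TagStudy-accessors genome sequences
#' @name TagStudy-accessors
#' @param x a `TagStudy`
#' @export
studyGenome <- function(x) x@genome

#' @describeIn TagStudy-accessors gene models
#' @export
studyGenes <- function(x) x@genes

#' @describeIn TagStudy-accessors insertion events
#' @export
studyInsertions <- function(x) x@insertions

#' @describeIn TagStudy-accessors Ac/NAc label table
#' @export
studyLabels <- function(x) x@labels

setMethod("show", "TagStudy", function(object) {
  cat("TagStudy:", length(object@genome), "chromosomes (",
      sum(Biostrings::width(object@genome)), "bp ),",
      length(object@genes), "genes,",
      nrow(object@insertions), "insertions,",
      nrow(object@labels), "labelled records\n")
  if (nrow(object@labels) > 0)
    cat("  labels:", sum(object@labels$label == "Ac"), "Ac /",
        sum(object@labels$label == "NAc"), "NAc\n")
})

#' @rdname activTag-classes
#' @slot beta0 intercept of the linear predictor.
#' @slot beta1 distance slope (per bp); negative when activation decays
#'   with distance.
#' @slot n number of records used in the fit (NA for the frozen default).
#' @slot converged logical convergence flag.
#' @exportClass DistanceLogisticModel
setClass("DistanceLogisticModel",
  representation(beta0 = "numeric", beta1 = "numeric", n = "integer",
                 converged = "logical"))

setMethod("show", "DistanceLogisticModel", function(object) {
  cat(sprintf("DistanceLogisticModel: pi(x) = plogis(%.4g + %.4g * x)",
              object@beta0, object@beta1), "\n")
  if (!is.na(object@n))
    cat("  fitted on n =", object@n,
        if (object@converged) "(converged)" else "(NOT converged)", "\n")
})

#' @rdname activTag-classes
#' @slot layer1 list of 8 per-(region, feature) classifier objects.
#' @slot combo character subset of feature names used by the integrator.
#' @slot layer2 Gaussian naive-Bayes integrator (plus bookkeeping).
#' @slot distanceModel the `DistanceLogisticModel` used for weighting.
#' @slot masks per-(region, feature) pattern masks from the t-test filter.
#' @slot motifLibrary the `MotifLibrary` the model was trained with.
#' @slot propertyTable reduced 16 x k dinucleotide property matrix.
#' @slot config effective configuration list.
#' @slot manifest training metadata (seeds, subset, reports).
#' @exportClass TwoLayerModel
setClass("TwoLayerModel",
  representation(layer1 = "list", combo = "character", layer2 = "list",
                 distanceModel = "DistanceLogisticModel", masks = "list",
                 motifLibrary = "MotifLibrary", propertyTable = "matrix",
                 config = "list", manifest = "list"))

setValidity("TwoLayerModel", function(object) {
  if (!all(object@combo %in% FEATURE_NAMES))
    return("combo must be a subset of the four feature names")
  if (length(object@combo) == 0) return("combo must be non-empty")
  TRUE
})

setMethod("show", "TwoLayerModel", function(object) {
  cat("TwoLayerModel\n")
  cat("  layer 1:", length(object@layer1), "models (",
      paste(vapply(object@layer1, function(m)
        paste0(m$region, ":", m$feature), character(1)), collapse = ", "),
      ")\n")
  cat("  layer 2 combo:", paste(object@combo, collapse = "+"), "\n")
  show(object@distanceModel)
})

#' @rdname activTag-classes
#' @slot model the selected `TwoLayerModel`.
#' @slot subsetModels per-subset `TwoLayerModel`s plus their combo sweeps.
#' @slot protocol protocol table (cv / self / exchange / independent).
#' @slot scores Eq-style model-quality scores per subset model.
#' @slot manifest run metadata.
#' @exportClass TwoLayerFit
setClass("TwoLayerFit",
  representation(model = "TwoLayerModel", subsetModels = "list",
                 protocol = "data.frame", scores = "list",
                 manifest = "list"))

setMethod("show", "TwoLayerFit", function(object) {
  cat("TwoLayerFit: selected", object@manifest$selected, "model, combo",
      paste(object@model@combo, collapse = "+"), "\n")
  print(object@protocol)
})

#' Selected model of a fit
#' @param x a `TwoLayerFit`
#' @export
selectedModel <- function(x) x@model

#' Protocol table of a fit
#' @param x a `TwoLayerFit`
#' @export
protocolTable <- function(x) x@protocol
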