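#' Default run configuration
#'
#' All tunables of the pipeline with their defaults, as a flat named
#' list (dotted namespaces). See the methods vignette for the rationale
#' behind each default.
#'
#' @return named list of configuration values.
#' @export
defaultRunConfig <- function() {
  list(
    distance.beta0 = 1.448,
    distance.beta1 = -7.099e-05,
    distance.weighting = "multiply",   # multiply | append | none
    distance.source = "fit",           # fit | config
    distance.enhancer_offset = 0,
    motif.p_threshold = 1e-4,
    patterns.alpha = 0.05,
    cgi.min_len = 200,
    cgi.gc_min = 50,
    cgi.oe_min = 0.6,
    cgi.window = 100,
    cgi.shift = 1,
    npc.components = 15,
    layer1.cost_grid = 2^c(-3, 2, 7),
    layer1.gamma_grid = 2^c(-7, -2, 3),
    layer1.inner_folds = 3,
    cv.folds = 5,
    pn_ratio = 1,
    predict.window = 30000,
    bins = c(0, 2000, 5000, 10000, 20000, 30000)
  )
}

validateRunConfig <- function(cfg) {
  chk <- function(ok, key, msg)
    if (!ok) stop("config ", key, ": ", msg, call. = FALSE)
  chk(cfg$patterns.alpha > 0 && cfg$patterns.alpha < 1,
      "patterns.alpha", "must be in (0, 1)")
  chk(cfg$motif.p_threshold > 0 && cfg$motif.p_threshold <= 1,
      "motif.p_threshold", "must be in (0, 1]")
  chk(cfg$distance.weighting %in% c("multiply", "append", "none"),
      "distance.weighting", "must be multiply, append or none")
  chk(cfg$distance.source %in% c("fit", "config"),
      "distance.source", "must be fit or config")
  chk(cfg$cv.folds >= 2, "cv.folds", "must be >= 2")
  chk(cfg$layer1.inner_folds >= 2, "layer1.inner_folds", "must be >= 2")
  chk(all(cfg$layer1.cost_grid > 0), "layer1.cost_grid",
      "must be positive")
  chk(all(cfg$layer1.gamma_grid > 0), "layer1.gamma_grid",
      "must be positive")
  chk(cfg$npc.components >= 1 && cfg$npc.components <= 15,
      "npc.components", "must be in 1..15")
  chk(cfg$cgi.min_len >= cfg$cgi.window, "cgi.min_len",
      "must be >= cgi.window")
  chk(cfg$pn_ratio > 0, "pn_ratio", "must be positive")
  chk(cfg$predict.window > 0, "predict.window", "must be positive")
  chk(all(diff(cfg$bins) > 0), "bins", "must be strictly increasing")
  invisible(cfg)
}

coerceConfigValue <- function(key, value, default) {
  if (is.numeric(default)) {
    v <- suppressWarnings(as.numeric(strsplit(value, ",")[[1]]))
    if (anyNA(v)) stop("config ", key, ": not numeric: ", value,
                       call. = FALSE)
    v
  } else {
    value
  }
}

#' Load a run configuration from a flat key=value file
#'
#' Lines of the form `key = value` (dotted namespaces, `#` comments,
#' comma-separated numeric vectors). Unknown keys are rejected with a
#' closest-match suggestion; command-line overrides take precedence
#' over file values.
#'
#' @param path config file, or NULL for pure defaults.
#' @param overrides named list applied after the file.
#' @return validated configuration list.
#' @export
loadRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultRunConfig()
  apply1 <- function(key, value, from) {
    if (!key %in% names(cfg)) {
      d <- pmin(utils::adist(key, names(cfg)),
                utils::adist(key, sub(".*\\.", "", names(cfg))))
      near <- names(cfg)[d <= 2]
      stop("unknown config key ", sQuote(key), " (", from, ")",
           if (length(near)) paste0("; did you mean ",
                                    sQuote(near[1]), "?") else "",
           call. = FALSE)
    }
    cfg[[key]] <<- if (is.character(value))
      coerceConfigValue(key, value, cfg[[key]]) else value
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    for (ln in readLines(path)) {
      ln <- sub("#.*$", "", ln)
      if (!grepl("=", ln)) next
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      apply1(trimws(kv[1]), trimws(paste(kv[-1], collapse = "=")),
             "config file")
    }
  }
  for (key in names(overrides)) apply1(key, overrides[[key]], "override")
  validateRunConfig(cfg)
}
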