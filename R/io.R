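#' Read a genome assembly from FASTA
#'
#' Loads chromosome sequences, normalising to uppercase A/C/G/T/N. Headers
#' are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return a named `DNAStringSet`.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate chromosome name: ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  if (any(Biostrings::width(g) == 0))
    stop("empty sequence for chromosome: ",
         paste(names(g)[Biostrings::width(g) == 0], collapse = ", "))
  g
}

#' Fetch a genomic interval
#'
#' 1-based inclusive coordinates; minus-strand requests are
#' reverse-complemented, so the result always reads 5' to 3' on the
#' requested strand.
#'
#' @param genome a `DNAStringSet` from [readGenome()].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return a character string of length `end - start + 1`.
#' @export
fetchSeq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 1 || end > len || start > end)
    stop(sprintf("interval %d-%d out of bounds for %s (length %d)",
                 start, end, chrom, len))
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Read gene models from GFF3
#'
#' Parses gene and CDS features. The translation start site (TLS, the
#' first base of the start codon) is the minimum CDS start for plus-strand
#' genes and the maximum CDS end for minus-strand genes. CDS features are
#' matched to genes directly through `Parent`, or through one intervening
#' transcript feature.
#'
#' @param path GFF3 file with gene and CDS features.
#' @return a `GRanges` of gene bodies with mcols `gene_id` and `tls`.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  gr <- rtracklayer::import(path)
  types <- as.character(gr$type)
  genes <- gr[types == "gene"]
  if (length(genes) == 0) stop("no gene features in ", path)
  cds <- gr[types == "CDS"]
  ids <- as.character(gr$ID)
  # map any feature ID to its owning gene (<= 2 Parent hops)
  parent1 <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  toGene <- function(fid) {
    for (i in 1:3) {
      hit <- match(fid, ids)
      if (is.na(hit)) return(NA_character_)
      if (types[hit] == "gene") return(as.character(gr$ID[hit]))
      fid <- parent1[hit]
      if (is.na(fid)) return(NA_character_)
    }
    NA_character_
  }
  cdsGene <- vapply(vapply(cds$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1)),
    toGene, character(1))

  keep <- logical(length(genes))
  tls <- integer(length(genes))
  for (i in seq_along(genes)) {
    gid <- as.character(genes$ID[i])
    gcds <- cds[!is.na(cdsGene) & cdsGene == gid]
    if (length(gcds) == 0) {
      warning("gene ", gid, " has no CDS; skipped")
      next
    }
    keep[i] <- TRUE
    tls[i] <- if (as.character(strand(genes[i])) == "-")
      max(end(gcds)) else min(start(gcds))
  }
  out <- genes[keep]
  mcols(out) <- S4Vectors::DataFrame(gene_id = as.character(out$ID),
                                     tls = tls[keep])
  out
}

#' Read T-DNA insertion events from TSV
#'
#' Expects a header with columns `line_id`, `chrom`, `position` and
#' optionally `orientation` (defaulting to `"unknown"`).
#'
#' @param path TSV file.
#' @return a `DataFrame` of insertion events.
#' @export
readInsertions <- function(path) {
  if (!file.exists(path)) stop("insertion file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("line_id", "chrom", "position")
  if (!all(need %in% colnames(tab)))
    stop("insertion table must have columns ", paste(need, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$position))
  if (anyNA(pos))
    stop("non-integer position in row ",
         paste(which(is.na(pos)) + 1L, collapse = ", "),
         " of ", path)
  ori <- if ("orientation" %in% colnames(tab)) tab$orientation
         else rep("unknown", nrow(tab))
  ori[is.na(ori) | ori == ""] <- "unknown"
  if (!all(ori %in% c("+", "-", "unknown")))
    stop("orientation must be +, - or unknown")
  S4Vectors::DataFrame(line_id = tab$line_id, chrom = tab$chrom,
                       position = pos, orientation = ori)
}

#' Read a motif library in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections. Zero
#' probabilities are replaced by a 1e-4 pseudocount and each column is
#' renormalised, so log-odds scores stay finite.
#'
#' @param path MEME minimal format file.
#' @param pseudocount value substituted for exact zeros before column
#'   renormalisation.
#' @return a [`MotifLibrary`][activTag-classes].
#' @export
readMotifLibrary <- function(path, pseudocount = 1e-4) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgAt <- grep("^Background letter frequencies", lines)
  if (length(bgAt)) {
    toks <- strsplit(trimws(lines[bgAt[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    names(vals) <- toks[c(TRUE, FALSE)]
    if (!anyNA(vals) && all(c("A", "C", "G", "T") %in% names(vals)))
      background <- vals[c("A", "C", "G", "T")] / sum(vals)
  }
  motifAt <- grep("^MOTIF\\b", lines)
  if (length(motifAt) == 0) stop("no motifs found in ", path)
  motifs <- list()
  for (m in motifAt) {
    id <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    hdr <- m + grep("letter-probability matrix",
                    lines[seq(m + 1, min(m + 10, length(lines)))])[1]
    if (is.na(hdr)) stop("motif ", id, ": no letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    if (is.na(w) || w < 1) stop("motif ", id, ": invalid width")
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    if (anyNA(mat)) stop("motif ", id, ": malformed probability row")
    pwm <- t(mat)                       # 4 x w
    rownames(pwm) <- c("A", "C", "G", "T")
    bad <- abs(colSums(pwm) - 1) > 0.01
    if (any(bad))
      stop("motif ", id, ": column ", which(bad)[1],
           " does not sum to 1 (tolerance 0.01)")
    pwm[pwm == 0] <- pseudocount
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
    motifs[[id]] <- pwm
  }
  new("MotifLibrary", motifs = motifs, background = unname(background))
}

#' Write a motif library in MEME minimal format
#'
#' @param library a `MotifLibrary`.
#' @param path output file.
#' @export
writeMemeMotifs <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", c("A", "C", "G", "T"),
                             library@background), collapse = " "), ""),
             con)
  for (id in motifIds(library)) {
    pwm <- library@motifs[[id]]
    writeLines(c(paste("MOTIF", id),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                         ncol(pwm))), con)
    for (j in seq_len(ncol(pwm)))
      writeLines(paste(sprintf("%.6f", pwm[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a dinucleotide physicochemical property table
#'
#' First column names the dinucleotide (AA..TT, all 16 required);
#' remaining columns are named numeric properties.
#'
#' @param path TSV file.
#' @return a 16 x P numeric matrix with dinucleotide rownames.
#' @export
readPropertyTable <- function(path) {
  if (!file.exists(path)) stop("property table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  dinucs <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 2)
  rn <- toupper(tab[[1]])
  if (!setequal(rn, dinucs) || nrow(tab) != 16)
    stop("property table must have exactly the 16 dinucleotides AA..TT")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat))
    stop("property values must be numeric and complete")
  rownames(mat) <- rn
  mat[dinucs, , drop = FALSE]
}

#' Save a trained model bundle
#'
#' Writes a directory containing `manifest.json` (format version, seeds,
#' selected feature combination, pattern-mask summary, motif-library
#' checksum) plus serialized model payloads. [loadModelBundle()] restores
#' a model that reproduces identical predictions.
#'
#' @param model a `TwoLayerModel`.
#' @param dir output directory (created if needed).
#' @export
saveModelBundle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  motifFile <- file.path(dir, "motifs.meme")
  writeMemeMotifs(model@motifLibrary, motifFile)
  saveRDS(model, file.path(dir, "model.rds"))
  for (key in names(model@masks)) {
    m <- model@masks[[key]]
    write.table(data.frame(pattern = names(m$p), p_value = m$p,
                           selected = m$mask),
                file.path(dir, paste0("mask-", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    format = "activTag-bundle-1",
    package_version = as.character(utils::packageVersion("activTag")),
    combo = model@combo,
    n_layer1 = length(model@layer1),
    masks = lapply(model@masks, function(m)
      list(n_selected = sum(m$mask), n_total = length(m$mask))),
    motif_md5 = unname(tools::md5sum(motifFile)),
    seed = model@manifest$seed,
    trained = model@manifest$subset %||% NA
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load a trained model bundle
#'
#' @param dir directory written by [saveModelBundle()].
#' @return a `TwoLayerModel`.
#' @export
loadModelBundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a model bundle (no manifest.json): ", dir)
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$format, "activTag-bundle-1"))
    stop("unsupported bundle format: ", manifest$format)
  model <- readRDS(file.path(dir, "model.rds"))
  md5 <- unname(tools::md5sum(file.path(dir, "motifs.meme")))
  if (!identical(md5, manifest$motif_md5))
    stop("motif library checksum mismatch; bundle is corrupt")
  validObject(model)
  model
}
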