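#' Extract the 1 kb promoter upstream of the translation start site
#'
#' Returns the bases immediately 5' of the TLS on the gene's coding
#' strand; the TLS base itself is excluded. Truncated with a warning when
#' the chromosome end leaves fewer than `size` bases.
#'
#' @param genome a `DNAStringSet`.
#' @param gene a single-row `GRanges` with mcols `gene_id` and `tls`.
#' @param size upstream window, default 1000 bp.
#' @return a character string of length <= `size`, 5'->3' on the coding
#'   strand.
#' @export
extractUps1k <- function(genome, gene, size = 1000L) {
  stopifnot(length(gene) == 1)
  chrom <- as.character(seqnames(gene))
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  tls <- gene$tls
  if (as.character(strand(gene)) == "-") {
    if (tls >= len)
      stop("gene ", gene$gene_id, ": no upstream sequence (TLS at edge)")
    s <- tls + 1L
    e <- min(len, tls + size)
    if (e - s + 1L < size)
      warning("gene ", gene$gene_id, ": upstream window truncated to ",
              e - s + 1L, " nt")
    fetchSeq(genome, chrom, s, e, "-")
  } else {
    if (tls <= 1L)
      stop("gene ", gene$gene_id, ": no upstream sequence (TLS at edge)")
    s <- max(1L, tls - size)
    e <- tls - 1L
    if (e - s + 1L < size)
      warning("gene ", gene$gene_id, ": upstream window truncated to ",
              e - s + 1L, " nt")
    fetchSeq(genome, chrom, s, e, "+")
  }
}

#' Enhancer-to-gene distance in bp
#'
#' Absolute distance from the insertion junction (standing in for the
#' 35S enhancer position, optionally shifted by a fixed offset) to the
#' gene's translation start site.
#'
#' @param gene single-row `GRanges` with mcol `tls`.
#' @param insertion one-row insertion record (`chrom`, `position`).
#' @param enhancer_offset fixed signed offset of the enhancer tetramer
#'   from the recorded junction, default 0.
#' @return non-negative integer distance.
#' @export
computeDistance <- function(gene, insertion, enhancer_offset = 0L) {
  if (as.character(seqnames(gene)) != insertion$chrom)
    stop("gene and insertion are on different chromosomes")
  abs((insertion$position + enhancer_offset) - gene$tls)
}

#' Extract the enhancer-to-start-codon interval (DISTANCE region)
#'
#' The genomic sequence between the TLS and the insertion position,
#' inclusive of both endpoints, reported 5'->3' on the gene's coding
#' strand. Its length is `distance + 1`.
#'
#' @inheritParams computeDistance
#' @param genome a `DNAStringSet`.
#' @export
extractDistanceSeq <- function(genome, gene, insertion,
                               enhancer_offset = 0L) {
  d <- computeDistance(gene, insertion, enhancer_offset)
  if (d < 1) stop("insertion coincides with the TLS; empty interval")
  pos <- insertion$position + enhancer_offset
  fetchSeq(genome, as.character(seqnames(gene)),
           min(gene$tls, pos), max(gene$tls, pos),
           as.character(strand(gene)))
}

#' Extract the central window of the DISTANCE region (MIDDLE)
#'
#' 150 bp either side of the central nucleotide (301 bp total when the
#' interval allows; the whole interval otherwise). For even lengths the
#' centre is `ceiling(L/2)`.
#'
#' @param distance_seq the DISTANCE region string.
#' @param flank half-window, default 150.
#' @export
extractMiddle <- function(distance_seq, flank = 150L) {
  L <- nchar(distance_seq)
  if (L < 1) stop("empty DISTANCE sequence")
  ctr <- ceiling(L / 2)
  substr(distance_seq, max(1, ctr - flank), min(L, ctr + flank))
}

#' Classify an insertion's location relative to a gene
#'
#' `IG` (intragenic) when the position falls inside the gene body;
#' otherwise `US`/`DS` depending on which side of the gene the insertion
#' sits on the coding strand (5' or 3').
#'
#' @inheritParams computeDistance
#' @return one of `"US"`, `"DS"`, `"IG"`.
#' @export
classifyLocation <- function(gene, insertion) {
  if (as.character(seqnames(gene)) != insertion$chrom)
    stop("gene and insertion are on different chromosomes")
  pos <- insertion$position
  if (pos >= start(gene) && pos <= end(gene)) return("IG")
  minus <- as.character(strand(gene)) == "-"
  if (pos < start(gene)) {
    if (minus) "DS" else "US"
  } else {
    if (minus) "US" else "DS"
  }
}

#' Extract region sequences for a batch of (gene, insertion) records
#'
#' For every row of `pairs` (columns `line_id`, `gene_id`) the three
#' regions are extracted and bundled in a [`RegionSet`][activTag-classes].
#' Records whose insertion coincides with the TLS get empty DISTANCE and
#' MIDDLE strings and are flagged in a warning.
#'
#' @param genome a `DNAStringSet`.
#' @param genes `GRanges` of gene models (mcols `gene_id`, `tls`).
#' @param insertions insertion table (`line_id`, `chrom`, `position`).
#' @param pairs data.frame-like with `line_id` and `gene_id`.
#' @param enhancer_offset see [computeDistance()].
#' @export
extractRegions <- function(genome, genes, insertions, pairs,
                           enhancer_offset = 0L) {
  gid <- match(pairs$gene_id, genes$gene_id)
  lid <- match(pairs$line_id, insertions$line_id)
  if (anyNA(gid)) stop("unknown gene_id: ",
                       paste(unique(pairs$gene_id[is.na(gid)]), collapse = ", "))
  if (anyNA(lid)) stop("unknown line_id: ",
                       paste(unique(pairs$line_id[is.na(lid)]), collapse = ", "))
  n <- nrow(pairs)
  ups <- dst <- mid <- character(n)
  dbp <- integer(n)
  loc <- character(n)
  zero <- 0L
  for (i in seq_len(n)) {
    gene <- genes[gid[i]]
    ins <- insertions[lid[i], ]
    ups[i] <- extractUps1k(genome, gene)
    dbp[i] <- computeDistance(gene, ins, enhancer_offset)
    loc[i] <- classifyLocation(gene, ins)
    if (dbp[i] >= 1) {
      dst[i] <- extractDistanceSeq(genome, gene, ins, enhancer_offset)
      mid[i] <- extractMiddle(dst[i])
    } else {
      zero <- zero + 1L
    }
  }
  if (zero > 0)
    warning(zero, " record(s) with insertion at the TLS have empty ",
            "DISTANCE/MIDDLE regions")
  new("RegionSet", records = S4Vectors::DataFrame(
    gene_id = pairs$gene_id, line_id = pairs$line_id,
    ups1k = ups, distance_seq = dst, middle = mid,
    distance_bp = dbp, location_class = loc))
}
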