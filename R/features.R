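#' Names of the k-mer feature columns (k = 3..6; 5440 columns)
#' @param ks k-mer sizes.
#' @export
ngramNames <- function(ks = 3:6) {
  unlist(lapply(ks, function(k)
    paste0(k, "mer:", Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))),
    use.names = FALSE)
}

#' Count overlapping k-mers (k = 3..6)
#'
#' Raw overlapping-window counts over the 64 + 256 + 1024 + 4096 = 5440
#' A/C/G/T k-mers; windows containing N contribute nothing.
#'
#' @param seq nucleotide string over A,C,G,T,N (empty allowed).
#' @param ks k-mer sizes, default 3:6.
#' @return named integer vector of length 5440 (for the default `ks`).
#' @export
countNgrams <- function(seq, ks = 3:6) {
  d <- if (nchar(seq) > 0) Biostrings::DNAString(seq) else NULL
  out <- lapply(ks, function(k) {
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    if (is.null(d) || nchar(seq) < k) {
      setNames(integer(length(kmers)), kmers)
    } else {
      Biostrings::oligonucleotideFrequency(d, width = k)
    }
  })
  v <- unlist(out, use.names = FALSE)
  names(v) <- ngramNames(ks)
  v
}

# -- PWM scanning with exact null p-values ---------------------------------

# Log2 odds of a PWM against a 0-order background.
pwmLogOdds <- function(pwm, background) {
  log2(pwm / background)
}

# Discretize a log-odds matrix onto an integer lattice and compute the
# exact null distribution of the window score under the background, by
# dynamic programming over columns (the FIMO construction). Returns the
# integer column offsets and the upper-tail probability at each lattice
# score.
pwmScoreDistribution <- function(lo, background, nbins = 8192L) {
  w <- ncol(lo)
  cmin <- apply(lo, 2, min)
  rng <- sum(apply(lo, 2, max)) - sum(cmin)
  eps <- if (rng > 0) rng / (nbins - 1) else 1
  ints <- round(sweep(lo, 2, cmin) / eps)
  storage.mode(ints) <- "integer"
  maxtot <- sum(apply(ints, 2, max))
  pmf <- c(1, numeric(maxtot))
  for (j in seq_len(w)) {
    upd <- numeric(maxtot + 1L)
    for (a in 1:4) {
      k <- ints[a, j]
      idx <- seq_len(maxtot + 1L - k)
      upd[idx + k] <- upd[idx + k] + background[a] * pmf[idx]
    }
    pmf <- upd
  }
  list(ints = ints, tail = rev(cumsum(rev(pmf))))
}

# Score one strand of a sequence with a log-odds matrix; returns real and
# lattice scores per window start (NA where the window contains N).
scanStrand <- function(codes, lo, ints) {
  w <- ncol(lo)
  L <- length(codes)
  n <- L - w + 1L
  if (n < 1) return(NULL)
  sc <- numeric(n)
  isc <- integer(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    sc <- sc + lo[cbind(cj, j)]
    isc <- isc + ints[cbind(cj, j)]
  }
  list(score = sc, iscore = isc)
}

#' Scan a sequence for motif occurrences
#'
#' Both strands are scored with log2-odds against the library's 0-order
#' background; per-window p-values come from the exact distribution of
#' the (score-discretized) PWM score under that background, computed by
#' dynamic programming. Occurrences with `pvalue <= p_threshold` are
#' returned sorted by start position.
#'
#' @param seq nucleotide string.
#' @param library a `MotifLibrary`.
#' @param p_threshold occurrence p-value cutoff (default 1e-4).
#' @return data.frame with columns motif_id, start, end, strand, score,
#'   pvalue.
#' @export
scanMotifs <- function(seq, library, p_threshold = 1e-4) {
  L <- nchar(seq)
  empty <- data.frame(motif_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  if (L == 0) return(empty)
  fwd <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  rev <- match(strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))), "")[[1]], c("A", "C", "G", "T"))
  bg <- library@background
  hits <- list()
  for (id in motifIds(library)) {
    pwm <- library@motifs[[id]]
    w <- ncol(pwm)
    if (w > L) next
    lo <- pwmLogOdds(pwm, bg)
    dist <- pwmScoreDistribution(lo, bg)
    for (str in c("+", "-")) {
      codes <- if (str == "+") fwd else rev
      sres <- scanStrand(codes, lo, dist$ints)
      if (is.null(sres)) next
      ok <- which(!is.na(sres$iscore))
      if (length(ok) == 0) next
      pv <- dist$tail[sres$iscore[ok] + 1L]
      keep <- ok[pv <= p_threshold]
      if (length(keep) == 0) next
      st <- if (str == "+") keep else L - (keep + w - 1L) + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = id, start = st, end = st + w - 1L, strand = str,
        score = sres$score[keep],
        pvalue = dist$tail[sres$iscore[keep] + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) return(empty)
  out <- do.call(rbind, hits)
  out[order(out$start, out$motif_id, out$strand), , drop = FALSE]
}

#' Motif channel names (6 per motif, library order)
#' @param library a `MotifLibrary`.
#' @export
motifChannelNames <- function(library) {
  ch <- c("number", "conserve", "pos_ori", "neg_ori", "density", "dis_tls")
  unlist(lapply(motifIds(library), function(id) paste0(id, ":", ch)),
         use.names = FALSE)
}

#' Encode motif occurrences as the six-channel motif feature vector
#'
#' Per motif: occurrence count; mean alignment score; fractions of hits
#' on the plus and minus strand; density = width x count / span of the
#' occupied interval; and the mean |TLS - occurrence start| distance.
#' Motifs without occurrences contribute six zeros.
#'
#' @param occurrences data.frame from [scanMotifs()] (one sequence).
#' @param library the `MotifLibrary` that produced them.
#' @param seq_len length of the scanned sequence.
#' @param tls_offset position of the TLS relative to the scanned
#'   sequence; for the upstream promoter this is `seq_len + 1`.
#' @return named numeric vector of length `6 * length(library)`.
#' @export
encodeMotifs <- function(occurrences, library, seq_len,
                         tls_offset = seq_len + 1L) {
  ids <- motifIds(library)
  widths <- motifWidths(library)
  out <- numeric(6L * length(ids))
  if (nrow(occurrences) > 0) {
    byMotif <- split(occurrences, factor(occurrences$motif_id, levels = ids))
    for (i in seq_along(ids)) {
      occ <- byMotif[[i]]
      if (is.null(occ) || nrow(occ) == 0) next
      n <- nrow(occ)
      span <- max(occ$end) - min(occ$start) + 1L
      out[(i - 1L) * 6L + 1:6] <- c(
        n,
        mean(occ$score),
        sum(occ$strand == "+") / n,
        sum(occ$strand == "-") / n,
        widths[i] * n / span,
        mean(abs(tls_offset - occ$start)))
    }
  }
  names(out) <- motifChannelNames(library)
  out
}

#' Reduce a dinucleotide property table by PCA
#'
#' Columns (properties) are centred and scaled to unit variance, and the
#' 16 dinucleotides are projected onto the top `k` principal components.
#' Sign convention: each component's largest-magnitude loading is
#' positive, so the reduction is deterministic.
#'
#' @param table 16 x P numeric matrix (rownames AA..TT), P >= k.
#' @param k number of components, default 15 (the maximum for 16
#'   centred observations).
#' @return 16 x k score matrix with columns `pc1..pck`.
#' @export
reducePropertyTable <- function(table, k = 15L) {
  if (nrow(table) != 16) stop("property table must have 16 rows")
  if (ncol(table) < k)
    stop("need at least ", k, " properties, got ", ncol(table))
  sds <- apply(table, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant property column(s) dropped")
    table <- table[, sds > 0, drop = FALSE]
  }
  p <- prcomp(table, center = TRUE, scale. = TRUE)
  nz <- sum(p$sdev > p$sdev[1] * 1e-8)
  if (nz < k)
    stop("property table has rank ", nz, " after scaling; cannot extract ",
         k, " components")
  scores <- p$x[, seq_len(k), drop = FALSE]
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    s <- sign(l[which.max(abs(l))])
    if (s == 0) 1 else s
  }, numeric(1))
  scores <- sweep(scores, 2, flip, "*")
  colnames(scores) <- paste0("pc", seq_len(k))
  rownames(scores) <- rownames(table)
  scores
}

#' Encode a sequence with reduced dinucleotide properties (NPC)
#'
#' Entry (di, j) = count(di) x reduced(di, j) / (number of valid
#' dinucleotide windows). Windows containing N are skipped; for a clean
#' sequence the denominator is `nchar(seq) - 1`.
#'
#' @param seq nucleotide string of length >= 2.
#' @param reduced 16 x k matrix from [reducePropertyTable()].
#' @return named numeric vector of length `16 * k`.
#' @export
encodeNpc <- function(seq, reduced) {
  if (nchar(seq) < 2) stop("sequence shorter than 2 nt")
  counts <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(seq))
  denom <- sum(counts)
  vals <- if (denom > 0) {
    sweep(reduced, 1, counts[rownames(reduced)], "*") / denom
  } else {
    reduced * 0
  }
  v <- as.vector(t(vals))    # dinucleotide-major: AA:pc1..pck, AC:pc1..
  names(v) <- as.vector(t(outer(rownames(reduced), colnames(reduced),
                                function(d, p) paste0("npc:", d, ":", p))))
  v
}

#' Detect CpG islands by sliding-window screening
#'
#' Windows of `window` nt (stride `shift`) pass when GC% >= `gc_min` and
#' the length-corrected observed/expected CpG ratio
#' `#CG * window / (#C * #G)` >= `oe_min`. Overlapping or adjacent
#' passing windows are merged; merged segments shorter than `min_len`
#' are discarded. Reported islands carry whole-island GC% and obs/exp.
#'
#' @param seq nucleotide string.
#' @param min_len minimum island length (default 200).
#' @param gc_min GC percentage threshold (default 50).
#' @param oe_min observed/expected CpG threshold (default 0.6).
#' @param window window size (default 100).
#' @param shift window stride (default 1).
#' @return data.frame: start, end, length, gc_percent, obs_exp.
#' @export
detectCpgIslands <- function(seq, min_len = 200L, gc_min = 50,
                             oe_min = 0.6, window = 100L, shift = 1L) {
  empty <- data.frame(start = integer(), end = integer(),
                      length = integer(), gc_percent = numeric(),
                      obs_exp = numeric())
  L <- nchar(seq)
  if (L < window) return(empty)
  v <- strsplit(toupper(seq), "")[[1]]
  isC <- as.integer(v == "C")
  isG <- as.integer(v == "G")
  cgAt <- c(as.integer(v[-L] == "C" & v[-1] == "G"), 0L)
  cumC <- c(0L, cumsum(isC))
  cumG <- c(0L, cumsum(isG))
  cumCG <- c(0L, cumsum(cgAt))
  starts <- seq.int(1L, L - window + 1L, by = shift)
  nC <- cumC[starts + window] - cumC[starts]
  nG <- cumG[starts + window] - cumG[starts]
  nCG <- cumCG[starts + window - 1L] - cumCG[starts]
  gc <- 100 * (nC + nG) / window
  oe <- ifelse(nC * nG > 0, nCG * window / (nC * nG), 0)
  pass <- starts[gc >= gc_min & oe >= oe_min]
  if (length(pass) == 0) return(empty)
  brk <- c(0L, which(diff(pass) > window), length(pass))
  isl <- lapply(seq_len(length(brk) - 1L), function(i) {
    s <- pass[brk[i] + 1L]
    e <- pass[brk[i + 1L]] + window - 1L
    c(s, e)
  })
  out <- do.call(rbind, isl)
  len <- out[, 2] - out[, 1] + 1L
  keep <- len >= min_len
  if (!any(keep)) return(empty)
  out <- out[keep, , drop = FALSE]
  len <- len[keep]
  gcI <- oeI <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    s <- out[i, 1]; e <- out[i, 2]
    c_ <- cumC[e + 1L] - cumC[s]
    g_ <- cumG[e + 1L] - cumG[s]
    cg_ <- cumCG[e] - cumCG[s]
    gcI[i] <- 100 * (c_ + g_) / (e - s + 1L)
    oeI[i] <- if (c_ * g_ > 0) cg_ * (e - s + 1L) / (c_ * g_) else 0
  }
  data.frame(start = out[, 1], end = out[, 2], length = len,
             gc_percent = gcI, obs_exp = oeI)
}

#' CpG-island feature channel names
#' @export
cgiChannelNames <- function() {
  paste0("cgi:", c("number", "length_ratio", "dis", "cg_ratio", "oe"))
}

#' Encode detected CpG islands as the five-channel CGI feature vector
#'
#' Channels: island count; total island length / promoter length;
#' |TLS - start of the island nearest the TLS|; mean per-island CpG
#' percentage (100 x #CG / (island length - 1)); and the plain
#' observed-to-expected ratio #CG / (#C x #G) pooled over islands --
#' deliberately without the length factor used during detection. All
#' zeros when no island was detected.
#'
#' @param islands data.frame from [detectCpgIslands()].
#' @param seq the scanned (promoter) sequence.
#' @param promoter_len its length.
#' @param tls_offset TLS position relative to the sequence
#'   (`promoter_len + 1` for the upstream promoter).
#' @return named numeric vector of length 5.
#' @export
encodeCgi <- function(islands, seq, promoter_len = nchar(seq),
                      tls_offset = promoter_len + 1L) {
  out <- numeric(5)
  names(out) <- cgiChannelNames()
  n <- nrow(islands)
  if (n == 0) return(out)
  v <- strsplit(toupper(seq), "")[[1]]
  cgPct <- numeric(n)
  totCG <- totC <- totG <- 0
  for (i in seq_len(n)) {
    s <- islands$start[i]; e <- islands$end[i]
    sub <- v[s:e]
    nC <- sum(sub == "C"); nG <- sum(sub == "G")
    nCG <- sum(sub[-length(sub)] == "C" & sub[-1] == "G")
    cgPct[i] <- 100 * nCG / (e - s)
    totCG <- totCG + nCG; totC <- totC + nC; totG <- totG + nG
  }
  nearest <- which.min(abs(tls_offset - islands$start))
  out[1] <- n
  out[2] <- sum(islands$length) / promoter_len
  out[3] <- abs(tls_offset - islands$start[nearest])
  out[4] <- mean(cgPct)
  out[5] <- if (totC * totG > 0) totCG / (totC * totG) else 0
  out
}

#' Select class-discriminating pattern columns by Welch t-test
#'
#' Per-column two-sided Welch two-sample t-test of Ac vs NAc record
#' counts; columns with `p < alpha` are selected. Columns with zero
#' variance in both classes are excluded with p recorded as 1.
#'
#' @param counts records x patterns numeric matrix.
#' @param labels `"Ac"`/`"NAc"` per record (each class needs >= 2).
#' @param alpha selection threshold, default 0.05.
#' @return list with `mask` (logical), `p` (numeric) and `alpha`; both
#'   vectors named by pattern column.
#' @export
selectPatterns <- function(counts, labels, alpha = 0.05) {
  y <- labels == "Ac"
  n1 <- sum(y); n2 <- sum(!y)
  if (n1 < 2 || n2 < 2)
    stop("each class needs at least 2 records (got ", n1, " Ac, ",
         n2, " NAc)")
  X1 <- counts[y, , drop = FALSE]
  X2 <- counts[!y, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X2^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  degenerate <- (v1 + v2) == 0
  p[degenerate | !is.finite(p)] <- 1
  mask <- p < alpha
  names(p) <- names(mask) <- colnames(counts)
  list(mask = mask, p = p, alpha = alpha)
}
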