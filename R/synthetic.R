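#' Specification of a synthetic activation-tagging study
#'
#' Defaults describe the study conditions the package is tested under:
#' one gene and one T-DNA insertion per record, enhancer-to-TLS
#' distances uniform on 100-30000 bp, activation labels drawn from the
#' frozen distance logistic, a short consensus motif planted into the
#' promoter and MIDDLE regions of activated records more often than
#' non-activated ones, and a class-independent CpG-island rate (so the
#' CGI feature carries no signal unless configured to).
#'
#' @param n_records number of (gene, insertion, label) records.
#' @param n_chromosomes chromosomes to spread records over.
#' @param cassette_bp genomic span reserved per record; must exceed
#'   `2 * max(distance_range) + max gene length`.
#' @param gc_fraction background GC content (0.43, rice-like euchromatin).
#' @param gene_length_range min/max gene body length (bp).
#' @param distance_range min/max enhancer-to-TLS distance (bp).
#' @param ig_prob probability an insertion is intragenic instead of
#'   flanking.
#' @param beta0,beta1 coefficients of the label-generating logistic.
#' @param planted_motifs named character vector of consensus strings
#'   planted as activation signal.
#' @param q_ac,q_nac per-motif, per-region planting probability for
#'   activated / non-activated records (`q_ac > q_nac` gives learnable
#'   signal).
#' @param cpg_rate_ac,cpg_rate_nac probability of planting a CpG-rich
#'   block into the promoter, per class.
#' @param seed default RNG seed for [generateStudy()].
#' @return a spec list.
#' @export
syntheticSpec <- function(n_records = 360L, n_chromosomes = 2L,
                          cassette_bp = 70000L, gc_fraction = 0.43,
                          gene_length_range = c(1000L, 3000L),
                          distance_range = c(100L, 30000L),
                          ig_prob = 0.05,
                          beta0 = 1.448, beta1 = -7.099e-05,
                          planted_motifs = c(act1 = "TGACGTCAGC",
                                             act2 = "CCACGTGTCA"),
                          q_ac = 0.8, q_nac = 0.2,
                          cpg_rate_ac = 0.15, cpg_rate_nac = 0.15,
                          seed = 7L) {
  stopifnot(gc_fraction > 0, gc_fraction < 1,
            q_ac >= 0, q_ac <= 1, q_nac >= 0, q_nac <= 1,
            distance_range[1] >= 1,
            cassette_bp > 2 * distance_range[2] +
              gene_length_range[2] + 2000)
  as.list(environment())
}

randomBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Fast random sequence: draw integer codes and convert once via UTF-8
# code points (A=65, C=67, G=71, T=84).
randomSeq <- function(n, gc) {
  codes <- sample.int(4L, n, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2,
                               (1 - gc) / 2))
  intToUtf8(c(65L, 67L, 71L, 84L)[codes])
}

#' Generate a random genome at a given GC fraction
#'
#' @param spec a [syntheticSpec()].
#' @param seed RNG seed.
#' @return a `DNAStringSet`; bases i.i.d. with the configured GC.
#' @export
generateGenome <- function(spec, seed = spec$seed) {
  perChrom <- ceiling(spec$n_records / spec$n_chromosomes)
  len <- perChrom * spec$cassette_bp
  withSeed(childSeed(seed, 1), {
    seqs <- vapply(seq_len(spec$n_chromosomes), function(i)
      randomSeq(len, spec$gc_fraction), character(1))
  })
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(spec$n_chromosomes))
  g
}

#' Place genes and matched T-DNA insertions
#'
#' Each record occupies its own genomic cassette, so gene bodies never
#' overlap. Strands are random; the insertion sits at a distance drawn
#' uniformly from `distance_range` on a random side of the TLS
#' (upstream/downstream on the genome), or inside the gene body with
#' probability `ig_prob`.
#'
#' @param spec a [syntheticSpec()].
#' @param genome from [generateGenome()].
#' @param seed RNG seed.
#' @return list: `genes` (`GRanges` with gene_id, tls), `insertions`
#'   (`DataFrame`), `pairs` (line_id/gene_id records).
#' @export
generateGenesAndInsertions <- function(spec, genome, seed = spec$seed) {
  n <- spec$n_records
  perChrom <- ceiling(n / spec$n_chromosomes)
  chromOf <- ((seq_len(n) - 1L) %/% perChrom) + 1L
  slotOf <- ((seq_len(n) - 1L) %% perChrom)
  withSeed(childSeed(seed, 2), {
    glen <- sample(spec$gene_length_range[1]:spec$gene_length_range[2],
                   n, replace = TRUE)
    strd <- sample(c("+", "-"), n, replace = TRUE)
    dist <- sample(spec$distance_range[1]:spec$distance_range[2],
                   n, replace = TRUE)
    side <- sample(c(-1L, 1L), n, replace = TRUE)
    ig <- runif(n) < spec$ig_prob
    igat <- integer(n)
    for (i in which(ig)) igat[i] <- sample.int(glen[i], 1L)
  })
  offset <- spec$distance_range[2] + 1500L   # room for distance + promoter
  gstart <- slotOf * spec$cassette_bp + offset
  gend <- gstart + glen - 1L
  tls <- ifelse(strd == "+", gstart, gend)
  pos <- ifelse(ig, gstart + igat - 1L, tls + side * dist)
  genes <- GenomicRanges::GRanges(
    seqnames = paste0("chr", chromOf),
    ranges = IRanges::IRanges(gstart, gend), strand = strd,
    gene_id = sprintf("s%dg%04d", seed, seq_len(n)),
    tls = as.integer(tls))
  ins <- S4Vectors::DataFrame(
    line_id = sprintf("s%dL%04d", seed, seq_len(n)),
    chrom = paste0("chr", chromOf), position = as.integer(pos),
    orientation = withSeed(childSeed(seed, 4),
                           sample(c("+", "-"), n, replace = TRUE)))
  list(genes = genes, insertions = ins,
       pairs = data.frame(line_id = ins$line_id,
                          gene_id = genes$gene_id))
}

# Genomic coordinates and strand-adjusted content for overwriting
# `motif` into a region so that the *extracted* (coding-strand) region
# shows the motif at 1-based `offset`.
plantCoords <- function(region_start, region_end, minus, offset, motif) {
  w <- nchar(motif)
  if (offset < 1 || offset + w - 1 > region_end - region_start + 1)
    stop("planted motif does not fit in the region")
  if (minus) {
    s <- region_end - offset - w + 2L
    content <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
  } else {
    s <- region_start + offset - 1L
    content <- motif
  }
  list(start = s, end = s + w - 1L, content = content)
}

#' Draw labels from the distance logistic and plant sequence signal
#'
#' Labels are Bernoulli with success probability
#' `plogis(beta0 + beta1 * distance)`. Each planted consensus motif is
#' then written into the promoter (UPS1K) and MIDDLE regions of each
#' record with probability `q_ac` (activated) or `q_nac`
#' (non-activated), at recorded, verifiable positions; CpG-rich blocks
#' are planted into promoters at the per-class rates.
#'
#' @param spec a [syntheticSpec()].
#' @param genome `DNAStringSet` (modified copy returned).
#' @param layout from [generateGenesAndInsertions()].
#' @param seed RNG seed.
#' @return list: `genome` (with planted signal), `labels`
#'   (`DataFrame`), `manifest` (planted positions and true
#'   probabilities).
#' @export
assignLabelsAndPlantSignal <- function(spec, genome, layout,
                                       seed = spec$seed) {
  genes <- layout$genes
  ins <- layout$insertions
  n <- length(genes)
  dist <- abs(ins$position - genes$tls)
  truePi <- plogis(spec$beta0 + spec$beta1 * dist)
  planted <- list()
  edits <- list()
  for (m in spec$planted_motifs)
    if (nchar(m) > 1000)
      stop("planted motif longer than the promoter region")

  withSeed(childSeed(seed, 5), {
    lab <- ifelse(runif(n) < truePi, "Ac", "NAc")
    for (i in seq_len(n)) {
      q <- if (lab[i] == "Ac") spec$q_ac else spec$q_nac
      cpg <- if (lab[i] == "Ac") spec$cpg_rate_ac else spec$cpg_rate_nac
      ch <- ins$chrom[i]
      minus <- as.character(strand(genes[i])) == "-"
      tls <- genes$tls[i]
      # promoter region in genomic coordinates
      if (minus) {
        us <- c(tls + 1L, tls + 1000L)
      } else {
        us <- c(tls - 1000L, tls - 1L)
      }
      # central window of the enhancer-to-TLS interval
      dlo <- min(tls, ins$position[i]); dhi <- max(tls, ins$position[i])
      L <- dhi - dlo + 1L
      ctr <- ceiling(L / 2)
      midx <- c(max(1L, ctr - 150L), min(L, ctr + 150L))
      mid <- if (minus) c(dhi - midx[2] + 1L, dhi - midx[1] + 1L)
             else c(dlo + midx[1] - 1L, dlo + midx[2] - 1L)
      # CpG block first: later motif plants may overwrite it, but a
      # recorded motif position is never overwritten afterwards
      if (runif(1) < cpg) {
        bv <- rep(c("C", "G"), 125)
        bv[sample.int(250L, 12L)] <- sample(c("A", "T"), 12L,
                                            replace = TRUE)
        block <- paste(bv, collapse = "")
        off <- sample.int(1000L - 250L + 1L, 1L)
        pc <- plantCoords(us[1], us[2], minus, off, block)
        edits[[length(edits) + 1L]] <-
          list(chrom = ch, start = pc$start, content = pc$content)
      }
      # motif plants must not collide genomically (UPS1K and MIDDLE can
      # overlap when the insertion is close upstream): resample the
      # offset a few times, else skip the plant
      occupied <- matrix(integer(), ncol = 2)
      for (mi in seq_along(spec$planted_motifs)) {
        mot <- spec$planted_motifs[mi]
        w <- nchar(mot)
        for (rg in c("UPS1K", "MIDDLE")) {
          if (runif(1) >= q) next
          bounds <- if (rg == "UPS1K") us else mid
          span <- bounds[2] - bounds[1] + 1L
          if (span < w) next
          pc <- NULL
          for (try in 1:20) {
            off <- sample.int(span - w + 1L, 1L)
            cand <- plantCoords(bounds[1], bounds[2], minus, off, mot)
            clash <- nrow(occupied) > 0 &&
              any(cand$start <= occupied[, 2] &
                  cand$end >= occupied[, 1])
            if (!clash) { pc <- cand; break }
          }
          if (is.null(pc)) next
          occupied <- rbind(occupied, c(pc$start, pc$end))
          edits[[length(edits) + 1L]] <-
            list(chrom = ch, start = pc$start, content = pc$content)
          planted[[length(planted) + 1L]] <- data.frame(
            line_id = ins$line_id[i], gene_id = genes$gene_id[i],
            region = rg, motif_id = names(spec$planted_motifs)[mi],
            offset = off, genomic_start = pc$start,
            genomic_end = pc$end,
            chrom = ch, strand = if (minus) "-" else "+")
        }
      }
    }
  })
  # apply all edits per chromosome on an integer code vector (one
  # conversion each way; in-place writes)
  chromStr <- as.list(as.character(genome))
  editChrom <- vapply(edits, `[[`, character(1), "chrom")
  for (ch in unique(editChrom)) {
    v <- utf8ToInt(chromStr[[ch]])
    for (e in edits[editChrom == ch]) {
      cv <- utf8ToInt(e$content)
      v[e$start:(e$start + length(cv) - 1L)] <- cv
    }
    chromStr[[ch]] <- intToUtf8(v)
  }
  g2 <- Biostrings::DNAStringSet(unlist(chromStr))
  names(g2) <- names(genome)
  labels <- S4Vectors::DataFrame(line_id = ins$line_id,
                                 gene_id = genes$gene_id, label = lab)
  manifest <- list(
    planted = if (length(planted)) do.call(rbind, planted)
              else data.frame(),
    true_pi = setNames(truePi, paste(ins$line_id, genes$gene_id,
                                     sep = "|")),
    distance_bp = setNames(as.integer(dist),
                           paste(ins$line_id, genes$gene_id, sep = "|")))
  list(genome = g2, labels = labels, manifest = manifest)
}

#' Generate a complete synthetic activation-tagging study
#'
#' @param spec a [syntheticSpec()].
#' @param seed RNG seed (default taken from the spec list).
#' @return a `TagStudy` whose manifest records planted motif positions
#'   and the true activation probability of every record.
#' @export
generateStudy <- function(spec = syntheticSpec(), seed = spec$seed) {
  genome <- generateGenome(spec, seed)
  layout <- generateGenesAndInsertions(spec, genome, seed)
  sig <- assignLabelsAndPlantSignal(spec, genome, layout, seed)
  new("TagStudy", genome = sig$genome, genes = layout$genes,
      insertions = layout$insertions, labels = sig$labels,
      manifest = c(sig$manifest, list(spec = spec, seed = seed)))
}

#' Motif library matching a synthetic study
#'
#' Builds near-indicator PWMs (probability 0.97 on the consensus base)
#' for the planted consensus motifs plus random-consensus decoy motifs,
#' so the scanning and encoding machinery sees both signal and noise.
#'
#' @param spec a [syntheticSpec()].
#' @param n_decoys decoy motifs to add (default 8).
#' @param seed RNG seed for the decoys.
#' @return a `MotifLibrary` with uniform background.
#' @export
syntheticMotifLibrary <- function(spec = syntheticSpec(), n_decoys = 8L,
                                  seed = spec$seed) {
  consensusPwm <- function(cons, p = 0.97) {
    v <- strsplit(cons, "")[[1]]
    pwm <- matrix((1 - p) / 3, 4, length(v),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm[cbind(match(v, c("A", "C", "G", "T")), seq_along(v))] <- p
    pwm
  }
  motifs <- lapply(spec$planted_motifs, consensusPwm)
  names(motifs) <- names(spec$planted_motifs)
  withSeed(childSeed(seed, 6), {
    for (i in seq_len(n_decoys)) {
      w <- sample(6:12, 1)
      motifs[[sprintf("decoy%02d", i)]] <-
        consensusPwm(paste(sample(c("A", "C", "G", "T"), w,
                                  replace = TRUE), collapse = ""))
    }
  })
  new("MotifLibrary", motifs = motifs,
      background = rep(0.25, 4))
}

#' Synthetic dinucleotide physicochemical property table
#'
#' A stand-in for a curated dinucleotide property database: each of the
#' 16 dinucleotides receives `n_properties` correlated pseudo-property
#' values (a low-rank structure plus noise), adequate for exercising
#' the PCA reduction and physicochemical encoding. Values are
#' synthetic, not measured physical quantities.
#'
#' @param n_properties number of property columns (default 125).
#' @param seed RNG seed.
#' @return 16 x `n_properties` matrix with dinucleotide rownames.
#' @export
syntheticPropertyTable <- function(n_properties = 125L, seed = 7L) {
  dinucs <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 2)
  withSeed(childSeed(seed, 8), {
    base <- matrix(rnorm(16 * 5), 16, 5)        # latent structure
    load <- matrix(rnorm(5 * n_properties), 5, n_properties)
    tab <- base %*% load + matrix(rnorm(16 * n_properties, sd = 0.3),
                                  16, n_properties)
  })
  rownames(tab) <- dinucs
  colnames(tab) <- paste0("prop", seq_len(n_properties))
  tab
}

#' A deterministic miniature worked study
#'
#' Two chromosomes, six genes on both strands, eight insertions
#' covering upstream, downstream and intragenic locations, with one
#' record whose enhancer-to-TLS interval is exactly 301 nt (so its
#' MIDDLE window is the entire interval). Regenerates identically on
#' every call; the test suite freezes extraction and encoding values
#' against it.
#'
#' @return a `TagStudy`.
#' @export
workedFixture <- function() {
  seqs <- withSeed(20240301, c(
    paste(randomBases(6000, 0.45), collapse = ""),
    paste(randomBases(4000, 0.45), collapse = "")))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- c("c1", "c2")
  genes <- GenomicRanges::GRanges(
    seqnames = c("c1", "c1", "c1", "c2", "c2", "c2"),
    ranges = IRanges::IRanges(
      start = c(2001, 4500, 1200, 1500, 3001, 1050),
      end = c(3500, 5500, 1800, 2600, 3600, 1400)),
    strand = c("+", "-", "+", "-", "+", "+"),
    gene_id = paste0("g", 1:6),
    tls = as.integer(c(2001, 5500, 1200, 2600, 3001, 1050)))
  ins <- S4Vectors::DataFrame(
    line_id = paste0("L", 1:8),
    chrom = c("c1", "c1", "c1", "c1", "c2", "c2", "c2", "c1"),
    position = as.integer(c(1501, 2301, 5900, 800, 1000, 3800, 2000,
                            3100)),
    orientation = c("+", "-", "+", "unknown", "-", "+", "+", "-"))
  labels <- S4Vectors::DataFrame(
    line_id = paste0("L", 1:8),
    gene_id = c("g1", "g1", "g2", "g3", "g4", "g5", "g6", "g1"),
    label = c("Ac", "Ac", "NAc", "Ac", "NAc", "Ac", "NAc", "Ac"))
  new("TagStudy", genome = genome, genes = genes, insertions = ins,
      labels = labels, manifest = list(fixture = "worked-miniature"))
}

#' Composition of the activation-tagging survey behind the method
#'
#' Record counts of the RT-PCR-validated flanking-gene survey the
#' modelling approach was developed on: mutant lines and validated
#' genes per expression state (activated, no significant effect,
#' non-detectable). Non-detectable records are dropped before training,
#' leaving a 280-record training set and a 48-record independent test
#' set; the 190 training positives are split into two 90-positive
#' groups that each join the 90 negatives to form two 180-record
#' training subsets.
#'
#' @return data.frame with columns dataset, lines, ac, ne, nd.
#' @export
referenceSurveyComposition <- function() {
  data.frame(dataset = c("training", "testing"),
             lines = c(226L, 11L),
             ac = c(190L, 26L), ne = c(90L, 22L), nd = c(13L, 17L))
}
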