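test_that("generated genomes hit the configured GC content", {
  spec <- syntheticSpec(n_records = 2L, cassette_bp = 70000L)
  g <- generateGenome(spec, seed = 1)
  expect_identical(length(g), 2L)
  gc <- Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)
  expect_lt(abs(gc - 0.43), 0.03)
  expect_identical(as.character(generateGenome(spec, seed = 1)[[1]]),
                   as.character(g[[1]]))
  atOnly <- generateGenome(syntheticSpec(n_records = 2L,
                                         gc_fraction = 1e-9), seed = 2)
  expect_equal(
    sum(Biostrings::letterFrequency(atOnly, c("G", "C"))), 0)
})

test_that("gene placement avoids overlap and respects distance bounds", {
  spec <- syntheticSpec(n_records = 20L)
  g <- generateGenome(spec, seed = 3)
  lay <- generateGenesAndInsertions(spec, g, seed = 3)
  ov <- GenomicRanges::findOverlaps(lay$genes, lay$genes)
  expect_identical(length(ov), 20L)           # only self-overlaps
  d <- abs(lay$insertions$position - lay$genes$tls)
  ig <- lay$insertions$position >= start(lay$genes) &
        lay$insertions$position <= end(lay$genes)
  expect_true(all(d[!ig] >= 100 & d[!ig] <= 30000))
  expect_true(all(lay$insertions$position >= 1))

  # strand balance over a larger draw
  spec200 <- syntheticSpec(n_records = 200L)
  lay200 <- generateGenesAndInsertions(spec200,
                                       generateGenome(spec200, seed = 4),
                                       seed = 4)
  nplus <- sum(as.character(strand(lay200$genes)) == "+")
  expect_gt(binom.test(nplus, 200)$p.value, 0.001)
})

test_that("planted signal is verifiable from the manifest", {
  spec <- syntheticSpec(n_records = 30L, q_ac = 1, q_nac = 0)
  study <- generateStudy(spec, seed = 9)
  man <- study@manifest
  labels <- as.data.frame(studyLabels(study))
  rg <- suppressWarnings(extractRegions(studyGenome(study),
                                        studyGenes(study),
                                        studyInsertions(study), labels))
  rec <- as.data.frame(regionRecords(rg))
  ids <- paste(rec$line_id, rec$gene_id, sep = "|")

  # every genomic coordinate in the manifest carries the motif content
  for (i in seq_len(nrow(man$planted))) {
    p <- man$planted[i, ]
    got <- fetchSeq(studyGenome(study), p$chrom, p$genomic_start,
                    p$genomic_end, p$strand)
    expect_identical(got, unname(spec$planted_motifs[p$motif_id]))
  }
  # with q_ac = 1 every activated promoter contains every consensus
  ac <- rec[labels$label == "Ac", ]
  for (m in spec$planted_motifs)
    expect_true(all(grepl(m, ac$ups1k, fixed = TRUE) |
                    nchar(ac$ups1k) < nchar(m)))
  # and the planted offsets match the extracted promoter strings
  ups <- setNames(rec$ups1k, ids)
  pl <- man$planted[man$planted$region == "UPS1K", ]
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    id <- paste(p$line_id, p$gene_id, sep = "|")
    mot <- unname(spec$planted_motifs[p$motif_id])
    expect_identical(unname(substr(ups[id], p$offset,
                                   p$offset + nchar(mot) - 1L)), mot)
  }
})

test_that("label frequencies follow the distance logistic", {
  study <- accStudy()          # default 360-record study, default seed
  man <- study@manifest
  acFrac <- mean(studyLabels(study)$label == "Ac")
  expect_lt(abs(acFrac - mean(man$true_pi)), 0.06)

  # a steeply negative slope kills activation beyond a few bp
  steep <- syntheticSpec(n_records = 40L, beta1 = -1)
  far <- generateStudy(steep, seed = 22)
  d <- abs(studyInsertions(far)$position - studyGenes(far)$tls)
  expect_true(all(studyLabels(far)$label[d > 100] == "NAc"))
})

test_that("the worked miniature study is frozen", {
  st <- workedFixture()
  st2 <- workedFixture()
  expect_identical(as.character(studyGenome(st)),
                   as.character(studyGenome(st2)))
  expect_identical(as.data.frame(studyLabels(st)),
                   as.data.frame(studyLabels(st2)))
  rec <- as.data.frame(regionRecords(fixtureRegions()))
  # frozen extraction values
  expect_identical(substr(rec$ups1k[1], 1, 10), "TCGATTATAT")
  expect_identical(rec$distance_bp,
                   c(500L, 300L, 400L, 400L, 1600L, 799L, 950L, 1099L))
  expect_identical(rec$location_class,
                   c("US", "IG", "US", "US", "DS", "DS", "DS", "IG"))
  # the 300 bp interval yields a MIDDLE equal to the whole interval
  expect_identical(rec$middle[2], rec$distance_seq[2])
  expect_identical(nchar(rec$middle[2]), 301L)
})

test_that("study writing and reading round-trips through standard formats", {
  st <- workedFixture()
  dir <- withr::local_tempdir()
  writeStudy(st, dir)
  back <- readStudy(file.path(dir, "genome.fa"),
                    file.path(dir, "genes.gff3"),
                    file.path(dir, "insertions.tsv"),
                    file.path(dir, "labels.tsv"))
  expect_identical(as.character(studyGenome(back)),
                   as.character(studyGenome(st)))
  expect_identical(studyGenes(back)$tls, studyGenes(st)$tls)
  expect_identical(studyGenes(back)$gene_id, studyGenes(st)$gene_id)
  expect_identical(as.character(strand(studyGenes(back))),
                   as.character(strand(studyGenes(st))))
  expect_identical(as.data.frame(studyInsertions(back)),
                   as.data.frame(studyInsertions(st)))
  expect_identical(as.data.frame(studyLabels(back)),
                   as.data.frame(studyLabels(st)))
})
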