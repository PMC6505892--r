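test_that("k-mer counting matches hand counts and skips N windows", {
  v <- countNgrams("ACGT")
  expect_identical(sum(v), 3L)               # two 3-mers + one 4-mer
  expect_identical(unname(v["3mer:ACG"]), 1L)
  expect_identical(unname(v["3mer:CGT"]), 1L)
  expect_identical(unname(v["4mer:ACGT"]), 1L)
  expect_identical(sum(v[startsWith(names(v), "5mer")]), 0L)

  v2 <- countNgrams("AAAA")
  expect_identical(unname(v2["3mer:AAA"]), 2L)
  expect_identical(unname(v2["4mer:AAAA"]), 1L)
  expect_identical(sum(v2[startsWith(names(v2), "3mer")]), 2L) # 4-3+1

  vn <- countNgrams("ACGNT")
  expect_identical(sum(vn[startsWith(names(vn), "3mer")]), 1L) # only ACG
  expect_identical(sum(countNgrams("")), 0L)
  expect_identical(length(v), 5440L)
})

test_that("k-mer counts equal a naive substring-scan oracle", {
  naiveCounts <- function(seq) {
    out <- setNames(integer(5440), ngramNames())
    for (k in 3:6) {
      L <- nchar(seq)
      if (L < k) next
      subs <- substring(seq, 1:(L - k + 1), k:L)
      subs <- subs[!grepl("N", subs, fixed = TRUE)]
      tab <- table(subs)
      out[paste0(k, "mer:", names(tab))] <- as.integer(tab)
    }
    out
  }
  withr::with_seed(31, {
    for (i in 1:12) {
      seq <- randomDna(200)
      if (i > 9) substr(seq, 50, 52) <- "NNN"   # a few N-containing cases
      expect_identical(countNgrams(seq), naiveCounts(seq))
    }
  })
})

test_that("property-table reduction is deterministic, full-rank and isometric", {
  tab <- syntheticPropertyTable(125, seed = 11)
  red <- reducePropertyTable(tab)
  expect_identical(dim(red), c(16L, 15L))
  expect_identical(colnames(red), paste0("pc", 1:15))
  expect_identical(red, reducePropertyTable(tab))

  # 15 components capture all of a rank-15 centred cloud: pairwise
  # distances of the scaled table are preserved exactly
  expect_equal(as.matrix(dist(red)), as.matrix(dist(scale(tab))),
               tolerance = 1e-8)

  # duplicating a property column leaves the full 15-component
  # projection's explained variance at 100%
  red2 <- reducePropertyTable(cbind(tab, dup = tab[, 1]))
  expect_equal(sum(red2^2) / sum(scale(cbind(tab, dup = tab[, 1]))^2), 1,
               tolerance = 1e-8)

  expect_error(reducePropertyTable(tab[, 1:10]), "at least 15")
  rankdef <- tab[, 1:15]
  rankdef[, 15] <- rankdef[, 1] * 2        # rank 14 after scaling
  expect_error(reducePropertyTable(rankdef), "rank")
})

test_that("physicochemical encoding is the count-weighted property mean", {
  red <- reducePropertyTable(syntheticPropertyTable(20, seed = 2), k = 15)
  v <- encodeNpc("AAAA", red)
  expect_identical(length(v), 240L)
  # homopolymer: 3 AA windows / 3 windows -> exactly the AA property row
  expect_equal(unname(v[paste0("npc:AA:pc", 1:15)]), unname(red["AA", ]))
  expect_true(all(v[!startsWith(names(v), "npc:AA")] == 0))

  # linearity: doubling one reduced property doubles its 16 entries
  red2 <- red
  red2[, "pc3"] <- red[, "pc3"] * 2
  s <- randomDna(80, seed = 3)
  v1 <- encodeNpc(s, red)
  v2 <- encodeNpc(s, red2)
  pc3 <- grepl(":pc3$", names(v1))
  expect_equal(v2[pc3], 2 * v1[pc3])
  expect_equal(v2[!pc3], v1[!pc3])

  # N windows are dropped from numerator and denominator alike
  vn <- encodeNpc("AANAA", red)
  expect_equal(unname(vn[paste0("npc:AA:pc", 1:15)]), unname(red["AA", ]))
  expect_error(encodeNpc("A", red), "shorter than 2")
})

test_that("CpG-island detection matches hand arithmetic", {
  expect_identical(nrow(detectCpgIslands(strrep("A", 1000))), 0L)

  cg300 <- strrep("CG", 150)
  isl <- detectCpgIslands(cg300)
  expect_identical(nrow(isl), 1L)
  expect_identical(isl$start, 1L)
  expect_identical(isl$length, 300L)
  expect_equal(isl$gc_percent, 100)
  # obs/exp = (#CG * len) / (#C * #G) = (150 * 300) / (150 * 150) = 2
  expect_equal(isl$obs_exp, 2)

  embedded <- paste0(strrep("A", 400), cg300, strrep("A", 300))
  isl2 <- detectCpgIslands(embedded)
  expect_identical(nrow(isl2), 1L)
  expect_true(abs(isl2$start - 401L) <= 99)   # within window - 1
  expect_true(abs(isl2$end - 700L) <= 99)

  # merged segments shorter than min_len are discarded (a 60 nt core
  # extends at most to the merged window span of 120 nt)
  short <- paste0(strrep("A", 300), strrep("CG", 30), strrep("A", 300))
  expect_identical(nrow(detectCpgIslands(short, min_len = 200)), 0L)
  expect_identical(nrow(detectCpgIslands("ACGT")), 0L)
})

test_that("CGI encoding reports the plain observed/expected ratio", {
  seq <- paste0(strrep("A", 100), "CGCGCG", strrep("A", 94))
  islands <- data.frame(start = 101L, end = 106L, length = 6L,
                        gc_percent = 100, obs_exp = 2)
  v <- encodeCgi(islands, seq, promoter_len = 200L, tls_offset = 201L)
  expect_identical(unname(v["cgi:number"]), 1)
  expect_equal(unname(v["cgi:length_ratio"]), 6 / 200)
  expect_equal(unname(v["cgi:dis"]), 100)        # |201 - 101|
  # CpG% = 100 * 3 / (6 - 1); plain OE = #CG / (#C * #G) = 3 / 9
  expect_equal(unname(v["cgi:cg_ratio"]), 100 * 3 / 5)
  expect_equal(unname(v["cgi:oe"]), 1 / 3)

  none <- encodeCgi(detectCpgIslands(strrep("A", 300)), strrep("A", 300))
  expect_identical(unname(none), rep(0, 5))

  # island covering the whole promoter: length ratio 1
  whole <- strrep("CG", 500)
  vI <- encodeCgi(detectCpgIslands(whole), whole)
  expect_equal(unname(vI["cgi:length_ratio"]), 1)
})

test_that("pattern selection agrees with stats::t.test and flags degeneracy", {
  withr::with_seed(21, {
    n <- 14
    counts <- cbind(
      flat = rep(3, 2 * n),
      signal = c(rnorm(n, 10), rnorm(n, 0)),
      noise = rnorm(2 * n))
    labels <- rep(c("Ac", "NAc"), each = n)
    sel <- selectPatterns(counts, labels)
    expect_identical(unname(sel$mask["flat"]), FALSE)
    expect_identical(unname(sel$p["flat"]), 1)
    expect_true(sel$mask["signal"])
    expect_lt(sel$p["signal"], 1e-6)
    # Welch p-values match the reference implementation
    for (col in c("signal", "noise")) {
      ref <- t.test(counts[labels == "Ac", col],
                    counts[labels == "NAc", col])$p.value
      expect_equal(unname(sel$p[col]), ref, tolerance = 1e-12)
    }
  })
  expect_error(selectPatterns(matrix(rnorm(8), 4), c("Ac", rep("NAc", 3))),
               "at least 2")
})

test_that("encoders are deterministic", {
  s <- randomDna(400, seed = 8)
  expect_identical(countNgrams(s), countNgrams(s))
  lib <- tinyLibrary()
  expect_identical(scanMotifs(s, lib, 0.01), scanMotifs(s, lib, 0.01))
  red <- reducePropertyTable(syntheticPropertyTable(30, seed = 1))
  expect_identical(encodeNpc(s, red), encodeNpc(s, red))
  expect_identical(detectCpgIslands(s), detectCpgIslands(s))
})
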