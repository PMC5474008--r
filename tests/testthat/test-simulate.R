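test_that("the replica genome validates and matches its design dimensions", {
  b <- arrangement_a()
  expect_s3_class(b$genome, "circular_genome")
  expect_equal(b$genome$length, 18730)
  expect_equal(nrow(b$features), 17)
  expect_equal(sum(b$features$kind == "PCG"), 14)
  expect_equal(sum(b$features$kind == "rRNA"), 2)
  expect_equal(sum(b$features$kind == "tRNA"), 1)
  ## round-trips through annotation write + load
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_annotation(b$genome, b$features, fa, tsv)
  back <- load_annotation(fa, features = tsv)
  expect_equal(back$genome$sequence, b$genome$sequence)
  ## PCGs have real start/stop codons and no premature in-frame stops
  for (i in which(b$features$kind == "PCG")) {
    cds <- genome_segment(b$genome, b$features$start[i], b$features$end[i],
                          b$features$strand[i])
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("generation is deterministic under a fixed seed", {
  b1 <- default_program("A", seed = 123)
  b2 <- default_program("A", seed = 123)
  expect_identical(b1$genome$sequence, b2$genome$sequence)
  s1 <- simulate_reads(b1$program, b1$features, b1$genome, depth = 3,
                       rrna_multiplier = 2, seed = 5)
  s2 <- simulate_reads(b2$program, b2$features, b2$genome, depth = 3,
                       rrna_multiplier = 2, seed = 5)
  expect_identical(s1$fragments, s2$fragments)
  j1 <- simulate_junction_reads(b1$program, b1$features, b1$genome,
                                n_per_end = 2, seed = 6)
  j2 <- simulate_junction_reads(b2$program, b2$features, b2$genome,
                                n_per_end = 2, seed = 6)
  expect_identical(j1$reads, j2$reads)
})

test_that("depth 0 yields an empty read set with a warning", {
  b <- arrangement_a()
  expect_warning(s <- simulate_reads(b$program, b$features, b$genome,
                                     depth = 0, seed = 1), "empty")
  expect_equal(nrow(s$fragments), 0)
})

test_that("per-gene mean depth tracks depth x relative abundance", {
  b <- arrangement_a()
  sim <- simulate_reads(b$program, b$features, b$genome, depth = 30,
                        readthrough_fraction = 0, seed = 31)
  prof <- compute_coverage(sim$fragments, b$genome)
  comb <- prof$depth_H + prof$depth_L
  ## genes in units without internal APA sites, where per-position relative
  ## abundance is the unit abundance (mtMutS tapers across its APA sites)
  for (gene in c("COI", "ND5", "COII", "CytB")) {
    row <- b$features[b$features$name == gene, ]
    m <- mean(comb[row$start:row$end])
    sdm <- sqrt(30 * 100 / (row$end - row$start + 1))  # Poisson fragment count
    expect_lt(abs(m - 30), 3 * sdm + 1)
  }
  ## rRNAs are the two most abundant features (multiplier 50)
  gene_means <- vapply(seq_len(nrow(b$features)), function(i)
    mean(comb[b$features$start[i]:b$features$end[i]]), numeric(1))
  top2 <- b$features$name[order(gene_means, decreasing = TRUE)][1:2]
  expect_setequal(top2, c("12S", "16S"))
})

test_that("arrangement truths carry the expected unit structures", {
  b <- arrangement_a()
  pcg_units <- Filter(function(u) {
    b$features$kind[match(u$genes[1], b$features$name)] == "PCG"
  }, b$program$units)
  cistrons <- sort(vapply(pcg_units, function(u) length(u$genes), integer(1)))
  expect_equal(cistrons, c(1, 1, 1, 2, 3, 3, 3))
  mt <- Filter(function(u) "mtMutS" %in% u$genes, b$program$units)[[1]]
  expect_equal(nrow(mt$apa), 6)
  expect_true(all(diff(sort(mt$apa$position)) >= 10))
  bc <- default_program("C", seed = 2)
  unit_ids <- vapply(bc$program$units, function(u)
    paste(u$genes, collapse = "-"), "")
  expect_true("COII-ATP8-ATP6-COIII" %in% unit_ids)
  expect_true("ND6-ND3-ND4L" %in% unit_ids)
  expect_equal(bc$genome$length, nchar(bc$genome$sequence))
})

test_that("junction read APA site frequencies follow the configured weights", {
  b <- arrangement_a()
  ## weighted mode: sample variants by weight for the mtMutS unit
  j <- simulate_junction_reads(b$program, b$features, b$genome,
                               n_total = 1000, seed = 13)
  tr <- j$truth[j$truth$unit_id == "ND3-ND4L-mtMutS", ]
  expect_equal(nrow(tr), 1000)
  obs <- table(tr$variant) / nrow(tr)
  mt <- Filter(function(u) "mtMutS" %in% u$genes, b$program$units)[[1]]
  expected <- c(mt$apa$weight, 1 - sum(mt$apa$weight))
  ## every variant within 4 multinomial SDs of its weight
  for (k in seq_len(nrow(mt$apa))) {
    w <- mt$apa$weight[k]
    o <- obs[paste0("ND3-ND4L-mtMutS:apa", k)]
    expect_lt(abs(o - w), 4 * sqrt(w * (1 - w) / 1000))
  }
})

test_that("fragment truth labels confine reads to their source transcript", {
  b <- arrangement_a()
  sim <- simulate_reads(b$program, b$features, b$genome, depth = 5,
                        rrna_multiplier = 3, readthrough_fraction = 0.01,
                        seed = 17)
  tx <- sim$transcripts
  fr <- sim$fragments
  idx <- match(fr$transcript, tx$id)
  expect_false(anyNA(idx))
  expect_true(all(fr$s1 >= tx$lo[idx]))
  expect_true(all(pmax(fr$e1, fr$e2, na.rm = TRUE) <= tx$hi[idx]))
  ## truth TSV round-trip
  tsv <- tempfile(fileext = ".tsv")
  write_truth_tsv(tx, tsv)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$id, tx$id)
  expect_equal(back$lo, tx$lo)
})

test_that("the synthetic congener alignment carries its planted divergence", {
  b <- arrangement_a()
  al <- make_congener_alignment(b$genome, seed = 4)
  expect_equal(nchar(al$row1), nchar(al$row2))
  expect_equal(nchar(gsub("-", "", al$row1)), 18730)
  expect_equal(nchar(gsub("-", "", al$row2)), 18718)  # 12 nt shorter
  pv <- pairwise_variability(al$row1, al$row2)
  expect_equal(round(pv$variability_pct, 2), 2.31)
  expect_equal(round(pv$ambiguity_pct, 2), 0.05)
  expect_equal(round(pv$gap_pct, 2), 0.16)
})
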