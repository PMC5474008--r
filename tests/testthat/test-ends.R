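test_that("constructed junction reads resolve to exact genomic ends", {
  ## adenine-free toy genome: the poly(A) tract is exactly the planted run
  set.seed(2)
  g <- circular_genome("noA", paste(sample(c("C", "G", "T"), 600,
                                           replace = TRUE), collapse = ""))
  read <- paste0(genome_segment(g, 380, 400, "H"), strrep("A", 30),
                 genome_segment(g, 95, 130, "H"))
  res <- resolve_crtpcr_junction(read, g)
  expect_equal(res$three_prime$position, 400)
  expect_equal(res$five_prime$position, 95)
  expect_equal(res$three_prime$polya_len, 30)
  expect_equal(res$three_prime$strand, "H")
  ## contiguous genomic segment with no A-run: no junction
  expect_error(resolve_crtpcr_junction(
    gsub("A", "C", genome_segment(g, 100, 220, "H")), g), "no junction")
})

test_that("junction resolution is exact over many generator constructions", {
  b <- arrangement_a()
  g <- b$genome
  set.seed(77)
  sense_base <- function(p, strand) genome_segment(g, p, p, strand)
  n_done <- 0; n_exact <- 0; tries <- 0
  while (n_done < 300 && tries < 3000) {
    tries <- tries + 1
    p3 <- sample(g$length, 1)
    p5 <- sample(g$length, 1)
    strand <- sample(c("H", "L"), 1)
    ## junction-adjacent bases must not be A, or the poly(A) run boundary
    ## genuinely shifts -- that is a property of the molecule, not the tool
    if (sense_base(p3, strand) == "A" || sense_base(p5, strand) == "A") next
    k <- sample(20:60, 1)
    read <- if (strand == "H")
      paste0(genome_segment(g, p3 - 39, p3, "H"), strrep("A", k),
             genome_segment(g, p5, p5 + 39, "H"))
    else
      paste0(genome_segment(g, p3, p3 + 39, "L"), strrep("A", k),
             genome_segment(g, p5 - 39, p5, "L"))
    n_done <- n_done + 1
    res <- tryCatch(resolve_crtpcr_junction(read, g), error = function(e) e)
    if (inherits(res, "error")) {
      ## only a genuinely multi-locus anchor may error
      expect_match(conditionMessage(res), "ambiguous")
      next
    }
    expect_equal(res$three_prime$position, p3)
    expect_equal(res$five_prime$position, p5)
    expect_equal(res$three_prime$strand, strand)
    expect_equal(res$three_prime$polya_len, k)
    n_exact <- n_exact + 1
  }
  expect_gte(n_exact, 290)
})

test_that("RACE reads strip adapters and map ends on both strands", {
  set.seed(3)
  g <- circular_genome("noA2", paste(sample(c("C", "G", "T"), 800,
                                            replace = TRUE), collapse = ""))
  adapter <- "GGTCCGTTAAGCAG"
  r5 <- paste0(adapter, genome_segment(g, 100, 160, "H"))
  e5 <- interpret_race_read(r5, g, adapter, side = "five")
  expect_equal(e5$position, 100)
  expect_equal(e5$kind, "five_prime")
  ## 3' read: insert + A-tail + adapter
  r3 <- paste0(genome_segment(g, 300, 360, "H"), strrep("A", 20), adapter)
  e3 <- interpret_race_read(r3, g, adapter, side = "three")
  expect_equal(e3$position, 360)
  expect_equal(e3$polya_len, 20)
  ## complement-strand segment reports the L strand
  rL <- paste0(adapter, genome_segment(g, 500, 560, "L"))
  eL <- interpret_race_read(rL, g, adapter, side = "five")
  expect_equal(eL$strand, "L")
  expect_equal(eL$position, 560)  # L-strand 5' end = higher coordinate
  expect_error(interpret_race_read("ACGTACGTACGTACGTACGT", g, adapter,
                                   side = "five"), "no adapter")
})

test_that("poly(A) soft-clip calls aggregate support and enforce A fraction", {
  g <- toy_genome(len = 900)
  empty <- data.frame(qname = "q", transcript = "t", strand = "H",
                      s1 = 1, e1 = 50, s2 = NA, e2 = NA,
                      softclip3 = NA_character_, clip_pos = NA_integer_,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(call_polya_sites(empty, g)), 0)
  fr <- do.call(rbind, lapply(1:5, function(i) {
    x <- empty; x$softclip3 <- "AAAAAAAAAA"; x$clip_pos <- 500L; x
  }))
  res <- call_polya_sites(fr, g)
  expect_equal(nrow(res), 1)
  expect_equal(res$position, 500)
  expect_equal(res$support, 5)
  ## 0.8 A fraction rejected under default 0.9
  bad <- empty; bad$softclip3 <- "AAGAA"; bad$clip_pos <- 120L
  expect_equal(nrow(call_polya_sites(bad, g)), 0)
})

test_that("APA clustering merges within tolerance and checks reading frame", {
  b <- arrangement_a()
  mf <- b$features[b$features$name == "mtMutS", ]
  ends <- data.frame(position = c(1000, 1001, 1002) + mf$start,
                     kind = "three_prime", strand = "H", method = "crtpcr",
                     polya_len = 30, support = c(2, 5, 1),
                     stringsAsFactors = FALSE)
  cl <- cluster_apa(ends, b$genome, mf)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$representative_position, mf$start + 1001)  # max support
  expect_equal(cl$support, 8)  # conservation of end counts
  ## in-frame arithmetic vs brute-force codon enumeration
  for (off in c(3, 6, 300, 301, 302)) {
    pos <- mf$start + off - 1
    e1 <- data.frame(position = pos, kind = "three_prime", strand = "H",
                     method = "crtpcr", polya_len = 10, support = 1,
                     stringsAsFactors = FALSE)
    got <- cluster_apa(e1, b$genome, mf)$in_frame
    codon_boundaries <- seq(mf$start + 2, mf$end, by = 3)
    expect_equal(got, pos %in% codon_boundaries, info = paste("offset", off))
  }
  ## mixed strands rejected
  mix <- rbind(ends, transform(ends, strand = "L"))
  expect_error(cluster_apa(mix, b$genome, mf), "mixed")
  ## input order invariance
  cl2 <- cluster_apa(ends[c(3, 1, 2), ], b$genome, mf)
  expect_equal(cl, cl2)
})

test_that("UTR annotation handles exact, zero-length and truncated leaders", {
  b <- arrangement_a()
  coi <- b$features[b$features$name == "COI", ]
  units <- data.frame(unit_id = "COI", genes = "COI", strand = "H",
                      n_genes = 1, n_cistrons = 1, status = "mature",
                      stringsAsFactors = FALSE)
  mkend <- function(pos, kind) data.frame(
    position = pos, kind = kind, strand = "H", method = "crtpcr",
    polya_len = NA, support = 1, stringsAsFactors = FALSE)
  ## 5' end exactly at the start codon: UTR 0
  u <- annotate_utrs(units, mkend(coi$start, "five_prime"), b$features, b$genome)
  expect_equal(u$utr5_len, 0)
  expect_false(u$truncated5)
  ## 5' end 6 nt inside the CDS: truncated flag, offset 6
  u <- annotate_utrs(units, mkend(coi$start + 6, "five_prime"),
                     b$features, b$genome)
  expect_true(u$truncated5)
  expect_equal(u$trunc_offset, 6)
  ## 3' end 12 nt after the stop
  u <- annotate_utrs(units, mkend(coi$end + 12, "three_prime"),
                     b$features, b$genome)
  expect_equal(u$utr3_len, 12)
})

test_that("ORF scanning and the four-way lncRNA rule behave at the edges", {
  ## constructed 60-codon ORF
  set.seed(8)
  body <- paste(sample_non_stop <- replicate(60, paste(
    sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")),
    collapse = "")
  ## replace any accidental stops with CCC, then frame it
  body <- gsub("TAA|TAG|TGA", "CCC", body)
  orf_seq <- paste0("ATG", body, "TAA")
  expect_gte(longest_orf(orf_seq), 60)
  expect_equal(longest_orf("AAAAAAAAAA"), 0)

  b <- arrangement_a()
  atp6 <- b$features[b$features$name == "ATP6", ]
  lnc <- b$program$antisense[[1]]
  res <- classify_lncrna(list(start = lnc$start, end = lnc$end, strand = "H"),
                         polyadenylated = TRUE, b$genome, b$features)
  expect_true(res$called)
  expect_equal(res$antisense_of, "ATP6")
  expect_equal(res$length, 212)
  ## 150 nt interval: too short
  res <- classify_lncrna(list(start = lnc$start, end = lnc$start + 149,
                              strand = "H"),
                         polyadenylated = TRUE, b$genome, b$features)
  expect_false(res$called)
  expect_false(res$criteria$length_gt_200)
  ## not polyadenylated: rejected
  res <- classify_lncrna(list(start = lnc$start, end = lnc$end, strand = "H"),
                         polyadenylated = FALSE, b$genome, b$features)
  expect_false(res$called)
})
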