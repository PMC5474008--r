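test_that("base composition matches a direct character-count oracle", {
  expect_equal(unname(base_composition("ACGT")$pct), c(25, 25, 25, 25))
  expect_equal(base_composition("ACGT")$gc_pct, 50)
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 1000, replace = TRUE,
                    prob = c(.3, .2, .2, .28, .02)), collapse = "")
  bc <- base_composition(s)
  chars <- strsplit(s, "")[[1]]
  for (b in c("A", "C", "G", "T"))
    expect_identical(unname(bc$counts[b]), sum(chars == b))
  expect_identical(bc$ambiguity_count, sum(chars == "N"))
  expect_equal(sum(bc$counts) + bc$ambiguity_count, 1000)
  ## circularity: composition is invariant under rotation
  rot <- paste0(substr(s, 501, 1000), substr(s, 1, 500))
  expect_identical(base_composition(rot)$counts, bc$counts)
})

test_that("igr_table agrees with the occupancy-array oracle on random circles", {
  for (seed in 1:12) {
    ann <- random_annotation(seed)
    res <- igr_table(ann$genome, ann$features)
    oracle <- occupancy_oracle(ann$genome, ann$features)
    expect_equal(sort(res$igrs$length[res$igrs$length > 0]),
                 oracle$igr_lengths, info = paste("seed", seed))
    expect_equal(sort(res$overlaps$overlap), oracle$overlap_lengths,
                 info = paste("seed", seed))
    ## partition property when no overlaps
    if (nrow(res$overlaps) == 0) {
      spans <- (ann$features$end - ann$features$start) %% ann$genome$length + 1
      expect_equal(sum(spans) + sum(res$igrs$length), ann$genome$length)
    }
  }
})

test_that("abutting genes yield a zero-length IGR and wrap pairs are included", {
  g <- toy_genome(len = 400)
  ft <- gene_features(data.frame(
    name = c("a", "b"), kind = "PCG", strand = "H",
    start = c(1, 101), end = c(100, 390)), g)
  res <- igr_table(g, ft)
  expect_equal(nrow(res$igrs), 2)
  expect_equal(res$igrs$length[res$igrs$left_gene == "a"], 0)
  ## wrap-around IGR b -> a spans positions 391..400
  expect_equal(res$igrs$length[res$igrs$left_gene == "b"], 10)
})

test_that("single feature covering the whole circle is accepted with no IGRs", {
  g <- toy_genome(len = 300)
  ft <- gene_features(data.frame(name = "all", kind = "PCG", strand = "H",
                                 start = 1, end = 300), g)
  expect_equal(nrow(ft), 1)
  expect_error(igr_table(g, ft), "two features")
})

test_that("pairwise variability counts mismatches among clean columns only", {
  pv <- pairwise_variability("ACGT", "ACGT")
  expect_equal(pv$variability_pct, 0)
  expect_equal(pv$gap_pct, 0)
  expect_equal(pv$ambiguity_pct, 0)
  ## 100 columns: 2 mismatches, 1 gap column, 1 N column
  r1 <- strsplit(strrep("A", 100), "")[[1]]
  r2 <- r1
  r2[c(3, 50)] <- "G"
  r2[70] <- "-"
  r2[80] <- "N"
  pv <- pairwise_variability(paste(r1, collapse = ""), paste(r2, collapse = ""))
  expect_equal(pv$n_informative, 98)
  expect_equal(pv$variability_pct, 2 / 98 * 100)
  expect_equal(pv$gap_pct, 1)
  expect_equal(pv$ambiguity_pct, 1)
  expect_error(pairwise_variability("ACGT", "ACG"), "unequal")
})

test_that("annotations round-trip through FASTA + TSV write and load", {
  ann <- random_annotation(99, n_genes = 10)
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_annotation(ann$genome, ann$features, fa, tsv)
  back <- load_annotation(fa, features = tsv)
  expect_equal(back$genome$sequence, ann$genome$sequence)
  expect_equal(back$genome$length, ann$genome$length)
  expect_equal(back$features[, c("name", "kind", "strand", "start", "end")],
               ann$features[, c("name", "kind", "strand", "start", "end")])
})

test_that("GenBank flat files parse with strand mapping and coordinates", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TOY0001        120 bp    DNA     circular",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..45",
    "                     /gene=\"geneA\"",
    "     rRNA            complement(50..80)",
    "                     /product=\"small rRNA\"",
    "     tRNA            90..115",
    "                     /gene=\"trnX\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), gb)
  ann <- load_annotation(gb)
  expect_equal(ann$genome$length, 120)
  expect_equal(nrow(ann$features), 3)
  a <- ann$features[ann$features$name == "geneA", ]
  expect_equal(c(a$start, a$end), c(10, 45))
  expect_equal(a$strand, "H")
  expect_equal(ann$features$strand[ann$features$name == "small rRNA"], "L")
  expect_equal(ann$features$kind[ann$features$name == "trnX"], "tRNA")
})

test_that("validation rejects bad coordinates, residues and duplicates", {
  g <- toy_genome(len = 200)
  expect_error(gene_features(data.frame(
    name = "x", kind = "PCG", strand = "H", start = 10, end = 250), g),
    "outside")
  expect_error(gene_features(data.frame(
    name = c("x", "x"), kind = "PCG", strand = "H",
    start = c(1, 50), end = c(40, 90)), g), "duplicate")
  expect_error(circular_genome("bad", "ACGTZ"), "unknown residue")
})

test_that("IGR BED export is 0-based half-open and splits wrapped regions", {
  g <- toy_genome(len = 400)
  ft <- gene_features(data.frame(
    name = c("a", "b"), kind = "PCG", strand = "H",
    start = c(21, 101), end = c(90, 390)), g)
  res <- igr_table(g, ft)
  bed <- tempfile(fileext = ".bed")
  write_igr_bed(res$igrs, g, bed)
  lines <- read.delim(bed, header = FALSE)
  ## a..b: positions 91..100 -> BED 90,100
  expect_true(any(lines$V2 == 90 & lines$V3 == 100))
  ## wrapped b..a IGR 391..400 + 1..20 -> two lines
  expect_true(any(lines$V2 == 390 & lines$V3 == 400))
  expect_true(any(lines$V2 == 0 & lines$V3 == 20))
})
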