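## Synthetic-data generator: a parameterized organellar transcription
## program (arrangement-A or -C octocoral-style mitogenome), read/junction
## simulators and qPCR simulators with ground-truth outputs.

## target base counts for the arrangement-A replica genome: chosen so the
## rounded percentages are A 30.2 / C 16.5 / G 19.3 / T 33.9 and G+C 35.8
A_BASE_COUNTS <- c(A = 5662L, C = 3096L, G = 3616L, T = 6356L)
A_GENOME_LENGTH <- 18730L

## conserved motif planted in IGRs flanking transcription units (synthetic
## stand-in for the conserved 11 bp processing motif)
UNIT_FLANK_MOTIF <- "TTCAGTGGCGA"

STOP_CODONS <- c("TAA", "TAG", "TGA")

## sample n codons with per-base target frequencies, excluding stop codons
sample_codons <- function(n, freqs) {
  bases <- names(freqs)
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  w <- vapply(strsplit(codons, ""), function(x) prod(freqs[x]), numeric(1))
  w[codons %in% STOP_CODONS] <- 0
  sample(codons, n, replace = TRUE, prob = w)
}

write_seq <- function(g, start, chars, L) {
  g[circ_pos(seq.int(start, length.out = length(chars)), L)] <- chars
  g
}

## arrangement-A gene layout: name, kind, strand, length and the IGR length
## following each gene in genome order (-13 encodes the 13 nt overlap)
arrangement_a_layout <- function() {
  data.frame(
    name = c("COI", "12S", "ND1", "CytB", "ND6", "ND3", "ND4L", "mtMutS",
             "16S", "ND2", "ND5", "ND4", "trnM", "COIII", "ATP6", "ATP8",
             "COII"),
    kind = c("PCG", "rRNA", "PCG", "PCG", "PCG", "PCG", "PCG", "PCG",
             "rRNA", "PCG", "PCG", "PCG", "tRNA", "PCG", "PCG", "PCG",
             "PCG"),
    strand = c("H", "H", "H", "H", "H", "H", "H", "H",
               "H", "H", "H", "H", "L", "L", "L", "L", "L"),
    len = c(1578L, 1050L, 981L, 1158L, 591L, 354L, 297L, 2982L,
            2088L, 1128L, 1818L, 1461L, 71L, 780L, 699L, 216L, 750L),
    igr_after = c(30L, 4L, 52L, 25L, 46L, 20L, 30L, 35L,
                  51L, 35L, -13L, 45L, 50L, 90L, 30L, 86L, 112L),
    stringsAsFactors = FALSE)
}

arrangement_c_layout <- function() {
  data.frame(
    name = c("COI", "12S", "ND1", "CytB", "16S", "ND2", "ND5", "ND4",
             "mtMutS", "trnM", "COIII", "ATP6", "ATP8", "COII", "ND4L",
             "ND3", "ND6"),
    kind = c("PCG", "rRNA", "PCG", "PCG", "rRNA", "PCG", "PCG", "PCG",
             "PCG", "tRNA", "PCG", "PCG", "PCG", "PCG", "PCG", "PCG",
             "PCG"),
    strand = c("H", "H", "H", "H", "H", "H", "H", "H",
               "H", "L", "L", "L", "L", "L", "L", "L", "L"),
    len = c(1578L, 1050L, 981L, 1158L, 2088L, 1128L, 1818L, 1461L,
            2982L, 71L, 780L, 699L, 216L, 750L, 297L, 354L, 591L),
    igr_after = c(rep(46L, 16), 120L),
    stringsAsFactors = FALSE)
}

layout_to_features <- function(layout, first_start, L) {
  n <- nrow(layout)
  start <- integer(n); end <- integer(n)
  s <- first_start
  for (i in seq_len(n)) {
    start[i] <- s
    end[i] <- s + layout$len[i] - 1L
    s <- end[i] + layout$igr_after[i] + 1L
  }
  data.frame(name = layout$name, kind = layout$kind, strand = layout$strand,
             start = start, end = end, wraps_origin = FALSE,
             len = layout$len, stringsAsFactors = FALSE)
}

## force the sense-strand base at a genomic end position to C (no stop codon
## contains a C, so this can never create an in-frame stop inside a CDS);
## keeps junction poly(A) runs from merging with flanking genomic adenines
plant_end_base <- function(g, pos, strand, L) {
  g[circ_pos(pos, L)] <- if (strand == "H") "C" else "G"
  g
}

#' Default transcription program, genome and annotation
#'
#' Builds a synthetic replica of an octocoral-style circular mitogenome
#' (14 protein-coding genes, two rRNAs, one tRNA-Met) together with the
#' transcription program that the read and junction simulators execute.
#' Arrangement `"A"` reproduces the arrangement-A unit structure: units COI;
#' CytB-ND6; ND3-ND4L-mtMutS (with six weighted alternative polyadenylation
#' sites); ND2-ND5-ND4; COII-ATP8-ATP6; ND1; COIII; the two rRNAs; tRNA-Met;
#' and an antisense lncRNA over ATP6. Its genome is built to the published
#' dimensions of the arrangement-A exemplar (18,730 nt; mtMutS 2,982 nt
#' longest and ATP8 216 nt shortest PCG; longest IGR 112 nt between COII and
#' COI, shortest 4 nt; one 13 nt overlap; exact base counts rounding to
#' A 30.2%, C 16.5%, G 19.3%, T 33.9%). Arrangement `"C"` carries the
#' alternative unit structure with a COII-ATP8-ATP6-COIII tetracistron and
#' ND6-ND3-ND4L, with its control region in the ND6-COI IGR.
#'
#' Stem-loops and a shared 11 nt motif are planted in the control region and
#' in the IGRs flanking transcription units; protein-coding genes get real
#' start/stop codons and no premature in-frame stops; the antisense lncRNA
#' interval is guaranteed free of ORFs of 50+ codons.
#'
#' @param arrangement `"A"` or `"C"`.
#' @param seed integer seed for the genome sequence.
#' @return list with `genome` (a `circular_genome`), `features` (validated
#'   feature table) and `program` (unit list with UTRs, abundances, APA
#'   sites, rRNA multiplier, read-through fraction, antisense transcripts).
#' @export
default_program <- function(arrangement = c("A", "C"), seed = 1L) {
  arrangement <- match.arg(arrangement)
  set.seed(seed)
  layout <- if (arrangement == "A") arrangement_a_layout() else arrangement_c_layout()
  L <- if (arrangement == "A") A_GENOME_LENGTH else {
    sum(layout$len) + sum(layout$igr_after)
  }
  ft <- layout_to_features(layout, first_start = 101L, L = L)
  freqs <- A_BASE_COUNTS / sum(A_BASE_COUNTS)

  ## 1. background sequence at target frequencies
  g <- sample(names(freqs), L, replace = TRUE, prob = freqs)

  ## 2. protein-coding genes: ATG + non-stop codons + TAA (transcript sense)
  write_cds <- function(g, row) {
    ncod <- row$len / 3L
    stopifnot(ncod == round(ncod))
    cds <- paste(c("ATG", sample_codons(ncod - 2L, freqs), "TAA"),
                 collapse = "")
    ## L-strand genes are stored as the reverse complement of their CDS
    if (row$strand == "L") cds <- revcomp(cds)
    write_seq(g, row$start, strsplit(cds, "")[[1]], L)
  }
  for (i in which(ft$kind == "PCG")) g <- write_cds(g, ft[i, ])

  ## overlapping gene pairs share sequence: the downstream gene's start codon
  ## sits inside the upstream gene, whose stop codon sits inside the
  ## downstream CDS. Rewrite each overlap so both reading frames are valid
  ## (H-strand pairs; the overlap length is 13 = 1 mod 3 here, and the filler
  ## below is stop-free in both frames)
  for (i in seq_len(nrow(ft) - 1L)) {
    a <- ft[i, ]; b2 <- ft[i + 1L, ]
    if (a$strand != "H" || b2$strand != "H") next
    if (b2$start > a$end) next
    S <- b2$start; E <- a$end
    if (E - S + 1L != 13L) next
    g <- write_seq(g, S, strsplit("ATGCCTCCTCTAA", "")[[1]], L)
    ## upstream-frame codon ending at S is (S-2, S-1, A): break TAA/TGA
    if (paste0(g[S - 2L], g[S - 1L]) %in% c("TA", "TG")) g[S - 1L] <- "C"
  }

  ## program definition
  un <- function(genes, utr5, utr3, abundance = 1, ends_known = TRUE,
                 apa = NULL)
    list(genes = genes, utr5 = utr5, utr3 = utr3, abundance = abundance,
         ends_known = ends_known, apa = apa)
  if (arrangement == "A") {
    apa_offsets <- c(592L, 617L, 757L, 2606L, 2797L, 2822L)
    mf <- ft[ft$name == "mtMutS", ]
    apa <- data.frame(position = mf$start + apa_offsets - 1L,
                      weight = c(0.12, 0.12, 0.12, 0.14, 0.14, 0.14))
    units <- list(
      un("COI", utr5 = 4L, utr3 = 1L),
      un(c("CytB", "ND6"), utr5 = -6L, utr3 = 8L),
      un(c("ND3", "ND4L", "mtMutS"), utr5 = 31L, utr3 = 1L, apa = apa),
      un(c("ND2", "ND5", "ND4"), utr5 = 1L, utr3 = 44L),
      un(c("COII", "ATP8", "ATP6"), utr5 = 3L, utr3 = 83L),
      un("ND1", utr5 = 0L, utr3 = 0L, ends_known = FALSE),
      un("COIII", utr5 = 0L, utr3 = 0L, ends_known = FALSE),
      un("12S", utr5 = 0L, utr3 = 0L, abundance = NA, ends_known = FALSE),
      un("16S", utr5 = 0L, utr3 = 0L, abundance = NA, ends_known = FALSE),
      un("trnM", utr5 = 0L, utr3 = 0L, abundance = 3, ends_known = FALSE))
    atp6 <- ft[ft$name == "ATP6", ]
    lnc_start <- atp6$start + 150L
    antisense <- list(list(id = "lncATP6", start = lnc_start,
                           end = lnc_start + 211L, strand = "H",
                           abundance = 0.5, polyadenylated = TRUE))
    cr_flanks <- c("COII_COI", "ND1_CytB", "ND6_ND3", "COIII_ATP6")
  } else {
    units <- list(
      un("COI", utr5 = 2L, utr3 = 1L),
      un(c("ND1", "CytB"), utr5 = 10L, utr3 = 5L),
      un(c("ND2", "ND5", "ND4"), utr5 = 1L, utr3 = 20L),
      un("mtMutS", utr5 = 0L, utr3 = 0L, abundance = 0.3, ends_known = FALSE),
      un(c("COII", "ATP8", "ATP6", "COIII"), utr5 = 3L, utr3 = 20L),
      un(c("ND6", "ND3", "ND4L"), utr5 = 5L, utr3 = 12L),
      un("12S", utr5 = 0L, utr3 = 0L, abundance = NA, ends_known = FALSE),
      un("16S", utr5 = 0L, utr3 = 0L, abundance = NA, ends_known = FALSE),
      un("trnM", utr5 = 0L, utr3 = 0L, abundance = 3, ends_known = FALSE))
    antisense <- list()
    cr_flanks <- c("ND6_COI", "CytB_16S", "mtMutS_trnM", "COIII_ATP6")
  }

  ## 3. plant hairpin + shared motif into the control region and the IGRs
  ## flanking transcription units
  genome_tmp <- structure(list(id = "tmp", sequence = paste(g, collapse = ""),
                               length = L), class = "circular_genome")
  igrs <- igr_table(genome_tmp, gene_features(ft, genome_tmp))$igrs
  planted <- integer(0)
  for (fl in cr_flanks) {
    parts <- strsplit(fl, "_")[[1]]
    row <- igrs[igrs$left_gene == parts[1] & igrs$right_gene == parts[2], ]
    if (nrow(row) == 0 || row$length < 42) next
    ## per-IGR random 12 bp stem arm (structures are conserved, sequences
    ## need not be); only the 11 nt motif is shared across IGRs
    stem <- paste(sample(DNA_BASES, 12, replace = TRUE), collapse = "")
    hp <- c(strsplit(stem, "")[[1]], strsplit("CAACC", "")[[1]],
            strsplit(revcomp(stem), "")[[1]])
    pos0 <- row$start
    g <- write_seq(g, pos0, hp, L)
    g <- write_seq(g, circ_pos(pos0 + length(hp) + 2L, L),
                   strsplit(UNIT_FLANK_MOTIF, "")[[1]], L)
    planted <- c(planted, circ_pos(seq.int(pos0, length.out = length(hp) +
                                             2L + nchar(UNIT_FLANK_MOTIF)), L))
  }

  ## 4. pin the sense-strand base at every simulated transcript end to C so
  ## poly(A) junctions stay delimited (C occurs in no stop codon)
  end_positions <- function(units, ft) {
    out <- list()
    for (u in units) {
      if (!u$ends_known) next
      rows <- ft[match(u$genes, ft$name), ]
      strand <- rows$strand[1]
      if (strand == "H") {
        p5 <- min(rows$start) - u$utr5
        p3 <- max(rows$end) + u$utr3
      } else {
        p5 <- max(rows$end) + u$utr5
        p3 <- min(rows$start) - u$utr3
      }
      out[[length(out) + 1]] <- data.frame(pos = c(p5, p3), strand = strand)
      if (!is.null(u$apa))
        out[[length(out) + 1]] <- data.frame(pos = u$apa$position,
                                             strand = strand)
    }
    do.call(rbind, out)
  }
  ep <- end_positions(units, ft)
  for (i in seq_len(nrow(ep)))
    g <- plant_end_base(g, ep$pos[i], ep$strand[i], L)
  for (a in antisense) {
    g <- plant_end_base(g, a$start, a$strand, L)
    g <- plant_end_base(g, a$end, a$strand, L)
    planted <- c(planted, a$start, a$end)
  }
  planted <- c(planted, circ_pos(ep$pos, L))

  ## 5. keep the antisense interval free of ORFs (resample third codon
  ## positions of the underlying gene, which cannot create sense stops)
  for (a in antisense) {
    guard <- 0L
    while (longest_orf(genome_segment(
      structure(list(id = "tmp", sequence = paste(g, collapse = ""),
                     length = L), class = "circular_genome"),
      a$start, a$end, a$strand)) >= 50L && guard < 50L) {
      ## break the longest ORF by rewriting one third-codon-position base of
      ## the host gene within the interval to C/G (sense of the host gene)
      host <- ft[ft$start <= a$start & ft$end >= a$end, ][1, ]
      off <- sample.int(a$end - a$start - 2L, 1L) + a$start
      ## third codon position of the host gene at or after `off`
      if (host$strand == "L") {
        ph <- host$end - (circ_len(off, host$end, L) %/% 3L) * 3L + 1L
        g[circ_pos(ph, L)] <- "G"
      } else {
        ph <- host$start + (circ_len(host$start, off, L) %/% 3L) * 3L - 1L
        g[circ_pos(ph, L)] <- "C"
      }
      guard <- guard + 1L
    }
  }

  ## 6. composition repair: adjust free positions (rRNA and tRNA interiors,
  ## unplanted IGR bases) so base counts hit the arrangement-A targets
  if (arrangement == "A") {
    free <- logical(L)
    for (i in which(ft$kind %in% c("rRNA", "tRNA"))) {
      len_i <- feature_length(ft$start[i], ft$end[i], ft$wraps_origin[i], L)
      free[circ_span(ft$start[i], len_i, L)] <- TRUE
    }
    for (i in seq_len(nrow(igrs))) {
      if (is.na(igrs$start[i]) || igrs$length[i] == 0) next
      free[circ_span(igrs$start[i], igrs$length[i], L)] <- TRUE
    }
    free[planted] <- FALSE
    tc <- A_BASE_COUNTS
    cc <- table(factor(g, levels = names(tc)))
    pool <- sample(which(free))  # randomized repair order
    for (p in pool) {
      b <- g[p]
      if (cc[b] > tc[b]) {
        deficit <- names(tc)[cc < tc]
        if (length(deficit) == 0) break
        d <- deficit[1]
        g[p] <- d
        cc[b] <- cc[b] - 1L; cc[d] <- cc[d] + 1L
      }
      if (all(cc == tc)) break
    }
  }

  genome <- circular_genome(
    if (arrangement == "A") "synthA_mitogenome" else "synthC_mitogenome",
    paste(g, collapse = ""))
  features <- gene_features(ft, genome)

  program <- list(
    arrangement = arrangement,
    units = units,
    rrna_multiplier = 50,
    readthrough_fraction = 0.01,
    antisense = antisense,
    polya_len_dist = c(mean = 40, sd = 5),
    seed = seed)
  list(genome = genome, features = features, program = program)
}

#' Transcript catalog implied by a transcription program
#'
#' Expands units (including each alternative polyadenylation variant),
#' rRNA/tRNA transcripts, antisense transcripts and -- when the read-through
#' fraction is positive -- one unprocessed precursor per strand into a table
#' of transcript intervals with relative abundances. This is the simulator's
#' ground truth.
#'
#' @param program,features,genome from [default_program()].
#' @param rrna_multiplier,readthrough_fraction overrides; `NULL` uses the
#'   program values.
#' @return data.frame `id`, `unit_id`, `strand`, `lo`, `hi` (genome
#'   interval), `tx5`, `tx3` (genomic end positions), `len`, `abundance`,
#'   `polyadenylated`, `class`.
#' @export
build_transcripts <- function(program, features, genome,
                              rrna_multiplier = NULL,
                              readthrough_fraction = NULL) {
  L <- genome$length
  if (is.null(rrna_multiplier)) rrna_multiplier <- program$rrna_multiplier
  if (is.null(readthrough_fraction))
    readthrough_fraction <- program$readthrough_fraction
  rows <- list()
  add <- function(id, unit_id, strand, tx5, tx3, abundance, polya, class) {
    lo <- min(tx5, tx3); hi <- max(tx5, tx3)
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, unit_id = unit_id, strand = strand, lo = lo, hi = hi,
      tx5 = tx5, tx3 = tx3, len = hi - lo + 1L, abundance = abundance,
      polyadenylated = polya, class = class, stringsAsFactors = FALSE)
  }
  for (u in program$units) {
    rowsf <- features[match(u$genes, features$name), , drop = FALSE]
    strand <- rowsf$strand[1]
    unit_id <- paste(u$genes, collapse = "-")
    kind <- features$kind[match(u$genes[1], features$name)]
    ab <- if (kind == "rRNA") rrna_multiplier else u$abundance
    if (strand == "H") {
      tx5 <- min(rowsf$start) - u$utr5
      tx3_full <- max(rowsf$end) + u$utr3
    } else {
      tx5 <- max(rowsf$end) + u$utr5
      tx3_full <- min(rowsf$start) - u$utr3
    }
    class <- if (kind == "rRNA") "rRNA" else if (kind == "tRNA") "tRNA" else "mRNA"
    polya <- class == "mRNA"
    if (is.null(u$apa)) {
      add(unit_id, unit_id, strand, tx5, tx3_full, ab, polya, class)
    } else {
      w_canon <- 1 - sum(u$apa$weight)
      add(paste0(unit_id, ":full"), unit_id, strand, tx5, tx3_full,
          ab * w_canon, polya, class)
      for (k in seq_len(nrow(u$apa)))
        add(paste0(unit_id, ":apa", k), unit_id, strand, tx5,
            u$apa$position[k], ab * u$apa$weight[k], polya, class)
    }
  }
  for (a in program$antisense)
    add(a$id, a$id, a$strand, if (a$strand == "H") a$start else a$end,
        if (a$strand == "H") a$end else a$start, a$abundance,
        isTRUE(a$polyadenylated), "antisense")
  if (readthrough_fraction > 0) {
    for (strand in c("H", "L")) {
      rowsf <- features[features$strand == strand, , drop = FALSE]
      if (nrow(rowsf) < 2) next
      lo <- min(rowsf$start); hi <- max(rowsf$end)
      t5 <- if (strand == "H") lo else hi
      t3 <- if (strand == "H") hi else lo
      add(paste0("precursor_", strand), paste0("precursor_", strand),
          strand, t5, t3, readthrough_fraction, FALSE, "precursor")
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Simulate a paired-end read set from a transcription program
#'
#' Fragments are drawn per transcript with expected count
#' `depth x abundance x length / (2 x read_len)`, so a transcript of
#' relative abundance 1 receives mean sequenced-base coverage `depth`.
#' Fragment lengths are Gaussian; fragments whose 3' end coincides with a
#' polyadenylated transcript's 3' end carry a poly(A) soft-clip, and a small
#' fraction of fragments is 3'-anchored (oligo-dT-style bias) so such clips
#' are observable.
#'
#' @param program,features,genome from [default_program()].
#' @param depth target mean per-base sequenced coverage of an abundance-1
#'   transcript.
#' @param read_len read length (nt).
#' @param frag_mean,frag_sd fragment length distribution.
#' @param rrna_multiplier,readthrough_fraction overrides of program values.
#' @param polya_anchor_frac fraction of mRNA fragments forced to end at the
#'   transcript 3' end.
#' @param seed integer seed.
#' @return list with `fragments` (data.frame `qname`, `transcript`, `strand`,
#'   `s1`, `e1`, `s2`, `e2`, `softclip3`, `clip_pos`) and `transcripts`
#'   (the truth catalog).
#' @export
simulate_reads <- function(program, features, genome, depth = 30,
                           read_len = 50L, frag_mean = 250, frag_sd = 40,
                           rrna_multiplier = NULL,
                           readthrough_fraction = NULL,
                           polya_anchor_frac = 0.05, seed = 1L) {
  set.seed(seed)
  tx <- build_transcripts(program, features, genome,
                          rrna_multiplier = rrna_multiplier,
                          readthrough_fraction = readthrough_fraction)
  if (depth <= 0) {
    warning("depth is 0: empty read set")
    return(list(fragments = data.frame(
      qname = character(), transcript = character(), strand = character(),
      s1 = integer(), e1 = integer(), s2 = integer(), e2 = integer(),
      softclip3 = character(), clip_pos = integer(),
      stringsAsFactors = FALSE), transcripts = tx))
  }
  pmean <- program$polya_len_dist["mean"]
  psd <- program$polya_len_dist["sd"]
  frag_rows <- list()
  for (t in seq_len(nrow(tx))) {
    lam <- depth * tx$abundance[t] * tx$len[t] / (2 * read_len)
    nfrag <- stats::rpois(1, lam)
    if (nfrag == 0) next
    flen <- pmax(read_len, pmin(tx$len[t],
                                round(stats::rnorm(nfrag, frag_mean, frag_sd))))
    anchored <- tx$polyadenylated[t] &
      stats::runif(nfrag) < polya_anchor_frac
    off <- ifelse(anchored, 0L,
                  vapply(tx$len[t] - flen + 1L,
                         function(m) sample.int(m, 1L) - 1L, integer(1)))
    ## `off` is measured from the transcript 3' end for anchored fragments;
    ## draw unanchored offsets from the 5' side then convert to 3'-side
    off <- ifelse(anchored, 0L, tx$len[t] - flen - off)
    if (tx$strand[t] == "H") {
      ## fragment occupies genomic [tx3 - off - flen + 1, tx3 - off]
      fe <- tx$tx3[t] - off
      fs <- fe - flen + 1L
      s1 <- fs; e1 <- fs + read_len - 1L
      s2 <- fe - read_len + 1L; e2 <- fe
      at_end <- fe == tx$tx3[t]
      clip_pos <- tx$tx3[t]
    } else {
      fs <- tx$tx3[t] + off
      fe <- fs + flen - 1L
      s1 <- fe - read_len + 1L; e1 <- fe
      s2 <- fs; e2 <- fs + read_len - 1L
      at_end <- fs == tx$tx3[t]
      clip_pos <- tx$tx3[t]
    }
    has_clip <- at_end & tx$polyadenylated[t]
    clip <- ifelse(has_clip,
                   strrep("A", pmax(5L, round(stats::rnorm(nfrag, pmean, psd)))),
                   NA_character_)
    frag_rows[[length(frag_rows) + 1]] <- data.frame(
      transcript = tx$id[t], strand = tx$strand[t],
      s1 = s1, e1 = e1, s2 = s2, e2 = e2,
      softclip3 = clip,
      clip_pos = ifelse(has_clip, clip_pos, NA_integer_),
      stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, frag_rows)
  if (is.null(frags)) frags <- data.frame(
    transcript = character(), strand = character(), s1 = integer(),
    e1 = integer(), s2 = integer(), e2 = integer(),
    softclip3 = character(), clip_pos = integer(), stringsAsFactors = FALSE)
  frags$qname <- sprintf("frag%06d", seq_len(nrow(frags)))
  frags <- frags[, c("qname", "transcript", "strand", "s1", "e1", "s2", "e2",
                     "softclip3", "clip_pos")]
  rownames(frags) <- NULL
  list(fragments = frags, transcripts = tx)
}

#' Simulate circularized-RT junction reads
#'
#' For every unit with known ends (and every alternative polyadenylation
#' variant) emits reads of the form `[3' flank][A^k][5' flank]` in
#' transcript sense, with `k` drawn from the program's poly(A) length
#' distribution and flanks of `flank` nt. With `n_total` set, one unit's
#' variants are sampled per read by APA weight instead of emitting
#' `n_per_end` reads per variant.
#'
#' @param program,features,genome from [default_program()].
#' @param n_per_end reads per end variant.
#' @param flank flank length (nt, >= 30 recommended).
#' @param error_rate per-base substitution error rate.
#' @param n_total if not `NULL`, total reads per unit drawn by variant weight.
#' @param seed integer seed.
#' @return list with `reads` (named character vector of read sequences) and
#'   `truth` (data.frame `read`, `unit_id`, `variant`, `tx5`, `tx3`,
#'   `polya_len`, `strand`).
#' @export
simulate_junction_reads <- function(program, features, genome,
                                    n_per_end = 8L, flank = 40L,
                                    error_rate = 0, n_total = NULL,
                                    seed = 1L) {
  set.seed(seed)
  tx <- build_transcripts(program, features, genome, readthrough_fraction = 0)
  tx <- tx[tx$polyadenylated, , drop = FALSE]
  known <- vapply(tx$unit_id, function(uid) {
    u <- Filter(function(x) paste(x$genes, collapse = "-") == uid,
                program$units)
    if (length(u) == 1) u[[1]]$ends_known else TRUE  # antisense: known
  }, logical(1))
  tx <- tx[known, , drop = FALSE]
  pmean <- program$polya_len_dist["mean"]
  psd <- program$polya_len_dist["sd"]
  reads <- character(0); truth <- list()
  emit <- function(trow, idx) {
    k <- max(10L, round(stats::rnorm(1, pmean, psd)))
    if (trow$strand == "H") {
      up <- genome_segment(genome, trow$tx3 - flank + 1L, trow$tx3, "H")
      down <- genome_segment(genome, trow$tx5, trow$tx5 + flank - 1L, "H")
    } else {
      up <- genome_segment(genome, trow$tx3, trow$tx3 + flank - 1L, "L")
      down <- genome_segment(genome, trow$tx5 - flank + 1L, trow$tx5, "L")
    }
    read <- paste0(up, strrep("A", k), down)
    if (error_rate > 0) {
      chars <- strsplit(read, "")[[1]]
      hit <- stats::runif(length(chars)) < error_rate
      chars[hit] <- sample(DNA_BASES, sum(hit), replace = TRUE)
      read <- paste(chars, collapse = "")
    }
    nm <- sprintf("junc_%s_%d", gsub("[^A-Za-z0-9]", "_", trow$id), idx)
    reads[[nm]] <<- read
    truth[[length(truth) + 1]] <<- data.frame(
      read = nm, unit_id = trow$unit_id, variant = trow$id,
      tx5 = trow$tx5, tx3 = trow$tx3, polya_len = k, strand = trow$strand,
      stringsAsFactors = FALSE)
  }
  if (is.null(n_total)) {
    for (t in seq_len(nrow(tx)))
      for (r in seq_len(n_per_end)) emit(tx[t, ], r)
  } else {
    for (uid in unique(tx$unit_id)) {
      vt <- tx[tx$unit_id == uid, , drop = FALSE]
      pick <- sample.int(nrow(vt), n_total, replace = TRUE,
                         prob = vt$abundance)
      for (r in seq_len(n_total)) emit(vt[pick[r], ], r)
    }
  }
  list(reads = unlist(reads),
       truth = do.call(rbind, truth))
}

#' Synthetic congener alignment
#'
#' Builds a SYNTHETIC pairwise alignment between the replica genome and a
#' constructed congener, emulating the divergence regime of two closely
#' related soft-coral species: the congener is 12 nt shorter, the alignment
#' carries 30 gap columns (9 insertions + 21 deletions relative to the
#' reference), 9 ambiguity columns and 432 substitutions among the clean
#' columns -- i.e. 2.31% variability, 0.05% ambiguities, 0.16% gaps at the
#' reference's scale. This is a stand-in for a real two-accession alignment,
#' used to exercise [pairwise_variability()].
#'
#' @param genome the replica `circular_genome` (length 18,730).
#' @param seed integer seed for placement of the edited columns.
#' @return list `row1`, `row2` (aligned sequences) and `truth` (the exact
#'   planted counts).
#' @export
make_congener_alignment <- function(genome, seed = 1L) {
  set.seed(seed)
  s <- strsplit(genome$sequence, "")[[1]]
  n_ins <- 9L; n_del <- 21L; n_amb <- 9L; n_mis <- 432L
  N <- length(s) + n_ins
  ## row1 = reference with n_ins gap columns inserted
  ins_at <- sort(sample.int(N, n_ins))
  row1 <- character(N)
  row1[ins_at] <- "-"
  row1[setdiff(seq_len(N), ins_at)] <- s
  row2 <- row1
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  ## insertions in the congener: row2 gets a base where row1 has a gap
  row2[ins_at] <- sample(c("A", "C", "G", "T"), n_ins, replace = TRUE)
  free <- setdiff(seq_len(N), ins_at)
  pick <- sample(free, n_del + n_amb + n_mis)
  del_at <- pick[seq_len(n_del)]
  amb_at <- pick[n_del + seq_len(n_amb)]
  mis_at <- pick[n_del + n_amb + seq_len(n_mis)]
  row2[del_at] <- "-"
  row2[amb_at] <- "N"
  for (i in mis_at) row2[i] <- other(row2[i])
  list(row1 = paste(row1, collapse = ""), row2 = paste(row2, collapse = ""),
       truth = list(n_columns = N, gaps = n_ins + n_del, ambiguities = n_amb,
                    mismatches = n_mis,
                    clean = N - n_ins - n_del - n_amb,
                    congener_length = N - n_ins - n_del))
}

#' Simulate qPCR wells from true abundance ratios
#'
#' `Cq = baseline - log_E(abundance) + N(0, noise_sd)`; the control condition
#' sits at abundance 1 for every gene, the sample condition at the gene's
#' true ratio. Include the reference gene at ratio 1 in `true_ratios`.
#'
#' @param true_ratios named numeric vector of sample/control abundance ratios.
#' @param efficiency amplification factor in (1, 2].
#' @param noise_sd Gaussian Cq noise.
#' @param replicates technical replicates per condition.
#' @param baseline baseline Cq.
#' @param seed integer seed.
#' @return well data.frame as consumed by [relative_ratio()].
#' @export
simulate_cq <- function(true_ratios, efficiency = 2, noise_sd = 0.1,
                        replicates = 3L, baseline = 24, seed = 1L) {
  if (replicates < 2)
    mitotx_error("at least 2 replicates required", "mitotx_validation_error")
  set.seed(seed)
  rows <- list()
  for (g in names(true_ratios)) {
    for (cond in c("sample", "control")) {
      ab <- if (cond == "sample") true_ratios[[g]] else 1
      cq <- baseline - log(ab, base = efficiency) +
        stats::rnorm(replicates, 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        target = g, condition = cond, replicate = seq_len(replicates),
        cq = cq, efficiency = efficiency, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write simulated fragments as SAM
#'
#' Paired records with FR orientation; poly(A) soft-clips appear as terminal
#' `S` CIGAR operations with the clip bases appended to the sequence.
#'
#' @param fragments fragment table from [simulate_reads()].
#' @param genome a `circular_genome`.
#' @param path output SAM path.
#' @export
write_sam <- function(fragments, genome, path) {
  L <- genome$length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$id, L)), con)
  lines <- character(0)
  for (i in seq_len(nrow(fragments))) {
    fr <- fragments[i, ]
    for (mate in 1:2) {
      s <- if (mate == 1) fr$s1 else fr$s2
      e <- if (mate == 1) fr$e1 else fr$e2
      if (is.na(s)) next
      rev_aln <- (fr$strand == "H") == (mate == 2)
      flag <- 1L + 2L + (if (rev_aln) 16L else 32L) +
        (if (mate == 1) 64L else 128L)
      seq <- genome_segment(genome, circ_pos(s, L), circ_pos(e, L), "H")
      cigar <- sprintf("%dM", e - s + 1L)
      has_clip <- !is.na(fr$softclip3) && !is.na(fr$clip_pos) &&
        ((fr$strand == "H" && e == fr$clip_pos) ||
           (fr$strand == "L" && s == fr$clip_pos))
      if (has_clip) {
        k <- nchar(fr$softclip3)
        if (fr$strand == "H") {
          cigar <- sprintf("%dM%dS", e - s + 1L, k)
          seq <- paste0(seq, fr$softclip3)
        } else {
          cigar <- sprintf("%dS%dM", k, e - s + 1L)
          seq <- paste0(revcomp(fr$softclip3), seq)
        }
      }
      ms <- if (mate == 1) fr$s2 else fr$s1
      tlen <- if (is.na(fr$s2)) 0L else {
        sgn <- if (mate == 1) 1L else -1L
        sgn * (max(fr$e1, fr$e2, na.rm = TRUE) -
                 min(fr$s1, fr$s2, na.rm = TRUE) + 1L) *
          (if (fr$strand == "H") 1L else -1L)
      }
      lines <- c(lines, sprintf(
        "%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t%s\t%s",
        fr$qname, flag, genome$id, circ_pos(s, L), cigar,
        if (is.na(ms)) "*" else "=", if (is.na(ms)) 0L else circ_pos(ms, L),
        tlen, seq, strrep("I", nchar(seq))))
    }
  }
  writeLines(lines, con)
  invisible(NULL)
}

#' Write simulated fragments as FASTQ (mate files)
#'
#' @param fragments fragment table from [simulate_reads()].
#' @param genome a `circular_genome`.
#' @param path1,path2 output paths for mate 1 and mate 2.
#' @export
write_fastq <- function(fragments, genome, path1, path2) {
  L <- genome$length
  rec <- function(name, seq) c(paste0("@", name), seq, "+",
                               strrep("I", nchar(seq)))
  out1 <- character(0); out2 <- character(0)
  for (i in seq_len(nrow(fragments))) {
    fr <- fragments[i, ]
    seq1 <- genome_segment(genome, circ_pos(fr$s1, L), circ_pos(fr$e1, L), "H")
    if (fr$strand == "L") seq1 <- revcomp(seq1)
    out1 <- c(out1, rec(paste0(fr$qname, "/1"), seq1))
    if (!is.na(fr$s2)) {
      seq2 <- genome_segment(genome, circ_pos(fr$s2, L), circ_pos(fr$e2, L), "H")
      if (fr$strand == "H") seq2 <- revcomp(seq2)
      out2 <- c(out2, rec(paste0(fr$qname, "/2"), seq2))
    }
  }
  writeLines(out1, path1)
  writeLines(out2, path2)
  invisible(NULL)
}

#' Write the transcript truth catalog as TSV
#'
#' @param transcripts catalog from [simulate_reads()] / [build_transcripts()].
#' @param path output path.
#' @export
write_truth_tsv <- function(transcripts, path) {
  utils::write.table(transcripts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
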