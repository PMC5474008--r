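## Transcript 5'/3' end resolution from circularized-RT junction reads,
## RACE reads and poly(A)-bearing soft-clips; APA clustering, UTR
## annotation, and antisense lncRNA classification.

## Exact circular anchoring of a read segment to the genome.
## `mode = "prefix"` anchors the first `k` bases and extends rightward,
## `mode = "suffix"` the last `k` bases extending leftward. Returns genomic
## coordinates of the matched segment's terminal base in transcript sense:
## for prefix mode the first transcript base, for suffix mode the last.
anchor_segment <- function(segment, genome, k, mode = c("prefix", "suffix")) {
  mode <- match.arg(mode)
  L <- genome$length
  if (nchar(segment) < k)
    mitotx_error("segment shorter than anchor size", "mitotx_anchor_error")
  kmer <- if (mode == "prefix") substr(segment, 1, k)
          else substr(segment, nchar(segment) - k + 1, nchar(segment))
  ## circular search space: genome doubled by k - 1 bases
  subject <- Biostrings::DNAString(
    paste0(genome$sequence, substr(genome$sequence, 1, k - 1)))
  hits <- list()
  for (strand in c("H", "L")) {
    pat <- if (strand == "H") kmer else revcomp(kmer)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject)
    if (length(m) > 0) {
      starts <- circ_pos(BiocGenerics::start(m), L)
      starts <- unique(starts)
      for (s in starts) hits[[length(hits) + 1]] <- list(strand = strand, gstart = s)
    }
  }
  if (length(hits) == 0)
    mitotx_error("anchor not found in genome", "mitotx_anchor_error")
  if (length(hits) > 1)
    mitotx_error("ambiguous anchor: k-mer occurs at multiple genomic loci",
                 "mitotx_ambiguous_anchor")
  hit <- hits[[1]]
  strand <- hit$strand
  ## map the anchored k-mer to genomic positions of its first/last base in
  ## transcript sense, then extend the exact match maximally
  if (strand == "H") {
    if (mode == "prefix") {
      first_pos <- hit$gstart
      ext <- extend_match(segment, genome, first_pos, strand, from = "start")
      list(strand = strand, pos = first_pos, matched = ext)
    } else {
      last_pos <- circ_pos(hit$gstart + k - 1L, L)
      ext <- extend_match(segment, genome, last_pos, strand, from = "end")
      list(strand = strand, pos = last_pos, matched = ext)
    }
  } else {
    ## L strand: the k-mer matched as revcomp; genomic start of the match is
    ## the transcript-sense *end* of the k-mer
    if (mode == "prefix") {
      first_pos <- circ_pos(hit$gstart + k - 1L, L)
      ext <- extend_match(segment, genome, first_pos, strand, from = "start")
      list(strand = strand, pos = first_pos, matched = ext)
    } else {
      last_pos <- hit$gstart
      ext <- extend_match(segment, genome, last_pos, strand, from = "end")
      list(strand = strand, pos = last_pos, matched = ext)
    }
  }
}

## number of bases of `segment` matching the genome walking from its start
## (transcript sense) at genomic position `pos`, or from its end backwards
extend_match <- function(segment, genome, pos, strand, from) {
  L <- genome$length
  seg <- strsplit(segment, "")[[1]]
  nmatch <- 0L
  if (from == "start") {
    for (i in seq_along(seg)) {
      gp <- if (strand == "H") circ_pos(pos + i - 1L, L) else circ_pos(pos - i + 1L, L)
      gb <- substr(genome$sequence, gp, gp)
      if (strand == "L") gb <- revcomp(gb)
      if (gb != seg[i]) break
      nmatch <- i
    }
  } else {
    nseg <- length(seg)
    for (i in seq_len(nseg)) {
      gp <- if (strand == "H") circ_pos(pos - i + 1L, L) else circ_pos(pos + i - 1L, L)
      gb <- substr(genome$sequence, gp, gp)
      if (strand == "L") gb <- revcomp(gb)
      if (gb != seg[nseg - i + 1L]) break
      nmatch <- i
    }
  }
  nmatch
}

## maximal A-run in a read; returns (start, length) or NULL
longest_a_run <- function(read, min_len) {
  r <- rle(strsplit(read, "")[[1]] == "A")
  if (!any(r$values & r$lengths >= min_len)) return(NULL)
  ends <- cumsum(r$lengths)
  cand <- which(r$values & r$lengths >= min_len)
  best <- cand[which.max(r$lengths[cand])]
  list(start = ends[best] - r$lengths[best] + 1L, length = r$lengths[best])
}

#' Resolve a circularized-RT junction read into a 3' and a 5' transcript end
#'
#' A circularized transcript read has the layout
#' `[3' flank][poly(A)][5' flank]`: the first-strand cDNA crosses the
#' ligation site, so the bases upstream of the poly(A) run are the
#' transcript's 3' end and the bases downstream its 5' end. The maximal A-run
#' of length >= `min_polya` is located, the two flanks are anchored to the
#' genome by exact `anchor_k`-mer search extended maximally, and the genomic
#' coordinates of the junction are reported.
#'
#' @param read DNA string (transcript sense, Sanger-quality).
#' @param genome a `circular_genome`.
#' @param anchor_k anchor seed length for exact search.
#' @param min_polya minimal A-run length accepted as the poly(A) tract.
#' @return list with `three_prime` and `five_prime` end records
#'   (`position`, `kind`, `strand`, `method`, `polya_len`, `support`).
#' @export
resolve_crtpcr_junction <- function(read, genome, anchor_k = 15L,
                                    min_polya = 5L) {
  read <- toupper(read)
  if (nchar(read) < 2 * anchor_k + min_polya)
    mitotx_error("read too short for junction resolution", "mitotx_validation_error")
  run <- longest_a_run(read, min_polya)
  if (is.null(run))
    mitotx_error("no junction found: read has no poly(A) run",
                 "mitotx_no_junction")
  up <- substr(read, 1, run$start - 1L)
  down <- substr(read, run$start + run$length, nchar(read))
  if (nchar(up) < anchor_k || nchar(down) < anchor_k)
    mitotx_error("no junction found: flank shorter than anchor",
                 "mitotx_no_junction")
  a3 <- anchor_segment(up, genome, anchor_k, mode = "suffix")
  a5 <- anchor_segment(down, genome, anchor_k, mode = "prefix")
  if (a3$strand != a5$strand)
    mitotx_error("strand conflict between junction flanks",
                 "mitotx_strand_conflict")
  list(
    three_prime = data.frame(position = a3$pos, kind = "three_prime",
                             strand = a3$strand, method = "crtpcr",
                             polya_len = run$length, support = 1L,
                             stringsAsFactors = FALSE),
    five_prime = data.frame(position = a5$pos, kind = "five_prime",
                            strand = a5$strand, method = "crtpcr",
                            polya_len = NA_integer_, support = 1L,
                            stringsAsFactors = FALSE))
}

#' Interpret a RACE read as a transcript end
#'
#' 5' RACE reads begin with the adapter followed by the transcript 5' end;
#' 3' RACE reads end with (poly(A) +) adapter preceded by the transcript
#' 3' end. The adapter (and any A-tail on the 3' side) is stripped and the
#' remaining sequence anchored exactly.
#'
#' @param read DNA string.
#' @param genome a `circular_genome`.
#' @param adapter adapter sequence as it appears in the read.
#' @param side `"five"` or `"three"`.
#' @param anchor_k anchor seed length.
#' @return one-row end data.frame as in [resolve_crtpcr_junction()].
#' @export
interpret_race_read <- function(read, genome, adapter,
                                side = c("five", "three"), anchor_k = 15L) {
  side <- match.arg(side)
  read <- toupper(read); adapter <- toupper(adapter)
  if (side == "five") {
    if (substr(read, 1, nchar(adapter)) != adapter)
      mitotx_error("no adapter at read start", "mitotx_no_adapter")
    insert <- substr(read, nchar(adapter) + 1L, nchar(read))
    a <- anchor_segment(insert, genome, anchor_k, mode = "prefix")
    data.frame(position = a$pos, kind = "five_prime", strand = a$strand,
               method = "race", polya_len = NA_integer_, support = 1L,
               stringsAsFactors = FALSE)
  } else {
    if (substr(read, nchar(read) - nchar(adapter) + 1L, nchar(read)) != adapter)
      mitotx_error("no adapter at read end", "mitotx_no_adapter")
    insert <- substr(read, 1, nchar(read) - nchar(adapter))
    insert <- sub("A+$", "", insert)  # strip the poly(A) tract
    polya <- nchar(read) - nchar(adapter) - nchar(insert)
    a <- anchor_segment(insert, genome, anchor_k, mode = "suffix")
    data.frame(position = a$pos, kind = "three_prime", strand = a$strand,
               method = "race", polya_len = as.integer(polya), support = 1L,
               stringsAsFactors = FALSE)
  }
}

#' Call poly(A) 3' ends from alignment soft-clips
#'
#' A 3'-side soft-clip of length >= `min_clip` whose adenine fraction is at
#' least `min_a_frac` (in transcript sense; clips of reverse-mapped reads
#' carry T on the reference view and are handled by the caller supplying
#' sense-strand clip sequences) calls a 3' end at the last aligned base.
#' Identical positions are aggregated into support counts.
#'
#' @param fragments fragment table carrying `softclip3` (NA when absent) and
#'   `clip_pos` (genomic position of the last aligned base) and `strand`.
#' @param genome a `circular_genome`.
#' @param min_clip minimal clip length.
#' @param min_a_frac minimal A fraction in the clip.
#' @return data.frame of `three_prime` ends with `method = "softclip"`.
#' @export
call_polya_sites <- function(fragments, genome, min_clip = 5L,
                             min_a_frac = 0.9) {
  empty <- data.frame(position = integer(), kind = character(),
                      strand = character(), method = character(),
                      polya_len = integer(), support = integer())
  if (is.null(fragments$softclip3)) return(empty)
  sel <- !is.na(fragments$softclip3) & nchar(fragments$softclip3) >= min_clip
  if (!any(sel)) return(empty)
  fr <- fragments[sel, , drop = FALSE]
  afrac <- vapply(strsplit(toupper(fr$softclip3), ""),
                  function(x) mean(x == "A"), numeric(1))
  fr <- fr[afrac >= min_a_frac, , drop = FALSE]
  if (nrow(fr) == 0) return(empty)
  key <- paste(fr$clip_pos, fr$strand)
  agg <- stats::aggregate(list(support = rep(1L, nrow(fr)),
                               polya_len = nchar(fr$softclip3)),
                          by = list(key = key), FUN = function(x) x[1])
  agg$support <- as.integer(table(key)[agg$key])
  parts <- strsplit(agg$key, " ")
  data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
             kind = "three_prime",
             strand = vapply(parts, `[`, "", 2),
             method = "softclip",
             polya_len = as.integer(agg$polya_len),
             support = agg$support, stringsAsFactors = FALSE)
}

#' Cluster alternative polyadenylation sites
#'
#' Single-linkage clustering of 3' ends within `cluster_tol` nt. The cluster
#' representative is its highest-support member; the end codon is the genomic
#' 3-mer (sense strand) ending at the representative, and `in_frame` states
#' whether the representative falls on a codon boundary of the reading frame
#' of the gene containing it.
#'
#' @param ends data.frame of `three_prime` ends on one strand.
#' @param genome a `circular_genome`.
#' @param unit_features feature rows of the transcription unit the ends
#'   belong to (used to determine each site's reading frame).
#' @param cluster_tol single-linkage tolerance (nt).
#' @return data.frame `representative_position`, `member_positions`
#'   (comma-joined), `support`, `end_codon`, `in_frame`.
#' @export
cluster_apa <- function(ends, genome, unit_features, cluster_tol = 3L) {
  if (nrow(ends) == 0)
    return(data.frame(representative_position = integer(),
                      member_positions = character(), support = integer(),
                      end_codon = character(), in_frame = logical()))
  if (length(unique(ends$strand)) > 1)
    mitotx_error("APA ends from mixed strands", "mitotx_validation_error")
  strand <- ends$strand[1]
  agg <- stats::aggregate(list(support = ends$support),
                          by = list(position = ends$position), FUN = sum)
  agg <- agg[order(agg$position), , drop = FALSE]
  grp <- cumsum(c(1L, diff(agg$position) > cluster_tol))
  out <- list()
  for (g in unique(grp)) {
    members <- agg[grp == g, , drop = FALSE]
    rep_pos <- members$position[which.max(members$support)]
    codon <- if (strand == "H") genome_segment(genome, rep_pos - 2L, rep_pos, "H")
             else genome_segment(genome, rep_pos, rep_pos + 2L, "L")
    out[[length(out) + 1]] <- data.frame(
      representative_position = rep_pos,
      member_positions = paste(members$position, collapse = ","),
      support = sum(members$support),
      end_codon = codon,
      in_frame = apa_in_frame(rep_pos, strand, unit_features, genome$length),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## codon-boundary check: distance from the containing CDS start (transcript
## sense) to the site, inclusive, must be a multiple of 3
apa_in_frame <- function(pos, strand, unit_features, L) {
  pcg <- unit_features[unit_features$kind == "PCG", , drop = FALSE]
  for (i in seq_len(nrow(pcg))) {
    inside <- circ_len(pcg$start[i], pos, L) <= feature_length(
      pcg$start[i], pcg$end[i], pcg$wraps_origin[i], L) &&
      circ_len(pos, pcg$end[i], L) <= feature_length(
        pcg$start[i], pcg$end[i], pcg$wraps_origin[i], L)
    if (!inside) next
    dist <- if (strand == "H") circ_len(pcg$start[i], pos, L)
            else circ_len(pos, pcg$end[i], L)
    return(dist %% 3L == 0L)
  }
  NA
}

#' Annotate UTR lengths of transcription units from mapped ends
#'
#' The 5' UTR is the distance from the mapped 5' end to the unit's first
#' start codon; the 3' UTR the distance from the unit's last stop codon to
#' the mapped 3' end (pre-poly(A)). A 5' end mapped downstream of the start
#' codon is a first-class result, reported with `truncated5 = TRUE` and the
#' offset into the CDS (such truncated leaders occur naturally, e.g. a
#' messenger starting two codons into the CDS). Alternative 5' ends yield
#' multiple records.
#'
#' @param units unit table from [call_units()].
#' @param ends data.frame of mapped ends (any method).
#' @param features feature table.
#' @param genome a `circular_genome`.
#' @param margin maximal distance (nt) of a mapped end from the unit's
#'   terminal CDS boundary for it to be taken as that unit's end; keeps
#'   neighbouring units' ends and internal APA sites out of the UTR
#'   computation.
#' @return data.frame `unit_id`, `utr5_len`, `utr3_len`, `truncated5`,
#'   `trunc_offset` (NA entries where an end was not mapped).
#' @export
annotate_utrs <- function(units, ends, features, genome, margin = 150L) {
  L <- genome$length
  circ_dist <- function(a, b) pmin((a - b) %% L, (b - a) %% L)
  out <- list()
  for (i in seq_len(nrow(units))) {
    genes <- strsplit(units$genes[i], ",")[[1]]
    rows <- features[match(genes, features$name), , drop = FALSE]
    strand <- units$strand[i]
    ## transcript-sense first CDS start and last CDS end
    first_gene <- rows[1, ]; last_gene <- rows[nrow(rows), ]
    cds_start <- if (strand == "H") first_gene$start else first_gene$end
    cds_end <- if (strand == "H") last_gene$end else last_gene$start
    e5 <- ends[ends$kind == "five_prime" & ends$strand == strand &
                 circ_dist(ends$position, cds_start) <= margin, , drop = FALSE]
    e3 <- ends[ends$kind == "three_prime" & ends$strand == strand &
                 circ_dist(ends$position, cds_end) <= margin, , drop = FALSE]
    utr3 <- if (nrow(e3) > 0) {
      p3 <- e3$position[which.max(e3$support)]
      d3 <- if (strand == "H") (p3 - cds_end) %% L else (cds_end - p3) %% L
      if (d3 > L / 2) d3 - L else d3  # negative = 3' end inside the CDS
    } else NA_integer_
    if (nrow(e5) == 0) {
      out[[length(out) + 1]] <- data.frame(
        unit_id = units$unit_id[i], utr5_len = NA_integer_, utr3_len = utr3,
        truncated5 = NA, trunc_offset = NA_integer_, stringsAsFactors = FALSE)
    } else {
      for (j in seq_len(nrow(e5))) {
        p5 <- e5$position[j]
        d <- if (strand == "H") (cds_start - p5) %% L else (p5 - cds_start) %% L
        if (d > L / 2) {  # 5' end inside the CDS: truncated leader
          off <- L - d
          out[[length(out) + 1]] <- data.frame(
            unit_id = units$unit_id[i], utr5_len = NA_integer_,
            utr3_len = utr3, truncated5 = TRUE, trunc_offset = off,
            stringsAsFactors = FALSE)
        } else {
          out[[length(out) + 1]] <- data.frame(
            unit_id = units$unit_id[i], utr5_len = d, utr3_len = utr3,
            truncated5 = FALSE, trunc_offset = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Longest open reading frame of a transcript
#'
#' Scans the given sense sequence in all three frames for ATG..stop ORFs.
#'
#' @param seq transcript-sense DNA string.
#' @return length in codons (ATG up to, excluding, the stop) of the longest
#'   complete ORF; 0 when none.
#' @export
longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (frame in 0:2) {
    codons <- substring(s, seq(1 + frame, n - 2, by = 3),
                        seq(3 + frame, n, by = 3))
    if (length(codons) == 0) next
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% stops) {
        best <- max(best, i - open_at)
        open_at <- NA_integer_
      }
    }
  }
  best
}

#' Classify a transcript as an antisense long noncoding RNA
#'
#' The call requires all four criteria: length > 200 nt, polyadenylated,
#' longest ORF below `orf_threshold` codons, and at least
#' `min_antisense_overlap` of the transcript overlapping a gene annotated on
#' the opposite strand.
#'
#' @param interval list/data.frame with `start`, `end`, `strand` of the
#'   transcript (1-based inclusive, `strand` is the transcript's strand).
#' @param polyadenylated logical.
#' @param genome a `circular_genome`.
#' @param features feature table.
#' @param orf_threshold maximal ORF length (codons) still called noncoding.
#' @param min_antisense_overlap minimal overlapped fraction of the transcript.
#' @return list with `called` (logical), `antisense_of`, `length`,
#'   `longest_orf_codons`, `polyadenylated` and per-criterion flags.
#' @export
classify_lncrna <- function(interval, polyadenylated, genome, features,
                            orf_threshold = 50L, min_antisense_overlap = 0.5) {
  L <- genome$length
  len <- circ_len(interval$start, interval$end, L)
  txseq <- genome_segment(genome, interval$start, interval$end,
                          strand = interval$strand)
  orf <- longest_orf(txseq)
  opp <- features[features$strand != interval$strand, , drop = FALSE]
  best_ov <- 0L; best_gene <- NA_character_
  for (i in seq_len(nrow(opp))) {
    ov <- interval_overlap(interval$start, interval$start + len - 1L,
                           opp$start[i], opp$end[i], L)
    if (ov > best_ov) { best_ov <- ov; best_gene <- opp$name[i] }
  }
  crit <- list(length_gt_200 = len > 200L,
               polyadenylated = isTRUE(polyadenylated),
               no_orf = orf < orf_threshold,
               antisense = best_ov / len >= min_antisense_overlap)
  list(called = all(unlist(crit)),
       antisense_of = if (crit$antisense) best_gene else NA_character_,
       length = len, longest_orf_codons = orf,
       polyadenylated = isTRUE(polyadenylated), criteria = crit)
}
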