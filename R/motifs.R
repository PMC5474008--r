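## Stem-loop (hairpin) detection by perfect inverted-repeat search, shared
## motif discovery across intergenic regions, and control-region prediction.

BASE_PAIRS <- c(A = "T", T = "A", G = "C", C = "G")

## can x pair with y? Watson-Crick plus the G.U wobble (T plays U on DNA)
can_pair <- function(x, y) {
  (BASE_PAIRS[x] == y) | (x == "G" & y == "T") | (x == "T" & y == "G")
}

#' Find stem-loop structures as perfect inverted repeats
#'
#' Enumerates all maximal perfect inverted repeats: a run of `stem_len`
#' consecutive base pairs (Watson-Crick or G.U) enclosing a loop of
#' `loop_min`..`loop_max` unpaired nt. Maximality means the stem cannot be
#' extended outward by another pairing position. Overlapping hairpins are
#' deduplicated to the longest stem per start position. Stability is
#' operationalized purely by stem/loop geometry, not folding energy.
#'
#' @param sequence DNA string.
#' @param min_stem minimal stem length (bp).
#' @param loop_min,loop_max allowed loop length range (nt).
#' @return data.frame `start` (1-based, first stem base), `stem_len`,
#'   `loop_len`, `end` (last base of the closing stem arm).
#' @export
find_hairpins <- function(sequence, min_stem = 6L, loop_min = 3L,
                          loop_max = 30L) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  empty <- data.frame(start = integer(), stem_len = integer(),
                      loop_len = integer(), end = integer())
  if (n < 2 * min_stem + loop_min) return(empty)
  out <- list()
  ## (i, j) = outermost candidate pair; extend inward while pairing holds
  for (i in seq_len(n - 2 * min_stem - loop_min + 1L)) {
    jmin <- i + 2 * min_stem + loop_min - 1L
    if (jmin > n) next
    for (j in seq.int(jmin, n)) {
      if (!can_pair(s[i], s[j])) next
      ## outward maximality
      if (i > 1 && j < n && can_pair(s[i - 1L], s[j + 1L])) next
      k <- 1L
      while (i + k <= j - k && can_pair(s[i + k], s[j - k])) k <- k + 1L
      stem <- k
      loop <- j - i + 1L - 2L * stem
      ## shrink the stem if the loop came out too short
      while (stem > 0 && loop < loop_min) { stem <- stem - 1L; loop <- loop + 2L }
      if (stem >= min_stem && loop >= loop_min && loop <= loop_max) {
        out[[length(out) + 1]] <- data.frame(start = i, stem_len = stem,
                                             loop_len = loop, end = j)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, -res$stem_len), , drop = FALSE]
  res <- res[!duplicated(res$start), , drop = FALSE]  # longest stem per start
  rownames(res) <- NULL
  res
}

#' Shared exact motifs across intergenic regions
#'
#' For each k in `k_range` (descending), finds k-mers occurring exactly in at
#' least `min_igrs` of the given IGR sequences, reporting maximal hits only:
#' a k-mer that is a substring of a longer reported motif shared by the same
#' IGR set is suppressed.
#'
#' @param igr_sequences named character vector of IGR sequences.
#' @param k_range integer vector `c(kmin, kmax)`.
#' @param min_igrs minimal number of IGRs a motif must occur in.
#' @param revcomp_too also count occurrences on the reverse complement.
#' @return data.frame `kmer`, `k`, `n_igrs`, `igr_names` (comma-joined).
#' @export
shared_igr_motifs <- function(igr_sequences, k_range = c(8L, 15L),
                              min_igrs = 3L, revcomp_too = FALSE) {
  if (length(igr_sequences) < min_igrs)
    mitotx_error("fewer IGR sequences than min_igrs", "mitotx_validation_error")
  seqs <- toupper(igr_sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("igr", seq_along(seqs))
  empty <- data.frame(kmer = character(), k = integer(), n_igrs = integer(),
                      igr_names = character(), stringsAsFactors = FALSE)
  hits <- list()
  for (k in seq(max(k_range), min(k_range))) {
    kmer_sets <- lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      km <- substring(s, 1:(n - k + 1), k:n)
      if (revcomp_too) km <- c(km, vapply(km, revcomp, ""))
      unique(km)
    })
    tab <- table(unlist(kmer_sets))
    shared <- names(tab)[tab >= min_igrs]
    for (m in shared) {
      igrs <- names(seqs)[vapply(kmer_sets, function(x) m %in% x, logical(1))]
      ## suppress if substring of an already-reported longer motif with the
      ## same IGR set
      redundant <- any(vapply(hits, function(h)
        grepl(m, h$kmer, fixed = TRUE) &&
          setequal(strsplit(h$igr_names, ",")[[1]], igrs), logical(1)))
      if (!redundant)
        hits[[length(hits) + 1]] <- data.frame(
          kmer = m, k = k, n_igrs = length(igrs),
          igr_names = paste(sort(igrs), collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) return(empty)
  res <- do.call(rbind, hits)
  res <- res[order(-res$k, res$kmer), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict control regions among intergenic regions
#'
#' Scores each IGR on four criteria: absent RNA-seq coverage (at least
#' `min_zero_frac` of IGR positions at zero depth -- UTR tails of flanking
#' transcripts may cover the IGR edges without making it a transcribed
#' region), presence of a stem-loop structure, inversion of polarities (the
#' flanking genes lie on opposite strands), and presence of a motif shared
#' with other IGRs. An IGR is called a control region when at least
#' `min_criteria` of the four hold (default: all four).
#'
#' @param igrs IGR table from [igr_table()].
#' @param profile a `coverage_profile`.
#' @param features feature table.
#' @param genome a `circular_genome`.
#' @param min_criteria how many of the four criteria must hold.
#' @param min_zero_frac minimal fraction of zero-depth IGR positions for the
#'   coverage criterion.
#' @param min_stem,loop_min,loop_max hairpin geometry, see [find_hairpins()].
#' @param k_range,min_igrs motif parameters, see [shared_igr_motifs()].
#' @return data.frame with per-IGR criterion flags and `called`.
#' @export
predict_control_region <- function(igrs, profile, features, genome,
                                   min_criteria = 4L, min_zero_frac = 0.9,
                                   min_stem = 6L, loop_min = 3L,
                                   loop_max = 30L, k_range = c(8L, 15L),
                                   min_igrs = 3L) {
  L <- genome$length
  real <- igrs[!is.na(igrs$start) & igrs$length > 0, , drop = FALSE]
  seqs <- vapply(seq_len(nrow(real)), function(i)
    genome_segment(genome, real$start[i], real$end[i], "H"), "")
  names(seqs) <- paste0(real$left_gene, "_", real$right_gene)
  motifs <- if (nrow(real) >= min_igrs)
    shared_igr_motifs(seqs, k_range = k_range, min_igrs = min_igrs)
  else data.frame(kmer = character(), igr_names = character())
  comb <- profile$depth_H + profile$depth_L
  out <- list()
  for (i in seq_len(nrow(real))) {
    pos <- circ_span(real$start[i], real$length[i], L)
    zero_cov <- mean(comb[pos] == 0) >= min_zero_frac
    hp <- find_hairpins(seqs[i], min_stem = min_stem,
                        loop_min = loop_min, loop_max = loop_max)
    strand_l <- features$strand[match(real$left_gene[i], features$name)]
    strand_r <- features$strand[match(real$right_gene[i], features$name)]
    inversion <- !is.na(strand_l) && !is.na(strand_r) && strand_l != strand_r
    motif_here <- nrow(motifs) > 0 && any(vapply(
      motifs$igr_names, function(x)
        names(seqs)[i] %in% strsplit(x, ",")[[1]], logical(1)))
    flags <- c(zero_coverage = zero_cov, has_hairpin = nrow(hp) > 0,
               polarity_inversion = inversion, motif_present = motif_here)
    out[[length(out) + 1]] <- data.frame(
      igr = names(seqs)[i], left_gene = real$left_gene[i],
      right_gene = real$right_gene[i], start = real$start[i],
      end = real$end[i], length = real$length[i],
      zero_coverage = zero_cov, has_hairpin = nrow(hp) > 0,
      polarity_inversion = inversion, motif_present = motif_here,
      n_criteria = sum(flags), called = sum(flags) >= min_criteria,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
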