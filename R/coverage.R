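## Strand-specific per-position read depth on the circular genome, the
## log-scale normalization used for display, zero-coverage segment detection
## and abrupt-drop breakpoint detection.

#' Per-position, per-strand read depth
#'
#' Accepts either a fragment table produced by [simulate_reads()] (columns
#' `strand`, `s1`, `e1` and optionally `s2`, `e2`; coordinates may run past
#' `L`, in which case they wrap the origin) or a path to a SAM/BAM file, read
#' via Rsamtools/GenomicAlignments (unmapped and secondary records are
#' dropped; deletions and skips in the CIGAR do not add depth).
#'
#' For alignment files the strand of transcription is protocol-dependent:
#' `protocol = "fr-firststrand"` assigns a pair to the strand opposite its
#' first mate, `"fr-secondstrand"` to the first mate's strand, and
#' `"unstranded"` (default; the kind of library the method was designed
#' around) takes the alignment strand at face value, `+` counting as H.
#'
#' @param x fragment data.frame or SAM/BAM path.
#' @param genome a `circular_genome`.
#' @param protocol library strandedness; see Details.
#' @return object of class `coverage_profile`: list with `genome_id`,
#'   integer vectors `depth_H`, `depth_L` of length `L`.
#' @export
compute_coverage <- function(x, genome,
                             protocol = c("unstranded", "fr-firststrand",
                                          "fr-secondstrand")) {
  protocol <- match.arg(protocol)
  L <- genome$length
  depth <- list(H = integer(L), L = integer(L))
  if (is.character(x)) {
    ivs <- read_alignment_intervals(x, genome, protocol)
  } else {
    ivs <- fragment_intervals(x)
  }
  for (strand in c("H", "L")) {
    sel <- ivs$strand == strand
    if (!any(sel)) next
    pos <- sequence(ivs$end[sel] - ivs$start[sel] + 1L, from = ivs$start[sel])
    pos <- circ_pos(pos, L)
    depth[[strand]] <- depth[[strand]] + tabulate(pos, nbins = L)
  }
  structure(list(genome_id = genome$id, depth_H = depth$H, depth_L = depth$L),
            class = "coverage_profile")
}

## Fragment table -> one interval per sequenced mate
fragment_intervals <- function(frags) {
  s <- c(frags$s1, if (!is.null(frags$s2)) frags$s2[!is.na(frags$s2)])
  e <- c(frags$e1, if (!is.null(frags$e2)) frags$e2[!is.na(frags$s2)])
  st <- c(frags$strand, if (!is.null(frags$s2)) frags$strand[!is.na(frags$s2)])
  list(start = s, end = e, strand = st)
}

read_alignment_intervals <- function(path, genome, protocol) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE),
      what = "flag"))
  ref_len <- GenomeInfoDb::seqlengths(gal)[1]
  if (!is.na(ref_len) && ref_len != genome$length)
    mitotx_error(sprintf(
      "alignment reference length (%d) differs from genome length (%d)",
      ref_len, genome$length), "mitotx_validation_error")
  ## per-record aligned blocks (CIGAR M segments; D/N excluded)
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(gal), pos = BiocGenerics::start(gal), ops = "M")
  aln_strand <- as.character(BiocGenerics::strand(gal))
  flag <- S4Vectors::mcols(gal)$flag
  first_mate <- bitwAnd(flag, 64L) > 0L
  strand_tx <- switch(protocol,
    "unstranded" = ifelse(aln_strand == "+", "H", "L"),
    "fr-secondstrand" = ifelse(xor(aln_strand == "+", !first_mate), "H", "L"),
    "fr-firststrand" = ifelse(xor(aln_strand == "+", first_mate), "H", "L"))
  starts <- unlist(IRanges::start(blocks))
  ends <- unlist(IRanges::end(blocks))
  reps <- lengths(blocks)
  list(start = starts, end = ends, strand = rep(strand_tx, reps))
}

#' Log-scale coverage normalization
#'
#' `out[i] = log(depth[i] + 1) / log(max_depth + 1)` per strand: 1 at the
#' deepest position, 0 where raw coverage is 0, invariant to the logarithm
#' base. The mean coverage level is reported both on the raw depth scale and
#' mapped through the same transform.
#'
#' @param profile a `coverage_profile`.
#' @return list with per-strand `values` in `[0, 1]`, `mean_raw` and
#'   `mean_level` (the raw mean pushed through the normalization).
#' @export
normalize_log <- function(profile) {
  out <- list()
  for (strand in c("H", "L")) {
    d <- profile[[paste0("depth_", strand)]]
    m <- max(d)
    if (m < 1) {
      warning("all-zero coverage profile on strand ", strand)
      vals <- rep(0, length(d))
    } else {
      vals <- log(d + 1) / log(m + 1)
    }
    out[[strand]] <- list(values = vals, mean_raw = mean(d),
                          mean_level = if (m < 1) 0 else
                            log(mean(d) + 1) / log(m + 1))
  }
  out
}

#' Maximal zero-coverage segments
#'
#' Runs of zero combined-strand depth of length at least `min_len`, merged
#' circularly across the origin.
#'
#' @param profile a `coverage_profile`.
#' @param min_len minimal segment length to report.
#' @return data.frame `start`, `end`, `length` (end < start means the segment
#'   wraps the origin).
#' @export
zero_coverage_segments <- function(profile, min_len = 1L) {
  if (min_len < 1) mitotx_error("min_len must be >= 1", "mitotx_validation_error")
  comb <- profile$depth_H + profile$depth_L
  L <- length(comb)
  z <- comb == 0
  if (!any(z)) return(data.frame(start = integer(), end = integer(),
                                 length = integer()))
  if (all(z)) return(data.frame(start = 1L, end = L, length = L))
  ## rotate so position 1 is covered, then take linear runs
  shift <- which(!z)[1] - 1L
  zr <- z[circ_pos(seq_len(L) + shift, L)]
  r <- rle(zr)
  ends_r <- cumsum(r$lengths)
  starts_r <- ends_r - r$lengths + 1L
  keep <- r$values
  segs <- data.frame(start = circ_pos(starts_r[keep] + shift, L),
                     end = circ_pos(ends_r[keep] + shift, L),
                     length = r$lengths[keep])
  segs <- segs[segs$length >= min_len, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Abrupt coverage-change breakpoints
#'
#' Scores every position by the ratio of the median depths of its two
#' flanking windows (medians resist single-read spikes) and reports positions
#' where the ratio reaches `min_ratio`, deduplicated to local ratio maxima.
#' The position reported is the first position of the right flank, i.e. the
#' base at which the new level starts.
#'
#' @param profile a `coverage_profile`.
#' @param window flank width in nt (default 50, about one read length).
#' @param min_ratio minimal max/min flank-median ratio.
#' @return data.frame `position`, `strand`, `drop_ratio`, `direction`
#'   (`fall` when the left flank is higher).
#' @export
find_breakpoints <- function(profile, window = 50L, min_ratio = 5) {
  if (window < 5) mitotx_error("window must be >= 5", "mitotx_validation_error")
  out <- list()
  for (strand in c("H", "L")) {
    d <- profile[[paste0("depth_", strand)]]
    L <- length(d)
    if (max(d) == 0) next
    dd <- c(d, d)  # unrolled circle for window lookups
    left_med <- right_med <- numeric(L)
    for (i in seq_len(L)) {
      left_med[i] <- stats::median(dd[(i + L - window):(i + L - 1)])
      right_med[i] <- stats::median(dd[(i + L):(i + L + window - 1)])
    }
    hi <- pmax(left_med, right_med)
    lo <- pmax(1, pmin(left_med, right_med))
    ratio <- hi / lo
    cand <- which(ratio >= min_ratio)
    if (length(cand) == 0) next
    ## dedupe: consecutive candidate runs collapse to their ratio argmax
    grp <- cumsum(c(1L, diff(cand) > 1L))
    for (g in unique(grp)) {
      idx <- cand[grp == g]
      ## the ratio is flat over a plateau of ~window positions around a
      ## clean step; its center is the change point, so break ties there
      mx <- max(ratio[idx])
      ties <- idx[ratio[idx] >= mx * (1 - 1e-9)]
      best <- ties[ceiling(length(ties) / 2)]
      out[[length(out) + 1]] <- data.frame(
        position = best, strand = strand, drop_ratio = ratio[best],
        direction = if (left_med[best] > right_med[best]) "fall" else "rise",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(position = integer(), strand = character(),
                      drop_ratio = numeric(), direction = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Coverage track plot
#'
#' Normalized log-scale coverage with a mean-level indicator and gene blocks,
#' one panel per strand.
#'
#' @param profile a `coverage_profile`.
#' @param features optional feature table drawn as blocks under the track.
#' @param main plot title.
#' @export
plot_coverage <- function(profile, features = NULL, main = profile$genome_id) {
  norm <- suppressWarnings(normalize_log(profile))
  old <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (strand in c("H", "L")) {
    v <- norm[[strand]]$values
    graphics::plot(v, type = "h", col = "grey40", ylim = c(-0.15, 1),
                   ylab = sprintf("log-normalized depth (%s)", strand),
                   xlab = "", main = if (strand == "H") main else "")
    graphics::abline(h = norm[[strand]]$mean_level, col = "blue", lty = 2)
    if (!is.null(features)) {
      sel <- features$strand == strand
      if (any(sel))
        graphics::rect(features$start[sel], -0.12, features$end[sel], -0.04,
                       col = ifelse(features$kind[sel] == "rRNA", "red", "darkgreen"),
                       border = NA)
    }
  }
  invisible(NULL)
}

#' Write per-position coverage as bedGraph
#'
#' @param profile a `coverage_profile`.
#' @param path output path; two tracks (H then L) separated by track lines.
#' @export
write_bedgraph <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (strand in c("H", "L")) {
    d <- profile[[paste0("depth_", strand)]]
    writeLines(sprintf("track type=bedGraph name=\"%s_%s\"",
                       profile$genome_id, strand), con)
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%d", profile$genome_id,
                       starts, ends, r$values), con)
  }
  invisible(NULL)
}
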