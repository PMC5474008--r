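## Shared fixtures, memoized per test session (the replica genome and the
## closed-loop pipeline run are reused by several files).

.fixture_cache <- new.env(parent = emptyenv())

arrangement_a <- function() {
  if (is.null(.fixture_cache$bundle))
    .fixture_cache$bundle <- default_program("A", seed = 1)
  .fixture_cache$bundle
}

closed_loop_report <- function() {
  if (is.null(.fixture_cache$report))
    .fixture_cache$report <- run_all(run_config(seed = 42,
                                                readthrough_fraction = 0))
  .fixture_cache$report
}

toy_genome <- function(seed = 7, len = 600) {
  set.seed(seed)
  circular_genome("toy", paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}

## random non-pathological circular annotation: adjacent-only overlaps,
## every gene longer than any overlap
random_annotation <- function(seed, n_genes = 6) {
  set.seed(seed)
  lens <- sample(50:150, n_genes, replace = TRUE)
  gaps <- sample(-20:60, n_genes - 1, replace = TRUE)
  final_gap <- sample(0:60, 1)
  start <- 1L
  starts <- integer(n_genes); ends <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    starts[i] <- start
    ends[i] <- start + lens[i] - 1L
    if (i < n_genes) start <- ends[i] + gaps[i] + 1L
  }
  L <- ends[n_genes] + final_gap
  ft <- data.frame(name = paste0("g", seq_len(n_genes)), kind = "PCG",
                   strand = "H", start = starts, end = ends,
                   wraps_origin = FALSE, stringsAsFactors = FALSE)
  set.seed(seed + 1)
  genome <- circular_genome("rand", paste(
    sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  list(genome = genome, features = gene_features(ft, genome))
}

## independent occupancy-array oracle for IGRs and overlaps
occupancy_oracle <- function(genome, features) {
  L <- genome$length
  cov <- integer(L)
  for (i in seq_len(nrow(features))) {
    len <- (features$end[i] - features$start[i]) %% L + 1L
    pos <- ((features$start[i] - 1L + seq_len(len) - 1L) %% L) + 1L
    cov[pos] <- cov[pos] + 1L
  }
  runs_of <- function(flag) {
    if (!any(flag)) return(integer(0))
    if (all(flag)) return(L)
    shift <- which(!flag)[1] - 1L
    fr <- flag[((seq_len(L) + shift - 1L) %% L) + 1L]
    r <- rle(fr)
    r$lengths[r$values]
  }
  list(igr_lengths = sort(runs_of(cov == 0)),
       overlap_lengths = sort(runs_of(cov >= 2)))
}

## exhaustive inverted-repeat oracle (definition-level reimplementation)
hairpin_oracle <- function(sequence, min_stem = 6, loop_min = 3,
                           loop_max = 30) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  pairs <- function(x, y)
    (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G") |
    (x == "G" & y == "T") | (x == "T" & y == "G")
  hits <- list()
  for (i in seq_len(n)) for (stem in min_stem:floor(n / 2)) {
    for (loop in loop_min:loop_max) {
      j <- i + 2 * stem + loop - 1L
      if (j > n) next
      ok <- all(vapply(0:(stem - 1), function(k)
        pairs(s[i + k], s[j - k]), logical(1)))
      if (!ok) next
      ## inward maximality: cannot grow the stem while loop >= loop_min
      grow_in <- loop - 2 >= loop_min && pairs(s[i + stem], s[j - stem])
      ## outward maximality
      grow_out <- i > 1 && j < n && pairs(s[i - 1], s[j + 1])
      if (grow_in || grow_out) next
      hits[[length(hits) + 1]] <- data.frame(start = i, stem_len = stem,
                                             loop_len = loop, end = j)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), stem_len = integer(),
                      loop_len = integer(), end = integer()))
  res <- do.call(rbind, hits)
  res <- res[order(res$start, -res$stem_len), , drop = FALSE]
  res <- res[!duplicated(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## brute-force shared k-mer oracle
motif_oracle <- function(seqs, k_range = c(8, 15), min_igrs = 3) {
  if (is.null(names(seqs))) names(seqs) <- paste0("igr", seq_along(seqs))
  found <- list()
  for (k in seq(max(k_range), min(k_range))) {
    sets <- lapply(toupper(seqs), function(s) {
      if (nchar(s) < k) return(character(0))
      unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
    })
    all_k <- unique(unlist(sets))
    for (m in all_k) {
      members <- names(seqs)[vapply(sets, function(x) m %in% x, logical(1))]
      if (length(members) < min_igrs) next
      redundant <- any(vapply(found, function(f)
        grepl(m, f$kmer, fixed = TRUE) && setequal(f$members, members),
        logical(1)))
      if (!redundant)
        found[[length(found) + 1]] <- list(kmer = m, members = members)
    }
  }
  found
}
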