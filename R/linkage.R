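## Transcription-unit calling from IGR-spanning read pairs, with
## discrimination of genuine mature polycistrons from low-abundance
## precursor read-through.

## Circular interval overlap (intervals may be stored unwrapped, end > L)
interval_overlap <- function(as, ae, bs, be, L) {
  ov <- pmax(0L, pmin(ae, be) - pmax(as, bs) + 1L)
  for (shift in c(-L, L)) {
    ov <- pmax(ov, pmax(0L, pmin(ae + shift, be) - pmax(as + shift, bs) + 1L))
  }
  ov
}

#' Read-pair linkage evidence across same-strand gene adjacencies
#'
#' For every pair of genes adjacent in circular genome order on the same
#' strand, counts fragments that span the intergenic region: either one mate
#' overlapping each gene by at least `min_overlap` nt, or a single read
#' overlapping both genes. Attaches IGR and flanking depth statistics used
#' downstream to discriminate precursor read-through, plus the number of
#' spanning fragments expected if the two genes were co-transcribed at the
#' lesser flank's coverage.
#'
#' @param fragments fragment table (`strand`, `s1`, `e1`, `s2`, `e2`).
#' @param features validated feature table.
#' @param genome a `circular_genome`.
#' @param profile optional precomputed `coverage_profile`; computed from the
#'   fragments when absent.
#' @param min_overlap minimal per-gene overlap of a mate to count (nt).
#' @return data.frame with one row per same-strand adjacency: `gene_a`,
#'   `gene_b` (transcription order), `strand`, `igr_len`, `n_spanning`,
#'   `igr_median_depth`, `flank_depth_ratio`, `min_flank_depth`,
#'   `expected_spanning`.
#' @export
collect_linkage <- function(fragments, features, genome, profile = NULL,
                            min_overlap = 1L) {
  L <- genome$length
  ft <- features[order(features$start), , drop = FALSE]
  if (is.null(profile)) profile <- compute_coverage(fragments, genome)
  n <- nrow(ft)

  paired <- !is.null(fragments$s2) && any(!is.na(fragments$s2))
  read_len <- if (nrow(fragments) > 0) mean(fragments$e1 - fragments$s1 + 1) else 50
  span_len <- if (nrow(fragments) > 0) {
    if (paired) mean(ifelse(is.na(fragments$e2), fragments$e1, fragments$e2) -
                       fragments$s1 + 1)
    else read_len
  } else 2 * read_len

  rows <- list()
  for (i in seq_len(n)) {
    a <- ft[i, ]; b <- ft[if (i == n) 1L else i + 1L, ]
    if (a$strand != b$strand) next
    strand <- a$strand
    igr_len <- circ_gap(a$end, b$start, L)
    ovl <- (a$end - b$start + 1L) %% L
    if (ovl >= 1 && ovl <= min(feature_length(a$start, a$end, a$wraps_origin, L),
                               feature_length(b$start, b$end, b$wraps_origin, L)))
      igr_len <- 0L

    sel <- fragments$strand == strand
    fr <- fragments[sel, , drop = FALSE]
    if (nrow(fr) > 0) {
      ov1a <- interval_overlap(fr$s1, fr$e1, a$start, a$end, L)
      ov1b <- interval_overlap(fr$s1, fr$e1, b$start, b$end, L)
      if (paired && !is.null(fr$s2)) {
        s2 <- ifelse(is.na(fr$s2), fr$s1, fr$s2)
        e2 <- ifelse(is.na(fr$e2), fr$e1, fr$e2)
        ov2a <- interval_overlap(s2, e2, a$start, a$end, L)
        ov2b <- interval_overlap(s2, e2, b$start, b$end, L)
      } else { ov2a <- ov1a; ov2b <- ov1b }
      spanning <- (ov1a >= min_overlap & ov2b >= min_overlap) |
                  (ov2a >= min_overlap & ov1b >= min_overlap) |
                  (ov1a >= min_overlap & ov1b >= min_overlap)
      n_spanning <- sum(spanning)
    } else n_spanning <- 0L

    d <- profile[[paste0("depth_", strand)]]
    igr_med <- if (igr_len > 0)
      stats::median(d[circ_span(circ_pos(a$end + 1L, L), igr_len, L)]) else NA_real_
    ## whole-gene medians: coverage ramps up over a fragment length at
    ## transcript edges, so narrow windows next to the IGR understate the
    ## expression-level difference the discrimination relies on
    med_a <- stats::median(d[circ_span(a$start,
      feature_length(a$start, a$end, a$wraps_origin, L), L)])
    med_b <- stats::median(d[circ_span(b$start,
      feature_length(b$start, b$end, b$wraps_origin, L), L)])
    ratio <- max(med_a, med_b) / max(1, min(med_a, med_b))
    min_flank <- min(med_a, med_b)
    expected <- min_flank * max(0, span_len - igr_len - 1) / (2 * read_len)

    ## transcription order: H pairs read left-to-right, L pairs right-to-left
    ga <- if (strand == "H") a$name else b$name
    gb <- if (strand == "H") b$name else a$name
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = ga, gene_b = gb, strand = strand, igr_len = igr_len,
      n_spanning = n_spanning, igr_median_depth = igr_med,
      flank_depth_ratio = ratio, min_flank_depth = min_flank,
      expected_spanning = expected, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Call transcription units from linkage evidence
#'
#' Adjacencies with `n_spanning >= min_support` are joined into units. A
#' joined adjacency is demoted to precursor read-through -- the units stay
#' split and the adjacency is flagged -- when the coverage levels on its two
#' flanks differ by at least `precursor_ratio` (or a breakpoint of that ratio
#' falls in the IGR) and its spanning support is no more than
#' `max(precursor_max_support, expected_spanning / precursor_ratio)`. The
#' expected-spanning term makes the support cap depth-adaptive: at sparse
#' coverage it reduces to the constant cap, at deep coverage a genuine
#' polycistron yields far more spanning pairs than any precursor.
#'
#' tRNA genes act as punctuation: adjacencies involving a tRNA are never
#' joined. Adjacencies across strand switches do not exist in the linkage
#' table (polycistrons are single-strand).
#'
#' @param linkage output of [collect_linkage()].
#' @param breakpoints optional [find_breakpoints()] output for corroboration.
#' @param features validated feature table.
#' @param min_support minimal spanning-fragment count to join.
#' @param precursor_ratio flank depth ratio at and above which a weakly
#'   supported junction is considered read-through.
#' @param precursor_max_support floor of the demotion support cap.
#' @return list with `units` (data.frame `unit_id`, `genes` in transcription
#'   order, `strand`, `n_genes`, `n_cistrons`, `status`) and `adjacencies`
#'   (per-adjacency join/demotion record).
#' @export
call_units <- function(linkage, breakpoints = NULL, features,
                       min_support = 1L, precursor_ratio = 10,
                       precursor_max_support = 2L) {
  ft <- features[order(features$start), , drop = FALSE]
  L_names <- ft$name
  n <- nrow(ft)

  adj <- linkage
  adj$joined <- FALSE
  adj$status <- "unlinked"
  for (i in seq_len(nrow(adj))) {
    if (adj$n_spanning[i] < min_support) next
    ka <- ft$kind[match(adj$gene_a[i], ft$name)]
    kb <- ft$kind[match(adj$gene_b[i], ft$name)]
    if (ka == "tRNA" || kb == "tRNA") { adj$status[i] <- "trna_boundary"; next }
    discont <- adj$flank_depth_ratio[i] >= precursor_ratio
    if (!discont && !is.null(breakpoints) && nrow(breakpoints) > 0 &&
        adj$igr_len[i] > 0) {
      ## breakpoint inside this adjacency's IGR on the right strand
      a_row <- ft[match(adj$gene_a[i], ft$name), ]
      b_row <- ft[match(adj$gene_b[i], ft$name), ]
      lo <- min(a_row$end, b_row$end); hi <- max(a_row$start, b_row$start)
      sel <- breakpoints$strand == adj$strand[i] &
        breakpoints$position > lo & breakpoints$position < hi &
        breakpoints$drop_ratio >= precursor_ratio
      discont <- any(sel)
    }
    cap <- max(precursor_max_support,
               adj$expected_spanning[i] / precursor_ratio)
    if (discont && adj$n_spanning[i] <= cap) {
      adj$status[i] <- "precursor_readthrough"
    } else {
      adj$joined[i] <- TRUE
      adj$status[i] <- "mature"
    }
  }

  ## merge genes along joined adjacencies (union-find over genome order)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in which(adj$joined)) {
    ia <- match(adj$gene_a[i], L_names); ib <- match(adj$gene_b[i], L_names)
    ra <- find(ia); rb <- find(ib)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(seq_len(n), find, integer(1))

  units <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    members <- ft[idx, , drop = FALSE]
    strand <- members$strand[1]
    ord <- order(members$start)
    if (strand == "L") ord <- rev(ord)  # transcription order
    genes <- members$name[ord]
    units[[length(units) + 1]] <- data.frame(
      unit_id = paste(genes, collapse = "-"),
      genes = paste(genes, collapse = ","),
      strand = strand, n_genes = length(genes),
      n_cistrons = sum(members$kind == "PCG"),
      status = "mature", stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, units)
  rownames(units) <- NULL
  list(units = units, adjacencies = adj)
}

#' Summarize called units
#'
#' @param units unit table from [call_units()].
#' @return list with counts of mono-, bi- and tricistronic PCG units, number
#'   of polycistronic units and PCGs contained in polycistrons.
#' @export
classify_units <- function(units) {
  pcg_units <- units[units$n_cistrons > 0, , drop = FALSE]
  list(n_units = nrow(units),
       n_pcg_units = nrow(pcg_units),
       n_monocistronic = sum(pcg_units$n_cistrons == 1),
       n_bicistronic = sum(pcg_units$n_cistrons == 2),
       n_tricistronic = sum(pcg_units$n_cistrons == 3),
       n_polycistronic = sum(pcg_units$n_cistrons >= 2),
       pcgs_in_polycistrons = sum(pcg_units$n_cistrons[pcg_units$n_cistrons >= 2]))
}

#' Write units as GFF3
#'
#' @param units unit table from [call_units()].
#' @param features feature table (for unit coordinates).
#' @param genome a `circular_genome`.
#' @param path output path.
#' @export
write_units_gff3 <- function(units, features, genome, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(units))) {
    genes <- strsplit(units$genes[i], ",")[[1]]
    rows <- features[features$name %in% genes, , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tmitotx\ttranscription_unit\t%d\t%d\t.\t%s\t.\tID=%s;genes=%s;cistrons=%d;status=%s",
      genome$id, min(rows$start), max(rows$end),
      if (units$strand[i] == "H") "+" else "-",
      units$unit_id[i], units$genes[i], units$n_cistrons[i], units$status[i]))
  }
  writeLines(lines, path)
  invisible(NULL)
}
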