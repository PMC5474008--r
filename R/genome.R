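## Annotated circular mitogenomes: constructors, I/O, intergenic-region
## arithmetic, base composition, pairwise variability.

#' Construct a circular genome object
#'
#' @param id sequence identifier.
#' @param sequence IUPAC DNA string; upper-cased on construction.
#' @return an object of class `circular_genome` with fields `id`, `sequence`,
#'   `length` and `topology = "circular"`.
#' @export
circular_genome <- function(id, sequence) {
  sequence <- toupper(as.character(sequence))
  chars <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(chars, DNA_IUPAC)
  if (length(bad) > 0)
    mitotx_error(sprintf("unknown residue character(s) in '%s': %s",
                         id, paste(bad, collapse = ", ")),
                 "mitotx_validation_error")
  structure(list(id = id, sequence = sequence, length = nchar(sequence),
                 topology = "circular"),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d nt (circular)\n", x$id, x$length))
  invisible(x)
}

#' Construct and validate a gene feature table
#'
#' Features are sorted by start position in genome order. Coordinates are
#' 1-based inclusive; a feature whose `end < start` wraps the origin and must
#' be flagged with `wraps_origin = TRUE`.
#'
#' @param df data.frame with columns `name`, `kind` (`PCG`, `rRNA`, `tRNA`),
#'   `strand` (`H`/`L`), `start`, `end`, and optionally `wraps_origin`.
#' @param genome a `circular_genome` used to validate coordinates.
#' @return validated, sorted data.frame of features.
#' @export
gene_features <- function(df, genome) {
  req <- c("name", "kind", "strand", "start", "end")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    mitotx_error(paste("feature table lacks column(s):",
                       paste(missing_cols, collapse = ", ")),
                 "mitotx_validation_error")
  if (is.null(df$wraps_origin)) df$wraps_origin <- df$end < df$start
  L <- genome$length
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  for (i in seq_len(nrow(df))) {
    if (df$start[i] < 1 || df$start[i] > L || df$end[i] < 1 || df$end[i] > L)
      mitotx_error(sprintf(
        "feature '%s' has coordinates outside [1, %d]", df$name[i], L),
        "mitotx_validation_error")
    if (!df$kind[i] %in% c("PCG", "rRNA", "tRNA"))
      mitotx_error(sprintf("feature '%s' has unknown kind '%s'",
                           df$name[i], df$kind[i]), "mitotx_validation_error")
    if (!df$strand[i] %in% c("H", "L"))
      mitotx_error(sprintf("feature '%s' has unknown strand '%s'",
                           df$name[i], df$strand[i]), "mitotx_validation_error")
    if (feature_length(df$start[i], df$end[i], df$wraps_origin[i], L) < 3)
      mitotx_error(sprintf("feature '%s' is shorter than 3 nt", df$name[i]),
                   "mitotx_validation_error")
  }
  if (anyDuplicated(df$name))
    mitotx_error(paste("duplicate feature name(s):",
                       paste(unique(df$name[duplicated(df$name)]), collapse = ", ")),
                 "mitotx_validation_error")
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Span length of a feature on the circle
#' @keywords internal
feature_length <- function(start, end, wraps_origin, L) {
  if (isTRUE(wraps_origin)) L - start + 1L + end else end - start + 1L
}

#' Load an annotated circular mitogenome
#'
#' Two input layouts are supported: a GenBank flat file (LOCUS / FEATURES /
#' ORIGIN; `gene`, `CDS`, `rRNA` and `tRNA` feature keys), or a FASTA file
#' plus a tab-separated feature table with columns
#' `name  kind  strand  start  end`. Feature strands written as `+`/`-` are
#' mapped to `H`/`L` by `plus_is` (`"+"` is the heavy strand by default: in
#' octocoral mitogenomes most genes lie on one strand, taken as H).
#'
#' @param path GenBank file, or FASTA file when `features` is given.
#' @param features optional path to the TSV feature table.
#' @param plus_is which annotation strand symbol maps to H; `"H"` means
#'   `+` == H (default), `"L"` means `+` == L.
#' @return `list(genome = circular_genome, features = data.frame)`.
#' @export
load_annotation <- function(path, features = NULL, plus_is = c("H", "L")) {
  plus_is <- match.arg(plus_is)
  if (is.null(features)) {
    parsed <- parse_genbank(path)
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) < 1) mitotx_error("no sequence in FASTA", "mitotx_validation_error")
    ft <- utils::read.delim(features, stringsAsFactors = FALSE)
    parsed <- list(id = sub("\\s.*$", "", names(seqs)[1]),
                   sequence = as.character(seqs[[1]]), features = ft)
  }
  if (nrow(parsed$features) < 1)
    mitotx_error("annotation contains no features", "mitotx_validation_error")
  ft <- parsed$features
  if (any(ft$strand %in% c("+", "-"))) {
    map <- if (plus_is == "H") c("+" = "H", "-" = "L") else c("+" = "L", "-" = "H")
    ft$strand <- ifelse(ft$strand %in% names(map), map[ft$strand], ft$strand)
  }
  genome <- circular_genome(parsed$id, parsed$sequence)
  list(genome = genome, features = gene_features(ft, genome))
}

## Minimal GenBank flat-file reader (no installed R package parses local
## GenBank records). Understands single-interval and complement() locations
## plus join() across the origin.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus) > 0) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else "genbank"
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0) mitotx_error("GenBank record has no ORIGIN block",
                                        "mitotx_validation_error")
  seq_lines <- lines[(ostart[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) mitotx_error("GenBank record has no FEATURES block",
                                        "mitotx_validation_error")
  flines <- lines[(fstart[1] + 1):(ostart[1] - 1)]
  keys <- grepl("^ {5}\\S", flines)
  idx <- which(keys)
  feats <- list()
  for (j in seq_along(idx)) {
    block <- flines[idx[j]:(if (j < length(idx)) idx[j + 1] - 1 else length(flines))]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    kind <- switch(key, CDS = "PCG", gene = NA_character_,
                   rRNA = "rRNA", tRNA = "tRNA", NA_character_)
    if (is.na(kind)) next
    loc <- sub("^ {5}\\S+\\s+", "", block[1])
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 2) next
    start <- nums[1]; end <- nums[length(nums)]
    quals <- paste(block[-1], collapse = " ")
    name <- if (grepl("/gene=", quals)) {
      sub('.*?/gene="([^"]+)".*', "\\1", quals)
    } else if (grepl("/product=", quals)) {
      sub('.*?/product="([^"]+)".*', "\\1", quals)
    } else sprintf("%s_%d", key, start)
    feats[[length(feats) + 1]] <- data.frame(
      name = name, kind = kind, strand = strand, start = start, end = end,
      wraps_origin = end < start, stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)
  ## a gene may appear as both `gene` and `CDS`; CDS/rRNA/tRNA rows are kept,
  ## duplicates by name collapsed to the first occurrence
  features <- features[!duplicated(features$name), , drop = FALSE]
  list(id = id, sequence = sequence, features = features)
}

#' Write an annotation as FASTA plus a TSV feature table
#'
#' The inverse of [load_annotation()] in FASTA + TSV form.
#'
#' @param genome a `circular_genome`.
#' @param features feature table.
#' @param fasta,tsv output paths.
#' @export
write_annotation <- function(genome, features, fasta, tsv) {
  writeLines(c(paste0(">", genome$id),
               gsub("(.{70})", "\\1\n", genome$sequence)), fasta)
  utils::write.table(
    features[, c("name", "kind", "strand", "start", "end", "wraps_origin")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Intergenic regions and overlaps between consecutive features
#'
#' Walks the features in circular genome order (including the wrap-around
#' pair): each consecutive pair yields either one intergenic region (IGR,
#' length >= 0; zero when the genes abut) or, when the downstream gene starts
#' before the upstream gene ends, one overlap entry (length >= 1). Overlapping
#' pairs are excluded from the IGR table and reported separately.
#'
#' @param genome a `circular_genome`.
#' @param features validated feature table (>= 2 rows).
#' @return `list(igrs = data.frame(left_gene, right_gene, start, end, length),
#'   overlaps = data.frame(left_gene, right_gene, overlap))`. For zero-length
#'   IGRs `start`/`end` are `NA`.
#' @export
igr_table <- function(genome, features) {
  if (nrow(features) < 2)
    mitotx_error("igr_table needs at least two features", "mitotx_validation_error")
  L <- genome$length
  ft <- features[order(features$start), , drop = FALSE]
  n <- nrow(ft)
  igrs <- list(); overlaps <- list()
  for (i in seq_len(n)) {
    a <- ft[i, ]; b <- ft[if (i == n) 1L else i + 1L, ]
    gap <- circ_gap(a$end, b$start, L)
    ovl <- (a$end - b$start + 1L) %% L
    len_a <- feature_length(a$start, a$end, a$wraps_origin, L)
    len_b <- feature_length(b$start, b$end, b$wraps_origin, L)
    ## an overlap cannot exceed either gene span, while a circular gap that
    ## large is geometrically impossible between consecutive features --
    ## this disambiguates gap from overlap without linearity assumptions
    if (ovl >= 1 && ovl <= min(len_a, len_b)) {
      overlaps[[length(overlaps) + 1]] <- data.frame(
        left_gene = a$name, right_gene = b$name, overlap = ovl,
        stringsAsFactors = FALSE)
    } else if (gap == 0) {
      igrs[[length(igrs) + 1]] <- data.frame(
        left_gene = a$name, right_gene = b$name,
        start = NA_integer_, end = NA_integer_, length = 0L,
        stringsAsFactors = FALSE)
    } else {
      igrs[[length(igrs) + 1]] <- data.frame(
        left_gene = a$name, right_gene = b$name,
        start = circ_pos(a$end + 1L, L), end = circ_pos(b$start - 1L, L),
        length = gap, stringsAsFactors = FALSE)
    }
  }
  list(igrs = if (length(igrs)) do.call(rbind, igrs) else
         data.frame(left_gene = character(), right_gene = character(),
                    start = integer(), end = integer(), length = integer()),
       overlaps = if (length(overlaps)) do.call(rbind, overlaps) else
         data.frame(left_gene = character(), right_gene = character(),
                    overlap = integer()))
}

#' Base composition of a genome
#'
#' Ambiguity codes are counted separately and excluded from the four-base
#' denominator. Reported percentages are rounded to one decimal.
#'
#' @param genome a `circular_genome` (or a plain DNA string).
#' @return list with `counts`, `pct` (named A/C/G/T, 1 decimal), `gc_pct`,
#'   and `ambiguity_count`.
#' @export
base_composition <- function(genome) {
  s <- if (inherits(genome, "circular_genome")) genome$sequence else toupper(genome)
  if (nchar(s) == 0) mitotx_error("empty sequence", "mitotx_validation_error")
  chars <- strsplit(s, "")[[1]]
  tab <- table(factor(chars, levels = DNA_IUPAC))
  counts <- as.integer(tab[DNA_BASES]); names(counts) <- DNA_BASES
  amb <- length(chars) - sum(counts)
  denom <- sum(counts)
  pct <- round(100 * counts / denom, 1)
  gc <- round(100 * (counts["G"] + counts["C"]) / denom, 1)
  list(counts = counts, pct = pct, gc_pct = unname(gc), ambiguity_count = amb)
}

#' Pairwise variability between two aligned sequences
#'
#' Variability is the percentage of mismatching columns among columns that are
#' gap-free and ambiguity-free in both rows; ambiguity and gap percentages are
#' fractions of all alignment columns containing an ambiguity code / a gap.
#'
#' @param row1,row2 aligned sequences of equal length (`-` = gap).
#' @return list `variability_pct`, `ambiguity_pct`, `gap_pct`,
#'   `n_columns`, `n_informative`.
#' @export
pairwise_variability <- function(row1, row2) {
  a <- strsplit(toupper(row1), "")[[1]]
  b <- strsplit(toupper(row2), "")[[1]]
  if (length(a) != length(b))
    mitotx_error("alignment rows have unequal lengths", "mitotx_validation_error")
  is_gap <- a == "-" | b == "-"
  is_amb <- (!a %in% c(DNA_BASES, "-")) | (!b %in% c(DNA_BASES, "-"))
  clean <- !is_gap & !is_amb
  n <- length(a)
  mism <- sum(a[clean] != b[clean])
  list(variability_pct = 100 * mism / sum(clean),
       ambiguity_pct = 100 * sum(is_amb) / n,
       gap_pct = 100 * sum(is_gap) / n,
       n_columns = n, n_informative = sum(clean))
}

#' Export IGRs as BED
#'
#' BED is 0-based half-open; conversion from the package's 1-based inclusive
#' coordinates is `start - 1`, `end`. Wrapping IGRs are split at the origin.
#'
#' @param igrs IGR table from [igr_table()].
#' @param genome a `circular_genome`.
#' @param path output path.
#' @export
write_igr_bed <- function(igrs, genome, path) {
  L <- genome$length
  rows <- character(0)
  for (i in seq_len(nrow(igrs))) {
    r <- igrs[i, ]
    if (is.na(r$start) || r$length == 0) next
    nm <- paste0("IGR_", r$left_gene, "_", r$right_gene)
    if (r$end >= r$start) {
      rows <- c(rows, sprintf("%s\t%d\t%d\t%s", genome$id, r$start - 1L, r$end, nm))
    } else {  # wraps the origin: emit two BED lines
      rows <- c(rows,
                sprintf("%s\t%d\t%d\t%s", genome$id, r$start - 1L, L, nm),
                sprintf("%s\t%d\t%d\t%s", genome$id, 0L, r$end, nm))
    }
  }
  writeLines(rows, path)
  invisible(NULL)
}
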