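## Orchestration: configuration, the end-to-end run and the JSON report.

CONFIG_DEFAULTS <- list(
  arrangement = "A",
  seed = 42L,
  depth = 30,
  read_len = 50L,
  frag_mean = 250,
  frag_sd = 40,
  rrna_multiplier = NULL,       # NULL = program default (50)
  readthrough_fraction = NULL,  # NULL = program default (0.01)
  n_per_end = 8L,
  min_support = 1L,
  precursor_ratio = 10,
  precursor_max_support = 2L,
  cluster_tol = 3L,
  orf_threshold = 50L,
  min_cr_criteria = 4L,
  outdir = NULL)

#' Build a run configuration
#'
#' Unknown keys are rejected; the configuration is echoed into every report
#' for provenance.
#'
#' @param ... overrides of the defaults (see `mitotx:::CONFIG_DEFAULTS`).
#' @return named list of class `mitotx_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0)
    mitotx_error(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
                 "mitotx_validation_error")
  cfg <- utils::modifyList(CONFIG_DEFAULTS, over, keep.null = TRUE)
  structure(cfg, class = c("mitotx_config", "list"))
}

## canonical 3' end of a unit in transcript sense: H = largest coordinate
canonical_cluster <- function(clusters, strand) {
  if (nrow(clusters) == 0) return(integer(0))
  if (strand == "H") which.max(clusters$representative_position)
  else which.min(clusters$representative_position)
}

#' Run the full inference pipeline on a simulated data set
#'
#' Generates the transcription program, simulates reads and junction reads,
#' then runs coverage -> linkage -> unit calling -> end mapping -> APA
#' clustering -> UTR annotation -> lncRNA classification -> control-region
#' prediction, and assembles a machine-readable report. With `outdir` set,
#' writes the report JSON plus unit GFF3, ends/APA TSVs and a bedGraph.
#'
#' @param config a `mitotx_config` from [run_config()].
#' @return report list (invisibly returns the same object that is serialized
#'   to JSON).
#' @export
run_all <- function(config = run_config()) {
  stages <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
  }
  bundle <- stages("program", default_program(config$arrangement,
                                              seed = config$seed))
  genome <- bundle$genome; features <- bundle$features
  program <- bundle$program

  sim <- stages("simulate_reads", simulate_reads(
    program, features, genome, depth = config$depth,
    read_len = config$read_len, frag_mean = config$frag_mean,
    frag_sd = config$frag_sd, rrna_multiplier = config$rrna_multiplier,
    readthrough_fraction = config$readthrough_fraction,
    seed = config$seed + 1L))

  profile <- stages("coverage", compute_coverage(sim$fragments, genome))
  linkage <- stages("linkage", collect_linkage(sim$fragments, features,
                                               genome, profile = profile))
  called <- stages("call_units", call_units(
    linkage, breakpoints = NULL, features = features,
    min_support = config$min_support,
    precursor_ratio = config$precursor_ratio,
    precursor_max_support = config$precursor_max_support))
  units <- called$units

  junc <- stages("junction_reads", simulate_junction_reads(
    program, features, genome, n_per_end = config$n_per_end,
    seed = config$seed + 2L))
  ends_rows <- list(); intervals <- list()
  for (i in seq_along(junc$reads)) {
    res <- tryCatch(resolve_crtpcr_junction(junc$reads[[i]], genome),
                    error = function(e) NULL)
    if (is.null(res)) next
    ends_rows[[length(ends_rows) + 1]] <- res$three_prime
    ends_rows[[length(ends_rows) + 1]] <- res$five_prime
    iv <- sort(c(res$three_prime$position, res$five_prime$position))
    intervals[[length(intervals) + 1]] <- data.frame(
      start = iv[1], end = iv[2], strand = res$three_prime$strand,
      stringsAsFactors = FALSE)
  }
  ends <- do.call(rbind, ends_rows)
  ## aggregate identical ends into support counts
  if (!is.null(ends)) {
    key <- paste(ends$position, ends$kind, ends$strand)
    supp <- as.integer(table(key)[key])
    ends$support <- supp
    ends <- ends[!duplicated(key), , drop = FALSE]
    rownames(ends) <- NULL
  }

  ## APA clustering per unit: a 3' end belongs to the unit whose gene span
  ## contains it, or failing that the unit whose CDS end is nearest (within
  ## 150 nt); this keeps neighbouring units' canonical ends apart
  L <- genome$length
  unit_of_end <- function(p, strand) {
    for (i in seq_len(nrow(units))) {
      if (units$strand[i] != strand) next
      genes <- strsplit(units$genes[i], ",")[[1]]
      rows <- features[match(genes, features$name), , drop = FALSE]
      if (p >= min(rows$start) && p <= max(rows$end)) return(i)
    }
    best <- NA_integer_; bestd <- 150L
    for (i in seq_len(nrow(units))) {
      if (units$strand[i] != strand) next
      genes <- strsplit(units$genes[i], ",")[[1]]
      rows <- features[match(genes, features$name), , drop = FALSE]
      cds_end <- if (strand == "H") max(rows$end) else min(rows$start)
      d <- min((p - cds_end) %% L, (cds_end - p) %% L)
      if (d <= bestd) { bestd <- d; best <- i }
    }
    best
  }
  apa <- list()
  if (!is.null(ends)) {
    e3_all <- ends[ends$kind == "three_prime", , drop = FALSE]
    e3_all$unit_idx <- vapply(seq_len(nrow(e3_all)), function(j)
      unit_of_end(e3_all$position[j], e3_all$strand[j]), integer(1))
    for (i in unique(stats::na.omit(e3_all$unit_idx))) {
      e3 <- e3_all[!is.na(e3_all$unit_idx) & e3_all$unit_idx == i, , drop = FALSE]
      genes <- strsplit(units$genes[i], ",")[[1]]
      rows <- features[match(genes, features$name), , drop = FALSE]
      cl <- cluster_apa(e3, genome, rows, cluster_tol = config$cluster_tol)
      canon <- canonical_cluster(cl, units$strand[i])
      cl$canonical <- seq_len(nrow(cl)) == canon
      cl$unit_id <- units$unit_id[i]
      apa[[length(apa) + 1]] <- cl
    }
  }
  apa <- if (length(apa)) do.call(rbind, apa) else NULL

  utrs <- stages("utrs", annotate_utrs(units, ends, features, genome))

  ## lncRNA classification over distinct resolved transcript intervals
  lnc_calls <- list()
  if (length(intervals) > 0) {
    iv <- unique(do.call(rbind, intervals))
    for (i in seq_len(nrow(iv))) {
      res <- classify_lncrna(
        list(start = iv$start[i], end = iv$end[i], strand = iv$strand[i]),
        polyadenylated = TRUE, genome = genome, features = features,
        orf_threshold = config$orf_threshold)
      if (res$called)
        lnc_calls[[length(lnc_calls) + 1]] <- data.frame(
          start = iv$start[i], end = iv$end[i], strand = iv$strand[i],
          antisense_of = res$antisense_of, length = res$length,
          longest_orf_codons = res$longest_orf_codons,
          stringsAsFactors = FALSE)
    }
  }
  lnc <- if (length(lnc_calls)) unique(do.call(rbind, lnc_calls)) else NULL

  igrs <- igr_table(genome, features)
  cr <- stages("control_region", predict_control_region(
    igrs$igrs, profile, features, genome,
    min_criteria = config$min_cr_criteria))

  report <- list(
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    genome = list(id = genome$id, length = genome$length,
                  composition = as.list(base_composition(genome)$pct),
                  gc_pct = base_composition(genome)$gc_pct),
    igr = list(n = nrow(igrs$igrs), max_length = max(igrs$igrs$length),
               min_length = min(igrs$igrs$length[igrs$igrs$length > 0]),
               overlaps = igrs$overlaps),
    units = units,
    unit_summary = classify_units(units),
    adjacencies = called$adjacencies,
    ends = ends,
    apa = apa,
    utrs = utrs,
    lncrna = lnc,
    control_region = cr[cr$called, , drop = FALSE])

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$outdir, f)
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = 10, dataframe = "rows", pretty = TRUE,
                         null = "null")
    write_units_gff3(units, features, genome, p("units.gff3"))
    if (!is.null(ends))
      utils::write.table(ends, p("ends.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    if (!is.null(apa))
      utils::write.table(apa, p("apa.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    write_bedgraph(profile, p("coverage.bedgraph"))
  }
  invisible(report)
}
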