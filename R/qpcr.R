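## Efficiency-corrected relative expression from Cq values, REST-style
## randomization testing, and RHAPA-based quantification of alternative
## polyadenylation isoforms.

validate_wells <- function(wells, genes) {
  req <- c("target", "condition", "replicate", "cq", "efficiency")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols) > 0)
    mitotx_error(paste("well table lacks column(s):",
                       paste(missing_cols, collapse = ", ")),
                 "mitotx_validation_error")
  if (any(!is.finite(wells$cq)))
    mitotx_error("non-finite Cq value", "mitotx_validation_error")
  if (any(wells$efficiency <= 1 | wells$efficiency > 2))
    mitotx_error("amplification efficiency outside (1, 2]",
                 "mitotx_validation_error")
  for (g in genes) for (cond in c("sample", "control")) {
    k <- sum(wells$target == g & wells$condition == cond)
    if (k == 0)
      mitotx_error(sprintf("no '%s' wells for gene '%s'", cond, g),
                   "mitotx_validation_error")
    if (k < 2)
      mitotx_error(sprintf("fewer than 2 replicates for gene '%s', %s", g, cond),
                   "mitotx_validation_error")
  }
  invisible(TRUE)
}

gene_stats <- function(wells, gene) {
  w <- wells[wells$target == gene, , drop = FALSE]
  list(E = mean(w$efficiency),
       cq_sample = w$cq[w$condition == "sample"],
       cq_control = w$cq[w$condition == "control"])
}

#' Efficiency-corrected relative expression ratio
#'
#' Computes `ratio = E_target^dCq_target / E_ref^dCq_ref` with
#' `dCq = mean Cq(control) - mean Cq(sample)` per gene and per-gene mean
#' amplification efficiency. The standard deviation is propagated from the
#' replicate Cq standard deviations by the delta method on the log-ratio;
#' the p-value comes from [randomization_test()]. The SD of per-replicate
#' ratios is also reported (`sd_replicate`), since either convention may be
#' meant by an "SD of technical triplicates".
#'
#' @param wells data.frame `target`, `condition` (`sample`/`control`),
#'   `replicate`, `cq`, `efficiency`.
#' @param target target gene name.
#' @param reference reference gene name.
#' @param n_randomizations permutations for the p-value (0 skips the test).
#' @param seed optional seed for the randomization test.
#' @return list `ratio`, `sd`, `sd_replicate`, `p_value`, `n_randomizations`,
#'   `dcq_target`, `dcq_reference`.
#' @export
relative_ratio <- function(wells, target, reference,
                           n_randomizations = 2000L, seed = NULL) {
  validate_wells(wells, c(target, reference))
  st <- gene_stats(wells, target)
  sr <- gene_stats(wells, reference)
  dcq_t <- mean(st$cq_control) - mean(st$cq_sample)
  dcq_r <- mean(sr$cq_control) - mean(sr$cq_sample)
  ratio <- st$E^dcq_t / sr$E^dcq_r
  ## delta method on log ratio: var(log ratio) =
  ## ln(E_t)^2 (var_ts/n_ts + var_tc/n_tc) + ln(E_r)^2 (...)
  vlog <- log(st$E)^2 * (stats::var(st$cq_sample) / length(st$cq_sample) +
                           stats::var(st$cq_control) / length(st$cq_control)) +
          log(sr$E)^2 * (stats::var(sr$cq_sample) / length(sr$cq_sample) +
                           stats::var(sr$cq_control) / length(sr$cq_control))
  sd_delta <- ratio * sqrt(vlog)
  ## per-replicate ratios (replicates paired by index)
  nrep <- min(length(st$cq_sample), length(st$cq_control),
              length(sr$cq_sample), length(sr$cq_control))
  rep_ratios <- vapply(seq_len(nrep), function(i)
    st$E^(st$cq_control[i] - st$cq_sample[i]) /
      sr$E^(sr$cq_control[i] - sr$cq_sample[i]), numeric(1))
  p <- if (n_randomizations > 0)
    randomization_test(wells, target, reference, n = n_randomizations,
                       seed = seed)
  else NA_real_
  list(target = target, reference = reference, ratio = ratio,
       sd = sd_delta, sd_replicate = stats::sd(rep_ratios), p_value = p,
       n_randomizations = if (n_randomizations > 0) n_randomizations else 0L,
       dcq_target = dcq_t, dcq_reference = dcq_r)
}

#' Randomization test for an expression ratio
#'
#' Permutes condition labels within each gene `n` times and counts
#' permutations whose absolute log ratio reaches the observed one
#' (two-sided); `p = (b + 1) / (n + 1)`.
#'
#' @inheritParams relative_ratio
#' @param n number of permutations (a warning below 100).
#' @param seed optional integer seed.
#' @return p-value in `(0, 1]`.
#' @export
randomization_test <- function(wells, target, reference, n = 2000L,
                               seed = NULL) {
  if (n < 100) warning("fewer than 100 randomizations; p-value is coarse")
  validate_wells(wells, c(target, reference))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  st <- gene_stats(wells, target)
  sr <- gene_stats(wells, reference)
  obs <- abs(log(st$E) * (mean(st$cq_control) - mean(st$cq_sample)) -
               log(sr$E) * (mean(sr$cq_control) - mean(sr$cq_sample)))
  perm_stat <- function(s) {
    all_cq <- c(s$cq_sample, s$cq_control)
    ns <- length(s$cq_sample)
    idx <- sample.int(length(all_cq), ns)
    mean(all_cq[-idx]) - mean(all_cq[idx])
  }
  b <- 0L
  for (i in seq_len(n)) {
    stat <- abs(log(st$E) * perm_stat(st) - log(sr$E) * perm_stat(sr))
    if (stat >= obs - 1e-12) b <- b + 1L
  }
  (b + 1) / (n + 1)
}

#' RHAPA: relative abundance of alternative polyadenylation isoforms
#'
#' After oligo-directed RNase H cleavage removes the full-length 3' end, only
#' alternatively polyadenylated isoforms remain amplifiable. Each amplicon's
#' expression (relative to the reference gene) is expressed relative to the
#' cleaved-off 3' comparator amplicon.
#'
#' @param wells well table covering all amplicons plus the reference gene.
#' @param amplicons character vector of amplicon target names.
#' @param comparator name of the cleaved-off 3' comparator amplicon.
#' @param reference reference gene name.
#' @param n_randomizations,seed passed to [relative_ratio()].
#' @return data.frame with one row per amplicon: `amplicon`, `ratio`
#'   (relative to the comparator), `sd`, `p_value`.
#' @export
rhapa_quantify <- function(wells, amplicons, comparator, reference,
                           n_randomizations = 2000L, seed = NULL) {
  if (!comparator %in% wells$target)
    mitotx_error(sprintf("comparator amplicon '%s' missing from wells",
                         comparator), "mitotx_validation_error")
  base <- relative_ratio(wells, comparator, reference,
                         n_randomizations = 0L)
  out <- list()
  for (i in seq_along(amplicons)) {
    a <- amplicons[i]
    r <- relative_ratio(wells, a, reference,
                        n_randomizations = n_randomizations,
                        seed = if (is.null(seed)) NULL else seed + i)
    out[[length(out) + 1]] <- data.frame(
      amplicon = a, ratio = r$ratio / base$ratio,
      sd = r$sd / base$ratio, p_value = r$p_value,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a qPCR well table from TSV
#'
#' Expected columns: `target`, `condition`, `replicate`, `cq`, `efficiency`.
#'
#' @param path TSV path.
#' @return data.frame of wells.
#' @export
read_qpcr_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
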