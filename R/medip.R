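# MeDIP CpG-island array differential-methylation calling.
#
# Two-channel design: Cy3 = input DNA, Cy5 = methylated (immunoprecipitated)
# fraction, so positive log2(Cy5/Cy3) means methylation enrichment. Probes are
# filtered with a two-stage cascade: a fourfold between-group difference of
# mean log ratios (|delta| > 2 on the log2 scale) combined with a
# melting-temperature-binned Z-score cutoff (|Z| > 5) in the group driving the
# difference.

#' Compute per-probe log2 methylation ratios
#'
#' Adds a `log2_ratio` column, defined as
#' `log2(max(cy5, floor) / max(cy3, floor))`: the methylated-fraction channel
#' (Cy5) over the input channel (Cy3). The intensity floor guards against
#' `-Inf` on background-subtracted zeros. Probes with a missing channel are
#' flagged (`flagged = TRUE`, `log2_ratio = NA`) and excluded downstream.
#'
#' @param probes Data frame with numeric columns `cy3` and `cy5` (one row per
#'   probe; typically also `probe_id`, `chrom`, `start`, `end`, `tm`).
#' @param floor Intensity floor applied to both channels before the log
#'   (arbitrary units, default 1).
#' @return `probes` with columns `log2_ratio` and logical `flagged` appended.
#' @examples
#' compute_log_ratios(data.frame(cy3 = 1000, cy5 = 4000))$log2_ratio  # 2
#' @export
compute_log_ratios <- function(probes, floor = 1) {
  stopifnot(is.data.frame(probes), all(c("cy3", "cy5") %in% names(probes)))
  bad <- !is.finite(probes$cy3) | !is.finite(probes$cy5)
  probes$log2_ratio <- ifelse(bad, NA_real_,
                              log2(pmax(probes$cy5, floor) / pmax(probes$cy3, floor)))
  probes$flagged <- bad
  probes
}

#' Melting-temperature-binned probe Z-scores
#'
#' Probes are stratified into `n_bins` equal-count melting-temperature (Tm)
#' quantile bins and each probe's log2 ratio is standardised against the
#' distribution of probes in its bin, reflecting the probe's distance to the
#' Gaussian population of other probes with similar Tm.
#'
#' Two estimators of that Gaussian are available:
#' \describe{
#'   \item{`"sample"`}{classical `z = (x - bin mean) / bin sample SD`; a bin
#'     with zero spread assigns `z = 0`.}
#'   \item{`"robust"`}{`z = (x - bin median) / (1.4826 * bin MAD)`. Because the
#'     centre and spread come from the bulk of the bin, genuinely differential
#'     probes do not inflate their own reference distribution; this is the
#'     estimator [medip_pipeline()] uses. When the MAD is zero (e.g. noiseless
#'     data) a probe at the centre gets `z = 0` and a displaced probe
#'     `z = +/-Inf`.}
#' }
#'
#' Bins with fewer than 2 probes yield `NA` Z-scores and set `flagged`.
#'
#' @param probes Data frame with columns `tm` and `log2_ratio`.
#' @param n_bins Number of Tm quantile bins (default 10).
#' @param method Z-score estimator, `"sample"` or `"robust"`.
#' @return `probes` with columns `tm_bin` (integer) and `z_score` appended.
#' @export
compute_tm_binned_zscores <- function(probes, n_bins = 10,
                                      method = c("sample", "robust")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(probes), all(c("tm", "log2_ratio") %in% names(probes)),
            n_bins >= 1)
  breaks <- unique(quantile(probes$tm, probs = seq(0, 1, length.out = n_bins + 1),
                            na.rm = TRUE))
  if (length(breaks) < 2) breaks <- c(-Inf, Inf)
  bin <- cut(probes$tm, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  z <- rep(NA_real_, nrow(probes))
  if (!"flagged" %in% names(probes)) probes$flagged <- FALSE
  for (b in unique(bin[!is.na(bin)])) {
    idx <- which(bin == b & !is.na(probes$log2_ratio))
    x <- probes$log2_ratio[idx]
    if (length(x) < 2) {
      probes$flagged[idx] <- TRUE
      next
    }
    if (method == "sample") {
      s <- sd(x)
      z[idx] <- if (s == 0) 0 else (x - mean(x)) / s
    } else {
      ctr <- median(x)
      s <- mad(x, center = ctr)
      if (s == 0) {
        dev <- x - ctr
        z[idx] <- ifelse(dev == 0, 0, sign(dev) * Inf)
      } else {
        z[idx] <- (x - ctr) / s
      }
    }
  }
  probes$tm_bin <- bin
  probes$z_score <- z
  probes
}

#' Call differentially methylated probes between two groups of arrays
#'
#' Applies the filter cascade to two groups of replicate arrays (e.g. one cell
#' line against the pooled remaining lines):
#' \enumerate{
#'   \item the between-group difference of mean log2 ratios must exceed the
#'     fourfold cutoff, `|mean_a - mean_b| > fold_cut`;
#'   \item the probe's mean `|Z|` in the \emph{driving} group (the group with
#'     the larger mean absolute ratio) must exceed `z_cut`.
#' }
#' Both conditions are strict inequalities; a probe is called only when both
#' hold. `direction` is `"hyper"` when group A is more methylated than group B
#' and `"hypo"` otherwise.
#'
#' @param group_a,group_b Lists of probe tables (replicate arrays) carrying
#'   `probe_id`, `log2_ratio` and `z_score` (see [compute_log_ratios()],
#'   [compute_tm_binned_zscores()]). All tables must share the same probe set.
#' @param fold_cut Log2 difference cutoff (default 2, i.e. fourfold).
#' @param z_cut Z-score cutoff (default 5).
#' @return Data frame with one row per probe: `probe_id`, `mean_a`, `mean_b`,
#'   `mean_diff`, `z_driving`, `called`, `direction`
#'   (`"hyper"`/`"hypo"`/`"unchanged"`).
#' @export
call_differential_probes <- function(group_a, group_b, fold_cut = 2, z_cut = 5) {
  if (is.data.frame(group_a)) group_a <- list(group_a)
  if (is.data.frame(group_b)) group_b <- list(group_b)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups need at least one replicate array")
  ids <- group_a[[1]]$probe_id
  grab <- function(tab, col) {
    stopifnot(identical(tab$probe_id, ids))
    tab[[col]]
  }
  ra <- vapply(group_a, grab, numeric(length(ids)), col = "log2_ratio")
  rb <- vapply(group_b, grab, numeric(length(ids)), col = "log2_ratio")
  za <- vapply(group_a, grab, numeric(length(ids)), col = "z_score")
  zb <- vapply(group_b, grab, numeric(length(ids)), col = "z_score")
  mean_a <- rowMeans(ra)
  mean_b <- rowMeans(rb)
  diff <- mean_a - mean_b
  a_drives <- abs(mean_a) >= abs(mean_b)
  z_drv <- ifelse(a_drives, rowMeans(za), rowMeans(zb))
  called <- !is.na(diff) & !is.na(z_drv) &
    abs(diff) > fold_cut & abs(z_drv) > z_cut
  data.frame(
    probe_id = ids,
    mean_a = mean_a,
    mean_b = mean_b,
    mean_diff = diff,
    z_driving = z_drv,
    called = called,
    direction = ifelse(called, ifelse(diff > 0, "hyper", "hypo"), "unchanged"),
    stringsAsFactors = FALSE
  )
}

#' Aggregate probe-level calls to gene-level methylation calls
#'
#' Each gene's status is the direction of its called probes; conflicting
#' directions resolve by majority, with ties reported as `"unchanged"` plus a
#' conflict flag. Probes without a gene assignment are tallied separately.
#'
#' @param probe_calls Output of [call_differential_probes()].
#' @param annotation Data frame mapping `probe_id` to `gene_id` (optionally a
#'   logical `known` column marking known genes; defaults to `TRUE`). Probes
#'   absent from the annotation, or with `NA` gene, count as unannotated.
#' @return Data frame with one row per gene: `gene_id`, `status`, `mean_diff`
#'   (mean over the gene's probes), `max_abs_z`, `n_probes`, `n_called`,
#'   `conflict`. An attribute `"summary"` carries the counts of called probes,
#'   called loci and called known genes, plus unannotated called probes.
#' @export
aggregate_probes_to_genes <- function(probe_calls, annotation) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(annotation)))
  if (!"known" %in% names(annotation)) annotation$known <- TRUE
  m <- merge(probe_calls, annotation[, c("probe_id", "gene_id", "known")],
             by = "probe_id", all.x = TRUE)
  unann <- is.na(m$gene_id)
  known_gene <- tapply(m$known[!unann], m$gene_id[!unann], any)
  dir_num <- ifelse(m$direction == "hyper", 1L, ifelse(m$direction == "hypo", -1L, 0L))
  agg <- function(f, x) tapply(x[!unann], m$gene_id[!unann], f)
  vote <- agg(sum, dir_num)
  n_called <- agg(sum, m$called)
  has_conflict <- tapply(dir_num[!unann], m$gene_id[!unann],
                         function(v) any(v > 0) && any(v < 0))
  status <- ifelse(n_called == 0 | vote == 0, "unchanged",
                   ifelse(vote > 0, "hyper", "hypo"))
  out <- data.frame(
    gene_id = names(vote),
    status = as.vector(status),
    mean_diff = as.vector(agg(mean, m$mean_diff)),
    max_abs_z = as.vector(agg(function(z) max(abs(z)), m$z_driving)),
    n_probes = as.vector(agg(length, m$probe_id)),
    n_called = as.vector(n_called),
    conflict = as.vector(has_conflict & status == "unchanged" & n_called > 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_called_probes = sum(probe_calls$called),
    n_called_loci = sum(out$status != "unchanged"),
    n_called_known_genes = sum(out$status != "unchanged" &
                                 known_gene[out$gene_id]),
    n_unannotated_called_probes = sum(m$called & unann)
  )
  out
}

#' Assign probes to genes by CpG-island interval overlap
#'
#' A probe annotates a gene when its interval overlaps the gene's CpG-island
#' interval; both use 0-based half-open coordinates. Overlap detection uses
#' `IRanges`. Probes overlapping no island map to `NA`.
#'
#' @param probes Data frame with `probe_id`, `chrom`, `start`, `end`.
#' @param islands Data frame with `gene_id`, `chrom`, `start`, `end` and
#'   optionally `known`.
#' @return Annotation data frame (`probe_id`, `gene_id`, `known`) usable with
#'   [aggregate_probes_to_genes()].
#' @export
map_probes_to_genes <- function(probes, islands) {
  if (!"known" %in% names(islands)) islands$known <- TRUE
  gene <- rep(NA_character_, nrow(probes))
  known <- rep(NA, nrow(probes))
  for (chr in unique(probes$chrom)) {
    pi <- which(probes$chrom == chr)
    gi <- which(islands$chrom == chr)
    if (!length(gi)) next
    # half-open [start, end) -> 1-based closed [start + 1, end]
    q <- IRanges::IRanges(probes$start[pi] + 1L, probes$end[pi])
    s <- IRanges::IRanges(islands$start[gi] + 1L, islands$end[gi])
    hit <- IRanges::findOverlaps(q, s, select = "first")
    gene[pi] <- islands$gene_id[gi][hit]
    known[pi] <- islands$known[gi][hit]
  }
  data.frame(probe_id = probes$probe_id, gene_id = gene, known = known,
             stringsAsFactors = FALSE)
}

#' Classify line-exclusive hyper/hypomethylated gene sets
#'
#' A gene belongs to a line's exclusive set when it is called (in a given
#' direction) in that line and unchanged in every other line. Genes called in
#' two or more lines are reported in a shared-intersection table.
#'
#' @param gene_calls Named list (one element per line) of gene-level call
#'   tables from [aggregate_probes_to_genes()]. All tables must cover the same
#'   gene universe.
#' @return List with `calls` (long data frame `gene_id`, `line`, `status`,
#'   `exclusive`), `exclusive` (per line, character vectors `hyper`/`hypo`),
#'   `shared` (genes called in more than one line with their per-line status),
#'   and `summary` (per-line exclusive hyper/hypo counts).
#' @export
classify_line_specific <- function(gene_calls) {
  lines <- names(gene_calls)
  stopifnot(length(lines) >= 2)
  genes <- sort(gene_calls[[1]]$gene_id)
  status <- sapply(gene_calls, function(tab) {
    stopifnot(identical(sort(tab$gene_id), genes))
    setNames(tab$status, tab$gene_id)[genes]
  })
  n_called <- rowSums(status != "unchanged")
  excl_gene <- n_called == 1
  long <- do.call(rbind, lapply(lines, function(l) {
    data.frame(gene_id = genes, line = l, status = status[, l],
               exclusive = excl_gene & status[, l] != "unchanged",
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  exclusive <- lapply(lines, function(l) {
    list(hyper = genes[excl_gene & status[, l] == "hyper"],
         hypo = genes[excl_gene & status[, l] == "hypo"])
  })
  names(exclusive) <- lines
  shared_idx <- which(n_called >= 2)
  shared <- data.frame(gene_id = genes[shared_idx],
                       status[shared_idx, , drop = FALSE],
                       stringsAsFactors = FALSE)
  rownames(shared) <- NULL
  summary <- data.frame(
    line = lines,
    n_hyper_exclusive = vapply(exclusive, function(e) length(e$hyper), 0L),
    n_hypo_exclusive = vapply(exclusive, function(e) length(e$hypo), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(calls = long, exclusive = exclusive, shared = shared, summary = summary)
}

#' Run the full MeDIP array calling pipeline
#'
#' For every line, its replicate arrays are compared against the pooled arrays
#' of all other lines: log ratios and Tm-binned Z-scores are computed per
#' array, the probe filter cascade is applied, probes are aggregated to genes,
#' and line-exclusive gene sets are classified. The pipeline defaults to the
#' robust Z-score estimator so that truly differential probes do not inflate
#' their own Tm-bin reference distribution (see
#' [compute_tm_binned_zscores()]).
#'
#' @param arrays Nested list `arrays[[line]][[replicate]]` of probe tables with
#'   `probe_id`, `tm`, `cy3`, `cy5` (as produced by [sim_cpg_arrays()]).
#' @param annotation Probe-to-gene annotation (see
#'   [aggregate_probes_to_genes()]).
#' @param fold_cut,z_cut Cascade cutoffs (defaults 2 and 5).
#' @param tm_bins Number of Tm quantile bins (default 10).
#' @param z_method Z-score estimator, `"robust"` (default) or `"sample"`.
#' @param floor Intensity floor for [compute_log_ratios()].
#' @return List with `probe_calls` and `gene_calls` (named per line) and the
#'   [classify_line_specific()] output under `line_specific`.
#' @export
medip_pipeline <- function(arrays, annotation, fold_cut = 2, z_cut = 5,
                           tm_bins = 10, z_method = c("robust", "sample"),
                           floor = 1) {
  z_method <- match.arg(z_method)
  lines <- names(arrays)
  prepped <- lapply(arrays, function(reps) {
    lapply(reps, function(tab) {
      compute_tm_binned_zscores(compute_log_ratios(tab, floor = floor),
                                n_bins = tm_bins, method = z_method)
    })
  })
  probe_calls <- list()
  gene_calls <- list()
  for (l in lines) {
    others <- unlist(prepped[setdiff(lines, l)], recursive = FALSE)
    probe_calls[[l]] <- call_differential_probes(prepped[[l]], others,
                                                 fold_cut = fold_cut,
                                                 z_cut = z_cut)
    gene_calls[[l]] <- aggregate_probes_to_genes(probe_calls[[l]], annotation)
  }
  list(probe_calls = probe_calls, gene_calls = gene_calls,
       line_specific = classify_line_specific(gene_calls))
}
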