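# qPCR-derived quantities: standard curves, absolute copy number,
# delta-delta-Ct expression, percent-input enrichment and Fluidigm
# delta-Ct matrices.

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of `Ct ~ log10(copies)` over a dilution series.
#' Amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (1 = perfect doubling). Curves with efficiency outside
#' `(0, 1.1]` are flagged with a warning; a non-negative slope (an inverted
#' curve) is an error.
#'
#' @param log10_copies,ct Numeric vectors (at least 3 dilution points), or a
#'   data frame with those columns passed as the first argument.
#' @return Object of class `standard_curve` with `slope`, `intercept`, `r2`,
#'   `efficiency` and `flagged`.
#' @examples
#' cv <- fit_standard_curve(0:5, 38 - 3.5 * (0:5))
#' cv$efficiency  # 10^(1/3.5) - 1
#' @export
fit_standard_curve <- function(log10_copies, ct) {
  if (is.data.frame(log10_copies)) {
    ct <- log10_copies$ct
    log10_copies <- log10_copies$log10_copies
  }
  stopifnot(length(log10_copies) == length(ct))
  ok <- complete.cases(log10_copies, ct)
  if (sum(ok) < 3) stop("a standard curve needs at least 3 dilution points")
  fit <- lm(ct[ok] ~ log10_copies[ok])
  slope <- unname(coef(fit)[2])
  if (is.na(slope) || slope >= 0)
    stop("inverted curve: slope must be negative (Ct decreases with template)")
  eff <- 10^(-1 / slope) - 1
  flagged <- !(eff > 0 && eff <= 1.1)
  if (flagged)
    warning(sprintf("amplification efficiency %.3f outside (0, 1.1]", eff))
  sst <- sum((ct[ok] - mean(ct[ok]))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r2 = r2, efficiency = eff, flagged = flagged),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.4f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.5f, efficiency = %.3f%s\n", x$r2, x$efficiency,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Invert a standard curve: Ct to copies
#'
#' `copies = 10^((ct - intercept) / slope)`; the exact inverse of the fitted
#' line, so quantification of a Ct generated from the curve returns the input
#' quantity.
#'
#' @param ct Observed Ct value(s), replicates already averaged.
#' @param curve A [fit_standard_curve()] result (or any list with `slope` and
#'   `intercept`).
#' @return Estimated template quantity (copies), vectorised over `ct`.
#' @export
quantify_from_curve <- function(ct, curve) {
  10^((ct - curve$intercept) / curve$slope)
}

#' mtDNA copies per cell from mtDNA and beta-actin quantities
#'
#' Absolute mtDNA copy number is referenced to cell number through the
#' single-copy nuclear beta-actin locus, present at `actin_copies_per_cell`
#' copies per (diploid) genome: `copies/cell = mtdna / (actin /
#' actin_copies_per_cell)`. The diploid convention (2 copies) is explicit and
#' configurable.
#'
#' @param mtdna,actin Absolute quantities from [quantify_from_curve()];
#'   `actin` must be positive, `mtdna` non-negative.
#' @param actin_copies_per_cell Copies of the reference locus per cell
#'   (default 2).
#' @return Copies of mtDNA per cell.
#' @examples
#' copies_per_cell(1e5, 2000)  # 100
#' @export
copies_per_cell <- function(mtdna, actin, actin_copies_per_cell = 2) {
  if (any(actin <= 0)) stop("beta-actin quantity must be positive")
  if (any(mtdna < 0)) stop("mtDNA quantity must be non-negative")
  mtdna / (actin / actin_copies_per_cell)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `fold = 2^-ddct` with
#' `ddct = (Ct_target - Ct_reference)_condition - (Ct_target -
#' Ct_reference)_calibrator`. All four mean Cts must be present.
#'
#' @param ct_target_cond,ct_ref_cond Mean target / reference-gene Ct in the
#'   condition of interest.
#' @param ct_target_calib,ct_ref_calib Same in the calibrator condition.
#' @return Fold change (1 = no change), vectorised.
#' @examples
#' ddct_fold_change(24, 20, 25, 20)  # 2
#' @export
ddct_fold_change <- function(ct_target_cond, ct_ref_cond,
                             ct_target_calib, ct_ref_calib) {
  vals <- cbind(ct_target_cond, ct_ref_cond, ct_target_calib, ct_ref_calib)
  if (any(!is.finite(vals)))
    stop("all four mean Ct values must be present and finite")
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_calib - ct_ref_calib)
  2^(-ddct)
}

#' Percent-input enrichment for MeDIP / ChIP qPCR
#'
#' The input Ct is first adjusted for the fraction of chromatin kept as input
#' (`ct_input - log2(1 / input_fraction)` is the Ct the full input would have
#' given), then enrichment is expressed as percent of input:
#' `100 * 2^(adjusted input Ct - ct_ip)`, equivalently
#' `100 * input_fraction * 2^(ct_input - ct_ip)`. Shift-invariant: adding a
#' constant to both Cts leaves the result unchanged.
#'
#' @param ct_ip Mean Ct of the immunoprecipitated sample.
#' @param ct_input Mean Ct of the input sample.
#' @param input_fraction Fraction of material kept as input, in `(0, 1]`
#'   (default 0.1).
#' @return Percent input (>= 0), vectorised.
#' @examples
#' percent_input(25, 25, input_fraction = 0.1)  # 10
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.1) {
  if (any(input_fraction <= 0 | input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  100 * input_fraction * 2^(ct_input - ct_ip)
}

#' Mean Ct per sample and target
#'
#' Averages replicate Cts arithmetically, dropping non-detects (`NA`) from the
#' mean; a sample/target pair with no detected wells yields `NA`.
#'
#' @param ct_table Data frame with `sample`, `target`, `ct` (and optionally
#'   `condition`, `replicate`).
#' @return Data frame `sample`, `target`, `ct` (one row per pair).
#' @export
mean_ct <- function(ct_table) {
  stopifnot(all(c("sample", "target", "ct") %in% names(ct_table)))
  agg <- aggregate(ct ~ sample + target, data = ct_table,
                   FUN = function(x) mean(x, na.rm = TRUE),
                   na.action = stats::na.pass)
  agg$ct[is.nan(agg$ct)] <- NA_real_
  agg
}

#' Fluidigm delta-Ct expression matrix with euclidean clustering
#'
#' Normalises each gene's mean Ct to the housekeeping gene within the same
#' sample (`dCt = Ct_gene - Ct_housekeeping`), builds the genes x samples
#' matrix, and clusters both rows and columns by average-linkage hierarchical
#' clustering on euclidean distances. Non-detects are imputed to `ct_ceiling`
#' before normalisation; samples whose housekeeping Ct is missing are dropped
#' with a warning.
#'
#' @param ct_table Data frame with `sample`, `target`, `ct` (replicates, if
#'   present, are averaged first via [mean_ct()]).
#' @param housekeeping Housekeeping target name (default `"18S"`).
#' @param ct_ceiling Ct imputed for non-detects (default 40).
#' @return List with `matrix` (genes x samples delta-Ct), `row_hclust`,
#'   `col_hclust` (`hclust` objects, `NULL` when fewer than 2 rows/columns),
#'   and `dropped_samples`.
#' @export
fluidigm_matrix <- function(ct_table, housekeeping = "18S", ct_ceiling = 40) {
  m <- mean_ct(ct_table)
  m$ct[is.na(m$ct)] <- ct_ceiling
  samples <- sort(unique(m$sample))
  hk <- m[m$target == housekeeping, ]
  hk_ct <- setNames(hk$ct, hk$sample)
  missing_hk <- setdiff(samples, hk$sample)
  if (length(missing_hk)) {
    warning("dropping sample(s) without housekeeping Ct: ",
            paste(missing_hk, collapse = ", "))
    samples <- setdiff(samples, missing_hk)
  }
  genes <- sort(setdiff(unique(m$target), housekeeping))
  mat <- matrix(ct_ceiling, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  keep <- m$target != housekeeping & m$sample %in% samples
  mat[cbind(m$target[keep], m$sample[keep])] <- m$ct[keep]
  mat <- sweep(mat, 2, hk_ct[samples])
  row_hc <- if (nrow(mat) >= 2)
    hclust(dist(mat, method = "euclidean"), method = "average") else NULL
  col_hc <- if (ncol(mat) >= 2)
    hclust(dist(t(mat), method = "euclidean"), method = "average") else NULL
  list(matrix = mat, row_hclust = row_hc, col_hclust = col_hc,
       dropped_samples = missing_hk)
}

#' Two-group differential expression on delta-Ct values
#'
#' Welch's t-test per gene on the delta-Ct matrix columns, a plain two-group
#' statistic (not a moderated/limma-style fit). `estimate` is the mean
#' delta-Ct difference (group A - group B); negative values mean higher
#' expression in group A.
#'
#' @param dct_matrix Genes x samples delta-Ct matrix
#'   (see [fluidigm_matrix()]).
#' @param group Factor/character of length `ncol(dct_matrix)` with exactly two
#'   levels.
#' @return Data frame `gene`, `estimate`, `t`, `p_value`, `method`
#'   (`"welch_t"`).
#' @export
fluidigm_diffexpr <- function(dct_matrix, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, length(group) == ncol(dct_matrix))
  a <- levels(group)[1]
  res <- t(apply(dct_matrix, 1, function(x) {
    tt <- t.test(x[group == a], x[group != a])
    c(estimate = unname(tt$estimate[1] - tt$estimate[2]),
      t = unname(tt$statistic), p_value = tt$p.value)
  }))
  data.frame(gene = rownames(dct_matrix), res, method = "welch_t",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export an hclust dendrogram as Newick
#'
#' @param hc An `hclust` object.
#' @param path Optional file; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
hclust_to_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
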