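# Composite mtDNA replicative-efficiency statistic: copy number per cell
# expressed against the 5mC/5hmC enrichment ratio at the PolgA exon-2 CpG
# island (5mC marks methylation, 5hmC the demethylation intermediate).

#' mtDNA replicative efficiency
#'
#' `efficiency = copies_per_cell / (e5mc / e5hmc) = copies_per_cell * e5hmc /
#' e5mc`. High methylation relative to demethylation at the PolgA exon-2
#' island suppresses the statistic; it is invariant to a common rescaling of
#' the two enrichments, strictly increasing in copy number and 5hmC, and
#' strictly decreasing in 5mC. `e5mc = 0` leaves the efficiency undefined
#' (`NA`); `e5hmc <= 0` is an error.
#'
#' @param copies_per_cell Non-negative mtDNA copies per cell.
#' @param e5mc,e5hmc Percent-input enrichment for 5mC and 5hmC at the PolgA
#'   exon-2 amplicon (`e5mc >= 0`, `e5hmc > 0`).
#' @return Numeric efficiency (copies per 5mC/5hmC unit), vectorised; `NA`
#'   where `e5mc` is zero.
#' @examples
#' replicative_efficiency(1000, 2, 1)  # 500
#' @export
replicative_efficiency <- function(copies_per_cell, e5mc, e5hmc) {
  if (any(e5hmc <= 0)) stop("5hmC enrichment must be positive")
  if (any(e5mc < 0)) stop("5mC enrichment must be non-negative")
  if (any(copies_per_cell < 0)) stop("copies_per_cell must be non-negative")
  ifelse(e5mc == 0, NA_real_, copies_per_cell * e5hmc / e5mc)
}

#' Replicative-efficiency timecourse across lines and days
#'
#' Computes the efficiency for every (line, day) row and adds the within-day
#' rank of lines (1 = most efficient). All rows are assumed to target the same
#' amplicon (PolgA exon 2).
#'
#' @param inputs Data frame with columns `line`, `day`, `copies_per_cell`,
#'   `e5mc`, `e5hmc` (typically days 0, 3, 12, 21).
#' @return `inputs` with `efficiency` and `rank_within_day` appended, ordered
#'   by day then rank.
#' @export
efficiency_timecourse <- function(inputs) {
  need <- c("line", "day", "copies_per_cell", "e5mc", "e5hmc")
  stopifnot(all(need %in% names(inputs)))
  inputs$efficiency <- replicative_efficiency(inputs$copies_per_cell,
                                              inputs$e5mc, inputs$e5hmc)
  inputs$rank_within_day <- ave(-inputs$efficiency, inputs$day,
                                FUN = function(x) rank(x, ties.method = "min",
                                                       na.last = "keep"))
  inputs[order(inputs$day, inputs$rank_within_day), , drop = FALSE]
}
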