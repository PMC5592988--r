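# Shared fixtures and independent oracles, built in code at test time.

# Minimal probe table with explicit log ratios / z-scores injected.
toy_probe_table <- function(ratio, z = NULL, tm = NULL, ids = NULL) {
  n <- length(ratio)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  out <- data.frame(probe_id = ids,
                    tm = if (is.null(tm)) seq(70, 90, length.out = n) else tm,
                    cy3 = 1000, cy5 = 1000 * 2^ratio,
                    log2_ratio = ratio, flagged = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(z)) out$z_score <- z
  out
}

# Gene-line confusion counts of a medip_pipeline result against planted truth.
planted_confusion <- function(result, sim) {
  tp <- fn <- fp <- tn <- 0L
  for (l in names(result$gene_calls)) {
    gc <- result$gene_calls[[l]]
    status <- setNames(gc$status, gc$gene_id)
    planted <- sim$truth[sim$truth$line == l, ]
    hit <- status[planted$gene_id] == planted$direction
    tp <- tp + sum(hit)
    fn <- fn + sum(!hit)
    un <- setdiff(gc$gene_id, planted$gene_id)
    fp <- fp + sum(status[un] != "unchanged")
    tn <- tn + sum(status[un] == "unchanged")
  }
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fn = fn, fp = fp, tn = tn)
}

# DNAbin matrix from character strings (one per taxon).
make_alignment <- function(...) {
  seqs <- list(...)
  chars <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(chars) <- names(seqs)
  ape::as.DNAbin(chars)
}

# Independent least-squares tree oracle for 4 taxa: enumerates the three
# unrooted topologies, fits branch lengths by ordinary least squares, and
# returns the sum of squared residuals per topology. Path incidence matrices
# are written out explicitly (edges: t1, t2, t3, t4 terminal; e internal).
ls_four_taxon_sse <- function(d, labels) {
  stopifnot(all(labels %in% rownames(d)))
  pair_rows <- t(combn(labels, 2))
  y <- apply(pair_rows, 1, function(p) d[p[1], p[2]])
  topologies <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  vapply(topologies, function(tp) {
    # cherry (tp[1], tp[2]) | (tp[3], tp[4]); columns: 4 tip edges + internal
    X <- matrix(0, nrow = 6, ncol = 5)
    for (r in seq_len(6)) {
      i <- match(pair_rows[r, 1], labels)
      j <- match(pair_rows[r, 2], labels)
      X[r, i] <- 1
      X[r, j] <- 1
      same_cherry <- (i %in% tp[1:2] && j %in% tp[1:2]) ||
        (i %in% tp[3:4] && j %in% tp[3:4])
      if (!same_cherry) X[r, 5] <- 1
    }
    sum(lm.fit(X, y)$residuals^2)
  }, numeric(1))
}

# Which cherry pairing the oracle prefers, as a sorted label pair.
ls_four_taxon_best_cherry <- function(d, labels) {
  sse <- ls_four_taxon_sse(d, labels)
  cherries <- list(labels[c(1, 2)], labels[c(1, 3)], labels[c(1, 4)])
  sort(cherries[[which.min(sse)]])
}

# Brute-force average-linkage euclidean agglomeration: returns merge heights
# in order, to compare with hclust.
brute_average_linkage_heights <- function(mat) {
  clusters <- lapply(seq_len(nrow(mat)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(as.matrix(dist(mat))[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Reference 5-taxon time tree mirroring the rodent calibration study design.
rodent_time_tree <- function() {
  ape::read.tree(text = paste0(
    "((((mus:1.82,spretus:1.82):2.06,dunni:3.88):2.56,",
    "pahari:6.44):3.56,rattus:10);"))
}

# Transition-heavy mtDNA-like GTR model used in simulations.
mtdna_like_model <- function(gamma_shape = 0.3734, n_categories = 5L) {
  gtr_model(c(1, 8, 1, 1, 16, 1), c(0.31, 0.29, 0.12, 0.28),
            gamma_shape, n_categories)
}
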