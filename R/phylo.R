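# Calibrated mtDNA divergence-time phylogenetics.
#
# Pairwise maximum-likelihood distances under a single alignment-wide
# GTR(+Gamma) parameterisation (the composite-likelihood convention: model
# parameters are shared across pairs, each pair profiles only its own
# distance), neighbor-joining with nonparametric bootstrap, and relative-rate
# divergence dating against a calibration interval.

#' General time-reversible substitution model
#'
#' @param rates Six symmetric exchangeabilities in lower-triangle order
#'   (AC, AG, AT, CG, CT, GT); all positive. Relative scale only.
#' @param freqs Stationary base frequencies (A, C, G, T), summing to 1.
#' @param gamma_shape Shape of the discrete gamma distribution of
#'   among-site rate variation (default 0.3734); `Inf` disables rate
#'   variation.
#' @param n_categories Number of discrete gamma categories (default 5).
#' @return Object of class `gtr_model`.
#' @export
gtr_model <- function(rates = rep(1, 6), freqs = rep(0.25, 4),
                      gamma_shape = 0.3734, n_categories = 5L) {
  stopifnot(length(rates) == 6, length(freqs) == 4, n_categories >= 1)
  if (any(rates <= 0)) stop("exchangeability rates must be positive")
  if (any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-6)
    stop("base frequencies must be positive and sum to 1")
  structure(list(rates = as.numeric(rates),
                 freqs = as.numeric(freqs) / sum(freqs),
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories)),
            class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR substitution model\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      sprintf("%.4g", x$rates), "\n")
  cat("  base frequencies (A C G T):", sprintf("%.4f", x$freqs), "\n")
  if (is.finite(x$gamma_shape))
    cat(sprintf("  gamma rate variation: shape %.4f, %d categories\n",
                x$gamma_shape, x$n_categories))
  else cat("  uniform rates across sites\n")
  invisible(x)
}

# Equal-probability discrete gamma category means (mean-one normalisation).
discrete_gamma_rates <- function(shape, k) {
  if (k == 1 || !is.finite(shape)) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  r <- k * diff(stats::pgamma(b, shape = shape + 1, rate = shape))
  r / mean(r) * 1  # guard tiny numerical drift; already mean 1 analytically
}

# Rate matrix normalised to one expected substitution per unit time.
gtr_q_matrix <- function(model) {
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- model$rates  # column-major: AC AG AT CG CT GT
  S <- S + t(S)
  Q <- S %*% diag(model$freqs)
  diag(Q) <- -rowSums(Q)
  Q / (-sum(model$freqs * diag(Q)))
}

# Symmetric eigen-decomposition of the reversible Q for fast P(t).
gtr_eigen <- function(model) {
  Q <- gtr_q_matrix(model)
  sq <- sqrt(model$freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(lambda = e$values,
       V1 = diag(1 / sq) %*% e$vectors,
       V2 = t(e$vectors) %*% diag(sq),
       freqs = model$freqs,
       rates_cat = discrete_gamma_rates(model$gamma_shape, model$n_categories))
}

# Transition-probability matrix P(t) = exp(Qt), rows renormalised against
# rounding (entries can dip to -1e-17).
gtr_pmat <- function(eg, t) {
  P <- eg$V1 %*% (exp(eg$lambda * t) * eg$V2)
  P[P < 0] <- 0
  P / rowSums(P)
}

# DNAbin (or character) matrix -> integer codes 1..4 (0 = gap/ambiguity).
dna_to_int <- function(aln) {
  x <- as.character(as.matrix(aln))
  m <- matrix(match(tolower(x), c("a", "c", "g", "t"), nomatch = 0L),
              nrow = nrow(x), dimnames = dimnames(x))
  m
}

# 16 pair-pattern counts (row-major i,j) for integer-coded sequences.
pair_pattern_counts <- function(xi, xj) {
  ok <- xi > 0L & xj > 0L
  tabulate((xi[ok] - 1L) * 4L + xj[ok], nbins = 16L)
}

# Mixture likelihood terms for a pattern-count vector at distance t.
# Returns list(L, dL): flattened row-major 4x4 site-pattern probabilities and
# their derivative in t (averaged over gamma categories).
pair_lik_terms <- function(t, eg) {
  k <- length(eg$rates_cat)
  L <- matrix(0, 4, 4)
  dL <- matrix(0, 4, 4)
  for (r in eg$rates_cat) {
    E <- exp(eg$lambda * t * r)
    P <- eg$V1 %*% (E * eg$V2)
    dP <- eg$V1 %*% ((eg$lambda * r * E) * eg$V2)
    L <- L + P / k
    dL <- dL + dP / k
  }
  L <- eg$freqs * L    # row i weighted by pi_i (column-major recycling)
  dL <- eg$freqs * dL
  list(L = as.vector(t(L)), dL = as.vector(t(dL)))
}

pair_loglik <- function(t, counts, eg) {
  lt <- pair_lik_terms(t, eg)
  sum(counts * log(pmax(lt$L, 1e-300)))
}

pair_score <- function(t, counts, eg) {
  lt <- pair_lik_terms(t, eg)
  sum(counts * lt$dL / pmax(lt$L, 1e-300))
}

# ML distance for one pair: root of the analytic score function, located to
# ~1e-12 so closed-form special cases (Jukes-Cantor) are matched to machine
# precision.
pair_mle_distance <- function(counts, eg, max_dist = 500) {
  mism <- sum(counts[-c(1, 6, 11, 16)])
  if (mism == 0) return(0)
  lo <- 1e-10
  if (pair_score(lo, counts, eg) <= 0) return(0)
  hi <- 0.5
  while (pair_score(hi, counts, eg) > 0) {
    hi <- hi * 2
    if (hi > max_dist) return(Inf)
  }
  uniroot(pair_score, c(lo, hi), counts = counts, eg = eg,
          tol = 1e-12)$root
}

#' Pairwise maximum-likelihood distances under GTR(+Gamma)
#'
#' For every taxon pair the expected number of substitutions per site is the
#' maximiser of the pairwise likelihood under the supplied model, with model
#' parameters (exchangeabilities, frequencies, gamma shape) shared across all
#' pairs — the composite convention of estimating them once from the whole
#' alignment. Sites with a gap or ambiguity in either sequence of a pair are
#' excluded pairwise. A saturated pair yields `Inf` with a warning.
#'
#' @param aln Alignment: a `DNAbin` matrix (or character matrix) of aligned
#'   sequences, at least 2 taxa and 100 pairwise-complete sites per pair.
#' @param model A [gtr_model()], e.g. from [fit_gtr_model()].
#' @return Symmetric distance matrix (substitutions/site) with taxon
#'   dimnames.
#' @export
pairwise_distances <- function(aln, model) {
  x <- dna_to_int(aln)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 taxa")
  eg <- gtr_eigen(model)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cnt <- pair_pattern_counts(x[i, ], x[j, ])
      if (sum(cnt) < 100)
        stop(sprintf("pair %s/%s has fewer than 100 pairwise-complete sites",
                     rownames(x)[i], rownames(x)[j]))
      dij <- pair_mle_distance(cnt, eg)
      if (is.infinite(dij))
        warning(sprintf("saturated pair %s/%s: distance undefined (+Inf)",
                        rownames(x)[i], rownames(x)[j]))
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Fit GTR exchangeabilities alignment-wide by composite likelihood
#'
#' Base frequencies are taken as the empirical alignment frequencies; the five
#' free exchangeabilities (GT fixed at 1) are found by maximising the sum of
#' pairwise log-likelihoods over all taxon pairs, with each pair's distance
#' profiled out. The gamma shape is held fixed (default 0.3734 with 5
#' categories).
#'
#' @inheritParams pairwise_distances
#' @param gamma_shape,n_categories Discrete gamma rate variation, as in
#'   [gtr_model()].
#' @return Fitted [gtr_model()] with attribute `"composite_loglik"`.
#' @export
fit_gtr_model <- function(aln, gamma_shape = 0.3734, n_categories = 5L) {
  x <- dna_to_int(aln)
  n <- nrow(x)
  stopifnot(n >= 2)
  tab <- tabulate(x[x > 0L], nbins = 4L)
  freqs <- tab / sum(tab)
  pairs <- utils::combn(n, 2)
  counts <- lapply(seq_len(ncol(pairs)),
                   function(k) pair_pattern_counts(x[pairs[1, k], ],
                                                   x[pairs[2, k], ]))
  obj <- function(logr) {
    m <- gtr_model(c(exp(logr), 1), freqs, gamma_shape, n_categories)
    eg <- gtr_eigen(m)
    ll <- 0
    for (cnt in counts) {
      t_hat <- pair_mle_distance(cnt, eg)
      if (is.infinite(t_hat)) return(1e10)
      ll <- ll + pair_loglik(t_hat, cnt, eg)
    }
    -ll
  }
  fit <- optim(rep(0, 5), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  out <- gtr_model(c(exp(fit$par), 1), freqs, gamma_shape, n_categories)
  attr(out, "composite_loglik") <- -fit$value
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); taxa are pre-sorted by label so
#' that ties resolve deterministically and outputs are stable across
#' otherwise-equivalent input orderings.
#'
#' @param d Symmetric, non-negative distance matrix (or `dist`) with labels;
#'   `NA`/`NaN`/`Inf` entries are an error.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (any(is.na(m)) || any(!is.finite(m)))
    stop("distance matrix contains NA/NaN/Inf entries")
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  if (any(m < 0) || max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be symmetric and non-negative")
  ord <- order(rownames(m))
  ape::nj(m[ord, ord])
}

#' Nonparametric bootstrap support for NJ bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' GTR(+Gamma) distances under the fixed supplied model for each replicate,
#' and reports the percentage of replicates containing each internal
#' bipartition of the original tree (via [ape::boot.phylo()]). A fixed seed
#' reproduces supports exactly.
#'
#' @inheritParams pairwise_distances
#' @param n_reps Number of bootstrap replicates (default 1000); `0` returns
#'   the tree with no supports.
#' @param seed Optional integer seed.
#' @return List with `tree` (NJ tree of the full alignment, `node.label` set
#'   to supports) and `support` (numeric, % per internal node; first entry is
#'   the root/trivial split).
#' @export
bootstrap_support <- function(aln, model, n_reps = 1000, seed = NULL) {
  x <- as.matrix(aln)
  tr <- nj_tree(pairwise_distances(x, model))
  if (n_reps == 0) return(list(tree = tr, support = numeric(0)))
  if (!is.null(seed)) set.seed(seed)
  bp <- ape::boot.phylo(tr, x,
                        function(m) nj_tree(pairwise_distances(m, model)),
                        B = n_reps, quiet = TRUE, rooted = FALSE)
  support <- 100 * bp / n_reps
  tr$node.label <- support
  list(tree = tr, support = support)
}

#' Relative-rate divergence times against a calibration interval
#'
#' The tree is rooted on the outgroup; each node's relative height is then
#' computed bottom-up as the average over its children of (child height +
#' connecting branch length), a per-lineage rate normalisation in the
#' relative-rate spirit: lineages that evolved faster do not pull their
#' ancestors older, because sister heights are averaged at every node. At the
#' root this average is invariant to where the root subdivides the outgroup
#' branch. Heights are scaled to absolute ages so the calibrated node (the
#' outgroup/ingroup split) sits at the midpoint of the calibration interval,
#' with the interval endpoints propagated to per-node age bounds.
#'
#' @param tree Unrooted (or rooted) `phylo` tree with branch lengths in
#'   substitutions/site.
#' @param outgroup Tip label used to root the tree; the calibration applies
#'   to the split between this outgroup and the ingroup.
#' @param calibration Two-sided calibration interval in Mya
#'   (default `c(8, 12)`).
#' @return List with `tree` (rooted, node labels = ages in Mya), `ages` (data
#'   frame `node`, `clade`, `age`, `age_lower`, `age_upper`), `calibration`
#'   and `method = "relative-rate (child-averaged heights)"`.
#' @export
divergence_times <- function(tree, outgroup, calibration = c(8, 12)) {
  stopifnot(inherits(tree, "phylo"), length(calibration) == 2,
            calibration[1] <= calibration[2])
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!outgroup %in% tree$tip.label)
    stop("calibration outgroup '", outgroup, "' absent from tree")
  rt <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  rt <- ape::reorder.phylo(rt, "postorder")
  n_tip <- length(rt$tip.label)
  n_all <- n_tip + rt$Nnode
  sums <- numeric(n_all)
  cnts <- integer(n_all)
  h <- numeric(n_all)
  for (e in seq_len(nrow(rt$edge))) {
    p <- rt$edge[e, 1]
    ch <- rt$edge[e, 2]
    if (ch > n_tip) h[ch] <- sums[ch] / cnts[ch]
    sums[p] <- sums[p] + h[ch] + rt$edge.length[e]
    cnts[p] <- cnts[p] + 1L
  }
  root <- n_tip + 1L
  h[root] <- sums[root] / cnts[root]
  if (h[root] <= 0) stop("degenerate tree: zero height at the calibrated node")
  mid <- mean(calibration)
  nodes <- (n_tip + 1L):n_all
  tipsets <- vapply(nodes, function(v) {
    tips <- ape::extract.clade(rt, v)$tip.label
    paste(sort(tips), collapse = ",")
  }, character(1))
  ages <- data.frame(
    node = nodes,
    clade = tipsets,
    age = h[nodes] * mid / h[root],
    age_lower = h[nodes] * calibration[1] / h[root],
    age_upper = h[nodes] * calibration[2] / h[root],
    stringsAsFactors = FALSE
  )
  rt$node.label <- signif(ages$age, 6)
  list(tree = rt, ages = ages, calibration = calibration,
       method = "relative-rate (child-averaged heights)")
}

#' Age of the most recent common ancestor of two taxa
#'
#' Convenience accessor on a [divergence_times()] result.
#'
#' @param dt Result of [divergence_times()].
#' @param taxa Character vector of tip labels.
#' @return Age in Mya of their MRCA.
#' @export
mrca_age <- function(dt, taxa) {
  node <- ape::getMRCA(dt$tree, taxa)
  dt$ages$age[dt$ages$node == node]
}
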