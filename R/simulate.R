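# Synthetic-data generators with planted ground truth.
#
# Every input the pipeline consumes can be simulated here: two-channel CpG
# array probe tables, qPCR Ct tables, clock-like sequence alignments and
# kinetic plate-reader traces. Fixing the seed makes each generator
# reproducible bit for bit.

#' Simulation configuration for synthetic CpG arrays
#'
#' @param n_genes Number of simulated genes (each with one CpG island).
#' @param probes_per_gene Probes covering each island.
#' @param tm_range Melting-temperature range, degrees C; probes draw Tm
#'   uniformly from it (default `c(70, 90)`, a plausible CpG-island range).
#' @param noise_sd Gaussian probe noise SD on the log2-ratio scale.
#' @param n_replicates Replicate arrays per cell line.
#' @param rng_seed Integer seed; the same seed reproduces identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, probes_per_gene = 2, tm_range = c(70, 90),
                       noise_sd = 0.3, n_replicates = 2, rng_seed = 1L) {
  stopifnot(n_genes >= 1, probes_per_gene >= 1, noise_sd >= 0,
            n_replicates >= 1, length(tm_range) == 2, tm_range[1] < tm_range[2])
  structure(list(n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 n_probes = as.integer(n_genes) * as.integer(probes_per_gene),
                 tm_range = as.numeric(tm_range),
                 noise_sd = as.numeric(noise_sd),
                 n_replicates = as.integer(n_replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Planted array truth table
#'
#' One row per planted (gene, line) effect. Hypermethylated genes must have a
#' positive planted log2 shift and hypomethylated genes a negative one; a
#' (gene, line) pair may appear at most once.
#'
#' @param gene_id,line,direction,planted_log2_shift Equal-length vectors;
#'   `line` in `c("mus", "spretus", "dunni", "pahari")`, `direction` in
#'   `c("hyper", "hypo")`.
#' @return Data frame of class `array_truth`.
#' @export
array_truth <- function(gene_id, line, direction, planted_log2_shift) {
  stopifnot(all(line %in% HAPLO_LINES), all(direction %in% c("hyper", "hypo")))
  if (any(direction == "hyper" & planted_log2_shift <= 0) ||
      any(direction == "hypo" & planted_log2_shift >= 0))
    stop("planted_log2_shift must be > 0 for hyper and < 0 for hypo")
  if (anyDuplicated(paste(gene_id, line)))
    stop("each (gene, line) pair may appear at most once")
  out <- data.frame(gene_id = gene_id, line = line, direction = direction,
                    planted_log2_shift = planted_log2_shift,
                    stringsAsFactors = FALSE)
  class(out) <- c("array_truth", "data.frame")
  out
}

#' Random planted truth under the default study conditions
#'
#' Plants `n_per_line` genes per cell line (disjoint across lines), half
#' hypermethylated at `+shift` and half hypomethylated at `-shift` log2 units.
#'
#' @param config A [sim_config()].
#' @param n_per_line Planted genes per line (default 20).
#' @param shift Magnitude of the planted log2 shift (default 3).
#' @return An [array_truth()] table.
#' @export
sim_array_truth <- function(config, n_per_line = 20, shift = 3) {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  need <- n_per_line * length(HAPLO_LINES)
  stopifnot(need <= config$n_genes)
  picked <- sample(genes, need)
  line <- rep(HAPLO_LINES, each = n_per_line)
  dir <- rep(rep(c("hyper", "hypo"), length.out = n_per_line), length(HAPLO_LINES))
  array_truth(picked, line, dir, ifelse(dir == "hyper", shift, -shift))
}

#' Generate two-channel CpG-array probe tables with planted truth
#'
#' Simulates replicate arrays for the four cell lines. Unaffected probes sit
#' at a baseline log2 ratio of 0; planted shifts are added in log space, plus
#' Gaussian noise of SD `config$noise_sd`. The input channel (Cy3) is fixed at
#' 1000 arbitrary units and Cy5 is derived from the log2 ratio, so a planted
#' shift of +3 at zero noise yields an exactly fourfold-cubed (8x) Cy5/Cy3
#' ratio. Tm is a probe property drawn once and shared across arrays.
#'
#' @param config A [sim_config()].
#' @param truth An [array_truth()] table; every gene must exist in the
#'   simulated annotation (`G0001 ...`), otherwise an error is raised.
#' @return List with `arrays` (`arrays[[line]][[replicate]]` probe tables:
#'   `probe_id`, `chrom`, `start`, `end`, `tm`, `cy3`, `cy5`), `annotation`
#'   (probe to gene map), `islands` (gene CpG-island intervals, 0-based
#'   half-open), `truth` and `config`.
#' @export
sim_cpg_arrays <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  if (!all(truth$gene_id %in% genes))
    stop("truth references unknown gene(s): ",
         paste(setdiff(truth$gene_id, genes), collapse = ", "))
  set.seed(config$rng_seed)
  ppg <- config$probes_per_gene
  n <- config$n_probes
  gene_of_probe <- rep(genes, each = ppg)
  island_start <- (seq_len(config$n_genes) - 1L) * 2000L
  probes <- data.frame(
    probe_id = sprintf("P%06d", seq_len(n)),
    chrom = "chr1",
    start = rep(island_start, each = ppg) + (seq_len(ppg) - 1L) * 100L,
    end = rep(island_start, each = ppg) + (seq_len(ppg) - 1L) * 100L + 60L,
    tm = runif(n, config$tm_range[1], config$tm_range[2]),
    stringsAsFactors = FALSE
  )
  annotation <- data.frame(probe_id = probes$probe_id, gene_id = gene_of_probe,
                           known = TRUE, stringsAsFactors = FALSE)
  islands <- data.frame(gene_id = genes, chrom = "chr1", start = island_start,
                        end = island_start + 1000L, known = TRUE,
                        stringsAsFactors = FALSE)
  shift <- matrix(0, nrow = n, ncol = length(HAPLO_LINES),
                  dimnames = list(NULL, HAPLO_LINES))
  for (k in seq_len(nrow(truth))) {
    idx <- gene_of_probe == truth$gene_id[k]
    shift[idx, truth$line[k]] <- truth$planted_log2_shift[k]
  }
  arrays <- lapply(HAPLO_LINES, function(l) {
    lapply(seq_len(config$n_replicates), function(r) {
      ratio <- shift[, l]
      if (config$noise_sd > 0) ratio <- ratio + rnorm(n, 0, config$noise_sd)
      out <- probes
      out$cy3 <- 1000
      out$cy5 <- 1000 * 2^ratio
      out
    })
  })
  names(arrays) <- HAPLO_LINES
  list(arrays = arrays, annotation = annotation, islands = islands,
       truth = truth, config = config)
}

#' Generate qPCR Ct tables from a known standard curve
#'
#' Emits replicate wells with `Ct = intercept + slope * log10(quantity) +
#' N(0, noise_sd)`, emulating dilution-series quantification against external
#' standards.
#'
#' @param quantities Named or unnamed vector of true template quantities
#'   (copies); all must be positive.
#' @param slope Standard-curve slope (Ct per log10 copies); must be negative.
#' @param intercept Ct at one copy.
#' @param noise_sd Gaussian Ct noise SD (cycles).
#' @param n_replicates Wells per sample.
#' @param seed Optional integer seed.
#' @return List with `ct` (`sample`, `replicate`, `ct`) and `truth`
#'   (`sample`, `quantity`).
#' @export
sim_qpcr_tables <- function(quantities, slope = -3.5, intercept = 38,
                            noise_sd = 0, n_replicates = 3, seed = NULL) {
  if (slope >= 0) stop("standard-curve slope must be negative")
  if (any(quantities <= 0)) stop("quantities must be positive")
  if (!is.null(seed)) set.seed(seed)
  samples <- names(quantities)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_along(quantities))
  ct <- expand.grid(replicate = seq_len(n_replicates),
                    sample = samples, stringsAsFactors = FALSE)
  q <- setNames(as.numeric(quantities), samples)
  mu <- intercept + slope * log10(q[ct$sample])
  ct$ct <- as.numeric(mu) + if (noise_sd > 0)
    rnorm(nrow(ct), 0, noise_sd) else 0
  list(ct = ct[, c("sample", "replicate", "ct")],
       truth = data.frame(sample = samples, quantity = as.numeric(q),
                          stringsAsFactors = FALSE))
}

#' Generate a linear kinetic absorbance trace
#'
#' Emulates an endpoint-free kinetic plate read: absorbance sampled every
#' `interval_s` seconds for `duration_min` minutes (61 points on the default
#' 30-min / 30-s grid), following `A(t) = intercept + rate * t + noise` with
#' `t` in minutes.
#'
#' @param rate Slope in absorbance units per minute.
#' @param intercept Absorbance at time zero.
#' @param duration_min,interval_s Read length (minutes) and sampling interval
#'   (seconds); the duration must be an integer number of intervals.
#' @param noise_sd Gaussian absorbance noise SD.
#' @param seed Optional integer seed.
#' @return Data frame with `time_s` and `absorbance`.
#' @export
sim_kinetic_trace <- function(rate, intercept = 0.1, duration_min = 30,
                              interval_s = 30, noise_sd = 0, seed = NULL) {
  n_int <- duration_min * 60 / interval_s
  if (abs(n_int - round(n_int)) > 1e-9)
    stop("duration must be an integer multiple of the sampling interval")
  if (!is.null(seed)) set.seed(seed)
  time_s <- seq(0, duration_min * 60, by = interval_s)
  a <- intercept + rate * time_s / 60
  if (noise_sd > 0) a <- a + rnorm(length(a), 0, noise_sd)
  data.frame(time_s = time_s, absorbance = a)
}

#' Simulate a clock-like alignment under GTR+Gamma
#'
#' Evolves nucleotide sequences site by site down an ultrametric time tree
#' under a [gtr_model()]: each site draws one of the model's discrete gamma
#' rate categories, branch durations (in My) are converted to expected
#' substitutions per site via `clock_rate`, and characters are propagated from
#' a stationary root draw through the exact GTR transition probabilities.
#'
#' @param tree An ultrametric `phylo` tree with branch lengths in time units
#'   (My); non-ultrametric input is rejected.
#' @param model A [gtr_model()].
#' @param n_sites Alignment length.
#' @param clock_rate Substitutions per site per My (default 0.01, a realistic
#'   rodent mtDNA rate).
#' @param seed Optional integer seed.
#' @return List with `alignment` (a `DNAbin` matrix), `tree`, `ages` (true
#'   internal-node ages, My) and `clock_rate`.
#' @export
sim_clock_alignment <- function(tree, model, n_sites, clock_rate = 0.01,
                                seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "gtr_model"), n_sites >= 1)
  depth <- ape::node.depth.edgelength(tree)
  tip_depth <- depth[seq_along(tree$tip.label)]
  # relative criterion; a zero-depth (all-zero-branch) tree is trivially clocklike
  if (max(tip_depth) > 0 && !ape::is.ultrametric(tree))
    stop("tree must be ultrametric in time to simulate a molecular clock")
  if (!is.null(seed)) set.seed(seed)
  eg <- gtr_eigen(model)
  rates_cat <- eg$rates_cat
  cat_of_site <- sample.int(length(rates_cat), n_sites, replace = TRUE)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  seqs <- matrix(0L, nrow = n_tip + n_node, ncol = n_sites)
  tr <- ape::reorder.phylo(tree, "cladewise")
  root <- n_tip + 1L
  seqs[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = model$freqs)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    t_sub <- tr$edge.length[e] * clock_rate
    if (t_sub == 0) {
      seqs[ch, ] <- seqs[p, ]
      next
    }
    for (k in seq_along(rates_cat)) {
      P <- gtr_pmat(eg, t_sub * rates_cat[k])
      for (b in 1:4) {
        idx <- which(cat_of_site == k & seqs[p, ] == b)
        if (length(idx))
          seqs[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                      prob = P[b, ])
      }
    }
  }
  chars <- matrix(c("a", "c", "g", "t")[seqs[seq_len(n_tip), ]], nrow = n_tip,
                  dimnames = list(tree$tip.label, NULL))
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_len(n_tip)]) - depth[(n_tip + 1):(n_tip + n_node)]
  list(alignment = ape::as.DNAbin(chars), tree = tree,
       ages = data.frame(node = (n_tip + 1):(n_tip + n_node), age = ages),
       clock_rate = clock_rate)
}

#' Write / read probe tables and annotations as TSV
#'
#' Probe tables use the header `ProbeID, Chr, Start, End, Tm, Cy3, Cy5` with
#' 0-based half-open coordinates; annotation files are BED-like
#' (`probe -> gene`). Round-trips are lossless up to numeric printing
#' precision (15 significant digits).
#'
#' @param probes,annotation Data frames as produced by [sim_cpg_arrays()].
#' @param path Output file.
#' @return `write_*` return `path` invisibly; `read_*` return data frames in
#'   the package's internal column naming.
#' @export
write_probe_table <- function(probes, path) {
  out <- data.frame(ProbeID = probes$probe_id, Chr = probes$chrom,
                    Start = probes$start, End = probes$end, Tm = probes$tm,
                    Cy3 = probes$cy3, Cy5 = probes$cy5)
  write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(probe_id = raw$ProbeID, chrom = raw$Chr,
             start = as.integer(raw$Start), end = as.integer(raw$End),
             tm = as.numeric(raw$Tm), cy3 = as.numeric(raw$Cy3),
             cy5 = as.numeric(raw$Cy5), stringsAsFactors = FALSE)
}

#' @rdname write_probe_table
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_annotation <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
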