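# Independent oracles used across the suite. Each reimplements the checked
# quantity by brute force or closed form, never by calling the package path
# it is checking.

# per-base brute-force segment->gene mapping: average segment value over the
# gene's covered bases, NA when no base is covered
brute_force_gene_dcn <- function(segments, annotation) {
  samples <- sort(unique(segments$sample))
  out <- matrix(NA_real_, nrow(annotation), length(samples),
                dimnames = list(annotation$gene_id, samples))
  for (g in seq_len(nrow(annotation))) {
    bases <- annotation$start[g]:(annotation$end[g] - 1L)
    for (s in seq_along(samples)) {
      seg <- segments[segments$sample == samples[s] &
                        segments$chromosome == annotation$chromosome[g], ,
                      drop = FALSE]
      if (nrow(seg) == 0L) next
      vals <- rep(NA_real_, length(bases))
      for (k in seq_len(nrow(seg))) {
        hit <- bases >= seg$start[k] & bases < seg$end[k]
        vals[hit] <- seg$value[k]
      }
      if (any(!is.na(vals))) out[g, s] <- mean(vals, na.rm = TRUE)
    }
  }
  out
}

# random mapping instance on one chromosome: n_genes genes, n_segs
# non-overlapping segments leaving random gaps
random_mapping_instance <- function(n_genes = 20, n_segs = 5, span = 10000) {
  gs <- sort(sample.int(span - 50L, n_genes))
  ann <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                    symbol = sprintf("g%02d", seq_len(n_genes)),
                    chromosome = "1",
                    start = gs, end = gs + sample(10:200, n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  ann$end <- pmin(ann$end, span)
  cuts <- sort(sample.int(span - 1L, 2L * n_segs))
  starts <- cuts[seq(1L, length(cuts), by = 2L)]
  ends <- cuts[seq(2L, length(cuts), by = 2L)]
  keep <- starts < ends
  segs <- data.frame(sample = "S1", chromosome = "1",
                     start = starts[keep], end = ends[keep],
                     value = round(stats::runif(sum(keep), 0.3, 3), 3),
                     stringsAsFactors = FALSE)
  list(annotation = ann, segments = segs)
}

# two-sided Fisher exact p by hypergeometric enumeration of all tables with
# the observed margins (probabilities <= observed, with fisher.test's
# relative tolerance)
fisher_two_sided_oracle <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by direct enumeration: q_(i) is the smallest
# running minimum of p_(j) * n / j over j >= i
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# hand Mantel-Haenszel log-rank chi-square from the O/E/V table
logrank_oracle <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d <- sum(t1 == t & e1 == 1) + sum(t2 == t & e2 == 1)
    o1 <- sum(t1 == t & e1 == 1)
    o_minus_e <- o_minus_e + o1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# a small deterministic expression/annotation fixture
tiny_annotation <- function() {
  data.frame(gene_id = c("gA", "gB", "gC"),
             symbol = c("gA", "gB", "gC"),
             chromosome = c("1", "1", "2"),
             start = c(0L, 500L, 100L), end = c(100L, 700L, 300L),
             stringsAsFactors = FALSE)
}

# sim_config scaled down for fast unit tests
small_config <- function(seed = 1, ...) {
  genome <- data.frame(chromosome = c("1", "13"), n_genes = 60L,
                       gene_length = 1000L, spacing = 1000L,
                       stringsAsFactors = FALSE)
  len <- 60L * 2000L
  events <- data.frame(chromosome = "13", start = len %/% 2L, end = len,
                       type = "loss", pi = 0.4, mu = -0.7,
                       stringsAsFactors = FALSE)
  args <- list(n_pt_dcn = 40, n_pt_expr = 38, n_overlap = 36, n_nt_expr = 12,
               genome = genome, scna_events = events,
               dosage_genes = sprintf("G13_%04d", 36:55),
               templates = NULL, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
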