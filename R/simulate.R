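#' Simulation configuration for a synthetic tumor/normal cohort
#'
#' Defines every parameter of the synthetic-cohort generator. The defaults
#' emulate a TCGA-LIHC-like study at desk scale: 376 tumor (PT) samples
#' with segmented DCN and a paired normal (NT) profile each, 371 PT
#' expression samples of which 369 also carry DCN, 50 NT expression
#' samples; a toy genome of 4 chromosomes x 500 genes; one recurrent
#' "13q-like" arm-level deletion (carrier fraction 0.4, mean log2 shift
#' -0.7) and one gain arm (0.3, +0.6); 100 dosage-coupled genes inside the
#' deletion arm whose expression follows gene-level copy number with slope
#' `beta`; exponential overall survival whose log-hazard depends on a
#' driver gene's standardized expression; and two planted subclass
#' signatures.
#'
#' @param n_pt_dcn Number of PT samples with DCN (each paired to an NT DCN
#'   profile).
#' @param n_pt_expr Number of PT expression samples.
#' @param n_overlap Number of PT samples carrying both assays (the
#'   remaining expression samples are expression-only).
#' @param n_nt_expr Number of NT expression samples.
#' @param genome `data.frame` with `chromosome`, `n_genes`, `gene_length`,
#'   `spacing` (bp).
#' @param scna_events `data.frame` with `chromosome`, `start`, `end`
#'   (0-based half-open bp), `type` (`"gain"`/`"loss"`), `pi` (tumor
#'   carrier fraction), `mu` (mean log2 shift, negative for loss).
#' @param segments_per_chromosome Segments per chromosome per sample into
#'   which the baseline profile is broken (noise is applied at segment
#'   level so segment-to-gene mapping is genuinely exercised).
#' @param sigma_c Segment-level log2 copy-ratio noise sd (> 0).
#' @param dosage_genes Gene ids whose expression is copy-coupled; `NULL`
#'   selects the default 100 genes inside the deletion arm.
#' @param beta Dosage coupling slope (log2 expression per log2 copy ratio).
#' @param baseline_log2_range Range of per-gene baseline log2 expression
#'   (drawn uniformly per gene).
#' @param sigma_e Expression noise sd on the log2 scale (> 0).
#' @param survival List: `h0` baseline hazard (> 0, per time unit),
#'   `driver_gene` (must be a simulated gene), `gamma` log-hazard slope on
#'   the driver's standardized log2 expression, `horizon` uniform
#'   censoring horizon.
#' @param templates List: `n_classes`, `genes_per_class`, `delta` (mean
#'   log2 shift added along each signature), `fractions` (per-class
#'   fraction of PT expression samples; must sum to <= 1), or `NULL` to
#'   plant no signatures.
#' @param seed Master seed; named substreams for copy number, expression,
#'   survival and templates are derived from it so changing one
#'   component's parameters does not perturb the other components' draws.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_pt_dcn = 376, n_pt_expr = 371, n_overlap = 369,
                       n_nt_expr = 50,
                       genome = default_genome(),
                       scna_events = default_scna_events(genome),
                       segments_per_chromosome = 5,
                       sigma_c = 0.1,
                       dosage_genes = NULL,
                       beta = 1.5,
                       baseline_log2_range = c(4, 8),
                       sigma_e = 0.55,
                       survival = list(h0 = 0.015, driver_gene = NULL,
                                       gamma = -0.5, horizon = 120),
                       templates = list(n_classes = 2, genes_per_class = 30,
                                        delta = 1.0, fractions = c(0.25, 0.25)),
                       seed = 1) {
  stopifnot(n_pt_dcn >= 1, n_pt_expr >= 1, n_nt_expr >= 1,
            n_overlap <= n_pt_dcn, n_overlap <= n_pt_expr)
  if (!(sigma_c > 0) || !(sigma_e > 0)) stop("sigma_c and sigma_e must be > 0")
  genome$chromosome <- normalize_chrom(genome$chromosome)
  ann <- build_annotation(genome)
  chrom_len <- stats::setNames(genome$n_genes * (genome$gene_length + genome$spacing),
                               genome$chromosome)
  if (nrow(scna_events) > 0L) {
    scna_events$chromosome <- normalize_chrom(scna_events$chromosome)
    if (!all(scna_events$chromosome %in% genome$chromosome)) {
      stop("config error: event chromosome outside the genome")
    }
    if (any(scna_events$start < 0 |
              scna_events$end > chrom_len[scna_events$chromosome] |
              scna_events$start >= scna_events$end)) {
      stop("config error: event region outside the genome")
    }
    if (any(scna_events$pi < 0 | scna_events$pi > 1)) {
      stop("config error: pi must be in [0, 1]")
    }
  }
  if (is.null(dosage_genes)) {
    loss <- which(scna_events$type == "loss")
    dosage_genes <- if (length(loss) > 0L) {
      ev <- scna_events[loss[1L], ]
      inside <- ann$gene_id[ann$chromosome == ev$chromosome &
                              ann$start >= ev$start & ann$end <= ev$end]
      utils::head(inside[seq(51L, length.out = min(100L, length(inside) - 50L))], 100L)
    } else character()
  }
  if (!all(dosage_genes %in% ann$gene_id)) stop("config error: unknown dosage gene")
  if (is.null(survival$driver_gene)) {
    survival$driver_gene <- if (length(dosage_genes) > 0L) {
      dosage_genes[ceiling(length(dosage_genes) / 2)]
    } else ann$gene_id[1L]
  }
  if (!survival$driver_gene %in% ann$gene_id) stop("config error: unknown driver gene")
  if (!(survival$h0 > 0)) stop("config error: h0 must be > 0")
  if (!is.null(templates)) {
    if (sum(templates$fractions) > 1 + 1e-12) {
      stop("config error: template fractions must sum to <= 1")
    }
    if (length(templates$fractions) != templates$n_classes) {
      stop("config error: one fraction per template class")
    }
  }
  set.seed(seed)
  substreams <- stats::setNames(sample.int(.Machine$integer.max - 1L, 4),
                                c("copy_number", "expression", "survival",
                                  "templates"))
  structure(list(n_pt_dcn = n_pt_dcn, n_pt_expr = n_pt_expr,
                 n_overlap = n_overlap, n_nt_expr = n_nt_expr,
                 genome = genome, annotation = ann, chrom_len = chrom_len,
                 scna_events = scna_events,
                 segments_per_chromosome = segments_per_chromosome,
                 sigma_c = sigma_c, dosage_genes = dosage_genes, beta = beta,
                 baseline_log2_range = baseline_log2_range, sigma_e = sigma_e,
                 survival = survival, templates = templates,
                 seed = seed, substreams = substreams),
            class = "sim_config")
}

#' Default toy genome: 4 chromosomes x 500 genes
#' @return Genome `data.frame` for [sim_config()].
#' @export
default_genome <- function() {
  data.frame(chromosome = c("1", "2", "8", "13"),
             n_genes = 500L, gene_length = 10000L, spacing = 10000L,
             stringsAsFactors = FALSE)
}

#' Default recurrent events: a 13q-like deletion arm and a gain arm
#'
#' The distal half of chromosome 13 is deleted in 40% of tumors (mean log2
#' shift -0.7) and the distal half of chromosome 8 gained in 30% (+0.6),
#' mirroring the recurrent loss/gain hotspots of hepatocellular carcinoma
#' at toy scale.
#'
#' @param genome Genome `data.frame`.
#' @return Event `data.frame` for [sim_config()].
#' @export
default_scna_events <- function(genome = default_genome()) {
  len <- genome$n_genes * (genome$gene_length + genome$spacing)
  half <- len %/% 2
  pick <- function(chr) which(genome$chromosome == chr)
  data.frame(chromosome = c("8", "13"),
             start = c(half[pick("8")], half[pick("13")]),
             end = c(len[pick("8")], len[pick("13")]),
             type = c("gain", "loss"),
             pi = c(0.3, 0.4), mu = c(0.6, -0.7),
             stringsAsFactors = FALSE)
}

# gene annotation laid out deterministically on the toy genome
build_annotation <- function(genome) {
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    g <- genome[i, ]
    idx <- seq_len(g$n_genes)
    start <- (idx - 1L) * (g$gene_length + g$spacing)
    data.frame(gene_id = sprintf("G%s_%04d", g$chromosome, idx),
               symbol = sprintf("G%s_%04d", g$chromosome, idx),
               chromosome = g$chromosome,
               start = as.integer(start),
               end = as.integer(start + g$gene_length),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate segmented copy-number profiles
#'
#' NT samples receive segment-level log2 copy ratios drawn from
#' `Normal(0, sigma_c)`; each PT sample independently carries each
#' configured arm event with probability `pi`, which shifts the log2 value
#' of every segment inside the region by `mu`. Segment boundaries are
#' random per sample/chromosome (plus the event boundaries for carriers),
#' and values are emitted on the linear scale. Every PT sample has a
#' paired NT sample.
#'
#' @param config A [sim_config()].
#' @return List with `dcn_pt`, `dcn_nt` (segment `data.frame`s),
#'   `seg_extra` (profiles of expression-only PT samples), `carriers`
#'   (PT-by-event 0/1 matrix incl. expression-only samples), `pt_ids`,
#'   `nt_ids`, `extra_ids`, `pairing`.
#' @export
simulate_copy_number <- function(config) {
  set.seed(config$substreams[["copy_number"]])
  n_extra <- config$n_pt_expr - config$n_overlap
  pt_ids <- sprintf("PT%04d", seq_len(config$n_pt_dcn))
  extra_ids <- if (n_extra > 0L) sprintf("PTX%03d", seq_len(n_extra)) else character()
  nt_ids <- sprintf("NT%04d", seq_len(config$n_pt_dcn))
  all_pt <- c(pt_ids, extra_ids)
  ev <- config$scna_events
  carriers <- matrix(0L, length(all_pt), nrow(ev),
                     dimnames = list(all_pt, if (nrow(ev)) paste0("event", seq_len(nrow(ev)))))
  for (j in seq_len(nrow(ev))) {
    carriers[, j] <- stats::rbinom(length(all_pt), 1L, ev$pi[j])
  }
  # accumulate plain vectors and build each segment table once (cheap at
  # hundreds of samples, where per-sample data.frame construction is not)
  sim_samples <- function(ids, carrier_rows) {
    acc <- list(sample = list(), chromosome = list(), start = list(),
                end = list(), value = list())
    pos <- 0L
    for (si in seq_along(ids)) {
      carry <- carrier_rows[si, ]
      for (i in seq_len(nrow(config$genome))) {
        chr <- config$genome$chromosome[i]
        L <- config$chrom_len[[chr]]
        k <- config$segments_per_chromosome
        cuts <- if (k > 1L) sort(sample.int(L - 1L, k - 1L, useHash = TRUE)) else integer()
        ev_here <- which(ev$chromosome == chr & carry == 1L)
        bounds <- sort(unique(c(0, cuts, ev$start[ev_here], ev$end[ev_here], L)))
        s <- bounds[-length(bounds)]
        e <- bounds[-1L]
        v <- stats::rnorm(length(s), 0, config$sigma_c)
        for (jj in ev_here) {
          inside <- s >= ev$start[jj] & e <= ev$end[jj]
          v[inside] <- v[inside] + ev$mu[jj]
        }
        pos <- pos + 1L
        acc$sample[[pos]] <- rep(ids[si], length(s))
        acc$chromosome[[pos]] <- rep(chr, length(s))
        acc$start[[pos]] <- as.integer(s)
        acc$end[[pos]] <- as.integer(e)
        acc$value[[pos]] <- 2^v
      }
    }
    data.frame(sample = unlist(acc$sample), chromosome = unlist(acc$chromosome),
               start = unlist(acc$start), end = unlist(acc$end),
               value = unlist(acc$value), stringsAsFactors = FALSE)
  }
  seg_pt <- sim_samples(pt_ids, carriers[seq_along(pt_ids), , drop = FALSE])
  seg_extra <- if (n_extra > 0L) {
    sim_samples(extra_ids,
                carriers[length(pt_ids) + seq_len(n_extra), , drop = FALSE])
  } else empty_seg()
  no_carry <- matrix(0L, length(nt_ids), nrow(ev))
  seg_nt <- sim_samples(nt_ids, no_carry)
  list(dcn_pt = seg_pt, dcn_nt = seg_nt, seg_extra = seg_extra,
       carriers = carriers, pt_ids = pt_ids, nt_ids = nt_ids,
       extra_ids = extra_ids,
       pairing = stats::setNames(nt_ids, pt_ids))
}

#' Simulate dosage-coupled expression
#'
#' For dosage genes, log2 expression is
#' `baseline + beta * c + Normal(0, sigma_e)` where `c` is the gene-level
#' log2 copy ratio obtained by mapping the sample's simulated segments onto
#' the gene annotation; for all other genes `beta = 0`. Values are emitted
#' as `2^log2`, hence nonnegative FPKM-like abundances.
#'
#' @param config A [sim_config()].
#' @param cn Output of [simulate_copy_number()].
#' @return List with `expression_pt`, `expression_nt` (matrices),
#'   `baseline` (per-gene log2 baseline), `copy_log2_pt` (gene-level log2
#'   copy ratios of the PT expression samples).
#' @export
simulate_expression <- function(config, cn) {
  set.seed(config$substreams[["expression"]])
  ann <- config$annotation
  pt_expr_ids <- c(cn$pt_ids[seq_len(config$n_overlap)], cn$extra_ids)
  nt_expr_ids <- cn$nt_ids[seq_len(config$n_nt_expr)]
  seg_expr <- rbind(cn$dcn_pt[cn$dcn_pt$sample %in% pt_expr_ids, , drop = FALSE],
                    cn$seg_extra)
  c_pt <- log2(map_segments_to_genes(seg_expr, ann))[, pt_expr_ids, drop = FALSE]
  seg_nt <- cn$dcn_nt[cn$dcn_nt$sample %in% nt_expr_ids, , drop = FALSE]
  c_nt <- log2(map_segments_to_genes(seg_nt, ann))[, nt_expr_ids, drop = FALSE]
  c_pt[is.na(c_pt)] <- 0
  c_nt[is.na(c_nt)] <- 0
  n_g <- nrow(ann)
  baseline <- stats::runif(n_g, config$baseline_log2_range[1],
                           config$baseline_log2_range[2])
  names(baseline) <- ann$gene_id
  beta_vec <- ifelse(ann$gene_id %in% config$dosage_genes, config$beta, 0)
  lp <- baseline + beta_vec * c_pt +
    matrix(stats::rnorm(n_g * length(pt_expr_ids), 0, config$sigma_e),
           n_g, length(pt_expr_ids))
  ln <- baseline + beta_vec * c_nt +
    matrix(stats::rnorm(n_g * length(nt_expr_ids), 0, config$sigma_e),
           n_g, length(nt_expr_ids))
  expression_pt <- 2^lp
  expression_nt <- 2^ln
  dimnames(expression_pt) <- list(ann$gene_id, pt_expr_ids)
  dimnames(expression_nt) <- list(ann$gene_id, nt_expr_ids)
  list(expression_pt = expression_pt, expression_nt = expression_nt,
       baseline = baseline, copy_log2_pt = c_pt)
}

# plant subclass signatures: add delta * direction to assigned samples'
# signature-gene log2 expression
plant_templates <- function(config, expression_pt) {
  tc <- config$templates
  if (is.null(tc)) {
    return(list(expression_pt = expression_pt, templates = NULL,
                subclass = stats::setNames(rep("none", ncol(expression_pt)),
                                           colnames(expression_pt))))
  }
  set.seed(config$substreams[["templates"]])
  ann <- config$annotation
  event_chroms <- unique(config$scna_events$chromosome)
  eligible <- ann$gene_id[!(ann$chromosome %in% event_chroms) &
                            !(ann$gene_id %in% config$dosage_genes)]
  total <- tc$n_classes * tc$genes_per_class
  if (length(eligible) < total) stop("config error: not enough genes for templates")
  picked <- sample(eligible, total)
  templates <- list()
  for (k in seq_len(tc$n_classes)) {
    g <- picked[((k - 1) * tc$genes_per_class + 1):(k * tc$genes_per_class)]
    templates[[paste0("class", k)]] <-
      data.frame(gene_id = g,
                 direction = sample(c(-1, 1), length(g), replace = TRUE),
                 stringsAsFactors = FALSE)
  }
  n <- ncol(expression_pt)
  counts <- round(tc$fractions * n)
  shuffled <- sample(colnames(expression_pt))
  subclass <- stats::setNames(rep("none", n), colnames(expression_pt))
  offset <- 0L
  for (k in seq_len(tc$n_classes)) {
    members <- shuffled[seq_len(counts[k]) + offset]
    offset <- offset + counts[k]
    subclass[members] <- paste0("class", k)
    tm <- templates[[paste0("class", k)]]
    expression_pt[tm$gene_id, members] <-
      expression_pt[tm$gene_id, members] * 2^(tc$delta * tm$direction)
  }
  list(expression_pt = expression_pt, templates = templates,
       subclass = subclass)
}

#' Simulate overall survival driven by a gene's expression
#'
#' Event times are exponential with rate `h0 * exp(gamma * z)` where `z` is
#' the driver gene's standardized log2 expression; censoring times are
#' uniform on `(0, horizon)`. With a negative `gamma`, low driver
#' expression confers a higher hazard (shorter survival), as for a
#' protective tumor-suppressor-like driver.
#'
#' @param config A [sim_config()].
#' @param expression_pt PT expression matrix containing the driver gene.
#' @return Clinical `data.frame` with `sample_id`, `os_time`, `os_event`.
#' @export
simulate_survival <- function(config, expression_pt) {
  set.seed(config$substreams[["survival"]])
  sv <- config$survival
  z <- as.vector(scale(log2(expression_pt[sv$driver_gene, ] + 1)))
  if (any(!is.finite(z))) z[!is.finite(z)] <- 0
  rate <- sv$h0 * exp(sv$gamma * z)
  t_event <- stats::rexp(length(rate), rate)
  t_cens <- stats::runif(length(rate), 0, sv$horizon)
  data.frame(sample_id = colnames(expression_pt),
             os_time = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the copy-number, expression, template and survival generators under
#' their named substreams and assembles the results into a
#' `cohort_dataset`. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a `cohort_dataset`), `truth` (ground truth:
#'   event carriers, dosage genes and slope, subclass assignment, survival
#'   parameters, per-gene baselines) and `templates` (the planted
#'   signature set, or `NULL`).
#' @export
simulate_cohort <- function(config) {
  cn <- simulate_copy_number(config)
  ex <- simulate_expression(config, cn)
  pl <- plant_templates(config, ex$expression_pt)
  clinical <- simulate_survival(config, pl$expression_pt)
  cohort <- suppressMessages(
    assemble_cohort(expression_pt = pl$expression_pt,
                    expression_nt = ex$expression_nt,
                    dcn_pt = cn$dcn_pt, dcn_nt = cn$dcn_nt,
                    annotation = config$annotation,
                    clinical = clinical, pairing = cn$pairing))
  truth <- list(carriers = cn$carriers, events = config$scna_events,
                dosage_genes = config$dosage_genes, beta = config$beta,
                baseline = ex$baseline, copy_log2_pt = ex$copy_log2_pt,
                subclass = pl$subclass, survival = config$survival,
                extra_ids = cn$extra_ids)
  list(cohort = cohort, truth = truth, templates = pl$templates)
}

#' Write a simulated cohort to disk
#'
#' Writes SEG files (PT/NT), expression TSVs, clinical TSV, annotation BED,
#' template TSV and a ground-truth TSV into a directory.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- sim$cohort
  paths <- c(seg_pt = file.path(dir, "dcn_pt.seg"),
             seg_nt = file.path(dir, "dcn_nt.seg"),
             expr_pt = file.path(dir, "expression_pt.tsv"),
             expr_nt = file.path(dir, "expression_nt.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             annotation = file.path(dir, "annotation.bed"),
             truth = file.path(dir, "ground_truth.tsv"))
  write_seg(co$dcn_pt, paths[["seg_pt"]])
  write_seg(co$dcn_nt, paths[["seg_nt"]])
  write_expression(co$expression_pt, paths[["expr_pt"]])
  write_expression(co$expression_nt, paths[["expr_nt"]])
  write_clinical(co$clinical, paths[["clinical"]])
  write_gene_annotation(co$annotation, paths[["annotation"]])
  truth_df <- data.frame(sample_id = rownames(sim$truth$carriers),
                         sim$truth$carriers,
                         subclass = sim$truth$subclass[rownames(sim$truth$carriers)],
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sim$templates)) {
    paths <- c(paths, templates = file.path(dir, "templates.tsv"))
    write_templates(sim$templates, paths[["templates"]])
  }
  invisible(paths)
}
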