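test_that("the simulated bundle is deterministic in the seed", {
  s1 <- simulate_cohort(small_config(seed = 3))
  s2 <- simulate_cohort(small_config(seed = 3))
  expect_identical(s1$cohort$expression_pt, s2$cohort$expression_pt)
  expect_identical(s1$cohort$dcn_pt, s2$cohort$dcn_pt)
  expect_identical(s1$cohort$clinical, s2$cohort$clinical)
  s3 <- simulate_cohort(small_config(seed = 4))
  expect_false(identical(s1$cohort$expression_pt, s3$cohort$expression_pt))
})

test_that("cohort dimensions follow the configuration", {
  cfg <- small_config(seed = 1)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  expect_equal(length(unique(co$dcn_pt$sample)), cfg$n_pt_dcn)
  expect_equal(length(unique(co$dcn_nt$sample)), cfg$n_pt_dcn)
  expect_equal(ncol(co$expression_pt), cfg$n_pt_expr)
  expect_equal(ncol(co$expression_nt), cfg$n_nt_expr)
  expect_equal(length(co$samples_both), cfg$n_overlap)
  expect_equal(nrow(co$clinical), cfg$n_pt_expr)
  expect_true(all(co$expression_pt >= 0))
  expect_true(all(co$dcn_pt$value > 0))
  # every PT DCN sample is paired
  expect_setequal(names(co$pairing), unique(co$dcn_pt$sample))
})

test_that("event-free tumors are distributed like normals", {
  cfg <- small_config(seed = 6)
  cfg$scna_events$pi <- 0
  sim <- simulate_copy_number(cfg)
  expect_true(all(sim$carriers == 0))
  ks <- suppressWarnings(
    ks.test(log2(sim$dcn_pt$value), log2(sim$dcn_nt$value)))
  expect_gt(ks$p.value, 0.001)
})

test_that("a certain deletion halves the linear copy ratio in the region", {
  cfg <- small_config(seed = 8, sigma_c = 1e-9)
  cfg$scna_events$pi <- 1
  cfg$scna_events$mu <- -1
  cn <- simulate_copy_number(cfg)
  gd <- map_segments_to_genes(cn$dcn_pt, cfg$annotation)
  ev <- cfg$scna_events[1, ]
  in_arm <- cfg$annotation$gene_id[cfg$annotation$chromosome == ev$chromosome &
                                     cfg$annotation$start >= ev$start]
  expect_equal(unname(as.vector(gd[in_arm, ])),
               rep(0.5, length(in_arm) * ncol(gd)), tolerance = 1e-6)
})

test_that("carrier fractions fall within binomial bounds", {
  cfg <- small_config(seed = 12, n_pt_dcn = 500, n_pt_expr = 500,
                      n_overlap = 500)
  cn <- simulate_copy_number(cfg)
  frac <- mean(cn$carriers[, 1])
  bounds <- qbinom(c(0.005, 0.995), 500, 0.4) / 500
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("dosage coupling reproduces the analytic DE-SCNA correlation", {
  # rho = beta * sd(c) / sqrt(beta^2 var(c) + sigma_e^2), with
  # var(c) = mu^2 pi (1 - pi) + sigma_c^2 for an in-arm gene
  cfg <- small_config(seed = 19, n_pt_dcn = 1000, n_pt_expr = 1000,
                      n_overlap = 1000, n_nt_expr = 60)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  dcn_pt <- map_segments_to_genes(co$dcn_pt, co$annotation)
  dcn_nt <- map_segments_to_genes(co$dcn_nt, co$annotation)
  de <- compute_de_matrix(co$expression_pt, co$expression_nt)
  scna <- compute_scna_matrix(dcn_pt, dcn_nt)
  cors <- gene_wise_correlation(de, scna)
  ev <- cfg$scna_events[1, ]
  var_c <- ev$mu^2 * ev$pi * (1 - ev$pi) + cfg$sigma_c^2
  rho <- cfg$beta * sqrt(var_c) / sqrt(cfg$beta^2 * var_c + cfg$sigma_e^2)
  mean_r <- mean(cors$cor_r[cors$gene_id %in% cfg$dosage_genes])
  expect_equal(mean_r, rho, tolerance = 0.05)
  # uncoupled genes show no dosage correlation
  null_genes <- setdiff(rownames(de)[1:60], cfg$dosage_genes)
  expect_lt(max(abs(cors$cor_r[cors$gene_id %in% null_genes])), 0.2)
})

test_that("uncoupled expression is uncorrelated with copy number", {
  cfg <- small_config(seed = 23, n_pt_dcn = 300, n_pt_expr = 300,
                      n_overlap = 300, beta = 1e-12)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  dcn_pt <- map_segments_to_genes(co$dcn_pt, co$annotation)
  dcn_nt <- map_segments_to_genes(co$dcn_nt, co$annotation)
  de <- compute_de_matrix(co$expression_pt, co$expression_nt)
  scna <- compute_scna_matrix(dcn_pt, dcn_nt)
  cors <- gene_wise_correlation(de, scna)
  r_dosage <- cors$cor_r[cors$gene_id %in% cfg$dosage_genes]
  expect_lt(mean(abs(r_dosage)), 0.1)
})

test_that("survival generation responds to the driver and the horizon", {
  cfg <- small_config(seed = 29, n_pt_dcn = 300, n_pt_expr = 300,
                      n_overlap = 300)
  cfg$survival$gamma <- -1
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  drv <- log2(co$expression_pt[cfg$survival$driver_gene, ] + 1)
  strat <- stratify_quartiles(drv, colnames(co$expression_pt))
  res <- stratified_survival(co$clinical, strat)
  m_high <- km_median(res$km_high)
  m_low <- km_median(res$km_low)
  expect_true(is.na(m_high) || m_low < m_high)  # low expression dies sooner

  cfg0 <- small_config(seed = 29)
  cfg0$survival$horizon <- 1e-9
  clin0 <- simulate_survival(cfg0, co$expression_pt)
  expect_true(all(clin0$os_event == 0))
  expect_true(all(clin0$os_time < 1e-9))
})

test_that("planted subclass signatures separate the assigned samples", {
  cfg <- small_config(seed = 31,
                      templates = list(n_classes = 2, genes_per_class = 10,
                                       delta = 1.5, fractions = c(0.3, 0.3)))
  sim <- simulate_cohort(cfg)
  expect_named(sim$templates, c("class1", "class2"))
  tab <- table(sim$truth$subclass)
  n <- ncol(sim$cohort$expression_pt)
  expect_equal(unname(tab[c("class1", "class2")]),
               rep(round(0.3 * n), 2), ignore_attr = TRUE)
  # signature genes of class1 differ in the assigned samples
  tm <- sim$templates$class1
  members <- names(sim$truth$subclass)[sim$truth$subclass == "class1"]
  others <- names(sim$truth$subclass)[sim$truth$subclass == "none"]
  lg <- log2(sim$cohort$expression_pt + 1)
  shift <- rowMeans(lg[tm$gene_id, members, drop = FALSE]) -
    rowMeans(lg[tm$gene_id, others, drop = FALSE])
  expect_gt(cor(shift, tm$direction), 0.9)
})

test_that("configuration validation rejects inconsistent parameters", {
  expect_error(small_config(sigma_e = 0), "sigma")
  genome <- data.frame(chromosome = "1", n_genes = 10L, gene_length = 100L,
                       spacing = 100L, stringsAsFactors = FALSE)
  ev_out <- data.frame(chromosome = "1", start = 0L, end = 99999L,
                       type = "loss", pi = 0.5, mu = -1)
  expect_error(sim_config(genome = genome, scna_events = ev_out,
                          dosage_genes = character(), templates = NULL),
               "outside the genome")
  ev_chr <- data.frame(chromosome = "7", start = 0L, end = 100L,
                       type = "loss", pi = 0.5, mu = -1)
  expect_error(sim_config(genome = genome, scna_events = ev_chr,
                          dosage_genes = character(), templates = NULL),
               "outside the genome")
  expect_error(small_config(templates = list(n_classes = 2, genes_per_class = 5,
                                             delta = 1, fractions = c(0.7, 0.7))),
               "fractions")
})

test_that("write_cohort emits a readable file bundle", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(small_config(seed = 37))
  paths <- write_cohort(sim, dir)
  expect_true(all(file.exists(paths)))
  seg_back <- read_seg(paths[["seg_pt"]])
  orig <- sim$cohort$dcn_pt
  ord <- function(d) d[order(d$sample, chrom_rank(d$chromosome), d$start), ]
  expect_equal(ord(seg_back)$value, ord(orig)$value)
  expr_back <- read_expression(paths[["expr_pt"]])
  expect_equal(expr_back, sim$cohort$expression_pt)
})
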