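test_that("permutation t-test handles degenerate and separable inputs", {
  res <- permutation_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # 20 label arrangements; only the observed split and its mirror reach |t|
  res2 <- permutation_t_test(c(1, 2, 3), c(101, 102, 103))
  expect_equal(res2$method, "exhaustive")
  expect_equal(res2$p, 2 / 20)

  # add-one lower bound in Monte Carlo mode
  res3 <- permutation_t_test(rnorm(20), rnorm(20) + 10, B = 99, seed = 1)
  expect_equal(res3$method, "monte-carlo")
  expect_gte(res3$p, 1 / 100)
})

test_that("permutation p-value is symmetric in group exchange", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(5, 1)
    p_ab <- permutation_t_test(a, b)$p
    p_ba <- permutation_t_test(b, a)$p
    expect_equal(p_ab, p_ba)
  }
})

test_that("vectorized screen agrees with the scalar test under enumeration", {
  set.seed(5)
  mat <- matrix(rnorm(48), 6, 8,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  screen <- permutation_de_screen(mat, paste0("s", 1:4), paste0("s", 5:8), B = 999)
  for (g in rownames(mat)) {
    ref <- permutation_t_test(mat[g, 1:4], mat[g, 5:8], B = 999)
    expect_equal(screen$perm_p[screen$gene_id == g], ref$p)
    expect_equal(screen$t[screen$gene_id == g], ref$t, tolerance = 1e-12)
  }
  expect_error(permutation_de_screen(mat, paste0("s", 1:4), paste0("s", 4:8)),
               "overlap")
})

test_that("gene-wise correlation matches hand formula and cor.test", {
  de <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4), g3 = c(1, 2, 3, 4))
  colnames(de) <- paste0("s", 1:4)
  scna <- rbind(g1 = c(1, 2, 3, 4), g2 = -c(1, 2, 3, 4), g3 = c(2, 1, 4, 3))
  colnames(scna) <- paste0("s", 1:4)
  res <- gene_wise_correlation(de, scna)
  expect_equal(res$cor_r[res$gene_id == "g1"], 1)
  expect_equal(res$cor_r[res$gene_id == "g2"], -1)
  expect_equal(res$cor_r[res$gene_id == "g3"], 0.6)  # hand: cov 3 / sqrt(5*5)
  ct <- cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$cor_p[res$gene_id == "g3"], ct$p.value, tolerance = 1e-12)

  # missing pairs reduce n; < 3 pairs -> missing
  scna2 <- scna; scna2["g3", 1:2] <- NA
  res2 <- gene_wise_correlation(de, scna2)
  expect_true(is.na(res2$cor_r[res2$gene_id == "g3"]))
  # zero variance -> missing with warning
  de3 <- rbind(g1 = rep(2, 4)); colnames(de3) <- paste0("s", 1:4)
  sc3 <- rbind(g1 = 1:4); colnames(sc3) <- paste0("s", 1:4)
  expect_warning(res3 <- gene_wise_correlation(de3, sc3), "zero variance")
  expect_true(is.na(res3$cor_r))
})

test_that("selection rule applies all three gates with concordance", {
  rec <- data.frame(
    gene_id = c("pass", "weak_r", "discordant", "weak_fc", "missing"),
    de_fc = c(0.5, 0.5, 0.5, 0.2, NA),
    perm_p = c(0.001, 0.001, 0.001, 0.001, 0.001),
    scna_fc = c(0.2, 0.2, -0.1, 0.2, 0.2),
    cor_r = c(0.7, 0.4, 0.7, 0.7, 0.7),
    cor_p = c(1e-5, 1e-5, 1e-5, 1e-5, 1e-5),
    stringsAsFactors = FALSE)
  out <- select_scna_dependent_genes(rec)
  expect_equal(out$gene_id[out$selected], "pass")
  expect_equal(out$direction[out$gene_id == "pass"], "up")
})

test_that("group DE screen recovers planted shifts and respects thresholds", {
  set.seed(21)
  n_null <- 1000; n_sig <- 50
  samples <- sprintf("s%03d", 1:120)
  high <- samples[1:60]; low <- samples[61:120]
  de <- matrix(rnorm((n_null + n_sig) * 120, 0, 0.3), n_null + n_sig, 120,
               dimnames = list(sprintf("g%04d", 1:(n_null + n_sig)), samples))
  planted <- sprintf("g%04d", 1:n_sig)
  de[planted, low] <- de[planted, low] + 1.0
  res <- group_differential_expression(de, high, low, B = 1999,
                                       p_thresh = 0.001, fd_thresh = 0.5,
                                       seed = 3, top_k = 25)
  flagged <- res$gene_id[res$flagged]
  expect_gte(sum(planted %in% flagged), 48)
  expect_lte(mean(setdiff(rownames(de), planted) %in% flagged), 0.01)
  expect_true(all(res$direction[res$gene_id %in% planted] == "up"))
  top <- attr(res, "top")
  expect_lte(nrow(top), 25)
  expect_true(all(top$flagged))

  # identical group compositions of values -> nothing flagged
  de_same <- de[1:50, c(high[1:5], high[1:5])]
  colnames(de_same) <- samples[1:10]
  none <- group_differential_expression(de_same, samples[1:5], samples[6:10],
                                        B = 199, seed = 1)
  expect_equal(sum(none$flagged), 0L)

  # infinite fold-difference threshold flags nothing
  res_inf <- group_differential_expression(de, high, low, B = 99,
                                           fd_thresh = Inf, seed = 1)
  expect_equal(sum(res_inf$flagged), 0L)
})

test_that("association screen assembles records with BH columns", {
  sim <- simulate_cohort(small_config(seed = 2))
  co <- sim$cohort
  dcn_pt <- map_segments_to_genes(co$dcn_pt, co$annotation)
  dcn_nt <- map_segments_to_genes(co$dcn_nt, co$annotation)
  de <- compute_de_matrix(co$expression_pt, co$expression_nt)
  scna <- compute_scna_matrix(dcn_pt, dcn_nt)
  rec <- association_screen(co$expression_pt, co$expression_nt, de, scna,
                            B = 199, seed = 4)
  expect_equal(nrow(rec), nrow(de))
  expect_true(all(rec$perm_p > 0 & rec$perm_p <= 1))
  expect_true(all(abs(rec$cor_r) <= 1, na.rm = TRUE))
  expect_true(all(rec$de_q >= rec$perm_p))
  expect_equal(rec$de_fc, unname(rowMeans(de)))
})
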