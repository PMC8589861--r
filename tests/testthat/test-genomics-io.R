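test_that("read_seg converts 1-based inclusive input to half-open coordinates", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchromosome\tstart\tend\tvalue",
               "S1\tchr13\t1\t1000\t0.5"), path)
  segs <- read_seg(path)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 0L)
  expect_equal(segs$end, 1000L)
  expect_equal(segs$chromosome, "13")
  expect_equal(segs$value, 0.5)
  # a 1 bp segment written as start = end = 5 has internal length 1
  writeLines(c("sample\tchromosome\tstart\tend\tvalue",
               "S1\t1\t5\t5\t1.2"), path)
  one <- read_seg(path)
  expect_equal(one$end - one$start, 1L)
})

test_that("read_seg handles empty files, bad headers and malformed rows", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines("sample\tchromosome\tstart\tend\tvalue", path)
  expect_equal(nrow(read_seg(path)), 0L)

  writeLines(c("sample\tchromosome\tstart\tend", "S1\t1\t1\t10"), path)
  expect_error(read_seg(path), "missing column.*value")

  writeLines(c("sample\tchromosome\tstart\tend\tvalue",
               "S1\t1\t1\t1000\t0.5",
               "S1\t1\t50\t10\t0.5"), path)
  expect_error(read_seg(path), "malformed row.*line.*3")
})

test_that("read_seg rejects overlapping segments, or warns when permissive", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchromosome\tstart\tend\tvalue",
               "S1\t1\t1\t1000\t0.5",
               "S1\t1\t500\t1500\t0.8"), path)
  expect_error(read_seg(path), "overlapping segments for sample S1")
  expect_warning(segs <- read_seg(path, permissive = TRUE), "overlapping")
  expect_equal(nrow(segs), 2L)
})

test_that("SEG and expression round-trips reproduce records exactly", {
  segs <- data.frame(sample = c("S1", "S1", "S2"), chromosome = c("1", "2", "X"),
                     start = c(0L, 10L, 100L), end = c(10L, 400L, 220L),
                     value = c(0.5, 1.25, 2), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(segs, path)
  expect_identical(read_seg(path), segs)

  mat <- matrix(c(0, 1.5, 2, 3, 4.25, 5), 2, 3,
                dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(mat, path2)
  expect_identical(read_expression(path2), mat)

  ann <- tiny_annotation()
  path3 <- withr::local_tempfile(fileext = ".bed")
  write_gene_annotation(ann, path3)
  expect_identical(read_gene_annotation(path3), ann)

  tmpl <- list(A = data.frame(gene_id = c("g1", "g2"), direction = c(1, -1),
                              stringsAsFactors = FALSE),
               B = data.frame(gene_id = c("g3", "g4", "g5"),
                              direction = c(-1, -1, 1), stringsAsFactors = FALSE))
  path4 <- withr::local_tempfile(fileext = ".tsv")
  write_templates(tmpl, path4)
  expect_identical(read_templates(path4), tmpl)
})

test_that("read_expression validates shape, duplicates and negative values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t0\t0.5\t4"), path)
  mat <- read_expression(path)
  expect_equal(dim(mat), c(2L, 3L))

  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), path)
  expect_error(read_expression(path), "duplicated gene_id")

  writeLines(c("gene_id\ts1\ts2", "g1\t1\t-1.0"), path)
  expect_error(read_expression(path), "negative")

  writeLines(c("gene_id\ts1\ts1", "g1\t1\t2"), path)
  expect_error(read_expression(path), "duplicated sample")
})

test_that("read_gene_annotation validates coordinates and chromosome labels", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t0\t100\tgA\tgA", "1\t500\t700\tgB\tgB", "2\t100\t300\tgC\tgC"),
             path)
  ann <- read_gene_annotation(path)
  expect_equal(nrow(ann), 3L)
  expect_true(all(ann$start < ann$end))

  writeLines("1\t500\t100\tgA\tgA", path)
  expect_error(read_gene_annotation(path), "start >= end")

  writeLines("chr99\t0\t100\tgA\tgA", path)
  expect_error(read_gene_annotation(path), "99")
})

test_that("read_templates validates directions and classes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("class\tgene_id\tdirection",
               paste("A", sprintf("g%d", 1:5), c(1, 1, -1, 1, -1), sep = "\t"),
               paste("B", sprintf("h%d", 1:5), -1, sep = "\t")), path)
  tmpl <- read_templates(path)
  expect_named(tmpl, c("A", "B"))
  expect_equal(nrow(tmpl$A), 5L)

  writeLines(c("class\tgene_id\tdirection", "A\tg1\t0"), path)
  expect_error(read_templates(path), "direction")

  writeLines(c("class\tgene_id\tdirection", "\tg1\t1"), path)
  expect_error(read_templates(path), "empty class")
})

test_that("assemble_cohort records assay intersections and enforces pairing", {
  expr_pt <- matrix(1, 2, 5, dimnames = list(c("g1", "g2"), paste0("P", 1:5)))
  expr_nt <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("N1", "N2")))
  seg <- function(ids) data.frame(sample = rep(ids, each = 1), chromosome = "1",
                                  start = 0L, end = 100L, value = 1,
                                  stringsAsFactors = FALSE)
  dcn_pt <- seg(paste0("P", 3:6))   # overlap with expression: P3, P4, P5
  dcn_nt <- seg(paste0("Q", 3:6))
  pairing <- setNames(paste0("Q", 3:6), paste0("P", 3:6))
  expect_message(
    co <- assemble_cohort(expr_pt, expr_nt, dcn_pt, dcn_nt, tiny_annotation(),
                          pairing = pairing),
    "3 PT samples with both")
  expect_setequal(co$samples_both, c("P3", "P4", "P5"))
  expect_setequal(co$samples_expression_only, c("P1", "P2"))
  expect_setequal(co$samples_dcn_only, "P6")

  clinical <- data.frame(sample_id = c("P1", "ZZ"), os_time = c(1, 2),
                         os_event = c(1, 0), stringsAsFactors = FALSE)
  expect_warning(
    co2 <- suppressMessages(
      assemble_cohort(expr_pt, expr_nt, dcn_pt, dcn_nt, tiny_annotation(),
                      clinical = clinical, pairing = pairing)),
    "kept aside")
  expect_equal(co2$clinical$sample_id, "P1")
  expect_equal(co2$clinical_unmatched$sample_id, "ZZ")

  expect_error(
    suppressMessages(
      assemble_cohort(expr_pt, expr_nt, dcn_pt, dcn_nt, tiny_annotation(),
                      pairing = pairing[-1])),
    "without a pairing entry")
})

test_that("the bundled MRP gene set is complete and well formed", {
  mrp <- mrp_genes()
  expect_equal(nrow(mrp), 82L)
  expect_false(anyDuplicated(mrp$symbol) > 0)
  expect_setequal(unique(mrp$subunit), c("SSU", "LSU"))
  expect_true(all(c("MRPS31", "DAP3", "PTCD3", "MRPL13", "MRPL58") %in% mrp$symbol))
})
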