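test_that("gene id normalization strips italics and family tags", {
  expect_equal(normalize_gene_id("*daf-21(Hsp90)*"), "daf-21")
  sp <- split_gene_id(c("daf-21(Hsp90)", "unc-45"))
  expect_equal(sp$gene_id, c("daf-21", "unc-45"))
  expect_equal(sp$tag, c("Hsp90", NA))
  # catalog rejects duplicates case-insensitively and empty ids
  expect_error(chap_catalog(c("a", "A")), "duplicate")
  expect_error(chap_catalog(c("a", "")), "empty")
})

test_that("wide-binary evidence tables parse, validate and deduplicate", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tex1\tex2\tex3",
               "daf-21\t1\t1\t1", "g2\t0\t1\t0", "g3\t0\t0\t0"), p)
  sets <- read_evidence_table(p, "occupancy")
  expect_length(sets, 3)
  expect_true(all(vapply(sets, function(s)
    "daf-21" %in% s$genes, logical(1))))
  expect_equal(sets[[2]]$genes, c("daf-21", "g2"))
  expect_equal(sets[[1]]$category, "occupancy")
  # non-binary cell is a validation error naming the column
  writeLines(c("gene_id\tex1", "g1\t2"), p)
  expect_error(read_evidence_table(p, "occupancy"), "non-binary.*ex1")
  # header without gene_id is a parse error
  writeLines(c("foo\tbar", "g1\t1"), p)
  expect_error(read_evidence_table(p, "occupancy"), "gene_id")
})

test_that("long gene-list layout is auto-detected; duplicates collapse", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("set,gene_id", "s1,g1", "s1,g2", "s1,g2", "s2,g3"), p)
  sets <- read_evidence_table(p, "enrichment")
  expect_length(sets, 2)
  s1 <- sets[[which(vapply(sets, `[[`, "", "name") == "s1")]]
  expect_equal(sort(s1$genes), c("g1", "g2"))  # duplicate counted once
  # empty body yields zero-member sets with a warning
  writeLines("gene_id\tex1", p)
  expect_warning(empty <- read_evidence_table(p, "required"), "empty")
  expect_true(all(lengths(lapply(empty, `[[`, "genes")) == 0))
})

test_that("expression matrix reader enforces shape, metadata and drops bad rows", {
  p <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("gene_id", paste0("s", 1:10, ":", (1:10) * 50)),
               collapse = "\t")
  rows <- vapply(1:5, function(i)
    paste(c(paste0("g", i), round(runif(10, 1, 100), 2)), collapse = "\t"),
    character(1))
  writeLines(c(hdr, rows), p)
  em <- read_expression_matrix(p)
  expect_equal(dim(em$values), c(5, 10))
  expect_equal(em$stage_minutes, (1:10) * 50)
  # NA cell drops the row with a message
  writeLines(c(hdr, rows, "g6\tNA\t1\t1\t1\t1\t1\t1\t1\t1\t1"), p)
  expect_message(em2 <- read_expression_matrix(p), "dropped")
  expect_equal(nrow(em2$values), 5)
  # duplicate gene and non-increasing minutes are errors
  writeLines(c(hdr, rows, rows[1]), p)
  expect_error(read_expression_matrix(p), "duplicate")
  expect_error(chap_expression(matrix(1, 2, 3), c("a", "b"),
                               c("x", "y", "z"), c(1, 5, 5)),
               "increasing")
  expect_error(chap_expression(matrix(1, 2, 1), c("a", "b"), "x", 1),
               "2 stages")
})

test_that("FASTA round-trips with uppercase normalization and alphabet checks", {
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(p1 = "acgtn", p2 = "GGCCTTAA"), p)
  seqs <- read_fasta(p)
  expect_equal(seqs, c(p1 = "ACGTN", p2 = "GGCCTTAA"))
  write_fasta(c(bad = "ACGU"), p)
  expect_error(read_fasta(p), "bad")
})

test_that("Ct table validation enforces schema, range and uniqueness", {
  df <- data.frame(gene_id = "g1", condition = "t", replicate = 1:3,
                   ct = c(20, 21, 22))
  expect_s3_class(chap_ct(df), "chap_ct")
  df2 <- df; df2$ct[1] <- 50
  expect_error(chap_ct(df2), "\\[0, 45\\]")
  df3 <- rbind(df, df[1, ])
  expect_error(chap_ct(df3), "duplicate")
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  expect_equal(read_ct_table(p)$ct, df$ct)
})

test_that("JSON report round-trips identically", {
  rep0 <- list(tool = "chaperonet", version = "1.0.0",
               stages = list(rank = list(n_genes = 97L,
                                         sizes = list(occupancy = 62L))),
               p_values = list(a = 0.00763, b = 0.0247),
               warnings = c("one", "two"))
  p <- withr::local_tempfile(fileext = ".json")
  write_report(rep0, p)
  expect_identical(read_report(p), rep0)
  # write(read(x)) is stable
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(read_report(p), p2)
  expect_identical(read_report(p2), read_report(p))
})

test_that("GFF3 gene models retain strand and 1-based coordinates", {
  skip_if_not_installed("rtracklayer")
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chrI", "test", "gene", "101", "200", ".", "-", ".",
                     "ID=gene:g1;Name=myo-3", sep = "\t")), p)
  gm <- read_gff3(p)
  expect_equal(gm$gene_id, "myo-3")
  expect_equal(gm$start, 101)
  expect_equal(gm$end, 200)
  expect_equal(gm$strand, "-")
})
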