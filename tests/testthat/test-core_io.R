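test_that("expression TSV round-trips and collapses duplicate gene rows", {
  dir <- withr::local_tempdir()
  set.seed(42)
  vals <- matrix(round(runif(12, 0, 100), 4), 3, 4,
                 dimnames = list(c("G1", "G2", "G3"), paste0("S", 1:4)))
  cond_path <- file.path(dir, "cond.tsv")
  write.table(data.frame(sample = paste0("S", 1:4),
                         condition = c("tumor", "tumor", "normal", "normal")),
              cond_path, sep = "\t", quote = FALSE, row.names = FALSE)
  em <- make_expr(vals, setNames(c("tumor", "tumor", "normal", "normal"),
                                 paste0("S", 1:4)))
  path <- file.path(dir, "expr.tsv")
  write_expression(em, path)
  back <- read_expression(path, cond_path)
  expect_equal(back$values, em$values)
  expect_equal(dim(back$values), c(3L, 4L))
  expect_equal(unname(back$sample_condition),
               c("tumor", "tumor", "normal", "normal"))

  # duplicate gene rows collapse by mean
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("gene\tS1\tS2\tS3\tS4",
               "GA\t2\t2\t2\t2",
               "GA\t4\t4\t4\t4",
               "GB\t1\t1\t1\t1"), dup)
  expect_message(em2 <- read_expression(dup, cond_path), "duplicate")
  expect_equal(unname(em2$values["GA", ]), rep(3, 4))

  # negative entries are a hard error naming the offender
  neg <- file.path(dir, "neg.tsv")
  writeLines(c("gene\tS1\tS2\tS3\tS4",
               "GA\t1\t-2\t1\t1"), neg)
  expect_error(read_expression(neg, cond_path), "GA.*S2")

  # sample absent from the condition map is fatal
  cond2 <- file.path(dir, "cond2.tsv")
  write.table(data.frame(sample = paste0("S", 1:3),
                         condition = rep("tumor", 3)),
              cond2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(path, cond2), "S4")
})

test_that("expression parsing is invariant to input row order", {
  dir <- withr::local_tempdir()
  cond <- file.path(dir, "cond.tsv")
  write.table(data.frame(s = paste0("S", 1:3), c = rep("tumor", 3)),
              cond, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- file.path(dir, "a.tsv"); b <- file.path(dir, "b.tsv")
  writeLines(c("gene\tS1\tS2\tS3", "GA\t1\t2\t3", "GB\t4\t5\t6"), a)
  writeLines(c("gene\tS1\tS2\tS3", "GB\t4\t5\t6", "GA\t1\t2\t3"), b)
  ea <- read_expression(a, cond); eb <- read_expression(b, cond)
  ord <- sort(rownames(ea$values))
  expect_identical(ea$values[ord, ], eb$values[ord, ])
})

test_that("GTF biotype extraction handles both attribute spellings", {
  dir <- withr::local_tempdir()
  gtf <- file.path(dir, "anno.gtf")
  writeLines(c(
    paste0("chr1\tsrc\tgene\t1\t100\t.\t+\t.\t",
           'gene_id "ENSG1"; gene_name "LncA"; gene_biotype "lncRNA";'),
    paste0("chr1\tsrc\texon\t1\t50\t.\t+\t.\t",
           'gene_id "ENSG1"; gene_name "LncA"; gene_biotype "lncRNA";')),
    gtf)
  bt <- read_gtf_biotypes(gtf)
  expect_identical(bt, c(LNCA = "lncRNA"))

  gtf2 <- file.path(dir, "anno2.gtf")
  writeLines(paste0("chr1\tsrc\tgene\t1\t100\t.\t+\t.\t",
                    'gene_id "ENSG2"; gene_name "LncB"; gene_type "lncRNA";'),
             gtf2)
  expect_identical(read_gtf_biotypes(gtf2), c(LNCB = "lncRNA"))

  gtf3 <- file.path(dir, "anno3.gtf")
  writeLines(paste0("chr1\tsrc\ttranscript\t1\t100\t.\t+\t.\t",
                    'gene_id "ENSG3"; gene_type "lncRNA";'), gtf3)
  expect_error(read_gtf_biotypes(gtf3), "gene")
})

test_that("clinical reader drops incomplete rows and validates encodings", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "clin.tsv")
  writeLines(c("sample_id\tos_time\tos_event\tage\tsex\tgrade\tstage",
               "P1\t100\t1\t70\tmale\thigh\tStage II",
               "P2\t200\t0\t61\tfemale\tlow\tIII",
               "P3\t\t1\t55\tmale\thigh\tI",
               "P4\t300\t1\t80\tfemale\thigh\tIV",
               "P5\t50\t0\t66\tmale\tlow\tII"), path)
  expect_message(cl <- read_clinical(path), "dropped 1")
  expect_equal(nrow(cl), 4L)
  expect_equal(attr(cl, "n_dropped"), 1L)
  expect_equal(cl$sex, c(1, 0, 0, 1))          # female = 0, male = 1
  expect_equal(cl$stage, c(2, 3, 4, 2))
  expect_equal(cl$grade, c(2, 1, 2, 1))

  # all-complete table passes through unchanged
  path2 <- file.path(dir, "clin2.tsv")
  writeLines(c("sample_id\tos_time\tos_event",
               "P1\t10\t1", "P2\t20\t0"), path2)
  cl2 <- read_clinical(path2)
  expect_equal(cl2$os_time, c(10, 20))
  expect_equal(attr(cl2, "n_dropped"), 0L)

  # an out-of-range event code is a contract violation
  path3 <- file.path(dir, "clin3.tsv")
  writeLines(c("sample_id\tos_time\tos_event", "P1\t10\t2"), path3)
  expect_error(read_clinical(path3), "os_event")
})

test_that("gene lists and biotype tables read with normalization", {
  dir <- withr::local_tempdir()
  gl <- file.path(dir, "genes.txt")
  writeLines(c("cd28", "IL2", "", "# comment", "CD28"), gl)
  expect_identical(read_gene_list(gl), c("CD28", "IL2"))
  bt <- file.path(dir, "bt.tsv")
  writeLines(c("gene\tbiotype", "lncA\tlncRNA", "GeneB\tprotein_coding"),
             bt)
  m <- read_biotype_table(bt)
  expect_identical(m[["LNCA"]], "lncRNA")
  em <- make_expr(matrix(1:4, 2, 2, dimnames = list(c("LNCA", "GENEB"),
                                                    c("S1", "S2"))))
  em <- set_gene_biotypes(em, m)
  expect_identical(unname(em$gene_biotype["LNCA"]), "lncRNA")
})
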