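test_that("packaged fixtures carry the documented promoter positions", {
  h <- mt_fixture("human")
  expect_equal(h$length, 16569)
  tss1 <- stats::setNames(h$promoters$tss + 1, h$promoters$name)
  expect_equal(tss1[["HSP1"]], 561)
  expect_equal(tss1[["HSP2"]], 646)
  expect_equal(tss1[["LSP"]], 407)
  expect_equal(h$promoters$strand, c("heavy", "heavy", "light"))

  r <- mt_fixture("rat")
  tss1 <- stats::setNames(r$promoters$tss + 1, r$promoters$name)
  expect_equal(tss1[["HSP1"]], 16298)
  expect_equal(tss1[["HSP2"]], 66)
  expect_equal(tss1[["LSP"]], 16193)

  f <- mt_fixture("frog")
  expect_setequal(f$promoters$name,
                  c("HSP1", "HSP2", "LSP1", "LSP2A", "LSP2B"))

  # mTERF site: 28 bp inside tRNA-Leu, just downstream of 16S
  fs <- h$factor_sites
  expect_equal(fs$end - fs$start, 28)
  leu <- h$genes[h$genes$name == "tRNA-Leu1", ]
  expect_true(fs$start >= leu$start && fs$end <= leu$end)
  s16 <- h$genes[h$genes$name == "16S", ]
  expect_equal(fs$start, s16$end)
})

test_that("TSV dialect round-trips all fixtures and origin-spanning features", {
  for (nm in mt_fixture_names()) {
    g <- mt_fixture(nm)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_geometry(g, path)
    g2 <- read_geometry(path)
    expect_equal(g[setdiff(names(g), "name")], g2[setdiff(names(g2), "name")],
                 info = nm)
  }
  # a gene across the origin survives the round trip modulo length
  g <- mt_geometry(1000,
                   genes = data.frame(name = "wrap", start = 950, end = 1050,
                                      strand = "heavy"))
  expect_equal(g$genes$start, 950)
  expect_equal(g$genes$end, 1050)   # stored as start + span
  path <- withr::local_tempfile(fileext = ".tsv")
  write_geometry(g, path)
  g2 <- read_geometry(path)
  expect_equal(g2$genes$start, 950)
  expect_equal(g2$genes$end, 1050)
})

test_that("coordinate normalization is idempotent and modular", {
  g <- mt_geometry(1000,
                   genes = data.frame(name = "a", start = 1950, end = 2050,
                                      strand = "light"))
  expect_equal(g$genes$start, 950)  # reduced modulo length
  g2 <- mt_geometry(1000, genes = g$genes)
  expect_equal(g2$genes, g$genes)
})

test_that("geometry validation rejects malformed input", {
  expect_error(mt_geometry(0), "positive")
  expect_error(mt_geometry(1000, circular = FALSE), "circular")
  expect_error(
    mt_geometry(1000, promoters = data.frame(
      name = c("A", "B"), tss = c(100, 100),
      strand = c("heavy", "heavy"))),
    "share the same")
  expect_error(
    mt_geometry(1000, genes = data.frame(name = "g", start = 10, end = 50,
                                         strand = "sideways")),
    "strand")
})

test_that("toy-genome construction is deterministic and checks overlap", {
  spec <- list(
    length = 2000,
    promoter_specs = list(list(name = "PH", tss = 50, strand = "heavy"),
                          list(name = "PL", tss = 1950, strand = "light")),
    gene_specs = list(list(name = "g1", start = 100, end = 600, strand = "heavy"),
                      list(name = "g2", start = 1200, end = 1800, strand = "light")))
  g1 <- do.call(make_toy_genome, spec)
  g2 <- do.call(make_toy_genome, spec)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 2)

  # empty gene list: usable by the simulator, zero counts downstream
  g0 <- make_toy_genome(2000, promoter_specs = spec$promoter_specs)
  tr <- run_trajectory(g0, sim_params(c(PH = 0.05, PL = 0.05), t_end = 50),
                       seed = 1)
  expect_length(tr$gene_counts, 0)
  expect_gt(tr$bindings, 0)

  expect_error(make_toy_genome(
    2000,
    promoter_specs = list(list(name = "A", tss = 100, strand = "heavy"),
                          list(name = "B", tss = 105, strand = "heavy"))),
    "overlapping promoter footprints")
})

test_that("TSV reader reports parse and range errors", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("no header here", "gene\tg\t1\t10\theavy\t."), bad)
  expect_error(read_geometry(bad), "header")

  oob <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#length=100 circular=1", "gene\tg\t1\t200\theavy\t."), oob)
  expect_error(read_geometry(oob), "outside")

  expect_error(read_geometry("/nonexistent/file.tsv"), "no such file")
})

test_that("GFF3 input loads genes with 1-based inclusive coordinates", {
  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrM 1 16569",
    "chrM\ttest\tgene\t577\t647\t.\t+\t.\tID=g1;Name=tRNA-Phe",
    "chrM\ttest\tgene\t14149\t14673\t.\t-\t.\tID=g2;Name=ND6",
    "chrM\ttest\tregion\t1\t16569\t.\t+\t.\tID=r1"), gff)
  g <- read_geometry(gff, format = "gff3")
  expect_equal(g$length, 16569)
  expect_equal(nrow(g$genes), 2)      # the region row is ignored
  phe <- g$genes[g$genes$name == "tRNA-Phe", ]
  expect_equal(phe$start, 576)        # internal 0-based half-open
  expect_equal(phe$end, 647)
  expect_equal(g$genes$strand[g$genes$name == "ND6"], "light")
})

test_that("GenBank flat files load genes, lengths and strands", {
  gbk <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       TESTMT              16569 bp    DNA     circular     01-JAN-2000",
    "DEFINITION  test mitochondrion.",
    "FEATURES             Location/Qualifiers",
    "     source          1..16569",
    "     gene            577..647",
    "                     /gene=\"TRNF\"",
    "     tRNA            577..647",
    "                     /product=\"tRNA-Phe\"",
    "     gene            complement(14149..14673)",
    "                     /gene=\"ND6\"",
    "ORIGIN",
    "//"), gbk)
  g <- read_geometry(gbk, format = "genbank")
  expect_equal(g$length, 16569)
  expect_equal(nrow(g$genes), 2)      # gene + identical tRNA deduplicated
  expect_equal(g$genes$start[1], 576)
  expect_equal(g$genes$end[1], 647)
  expect_equal(g$genes$strand[2], "light")
})

test_that("frog promoter intensities scale from LSP1", {
  x <- frog_promoter_intensities(1.0)
  expect_equal(x[["HSP2"]], 0.600)
  expect_equal(x[["HSP1"]], 0.136)
  expect_equal(x[["LSP1"]], 1.0)
  expect_equal(unname(frog_promoter_intensities(0)), rep(0, 5))
  expect_equal(frog_promoter_intensities(0.0034)[["LSP2B"]], 0.0012988)
  expect_error(frog_promoter_intensities(-1), "non-negative")
})

test_that("merging a regulatory overlay onto gene-only geometry works", {
  genes_only <- mt_geometry(16569, genes = mt_fixture("human")$genes)
  merged <- merge_geometry(genes_only, mt_fixture("human"))
  expect_equal(merged$promoters, mt_fixture("human")$promoters)
  expect_error(merge_geometry(genes_only, mt_fixture("rat")),
               "different lengths")
})
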