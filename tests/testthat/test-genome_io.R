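test_that("FASTA reading parses ids, descriptions and sequences in file order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a some description", "ACGT", ">b", "NN", "AC"), f)
  asm <- read_fasta(f)
  expect_s3_class(asm, "genome_assembly")
  expect_identical(asm$id, c("a", "b"))
  expect_identical(unname(seq_lengths(asm)), c(4L, 4L))
  expect_identical(get_seq(asm, "b"), "NNAC")
  expect_identical(unname(asm$description["a"]), "some description")
})

test_that("FASTA write/read round trip is the identity, preserving case", {
  asm <- genome_assembly(c("s1", "s2"), c("acgTNNca", "GGGTTTAAACCC"),
                         c("soft-masked", ""))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(asm, f)
  back <- read_fasta(f)
  expect_identical(back$id, asm$id)
  expect_identical(back$residues, asm$residues)
  expect_identical(unname(back$description["s1"]), "soft-masked")
})

test_that("duplicate FASTA ids and empty files are errors naming the problem", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(read_fasta(f), "a")
  f2 <- withr::local_tempfile(fileext = ".fa")
  file.create(f2)
  expect_error(read_fasta(f2))
  expect_error(genome_assembly(c("x", "x"), c("A", "C")), "duplicate")
})

make_gff <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("GFF3 coordinates convert to 0-based half-open with intron derivation", {
  f <- make_gff(c(
    "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=g1;gene_biotype=protein_coding",
    "chr1\tx\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tx\texon\t101\t140\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\tx\texon\t161\t200\t.\t+\t.\tID=e2;Parent=t1",
    "chr1\tx\tCDS\t110\t140\t.\t+\t0\tID=c1;Parent=t1"
  ))
  ann <- read_gff3(f)
  g <- ann$genes[["g1"]]
  expect_identical(c(g$start, g$end), c(100L, 200L))
  expect_equal(unname(gene_exons(g)), rbind(c(100L, 140L), c(160L, 200L)),
               ignore_attr = TRUE)
  expect_equal(unname(gene_introns(g)), rbind(c(140L, 160L)), ignore_attr = TRUE)
  # printed width identity: end - start == printed_end - printed_start + 1
  expect_identical(g$end - g$start, 200L - 101L + 1L)
})

test_that("biotype is taken from gene_biotype or inferred from CDS presence", {
  f <- make_gff(c(
    "chr1\tx\tgene\t1\t50\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t1\t50\t.\t+\t.\tID=tA;Parent=gA",
    "chr1\tx\texon\t1\t50\t.\t+\t.\tID=eA;Parent=tA",
    "chr1\tx\tCDS\t10\t40\t.\t+\t0\tID=cA;Parent=tA",
    "chr1\tx\tgene\t100\t150\t.\t-\t.\tID=gB",
    "chr1\tx\tmRNA\t100\t150\t.\t-\t.\tID=tB;Parent=gB",
    "chr1\tx\texon\t100\t120\t.\t-\t.\tID=eB1;Parent=tB",
    "chr1\tx\texon\t130\t150\t.\t-\t.\tID=eB2;Parent=tB"
  ))
  ann <- read_gff3(f)
  expect_identical(ann$genes[["gA"]]$biotype, "protein_coding")
  expect_identical(ann$genes[["gB"]]$biotype, "noncoding")
  # minus-strand exons stay in genomic order
  ex <- gene_exons(ann$genes[["gB"]])
  expect_true(all(diff(ex[, 1L]) > 0))
  expect_identical(ann$genes[["gB"]]$strand, "-")
})

test_that("gene-level exon and CDS sets are unions over transcripts", {
  f <- make_gff(c(
    "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=g;gene_biotype=protein_coding",
    "chr1\tx\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g",
    "chr1\tx\texon\t1\t40\t.\t+\t.\tID=a;Parent=t1",
    "chr1\tx\tCDS\t10\t40\t.\t+\t0\tID=ca;Parent=t1",
    "chr1\tx\tmRNA\t1\t100\t.\t+\t.\tID=t2;Parent=g",
    "chr1\tx\texon\t30\t100\t.\t+\t.\tID=b;Parent=t2",
    "chr1\tx\tCDS\t30\t90\t.\t+\t0\tID=cb;Parent=t2"
  ))
  g <- read_gff3(f)$genes[["g"]]
  expect_equal(unname(gene_exons(g)), rbind(c(0L, 100L)), ignore_attr = TRUE)
  expect_equal(unname(gene_cds(g)), rbind(c(9L, 90L)), ignore_attr = TRUE)
})

test_that("GFF3 with unresolvable Parent or inverted coordinates errors", {
  f <- make_gff(c(
    "chr1\tx\tgene\t1\t50\t.\t+\t.\tID=g1",
    "chr1\tx\texon\t1\t50\t.\t+\t.\tID=e;Parent=missing_tx"
  ))
  expect_error(read_gff3(f), "Parent")
})

test_that("GFF3 write/read round trip preserves gene models", {
  sim <- simulate_genome(sim_config(seed = 21, n_chromosomes = 2,
                                    genes_per_chromosome = 3,
                                    chrom_length = c(8000L, 10000L)))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$annotation, f)
  back <- read_gff3(f)
  expect_setequal(names(back$genes), names(sim$annotation$genes))
  for (gid in names(sim$annotation$genes)) {
    a <- sim$annotation$genes[[gid]]; b <- back$genes[[gid]]
    expect_identical(c(a$start, a$end, a$strand, a$biotype),
                     c(b$start, b$end, b$strand, b$biotype))
    expect_equal(gene_exons(a), gene_exons(b))
    expect_equal(gene_cds(a), gene_cds(b))
  }
})

test_that("RepeatMasker .out parsing handles toy rows, empty body and bad rows", {
  f <- withr::local_tempfile(fileext = ".out")
  hits <- data.frame(seq_id = c("chr1", "chr1"), begin = c(99L, 500L),
                     end = c(199L, 650L), strand = c("+", "-"),
                     repeat_name = c("L2-1", "SAT-X"),
                     class_family = c("LINE/L2", "Satellite"),
                     divergence_pct = c(12.5, 3.1), stringsAsFactors = FALSE)
  write_repeatmasker_out(hits, f)
  back <- read_repeatmasker_out(f)
  expect_identical(back$begin, hits$begin)
  expect_identical(back$end, hits$end)
  expect_identical(back$class_family, hits$class_family)
  expect_identical(back$strand, hits$strand)
  # header-only file -> empty frame
  writeLines(readLines(f)[1:3], f)
  expect_identical(nrow(read_repeatmasker_out(f)), 0L)
  # end < begin -> parse error with line number
  writeLines(c(readLines(f),
               " 1000 10.0 0.0 0.0 chr1 500 400 (0) + L2 LINE/L2 1 100 (0) 1"), f)
  expect_error(read_repeatmasker_out(f), "line 4")
})
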