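# A 500-bp scaffold with a plus-strand gene at [300, 400) built from two
# exons, used across the toy cases below.
toy_annotation <- function(strand = "+") {
  g <- list(gene_id = "g1", seq_id = "s", strand = strand,
            start = 300L, end = 400L, biotype = "protein_coding",
            transcripts = list(t1 = list(
              exons = cbind(start = c(300L, 360L), end = c(340L, 400L)),
              cds = cbind(start = c(310L, 360L), end = c(340L, 390L)))))
  structure(list(genes = list(g1 = g), by_seq = list(s = "g1")),
            class = "annotation_set")
}

toy_scaffold <- function(gap_at = NULL, gap_len = 5L) {
  s <- random_dna(500, seed = 404)
  asm <- genome_assembly("s", s)
  if (!is.null(gap_at)) asm <- plant_gap(asm, "s", gap_at, gap_len)
  asm
}

test_that("flank flags are strand-aware and clipped at scaffold edges", {
  # + strand gene [300,400): upstream window is [0,300) after clipping
  ctx <- scan_gene_context(toy_scaffold(gap_at = 100L), toy_annotation("+"))
  pg <- ctx$per_gene
  expect_true(pg$has_N_upstream)
  expect_false(pg$has_N_downstream || pg$has_N_cds || pg$has_N_intron)
  # same gene on -, gap at [450,455): upstream window is now [400,500)
  ctx2 <- scan_gene_context(toy_scaffold(gap_at = 450L), toy_annotation("-"))
  expect_true(ctx2$per_gene$has_N_upstream)
  expect_false(ctx2$per_gene$has_N_downstream)
  # strand-agnostic mode calls the same gap downstream instead
  ctx3 <- scan_gene_context(toy_scaffold(gap_at = 450L), toy_annotation("-"),
                            strand_aware = FALSE)
  expect_false(ctx3$per_gene$has_N_upstream)
  expect_true(ctx3$per_gene$has_N_downstream)
})

test_that("intron gaps flag the intron but not the coding sequence", {
  # exons [300,340),[360,400): a gap at [345,350) is intronic only
  ctx <- scan_gene_context(toy_scaffold(gap_at = 345L), toy_annotation())
  expect_true(ctx$per_gene$has_N_intron)
  expect_false(ctx$per_gene$has_N_cds)
  # a gap inside the CDS flags coding sequence
  ctx2 <- scan_gene_context(toy_scaffold(gap_at = 320L), toy_annotation())
  expect_true(ctx2$per_gene$has_N_cds)
  # exon-union mode counts UTR-exon gaps as coding-sequence overlap
  ctx3 <- scan_gene_context(toy_scaffold(gap_at = 303L), toy_annotation())
  expect_false(ctx3$per_gene$has_N_cds)
  ctx4 <- scan_gene_context(toy_scaffold(gap_at = 303L), toy_annotation(),
                            cds_mode = "exon")
  expect_true(ctx4$per_gene$has_N_cds)
})

test_that("a gapless assembly yields all-false flags", {
  sim <- simulate_genome(sim_config(seed = 31, gap_rate = 0))
  ctx <- scan_gene_context(sim$assembly, sim$annotation)
  expect_false(any(as.matrix(ctx$per_gene[, c("has_N_upstream", "has_N_downstream",
                                              "has_N_cds", "has_N_intron")])))
  expect_equal(ctx$summary$genes_considered, length(sim$annotation$genes))
})

test_that("planting one intronic gap flips exactly that gene's intron flag", {
  for (seed in c(11, 12, 13, 14, 15)) {
    sim <- simulate_genome(sim_config(seed = seed, gap_rate = 0))
    base <- scan_gene_context(sim$assembly, sim$annotation)
    # pick a gene with an intron wide enough for a 10-bp gap
    gid <- NULL
    for (g in sim$annotation$genes) {
      iv <- gene_introns(g)
      if (nrow(iv) && any(iv[, 2L] - iv[, 1L] > 20L)) { gid <- g$gene_id; break }
    }
    g <- sim$annotation$genes[[gid]]
    iv <- gene_introns(g)
    iv <- iv[iv[, 2L] - iv[, 1L] > 20L, , drop = FALSE]
    planted <- plant_gap(sim$assembly, g$seq_id, iv[1L, 1L] + 5L, 10L)
    ctx <- scan_gene_context(planted, sim$annotation)
    flip <- ctx$per_gene$has_N_intron != base$per_gene$has_N_intron
    expect_identical(ctx$per_gene$gene_id[flip], gid)
    # CDS flags unchanged everywhere
    expect_identical(ctx$per_gene$has_N_cds, base$per_gene$has_N_cds)
  }
})

test_that("flags match simulation truth and survive scaffold reordering", {
  sim <- simulate_genome(sim_config(seed = 77))
  ctx <- scan_gene_context(sim$assembly, sim$annotation)
  cols <- c("has_N_upstream", "has_N_downstream", "has_N_cds", "has_N_intron")
  pg <- ctx$per_gene[order(ctx$per_gene$gene_id), ]
  expect_equal(unname(as.matrix(pg[cols])),
               unname(as.matrix(sim$truth$gene_context[cols])))
  # reorder the FASTA records: results identical
  rev_asm <- genome_assembly(rev(sim$assembly$id),
                             rev(sim$assembly$residues))
  ctx2 <- scan_gene_context(rev_asm, sim$annotation)
  pg2 <- ctx2$per_gene[order(ctx2$per_gene$gene_id), ]
  expect_equal(pg[cols], pg2[cols], ignore_attr = TRUE)
})

test_that("genes on scaffolds absent from the assembly raise an error", {
  ann <- toy_annotation()
  ann$genes$g1$seq_id <- "missing"
  expect_error(scan_gene_context(toy_scaffold(), ann), "g1")
})
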