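#!/usr/bin/env Rscript
# Stage 4: protein homology, reciprocal best hits, chromosome matching and
# a k-mer anchor dot plot.
#
# All-vs-all global protein alignments between the two simulated genomes
# stand in for a blastp search at this scale (on real data, read a BLAST
# outfmt-6 table with read_blast_tab() instead). Reciprocal best hits are
# pooled into shared-gene counts per chromosome pair; chromosomes with the
# most shared genes are called homologs. Writes results/tables/rbh.tsv,
# chromosome_homology.tsv and dotplot_anchors.tsv.

suppressMessages(library(killistat))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

asm_a <- read_fasta("results/sim/genomeA_scaffolds.fa")
ann_a <- read_gff3("results/sim/genomeA.gff3")
asm_b <- read_fasta("results/sim/genomeB.fa")
ann_b <- read_gff3("results/sim/genomeB.gff3")

prot <- function(asm, ann) {
  cds <- lapply(ann$genes, function(g) extract_cds(asm, g))
  cds <- cds[!grepl("N", cds)]            # genes interrupted by gaps
  vapply(cds, function(s) {
    n3 <- (nchar(s) %/% 3L) * 3L
    as.character(Biostrings::translate(Biostrings::DNAString(substr(toupper(s), 1, n3)),
                                       if.fuzzy.codon = "solve"))
  }, "")
}
# stage-1 contigs are rejoined losslessly, so genome A coordinates apply
pa <- prot(asm_a, ann_a)
pb <- prot(asm_b, ann_b)
cat("Aligning", length(pa), "x", length(pb), "protein pairs ...\n")
hits <- do.call(rbind, lapply(names(pa), function(qa) {
  do.call(rbind, lapply(names(pb), function(qb) {
    al <- align_protein_pair(pa[[qa]], pb[[qb]])
    data.frame(query_id = qa, subject_id = qb, score = al$score,
               identity = al$identity, stringsAsFactors = FALSE)
  }))
}))

rbh <- reciprocal_best_hits(hits)
write.table(rbh, "results/tables/rbh.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
gene_map <- read.delim("results/sim/truth_gene_map.tsv")
truth_map <- setNames(gene_map$gene_b, gene_map$gene_a)
cat(sprintf("Reciprocal best hits: %d pairs, %.1f%% true orthologs\n",
            nrow(rbh), 100 * mean(truth_map[rbh$gene_a] == rbh$gene_b)))

loc_a <- vapply(ann_a$genes, `[[`, "", "seq_id")
loc_b <- vapply(ann_b$genes, `[[`, "", "seq_id")
ch <- chromosome_homology(rbh, loc_a, loc_b)
write.table(ch$pairs, "results/tables/chromosome_homology.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
chrom_map <- read.delim("results/sim/truth_chrom_map.tsv")
tm <- setNames(chrom_map$chrom_b, chrom_map$chrom_a)
cat(sprintf("Chromosome homology: %d/%d pairs match the planted map\n",
            sum(ch$assignment[names(tm)] == tm), length(tm)))

# dot plot of the first homologous chromosome pair
ca <- names(ch$assignment)[1L]; cb <- ch$assignment[[1L]]
anchors <- kmer_anchor_dotplot(get_seq(asm_a, ca), get_seq(asm_b, cb),
                               k = 15L, max_occurrences = 10L)
write.table(anchors, "results/tables/dotplot_anchors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Dot plot %s vs %s: %d anchors, %.1f%% on the main diagonal band\n",
            ca, cb, nrow(anchors),
            100 * mean(abs(anchors$x_pos - anchors$y_pos) < 1000)))
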