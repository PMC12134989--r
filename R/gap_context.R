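# Gene-proximal gap context: for every protein-coding gene, does an assembly
# gap (run of Ns) fall within the upstream flank, downstream flank, coding
# sequence, or an intron?

.overlaps_any <- function(ivs, gap_ir) {
  if (nrow(ivs) == 0L || length(gap_ir) == 0L) return(FALSE)
  q <- IRanges::IRanges(start = ivs[, 1L] + 1L, end = ivs[, 2L])
  any(IRanges::overlapsAny(q, gap_ir))
}

#' Scan genes for nearby assembly gaps
#'
#' For each protein-coding gene, flags whether at least one gap base overlaps
#' (i) the flank within `flank_size` bp upstream, (ii) the flank downstream,
#' (iii) the coding sequence, and (iv) any intron. Upstream/downstream are
#' strand-aware by default (upstream = 5' of the gene span in transcription
#' direction); flanks are clipped to the scaffold. The coding-sequence flag
#' uses the union of CDS intervals; set `cds_mode = "exon"` to test whole
#' exons instead. Introns are the gene span minus the exon union.
#'
#' @param assembly a `genome_assembly`.
#' @param annotation an `annotation_set` whose seq_ids resolve in `assembly`.
#' @param flank_size flank width in bp (default 10,000).
#' @param cds_mode `"cds"` (default) or `"exon"`.
#' @param strand_aware logical; when FALSE, upstream means left of the span.
#' @param min_gap_length minimum N-run length counted as a gap.
#' @return A `gap_context_report`: list with `per_gene` (data.frame of
#'   per-gene flags), `summary` (counts and fractions over protein-coding
#'   genes) and the parameters used.
#' @export
scan_gene_context <- function(assembly, annotation, flank_size = 10000L,
                              cds_mode = c("cds", "exon"), strand_aware = TRUE,
                              min_gap_length = 1L) {
  cds_mode <- match.arg(cds_mode)
  genes <- Filter(function(g) g$biotype == "protein_coding", annotation$genes)
  bad <- vapply(genes, function(g) !(g$seq_id %in% assembly$id), TRUE)
  if (any(bad)) {
    stop("gene(s) on unknown scaffold: ",
         paste(names(genes)[bad], collapse = ", "))
  }
  gap_by_seq <- list()
  for (sid in unique(vapply(genes, `[[`, "", "seq_id"))) {
    g <- find_gap_runs(assembly$residues[[sid]], seq_id = sid,
                       min_length = min_gap_length)
    gap_by_seq[[sid]] <- IRanges::IRanges(start = g$start + 1L, end = g$end)
  }
  rows <- lapply(genes, function(g) {
    gaps <- gap_by_seq[[g$seq_id]]
    slen <- nchar(assembly$residues[[g$seq_id]])
    left <- .iv_mat(max(0L, g$start - flank_size), g$start)
    right <- .iv_mat(g$end, min(slen, g$end + flank_size))
    if (left[1L, 1L] >= left[1L, 2L]) left <- left[0L, , drop = FALSE]
    if (right[1L, 1L] >= right[1L, 2L]) right <- right[0L, , drop = FALSE]
    minus <- strand_aware && identical(g$strand, "-")
    up <- if (minus) right else left
    down <- if (minus) left else right
    coding <- if (cds_mode == "cds") gene_cds(g) else gene_exons(g)
    data.frame(
      gene_id = g$gene_id, seq_id = g$seq_id, strand = g$strand,
      has_N_upstream = .overlaps_any(up, gaps),
      has_N_downstream = .overlaps_any(down, gaps),
      has_N_cds = .overlaps_any(coding, gaps),
      has_N_intron = .overlaps_any(gene_introns(g), gaps),
      stringsAsFactors = FALSE
    )
  })
  per_gene <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(gene_id = character(), seq_id = character(), strand = character(),
               has_N_upstream = logical(), has_N_downstream = logical(),
               has_N_cds = logical(), has_N_intron = logical())
  n <- nrow(per_gene)
  cnt <- function(col) sum(per_gene[[col]])
  summary <- data.frame(
    genes_considered = n,
    n_upstream = cnt("has_N_upstream"), n_downstream = cnt("has_N_downstream"),
    n_cds = cnt("has_N_cds"), n_intron = cnt("has_N_intron")
  )
  for (col in c("n_upstream", "n_downstream", "n_cds", "n_intron")) {
    summary[[sub("^n_", "frac_", col)]] <- if (n) summary[[col]] / n else NA_real_
  }
  structure(list(per_gene = per_gene, summary = summary,
                 flank_size = flank_size, cds_mode = cds_mode,
                 strand_aware = strand_aware),
            class = "gap_context_report")
}

#' @export
print.gap_context_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("gap_context_report (%d protein-coding genes, %d bp flanks, %s mode)\n",
              s$genes_considered, x$flank_size, x$cds_mode))
  cat(sprintf("  Ns upstream:   %d (%.1f%%)\n", s$n_upstream, 100 * s$frac_upstream))
  cat(sprintf("  Ns downstream: %d (%.1f%%)\n", s$n_downstream, 100 * s$frac_downstream))
  cat(sprintf("  Ns in CDS:     %d (%.1f%%)\n", s$n_cds, 100 * s$frac_cds))
  cat(sprintf("  Ns in introns: %d (%.1f%%)\n", s$n_intron, 100 * s$frac_intron))
  invisible(x)
}
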