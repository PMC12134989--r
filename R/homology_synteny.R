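# Protein similarity, reciprocal best hits, chromosome homology by shared
# genes, and exact k-mer anchor dot plots.

.aln_identity <- function(p, s) {
  # matches / aligned columns, gap columns included in the denominator
  pc <- strsplit(p, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  sum(toupper(pc) == toupper(sc) & pc != "-") / length(pc)
}

#' Globally align two protein sequences
#'
#' Needleman-Wunsch with affine gaps over a standard substitution matrix.
#' Identity is matches divided by aligned columns, gap columns included.
#'
#' @param a,b residue strings over the 20-letter amino-acid alphabet plus X/*.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend positive gap penalties.
#' @return list with `score`, `identity`, and the two aligned strings
#'   (`aligned_a`, `aligned_b`).
#' @export
align_protein_pair <- function(a, b, matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_extend
  )
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  list(score = Biostrings::score(pa), identity = .aln_identity(ap, as),
       aligned_a = ap, aligned_b = as)
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Default 12-column layout: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore.
#'
#' @param path path to a BLAST `-outfmt 6` TSV.
#' @return data.frame with `query_id`, `subject_id`, `identity` (fraction)
#'   and `score` (bitscore).
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(query_id = df[[1L]], subject_id = df[[2L]],
             identity = df[[3L]] / 100, score = df[[12L]],
             stringsAsFactors = FALSE)
}

#' Reciprocal best hits between two gene sets
#'
#' A pair (a, b) is kept iff b is a's highest-scoring hit and a is b's.
#' Ties are broken by higher identity, then by lexicographically smaller
#' partner id. Self-hits are ignored; hits may be given in either or both
#' directions.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`, `score`,
#'   and optionally `identity`.
#' @return data.frame with `gene_a`, `gene_b`, `score`; `gene_a` is the
#'   lexicographically smaller partner. Empty input gives an empty frame.
#' @export
reciprocal_best_hits <- function(hits) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if (is.null(hits$identity)) hits$identity <- 0
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  best <- new.env(parent = emptyenv())
  consider <- function(q, s, sc, id) {
    cur <- best[[q]]
    if (is.null(cur) || sc > cur$score ||
        (sc == cur$score && (id > cur$identity ||
          (id == cur$identity && s < cur$partner)))) {
      best[[q]] <- list(partner = s, score = sc, identity = id)
    }
  }
  for (i in seq_len(nrow(hits))) {
    consider(hits$query_id[i], hits$subject_id[i], hits$score[i], hits$identity[i])
    consider(hits$subject_id[i], hits$query_id[i], hits$score[i], hits$identity[i])
  }
  out <- list()
  for (q in ls(best)) {
    p <- best[[q]]$partner
    if (q < p && !is.null(best[[p]]) && identical(best[[p]]$partner, q)) {
      out[[q]] <- data.frame(gene_a = q, gene_b = p, score = best[[q]]$score,
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, c(unname(out), make.row.names = FALSE))
  res[order(res$gene_a), , drop = FALSE]
}

#' Chromosome homology by shared-gene counts
#'
#' Counts reciprocal-best-hit genes shared by each chromosome pair and
#' greedily assigns homologs in descending count order, skipping chromosomes
#' already taken; count ties break by lexicographic chromosome ids. The
#' resulting assignment is injective.
#'
#' @param rbh data.frame from [reciprocal_best_hits()].
#' @param loc_a,loc_b named character vectors mapping gene id to chromosome
#'   for the two genomes (`loc_a` covers `gene_a`, `loc_b` covers `gene_b`).
#' @return list with `pairs` (data.frame `chrom_a`, `chrom_b`,
#'   `shared_gene_count`, all observed pairs, descending) and `assignment`
#'   (named character vector chrom_a -> chrom_b).
#' @export
chromosome_homology <- function(rbh, loc_a, loc_b) {
  if (nrow(rbh) == 0L) {
    return(list(pairs = data.frame(chrom_a = character(), chrom_b = character(),
                                   shared_gene_count = integer()),
                assignment = setNames(character(), character())))
  }
  miss_a <- setdiff(rbh$gene_a, names(loc_a))
  miss_b <- setdiff(rbh$gene_b, names(loc_b))
  if (length(miss_a) || length(miss_b)) {
    stop("gene(s) without a chromosome location: ",
         paste(head(c(miss_a, miss_b), 5L), collapse = ", "))
  }
  tab <- table(chrom_a = loc_a[rbh$gene_a], chrom_b = loc_b[rbh$gene_b])
  pairs <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(pairs)[3L] <- "shared_gene_count"
  pairs <- pairs[pairs$shared_gene_count > 0L, , drop = FALSE]
  pairs <- pairs[order(-pairs$shared_gene_count, pairs$chrom_a, pairs$chrom_b), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  assignment <- character()
  used_b <- character()
  for (i in seq_len(nrow(pairs))) {
    ca <- pairs$chrom_a[i]; cb <- pairs$chrom_b[i]
    if (!ca %in% names(assignment) && !cb %in% used_b) {
      assignment[ca] <- cb
      used_b <- c(used_b, cb)
    }
  }
  list(pairs = pairs, assignment = assignment)
}

#' Exact k-mer anchors between two sequences
#'
#' Reports one anchor for every position pair sharing a k-mer, on the forward
#' strand (`+`) or via reverse complement (`-`). k-mers occurring more than
#' `max_occurrences` times in either sequence, or containing N, are
#' suppressed (this tames satellite-block saturation).
#'
#' @param seq_x,seq_y residue strings.
#' @param k k-mer size (>= 8; default 15).
#' @param max_occurrences per-sequence k-mer occurrence cap (default 10).
#' @return data.frame of anchors: `x_pos`, `y_pos` (0-based start positions),
#'   `strand`, `length` (= k).
#' @export
kmer_anchor_dotplot <- function(seq_x, seq_y, k = 15L, max_occurrences = 10L) {
  if (k < 8L) stop("k must be >= 8")
  if (!nzchar(seq_x) || !nzchar(seq_y)) stop("empty sequence")
  kmers <- function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }
  kx <- kmers(seq_x)
  ky_fwd <- kmers(seq_y)
  ky_rev <- kmers(revcomp(seq_y))
  valid <- function(km) !grepl("N", km, fixed = TRUE)
  # occurrence caps are per sequence (y counts pooled over both strands)
  cx <- table(kx[valid(kx)])
  cy <- table(c(ky_fwd[valid(ky_fwd)], ky_rev[valid(ky_rev)]))
  ok <- function(km) valid(km) & !is.na(km) &
    (as.vector(cx[km]) <= max_occurrences) & !is.na(cx[km]) &
    (as.vector(cy[km]) <= max_occurrences) & !is.na(cy[km])
  anchors <- function(ky, strand) {
    shared <- intersect(kx, ky)
    shared <- shared[ok(shared)]
    if (!length(shared)) return(NULL)
    px <- split(seq_along(kx) - 1L, kx)[shared]
    py <- split(seq_along(ky) - 1L, ky)[shared]
    do.call(rbind, lapply(seq_along(shared), function(i) {
      g <- expand.grid(x_pos = px[[i]], y_pos = py[[i]])
      g$strand <- strand; g$length <- k
      g
    }))
  }
  fwd <- anchors(ky_fwd, "+")
  rev_ <- anchors(ky_rev, "-")
  ny <- nchar(seq_y)
  if (!is.null(rev_)) rev_$y_pos <- ny - k - rev_$y_pos  # back to forward coords
  out <- rbind(fwd, rev_)
  if (is.null(out)) {
    return(data.frame(x_pos = integer(), y_pos = integer(),
                      strand = character(), length = integer()))
  }
  out <- out[order(out$x_pos, out$y_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
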