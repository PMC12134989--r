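# Independent oracles used to check the package implementations.
# These deliberately use different primitives than the code under test.

# Gap runs by run-length encoding over the character vector (the package
# scans with a regex).
oracle_gap_runs <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  r <- rle(chars %in% c("N", "n"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

# Nx by explicit accumulation loop.
oracle_nx <- function(lengths, level) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= level / 100 * total) return(list(value = s[i], rank = i))
  }
}

# Interval union length by marking a logical vector.
oracle_union_bp <- function(begin, end) {
  if (!length(begin)) return(0L)
  mask <- logical(max(end))
  for (i in seq_along(begin)) mask[(begin[i] + 1L):end[i]] <- TRUE
  sum(mask)
}

# Best injective chromosome assignment by brute force over permutations.
# Returns the maximal total shared-gene count.
oracle_best_assignment <- function(counts) {
  # counts: matrix chrom_a x chrom_b
  na <- nrow(counts); nb <- ncol(counts)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  k <- min(na, nb)
  best <- -Inf
  rows_sets <- utils::combn(na, k, simplify = FALSE)
  cols_sets <- utils::combn(nb, k, simplify = FALSE)
  for (rs in rows_sets) {
    for (cs in cols_sets) {
      for (p in perms(cs)) {
        tot <- sum(counts[cbind(rs, p)])
        if (tot > best) best <- tot
      }
    }
  }
  best
}

# Exhaustive reciprocal-best-hit pairs from a full score table.
oracle_rbh <- function(hits) {
  ids <- unique(c(hits$query_id, hits$subject_id))
  best_of <- function(id) {
    sub <- hits[(hits$query_id == id | hits$subject_id == id) &
                  hits$query_id != hits$subject_id, , drop = FALSE]
    if (!nrow(sub)) return(NA_character_)
    partner <- ifelse(sub$query_id == id, sub$subject_id, sub$query_id)
    o <- order(-sub$score, -sub$identity, partner)
    partner[o][1L]
  }
  bests <- vapply(ids, best_of, "")
  out <- character(0)
  for (a in ids) {
    b <- bests[[a]]
    if (!is.na(b) && a < b && identical(bests[[b]], a)) {
      out <- c(out, paste(a, b))
    }
  }
  sort(out)
}

# Random instance for chromosome-homology tests: a dominant "true pairing"
# with sparse off-diagonal noise, as reciprocal-best-hit counts look in
# practice.
random_homology_instance <- function(seed, n_a, n_b) {
  set.seed(seed)
  k <- min(n_a, n_b)
  counts <- matrix(sample(0:3, n_a * n_b, replace = TRUE), n_a, n_b)
  true_pairs <- cbind(sample(n_a, k), sample(n_b, k))
  counts[true_pairs] <- sample(10:40, k, replace = TRUE)
  dimnames(counts) <- list(sprintf("a%02d", 1:n_a), sprintf("b%02d", 1:n_b))
  counts
}

# Expand a count matrix into per-gene RBH rows + locations.
counts_to_rbh <- function(counts) {
  rows <- list(); loc_a <- character(); loc_b <- character(); g <- 0L
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      for (n in seq_len(counts[i, j])) {
        g <- g + 1L
        ga <- sprintf("gA%04d", g); gb <- sprintf("gB%04d", g)
        rows[[g]] <- data.frame(gene_a = ga, gene_b = gb, score = 100,
                                stringsAsFactors = FALSE)
        loc_a[ga] <- rownames(counts)[i]
        loc_b[gb] <- colnames(counts)[j]
      }
    }
  }
  list(rbh = do.call(rbind, rows), loc_a = loc_a, loc_b = loc_b)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
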