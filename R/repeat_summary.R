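# RepeatMasker landscape summarization: map raw class/family strings to
# report categories and aggregate element counts and masked fractions.

#' Default repeat class/family to category mapping
#'
#' Regular-expression rules mapping RepeatMasker `class/family` strings to
#' report categories, with parent groupings (Retroelements, DNA transposons).
#' Rules are applied top to bottom; the first match wins. Edit or extend the
#' returned frame and pass it back through `category_map` to adapt to a
#' different repeat library's naming.
#'
#' @return data.frame with columns `pattern`, `category`, `parent`.
#' @export
repeat_category_map <- function() {
  rules <- rbind(
    c("^SINE",                                "SINEs",             "Retroelements"),
    c("^LINE",                                "LINEs",             "Retroelements"),
    c("^LTR",                                 "LTR elements",      "Retroelements"),
    c("^Retroposon",                          "SINEs",             "Retroelements"),
    c("^DNA/hAT",                             "hobo-Activator",    "DNA transposons"),
    c("^DNA/TcMar|^DNA/Tc1|^DNA/IS630|^DNA/Pogo", "Tc1-IS630-Pogo", "DNA transposons"),
    c("^DNA/CMC|^DNA/En-Spm|^DNA/CACTA",      "En-Spm",            "DNA transposons"),
    c("^DNA/MULE|^DNA/MuDR",                  "MULE-MuDR",         "DNA transposons"),
    c("^DNA/PiggyBac",                        "PiggyBac",          "DNA transposons"),
    c("^DNA/PIF|^DNA/Harbinger|^DNA/Tourist", "Tourist/Harbinger", "DNA transposons"),
    c("^DNA",                                 "DNA-other",         "DNA transposons"),
    c("^RC/Helitron|^RC",                     "Rolling-circles",   "none"),
    c("^Unknown|^Unspecified",                "Unclassified",      "none"),
    c("^snRNA$|^tRNA$|^rRNA$|^srpRNA$|^scRNA$|^Small RNA", "Small RNA", "none"),
    c("^Satellite",                           "Satellites",        "none"),
    c("^Simple_repeat",                       "Simple repeats",    "none"),
    c("^Low_complexity",                      "Low complexity",    "none")
  )
  data.frame(pattern = rules[, 1L], category = rules[, 2L],
             parent = rules[, 3L], stringsAsFactors = FALSE)
}

.categorize <- function(class_family, category_map) {
  out <- rep(NA_character_, length(class_family))
  for (i in seq_len(nrow(category_map))) {
    hit <- is.na(out) & grepl(category_map$pattern[i], class_family)
    out[hit] <- category_map$category[i]
  }
  out[is.na(out)] <- "Unclassified"
  out
}

.union_bp <- function(begin, end) {
  if (!length(begin)) return(0)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = begin + 1L, end = end))))
}

#' Summarize RepeatMasker annotations into a category report
#'
#' Element counts, masked bases and percent of sequence per category, with
#' parent-group and interspersed totals. Within a category, overlapping
#' annotations are not double-counted (interval union per sequence); the
#' overall masked percentage is the union across all categories. The
#' denominator is conventionally the assembly's non-N length.
#'
#' @param hits data.frame of repeat hits (see [read_repeatmasker_out()]).
#' @param denominator_bases sequence length the percentages refer to
#'   (typically total length excluding Ns); must be positive.
#' @param seq_lengths optional named vector of sequence lengths; when given,
#'   any hit extending beyond its sequence is an error.
#' @param category_map mapping rules, default [repeat_category_map()].
#' @return A `repeat_summary` list: `by_category` (data.frame `category`,
#'   `parent`, `element_count`, `masked_bases`, `pct_of_sequence`),
#'   `parent_totals`, `total_interspersed_pct`, `overall_masked_pct`,
#'   `denominator_bases`.
#' @export
summarize_repeats <- function(hits, denominator_bases, seq_lengths = NULL,
                              category_map = repeat_category_map()) {
  if (denominator_bases <= 0) stop("denominator_bases must be positive")
  if (!is.null(seq_lengths) && nrow(hits)) {
    over <- hits$end > seq_lengths[hits$seq_id]
    if (any(is.na(over) | over)) {
      stop("repeat hit(s) extend beyond the supplied sequence length")
    }
  }
  cats <- c("SINEs", "LINEs", "LTR elements", "hobo-Activator",
            "Tc1-IS630-Pogo", "En-Spm", "MULE-MuDR", "PiggyBac",
            "Tourist/Harbinger", "DNA-other", "Rolling-circles",
            "Unclassified", "Small RNA", "Satellites", "Simple repeats",
            "Low complexity")
  parent_of <- setNames(rep("none", length(cats)), cats)
  parent_of[c("SINEs", "LINEs", "LTR elements")] <- "Retroelements"
  parent_of[c("hobo-Activator", "Tc1-IS630-Pogo", "En-Spm", "MULE-MuDR",
              "PiggyBac", "Tourist/Harbinger", "DNA-other")] <- "DNA transposons"
  if (nrow(hits)) hits$category <- .categorize(hits$class_family, category_map)
  by_cat <- data.frame(category = cats, parent = parent_of[cats],
                       element_count = 0L, masked_bases = 0,
                       pct_of_sequence = 0, stringsAsFactors = FALSE,
                       row.names = NULL)
  if (nrow(hits)) {
    for (i in seq_along(cats)) {
      sub <- hits[hits$category == cats[i], , drop = FALSE]
      by_cat$element_count[i] <- nrow(sub)
      if (nrow(sub)) {
        by_cat$masked_bases[i] <- sum(vapply(
          split(sub, sub$seq_id),
          function(s) .union_bp(s$begin, s$end), 0))
      }
    }
  }
  by_cat$pct_of_sequence <- 100 * by_cat$masked_bases / denominator_bases
  parent_totals <- do.call(rbind, lapply(c("Retroelements", "DNA transposons"), function(p) {
    sub <- by_cat[by_cat$parent == p, , drop = FALSE]
    data.frame(parent = p, element_count = sum(sub$element_count),
               masked_bases = sum(sub$masked_bases),
               pct_of_sequence = sum(sub$pct_of_sequence),
               stringsAsFactors = FALSE)
  }))
  interspersed <- c("SINEs", "LINEs", "LTR elements", "hobo-Activator",
                    "Tc1-IS630-Pogo", "En-Spm", "MULE-MuDR", "PiggyBac",
                    "Tourist/Harbinger", "DNA-other", "Rolling-circles",
                    "Unclassified")
  overall_bp <- if (nrow(hits)) {
    sum(vapply(split(hits, hits$seq_id), function(s) .union_bp(s$begin, s$end), 0))
  } else 0
  structure(list(
    by_category = by_cat,
    parent_totals = parent_totals,
    total_interspersed_pct = sum(by_cat$pct_of_sequence[by_cat$category %in% interspersed]),
    overall_masked_pct = 100 * overall_bp / denominator_bases,
    denominator_bases = denominator_bases
  ), class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("repeat_summary over %s bp: %.2f%% masked overall\n",
              format(x$denominator_bases, big.mark = ","), x$overall_masked_pct))
  p <- x$by_category[x$by_category$element_count > 0L, , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-18s %8d elements  %6.2f%%\n", p$category[i],
                p$element_count[i], p$pct_of_sequence[i]))
  }
  cat(sprintf("  total interspersed: %.2f%%\n", x$total_interspersed_pct))
  invisible(x)
}
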