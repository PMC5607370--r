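GLY_CODONS <- c("GGT", "GGC", "GGA", "GGG")

#' Observed adjacent Gly-Gly codon-pair counts
#'
#' Counts ordered in-frame adjacent codon pairs (i, i+1) within each gene
#' where both codons encode glycine. Pairs never span gene boundaries.
#' SD-like GGA/GGG-built hexamers (GGAGG...) are the pairs that can pause
#' ribosomes via anti-Shine-Dalgarno pairing.
#'
#' @param codon_lists List of per-gene codon vectors (from
#'   [coding_codons()]).
#' @return data.frame over the 16 ordered pairs: `codon1`, `codon2`,
#'   `observed`.
#' @export
gly_gly_pairs <- function(codon_lists) {
  pairs <- expand.grid(codon1 = GLY_CODONS, codon2 = GLY_CODONS,
                       stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$codon1, pairs$codon2), ]
  rownames(pairs) <- NULL
  key <- paste(pairs$codon1, pairs$codon2)
  counts <- stats::setNames(integer(length(key)), key)
  for (codons in codon_lists) {
    n <- length(codons)
    if (n < 2L) next
    a <- codons[-n]
    b <- codons[-1L]
    gg <- a %in% GLY_CODONS & b %in% GLY_CODONS
    if (any(gg)) {
      tab <- table(paste(a[gg], b[gg]))
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  pairs$observed <- as.integer(counts)
  pairs
}

#' Expected adjacent codon-pair counts under codon-frequency independence
#'
#' E\[(a,b)\] = P(a) P(b) N_adj with P(x) the genome-wide codon frequency
#' and N_adj the total number of adjacent in-gene codon pairs.
#'
#' @param codon_counts Named integer vector of codon counts over the gene set.
#' @param total_codons Total codon count (denominator of P).
#' @param n_adjacent Total number of adjacent in-gene codon pairs.
#' @param pairs data.frame with `codon1`, `codon2` (default: 16 Gly pairs).
#' @return The `pairs` data.frame with an `expected` column.
#' @export
expected_pair_counts <- function(codon_counts, total_codons, n_adjacent,
                                 pairs = NULL) {
  if (total_codons == 0) stop("total_codons must be positive")
  if (is.null(pairs)) {
    pairs <- expand.grid(codon1 = GLY_CODONS, codon2 = GLY_CODONS,
                         stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$codon1, pairs$codon2), ]
    rownames(pairs) <- NULL
  }
  p <- function(x) {
    cnt <- codon_counts[x]
    cnt[is.na(cnt)] <- 0
    as.numeric(cnt) / total_codons
  }
  pairs$expected <- p(pairs$codon1) * p(pairs$codon2) * n_adjacent
  pairs
}

#' Gly-Gly codon-pair observed:expected statistics for a gene set
#'
#' @param codon_lists List of per-gene codon vectors.
#' @return data.frame over the 16 ordered Gly pairs with `observed`,
#'   `expected`, `o_e_ratio`, plus attributes `total_codons` and
#'   `n_adjacent`.
#' @export
codon_pair_stats <- function(codon_lists) {
  obs <- gly_gly_pairs(codon_lists)
  all_codons <- unlist(codon_lists, use.names = FALSE)
  counts <- table(all_codons)
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_adj <- sum(pmax(lengths(codon_lists) - 1L, 0L))
  stats <- expected_pair_counts(counts, length(all_codons), n_adj, obs)
  stats$o_e_ratio <- ifelse(stats$expected > 0,
                            stats$observed / stats$expected, NA_real_)
  attr(stats, "total_codons") <- length(all_codons)
  attr(stats, "n_adjacent") <- n_adj
  stats
}

#' Default anti-Shine-Dalgarno affinity table for Gly-Gly hexamers
#'
#' The anti-SD core at the 16S rRNA 3' end pairs with G/A-rich mRNA runs;
#' hexamers built from GGA and GGG (GGAGGA-like) hybridize strongly while
#' GGT/GGC-built hexamers do not. The default scores each codon (GGA = 2,
#' GGG = 1, GGT = GGC = 0), sums the two codons, and bins the 0-4 score
#' range into four affinity bins (lowest to highest). Fully overridable: any
#' data.frame with `codon1`, `codon2`, `affinity`, `bin` works downstream.
#'
#' @return data.frame with `codon1`, `codon2`, `affinity`, `bin` (ordered
#'   factor, low to high).
#' @export
default_affinity_table <- function() {
  score <- c(GGA = 2, GGG = 1, GGT = 0, GGC = 0)
  tab <- expand.grid(codon1 = GLY_CODONS, codon2 = GLY_CODONS,
                     stringsAsFactors = FALSE)
  tab <- tab[order(tab$codon1, tab$codon2), ]
  rownames(tab) <- NULL
  tab$affinity <- score[tab$codon1] + score[tab$codon2]
  edges <- c(-Inf, 0.5, 1.5, 2.5, Inf)  # score 0 | 1 | 2 | 3-4
  tab$bin <- cut(tab$affinity, edges,
                 labels = c("low", "mid_low", "mid_high", "high"),
                 ordered_result = TRUE)
  tab
}

#' Pool Gly-Gly O/E by anti-SD affinity bin
#'
#' Pooled O/E per bin = sum(observed) / sum(expected) within the bin,
#' ordered from low to high affinity.
#'
#' @param pair_stats Output of [codon_pair_stats()].
#' @param affinity_table A table from [default_affinity_table()] (or custom;
#'   must map all 16 pairs).
#' @return data.frame: `bin`, `observed`, `expected`, `o_e_ratio`. Bins with
#'   zero expected are dropped with a warning.
#' @export
bin_by_affinity <- function(pair_stats, affinity_table = default_affinity_table()) {
  key <- function(d) paste(d$codon1, d$codon2)
  m <- match(key(pair_stats), key(affinity_table))
  if (anyNA(m)) {
    stop("configuration error: affinity table does not map all codon pairs")
  }
  bin <- affinity_table$bin[m]
  agg <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- bin == b
    data.frame(bin = b, observed = sum(pair_stats$observed[sel]),
               expected = sum(pair_stats$expected[sel]),
               stringsAsFactors = FALSE)
  }))
  if (any(agg$expected == 0)) {
    warning("dropping affinity bin(s) with zero expected count")
    agg <- agg[agg$expected > 0, , drop = FALSE]
  }
  agg$o_e_ratio <- agg$observed / agg$expected
  rownames(agg) <- NULL
  agg
}

region_seqs <- function(regions, genome) {
  vapply(seq_len(nrow(regions)), function(i) {
    genome_slice(genome, regions$start[i], regions$end[i])
  }, character(1))
}

class_indicator <- function(seq, alphabet_class) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (alphabet_class == "pyrimidine") b %in% c("C", "T") else b %in% c("A", "G")
}

#' Count composition-rich k-mers in a region set
#'
#' Number of length-`k` windows (every start offset; overlapping windows all
#' count) fully inside a region with at least
#' `ceiling(fraction_threshold * k)` bases of the class (pyrimidine = C/T,
#' purine = A/G). With `collapse = TRUE`, overlapping qualifying windows are
#' merged into maximal runs and runs are counted instead.
#'
#' @param regions data.frame with `start`, `end` (0-based half-open).
#' @param genome A `genome_record`.
#' @param k Window length (>= 2).
#' @param fraction_threshold Minimum class fraction (e.g. 0.8).
#' @param alphabet_class `"pyrimidine"` or `"purine"`.
#' @param collapse Count maximal runs instead of windows.
#' @return Integer count.
#' @export
rich_motif_count <- function(regions, genome, k = 10, fraction_threshold = 0.8,
                             alphabet_class = c("pyrimidine", "purine"),
                             collapse = FALSE) {
  alphabet_class <- match.arg(alphabet_class)
  stopifnot(k >= 2)
  need <- ceiling(fraction_threshold * k)
  total <- 0L
  for (s in region_seqs(regions, genome)) {
    n <- nchar(s)
    if (n < k) next
    ind <- as.integer(class_indicator(s, alphabet_class))
    cs <- c(0L, cumsum(ind))
    wins <- cs[(k + 1L):(n + 1L)] - cs[1L:(n - k + 1L)]
    ok <- wins >= need
    if (collapse) {
      r <- rle(ok)
      total <- total + sum(r$values)
    } else {
      total <- total + sum(ok)
    }
  }
  total
}

#' Expected composition-rich k-mer count under a binomial null
#'
#' Expected = N_windows * P(X >= ceiling(fraction_threshold * k)) with
#' X ~ Binomial(k, p), where p is the class fraction of the region set
#' itself (`null = "region"`) or of the whole genome (`null = "genome"`).
#'
#' @inheritParams rich_motif_count
#' @param null Composition source for p.
#' @return List: `expected`, `n_windows`, `p_class`.
#' @export
expected_motif_count <- function(regions, genome, k = 10,
                                 fraction_threshold = 0.8,
                                 alphabet_class = c("pyrimidine", "purine"),
                                 null = c("region", "genome")) {
  alphabet_class <- match.arg(alphabet_class)
  null <- match.arg(null)
  if (nrow(regions) == 0L) stop("empty region set")
  seqs <- region_seqs(regions, genome)
  lens <- nchar(seqs)
  n_windows <- sum(pmax(lens - k + 1L, 0L))
  src <- if (null == "region") paste0(seqs, collapse = "") else genome$sequence
  ind <- class_indicator(src, alphabet_class)
  p_class <- mean(ind)
  need <- ceiling(fraction_threshold * k)
  tail_p <- stats::pbinom(need - 1L, k, p_class, lower.tail = FALSE)
  list(expected = n_windows * tail_p, n_windows = n_windows, p_class = p_class)
}

#' Fisher's exact test on normalized (rounded) counts
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' \[\[observed_a, round(expected_a)\], \[observed_b, round(expected_b)\]\].
#' Expected values are rounded because the exact test requires integers. A
#' degenerate table (any zero margin) returns p = 1 with a `degenerate`
#' flag.
#'
#' @param observed_a,expected_a,observed_b,expected_b Cell values (>= 0).
#' @return List: `p_value`, `table`, `degenerate`.
#' @export
fisher_normalized <- function(observed_a, expected_a, observed_b, expected_b) {
  stopifnot(observed_a >= 0, expected_a >= 0, observed_b >= 0, expected_b >= 0)
  tab <- matrix(c(round(observed_a), round(expected_a),
                  round(observed_b), round(expected_b)),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p_value = 1, table = tab, degenerate = TRUE))
  }
  list(p_value = stats::fisher.test(tab)$p.value, table = tab,
       degenerate = FALSE)
}

iupac_ok <- function(pattern) {
  grepl("^[ACGTRYSWKMBDHVN]+$", toupper(pattern))
}

#' Scan for NtcA promoter boxes upstream of translational starts
#'
#' Scans the strand-aware upstream region of each gene (on the coding
#' strand) for an IUPAC-degenerate promoter pattern; the default
#' `GTAN8TAC` is the canonical cyanobacterial NtcA box. A site counts only
#' if its 5'-most base lies strictly less than `max_upstream` bp upstream of
#' the translational start.
#'
#' @param genes Annotation data.frame.
#' @param genome A `genome_record`.
#' @param motif_pattern IUPAC pattern (default `"GTANNNNNNNNTAC"`).
#' @param max_upstream Upstream window in bp (default 100; strict `<`).
#' @return List: `hits` (data.frame `gene_id`, `site_position` genomic
#'   0-based, `distance_to_start`, `matched_sequence` on the coding strand)
#'   and `n_genes` (distinct genes with >= 1 hit).
#' @export
ntca_scan <- function(genes, genome, motif_pattern = "GTANNNNNNNNTAC",
                      max_upstream = 100) {
  motif_pattern <- toupper(motif_pattern)
  if (!iupac_ok(motif_pattern)) {
    stop("configuration error: malformed IUPAC pattern '", motif_pattern, "'")
  }
  plen <- nchar(motif_pattern)
  pat <- Biostrings::DNAString(motif_pattern)
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    reg <- upstream_region(g, max_upstream, genome$length)
    if (reg$end - reg$start < plen) next
    s <- genome_slice(genome, reg$start, reg$end)
    if (g$strand == "-") s <- revcomp(s)
    wlen <- nchar(s)
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(s), fixed = FALSE)
    if (length(m) == 0L) next
    starts <- Biostrings::start(m)  # 1-based offset within the upstream window
    for (st in starts) {
      dist <- wlen - (st - 1L)  # distance of the motif 5' base to the gene start
      if (dist >= max_upstream) next  # strict "< max_upstream bp upstream"
      gpos <- if (g$strand == "+") reg$start + st - 1L
              else reg$end - (st - 1L) - plen
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = g$gene_id, site_position = gpos, distance_to_start = dist,
        matched_sequence = substr(s, st, st + plen - 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  hits_df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene_id = character(), site_position = integer(),
               distance_to_start = integer(), matched_sequence = character())
  list(hits = hits_df, n_genes = length(unique(hits_df$gene_id)))
}

#' Full motif report for one region set
#'
#' Convenience wrapper combining observed and expected rich-motif counts
#' with the Fisher test against the opposite base class.
#'
#' @inheritParams rich_motif_count
#' @param null See [expected_motif_count()].
#' @return One-row data.frame: `region_set`, `k`, `threshold`, `class`,
#'   `observed`, `expected`, `o_e_ratio`, `fisher_p` (vs the complementary
#'   class's observed/expected).
#' @export
motif_report <- function(regions, genome, k = 10, fraction_threshold = 0.8,
                         alphabet_class = "pyrimidine",
                         null = "region", region_set = "regions") {
  other <- if (alphabet_class == "pyrimidine") "purine" else "pyrimidine"
  obs <- rich_motif_count(regions, genome, k, fraction_threshold, alphabet_class)
  exp <- expected_motif_count(regions, genome, k, fraction_threshold,
                              alphabet_class, null)
  obs_o <- rich_motif_count(regions, genome, k, fraction_threshold, other)
  exp_o <- expected_motif_count(regions, genome, k, fraction_threshold,
                                other, null)
  ft <- fisher_normalized(obs, exp$expected, obs_o, exp_o$expected)
  data.frame(region_set = region_set, k = k, threshold = fraction_threshold,
             class = alphabet_class, observed = obs, expected = exp$expected,
             o_e_ratio = if (exp$expected > 0) obs / exp$expected else NA_real_,
             fisher_p = ft$p_value, stringsAsFactors = FALSE)
}
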