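test_that("Gly-Gly pair counting is in-frame, adjacent, within-gene", {
  expect_equal(sum(gly_gly_pairs(list(c("ATG", "GGA", "GGT", "TAA")))$observed), 1L)
  st <- gly_gly_pairs(list(c("ATG", "GGA", "GGT", "TAA")))
  expect_equal(st$observed[st$codon1 == "GGA" & st$codon2 == "GGT"], 1L)
  expect_equal(sum(gly_gly_pairs(list(c("ATG", "GGA", "AAA", "GGT", "TAA")))$observed), 0L)
  # pairs never span gene boundaries
  two <- list(c("ATG", "GGA", "TAA"), c("GGT", "AAA", "TAA"))
  expect_equal(sum(gly_gly_pairs(two)$observed), 0L)

  # brute-force sliding-window oracle on random codon lists
  set.seed(8)
  sense <- names(default_codon_weights())
  gly <- c("GGT", "GGC", "GGA", "GGG")
  for (rep in 1:10) {
    lists <- lapply(1:5, function(i) {
      sample(c(sense, rep(gly, 8)), sample(20:80, 1), replace = TRUE)
    })
    oracle <- 0L
    for (cl in lists) {
      for (j in seq_len(length(cl) - 1)) {
        if (cl[j] %in% gly && cl[j + 1] %in% gly) oracle <- oracle + 1L
      }
    }
    expect_equal(sum(gly_gly_pairs(lists)$observed), oracle)
  }
})

test_that("expected pair counts implement the independence null", {
  counts <- c(GGA = 20, GGT = 20)  # P = 0.05 each at 400 total codons
  ex <- expected_pair_counts(counts, 400, 400)
  expect_equal(ex$expected[ex$codon1 == "GGA" & ex$codon2 == "GGT"], 1.0)
  expect_equal(ex$expected[ex$codon1 == "GGC" & ex$codon2 == "GGC"], 0.0)
  expect_error(expected_pair_counts(counts, 0, 10), "positive")
})

test_that("affinity binning pools observed and expected per bin", {
  lists <- list(c("ATG", "GGA", "GGA", "GGT", "GGC", "AAA", "TAA"))
  st <- codon_pair_stats(lists)
  # a single-bin table pools to the global O/E
  onebin <- default_affinity_table()
  onebin$bin <- factor(rep("all", 16))
  pooled <- bin_by_affinity(st, onebin)
  expect_equal(pooled$o_e_ratio,
               sum(st$observed) / sum(st$expected))

  # unmapped pairs are a configuration error
  expect_error(bin_by_affinity(st, onebin[-1, ]), "configuration error")

  # planted 2x depletion of the high-affinity bin: destroy half of the
  # GGA/GGG adjacencies by swapping the second codon with a distant non-Gly
  # codon (swaps preserve codon counts, so expectations are unchanged)
  set.seed(12)
  sense <- names(default_codon_weights())
  gly_hi <- c("GGA", "GGG")
  lists <- lapply(1:60, function(i) {
    sample(c(sense, rep(gly_hi, 12)), 120, replace = TRUE)
  })
  aff <- default_affinity_table()
  hi_pairs <- paste(aff$codon1, aff$codon2)[aff$bin == "high"]
  depleted <- lapply(lists, function(cl) {
    n <- length(cl)
    for (j in seq_len(n - 1)) {
      if (paste(cl[j], cl[j + 1]) %in% hi_pairs && runif(1) < 0.5) {
        gly <- c("GGT", "GGC", "GGA", "GGG")
        ok <- which(!cl %in% gly)
        # avoid creating a new Gly-Gly adjacency at the landing site
        ok <- ok[!(cl[pmax(ok - 1, 1)] %in% gly) &
                   !(cl[pmin(ok + 1, n)] %in% gly)]
        ok <- setdiff(ok, c(j - 1, j, j + 1, j + 2))
        if (!length(ok)) next
        k <- if (length(ok) == 1) ok else sample(ok, 1)
        tmp <- cl[j + 1]; cl[j + 1] <- cl[k]; cl[k] <- tmp
      }
    }
    cl
  })
  bins <- bin_by_affinity(codon_pair_stats(depleted))
  hi <- bins$o_e_ratio[bins$bin == "high"]
  expect_lt(hi, 0.7)
  expect_gt(hi, 0.3)
})

test_that("rich-motif window counts match a brute-force oracle", {
  genome <- make_genome("CCCCCCCCCC")
  reg <- data.frame(start = 0L, end = 10L)
  expect_equal(rich_motif_count(reg, genome, 10, 0.8, "pyrimidine"), 1L)

  genome2 <- make_genome("CCCCCCCCAA")
  reg2 <- data.frame(start = 0L, end = 10L)
  # 8/10 = 0.8 satisfies "at least 80%"
  expect_equal(rich_motif_count(reg2, genome2, 10, 0.8, "pyrimidine"), 1L)
  genome3 <- make_genome("CCCCCCCAAA")
  expect_equal(rich_motif_count(reg2, genome3, 10, 0.8, "pyrimidine"), 0L)
  # region shorter than k contributes nothing
  expect_equal(rich_motif_count(data.frame(start = 0L, end = 5L),
                                genome, 10, 0.8, "pyrimidine"), 0L)

  brute <- function(s, k, thr, cls) {
    bases <- if (cls == "pyrimidine") c("C", "T") else c("A", "G")
    n <- nchar(s); cnt <- 0L
    if (n < k) return(0L)
    for (i in 1:(n - k + 1)) {
      w <- strsplit(substr(s, i, i + k - 1), "")[[1]]
      if (sum(w %in% bases) >= ceiling(thr * k)) cnt <- cnt + 1L
    }
    cnt
  }
  set.seed(4)
  for (rep in 1:15) {
    s <- paste0(sample(c("A", "C", "G", "T"), 120, replace = TRUE,
                       prob = c(0.2, 0.35, 0.15, 0.3)), collapse = "")
    g <- make_genome(s)
    r <- data.frame(start = 0L, end = 120L)
    for (k in c(10, 12)) {
      for (cls in c("pyrimidine", "purine")) {
        expect_equal(rich_motif_count(r, g, k, 0.8, cls),
                     brute(s, k, 0.8, cls))
      }
    }
  }

  # complementarity: pyrimidine windows on s equal purine windows on complement
  s <- strrep("CTAGCCTTAG", 12)
  comp <- chartr("ACGT", "TGCA", s)
  r <- data.frame(start = 0L, end = nchar(s))
  expect_equal(rich_motif_count(r, make_genome(s), 10, 0.8, "pyrimidine"),
               rich_motif_count(r, make_genome(comp), 10, 0.8, "purine"))
})

test_that("expected motif counts use the exact binomial tail", {
  genome <- make_genome(strrep("CT", 50))
  reg <- data.frame(start = 0L, end = 100L)
  ex <- expected_motif_count(reg, genome, 10, 0.8, "pyrimidine")
  expect_equal(ex$p_class, 1.0)
  expect_equal(ex$expected, ex$n_windows)

  # p = 0.5, k = 10, threshold 0.8: tail P(X >= 8) = 56/1024
  genome2 <- make_genome(strrep("CA", 50))
  ex2 <- expected_motif_count(reg, genome2, 10, 0.8, "pyrimidine")
  expect_equal(ex2$p_class, 0.5)
  expect_equal(ex2$expected, 91 * 0.0546875)
  expect_error(expected_motif_count(reg[0, ], genome, 10, 0.8), "empty")
})

test_that("O/E is centered at 1 on neutral sequence (simulation null)", {
  set.seed(6)
  oes <- replicate(40, {
    s <- paste0(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                collapse = "")
    g <- make_genome(s)
    r <- data.frame(start = 0L, end = 4000L)
    obs <- rich_motif_count(r, g, 10, 0.8, "pyrimidine")
    ex <- expected_motif_count(r, g, 10, 0.8, "pyrimidine")
    obs / ex$expected
  })
  se <- sd(oes) / sqrt(length(oes))
  expect_lt(abs(mean(oes) - 1), 3 * se + 0.05)
})

test_that("Fisher tests on normalized counts match hypergeometric enumeration", {
  expect_equal(fisher_normalized(10, 10, 10, 10)$p_value, 1.0)
  z <- fisher_normalized(0, 0, 5, 5)
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)

  # exact enumeration oracle for the two-sided p
  enum_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  cases <- list(c(9, 7, 5, 10), c(91, 68, 10, 10), c(3, 12, 14, 2))
  for (cs in cases) {
    expect_equal(fisher_normalized(cs[1], cs[2], cs[3], cs[4])$p_value,
                 enum_fisher(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10)
    # swapping rows leaves the two-sided p unchanged
    expect_equal(fisher_normalized(cs[1], cs[2], cs[3], cs[4])$p_value,
                 fisher_normalized(cs[3], cs[4], cs[1], cs[2])$p_value)
  }
  # expected values are rounded to integers for the table
  expect_equal(fisher_normalized(9, 6.7, 5, 10.2)$p_value,
               fisher_normalized(9, 7, 5, 10)$p_value)
})

test_that("NtcA scanning matches planted sites and the distance rule", {
  # direct pattern hit: GTA + 8 arbitrary + TAC
  up <- paste0(strrep("A", 40), "GTACGATCGAGTAC", strrep("A", 26))
  genome <- make_genome(paste0(up, "ATGAAATAA", strrep("A", 20)))
  gene <- make_gene("gA", 80, 89, "+")
  sc <- ntca_scan(gene, genome)
  expect_equal(sc$n_genes, 1L)
  expect_equal(sc$hits$matched_sequence, "GTACGATCGAGTAC")
  expect_equal(sc$hits$distance_to_start, 40L)

  # a site starting exactly 100 bp upstream is excluded (strict <100)
  far <- paste0("GTACGATCGAGTAC", strrep("A", 86))
  genome2 <- make_genome(paste0(far, "ATGAAATAA"))
  gene2 <- make_gene("gA", 100, 109, "+")
  expect_equal(ntca_scan(gene2, genome2)$n_genes, 0L)
  # one bp closer it is included
  gene3 <- make_gene("gA", 99, 108, "+")
  expect_equal(ntca_scan(gene3, make_genome(paste0(far, "AATGAAATAA")))$n_genes, 1L)

  expect_error(ntca_scan(gene, genome, motif_pattern = "GTA-N8"), "malformed")

  # planted-site fixture: recovered genes equal planted genes exactly
  sim <- simulate_genome(n_genes = 30, mean_gene_len = 80, ntca_sites = 8,
                         seed = 29)
  sc2 <- ntca_scan(sim$genes, sim$genome)
  expect_setequal(intersect(sc2$hits$gene_id, sim$truth$ntca_sites$gene_id),
                  sim$truth$ntca_sites$gene_id)
  planted <- sim$truth$ntca_sites
  found <- sc2$hits[match(planted$gene_id, sc2$hits$gene_id), ]
  expect_equal(found$distance_to_start, planted$distance_to_start)
})
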