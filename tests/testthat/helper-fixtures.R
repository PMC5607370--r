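# In-code fixture builders shared across the suite.

make_genome <- function(seq, id = "g") genome_record(id, seq)

make_gene <- function(id, start, end, strand = "+", coding = TRUE) {
  data.frame(gene_id = id, start = as.integer(start), end = as.integer(end),
             strand = strand, is_coding = coding, stringsAsFactors = FALSE)
}

make_cov <- function(plus, minus = NULL, label = "lib") {
  if (is.null(minus)) minus <- integer(length(plus))
  five_prime_coverage(plus, minus, label = label)
}

# Brute-force two-Poisson convolution: P(E - C >= k), E~Pois(m1), C~Pois(m2).
# Independent of the Bessel-based implementation.
skellam_tail_oracle <- function(k, m1, m2) {
  cmax <- ceiling(10 * m2) + 100
  j <- 0:cmax
  sum(stats::dpois(j, m2) * stats::ppois(j + k - 1, m1, lower.tail = FALSE))
}

# Standard small simulated study reused by several tests.
small_study <- function(seed = 11, n_genes = 20) {
  sim <- simulate_genome(n_genes = n_genes, mean_gene_len = 120,
                         intergenic_len = 150, seed = seed)
  tss <- plant_tss(sim$genes, sim$genome, primary_mean = 2000,
                   ratio_replete = 0.4, ratio_deplete = 0.4, seed = seed)
  sim$truth$tss <- tss
  sim
}

# TSS recall/precision of calls against a planted truth table.
match_calls <- function(calls, truth, tol = 5) {
  hit_truth <- vapply(seq_len(nrow(truth)), function(i) {
    same <- calls$strand == truth$strand[i]
    any(abs(calls$position[same] - truth$position[i]) <= tol)
  }, logical(1))
  hit_call <- vapply(seq_len(nrow(calls)), function(i) {
    same <- truth$strand == calls$strand[i]
    any(abs(truth$position[same] - calls$position[i]) <= tol)
  }, logical(1))
  list(recall = mean(hit_truth), precision = mean(hit_call))
}
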