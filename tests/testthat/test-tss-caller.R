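test_that("background estimation is robust to TSS spikes", {
  cov <- make_cov(rep(2L, 100), rep(2L, 100))
  expect_equal(unname(estimate_background(cov)["plus"]), 2.0)

  zero <- make_cov(integer(100))
  # warns once per all-zero strand
  expect_warning(expect_warning(bg <- estimate_background(zero), "all-zero"),
                 "all-zero")
  expect_equal(unname(bg["plus"]), 0.01)

  spiky <- make_cov(c(rep(1L, 99), 1000000L), rep(1L, 100))
  expect_equal(unname(estimate_background(spiky)["plus"]), 1.0)
})

test_that("Skellam upper tail behaves like a tail probability", {
  expect_gte(skellam_pvalue(0, 0, 1, 1), 0.5)
  expect_lt(skellam_pvalue(50, 0, 1, 1), 1e-10)
  p <- vapply(c(0, 2, 5, 10, 20, 50), function(e) skellam_pvalue(e, 0, 1, 1),
              numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_error(skellam_pvalue(1, 0, Inf, 1), "parameter error")
})

test_that("Skellam p-values match the two-Poisson convolution oracle", {
  for (m1 in c(0.1, 1, 5)) {
    for (m2 in c(0.5, 2)) {
      for (k in c(-3, 0, 2, 7, 15)) {
        expect_equal(skellam_pvalue(k, 0, m1, m2),
                     skellam_tail_oracle(k, m1, m2), tolerance = 1e-12)
      }
    }
  }
})

test_that("call_tss applies noise, significance, merge and curation rules", {
  # nothing reaches the noise threshold -> empty
  quiet <- make_cov(rep(1L, 200))
  ctrl <- make_cov(rep(1L, 200))
  expect_equal(nrow(suppressWarnings(call_tss(quiet, ctrl))), 0L)

  # enriched=150, control=100: significant but curation removes (diff 50 < 100)
  e <- rep(0L, 200); c0 <- rep(0L, 200)
  e[51] <- 150L; c0[51] <- 100L
  calls <- suppressWarnings(call_tss(make_cov(e), make_cov(c0),
                                     tss_params(normalize = FALSE)))
  expect_equal(nrow(calls), 0L)

  # diff >= 100 retained
  e[51] <- 250L
  calls <- suppressWarnings(call_tss(make_cov(e), make_cov(c0),
                                     tss_params(normalize = FALSE)))
  expect_equal(calls$position, 50L)
  expect_lt(calls$p_value, 1e-10)
})

test_that("merge_calls keeps the max-count call and is idempotent", {
  calls <- data.frame(position = c(100L, 103L), strand = "+",
                      enriched_count = c(10L, 40L), control_count = 0L,
                      control_scaled = 0, p_value = 1e-20)
  m <- merge_calls(calls, 5)
  expect_equal(m$position, 103L)

  calls2 <- calls; calls2$position <- c(100L, 106L)
  expect_equal(nrow(merge_calls(calls2, 5)), 2L)

  # ties break toward the smaller coordinate
  calls3 <- calls; calls3$enriched_count <- c(40L, 40L)
  expect_equal(merge_calls(calls3, 5)$position, 100L)

  # idempotence on a random call set
  set.seed(1)
  big <- data.frame(position = sort(sample(1:500, 40)),
                    strand = sample(c("+", "-"), 40, replace = TRUE),
                    enriched_count = sample(10:99, 40, replace = TRUE),
                    control_count = 0L, control_scaled = 0, p_value = 0)
  once <- merge_calls(big, 5)
  expect_identical(merge_calls(once, 5), once)
})

test_that("positional classification covers all five categories", {
  genes <- make_gene("gA", 500, 900, "+")
  params <- tss_params()
  mk <- function(pos, strand) {
    structure(data.frame(position = pos, strand = strand,
                         enriched_count = 500L, control_count = 0L,
                         control_scaled = 0, p_value = 0),
              class = c("tss_calls", "data.frame"))
  }
  expect_true(classify_tss(mk(480L, "+"), genes, params)$primary)
  cl <- classify_tss(mk(600L, "+"), genes, params)
  expect_true(cl$internal); expect_false(cl$primary)
  expect_true(classify_tss(mk(600L, "-"), genes, params)$antisense)
  expect_true(classify_tss(mk(920L, "+"), genes, params)$downstream)
  far <- classify_tss(mk(2000L, "+"), genes, params)
  expect_true(far$orphan)
  expect_equal(far$categories[[1]], "orphan")

  # boundary: exactly 250 upstream is primary (inclusive), 251 is not
  expect_true(classify_tss(mk(250L, "+"), genes, params)$primary)
  expect_false(classify_tss(mk(249L, "+"), genes, params)$primary)
  # boundary: 29 nt downstream in, 30 out (strict <30)
  expect_true(classify_tss(mk(929L, "+"), genes, params)$downstream)
  expect_false(classify_tss(mk(930L, "+"), genes, params)$downstream)

  # a call can carry several categories at once
  genes2 <- rbind(genes, make_gene("gB", 950, 1300, "+"))
  multi <- classify_tss(mk(880L, "+"), genes2, params)
  expect_true(multi$internal && multi$primary)
  expect_equal(multi$internal_gene, "gA")
  expect_equal(multi$primary_gene, "gB")
})

test_that("category census counts each combination once", {
  genes <- rbind(make_gene("gA", 500, 900, "+"),
                 make_gene("gB", 600, 1000, "-"))
  calls <- structure(
    data.frame(position = c(700L, 100L), strand = "+",
               enriched_count = 500L, control_count = 0L,
               control_scaled = 0, p_value = 0),
    class = c("tss_calls", "data.frame"))
  cl <- classify_tss(calls, genes, tss_params())
  cen <- category_census(cl)
  expect_equal(unname(cen["Internal antisense"]), 1L)
  expect_equal(unname(cen["Orphan"]), 1L)
  expect_equal(sum(cen), nrow(calls))
})

test_that("planted TSSs are recovered and classified per the truth table", {
  sim <- small_study(seed = 31, n_genes = 20)
  cov <- simulate_coverage(sim$genome,
                           transform(sim$truth$tss, mean_count = mean_replete),
                           noise_rate = 0.5, seed = 31)
  calls <- call_tss(cov$enriched, cov$control)
  perf <- match_calls(calls, sim$truth$tss)
  expect_gte(perf$recall, 0.95)
  expect_gte(perf$precision, 0.95)

  cl <- classify_tss(calls, sim$genes, tss_params())
  # every planted internal TSS that was called is classified internal
  for (i in which(sim$truth$tss$kind == "internal")) {
    hit <- cl$position == sim$truth$tss$position[i] &
      cl$strand == sim$truth$tss$strand[i]
    if (any(hit)) expect_true(all(cl$internal[hit]))
  }
})

test_that("leaderless fraction counts primary TSSs near the start codon", {
  genes <- make_gene("gA", 500, 900, "+")
  mk <- function(pos) {
    structure(data.frame(position = pos, strand = "+",
                         enriched_count = 500L, control_count = 0L,
                         control_scaled = 0, p_value = 0),
              class = c("tss_calls", "data.frame"))
  }
  at_start <- classify_tss(mk(500L), genes, tss_params())
  expect_equal(leaderless_fraction(at_start, genes), 1.0)
  eleven <- classify_tss(mk(489L), genes, tss_params())
  expect_equal(leaderless_fraction(eleven, genes), 0.0)
  ten <- classify_tss(mk(490L), genes, tss_params())
  expect_equal(leaderless_fraction(ten, genes), 1.0)

  # fixture: 2 of 20 planted primaries are leaderless
  sim <- simulate_genome(n_genes = 20, mean_gene_len = 100, seed = 17)
  tss <- plant_tss(sim$genes, sim$genome, internal_genes = character(0),
                   leaderless_genes = sim$genes$gene_id[1:2], seed = 17)
  cov <- simulate_coverage(sim$genome,
                           transform(tss, mean_count = mean_replete),
                           noise_rate = 0.5, seed = 17)
  cl <- classify_tss(call_tss(cov$enriched, cov$control), sim$genes,
                     tss_params())
  expect_equal(leaderless_fraction(cl[cl$primary, ], sim$genes), 0.10)
})

test_that("null coverage yields calls at no more than twice the nominal rate", {
  set.seed(99)
  L <- 20000L
  lam <- 5
  enr <- five_prime_coverage(rpois(L, lam), rpois(L, lam))
  ctl <- five_prime_coverage(rpois(L, lam), rpois(L, lam))
  params <- tss_params(p_threshold = 1e-3, noise_threshold = 1,
                       curation_min_diff = 1, normalize = FALSE)
  # count significant candidate positions before merge/curation shape them
  bg_e <- estimate_background(enr)
  bg_c <- estimate_background(ctl)
  n_sig <- 0L; n_cand <- 0L
  for (strand in c("+", "-")) {
    e <- if (strand == "+") enr$plus else enr$minus
    co <- if (strand == "+") ctl$plus else ctl$minus
    cand <- which(e >= 1L)
    pv <- vapply(cand, function(i) skellam_pvalue(
      e[i], co[i], bg_e[[if (strand == "+") "plus" else "minus"]],
      bg_c[[if (strand == "+") "plus" else "minus"]]), numeric(1))
    n_sig <- n_sig + sum(pv < 1e-3)
    n_cand <- n_cand + length(cand)
  }
  expect_lte(n_sig / n_cand, 2 * 1e-3)
})
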