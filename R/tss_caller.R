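#' TSS caller parameters
#'
#' Defaults follow the published dRNA-seq annotation settings: significance
#' threshold 1e-10 on the Skellam test, a noise floor of 4 enriched 5' ends,
#' a merge range of 5 nt, and a curation filter removing calls whose
#' enriched-minus-control count difference is below 100. Classification
#' windows: primary within 250 nt upstream (inclusive), downstream strictly
#' less than 30 nt past the gene end.
#'
#' @param p_threshold Skellam p-value cutoff.
#' @param noise_threshold Minimum enriched 5'-end count at a candidate.
#' @param merge_range Calls on the same strand within this many nt are merged.
#' @param curation_min_diff Minimum enriched-control difference retained.
#' @param primary_window Upstream window (nt) for the primary category.
#' @param downstream_window Downstream window (nt) for the downstream category.
#' @param normalize Scale control counts by total-depth ratio before testing
#'   (set `FALSE` to reproduce raw-count behaviour).
#' @param background_floor Lower bound on estimated background rates.
#' @return A list of class `tss_params`.
#' @export
tss_params <- function(p_threshold = 1e-10, noise_threshold = 4,
                       merge_range = 5, curation_min_diff = 100,
                       primary_window = 250, downstream_window = 30,
                       normalize = TRUE, background_floor = 0.01) {
  stopifnot(p_threshold > 0, p_threshold < 1, noise_threshold > 0,
            merge_range > 0, curation_min_diff > 0, primary_window > 0,
            downstream_window > 0, background_floor > 0)
  structure(list(p_threshold = p_threshold, noise_threshold = noise_threshold,
                 merge_range = merge_range,
                 curation_min_diff = curation_min_diff,
                 primary_window = primary_window,
                 downstream_window = downstream_window,
                 normalize = normalize, background_floor = background_floor),
            class = "tss_params")
}

#' Estimate per-strand background 5'-end rates
#'
#' Robust trimmed mean: positions whose count is at or below the 95th
#' percentile of the nonzero counts are averaged, which keeps TSS spikes out
#' of the background. The result is floored at `floor` (never zero).
#'
#' @param coverage A `five_prime_coverage`.
#' @param trim Percentile (of nonzero counts) above which positions are
#'   excluded from the mean.
#' @param floor Lower bound for the returned rates.
#' @return Named numeric `c(plus = ..., minus = ...)`.
#' @export
estimate_background <- function(coverage, trim = 0.95, floor = 0.01) {
  one <- function(x) {
    nz <- x[x > 0L]
    if (length(nz) == 0L) {
      warning("all-zero strand; background floored at ", floor)
      return(floor)
    }
    q <- stats::quantile(nz, trim, names = FALSE)
    max(mean(x[x <= q]), floor)
  }
  c(plus = one(coverage$plus), minus = one(coverage$minus))
}

skellam_log_pmf <- function(d, rate_e, rate_c) {
  x <- 2 * sqrt(rate_e * rate_c)
  # exponentially scaled Bessel keeps this finite for large rates; at very
  # large order it underflows to 0 (with a precision warning), which is the
  # correct limit here, so the warning is muffled and NaN mapped to -Inf
  bi <- suppressWarnings(besselI(x, abs(d), expon.scaled = TRUE))
  bi[!is.finite(bi) | bi < 0] <- 0
  -(sqrt(rate_e) - sqrt(rate_c))^2 + (d / 2) * log(rate_e / rate_c) + log(bi)
}

#' Upper-tail Skellam probability for a count difference
#'
#' Probability that a Skellam(rate_e, rate_c) variable (difference of two
#' independent Poisson counts) is at least `enriched_count - control_count`.
#' This is the null probability of observing at least the seen excess of
#' enriched over non-enriched 5' ends from background alone. Evaluated by
#' summing the Bessel-function form of the Skellam mass function in log
#' space.
#'
#' @param enriched_count,control_count Observed counts (control may be
#'   depth-scaled, hence non-integer; the difference is ceiled).
#' @param rate_e,rate_c Background rates of the two libraries (> 0).
#' @return Upper-tail probability in \[0, 1\].
#' @export
skellam_pvalue <- function(enriched_count, control_count, rate_e, rate_c) {
  if (!is.finite(rate_e) || !is.finite(rate_c) || rate_e <= 0 || rate_c <= 0) {
    stop("parameter error: rates must be finite and positive")
  }
  k <- ceiling(enriched_count - control_count)
  mu <- rate_e - rate_c
  sd <- sqrt(rate_e + rate_c)
  if (k <= mu - 40 * sd - 40) return(1)
  upper <- max(k, ceiling(mu)) + ceiling(40 * sd) + 200
  d <- k:upper
  p <- sum(exp(skellam_log_pmf(d, rate_e, rate_c)))
  min(max(p, 0), 1)
}

#' Detect TSSs from an enriched / non-enriched library pair
#'
#' Candidate positions are those with at least `noise_threshold` enriched 5'
#' ends; candidates significant under the Skellam test are merged within
#' `merge_range` nt (keeping the highest-count position) and finally
#' filtered by the curation rule (enriched-minus-control difference of at
#' least `curation_min_diff`). Control counts are depth-normalized first
#' unless `params$normalize` is `FALSE`.
#'
#' @param enriched,control `five_prime_coverage` objects over the same genome.
#' @param params A [tss_params()] list.
#' @return data.frame of class `tss_calls` with columns `position` (0-based),
#'   `strand`, `enriched_count`, `control_count` (raw), `control_scaled`,
#'   `p_value`.
#' @export
call_tss <- function(enriched, control, params = tss_params()) {
  if (length(enriched$plus) != length(control$plus)) {
    stop("input error: mismatched coverage lengths")
  }
  sf <- 1
  if (isTRUE(params$normalize)) {
    dc <- library_depth(control)
    if (dc > 0) sf <- library_depth(enriched) / dc
  }
  bg_e <- estimate_background(enriched, floor = params$background_floor)
  bg_c <- estimate_background(control, floor = params$background_floor)
  out <- list()
  for (strand in c("+", "-")) {
    e <- strand_counts(enriched, strand)
    co <- strand_counts(control, strand)
    re <- bg_e[[if (strand == "+") "plus" else "minus"]]
    rc <- bg_c[[if (strand == "+") "plus" else "minus"]] * sf
    cand <- which(e >= params$noise_threshold)
    if (length(cand) == 0L) next
    pv <- vapply(cand, function(i) {
      skellam_pvalue(e[i], co[i] * sf, re, rc)
    }, numeric(1))
    keep <- pv < params$p_threshold
    if (!any(keep)) next
    out[[strand]] <- data.frame(
      position = cand[keep] - 1L, strand = strand,
      enriched_count = e[cand[keep]], control_count = co[cand[keep]],
      control_scaled = co[cand[keep]] * sf, p_value = pv[keep],
      stringsAsFactors = FALSE
    )
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(), strand = character(),
               enriched_count = integer(), control_count = integer(),
               control_scaled = numeric(), p_value = numeric())
  rownames(calls) <- NULL
  calls <- merge_calls(calls, params$merge_range)
  calls <- calls[(calls$enriched_count - calls$control_scaled) >=
                   params$curation_min_diff, , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("tss_calls", "data.frame")
  calls
}

#' Merge nearby TSS calls
#'
#' Same-strand calls chained within `merge_range` nt collapse to the single
#' call with the highest enriched count (ties to the smaller coordinate).
#' Idempotent.
#'
#' @param calls `tss_calls` data.frame.
#' @param merge_range Distance in nt.
#' @return Merged `tss_calls` data.frame.
#' @export
merge_calls <- function(calls, merge_range) {
  if (nrow(calls) <= 1L) return(calls)
  res <- list()
  for (strand in unique(calls$strand)) {
    cs <- calls[calls$strand == strand, , drop = FALSE]
    cs <- cs[order(cs$position), , drop = FALSE]
    gap <- c(Inf, diff(cs$position))
    grp <- cumsum(gap > merge_range)
    for (g in unique(grp)) {
      block <- cs[grp == g, , drop = FALSE]
      best <- which(block$enriched_count == max(block$enriched_count))[1L]
      res[[length(res) + 1L]] <- block[best, , drop = FALSE]
    }
  }
  merged <- do.call(rbind, res)
  merged <- merged[order(merged$strand, merged$position), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Classify TSS calls against gene annotation
#'
#' Each call receives the set of all satisfied positional categories over all
#' genes: `primary` (within `primary_window` nt upstream of a same-strand
#' gene start, inclusive, including distance 0), `internal` (within a
#' same-strand gene body), `antisense` (within an opposite-strand gene body),
#' `downstream` (less than `downstream_window` nt past a same-strand gene
#' end), and `orphan` if and only if no other category holds. A call may
#' carry multiple categories.
#'
#' @param calls `tss_calls` data.frame.
#' @param genes Annotation data.frame.
#' @param params A [tss_params()] list (windows).
#' @return The calls with added logical columns `primary`, `internal`,
#'   `antisense`, `downstream`, `orphan`, list-column `categories`, and
#'   character columns `primary_gene`, `internal_gene`, `antisense_gene`,
#'   `downstream_gene` (comma-joined gene ids, `NA` if none).
#' @export
classify_tss <- function(calls, genes, params = tss_params()) {
  n <- nrow(calls)
  cats <- c("primary", "internal", "antisense", "downstream")
  for (cc in cats) {
    calls[[cc]] <- logical(n)
    calls[[paste0(cc, "_gene")]] <- NA_character_
  }
  five_prime <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  three_end <- ifelse(genes$strand == "+", genes$end, genes$start)
  for (i in seq_len(n)) {
    pos <- calls$position[i]
    str <- calls$strand[i]
    same <- genes$strand == str
    inside <- pos >= genes$start & pos < genes$end
    # strand-aware distance from call to the gene's annotated 5' end (>0 = upstream)
    updist <- ifelse(genes$strand == "+", five_prime - pos, pos - five_prime)
    # strand-aware distance past the gene's 3' end (>=0 = downstream of gene)
    downdist <- ifelse(genes$strand == "+", pos - three_end, three_end - 1L - pos)
    hit <- list(
      primary = same & updist >= 0 & updist <= params$primary_window,
      internal = same & inside,
      antisense = !same & inside,
      downstream = same & downdist >= 0 & downdist < params$downstream_window
    )
    for (cc in cats) {
      if (any(hit[[cc]])) {
        calls[[cc]][i] <- TRUE
        calls[[paste0(cc, "_gene")]][i] <-
          paste(genes$gene_id[hit[[cc]]], collapse = ",")
      }
    }
  }
  calls$orphan <- !(calls$primary | calls$internal | calls$antisense |
                      calls$downstream)
  calls$categories <- lapply(seq_len(n), function(i) {
    out <- c(cats, "orphan")[c(calls$primary[i], calls$internal[i],
                               calls$antisense[i], calls$downstream[i],
                               calls$orphan[i])]
    out
  })
  class(calls) <- c("tss_calls", "data.frame")
  calls
}

#' Census of TSS category combinations
#'
#' Tabulates classified calls by their full category combination (e.g.
#' `"Internal antisense"`), counting each call exactly once.
#'
#' @param calls Classified `tss_calls`.
#' @return Named integer vector of counts per combination label.
#' @export
category_census <- function(calls) {
  if (nrow(calls) == 0L) return(stats::setNames(integer(0), character(0)))
  order_ref <- c("internal", "primary", "antisense", "downstream", "orphan")
  labels <- vapply(calls$categories, function(cs) {
    cs <- order_ref[order_ref %in% cs]
    lab <- paste(cs, collapse = " ")
    paste0(toupper(substr(lab, 1, 1)), substr(lab, 2, nchar(lab)))
  }, character(1))
  tab <- table(labels)
  stats::setNames(as.integer(tab), names(tab))
}

#' Fraction of primary TSSs at leaderless distance
#'
#' Fraction of primary-category calls lying within `window_nt` of the
#' associated gene's translational start (strand-aware distance; a call
#' exactly at the start codon has distance 0). Transcripts this close to the
#' start codon lack a ribosome-binding 5' UTR and are candidates for
#' leaderless (70S monosome) initiation.
#'
#' @param calls Classified `tss_calls`.
#' @param genes Annotation data.frame.
#' @param window_nt Distance window (default 10).
#' @return Fraction, or `NA` if there are no primary calls.
#' @export
leaderless_fraction <- function(calls, genes, window_nt = 10) {
  stopifnot(window_nt >= 0)
  prim <- calls[calls$primary, , drop = FALSE]
  if (nrow(prim) == 0L) return(NA_real_)
  five_prime <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  near <- vapply(seq_len(nrow(prim)), function(i) {
    gids <- strsplit(prim$primary_gene[i], ",", fixed = TRUE)[[1L]]
    idx <- match(gids, genes$gene_id)
    d <- ifelse(genes$strand[idx] == "+",
                five_prime[idx] - prim$position[i],
                prim$position[i] - five_prime[idx])
    min(d) <= window_nt
  }, logical(1))
  mean(near)
}
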