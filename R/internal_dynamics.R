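#' 5'-end read abundance at a TSS
#'
#' Sum of 5'-end counts in the strand-aware downstream-inclusive window
#' `[position, position + window_nt]` (mirrored for the minus strand);
#' `window_nt = 0` gives the single-position count.
#'
#' @param coverage A `five_prime_coverage`.
#' @param position 0-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param window_nt Window length in nt (>= 0).
#' @return Integer count.
#' @export
tss_read_abundance <- function(coverage, position, strand, window_nt = 5) {
  stopifnot(window_nt >= 0)
  L <- length(coverage$plus)
  if (position < 0 || position >= L) stop("position out of range: ", position)
  x <- strand_counts(coverage, strand)
  idx <- if (strand == "+") position:(position + window_nt)
         else (position - window_nt):position
  idx <- idx[idx >= 0 & idx < L]
  sum(x[idx + 1L])
}

#' Internal transcription ratio
#'
#' Read abundance at the internal TSS divided by read abundance at the
#' primary TSS, both taken from the same (enriched) library over the same
#' strand-aware window.
#'
#' @inheritParams tss_read_abundance
#' @param internal_pos,primary_pos 0-based TSS positions.
#' @return Ratio (>= 0), or `NA` with a `"no_primary"` attribute when the
#'   primary abundance is zero (such genes are routed to
#'   [direct_internal_comparison()]).
#' @export
internal_ratio <- function(coverage, internal_pos, primary_pos, strand,
                           window_nt = 5) {
  a_int <- tss_read_abundance(coverage, internal_pos, strand, window_nt)
  a_pri <- tss_read_abundance(coverage, primary_pos, strand, window_nt)
  if (a_pri == 0) {
    out <- NA_real_
    attr(out, "no_primary") <- TRUE
    return(out)
  }
  a_int / a_pri
}

#' Does a ratio pass the internal-transcription filter?
#'
#' The published rule keeps internal TSSs whose transcript abundance exceeds
#' 10% of the primary TSS. `boundary_tol` is a small relative allowance at
#' the cutoff so a gene whose true ratio sits exactly on the threshold is not
#' dropped by counting noise alone; set it to 0 for a literal strict reading.
#'
#' @param ratio Estimated internal:primary ratio.
#' @param min_ratio Cutoff (default 0.10).
#' @param boundary_tol Relative tolerance at the cutoff (default 0.05).
#' @return Logical.
#' @export
passes_ratio_filter <- function(ratio, min_ratio = 0.10, boundary_tol = 0.05) {
  !is.na(ratio) & ratio >= min_ratio * (1 - boundary_tol)
}

#' Compare internal transcription between conditions for one gene
#'
#' Computes the internal transcription ratio in the N-deplete and N-replete
#' enriched libraries, a paired Wilcoxon signed-rank test on per-position
#' normalized counts (each position's count in the +/-`window_nt` window
#' around the internal TSS divided by the total primary-window abundance of
#' that condition, paired by position between conditions), and a three-way
#' direction call: `similar` when the deplete:replete fold change lies in
#' `[1/similar_band, similar_band]`, otherwise `up_in_deplete` /
#' `up_in_replete`. Pairing by position is essential: per-position means
#' vary over orders of magnitude along the saw-tooth, so an unpaired
#' rank-sum comparison would be swamped by positional structure shared by
#' both conditions.
#'
#' @param gene_id Gene identifier carried into the result.
#' @param internal_pos,primary_pos 0-based TSS positions (primary may be `NA`).
#' @param strand `"+"` or `"-"`.
#' @param coverage_deplete,coverage_replete Enriched `five_prime_coverage`
#'   for the two conditions.
#' @param window_nt Abundance window (default 5).
#' @param similar_band Fold-change band treated as "similar" (default 1.2).
#' @return One-row data.frame: `gene_id`, `internal_tss_position`,
#'   `primary_tss_position`, `ratio_replete`, `ratio_deplete`,
#'   `ratio_fold_change`, `wilcoxon_p`, `direction`.
#' @export
compare_conditions <- function(gene_id, internal_pos, primary_pos, strand,
                               coverage_deplete, coverage_replete,
                               window_nt = 5, similar_band = 1.2) {
  r_dep <- internal_ratio(coverage_deplete, internal_pos, primary_pos, strand,
                          window_nt)
  r_rep <- internal_ratio(coverage_replete, internal_pos, primary_pos, strand,
                          window_nt)
  fold <- r_dep / r_rep
  direction <- if (!is.finite(fold)) {
    NA_character_
  } else if (fold >= 1 / similar_band && fold <= similar_band) {
    "similar"
  } else if (fold > similar_band) "up_in_deplete" else "up_in_replete"
  # positional vectors around the internal TSS, normalized by primary abundance
  win_vec <- function(cov) {
    L <- length(cov$plus)
    idx <- (internal_pos - window_nt):(internal_pos + window_nt)
    idx <- idx[idx >= 0 & idx < L]
    strand_counts(cov, strand)[idx + 1L]
  }
  v_dep <- win_vec(coverage_deplete)
  v_rep <- win_vec(coverage_replete)
  a_pri_dep <- tss_read_abundance(coverage_deplete, primary_pos, strand, window_nt)
  a_pri_rep <- tss_read_abundance(coverage_replete, primary_pos, strand, window_nt)
  wp <- NA_real_
  if (sum(v_dep > 0) >= 3 && sum(v_rep > 0) >= 3 &&
      a_pri_dep > 0 && a_pri_rep > 0 && length(v_dep) == length(v_rep)) {
    wp <- tryCatch(
      suppressWarnings(
        stats::wilcox.test(v_dep / a_pri_dep, v_rep / a_pri_rep,
                           paired = TRUE)$p.value
      ),
      error = function(e) NA_real_
    )
  }
  data.frame(gene_id = gene_id, internal_tss_position = internal_pos,
             primary_tss_position = if (is.na(primary_pos)) NA_integer_ else primary_pos,
             ratio_replete = as.numeric(r_rep), ratio_deplete = as.numeric(r_dep),
             ratio_fold_change = as.numeric(fold), wilcoxon_p = wp,
             direction = direction, stringsAsFactors = FALSE)
}

#' Direct internal comparison when no primary TSS exists
#'
#' Depth-normalized fold change of internal-TSS abundance, N-deplete over
#' N-replete. Returns `Inf` when the replete abundance is zero but the
#' deplete abundance is positive, and `NA` when both are zero.
#'
#' @param coverage_deplete,coverage_replete Enriched libraries.
#' @param internal_pos 0-based internal TSS position.
#' @param strand `"+"` or `"-"`.
#' @param window_nt Abundance window.
#' @return Fold change (possibly `Inf` or `NA`).
#' @export
direct_internal_comparison <- function(coverage_deplete, coverage_replete,
                                       internal_pos, strand, window_nt = 5) {
  a_dep <- tss_read_abundance(coverage_deplete, internal_pos, strand, window_nt)
  a_rep <- tss_read_abundance(coverage_replete, internal_pos, strand, window_nt)
  d_dep <- library_depth(coverage_deplete)
  d_rep <- library_depth(coverage_replete)
  n_dep <- if (d_dep > 0) a_dep / d_dep else 0
  n_rep <- if (d_rep > 0) a_rep / d_rep else 0
  if (a_dep == 0 && a_rep == 0) return(NA_real_)
  if (n_rep == 0) return(Inf)
  n_dep / n_rep
}

#' Conservation of TSS calls between time points
#'
#' A 12 h TSS is conserved if a 24 h call exists on the same strand within
#' `merge_range` nt.
#'
#' @param calls_12h,calls_24h `tss_calls` data.frames.
#' @param merge_range Distance in nt (default 5).
#' @return Logical vector aligned with `calls_12h` rows.
#' @export
conservation <- function(calls_12h, calls_24h, merge_range = 5) {
  vapply(seq_len(nrow(calls_12h)), function(i) {
    same <- calls_24h$strand == calls_12h$strand[i]
    any(abs(calls_24h$position[same] - calls_12h$position[i]) <= merge_range)
  }, logical(1))
}

#' Per-gene internal-transcription dynamics table
#'
#' Pairs each internal TSS with its gene's primary TSS (when both were
#' called), applies the internal:primary ratio filter in at least one
#' condition, runs [compare_conditions()] for primary+internal genes and
#' [direct_internal_comparison()] for internal-only genes, and flags 24 h
#' conservation when 24 h calls are supplied.
#'
#' @param classified_dep,classified_rep Classified `tss_calls` from the
#'   deplete and replete 12 h library pairs.
#' @param coverage_deplete,coverage_replete The matching enriched libraries.
#' @param calls_24h Optional classified deplete 24 h calls for conservation.
#' @param window_nt Abundance window.
#' @param min_ratio,boundary_tol Ratio filter (see [passes_ratio_filter()]).
#' @param merge_range Pairing / conservation tolerance in nt.
#' @return data.frame with one row per (gene, internal TSS): the
#'   [compare_conditions()] columns plus `mode`
#'   (`"primary_and_internal"` or `"internal_only"`), `direct_fold_change`,
#'   `conserved_24h`.
#' @export
internal_dynamics_table <- function(classified_dep, classified_rep,
                                    coverage_deplete, coverage_replete,
                                    calls_24h = NULL, window_nt = 5,
                                    min_ratio = 0.10, boundary_tol = 0.05,
                                    merge_range = 5) {
  int_dep <- classified_dep[classified_dep$internal, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(int_dep))) {
    call <- int_dep[i, ]
    gids <- strsplit(call$internal_gene, ",", fixed = TRUE)[[1L]]
    for (gid in gids) {
      # primary TSS for this gene, called in BOTH conditions
      pri_dep <- classified_dep[classified_dep$primary &
        grepl(gid, classified_dep$primary_gene, fixed = TRUE), , drop = FALSE]
      pri_rep <- classified_rep[classified_rep$primary &
        grepl(gid, classified_rep$primary_gene, fixed = TRUE), , drop = FALSE]
      has_primary <- nrow(pri_dep) > 0 && nrow(pri_rep) > 0
      if (has_primary) {
        ppos <- pri_dep$position[which.max(pri_dep$enriched_count)]
        # a leaderless primary TSS sits at the gene start and is also
        # classified internal; it is not an internal site of its own gene
        if (abs(call$position - ppos) <= merge_range) next
        res <- compare_conditions(gid, call$position, ppos, call$strand,
                                  coverage_deplete, coverage_replete,
                                  window_nt = window_nt)
        keep <- passes_ratio_filter(res$ratio_deplete, min_ratio, boundary_tol) |
          passes_ratio_filter(res$ratio_replete, min_ratio, boundary_tol)
        if (!isTRUE(keep)) next
        res$mode <- "primary_and_internal"
        res$direct_fold_change <- NA_real_
      } else {
        fc <- direct_internal_comparison(coverage_deplete, coverage_replete,
                                         call$position, call$strand, window_nt)
        res <- data.frame(
          gene_id = gid, internal_tss_position = call$position,
          primary_tss_position = NA_integer_, ratio_replete = NA_real_,
          ratio_deplete = NA_real_, ratio_fold_change = NA_real_,
          wilcoxon_p = NA_real_,
          direction = if (is.na(fc)) NA_character_
                      else if (fc > 1.2) "up_in_deplete"
                      else if (fc < 1 / 1.2) "up_in_replete" else "similar",
          mode = "internal_only", direct_fold_change = fc,
          stringsAsFactors = FALSE
        )
      }
      res$strand <- call$strand
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) {
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  if (!is.null(calls_24h)) {
    out$conserved_24h <- vapply(seq_len(nrow(out)), function(i) {
      same <- calls_24h$strand == out$strand[i]
      any(abs(calls_24h$position[same] - out$internal_tss_position[i]) <=
            merge_range)
    }, logical(1))
  } else {
    out$conserved_24h <- NA
  }
  rownames(out) <- NULL
  out
}

#' Direction census of an internal-dynamics table
#'
#' @param dynamics Output of [internal_dynamics_table()] (or any data.frame
#'   with a `direction` column).
#' @return Named integer vector over
#'   `c(up_in_deplete, up_in_replete, similar)`.
#' @export
direction_census <- function(dynamics) {
  lev <- c("up_in_deplete", "up_in_replete", "similar")
  tab <- table(factor(dynamics$direction, levels = lev))
  stats::setNames(as.integer(tab), lev)
}
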