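#' Validate a pipeline configuration
#'
#' Reads a YAML configuration, checks every referenced path, parameter range
#' and label, and returns either the validated config or the aggregated
#' error list (not fail-fast).
#'
#' @param path Path to a YAML config file (see the package vignette for the
#'   layout), or an already-parsed list.
#' @return On success, the config list with class `pipeline_config`; on
#'   failure, a character vector of errors with class `config_errors`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  errors <- character(0)
  need <- function(key) {
    if (is.null(cfg[[key]])) errors <<- c(errors, paste0("missing key: ", key))
  }
  need("fasta"); need("gff"); need("coverage"); need("out_dir")
  for (key in c("fasta", "gff")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      errors <- c(errors, paste0(key, ": file not found: ", cfg[[key]]))
    }
  }
  if (!is.null(cfg$coverage)) {
    labs <- names(cfg$coverage)
    if (anyDuplicated(labs)) {
      errors <- c(errors, "coverage: duplicate library labels")
    }
    for (lab in labs) {
      lib <- cfg$coverage[[lab]]
      for (key in c("enriched_plus", "enriched_minus", "control_plus",
                    "control_minus")) {
        if (is.null(lib[[key]])) {
          errors <- c(errors, paste0("coverage.", lab, ": missing ", key))
        } else if (!file.exists(lib[[key]])) {
          errors <- c(errors, paste0("coverage.", lab, ".", key,
                                     ": file not found: ", lib[[key]]))
        }
      }
    }
  }
  p <- cfg$params %||% list()
  chk_range <- function(key, lo, hi) {
    v <- p[[key]]
    if (!is.null(v) && (!is.numeric(v) || v <= lo || v >= hi)) {
      errors <- c(errors, paste0("params.", key, ": out of range (", lo,
                                 ", ", hi, ")"))
    }
    errors
  }
  errors <- chk_range("p_threshold", 0, 1)
  errors <- chk_range("min_ratio", 0, 1)
  if (length(errors)) return(structure(errors, class = "config_errors"))
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "pipeline_config")
}

apply_params <- function(p) {
  p <- p %||% list()
  tss_params(
    p_threshold = p$p_threshold %||% 1e-10,
    noise_threshold = p$noise_threshold %||% 4,
    merge_range = p$merge_range %||% 5,
    curation_min_diff = p$curation_min_diff %||% 100,
    primary_window = p$primary_window %||% 250,
    downstream_window = p$downstream_window %||% 30,
    normalize = p$normalize %||% TRUE
  )
}

write_tsv <- function(df, path) {
  df2 <- df
  df2$categories <- NULL  # list columns do not serialize to TSV
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full N-deprivation transcriptome pipeline
#'
#' Stages: TSS calling per condition/time point, positional classification
#' and category census, internal-transcription dynamics (ratio table and
#' direction census), truncated-isoform nitrogen accounting for qualifying
#' sense internal TSSs, and genome-scale motif statistics. All stage tables
#' are written as TSV under `config$out_dir`, a summary as JSON, plus a
#' manifest carrying the seed and parameters; outputs are a pure function of
#' (inputs, config, seed).
#'
#' @param config A `pipeline_config` from [validate_config()] (or an
#'   equivalent list; it is validated first).
#' @return Invisibly, a list with all stage results (`calls`, `census`,
#'   `dynamics`, `direction_census`, `truncations`, `savings`, `motifs`,
#'   `summary`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (inherits(cfg, "config_errors")) {
    stop("invalid config:\n", paste(cfg, collapse = "\n"))
  }
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  params <- apply_params(cfg$params)
  window_nt <- cfg$params$ratio_window %||% 5
  min_ratio <- cfg$params$min_ratio %||% 0.10

  genome <- load_genome(cfg$fasta)
  genes <- load_annotation(cfg$gff, genome)

  calls <- list()
  enriched_libs <- list()
  for (lab in names(cfg$coverage)) {
    lib <- cfg$coverage[[lab]]
    enriched <- load_coverage(lib$enriched_plus, lib$enriched_minus,
                              genome$length, label = paste0(lab, "_enriched"))
    control <- load_coverage(lib$control_plus, lib$control_minus,
                             genome$length, label = paste0(lab, "_control"))
    enriched_libs[[lab]] <- enriched
    cl <- call_tss(enriched, control, params)
    cl <- classify_tss(cl, genes, params)
    calls[[lab]] <- cl
    write_tsv(cl, file.path(out, paste0("tss_calls_", lab, ".tsv")))
    message("stage call_tss[", lab, "]: ", nrow(cl), " TSS calls")
  }

  census <- lapply(calls, category_census)
  jsonlite::write_json(census, file.path(out, "category_census.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  dep_lab <- cfg$labels$deplete_12h %||% "deplete_12h"
  rep_lab <- cfg$labels$replete_12h %||% "replete_12h"
  dep24_lab <- cfg$labels$deplete_24h %||% "deplete_24h"
  dynamics <- NULL
  dcensus <- NULL
  if (all(c(dep_lab, rep_lab) %in% names(calls))) {
    dynamics <- internal_dynamics_table(
      calls[[dep_lab]], calls[[rep_lab]],
      enriched_libs[[dep_lab]], enriched_libs[[rep_lab]],
      calls_24h = calls[[dep24_lab]], window_nt = window_nt,
      min_ratio = min_ratio, merge_range = params$merge_range
    )
    if (nrow(dynamics)) {
      write_tsv(dynamics, file.path(out, "internal_dynamics.tsv"))
      dcensus <- direction_census(dynamics)
      message("stage internal_dynamics: ", nrow(dynamics), " (gene, TSS) rows; ",
              "up_in_deplete=", dcensus[["up_in_deplete"]],
              " up_in_replete=", dcensus[["up_in_replete"]],
              " similar=", dcensus[["similar"]])
    }
  }

  truncations <- NULL
  savings <- NULL
  if (!is.null(dynamics) && nrow(dynamics)) {
    qual <- dynamics[!is.na(dynamics$direction), , drop = FALSE]
    recs <- list()
    for (i in seq_len(nrow(qual))) {
      gid <- qual$gene_id[i]
      g <- genes[genes$gene_id == gid, , drop = FALSE]
      if (nrow(g) != 1L || !g$is_coding) next
      pos <- qual$internal_tss_position[i]
      if (pos < g$start || pos >= g$end) next
      rec <- tryCatch(
        suppressMessages(truncation_saving(g, genome, pos)),
        error = function(e) NULL
      )
      if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
    }
    if (length(recs)) {
      truncations <- do.call(rbind, recs)
      write_tsv(truncations, file.path(out, "truncation_records.tsv"))
      savings <- aggregate_savings(truncations)
      message("stage truncation_cost: ", nrow(truncations), " isoforms, pooled ",
              round(savings$pooled_pct, 1), "% N saving")
    }
  }

  coding <- genes[genes$is_coding, , drop = FALSE]
  codon_lists <- lapply(seq_len(nrow(coding)), function(i) {
    tryCatch(coding_codons(coding[i, ], genome), error = function(e) NULL)
  })
  codon_lists <- Filter(Negate(is.null), codon_lists)
  # genes with ambiguous bases are excluded from codon statistics
  codon_lists <- Filter(function(cl) !any(grepl("N", cl, fixed = TRUE)),
                        codon_lists)
  pair_stats <- codon_pair_stats(codon_lists)
  bins <- bin_by_affinity(pair_stats)
  nc <- noncoding_regions(genome, genes)
  motifs <- do.call(rbind, lapply(cfg$params$rich_k %||% c(10, 12), function(k) {
    motif_report(nc, genome, k = k,
                 fraction_threshold = cfg$params$rich_fraction %||% 0.8,
                 alphabet_class = "pyrimidine", region_set = "noncoding")
  }))
  ntca <- ntca_scan(genes, genome,
                    motif_pattern = cfg$params$ntca_pattern %||% "GTANNNNNNNNTAC",
                    max_upstream = cfg$params$ntca_max_upstream %||% 100)
  write_tsv(pair_stats, file.path(out, "glygly_pair_stats.tsv"))
  write_tsv(bins, file.path(out, "glygly_affinity_bins.tsv"))
  write_tsv(motifs, file.path(out, "rich_motif_reports.tsv"))
  write_tsv(ntca$hits, file.path(out, "ntca_hits.tsv"))

  leaderless <- if (length(calls)) {
    vapply(calls, function(cl) leaderless_fraction(cl, genes), numeric(1))
  } else NULL

  summary <- list(
    n_tss_calls = vapply(calls, nrow, integer(1)),
    category_census = census,
    direction_census = as.list(dcensus),
    n_dynamics_rows = if (is.null(dynamics)) 0L else nrow(dynamics),
    nitrogen_savings = savings,
    leaderless_fraction = as.list(leaderless),
    glygly_bins = bins,
    rich_motifs = motifs,
    ntca_genes = ntca$n_genes
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ncostmin")),
    seed = cfg$seed,
    params = cfg$params %||% list(),
    inputs = list(fasta = cfg$fasta, gff = cfg$gff),
    libraries = names(cfg$coverage)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(calls = calls, census = census, dynamics = dynamics,
                 direction_census = dcensus, truncations = truncations,
                 savings = savings, glygly = list(pairs = pair_stats, bins = bins),
                 motifs = motifs, ntca = ntca, leaderless = leaderless,
                 summary = summary))
}
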