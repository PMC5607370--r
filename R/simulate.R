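#' Default sense-codon weights
#'
#' Uniform distribution over the 61 sense codons of the bacterial code, with
#' an optional glycine reweighting used to plant anti-Shine-Dalgarno-affine
#' (GGA/GGG) versus neutral (GGT/GGC) glycine codon usage.
#'
#' @param gly_weights Optional named numeric over `c(GGT,GGC,GGA,GGG)` giving
#'   relative weights within glycine (renormalized; total Gly mass preserved).
#' @return Named numeric vector over the 61 sense codons summing to 1.
#' @export
default_codon_weights <- function(gly_weights = NULL) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(codons, stops)
  w <- stats::setNames(rep(1 / length(sense), length(sense)), sense)
  if (!is.null(gly_weights)) {
    gly <- c("GGT", "GGC", "GGA", "GGG")
    stopifnot(all(names(gly_weights) %in% gly))
    gmass <- sum(w[gly])
    gw <- stats::setNames(rep(0, 4), gly)
    gw[names(gly_weights)] <- gly_weights
    w[gly] <- gmass * gw / sum(gw)
  }
  w / sum(w)
}

sample_intergenic <- function(n, pyr_fraction) {
  if (n <= 0L) return("")
  pyr <- stats::runif(n) < pyr_fraction
  out <- character(n)
  out[pyr] <- sample(c("C", "T"), sum(pyr), replace = TRUE)
  out[!pyr] <- sample(c("A", "G"), sum(!pyr), replace = TRUE)
  paste0(out, collapse = "")
}

#' Simulate a bacterial genome with planted features
#'
#' Generates `n_genes` coding genes (ATG start, codons drawn i.i.d. from
#' `codon_weights`, single TAA stop) separated by intergenic spacers with a
#' controlled pyrimidine fraction, optionally planting NtcA promoter boxes
#' (default pattern `GTA` + 8 random bases + `TAC`) within 100 bp upstream of
#' randomly chosen genes. Gene strands alternate so both orientations are
#' exercised.
#'
#' @param n_genes Number of coding genes.
#' @param mean_gene_len Mean CDS length in codons (including start, excluding
#'   stop); actual lengths are drawn uniformly within +/-20%.
#' @param intergenic_len Spacer length between genes (bp).
#' @param codon_weights Named distribution over the 61 sense codons.
#' @param intergenic_pyr_fraction Probability that an intergenic base is C/T.
#' @param ntca_sites Number of genes to receive a planted NtcA box.
#' @param internal_met_frac Length-2 range: each gene gets an in-frame ATG
#'   planted at a fraction of its CDS drawn uniformly from this range,
#'   emulating genes whose internal transcripts begin near a viable internal
#'   start codon (truncated isoforms then lose roughly that fraction of
#'   their residues). `NULL` disables planting.
#' @param seed Integer seed; the whole fixture is reproducible from it.
#' @return List with `genome` (`genome_record`), `genes` (annotation
#'   data.frame) and `truth` (list with `seed`, `params`, `ntca_sites`
#'   data.frame and an empty `tss` slot to be filled by [plant_tss()]).
#' @export
simulate_genome <- function(n_genes = 50, mean_gene_len = 200,
                            intergenic_len = 150,
                            codon_weights = default_codon_weights(),
                            intergenic_pyr_fraction = 0.5,
                            ntca_sites = 0,
                            internal_met_frac = c(0.1, 0.35), seed = 1) {
  stopifnot(intergenic_pyr_fraction >= 0, intergenic_pyr_fraction <= 1,
            abs(sum(codon_weights) - 1) < 1e-8)
  if (ntca_sites > 0 && intergenic_len < 140L) {
    stop("configuration error: intergenic_len too small to host a planted NtcA site")
  }
  if (ntca_sites > n_genes) {
    stop("configuration error: more NtcA sites than genes")
  }
  set.seed(seed)
  sense <- names(codon_weights)
  pieces <- character(0)
  genes <- vector("list", n_genes)
  pos <- 0L
  pieces <- c(pieces, sample_intergenic(intergenic_len, intergenic_pyr_fraction))
  pos <- pos + intergenic_len
  ntca_genes <- if (ntca_sites > 0 && n_genes > 0) {
    sort(sample.int(n_genes, ntca_sites))
  } else integer(0)
  ntca_rec <- list()
  for (i in seq_len(n_genes)) {
    len_codons <- max(10L, round(stats::runif(1, 0.8, 1.2) * mean_gene_len))
    body <- sample(sense, len_codons - 1L, replace = TRUE, prob = codon_weights)
    met_codon <- NA_integer_
    if (!is.null(internal_met_frac)) {
      frac <- stats::runif(1, internal_met_frac[1], internal_met_frac[2])
      met_codon <- min(len_codons - 2L, max(3L, round(frac * len_codons)))
      body[met_codon] <- "ATG"  # codon index met_codon (0-based over the CDS)
    }
    cds <- paste0(c("ATG", body, "TAA"), collapse = "")
    strand <- if (i %% 2L == 1L) "+" else "-"
    gene_seq <- if (strand == "+") cds else revcomp(cds)
    gstart <- pos
    gend <- pos + nchar(cds)
    genes[[i]] <- data.frame(
      gene_id = sprintf("SIM%04d", i), start = gstart, end = gend,
      strand = strand, is_coding = TRUE, internal_met_codon = met_codon,
      stringsAsFactors = FALSE
    )
    pieces <- c(pieces, gene_seq)
    pos <- gend
    # plant an NtcA box in the spacer upstream of selected genes; distance
    # ranges are chosen so two genes flanking one spacer cannot collide
    if (i %in% ntca_genes && strand == "+") {
      site <- paste0("GTA", sample_intergenic(8, 0.5), "TAC")
      dist <- sample(20:60, 1L)
      prev <- pieces[length(pieces) - 1L]
      off <- nchar(prev) - dist  # 0-based offset of motif within the spacer
      substr(prev, off + 1L, off + 14L) <- site
      pieces[length(pieces) - 1L] <- prev
      ntca_rec[[length(ntca_rec) + 1L]] <- data.frame(
        gene_id = sprintf("SIM%04d", i), site_position = gstart - dist,
        distance_to_start = dist, matched_sequence = site,
        stringsAsFactors = FALSE
      )
    }
    pieces <- c(pieces, sample_intergenic(intergenic_len, intergenic_pyr_fraction))
    pos <- pos + intergenic_len
    if (i %in% ntca_genes && strand == "-") {
      # upstream of a minus-strand gene lies to its right; the motif is laid
      # down reverse-complemented in genome (plus-strand) orientation
      site <- paste0("GTA", sample_intergenic(8, 0.5), "TAC")
      dist <- sample(20:60, 1L)  # distance of the motif 5' base to the gene 5' base
      prev <- pieces[length(pieces)]
      off <- dist - 14L  # 0-based offset within the spacer (spacer starts at gend)
      substr(prev, off + 1L, off + 14L) <- revcomp(site)
      pieces[length(pieces)] <- prev
      ntca_rec[[length(ntca_rec) + 1L]] <- data.frame(
        gene_id = sprintf("SIM%04d", i), site_position = gend + off,
        distance_to_start = dist, matched_sequence = site,
        stringsAsFactors = FALSE
      )
    }
  }
  sequence <- paste0(pieces, collapse = "")
  genome <- genome_record(id = "sim_genome", sequence = sequence)
  genes <- if (n_genes > 0) do.call(rbind, genes) else
    data.frame(gene_id = character(), start = integer(), end = integer(),
               strand = character(), is_coding = logical())
  ntca_df <- if (length(ntca_rec)) do.call(rbind, ntca_rec) else
    data.frame(gene_id = character(), site_position = integer(),
               distance_to_start = integer(), matched_sequence = character())
  truth <- list(seed = seed,
                params = list(n_genes = n_genes, mean_gene_len = mean_gene_len,
                              intergenic_len = intergenic_len,
                              intergenic_pyr_fraction = intergenic_pyr_fraction),
                ntca_sites = ntca_df,
                tss = NULL)
  list(genome = genome, genes = genes, truth = truth)
}

#' Plant a transcription-start-site program on simulated genes
#'
#' Builds the ground-truth TSS table used by [simulate_coverage()]. Every
#' selected gene receives a primary TSS a short distance upstream of its
#' start; genes listed in `internal_genes` additionally receive an internal
#' TSS inside the CDS with condition-specific expected counts implementing a
#' planted internal:primary ratio per condition.
#'
#' @param genes Gene annotation data.frame.
#' @param genome A `genome_record` (for boundary clipping).
#' @param primary_mean Expected enriched-library 5'-end count at primary TSSs.
#' @param enrichment_factor Enriched:non-enriched expected count ratio at true
#'   TSSs (>= 1).
#' @param internal_genes Character vector of gene_ids receiving an internal
#'   TSS (default: every other gene).
#' @param ratio_replete,ratio_deplete Named (by gene_id) or scalar planted
#'   internal:primary ratios per condition.
#' @param internal_mean Optional expected internal-TSS count; when given, the
#'   primary mean of that gene is set to `internal_mean / ratio` so the
#'   internal TSS itself has this expected count (ratios preserved).
#' @param primary_offset Range (length-2 integer) of distances upstream of the
#'   gene start where the primary TSS is placed.
#' @param conserved_24h Fraction (or logical vector per internal TSS) of
#'   internal TSSs still active at the 24 h time point.
#' @param leaderless_genes Gene ids whose primary TSS is placed exactly at
#'   the translational start (leaderless transcripts).
#' @param seed Integer seed.
#' @return data.frame (the truth TSS table) with columns `position`,
#'   `strand`, `kind`, `gene_id`, `enrichment_factor`, `mean_replete`,
#'   `mean_deplete`, `conserved_24h`.
#' @export
plant_tss <- function(genes, genome, primary_mean = 1000,
                      enrichment_factor = 10,
                      internal_genes = genes$gene_id[c(FALSE, TRUE)],
                      ratio_replete = 0.2, ratio_deplete = 0.2,
                      internal_mean = NULL,
                      primary_offset = c(20L, 60L),
                      conserved_24h = 1,
                      leaderless_genes = character(0),
                      seed = 1) {
  set.seed(seed + 1L)
  get_ratio <- function(r, gid) {
    if (is.null(names(r))) r[[1L]] else unname(r[[gid]])
  }
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    has_internal <- g$gene_id %in% internal_genes
    rr <- get_ratio(ratio_replete, g$gene_id)
    rd <- get_ratio(ratio_deplete, g$gene_id)
    pmean <- primary_mean
    if (has_internal && !is.null(internal_mean)) {
      pmean <- internal_mean / max(rr, rd)
    }
    d <- if (g$gene_id %in% leaderless_genes) 0L else
      sample(primary_offset[1]:primary_offset[2], 1L)
    ppos <- if (g$strand == "+") g$start - d else g$end - 1L + d
    if (ppos >= 0L && ppos < genome$length) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = ppos, strand = g$strand, kind = "primary",
        gene_id = g$gene_id, enrichment_factor = enrichment_factor,
        mean_replete = pmean, mean_deplete = pmean,
        conserved_24h = TRUE, stringsAsFactors = FALSE
      )
    }
    if (has_internal) {
      glen <- g$end - g$start
      # at the planted in-frame Met when the generator provided one, so the
      # internal transcript starts at a viable truncated-isoform start
      off <- if (!is.null(g$internal_met_codon) && !is.na(g$internal_met_codon))
        3L * g$internal_met_codon else round(glen * 0.4)
      ipos <- if (g$strand == "+") g$start + off else g$end - 1L - off
      rows[[length(rows) + 1L]] <- data.frame(
        position = ipos, strand = g$strand, kind = "internal",
        gene_id = g$gene_id, enrichment_factor = enrichment_factor,
        mean_replete = pmean * rr, mean_deplete = pmean * rd,
        conserved_24h = NA, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(position = integer(), strand = character(),
                      kind = character(), gene_id = character(),
                      enrichment_factor = numeric(), mean_replete = numeric(),
                      mean_deplete = numeric(), conserved_24h = logical()))
  }
  tss <- do.call(rbind, rows)
  is_int <- tss$kind == "internal"
  n_int <- sum(is_int)
  if (length(conserved_24h) == 1L && is.numeric(conserved_24h)) {
    keep <- rep(FALSE, n_int)
    keep[sample.int(n_int, round(conserved_24h * n_int))] <- TRUE
    tss$conserved_24h[is_int] <- keep
  } else {
    tss$conserved_24h[is_int] <- conserved_24h
  }
  rownames(tss) <- NULL
  tss
}

#' Simulate an enriched/non-enriched 5'-end coverage pair
#'
#' Per position, counts are drawn from a Poisson law whose mean is the
#' background `noise_rate` plus, at planted TSS positions, the TSS mean
#' (enriched library) or mean / enrichment_factor (non-enriched). A geometric
#' decay downstream of each TSS (factor `decay` per nt over `decay_len` nt,
#' strand-aware) creates the saw-tooth 5'-end pileup characteristic of dRNA-seq.
#'
#' @param genome A `genome_record` (or integer genome length).
#' @param tss Truth TSS data.frame with columns `position`, `strand`,
#'   `mean_count`, `enrichment_factor`.
#' @param noise_rate Background expected 5'-end count per position.
#' @param decay,decay_len Saw-tooth tail shape parameters.
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @param label Library label prefix.
#' @param condition,timepoint_h Metadata stamped on both libraries.
#' @return List with elements `enriched` and `control`
#'   (`five_prime_coverage` objects).
#' @export
simulate_coverage <- function(genome, tss, noise_rate = 0.5, decay = 0.5,
                              decay_len = 5, seed = 1, label = "sim",
                              condition = NA_character_, timepoint_h = NA_real_) {
  stopifnot(noise_rate >= 0)
  L <- if (inherits(genome, "genome_record")) genome$length else as.integer(genome)
  set.seed(seed)
  mean_arrays <- function(scale_down) {
    mp <- rep(noise_rate, L)
    mm <- rep(noise_rate, L)
    for (i in seq_len(nrow(tss))) {
      mu <- tss$mean_count[i] / (if (scale_down) tss$enrichment_factor[i] else 1)
      if (mu <= 0) next
      offs <- 0:decay_len
      contrib <- mu * decay^offs
      if (tss$strand[i] == "+") {
        idx <- tss$position[i] + offs
      } else {
        idx <- tss$position[i] - offs
      }
      ok <- idx >= 0L & idx < L
      if (tss$strand[i] == "+") {
        mp[idx[ok] + 1L] <- mp[idx[ok] + 1L] + contrib[ok]
      } else {
        mm[idx[ok] + 1L] <- mm[idx[ok] + 1L] + contrib[ok]
      }
    }
    list(plus = mp, minus = mm)
  }
  if (is.null(tss) || nrow(tss) == 0L) {
    me <- list(plus = rep(noise_rate, L), minus = rep(noise_rate, L))
    mc <- me
  } else {
    me <- mean_arrays(FALSE)
    mc <- mean_arrays(TRUE)
  }
  enriched <- five_prime_coverage(
    plus = stats::rpois(L, me$plus), minus = stats::rpois(L, me$minus),
    label = paste0(label, "_enriched"), condition = condition,
    timepoint_h = timepoint_h
  )
  control <- five_prime_coverage(
    plus = stats::rpois(L, mc$plus), minus = stats::rpois(L, mc$minus),
    label = paste0(label, "_control"), condition = condition,
    timepoint_h = timepoint_h
  )
  list(enriched = enriched, control = control)
}

#' Simulate the full two-condition, two-timepoint library set
#'
#' Produces enriched and non-enriched libraries for N-replete and N-deplete
#' conditions at 12 h and 24 h. The truth table's `mean_replete` /
#' `mean_deplete` columns set the 12 h expected counts; at 24 h,
#' internal TSSs with `conserved_24h == FALSE` are silenced (mean 0) while
#' all other TSSs keep their 12 h means.
#'
#' @param genome A `genome_record`.
#' @param tss Truth TSS table from [plant_tss()].
#' @param noise_rate,decay,decay_len See [simulate_coverage()].
#' @param seed Integer seed.
#' @return Named list of library pairs, e.g. `$replete_12h$enriched`;
#'   names are `<condition>_<timepoint>h`.
#' @export
simulate_experiment <- function(genome, tss, noise_rate = 0.5, decay = 0.5,
                                decay_len = 5, seed = 1) {
  libs <- list()
  k <- 0L
  for (cond in c("replete", "deplete")) {
    for (tp in c(12, 24)) {
      t2 <- tss
      t2$mean_count <- t2[[paste0("mean_", cond)]]
      if (tp == 24) {
        off <- t2$kind == "internal" & !t2$conserved_24h
        t2$mean_count[off] <- 0
      }
      k <- k + 1L
      nm <- paste0(cond, "_", tp, "h")
      libs[[nm]] <- simulate_coverage(
        genome, t2, noise_rate = noise_rate, decay = decay,
        decay_len = decay_len, seed = seed + 97L * k, label = nm,
        condition = cond, timepoint_h = tp
      )
    }
  }
  libs
}

#' Write a complete synthetic fixture to disk
#'
#' Writes the genome (FASTA), annotation (GFF3), every coverage library as a
#' bedGraph pair, the truth TSS table (TSV) and a JSON manifest listing all
#' paths and the seed.
#'
#' @param dir Output directory (created if needed).
#' @param genome A `genome_record`.
#' @param genes Annotation data.frame.
#' @param coverages Named list of `five_prime_coverage` objects, or the
#'   nested list from [simulate_experiment()].
#' @param truth Truth list (must carry `seed`; `tss` table written as TSV).
#' @return The manifest (list), invisibly written as `manifest.json`.
#' @export
write_fixture <- function(dir, genome, genes, coverages, truth) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, fasta)
  gff <- file.path(dir, "annotation.gff3")
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$locus_tag <- genes$gene_id
  rtracklayer::export(gr, gff, format = "gff3")
  # flatten nested condition lists into <name>_<enriched|control>
  flat <- list()
  for (nm in names(coverages)) {
    x <- coverages[[nm]]
    if (inherits(x, "five_prime_coverage")) {
      flat[[nm]] <- x
    } else {
      for (sub in names(x)) flat[[paste0(nm, "_", sub)]] <- x[[sub]]
    }
  }
  cov_paths <- list()
  for (nm in names(flat)) {
    cov_paths[[nm]] <- as.list(write_coverage(flat[[nm]], dir, prefix = nm))
  }
  truth_path <- file.path(dir, "truth_tss.tsv")
  if (!is.null(truth$tss)) {
    utils::write.table(truth$tss, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- list(
    seed = truth$seed,
    genome_fasta = fasta, annotation_gff = gff,
    genome_length = genome$length,
    truth_tss = if (!is.null(truth$tss)) truth_path else NULL,
    coverage = cov_paths
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Reload a fixture written by [write_fixture()]
#'
#' @param dir Fixture directory containing `manifest.json`.
#' @return List with `genome`, `genes`, `coverages` (flat named list of
#'   `five_prime_coverage`), `truth_tss` (data.frame or NULL), `manifest`.
#' @export
read_fixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  genome <- load_genome(manifest$genome_fasta)
  genes <- load_annotation(manifest$annotation_gff, genome)
  covs <- list()
  for (nm in names(manifest$coverage)) {
    p <- manifest$coverage[[nm]]
    covs[[nm]] <- load_coverage(p$plus, p$minus, genome$length, label = nm)
  }
  truth_tss <- if (!is.null(manifest$truth_tss)) {
    utils::read.table(manifest$truth_tss, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else NULL
  list(genome = genome, genes = genes, coverages = covs,
       truth_tss = truth_tss, manifest = manifest)
}
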