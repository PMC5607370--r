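#' Nitrogen atoms per amino-acid residue
#'
#' Whole-residue budget in peptide linkage: 1 backbone N per residue plus the
#' side-chain increments Arg +3, Lys +1, His +2, Asn +1, Gln +1, Trp +1.
#'
#' @format Named integer vector over the 20 standard one-letter codes.
#' @export
NITROGEN_PER_RESIDUE <- c(
  A = 1L, R = 4L, N = 2L, D = 1L, C = 1L, E = 1L, Q = 2L, G = 1L, H = 3L,
  I = 1L, L = 1L, K = 2L, M = 1L, F = 1L, P = 1L, S = 1L, T = 1L, W = 2L,
  Y = 1L, V = 1L
)

#' Carbon atoms per amino-acid residue (whole residue)
#' @format Named integer vector over the 20 standard one-letter codes.
#' @export
CARBON_PER_RESIDUE <- c(
  A = 3L, R = 6L, N = 4L, D = 4L, C = 3L, E = 5L, Q = 5L, G = 2L, H = 6L,
  I = 6L, L = 6L, K = 6L, M = 5L, F = 9L, P = 5L, S = 3L, T = 4L, W = 11L,
  Y = 9L, V = 5L
)

#' Nitrogen atoms of a protein (mol N per mol protein)
#'
#' @param protein Amino-acid string over the 20 standard residues.
#' @param side_chain_only Count only side-chain N (subtract the backbone N of
#'   every residue). Default `FALSE`: whole-residue accounting.
#' @return Integer total.
#' @export
nitrogen_atoms <- function(protein, side_chain_only = FALSE) {
  if (nchar(protein) == 0L) return(0L)
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(NITROGEN_PER_RESIDUE))
  if (length(bad)) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  }
  total <- sum(NITROGEN_PER_RESIDUE[aa])
  if (side_chain_only) total <- total - length(aa)
  as.integer(total)
}

#' Carbon atoms of a protein
#' @inheritParams nitrogen_atoms
#' @return Integer total.
#' @export
carbon_atoms <- function(protein) {
  if (nchar(protein) == 0L) return(0L)
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(CARBON_PER_RESIDUE))
  if (length(bad)) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  }
  as.integer(sum(CARBON_PER_RESIDUE[aa]))
}

#' Nitrogen atoms of an RNA segment
#'
#' Base N budgets A=5, G=5, C=3, U=2 (T counted as U for a DNA template).
#'
#' @param seq RNA or DNA string.
#' @return Integer total.
#' @export
rna_nitrogen_atoms <- function(seq) {
  n_per_base <- c(A = 5L, G = 5L, C = 3L, U = 2L, T = 2L)
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- setdiff(b, names(n_per_base))
  if (length(bad)) stop("illegal base(s): ", paste(unique(bad), collapse = ", "))
  as.integer(sum(n_per_base[b]))
}

#' Translate codons with the bacterial genetic code
#'
#' Standard (table 11) translation. The initiator codon is translated as Met
#' also for the GTG/TTG near-cognate starts; the trailing stop codon is
#' excluded. An internal stop raises an error naming the codon index.
#'
#' @param codons Character vector of length-3 codons, ending with a stop.
#' @param initiator Treat codon 0 as the initiator (default `TRUE`).
#' @return Amino-acid string.
#' @export
translate_codons <- function(codons, initiator = TRUE) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(codons[is.na(aa)], collapse = ", "))
  n <- length(aa)
  if (aa[n] != "*") stop("codon list must end with a stop codon")
  aa <- aa[-n]
  if (initiator && length(aa) > 0 && codons[1L] %in% c("ATG", "GTG", "TTG")) {
    aa[1L] <- "M"
  }
  internal_stop <- which(aa == "*")
  if (length(internal_stop)) {
    stop("translation error: internal stop at codon index ",
         internal_stop[1L] - 1L)
  }
  paste0(aa, collapse = "")
}

#' Nearest downstream in-frame methionine
#'
#' Index (0-based, in the annotated reading frame) of the first Met codon
#' whose genomic first base lies at or downstream - in the transcript
#' direction - of the internal TSS. Assumes translation of the truncated
#' isoform initiates at a methionine.
#'
#' @param gene One-row gene data.frame.
#' @param genome A `genome_record`.
#' @param internal_tss_position 0-based TSS position inside the gene body.
#' @return Integer residue index, or `NA` (with a message) when no in-frame
#'   Met exists between the TSS and the stop.
#' @export
nearest_downstream_met <- function(gene, genome, internal_tss_position) {
  if (internal_tss_position < gene$start || internal_tss_position >= gene$end) {
    stop("internal TSS ", internal_tss_position, " outside gene body")
  }
  codons <- coding_codons(gene, genome)
  n_cod <- length(codons)
  idx <- seq_len(n_cod) - 1L
  codon_start <- if (gene$strand == "+") {
    gene$start + 3L * idx
  } else {
    gene$end - 1L - 3L * idx
  }
  at_or_down <- if (gene$strand == "+") {
    codon_start >= internal_tss_position
  } else {
    codon_start <= internal_tss_position
  }
  is_met <- codons == "ATG"
  # exclude the trailing stop from consideration
  is_met[n_cod] <- FALSE
  hit <- which(at_or_down & is_met)
  if (!length(hit)) {
    message("no in-frame Met downstream of TSS ", internal_tss_position,
            " in gene ", gene$gene_id)
    return(NA_integer_)
  }
  hit[1L] - 1L
}

#' Truncated-isoform nitrogen saving for one internal TSS
#'
#' Translates the full-length protein and the isoform starting at the
#' nearest downstream in-frame Met, and accounts whole-residue nitrogen for
#' both. The truncated protein is an exact suffix of the full protein
#' beginning at a Met.
#'
#' @param gene One-row gene data.frame.
#' @param genome A `genome_record`.
#' @param internal_tss 0-based internal TSS position.
#' @param side_chain_only Use side-chain-only N accounting.
#' @return One-row data.frame (`truncation_record`): `gene_id`,
#'   `internal_tss_position`, `start_codon_offset_aa`, `full_protein`,
#'   `truncated_protein`, `n_full`, `n_trunc`, `n_saving`, `pct_saving`,
#'   `rna_n_saving` (N atoms of the removed 5' CDS segment); or `NULL` when
#'   no downstream Met exists.
#' @export
truncation_saving <- function(gene, genome, internal_tss,
                              side_chain_only = FALSE) {
  met_idx <- nearest_downstream_met(gene, genome, internal_tss)
  if (is.na(met_idx)) return(NULL)
  codons <- coding_codons(gene, genome)
  full <- translate_codons(codons)
  trunc_codons <- codons[(met_idx + 1L):length(codons)]
  truncated <- translate_codons(trunc_codons)
  n_full <- nitrogen_atoms(full, side_chain_only)
  n_trunc <- nitrogen_atoms(truncated, side_chain_only)
  removed_nt <- paste0(codons[seq_len(met_idx)], collapse = "")
  data.frame(
    gene_id = gene$gene_id, internal_tss_position = internal_tss,
    start_codon_offset_aa = met_idx,
    full_protein = full, truncated_protein = truncated,
    n_full = n_full, n_trunc = n_trunc, n_saving = n_full - n_trunc,
    pct_saving = 100 * (n_full - n_trunc) / n_full,
    rna_n_saving = if (met_idx > 0) rna_nitrogen_atoms(removed_nt) else 0L,
    stringsAsFactors = FALSE
  )
}

#' Aggregate nitrogen savings over truncation records
#'
#' Reports the total saving, the pooled percent (100 * total saving / total
#' full-length N), the mean of per-record percents, and the per-record
#' percent range. Pooled and mean-of-percents aggregations are both given
#' because an average saving can be stated either way.
#'
#' @param records data.frame of rows from [truncation_saving()].
#' @return List: `n_records`, `total_n_saving`, `pooled_pct`, `mean_pct`,
#'   `pct_range`.
#' @export
aggregate_savings <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("aggregate_savings requires at least one record")
  }
  list(
    n_records = nrow(records),
    total_n_saving = sum(records$n_saving),
    pooled_pct = 100 * sum(records$n_saving) / sum(records$n_full),
    mean_pct = mean(records$pct_saving),
    pct_range = range(records$pct_saving)
  )
}
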