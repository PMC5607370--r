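#' Load a genome from FASTA
#'
#' Reads a (single- or multi-record) FASTA file and returns a validated genome
#' record. In single-replicon mode (the default, suitable for most marine
#' cyanobacteria) only the first record is used. Lowercase bases are
#' normalized to uppercase; the alphabet is restricted to A, C, G, T, N.
#'
#' @param fasta_path Path to a FASTA file.
#' @return An object of class `genome_record`: a list with elements `id`
#'   (record name), `sequence` (uppercase DNA string) and `length` (bp).
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  set <- Biostrings::readDNAStringSet(fasta_path)
  if (length(set) == 0L) {
    stop("FASTA format error: no records in ", fasta_path)
  }
  seq <- toupper(as.character(set[[1L]]))
  genome_record(id = names(set)[1L], sequence = seq)
}

#' Construct a genome record from an in-memory sequence
#'
#' @param id Record identifier.
#' @param sequence DNA string; lowercase accepted and normalized.
#' @return A `genome_record`.
#' @export
genome_record <- function(id, sequence) {
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop("alphabet error: illegal character '",
         substr(sequence, bad, bad), "' at offset ", bad - 1L)
  }
  if (nchar(sequence) == 0L) stop("format error: empty sequence")
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$id, ":", x$length, "bp\n")
  invisible(x)
}

#' Load gene annotation from GFF3
#'
#' Imports gene/CDS features and converts them from the on-disk 1-based
#' inclusive convention to the package's internal 0-based half-open offsets.
#' Features without a strand are dropped with a warning; features outside the
#' genome raise an error.
#'
#' @param gff_path Path to a GFF3 file.
#' @param genome A `genome_record` the coordinates are validated against.
#' @param feature_types GFF `type` values treated as genes (default
#'   `c("gene", "CDS")`; when both are present for a locus the `gene` row wins).
#' @return A data.frame with columns `gene_id`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand` (`+`/`-`), `is_coding`, sorted by
#'   `start`.
#' @export
load_annotation <- function(gff_path, genome, feature_types = c("gene", "CDS")) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      is_coding = logical()))
  }
  id <- as.character(gr$ID)
  if ("locus_tag" %in% names(S4Vectors::mcols(gr))) {
    lt <- as.character(gr$locus_tag)
    id[!is.na(lt)] <- lt[!is.na(lt)]
  }
  id[is.na(id)] <- paste0("feature_", seq_along(gr))[is.na(id)]
  biotype <- S4Vectors::mcols(gr)$gene_biotype %||% rep(NA_character_, length(gr))
  ann <- data.frame(
    gene_id = id,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    is_coding = is.na(biotype) | biotype == "protein_coding",
    stringsAsFactors = FALSE
  )
  # a locus annotated as both gene and CDS is one gene; prefer a single row
  ann <- ann[!duplicated(ann[, c("gene_id", "start", "end", "strand")]), ]
  dup <- duplicated(ann$gene_id)
  if (any(dup)) ann <- ann[!dup, ]
  if (any(ann$strand == "*")) {
    warning("dropping ", sum(ann$strand == "*"), " feature(s) with missing strand")
    ann <- ann[ann$strand != "*", ]
  }
  if (any(ann$start < 0L | ann$start >= ann$end)) {
    stop("coordinate error: feature with start >= end or negative start")
  }
  if (any(ann$end > genome$length)) {
    stop("coordinate error: feature exceeds genome length ", genome$length)
  }
  ann <- ann[order(ann$start, ann$end), ]
  rownames(ann) <- NULL
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Upstream region of a gene
#'
#' Strand-aware interval of up to `length_bp` bases immediately 5' of the
#' gene's annotated start, clipped at the genome boundaries.
#'
#' @param gene One-row data.frame (or list) with `start`, `end`, `strand`.
#' @param length_bp Positive window size in bp.
#' @param genome_length Genome length used for clipping.
#' @return A list with `start`, `end` (0-based half-open) and `strand`.
#' @export
upstream_region <- function(gene, length_bp, genome_length) {
  stopifnot(length_bp > 0)
  if (gene$strand == "+") {
    list(start = max(0L, gene$start - as.integer(length_bp)),
         end = gene$start, strand = "+")
  } else {
    list(start = gene$end,
         end = min(as.integer(genome_length), gene$end + as.integer(length_bp)),
         strand = "-")
  }
}

#' Noncoding (intergenic) regions of a genome
#'
#' Strand-agnostic complement of the union of all annotated gene bodies.
#'
#' @param genome A `genome_record`.
#' @param genes Gene annotation data.frame from [load_annotation()].
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `strand` (`"*"`), sorted and non-overlapping.
#' @export
noncoding_regions <- function(genome, genes) {
  L <- genome$length
  if (nrow(genes) == 0L) {
    return(data.frame(start = 0L, end = L, strand = "*"))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = L)
  data.frame(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps),
             strand = rep("*", length(gaps)), stringsAsFactors = FALSE)
}

#' Extract a genomic subsequence (plus-strand orientation)
#'
#' @param genome A `genome_record`.
#' @param start,end 0-based half-open offsets.
#' @return Character DNA string.
#' @export
genome_slice <- function(genome, start, end) {
  stopifnot(start >= 0, end <= genome$length, start <= end)
  substr(genome$sequence, start + 1L, end)
}

#' Reverse complement of a DNA string
#' @param seq DNA string over A,C,G,T,N.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Codons of a coding gene
#'
#' Splits the coding sequence (reverse-complemented first for minus-strand
#' genes) into in-frame triplets. Codon 0 is the initiator; the trailing stop
#' codon, when annotated, is retained (translation strips it).
#'
#' @param gene One-row gene data.frame; must be coding.
#' @param genome A `genome_record`.
#' @return Character vector of length-3 codons.
#' @export
coding_codons <- function(gene, genome) {
  if (!is.null(gene$is_coding) && !isTRUE(gene$is_coding[[1L]])) {
    stop("coding_codons requires a coding gene")
  }
  s <- genome_slice(genome, gene$start, gene$end)
  if (gene$strand == "-") s <- revcomp(s)
  n <- nchar(s)
  if (n %% 3L != 0L) {
    stop("frame error: CDS length ", n, " not divisible by 3 for gene ",
         gene$gene_id %||% "?")
  }
  substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' GC content of a sequence
#'
#' Fraction (G+C)/(A+C+G+T); ambiguous N bases are excluded from the
#' denominator.
#'
#' @param sequence DNA string.
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  stopifnot(nchar(sequence) > 0)
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  gc <- sum(s %in% c("G", "C"))
  acgt <- sum(s %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}

#' Write genomic intervals as BED
#'
#' @param regions data.frame with `start`, `end` and optional `strand`, `name`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  name <- regions$name %||% paste0("region_", seq_len(nrow(regions)))
  strand <- regions$strand %||% rep(".", nrow(regions))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = rep("genome", nrow(regions)),
                   start = regions$start, end = regions$end,
                   name = name, score = 0L, strand = strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
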