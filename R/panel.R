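# Gene panel: the targeted set of OXPHOS transcripts with genome-compartment,
# complex and isoform annotation, plus codon-effect annotation of variants.

VALID_COMPLEXES <- c("CI", "CII", "CIII", "CIV", "CV", "CYCS")
VALID_GENOMES <- c("nuclear", "mitochondrial")

# Standard nuclear genetic code, codon -> one-letter amino acid ("*" = stop).
STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Vertebrate mitochondrial code: as the standard code except AGA/AGG are stops,
# ATA codes Met and TGA codes Trp. Mitochondrial-encoded subunits must be
# translated with this table, never the standard one.
VERTEBRATE_MITO_CODE <- local({
  code <- STANDARD_CODE
  code[c("AGA", "AGG")] <- "*"
  code[["ATA"]] <- "M"
  code[["TGA"]] <- "W"
  code
})

genetic_code_for <- function(genome) {
  if (identical(genome, "mitochondrial")) VERTEBRATE_MITO_CODE else STANDARD_CODE
}

#' Translate a coding sequence
#'
#' @param cds Nucleotide string over A/C/G/T, length a multiple of 3.
#' @param genome `"nuclear"` (standard code) or `"mitochondrial"`
#'   (vertebrate mitochondrial code).
#' @return Character scalar of one-letter amino acids (`*` for stop).
#' @export
translate_cds <- function(cds, genome = "nuclear") {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3, got ", n)
  }
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- genetic_code_for(genome)[codons]
  if (anyNA(aa)) stop("CDS contains non-ACGT codons: ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  paste(aa, collapse = "")
}

new_gene_panel <- function(df) {
  df <- tibble::as_tibble(df)
  structure(df, class = c("gene_panel", class(df)))
}

validate_panel <- function(df) {
  required <- c("gene_id", "complex_label", "genome", "isoform_group", "cds")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty panel")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id in panel: ", paste(unique(dup), collapse = ", "))
  }
  bad_complex <- setdiff(unique(df$complex_label), VALID_COMPLEXES)
  if (length(bad_complex) > 0) {
    stop("unknown complex label(s): ", paste(bad_complex, collapse = ", "))
  }
  bad_genome <- setdiff(unique(df$genome), VALID_GENOMES)
  if (length(bad_genome) > 0) {
    stop("unknown genome compartment(s): ", paste(bad_genome, collapse = ", "))
  }
  df$cds <- toupper(df$cds)
  bad_len <- nchar(df$cds) == 0L | nchar(df$cds) %% 3L != 0L
  if (any(bad_len)) {
    stop("CDS length not a positive multiple of 3 for gene(s): ",
         paste(df$gene_id[bad_len], collapse = ", "))
  }
  bad_alpha <- grepl("[^ACGT]", df$cds)
  if (any(bad_alpha)) {
    stop("CDS contains non-ACGT characters for gene(s): ",
         paste(df$gene_id[bad_alpha], collapse = ", "))
  }
  df$length <- nchar(df$cds)
  new_gene_panel(df)
}

#' Build a gene panel from in-memory annotation
#'
#' @param df Data frame with columns `gene_id`, `complex_label`
#'   (CI/CII/CIII/CIV/CV/CYCS), `genome` (nuclear/mitochondrial),
#'   `isoform_group` (NA when the gene has no isoform partner) and `cds`.
#' @return A validated `gene_panel` tibble (adds a `length` column).
#' @export
gene_panel <- function(df) {
  validate_panel(df)
}

#' Load a gene panel from FASTA plus annotation TSV
#'
#' The panel arrives as two files: a FASTA of mRNA coding sequences and a
#' 4-column tab-separated annotation (`gene_id`, `complex`, `genome`,
#' `isoform_group`, header row required) keyed by the FASTA record ids.
#' Every FASTA record must be annotated; CDS are uppercased and must have
#' length a positive multiple of 3.
#'
#' @param fasta_path Path to the panel FASTA (wrapped or unwrapped).
#' @param annotation_path Path to the annotation TSV.
#' @return A validated `gene_panel` tibble.
#' @export
load_panel <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty panel: no FASTA records in ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- readr::read_tsv(annotation_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(ann)[names(ann) == "complex"] <- "complex_label"
  unannotated <- setdiff(ids, ann$gene_id)
  if (length(unannotated) > 0) {
    stop("FASTA record(s) missing from annotation: ",
         paste(unannotated, collapse = ", "))
  }
  df <- tibble::tibble(
    gene_id = ids,
    cds = as.character(seqs)
  ) |>
    dplyr::left_join(
      dplyr::select(ann, "gene_id", "complex_label", "genome", "isoform_group"),
      by = "gene_id"
    ) |>
    dplyr::select("gene_id", "complex_label", "genome", "isoform_group", "cds")
  df$isoform_group[df$isoform_group %in% c("", "NA", ".")] <- NA_character_
  validate_panel(df)
}

#' Write a gene panel to FASTA plus annotation TSV
#'
#' @param panel A `gene_panel`.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the panel.
#' @export
write_panel <- function(panel, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(panel$cds)
  names(seqs) <- panel$gene_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- dplyr::select(as.data.frame(panel), "gene_id",
                       complex = "complex_label", "genome", "isoform_group")
  readr::write_tsv(ann, annotation_path, na = "")
  invisible(panel)
}

#' Summarize a gene panel
#'
#' One row per gene (id, complex, genome, CDS length, isoform group) suitable
#' for export, plus compartment totals as attributes.
#'
#' @param panel A `gene_panel`.
#' @return A tibble.
#' @export
panel_summary <- function(panel) {
  tibble::tibble(
    gene_id = panel$gene_id,
    complex = panel$complex_label,
    genome = panel$genome,
    length = nchar(panel$cds),
    isoform_group = panel$isoform_group
  )
}

#' Compartment gene counts
#'
#' @param panel A `gene_panel`.
#' @return Named integer vector with `nuclear`, `mitochondrial` and `total`.
#' @export
compartment_counts <- function(panel) {
  c(
    nuclear = sum(panel$genome == "nuclear"),
    mitochondrial = sum(panel$genome == "mitochondrial"),
    total = nrow(panel)
  )
}

#' Annotate the codon effect of a single-base substitution
#'
#' Coordinates are 1-based on the coding strand of the CDS. The reference
#' base must match the panel sequence (a mismatch signals a coordinate
#' convention bug upstream and is an error). Nuclear genes are translated
#' with the standard genetic code, mitochondrial genes with the vertebrate
#' mitochondrial code.
#'
#' @param panel A `gene_panel`.
#' @param gene_id Gene identifier in the panel.
#' @param position 1-based CDS position of the substitution.
#' @param ref_base,alt_base Single upper-case bases.
#' @return A one-row tibble: `gene_id`, `position`, `codon_index`,
#'   `codon_position` (1-3), `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `synonymous`.
#' @export
codon_effect <- function(panel, gene_id, position, ref_base, alt_base) {
  row <- which(panel$gene_id == gene_id)
  if (length(row) != 1) stop("gene not in panel: ", gene_id)
  cds <- panel$cds[row]
  genome <- panel$genome[row]
  if (position < 1 || position > nchar(cds)) {
    stop("position ", position, " out of range for ", gene_id,
         " (CDS length ", nchar(cds), ")")
  }
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  observed <- substr(cds, position, position)
  if (observed != ref_base) {
    stop("reference mismatch for ", gene_id, " position ", position,
         ": panel has ", observed, ", caller supplied ", ref_base)
  }
  codon_index <- ceiling(position / 3)
  codon_position <- ((position - 1L) %% 3L) + 1L
  start <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, start, start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, codon_position, codon_position) <- alt_base
  code <- genetic_code_for(genome)
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  if (is.na(alt_aa)) stop("alt base must be one of A/C/G/T, got ", alt_base)
  tibble::tibble(
    gene_id = gene_id,
    position = as.integer(position),
    codon_index = as.integer(codon_index),
    codon_position = as.integer(codon_position),
    ref_codon = ref_codon,
    alt_codon = alt_codon,
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    synonymous = ref_aa == alt_aa
  )
}

#' @export
print.gene_panel <- function(x, ...) {
  counts <- compartment_counts(x)
  cat("<gene_panel> ", counts[["total"]], " transcripts (",
      counts[["nuclear"]], " nuclear, ", counts[["mitochondrial"]],
      " mitochondrial)\n", sep = "")
  NextMethod()
}
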