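# Alignment-free quantification: unique k-mer voting assigns reads to panel
# transcripts; assigned reads are placed ungapped by their first unique
# k-mer to build per-site base-count pileups for the variant caller.

kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Build a unique k-mer index over a gene panel
#'
#' Every k-mer occurring in exactly one panel gene maps to that gene
#' (k-mers repeated within a single gene still vote for it but cannot place
#' a read); k-mers shared between two or more genes — typically isoform
#' partners — are recorded as ambiguous and never vote.
#'
#' @param panel A `gene_panel`.
#' @param k Odd k-mer length, 11-63, at most the shortest CDS.
#' @return A `kmer_index` (list: `k`, `genes`, lookup environment,
#'   `n_ambiguous`).
#' @export
build_index <- function(panel, k = 31L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 63L) {
    stop("k must be odd and between 11 and 63, got ", k)
  }
  if (k > min(nchar(panel$cds))) {
    stop("k = ", k, " exceeds the shortest CDS (", min(nchar(panel$cds)), " nt)")
  }
  tabs <- purrr::map(seq_len(nrow(panel)), function(i) {
    km <- kmers_of(panel$cds[i], k)
    tibble::tibble(kmer = km, gene = i, pos = seq_along(km))
  })
  all_km <- dplyr::bind_rows(tabs)
  per_gene <- dplyr::summarise(
    dplyr::group_by(all_km, .data$kmer, .data$gene),
    pos = if (dplyr::n() == 1L) .data$pos[1] else NA_integer_,
    .groups = "drop"
  )
  gene_counts <- dplyr::count(per_gene, .data$kmer)
  ambiguous <- gene_counts$kmer[gene_counts$n > 1L]
  unique_km <- per_gene[!per_gene$kmer %in% ambiguous, ]
  env <- new.env(parent = emptyenv(), size = nrow(unique_km) * 2L)
  for (i in seq_len(nrow(unique_km))) {
    assign(unique_km$kmer[i], c(unique_km$gene[i], unique_km$pos[i]),
           envir = env)
  }
  structure(
    list(k = k, genes = panel$gene_id, map = env,
         n_unique = nrow(unique_km), n_ambiguous = length(ambiguous)),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", ", length(x$genes), " genes, ",
      x$n_unique, " unique k-mers, ", x$n_ambiguous, " ambiguous\n", sep = "")
  invisible(x)
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

lookup_kmers <- function(kmers, index) {
  hits <- mget(kmers, envir = index$map, ifnotfound = list(NULL))
  genes <- vapply(hits, function(h) if (is.null(h)) NA_integer_ else h[1],
                  integer(1))
  pos <- vapply(hits, function(h) if (is.null(h)) NA_integer_ else h[2],
                integer(1))
  list(genes = genes, pos = pos)
}

# One orientation's unique-k-mer hits for a batch of reads: a tibble of
# (read, offset-within-read, gene, indexed position).
orientation_hits <- function(seqs, index) {
  km_list <- lapply(seqs, kmers_of, k = index$k)
  counts <- lengths(km_list)
  if (sum(counts) == 0) {
    return(tibble::tibble(read = integer(), offset = integer(),
                          gene = integer(), pos = integer()))
  }
  kms <- unlist(km_list, use.names = FALSE)
  hit <- lookup_kmers(kms, index)
  keep <- !is.na(hit$genes)
  tibble::tibble(
    read = rep.int(seq_along(seqs), counts)[keep],
    offset = sequence(counts)[keep],
    gene = hit$genes[keep],
    pos = hit$pos[keep]
  )
}

# Majority-vote assignment for a batch of reads. Returns one row per read:
# gene index (NA = unassigned), orientation, CDS start of an ungapped
# placement (NA when no positionally unique k-mer supports one).
vote_reads <- function(reads, index, rc = TRUE) {
  reads <- toupper(reads)
  n <- length(reads)
  out <- tibble::tibble(read = seq_len(n), gene = NA_integer_,
                        orientation = NA_character_, start = NA_integer_)
  if (n == 0) return(out)
  fwd <- orientation_hits(reads, index)
  fwd$orientation <- "fwd"
  hits <- fwd
  rc_seqs <- NULL
  if (rc) {
    rc_seqs <- revcomp(reads)
    bwd <- orientation_hits(rc_seqs, index)
    bwd$orientation <- "rc"
    hits <- dplyr::bind_rows(fwd, bwd)
  }
  if (nrow(hits) == 0) return(out)
  # pick the orientation with more unique-k-mer hits (forward wins ties)
  orient_votes <- dplyr::count(hits, .data$read, .data$orientation)
  orient_votes <- orient_votes[order(orient_votes$read,
                                     -orient_votes$n,
                                     orient_votes$orientation), ]
  chosen <- orient_votes[!duplicated(orient_votes$read), c("read", "orientation")]
  hits <- dplyr::inner_join(hits, chosen, by = c("read", "orientation"))
  votes <- dplyr::count(hits, .data$read, .data$orientation, .data$gene)
  totals <- dplyr::summarise(dplyr::group_by(votes, .data$read),
                             total = sum(.data$n), .groups = "drop")
  votes <- votes[order(votes$read, -votes$n), ]
  top <- votes[!duplicated(votes$read), ]
  top <- dplyr::inner_join(top, totals, by = "read")
  winners <- top[top$n * 2L > top$total, ]
  out$gene[winners$read] <- winners$gene
  out$orientation[winners$read] <- winners$orientation
  # placement: first (smallest read offset) positionally unique k-mer of
  # the winning gene in the chosen orientation
  placeable <- dplyr::inner_join(
    hits[!is.na(hits$pos), ],
    winners[, c("read", "gene")], by = c("read", "gene"))
  if (nrow(placeable) > 0) {
    placeable <- placeable[order(placeable$read, placeable$offset), ]
    first <- placeable[!duplicated(placeable$read), ]
    out$start[first$read] <- first$pos - first$offset + 1L
  }
  attr(out, "rc_seqs") <- rc_seqs
  out
}

#' Assign a read to a panel gene by unique k-mer voting
#'
#' Each k-mer of the read that is unique to one gene casts a vote; the read
#' is assigned to the gene holding a strict majority of votes, in the
#' orientation (forward or reverse-complement) with more unique-k-mer hits.
#' Ties and vote-free reads are unassigned. Non-ACGT characters simply
#' yield non-voting k-mers.
#'
#' @param reads Character vector of read sequences.
#' @param index A `kmer_index`.
#' @param rc Also try the reverse complement (default TRUE).
#' @return Character vector of gene ids, `NA` for unassigned reads.
#' @export
assign_read <- function(reads, index, rc = TRUE) {
  v <- vote_reads(reads, index, rc = rc)
  ifelse(is.na(v$gene), NA_character_, index$genes[v$gene])
}

# Strict 4-line-record FASTQ reader; errors name the offending record.
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ ", path, ": truncated record ",
         length(lines) %/% 4L + 1L)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(character(0))
  heads <- lines[seq(1L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0) {
    stop("malformed FASTQ ", path, ": record ", bad[1],
         " lacks @/+ markers")
  }
  toupper(lines[seq(2L, by = 4L, length.out = n)])
}

#' Count a FASTQ library against a k-mer index
#'
#' @param fastq Path to a FASTQ file.
#' @param index A `kmer_index`.
#' @param library_id Library identifier for the output column (defaults to
#'   the file name without extension).
#' @param rc Match reads in both orientations (default TRUE).
#' @return Tibble `gene_id`, `library_id`, `count` covering every indexed
#'   gene; the number of unassigned reads is attached as attribute
#'   `unassigned` and reported via `message()`.
#' @export
count_library <- function(fastq, index, library_id = NULL, rc = TRUE) {
  library_id <- library_id %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  reads <- read_fastq(fastq)
  assigned <- assign_read(reads, index, rc = rc)
  tab <- table(factor(assigned, levels = index$genes))
  unassigned <- sum(is.na(assigned))
  message("count_library: ", library_id, ": ", length(reads), " reads, ",
          unassigned, " unassigned")
  out <- tibble::tibble(
    gene_id = index$genes,
    library_id = library_id,
    count = as.integer(tab)
  )
  attr(out, "unassigned") <- unassigned
  out
}

#' Quantify a set of FASTQ libraries
#'
#' @param manifest Tibble with `library_id` and `path` columns (as returned
#'   by [simulate_reads()]).
#' @param index A `kmer_index`.
#' @param rc Match reads in both orientations.
#' @return Long count tibble `gene_id`, `library_id`, `count`.
#' @export
quantify_libraries <- function(manifest, index, rc = TRUE) {
  dplyr::bind_rows(purrr::map(seq_len(nrow(manifest)), function(i) {
    count_library(manifest$path[i], index,
                  library_id = manifest$library_id[i], rc = rc)
  }))
}

#' Build per-site base-count pileups from a FASTQ library
#'
#' Assigned reads are placed ungapped on their gene by the first
#' positionally unique k-mer; every aligned base increments the site's
#' base count. Bases falling outside the CDS are dropped silently.
#'
#' @param fastq Path to a FASTQ file.
#' @param panel A `gene_panel`.
#' @param index A `kmer_index` built from the same panel.
#' @param library_id Library identifier (defaults to the file name).
#' @param rc Match reads in both orientations.
#' @return Tibble `gene_id`, `position`, `A`, `C`, `G`, `T`, `library_id`,
#'   one row per covered site.
#' @export
build_pileup <- function(fastq, panel, index, library_id = NULL, rc = TRUE) {
  stopifnot(identical(index$genes, panel$gene_id))
  library_id <- library_id %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  reads <- read_fastq(fastq)
  lens <- nchar(panel$cds)
  empty <- tibble::tibble(gene_id = character(), position = integer(),
                          A = integer(), C = integer(), G = integer(),
                          T = integer(), library_id = character())
  if (length(reads) == 0) return(empty)
  v <- vote_reads(reads, index, rc = rc)
  rc_seqs <- attr(v, "rc_seqs")
  placed <- which(!is.na(v$gene) & !is.na(v$start))
  if (length(placed) == 0) return(empty)
  seqs <- reads[placed]
  if (!is.null(rc_seqs)) {
    use_rc <- v$orientation[placed] == "rc"
    seqs[use_rc] <- rc_seqs[placed][use_rc]
  }
  L <- nchar(seqs)
  gene <- rep.int(v$gene[placed], L)
  pos <- sequence(L) + rep.int(v$start[placed], L) - 1L
  base <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  keep <- pos >= 1L & pos <= lens[gene] & base %in% c("A", "C", "G", "T")
  if (!any(keep)) return(empty)
  tab <- tibble::tibble(gene = gene[keep], position = pos[keep],
                        base = base[keep]) |>
    dplyr::count(.data$gene, .data$position, .data$base) |>
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L)
  for (b in c("A", "C", "G", "T")) {
    if (!b %in% names(tab)) tab[[b]] <- 0L
  }
  tibble::tibble(
    gene_id = panel$gene_id[tab$gene],
    position = tab$position,
    A = tab$A, C = tab$C, G = tab$G, T = tab$T,
    library_id = library_id
  ) |>
    dplyr::arrange(.data$gene_id, .data$position)
}

#' Read/write long count tables
#'
#' Counts are stored on disk in the conventional wide layout (genes as
#' rows, libraries as columns, header row) and used in memory as long
#' tibbles.
#'
#' @param counts Long tibble `gene_id`, `library_id`, `count`.
#' @param path TSV path.
#' @return `write_counts` returns the input invisibly; `read_counts`
#'   returns a long tibble.
#' @export
write_counts <- function(counts, path) {
  wide <- tidyr::pivot_wider(counts, names_from = "library_id",
                             values_from = "count", values_fill = 0L)
  readr::write_tsv(wide, path)
  invisible(counts)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "i"), progress = FALSE)
  tidyr::pivot_longer(wide, -"gene_id", names_to = "library_id",
                      values_to = "count")
}
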