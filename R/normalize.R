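# Per-compartment proportional expression indices: each gene's count
# divided by the summed counts of its genome compartment (nuclear or
# mitochondrial) in that library, times 1,000. Nuclear and mitochondrial
# transcripts are normalized separately because cells carry one diploid
# nucleus but widely varying numbers of mitochondrial genome copies.

#' Compute per-compartment expression indices
#'
#' `index(g, s) = 1000 * count(g, s) / sum of counts of g's compartment in
#' library s`. A library whose entire compartment is zero gets indices of 0
#' for that compartment (with a warning) rather than NaN.
#'
#' @param counts Long tibble `gene_id`, `library_id`, `count`.
#' @param panel A `gene_panel` covering every gene in `counts`.
#' @return Long tibble `gene_id`, `library_id`, `genome`, `count`, `index`.
#' @export
expression_index <- function(counts, panel) {
  unknown <- setdiff(unique(counts$gene_id), panel$gene_id)
  if (length(unknown) > 0) {
    stop("count table contains gene(s) absent from the panel: ",
         paste(unknown, collapse = ", "))
  }
  out <- counts |>
    dplyr::left_join(
      tibble::tibble(gene_id = panel$gene_id, genome = panel$genome),
      by = "gene_id"
    ) |>
    dplyr::group_by(.data$library_id, .data$genome) |>
    dplyr::mutate(compartment_total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(index = ifelse(.data$compartment_total > 0,
                                 1000 * .data$count / .data$compartment_total,
                                 0))
  dead <- dplyr::distinct(
    out[out$compartment_total == 0, ], .data$library_id, .data$genome)
  if (nrow(dead) > 0) {
    warning("all-zero compartment(s): ",
            paste(dead$genome, "in", dead$library_id, collapse = "; "),
            call. = FALSE)
  }
  dplyr::select(out, "gene_id", "library_id", "genome", "count", "index")
}

#' Log-transform expression indices
#'
#' `log2(index + pseudo)` with a pseudocount in index units (default 0.5)
#' to handle zeros; the transform is monotone so orderings are preserved.
#'
#' @param expr Tibble from [expression_index()].
#' @param pseudo Positive pseudocount in index units.
#' @param base Logarithm base (default 2, matching fold-change conventions).
#' @return The input with a `log_index` column added.
#' @export
log_transform <- function(expr, pseudo = 0.5, base = 2) {
  if (!is.numeric(pseudo) || pseudo <= 0) {
    stop("pseudo must be a positive pseudocount, got ", pseudo)
  }
  dplyr::mutate(expr, log_index = log(.data$index + pseudo, base = base))
}

#' Write expression indices to TSV
#'
#' Genes as rows, libraries as columns, with a leading compartment column.
#'
#' @param expr Tibble from [expression_index()] (optionally after
#'   [log_transform()]).
#' @param path Output TSV path.
#' @param value Which column to spread: `"index"` or `"log_index"`.
#' @export
write_expression <- function(expr, path, value = c("index", "log_index")) {
  value <- match.arg(value)
  wide <- expr |>
    dplyr::select("gene_id", "genome", "library_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "library_id", values_from = value)
  readr::write_tsv(wide, path)
  invisible(expr)
}
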