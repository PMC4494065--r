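# Pooled-sample variant / RNA-editing caller. Each site in each library is
# scored as the excess of the highest-count non-reference base fraction over
# a binomial-error estimate, expressed in Wilson confidence-interval
# halfwidth units ("CI units"). Per-population chi-squares aggregate the
# scores across libraries and an F-test on the ratio of two chi-squares
# compares populations.

wilson_halfwidth <- function(p_hat, n, z) {
  (z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
}

#' Score one or many pileup sites in CI units
#'
#' For each site: the putative variant is the highest-count non-reference
#' base (`alt`); the sequencing-error rate is estimated from the smallest
#' strictly positive count among the remaining bases (those that are
#' neither the reference nor the putative variant), floored at one read —
#' `p_hat = max(smallest, 1) / n` — since a finite pileup cannot certify a
#' zero error rate; `p_hat = 0` only when no non-reference base is observed
#' at all. The score is `s = (alt_count/n - p_hat) / halfwidth`, with the
#' Wilson score-interval halfwidth of Binomial(n, p_hat) at the configured
#' z. A site is called when `s` exceeds the threshold (default 1 CI unit).
#'
#' @param pileup Tibble with columns `gene_id`, `position`, `A`, `C`, `G`,
#'   `T` and optionally `library_id`.
#' @param panel A `gene_panel` (source of reference bases).
#' @param ci_z Normal quantile for the confidence interval (default 1.96).
#' @param threshold Call threshold in CI units (default 1).
#' @return The input plus `ref`, `alt`, `n`, `alt_count`, `p_hat`,
#'   `ci_halfwidth`, `score`, `called`, `alt_tie` (TRUE where the top
#'   non-reference count was tied and broken lexicographically).
#' @export
score_site <- function(pileup, panel, ci_z = 1.96, threshold = 1) {
  bases <- c("A", "C", "G", "T")
  counts <- as.matrix(pileup[, bases])
  n <- rowSums(counts)
  if (any(n == 0)) {
    bad <- which(n == 0)[1]
    stop("no coverage at ", pileup$gene_id[bad], ":", pileup$position[bad])
  }
  ref <- reference_base(panel, pileup$gene_id, pileup$position)
  ref_idx <- match(ref, bases)
  nonref <- counts
  nonref[cbind(seq_len(nrow(counts)), ref_idx)] <- -1L
  alt_idx <- max.col(nonref, ties.method = "first")
  alt_count <- counts[cbind(seq_len(nrow(counts)), alt_idx)]
  n_at_max <- rowSums(nonref == alt_count & nonref >= 0)
  alt_tie <- alt_count > 0 & n_at_max > 1
  alt <- bases[alt_idx]
  # error-rate estimate: smallest positive count among the residual bases
  residual <- counts
  residual[cbind(seq_len(nrow(counts)), ref_idx)] <- NA_integer_
  residual[cbind(seq_len(nrow(counts)), alt_idx)] <- NA_integer_
  residual[residual == 0L] <- NA_integer_
  smallest <- suppressWarnings(apply(residual, 1, min, na.rm = TRUE))
  smallest[!is.finite(smallest)] <- 0
  # floor the error estimate at one observed read when any alternate exists
  p_hat <- pmax(smallest, 1) / n
  p_hat[alt_count == 0] <- 0
  hw <- wilson_halfwidth(p_hat, n, ci_z)
  score <- ifelse(hw > 0, (alt_count / n - p_hat) / hw, 0)
  score[alt_count == 0] <- 0
  out <- pileup
  out$ref <- ref
  out$alt <- alt
  out$n <- as.integer(n)
  out$alt_count <- as.integer(alt_count)
  out$p_hat <- p_hat
  out$ci_halfwidth <- hw
  out$score <- score
  out$called <- score > threshold
  out$alt_tie <- alt_tie
  tibble::as_tibble(out)
}

reference_base <- function(panel, gene_id, position) {
  idx <- match(gene_id, panel$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) not in panel: ",
         paste(unique(gene_id[is.na(idx)]), collapse = ", "))
  }
  out_of_range <- position < 1 | position > nchar(panel$cds)[idx]
  if (any(out_of_range)) {
    bad <- which(out_of_range)[1]
    stop("position ", position[bad], " outside the CDS of ", gene_id[bad])
  }
  substr(panel$cds[idx], position, position) |>
    vapply(identity, character(1), USE.NAMES = FALSE)
}

#' Aggregate site scores into a population chi-square
#'
#' The chi-square for one population at one site is the sum of squared CI
#' scores over that population's libraries; the degrees of freedom are the
#' number of contributing libraries.
#'
#' @param scores Numeric vector of CI-unit scores (one per library).
#' @return Named list `chi_sq`, `df`.
#' @export
population_chi_sq <- function(scores) {
  if (length(scores) == 0) stop("no scores supplied")
  list(chi_sq = sum(scores^2), df = length(scores))
}

#' F-test comparing two populations' site chi-squares
#'
#' `F = (chi_sq_a / df_a) / (chi_sq_b / df_b)`, with a two-sided p-value
#' from the F(df_a, df_b) distribution. A zero denominator chi-square gives
#' `F = Inf`, `p = 0`, flagged degenerate.
#'
#' @param a,b Lists with `chi_sq` and `df` (from [population_chi_sq()]).
#' @return Tibble `F`, `p.value`, `degenerate`.
#' @export
population_difference <- function(a, b) {
  if (a$df < 1 || b$df < 1) stop("both populations need df >= 1")
  if (a$chi_sq < 0 || b$chi_sq < 0) stop("chi-squares must be non-negative")
  if (b$chi_sq == 0) {
    return(tibble::tibble(F = Inf, p.value = 0, degenerate = TRUE))
  }
  f <- (a$chi_sq / a$df) / (b$chi_sq / b$df)
  lower <- stats::pf(f, a$df, b$df)
  p <- min(1, 2 * min(lower, 1 - lower))
  tibble::tibble(F = f, p.value = p, degenerate = FALSE)
}

#' Classify a variant's presence pattern across populations
#'
#' A variant is "present" in a population when it is called in at least
#' `min_fraction` of that population's scored libraries — with the default
#' 0 meaning at least one library, since each pooled library already
#' aggregates three fish. A population with no scored libraries is
#' "unknown".
#'
#' @param calls Tibble with `strain` and `called` columns (one row per
#'   scored library at the site).
#' @param min_fraction Minimum called fraction for presence (default 0 =
#'   any single library).
#' @param strains Population order for the output.
#' @return Tibble `strain`, `n_scored`, `n_called`, `presence`.
#' @export
classify_presence <- function(calls, min_fraction = 0, strains = STRAINS) {
  tallies <- calls |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(n_scored = dplyr::n(),
                     n_called = sum(.data$called), .groups = "drop")
  out <- tibble::tibble(strain = strains) |>
    dplyr::left_join(tallies, by = "strain") |>
    dplyr::mutate(
      n_scored = tidyr::replace_na(.data$n_scored, 0L),
      n_called = tidyr::replace_na(.data$n_called, 0L),
      needed = pmax(1L, ceiling(min_fraction * .data$n_scored)),
      presence = dplyr::case_when(
        n_scored == 0 ~ "unknown",
        n_called >= needed ~ "present",
        TRUE ~ "absent"
      )
    ) |>
    dplyr::select("strain", "n_scored", "n_called", "presence")
  out
}

#' Flag A-to-G RNA-editing candidates
#'
#' Adenosine-to-inosine editing is read as G by the sequencer, so an A
#' reference with a G alternate on the coding strand is an editing
#' candidate; the direction matters (G-to-A is not flagged).
#'
#' @param ref,alt Single-base character vectors.
#' @return Logical vector.
#' @export
flag_editing <- function(ref, alt) {
  ref == "A" & alt == "G"
}

#' Scan for fixed differences between two populations
#'
#' Sums pileups within each population and reports sites where the two
#' major alleles differ and each population's major-allele frequency is at
#' least the fixation threshold, at sites covered by both populations.
#'
#' @param pileups Tibble of per-library pileups (`gene_id`, `position`,
#'   `A`, `C`, `G`, `T`, `library_id`).
#' @param design Design tibble mapping `library_id` to `strain`.
#' @param populations The two populations to compare.
#' @param min_coverage Minimum per-population coverage at a compared site.
#' @param fixation Major-allele frequency threshold (default 0.99).
#' @return Tibble `gene_id`, `position`, `major_a`, `freq_a`, `major_b`,
#'   `freq_b` (empty when no fixed difference is found).
#' @export
fixed_difference_scan <- function(pileups, design,
                                  populations = c("desert", "montane"),
                                  min_coverage = 50, fixation = 0.99) {
  stopifnot(length(populations) == 2)
  bases <- c("A", "C", "G", "T")
  pooled <- pileups |>
    dplyr::inner_join(dplyr::select(design, "library_id", "strain"),
                      by = "library_id") |>
    dplyr::filter(.data$strain %in% populations) |>
    dplyr::group_by(.data$gene_id, .data$position, .data$strain) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(bases), sum),
                     .groups = "drop")
  major_of <- function(df) {
    m <- as.matrix(df[, bases])
    idx <- max.col(m, ties.method = "first")
    tibble::tibble(gene_id = df$gene_id, position = df$position,
                   coverage = rowSums(m),
                   major = bases[idx],
                   freq = m[cbind(seq_len(nrow(m)), idx)] / rowSums(m))
  }
  a <- major_of(pooled[pooled$strain == populations[1], ])
  b <- major_of(pooled[pooled$strain == populations[2], ])
  joined <- dplyr::inner_join(a, b, by = c("gene_id", "position"),
                              suffix = c("_a", "_b"))
  joined |>
    dplyr::filter(.data$coverage_a >= min_coverage,
                  .data$coverage_b >= min_coverage,
                  .data$major_a != .data$major_b,
                  .data$freq_a >= fixation, .data$freq_b >= fixation) |>
    dplyr::select("gene_id", "position", "major_a", "freq_a", "major_b",
                  "freq_b")
}

#' Call variants across a set of library pileups
#'
#' Scores every covered site in every library, keeps sites called in at
#' least one library, and for each such site aggregates per-population
#' chi-squares, tests desert vs montane with the chi-square-ratio F-test,
#' classifies the presence pattern across populations, flags A-to-G
#' editing candidates and annotates the codon effect.
#'
#' @param pileups Tibble of per-library pileups.
#' @param panel A `gene_panel`.
#' @param design Design tibble with `library_id` and `strain`.
#' @param ci_z,threshold Score parameters (see [score_site()]).
#' @param min_fraction Presence rule (see [classify_presence()]).
#' @return An `oxphos_variants` object: list with `sites` (one row per
#'   candidate site) and `scores` (all per-library site scores).
#' @export
call_variants <- function(pileups, panel, design, ci_z = 1.96,
                          threshold = 1, min_fraction = 0) {
  scores <- score_site(pileups, panel, ci_z = ci_z, threshold = threshold) |>
    dplyr::inner_join(dplyr::select(design, "library_id", "strain"),
                      by = "library_id")
  candidates <- scores |>
    dplyr::group_by(.data$gene_id, .data$position) |>
    dplyr::filter(any(.data$called)) |>
    dplyr::ungroup()
  if (nrow(candidates) == 0) {
    return(structure(list(
      sites = tibble::tibble(), scores = scores), class = "oxphos_variants"))
  }
  site_keys <- dplyr::distinct(candidates, .data$gene_id, .data$position)
  sites <- purrr::map(seq_len(nrow(site_keys)), function(i) {
    g <- site_keys$gene_id[i]
    p <- site_keys$position[i]
    sc <- candidates[candidates$gene_id == g & candidates$position == p, ]
    # consensus alternate: the most frequent alt among calling libraries;
    # a library calling a different alternate base is a different variant
    # and does not contribute to this site's presence pattern
    called <- sc[sc$called, ]
    alt <- names(sort(table(called$alt), decreasing = TRUE))[1]
    ref <- sc$ref[1]
    pattern_calls <- tibble::tibble(strain = sc$strain,
                                    called = sc$called & sc$alt == alt)
    presence <- classify_presence(pattern_calls, min_fraction = min_fraction)
    chis <- purrr::map(STRAINS, function(s) {
      v <- sc$score[sc$strain == s]
      if (length(v) == 0) list(chi_sq = NA_real_, df = 0L)
      else population_chi_sq(v)
    })
    names(chis) <- STRAINS
    ftest <- if (chis$desert$df >= 1 && chis$montane$df >= 1 &&
                   !is.na(chis$montane$chi_sq)) {
      population_difference(chis$desert, chis$montane)
    } else {
      tibble::tibble(F = NA_real_, p.value = NA_real_, degenerate = NA)
    }
    effect <- codon_effect(panel, g, p, ref, alt)
    tibble::tibble(
      gene_id = g, position = p, ref = ref, alt = alt,
      n_libraries = nrow(sc), n_called = sum(sc$called),
      desert = presence$presence[presence$strain == "desert"],
      montane = presence$presence[presence$strain == "montane"],
      hybrid = presence$presence[presence$strain == "hybrid"],
      chi_sq_desert = chis$desert$chi_sq, df_desert = chis$desert$df,
      chi_sq_montane = chis$montane$chi_sq, df_montane = chis$montane$df,
      chi_sq_hybrid = chis$hybrid$chi_sq, df_hybrid = chis$hybrid$df,
      F_desert_montane = ftest$F, p_desert_montane = ftest$p.value,
      editing_candidate = flag_editing(ref, alt),
      codon_position = effect$codon_position,
      ref_aa = effect$ref_aa, alt_aa = effect$alt_aa,
      synonymous = effect$synonymous
    )
  })
  structure(list(sites = dplyr::bind_rows(sites), scores = scores),
            class = "oxphos_variants")
}

#' @export
print.oxphos_variants <- function(x, ...) {
  cat("<oxphos_variants> ", nrow(x$sites), " candidate site(s), ",
      sum(x$sites$editing_candidate %||% logical(0)),
      " A-to-G editing candidate(s)\n", sep = "")
  invisible(x)
}

#' @rdname tidy.oxphos_de
#' @method tidy oxphos_variants
#' @export
tidy.oxphos_variants <- function(x, ...) x$sites

#' @rdname glance.oxphos_de
#' @method glance oxphos_variants
#' @export
glance.oxphos_variants <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$sites),
    n_editing = if (nrow(x$sites)) sum(x$sites$editing_candidate) else 0L,
    n_nonsynonymous = if (nrow(x$sites)) sum(!x$sites$synonymous) else 0L
  )
}

#' Write variant calls as minimal VCF v4.2
#'
#' Coordinates are transcript space: CHROM is the gene id and POS the
#' 1-based CDS position. INFO carries the per-population chi-squares, the
#' desert/montane F-test, the presence pattern, the editing flag and the
#' codon effect. This is a minimal single-base-substitution writer, not a
#' general-purpose VCF emitter.
#'
#' @param variants An `oxphos_variants` object.
#' @param panel A `gene_panel` (for contig lengths).
#' @param path Output path.
#' @export
write_vcf <- function(variants, panel, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=oxphosseq",
    sprintf("##contig=<ID=%s,length=%d>", panel$gene_id, nchar(panel$cds)),
    "##INFO=<ID=NCALL,Number=1,Type=Integer,Description=\"Libraries calling the site\">",
    "##INFO=<ID=CHI2,Number=3,Type=Float,Description=\"Chi-square desert,montane,hybrid\">",
    "##INFO=<ID=FDM,Number=1,Type=Float,Description=\"F desert vs montane\">",
    "##INFO=<ID=PDM,Number=1,Type=Float,Description=\"Two-sided p for FDM\">",
    "##INFO=<ID=PATTERN,Number=1,Type=String,Description=\"Presence desert/montane/hybrid\">",
    "##INFO=<ID=EDIT,Number=0,Type=Flag,Description=\"A-to-G editing candidate\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Codon effect ref_aa>alt_aa\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  s <- variants$sites
  rows <- character(0)
  if (!is.null(s) && nrow(s) > 0) {
    fmt_num <- function(x) ifelse(is.na(x), ".", formatC(x, digits = 4, format = "g"))
    info <- sprintf(
      "NCALL=%d;CHI2=%s,%s,%s;FDM=%s;PDM=%s;PATTERN=%s/%s/%s;EFFECT=%s>%s%s",
      s$n_called, fmt_num(s$chi_sq_desert), fmt_num(s$chi_sq_montane),
      fmt_num(s$chi_sq_hybrid), fmt_num(s$F_desert_montane),
      fmt_num(s$p_desert_montane), s$desert, s$montane, s$hybrid,
      s$ref_aa, s$alt_aa, ifelse(s$editing_candidate, ";EDIT", "")
    )
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    s$gene_id, s$position, s$ref, s$alt, info)
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read the published SNP table fixture
#'
#' A literal transcription of the nine SNPs reported in desert and montane
#' samples but absent from the F1 hybrids, with the printed bold (potential
#' RNA-editing) and nonsynonymous annotations. Gene ids are normalized to
#' the panel's naming (QCR07 -> QCR7).
#'
#' @param path Path to the TSV (defaults to the copy shipped with the
#'   package).
#' @return Tibble `label`, `gene_id`, `position`, `ref`, `alt`, `bold`,
#'   `nonsynonymous_note`.
#' @export
read_snp_table <- function(path = system.file("extdata", "table1_snps.tsv",
                                              package = "oxphosseq")) {
  readr::read_tsv(path, col_types = "cciccll", progress = FALSE)
}
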