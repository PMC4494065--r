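# Differential expression: per-gene two-way ANOVA on tank means (temperature
# x population), Welch post-hoc contrasts within nested groups,
# Benjamini-Yekutieli FDR across the panel, and signed fold-changes on the
# index scale.

#' Average expression over sampling days
#'
#' Collapses the four sampling days to one value per (gene, strain,
#' temperature, tank): the experimental unit for all downstream tests is
#' the tank, with days treated as repeated measures averaged out. Both the
#' log-scale mean (used for testing) and the index-scale mean (used for
#' fold-changes) are kept. Missing days reduce the divisor with a message;
#' a cell with no libraries at all is an error.
#'
#' @param expr Tibble from [log_transform()] (must carry `log_index`).
#' @param design Design tibble with `library_id`, `strain`, `temperature`,
#'   `tank`, `day`.
#' @return Tibble `gene_id`, `strain`, `temperature`, `tank`, `n_days`,
#'   `mean_log`, `mean_index` (18 rows per gene for the full design).
#' @export
average_over_time <- function(expr, design) {
  cells_present <- dplyr::distinct(design, .data$strain, .data$temperature,
                                   .data$tank)
  full <- tidyr::expand_grid(strain = unique(design$strain),
                             temperature = unique(design$temperature),
                             tank = unique(design$tank))
  missing <- dplyr::anti_join(full, cells_present,
                              by = c("strain", "temperature", "tank"))
  if (nrow(missing) > 0) {
    stop("design has empty (strain, temperature, tank) cell(s): ",
         paste(sprintf("(%s, %d, %d)", missing$strain, missing$temperature,
                       missing$tank), collapse = ", "))
  }
  n_days <- length(unique(design$day))
  out <- expr |>
    dplyr::inner_join(dplyr::select(design, "library_id", "strain",
                                    "temperature", "tank"),
                      by = "library_id") |>
    dplyr::group_by(.data$gene_id, .data$strain, .data$temperature,
                    .data$tank) |>
    dplyr::summarise(n_days = dplyr::n(),
                     mean_log = mean(.data$log_index),
                     mean_index = mean(.data$index), .groups = "drop")
  if (any(out$n_days < n_days)) {
    message("average_over_time: some cells have fewer than ", n_days,
            " days; means use the available days")
  }
  out
}

# Classical balanced fixed-effects two-way decomposition for one gene's 18
# tank means, via least squares (stats::lm/anova). Terms: temperature (1 df),
# population (2 df), interaction (2 df), error (12 df).
anova_one_gene <- function(cell) {
  df <- data.frame(
    y = cell$mean_log,
    temperature = factor(cell$temperature),
    strain = factor(cell$strain)
  )
  fit <- stats::lm(y ~ temperature + strain + temperature:strain, data = df)
  tab <- stats::anova(fit)
  out <- tibble::tibble(
    term = c("temperature", "population", "interaction", "error"),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
  # degenerate: no variation anywhere -> report p = 1 rather than NaN
  degenerate <- sum(tab$`Sum Sq`) < 1e-24
  if (degenerate) {
    out$statistic[1:3] <- 0
    out$p.value[1:3] <- 1
  }
  out$degenerate <- degenerate
  out
}

#' Per-gene two-way ANOVA on tank means
#'
#' Fixed-effects temperature x population ANOVA with interaction, fitted to
#' the 18 tank means of each gene (3 strains x 2 temperatures x 3 tanks).
#' F statistics use the within-cell (tank-to-tank) mean square with 12
#' error df.
#'
#' @param cells Tibble from [average_over_time()].
#' @param genes Genes to fit (default: all in `cells`).
#' @return Tibble with one row per gene and term: `gene_id`, `term`
#'   (temperature/population/interaction/error), `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`, `degenerate`.
#' @export
two_way_anova <- function(cells, genes = unique(cells$gene_id)) {
  dplyr::bind_rows(purrr::map(genes, function(g) {
    cell <- cells[cells$gene_id == g, ]
    if (nrow(cell) != 18) {
      stop("gene ", g, " has ", nrow(cell),
           " cells; a balanced 3x2x3 design (18 tank means) is required")
    }
    dplyr::bind_cols(tibble::tibble(gene_id = g), anova_one_gene(cell))
  }))
}

welch_p <- function(a, b, var_equal = FALSE) {
  if (stats::var(a) + stats::var(b) < 1e-24) {
    return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
  }
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

#' Post-hoc contrasts on tank means
#'
#' Within each strain, a two-sample t-test of the three 15 degC tank means
#' against the three 28 degC tank means; among strains at 15 degC, t-tests
#' for the three strain pairs (desert/montane, desert/hybrid,
#' montane/hybrid). The default is the pooled-variance t (4 df): with only
#' three tanks per group the Welch correction can drop to 2 df, whose heavy
#' tails bound p-values away from panel-wide BY thresholds regardless of
#' effect size. Set `var_equal = FALSE` for Welch. Zero variance in both
#' groups with equal means gives p = 1.
#'
#' @param cells Tibble from [average_over_time()].
#' @param genes Genes to test (default all).
#' @param var_equal Pooled-variance t (default TRUE) or Welch (FALSE).
#' @return Tibble `gene_id`, `contrast`, `family` (`"within_strain"` or
#'   `"among_strain_15"`), `mean_a`, `mean_b` (index scale), `diff_log`,
#'   `p.value`. For within-strain contrasts group a is 28 degC (treatment)
#'   and group b is 15 degC (control).
#' @export
posthoc_contrasts <- function(cells, genes = unique(cells$gene_id),
                              var_equal = TRUE) {
  one_gene <- function(g) {
    cell <- cells[cells$gene_id == g, ]
    rows <- list()
    for (s in unique(cell$strain)) {
      hot <- cell[cell$strain == s & cell$temperature == 28, ]
      cold <- cell[cell$strain == s & cell$temperature == 15, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = g,
        contrast = paste0(s, "_15v28"),
        family = "within_strain",
        mean_a = mean(hot$mean_index),
        mean_b = mean(cold$mean_index),
        diff_log = mean(hot$mean_log) - mean(cold$mean_log),
        p.value = welch_p(hot$mean_log, cold$mean_log, var_equal)
      )
    }
    strains <- intersect(STRAINS, unique(cell$strain))
    if (length(strains) > 1) {
      pairs <- utils::combn(strains, 2, simplify = FALSE)
      for (pr in pairs) {
        a <- cell[cell$strain == pr[1] & cell$temperature == 15, ]
        b <- cell[cell$strain == pr[2] & cell$temperature == 15, ]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = g,
          contrast = paste0(pr[1], "_vs_", pr[2], "_15"),
          family = "among_strain_15",
          mean_a = mean(a$mean_index),
          mean_b = mean(b$mean_index),
          diff_log = mean(a$mean_log) - mean(b$mean_log),
          p.value = welch_p(a$mean_log, b$mean_log, var_equal)
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(purrr::map(genes, one_gene))
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up BY procedure, valid under arbitrary dependence: the adjustment
#' carries the harmonic-sum factor c(m) = sum_{k<=m} 1/k, so BY q-values
#' never fall below Benjamini-Hochberg ones. Implemented via
#' `stats::p.adjust(method = "BY")`.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param alpha Rejection level on the q-value scale (default 0.01).
#' @return Tibble `p.value`, `q.value`, `reject`.
#' @export
by_fdr <- function(pvalues, alpha = 0.01) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  q <- stats::p.adjust(pvalues, method = "BY")
  tibble::tibble(p.value = pvalues, q.value = q, reject = q <= alpha)
}

#' Signed fold-change on the index scale
#'
#' `mean_a / mean_b` when the ratio is at least 1, otherwise the negative
#' reciprocal `-mean_b / mean_a`, so the magnitude is always >= 1 and the
#' sign gives the direction (e.g. -1.3 means a is 1.3-fold lower than b).
#'
#' @param mean_a,mean_b Index-scale means (vectors recycle).
#' @return Signed fold-changes; `NA` where `mean_b` is 0.
#' @export
fold_change <- function(mean_a, mean_b) {
  r <- mean_a / mean_b
  out <- ifelse(r >= 1, r, -1 / r)
  out[mean_b == 0] <- NA_real_
  if (any(mean_b == 0)) {
    warning("fold_change: zero denominator mean(s) reported as NA",
            call. = FALSE)
  }
  out
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "**", p < 0.01 ~ "*", TRUE ~ "")
}

#' Run the differential-expression stage
#'
#' Averages days to tank means, fits the per-gene two-way ANOVA, runs the
#' nested post-hoc contrasts, applies BY-FDR within each contrast family
#' across all genes, and reports signed fold-changes of the normalized
#' indices with direction calls and significance stars (one star p < 0.01,
#' two p < 0.001).
#'
#' @param expr Tibble from [log_transform()].
#' @param design Design tibble.
#' @param panel A `gene_panel`.
#' @param alpha BY-FDR level (default 0.01).
#' @param var_equal Pooled-variance (default) or Welch post-hoc tests.
#' @return An `oxphos_de` object (list with `results`, `anova`, `cells`,
#'   `alpha`); see [tidy.oxphos_de()].
#' @export
run_diffexpr <- function(expr, design, panel, alpha = 0.01,
                         var_equal = TRUE) {
  cells <- average_over_time(expr, design)
  anova_tab <- two_way_anova(cells)
  contrasts <- posthoc_contrasts(cells, var_equal = var_equal)
  results <- contrasts |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(q.value = by_fdr(.data$p.value, alpha)$q.value) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fold_change = fold_change(.data$mean_a, .data$mean_b),
      direction = dplyr::case_when(
        .data$q.value > alpha ~ "ns",
        .data$diff_log > 0 ~ "up",
        TRUE ~ "down"
      ),
      stars = significance_stars(.data$p.value)
    ) |>
    dplyr::left_join(
      tibble::tibble(gene_id = panel$gene_id, complex = panel$complex_label,
                     genome = panel$genome),
      by = "gene_id"
    ) |>
    dplyr::select("gene_id", "complex", "genome", "contrast", "family",
                  "mean_a", "mean_b", "fold_change", "p.value", "q.value",
                  "direction", "stars")
  structure(
    list(results = results, anova = anova_tab, cells = cells, alpha = alpha,
         panel = panel_summary(panel)),
    class = "oxphos_de"
  )
}

#' @export
print.oxphos_de <- function(x, ...) {
  n_sig <- sum(x$results$direction != "ns")
  cat("<oxphos_de> ", length(unique(x$results$gene_id)), " genes, ",
      length(unique(x$results$contrast)), " contrasts, ", n_sig,
      " significant at BY q <= ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Tidy a differential-expression result
#'
#' @param x An `oxphos_de` object.
#' @param ... Unused.
#' @return The per-gene, per-contrast results tibble.
#' @method tidy oxphos_de
#' @export
tidy.oxphos_de <- function(x, ...) x$results

#' One-row summary of a differential-expression result
#'
#' @param x An `oxphos_de` object.
#' @param ... Unused.
#' @return Tibble: numbers of genes, contrasts and rejections, alpha.
#' @method glance oxphos_de
#' @export
glance.oxphos_de <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$results$gene_id)),
    n_contrasts = length(unique(x$results$contrast)),
    n_significant = sum(x$results$direction != "ns"),
    alpha = x$alpha
  )
}

#' Summarize DE calls by complex and genome compartment
#'
#' Counts rejected within-strain (control vs treatment) contrasts per
#' OXPHOS complex and genome compartment for each strain, and appends
#' per-compartment percentage rows (`complex = "pct"`): DE genes as a
#' percentage of the panel's genes in that compartment.
#'
#' @param de An `oxphos_de` object.
#' @param panel A `gene_panel` (gives the denominators).
#' @return Tibble `complex`, `genome`, `desert`, `montane`, `hybrid`.
#' @export
summarize_by_complex <- function(de, panel) {
  within <- de$results[de$results$family == "within_strain" &
                         de$results$direction != "ns", ]
  within$strain <- sub("_15v28$", "", within$contrast)
  grid <- tidyr::expand_grid(
    complex = VALID_COMPLEXES,
    genome = VALID_GENOMES,
    strain = STRAINS
  ) |>
    dplyr::semi_join(
      dplyr::distinct(tibble::tibble(complex = panel$complex_label,
                                     genome = panel$genome)),
      by = c("complex", "genome")
    )
  counts <- within |>
    dplyr::count(.data$complex, .data$genome, .data$strain, name = "n_de") |>
    dplyr::right_join(grid, by = c("complex", "genome", "strain")) |>
    dplyr::mutate(n_de = tidyr::replace_na(.data$n_de, 0L)) |>
    tidyr::pivot_wider(names_from = "strain", values_from = "n_de")
  totals <- compartment_counts(panel)
  pct <- within |>
    dplyr::count(.data$genome, .data$strain, name = "n_de") |>
    dplyr::right_join(tidyr::expand_grid(genome = VALID_GENOMES,
                                         strain = STRAINS),
                      by = c("genome", "strain")) |>
    dplyr::mutate(
      n_de = tidyr::replace_na(.data$n_de, 0L),
      pct = 100 * .data$n_de / unname(totals[.data$genome])
    ) |>
    dplyr::select("genome", "strain", "pct") |>
    tidyr::pivot_wider(names_from = "strain", values_from = "pct") |>
    dplyr::mutate(complex = "pct", .before = 1)
  out <- dplyr::bind_rows(counts, pct)
  dplyr::select(out, "complex", "genome", dplyr::all_of(STRAINS))
}
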