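# CI-unit site scoring, population chi-squares and F-tests, presence
# patterns, editing flags, fixed-difference scan, and the published SNP
# table worked example.

site_row <- function(panel, gene, pos, a, c, g, t, lib = "L1") {
  tibble::tibble(gene_id = gene, position = pos, A = a, C = c, G = g, T = t,
                 library_id = lib)
}

test_that("site scores follow the Wilson CI-unit definition", {
  panel <- tiny_panel()  # NUC1 position 1 has reference base G
  # monomorphic site: no alternate observed, score 0
  mono <- score_site(site_row(panel, "NUC1", 1, 0, 0, 100, 0), panel)
  expect_equal(mono$ref, "G")
  expect_equal(mono$alt_count, 0L)
  expect_equal(mono$score, 0)
  expect_false(mono$called)

  # heterozygous-like site: far outside any CI
  het <- score_site(site_row(panel, "NUC1", 1, 50, 0, 50, 0), panel)
  expect_equal(het$alt, "A")
  expect_gt(het$score, 5)
  expect_true(het$called)

  # the worked example (ref 96, alt 3, residual 1 at n = 100) against the
  # independent Wilson oracle; position 4 of NUC2 has reference G
  ex <- score_site(site_row(panel, "NUC2", 4, 3, 1, 96, 0), panel)
  expect_equal(ex$ref, "G")
  expect_equal(ex$alt, "A")
  want <- oracle_wilson_score(alt_count = 3, n = 100, smallest_other = 1)
  expect_equal(ex$p_hat, want$p_hat)
  expect_equal(ex$ci_halfwidth, want$halfwidth, tolerance = 1e-12)
  expect_equal(ex$score, want$score, tolerance = 1e-12)
  expect_equal(ex$called, want$score > 1)

  expect_error(score_site(site_row(panel, "NUC1", 1, 0, 0, 0, 0), panel),
               "no coverage")
})

test_that("scores are non-decreasing in the alternate fraction at fixed coverage", {
  panel <- tiny_panel()
  n <- 200
  scores <- vapply(0:60, function(alt) {
    score_site(site_row(panel, "NUC1", 1, alt, 1, n - alt - 1, 0), panel)$score
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("population chi-squares aggregate squared scores with library df", {
  expect_equal(population_chi_sq(c(0, 0, 0)), list(chi_sq = 0, df = 3L))
  expect_equal(population_chi_sq(c(1, 2, 2)), list(chi_sq = 9, df = 3L))
  expect_error(population_chi_sq(numeric(0)), "no scores")

  # planted-variant pileups dominate error-only pileups stochastically
  panel <- tiny_panel()
  set.seed(55)
  null_chi <- replicate(40, {
    pu <- simulate_pileup_sites(1, 100, ref = "G", alt = "A", af = 0,
                                gene = "NUC2", positions = 4L)
    population_chi_sq(score_site(pu, panel)$score)$chi_sq
  })
  var_chi <- replicate(40, {
    pu <- simulate_pileup_sites(1, 100, ref = "G", alt = "A", af = 0.3,
                                gene = "NUC2", positions = 4L)
    population_chi_sq(score_site(pu, panel)$score)$chi_sq
  })
  expect_gt(stats::median(var_chi), stats::median(null_chi))
  expect_gt(mean(var_chi > stats::quantile(null_chi, 0.95)), 0.9)
})

test_that("the chi-square ratio F-test matches the F distribution and its symmetries", {
  eq <- population_difference(list(chi_sq = 6, df = 3), list(chi_sq = 6, df = 3))
  expect_equal(eq$F, 1)
  expect_equal(eq$p.value, 1)

  ab <- population_difference(list(chi_sq = 9, df = 3), list(chi_sq = 3, df = 3))
  expect_equal(ab$F, 3)
  expect_equal(ab$p.value, 2 * (1 - stats::pf(3, 3, 3)), tolerance = 1e-12)

  ba <- population_difference(list(chi_sq = 3, df = 3), list(chi_sq = 9, df = 3))
  expect_equal(ba$F, 1 / 3)
  expect_equal(ba$p.value, ab$p.value, tolerance = 1e-12)

  deg <- population_difference(list(chi_sq = 5, df = 3), list(chi_sq = 0, df = 3))
  expect_true(is.infinite(deg$F) && deg$p.value == 0 && deg$degenerate)
  expect_error(population_difference(list(chi_sq = 1, df = 0),
                                     list(chi_sq = 1, df = 3)), "df")
})

test_that("presence patterns honour the per-population call rule", {
  calls <- tibble::tibble(
    strain = rep(c("desert", "montane", "hybrid"), each = 4),
    called = c(rep(TRUE, 4), rep(TRUE, 4), rep(FALSE, 4))
  )
  pat <- classify_presence(calls)
  expect_equal(pat$presence, c("present", "present", "absent"))

  none <- calls; none$called <- FALSE
  expect_equal(classify_presence(none)$presence, rep("absent", 3))

  missing_pop <- calls[calls$strain != "hybrid", ]
  expect_equal(classify_presence(missing_pop)$presence,
               c("present", "present", "unknown"))

  # a stricter fraction rule
  sparse <- calls
  sparse$called <- c(TRUE, rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(classify_presence(sparse, min_fraction = 0.5)$presence,
               c("absent", "present", "absent"))
})

test_that("editing flags mark coding-strand A-to-G only", {
  expect_true(flag_editing("A", "G"))
  expect_false(flag_editing("C", "T"))
  expect_false(flag_editing("G", "A"))
  expect_equal(flag_editing(c("A", "A"), c("G", "T")), c(TRUE, FALSE))
})

test_that("fixed differences are reported only when both populations are near-monomorphic", {
  design <- make_design()
  mk <- function(lib, a, g) tibble::tibble(
    gene_id = "NUC1", position = 1L, A = a, C = 0L, G = g, T = 0L,
    library_id = lib)
  # identical pileups -> nothing
  pu_same <- dplyr::bind_rows(mk("desert_15_t1_d01", 100L, 0L),
                              mk("montane_15_t1_d01", 100L, 0L))
  expect_equal(nrow(fixed_difference_scan(pu_same, design)), 0L)
  # planted fixed difference -> exactly that site
  pu_fixed <- dplyr::bind_rows(mk("desert_15_t1_d01", 100L, 0L),
                               mk("montane_15_t1_d01", 0L, 100L))
  hit <- fixed_difference_scan(pu_fixed, design)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$major_a, "A"); expect_equal(hit$major_b, "G")
  # a shared 50% polymorphism is not fixed
  pu_poly <- dplyr::bind_rows(mk("desert_15_t1_d01", 50L, 50L),
                              mk("montane_15_t1_d01", 50L, 50L))
  expect_equal(nrow(fixed_difference_scan(pu_poly, design)), 0L)
  # below the coverage floor nothing is compared
  pu_thin <- dplyr::bind_rows(mk("desert_15_t1_d01", 10L, 0L),
                              mk("montane_15_t1_d01", 0L, 10L))
  expect_equal(nrow(fixed_difference_scan(pu_thin, design)), 0L)
})

test_that("the published SNP table yields 7 mitochondrial entries, 5 editing candidates and 1 non-third-position variant", {
  snps <- read_snp_table()
  panel <- simulate_panel(seed = 1)
  expect_equal(nrow(snps), 9L)

  genome <- stats::setNames(panel$genome, panel$gene_id)
  expect_equal(sum(genome[snps$gene_id] == "mitochondrial"), 7L)

  editing <- flag_editing(snps$ref, snps$alt)
  expect_equal(sum(editing), 5L)
  expect_equal(editing, snps$bold)  # the printed bold rows are the A>G rows

  effects <- dplyr::bind_rows(lapply(seq_len(nrow(snps)), function(i) {
    codon_effect(panel, snps$gene_id[i], snps$position[i], snps$ref[i],
                 snps$alt[i])
  }))
  expect_equal(sum(effects$codon_position != 3L), 1L)
  qcr7 <- effects[effects$gene_id == "QCR7", ]
  expect_false(qcr7$synonymous)
  expect_equal(paste0(qcr7$ref_aa, ">", qcr7$alt_aa), "G>E")
})

test_that("call_variants recovers planted presence patterns and writes valid minimal VCF", {
  panel <- simulate_panel(seed = 1)
  keep <- c("MTCO2", "QCR7", "ATP5O", "CYCS")
  sub <- gene_panel(as.data.frame(panel[panel$gene_id %in% keep, ])[, 1:5])
  design <- make_design()[make_design()$day == 1, ]
  ref_cycs <- substr(sub$cds[sub$gene_id == "CYCS"], 10, 10)
  set.seed(88)
  pus <- dplyr::bind_rows(lapply(seq_len(nrow(design)), function(i) {
    strain <- design$strain[i]
    af_snp <- if (strain %in% c("desert", "montane")) 0.5 else 0
    dplyr::bind_rows(
      simulate_pileup_sites(1, 150, ref = "C", alt = "T", af = af_snp,
                            gene = "MTCO2", positions = 624L,
                            library_id = design$library_id[i]),
      simulate_pileup_sites(1, 150, ref = "A", alt = "G", af = 0.3,
                            gene = "ATP5O", positions = 537L,
                            library_id = design$library_id[i]),
      simulate_pileup_sites(1, 150, ref = ref_cycs, alt = "G", af = 0,
                            gene = "CYCS", positions = 10L,
                            library_id = design$library_id[i])
    )
  }))
  cv <- call_variants(pus, sub, design)
  sites <- tidy(cv)
  snp <- sites[sites$gene_id == "MTCO2", ]
  expect_equal(c(snp$desert, snp$montane, snp$hybrid),
               c("present", "present", "absent"))
  expect_false(snp$editing_candidate)
  edit <- sites[sites$gene_id == "ATP5O", ]
  expect_equal(c(edit$desert, edit$montane, edit$hybrid), rep("present", 3))
  expect_true(edit$editing_candidate)
  # the error-only site is at most sporadically called, never a pattern
  cycs <- sites[sites$gene_id == "CYCS", ]
  expect_true(nrow(cycs) == 0 || cycs$n_called <= 1)
  expect_gt(snp$F_desert_montane, 0)

  g <- glance(cv)
  expect_equal(g$n_sites, nrow(sites))
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(cv, sub, vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(sites))
  expect_true(all(grepl("PATTERN=", body)))
  expect_s3_class(autoplot(cv), "ggplot")
})
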