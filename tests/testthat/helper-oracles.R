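# Fixture builders and independent oracles used across the suite. Oracles
# deliberately avoid the package's own code paths.

# -- tiny hand-written panel -------------------------------------------------

tiny_panel <- function() {
  gene_panel(data.frame(
    gene_id = c("NUC1", "NUC2", "MITO1"),
    complex_label = c("CI", "CIII", "CIV"),
    genome = c("nuclear", "nuclear", "mitochondrial"),
    isoform_group = NA_character_,
    cds = c(
      paste(rep("GCTAAACCC", 20), collapse = ""),      # 180 nt
      paste(rep("TTTGGACAT", 20), collapse = ""),      # 180 nt
      paste(rep("ATACCAGGG", 20), collapse = "")       # 180 nt
    )
  ))
}

# random sense panel of n genes with given lengths (multiples of 3)
random_panel <- function(n, len = 300, seed = 42) {
  set.seed(seed)
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  cds <- vapply(seq_len(n), function(i) {
    paste(sample(codons, len / 3, replace = TRUE), collapse = "")
  }, character(1))
  gene_panel(data.frame(
    gene_id = sprintf("G%02d", seq_len(n)),
    complex_label = "CI",
    genome = rep(c("nuclear", "mitochondrial"), length.out = n),
    isoform_group = NA_character_,
    cds = cds
  ))
}

# -- translation oracle (Biostrings' genetic-code tables) ---------------------

oracle_translate <- function(cds, genome) {
  code <- Biostrings::getGeneticCode(if (genome == "mitochondrial") "2" else "1")
  n <- nchar(cds)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  unname(code[codons])
}

# -- Benjamini-Yekutieli step-up, evaluated from the published formula --------

oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m * cm / seq_len(m))
  # step-up: enforce monotonicity from the largest rank down
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# -- balanced two-way ANOVA by explicit mean decomposition --------------------

oracle_anova <- function(cell) {
  y <- cell$mean_log
  grand <- mean(y)
  temps <- unique(cell$temperature)
  strains <- unique(cell$strain)
  r <- length(unique(cell$tank))
  ss_temp <- sum(vapply(temps, function(t) {
    length(strains) * r * (mean(y[cell$temperature == t]) - grand)^2
  }, numeric(1)))
  ss_pop <- sum(vapply(strains, function(s) {
    length(temps) * r * (mean(y[cell$strain == s]) - grand)^2
  }, numeric(1)))
  ss_cells <- 0
  ss_err <- 0
  for (t in temps) for (s in strains) {
    sel <- cell$temperature == t & cell$strain == s
    cm <- mean(y[sel])
    ss_cells <- ss_cells + r * (cm - grand)^2
    ss_err <- ss_err + sum((y[sel] - cm)^2)
  }
  ss_int <- ss_cells - ss_temp - ss_pop
  df <- c(1, 2, 2, 12)
  ss <- c(ss_temp, ss_pop, ss_int, ss_err)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  data.frame(term = c("temperature", "population", "interaction", "error"),
             df = df, sumsq = ss, meansq = ms, statistic = f, p.value = p)
}

# -- Wilson interval oracle: full lower/upper bounds --------------------------

oracle_wilson_score <- function(alt_count, n, smallest_other, z = 1.96) {
  p_hat <- max(smallest_other, if (alt_count > 0) 1 else 0) / n
  centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
  hw <- (z / (1 + z^2 / n)) * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))
  s <- if (alt_count == 0 || hw == 0) 0 else (alt_count / n - p_hat) / hw
  list(p_hat = p_hat, halfwidth = hw, score = s,
       lower = centre - hw, upper = centre + hw)
}

# -- brute-force k-mer ambiguity count ---------------------------------------

oracle_ambiguous_kmers <- function(cds_vec, k) {
  per_gene <- lapply(cds_vec, function(s) {
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  tab <- table(unlist(per_gene))
  names(tab)[tab > 1]
}

# -- exhaustive Hamming best-match read assignment ----------------------------

oracle_best_match <- function(read, cds_vec) {
  L <- nchar(read)
  best <- vapply(cds_vec, function(s) {
    n <- nchar(s)
    if (n < L) return(Inf)
    starts <- 1:(n - L + 1)
    min(vapply(starts, function(st) {
      sum(utf8ToInt(substr(s, st, st + L - 1)) != utf8ToInt(read))
    }, numeric(1)))
  }, numeric(1))
  names(best) <- names(cds_vec)
  best
}

# -- direct multinomial pileup simulator -------------------------------------

simulate_pileup_sites <- function(n_sites, coverage, ref = "A", alt = "G",
                                  af = 0, error_rate = 0.01,
                                  library_id = "lib1", gene = "G01",
                                  positions = seq_len(n_sites)) {
  bases <- c("A", "C", "G", "T")
  ref_i <- match(ref, bases); alt_i <- match(alt, bases)
  probs <- rep(error_rate / 3, 4)
  probs[alt_i] <- af + (if (alt_i != ref_i) error_rate / 3 else 0)
  probs[ref_i] <- 1 - sum(probs[-ref_i])
  m <- t(stats::rmultinom(n_sites, coverage, probs))
  tibble::tibble(gene_id = gene, position = positions,
                 A = m[, 1], C = m[, 2], G = m[, 3], T = m[, 4],
                 library_id = library_id)
}

write_fastq_records <- function(path, seqs, ids = sprintf("@r%d", seq_along(seqs))) {
  writeLines(rbind(ids, seqs, "+", strrep("I", nchar(seqs))), path)
}
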