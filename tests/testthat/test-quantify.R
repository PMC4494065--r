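# Unique k-mer index, read assignment, counting, and pileups.

make_shared_block_panel <- function(block_len = 200, k_context = 120) {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  block <- paste(sample(bases, block_len, replace = TRUE), collapse = "")
  flank <- function() paste(sample(bases, k_context, replace = TRUE), collapse = "")
  len_pad <- function(s) substr(s, 1, 3 * (nchar(s) %/% 3))
  gene_panel(data.frame(
    gene_id = c("ISO1", "ISO2"),
    complex_label = "CIV",
    genome = "nuclear",
    isoform_group = "ISO",
    cds = c(len_pad(paste0(flank(), block, flank())),
            len_pad(paste0(flank(), block, flank())))
  ))
}

test_that("k-mers inside a shared block are ambiguous, and exactly match brute-force enumeration", {
  panel <- make_shared_block_panel()
  idx <- build_index(panel, 31)
  oracle <- oracle_ambiguous_kmers(panel$cds, 31)
  expect_equal(idx$n_ambiguous, length(oracle))
  # every k-mer fully inside the shared 200-nt block is ambiguous
  block_start <- 121
  inside <- substring(panel$cds[1], block_start:(block_start + 200 - 31),
                      (block_start + 30):(block_start + 199))
  expect_true(all(inside %in% oracle))

  single <- gene_panel(data.frame(
    gene_id = "ONE", complex_label = "CI", genome = "nuclear",
    isoform_group = NA, cds = random_panel(1, len = 300)$cds
  ))
  idx1 <- build_index(single, 31)
  expect_equal(idx1$n_ambiguous, 0L)
  expect_equal(idx1$n_unique, 300 - 31 + 1)

  expect_error(build_index(panel, 32), "odd")
  short <- random_panel(1, len = 60, seed = 3)
  expect_error(build_index(short, 63), "shortest CDS")
})

test_that("isoform-pair ambiguity matches direct enumeration on the synthetic panel", {
  panel <- simulate_panel(seed = 2)
  pair <- panel[panel$gene_id %in% c("COX6B1", "COX6B2"), ]
  idx <- build_index(gene_panel(as.data.frame(pair)[, 1:5]), 31)
  oracle <- oracle_ambiguous_kmers(pair$cds, 31)
  expect_equal(idx$n_ambiguous, length(oracle))
  expect_gt(idx$n_ambiguous, 0)
})

test_that("reads are assigned by strict-majority unique-k-mer voting", {
  panel <- random_panel(5, len = 300, seed = 17)
  idx <- build_index(panel, 31)

  # exact substring -> its gene
  read <- substr(panel$cds[3], 41, 140)
  expect_equal(assign_read(read, idx), "G03")
  # reverse-complement matching
  rcread <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  expect_equal(assign_read(rcread, idx), "G03")
  expect_true(is.na(assign_read(rcread, idx, rc = FALSE)))

  # read entirely within an isoform-shared block -> zero unique votes
  shared <- make_shared_block_panel()
  sidx <- build_index(shared, 31)
  block_read <- substr(shared$cds[1], 131, 230)  # inside the shared block
  expect_true(is.na(assign_read(block_read, sidx)))

  # one sequencing error: still assigned, agreeing with a Hamming-scan oracle
  set.seed(7)
  for (i in 1:20) {
    g <- sample(5, 1)
    st <- sample(200, 1)
    r <- substr(panel$cds[g], st, st + 99)
    p <- sample(100, 1)
    substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
    ham <- oracle_best_match(r, stats::setNames(panel$cds, panel$gene_id))
    expect_equal(assign_read(r, idx), names(which.min(ham)))
  }
})

test_that("count_library recovers noiseless libraries exactly and is read-order invariant", {
  panel <- random_panel(6, len = 300, seed = 23)
  design <- make_design()[c(1, 30, 60), ]
  cfg <- sim_config(seed = 12, reads_per_library = 400, error_rate = 0,
                    read_length = 80L)
  sim <- simulate_reads(panel, design, cfg, tempfile())
  idx <- build_index(panel, 31)
  for (i in seq_len(nrow(sim$manifest))) {
    col <- suppressMessages(count_library(sim$manifest$path[i], idx,
                                          sim$manifest$library_id[i]))
    truth <- sim$origins[sim$origins$library_id == sim$manifest$library_id[i], ]
    got <- stats::setNames(col$count, col$gene_id)[truth$gene_id]
    expect_equal(unname(got), as.integer(truth$n_reads))
    expect_equal(sum(col$count) + attr(col, "unassigned"),
                 sim$manifest$n_reads[i])
  }
  # shuffling records leaves counts unchanged
  lines <- readLines(sim$manifest$path[1])
  rec <- matrix(lines, nrow = 4)
  set.seed(1); rec <- rec[, sample(ncol(rec))]
  shuf <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rec), shuf)
  a <- suppressMessages(count_library(sim$manifest$path[1], idx, "a"))
  b <- suppressMessages(count_library(shuf, idx, "b"))
  expect_equal(a$count, b$count)
})

test_that("count_library handles empty, foreign and malformed FASTQ inputs", {
  panel <- random_panel(3, len = 300, seed = 29)
  idx <- build_index(panel, 31)

  empty <- tempfile(fileext = ".fastq"); writeLines(character(0), empty)
  col <- suppressMessages(count_library(empty, idx, "empty"))
  expect_true(all(col$count == 0))

  # reads from a gene not in the panel are all unassigned
  foreign <- random_panel(1, len = 300, seed = 999)
  reads <- substring(foreign$cds, 1:50, 100:149)
  fq <- tempfile(fileext = ".fastq")
  write_fastq_records(fq, reads)
  col2 <- suppressMessages(count_library(fq, idx, "foreign"))
  expect_true(all(col2$count == 0))
  expect_equal(attr(col2, "unassigned"), 50L)

  truncated <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), truncated)
  expect_error(count_library(truncated, idx), "record 2")
  badmark <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), badmark)
  expect_error(count_library(badmark, idx), "record 2")
})

test_that("pileups concentrate on the reference and match assigned-read coverage exactly when noiseless", {
  panel <- random_panel(4, len = 240, seed = 37)
  design <- make_design()[1:2, ]
  cfg <- sim_config(seed = 6, reads_per_library = 300, error_rate = 0,
                    read_length = 60L)
  sim <- simulate_reads(panel, design, cfg, tempfile())
  idx <- build_index(panel, 31)
  pu <- suppressMessages(build_pileup(sim$manifest$path[1], panel, idx))
  # each covered site carries only the panel reference base
  for (g in unique(pu$gene_id)) {
    rows <- pu[pu$gene_id == g, ]
    cds <- panel$cds[panel$gene_id == g]
    refs <- substring(cds, rows$position, rows$position)
    off_ref <- vapply(seq_len(nrow(rows)), function(i) {
      tot <- rows$A[i] + rows$C[i] + rows$G[i] + rows$T[i]
      tot - rows[[refs[i]]][i]
    }, numeric(1))
    expect_true(all(off_ref == 0))
  }
  # total aligned bases = assigned reads x read length (all placements interior)
  col <- suppressMessages(count_library(sim$manifest$path[1], idx))
  expect_equal(sum(pu$A + pu$C + pu$G + pu$T), sum(col$count) * 60)
})

test_that("read placements overhanging the CDS end are clipped without error", {
  panel <- random_panel(2, len = 240, seed = 41)
  idx <- build_index(panel, 31)
  # 80 nt of real 3' sequence followed by 20 nt of junk: placement starts at
  # 161 and the final 20 aligned positions fall beyond the CDS
  tail80 <- substr(panel$cds[1], 161, 240)
  junk <- strrep("A", 20)
  fq <- tempfile(fileext = ".fastq")
  write_fastq_records(fq, paste0(tail80, junk))
  pu <- suppressMessages(build_pileup(fq, panel, idx))
  expect_equal(max(pu$position), 240)
  expect_equal(nrow(pu), 80L)
  expect_true(all(pu$gene_id == "G01"))
})

test_that("count tables round-trip through the wide TSV layout", {
  counts <- tibble::tibble(
    gene_id = rep(c("A1", "B2"), each = 3),
    library_id = rep(c("l1", "l2", "l3"), 2),
    count = c(5L, 0L, 2L, 1L, 9L, 4L)
  )
  path <- tempfile(fileext = ".tsv")
  write_counts(counts, path)
  back <- read_counts(path)
  expect_equal(dplyr::arrange(back, gene_id, library_id),
               dplyr::arrange(counts, gene_id, library_id))
})
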