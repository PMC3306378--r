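test_that("per-line genotype rule honors the >5% and two-read thresholds", {
  expect_equal(call_line_genotype(c(10, 0, 0, 0))$allele, "A")
  # C fails both rules: 1 < 2 reads and 1/20 = 5% is not > 5%
  expect_equal(call_line_genotype(c(19, 1, 0, 0))$allele, "A")
  # C passes (2 >= 2 and 2/32 = 6.25% > 5%): two alleles pass -> missing
  res <- call_line_genotype(c(30, 2, 0, 0))
  expect_true(is.na(res$allele))
  expect_equal(res$passing_alleles, "A,C")
  # zero coverage is missing, not an error
  expect_true(is.na(call_line_genotype(c(0, 0, 0, 0))$allele))
  expect_error(call_line_genotype(c(-1, 0, 0, 0)), "nonnegative")
})

test_that("genotype rule matches brute force exhaustively and at random", {
  # exhaustive over the full grid of count vectors with each count <= 12
  grid <- as.matrix(expand.grid(0:12, 0:12, 0:12, 0:12))
  got <- call_line_genotype(grid)$allele
  want <- apply(grid, 1, oracle_line_call)
  expect_identical(got, unname(want))

  # random vectors with larger totals, up to 40 reads
  withr::with_seed(42, {
    rnd <- t(replicate(500, {
      d <- sample(0:40, 1)
      tabulate(sample(1:4, d, replace = TRUE), 4)
    }))
  })
  expect_identical(call_line_genotype(rnd)$allele,
                   unname(apply(rnd, 1, oracle_line_call)))
})

test_that("allele confirmation requires two supporting lines", {
  expect_equal(confirm_alleles(c("A", "A", "C", "C")), c("A", "C"))
  expect_equal(confirm_alleles(c("A", "A", "A", "C")), "A")
  expect_equal(confirm_alleles(rep(NA_character_, 4)), character(0))
})

test_that("discover_snps emits confirmed multi-allele loci only", {
  bc <- tibble::tibble(
    line_id = paste0("L", 1:4), chrom = "chr1", pos = 100,
    count_A = c(10, 10, 0, 0), count_C = c(0, 0, 10, 10),
    count_G = 0, count_T = 0
  )
  gm <- discover_snps(bc)
  expect_equal(nrow(gm), 1)
  expect_equal(gm$confirmed_alleles, "A,C")
  expect_equal(unlist(gm[1, paste0("L", 1:4)], use.names = FALSE),
               c("A", "A", "C", "C"))

  # monomorphic panel: no locus
  mono <- bc
  mono$count_C <- 0
  mono$count_A <- 10
  expect_equal(nrow(discover_snps(mono)), 0)

  # single-line alternative allele is not confirmed: no locus
  single <- bc
  single$count_C <- c(0, 0, 0, 10)
  single$count_A <- c(10, 10, 10, 0)
  expect_equal(nrow(discover_snps(single)), 0)
})

test_that("discover_snps equals exhaustive rule application on random tables", {
  withr::with_seed(7, {
    for (rep in 1:30) {
      n_lines <- sample(3:6, 1)
      lines <- paste0("L", seq_len(n_lines))
      bc <- random_basecount_table(n_lines, n_pos = sample(10:50, 1))
      gm <- discover_snps(bc, lines = lines)
      want <- oracle_discover(as.data.frame(bc), lines)
      if (is.null(want)) {
        expect_equal(nrow(gm), 0)
      } else {
        expect_equal(nrow(gm), nrow(want))
        expect_equal(gm$pos, want$pos)
        expect_equal(gm$confirmed_alleles, want$confirmed_alleles)
        for (l in lines) {
          expect_identical(gm[[l]], want[[l]])
        }
      }
    }
  })
})

test_that("every emitted locus has at least four lines with data", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      bc <- random_basecount_table(6, n_pos = 30)
      gm <- discover_snps(bc)
      if (nrow(gm) > 0) {
        m <- as.matrix(tibble::as_tibble(gm)[, attr(gm, "lines")])
        expect_true(all(rowSums(!is.na(m)) >= 4))
      }
    }
  })
})

test_that("calls are monotone in supporting reads and lines", {
  withr::with_seed(99, {
    for (rep in 1:200) {
      counts <- tabulate(sample(1:4, sample(0:30, 1), replace = TRUE), 4)
      call <- call_line_genotype(counts)$allele
      if (!is.na(call)) {
        # adding reads of the passing allele never changes the call
        more <- counts
        k <- match(call, c("A", "C", "G", "T"))
        more[k] <- more[k] + sample(1:10, 1)
        expect_identical(call_line_genotype(more)$allele, call)
      }
    }
  })

  # adding a second line carrying an already-confirmed allele keeps the locus
  bc <- tibble::tibble(
    line_id = paste0("L", 1:4), chrom = "chr1", pos = 1,
    count_A = c(10, 10, 0, 0), count_C = c(0, 0, 10, 10),
    count_G = 0, count_T = 0
  )
  bc5 <- dplyr::bind_rows(bc, tibble::tibble(
    line_id = "L5", chrom = "chr1", pos = 1,
    count_A = 10, count_C = 0, count_G = 0, count_T = 0
  ))
  expect_equal(nrow(discover_snps(bc5)), 1)
})

test_that("per-gene SNP counts use exon containment and length normalisation", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 1L, end = 1400L, strand = "+",
    exons = list(tibble::tibble(start = c(1L, 1001L), end = c(500L, 1500L))),
    exonic_length = 1000
  )
  # 5 exonic SNPs + 1 intronic (pos 700)
  gm <- tibble::tibble(chrom = "chr1",
                       pos = c(10, 20, 30, 1100, 1200, 700),
                       confirmed_alleles = "A,C")
  attr(gm, "lines") <- character()
  stats <- snp_gene_stats(gm, genes)
  expect_equal(stats$snp_count, 5)
  expect_equal(stats$snps_per_100bp, 0.5)
  expect_equal(attr(stats, "n_unassigned"), 1)

  # brute-force interval containment on random placements
  withr::with_seed(5, {
    genes2 <- simulate_population(sim_config(
      n_lines = 4, group_sizes = c(SSS = 2, NSS = 2), n_genes = 20,
      n_snps = 50, n_invariant_sites = 10, n_novel_transcripts = 5,
      n_background_transcripts = 5, seed = 2
    ))$genes
    pos <- sample(1:max(genes2$end), 300)
    gm2 <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                          pos = pos, confirmed_alleles = "A,C")
    attr(gm2, "lines") <- character()
    stats2 <- snp_gene_stats(gm2, genes2)
    brute <- vapply(seq_len(nrow(genes2)), function(i) {
      ex <- genes2$exons[[i]]
      hits <- 0
      for (r in seq_len(nrow(gm2))) {
        if (gm2$chrom[r] == genes2$chrom[i] &&
            any(gm2$pos[r] >= ex$start & gm2$pos[r] <= ex$end)) hits <- hits + 1
      }
      hits
    }, numeric(1))
    expect_equal(stats2$snp_count, brute)
  })
})

test_that("window density bins SNPs by position and genes by midpoint", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(1L, 1500000L), end = c(2000L, 1501000L), strand = "+",
    exons = list(tibble::tibble(start = 1L, end = 2000L),
                 tibble::tibble(start = 1500000L, end = 1501000L)),
    exonic_length = c(2000, 1001)
  )
  gm <- tibble::tibble(chrom = "chr1", pos = c(1, 5, 1200000),
                       confirmed_alleles = "A,C")
  attr(gm, "lines") <- character()
  # g1 expressed in 4 lines, g2 in only 3 -> g2 not counted as expressed
  fpkm <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g1", line_id = paste0("L", 1:4),
                   fpkm = 10, conf_lo = 1, conf_hi = 20),
    tibble::tibble(gene_id = "g2", line_id = paste0("L", 1:4),
                   fpkm = 10, conf_lo = c(1, 1, 1, 0), conf_hi = 20)
  )
  wd <- window_density(gm, genes, fpkm, window = 1e6)
  w1 <- wd[wd$window_start == 1, ]
  w2 <- wd[wd$window_start == 1e6 + 1, ]
  expect_equal(w1$n_snps, 2)       # positions 1 and 5
  expect_equal(w1$n_genes, 1)      # g1 midpoint 1000
  expect_equal(w1$n_expressed_genes, 1)
  expect_equal(w2$n_snps, 1)       # position 1.2e6
  expect_equal(w2$n_genes, 1)      # g2 midpoint 1.5005e6
  expect_equal(w2$n_expressed_genes, 0)

  # random data against brute-force binning
  withr::with_seed(13, {
    pos <- sample(1:5e6, 200)
    gmr <- tibble::tibble(chrom = "chr1", pos = pos, confirmed_alleles = "A,C")
    attr(gmr, "lines") <- character()
    wdr <- window_density(gmr, genes, fpkm, window = 1e6)
    for (k in 0:4) {
      want <- sum(pos >= k * 1e6 + 1 & pos <= (k + 1) * 1e6)
      got <- wdr$n_snps[wdr$window_start == k * 1e6 + 1]
      expect_equal(if (length(got) == 0) 0 else got, want)
    }
  })
})

test_that("per-line coverage statistics count loci and genes with coverage", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(1L, 1000L), end = c(500L, 1500L), strand = "+",
    exons = list(tibble::tibble(start = 1L, end = 500L),
                 tibble::tibble(start = 1000L, end = 1500L)),
    exonic_length = c(500, 501)
  )
  bc <- tibble::tibble(
    line_id = c("L1", "L1", "L2"), chrom = "chr1", pos = c(100, 1100, 100),
    count_A = c(5, 5, 5), count_C = 0, count_G = 0, count_T = 0
  )
  gm <- tibble::tibble(chrom = "chr1", pos = c(100, 1100),
                       confirmed_alleles = "A,C")
  attr(gm, "lines") <- c("L1", "L2", "L3")
  cov <- per_line_coverage_stats(bc, gm, genes)
  expect_equal(cov$pct_snps_covered, c(100, 50, 0))
  expect_equal(cov$pct_genes_covered, c(100, 50, 0))
})
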