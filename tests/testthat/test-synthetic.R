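small_cfg <- function(...) {
  defaults <- list(
    n_lines = 6, group_sizes = c(SSS = 3, NSS = 3), n_genes = 20,
    n_snps = 100, n_invariant_sites = 100,
    n_novel_transcripts = 20, n_background_transcripts = 20, seed = 101
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(sim_config, defaults)
}

test_that("the simulator is deterministic given config and seed", {
  cfg <- small_cfg()
  t1 <- simulate_population(cfg)
  t2 <- simulate_population(cfg)
  expect_identical(t1$snps, t2$snps)
  expect_identical(t1$expression, t2$expression)
  expect_identical(t1$novel_presence, t2$novel_presence)
  expect_identical(simulate_basecounts(t1), simulate_basecounts(t2))
  expect_identical(simulate_fpkm_table(t1), simulate_fpkm_table(t2))
  expect_identical(simulate_gbs_counts(t1), simulate_gbs_counts(t2))
  # a different seed changes the draw
  t3 <- simulate_population(small_cfg(seed = 202))
  expect_false(identical(t1$snps, t3$snps))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_lines = 5, group_sizes = c(SSS = 2, NSS = 2)),
               "sum to")
  expect_error(sim_config(group_private_snp_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(mean_depth = 0), "positive")
  expect_error(sim_config(group_sizes = c(Flint = 21)), "labels from")
})

test_that("truth respects the configured population structure", {
  cfg <- small_cfg()
  truth <- simulate_population(cfg)
  lines <- truth$lines
  expect_equal(nrow(lines), 6)
  expect_equal(as.integer(table(lines$group)[c("SSS", "NSS")]), c(3L, 3L))

  # homozygous truth: single allele per line per locus; >= 2 alleles/locus
  calls <- as.matrix(truth$snps[, lines$line_id])
  expect_true(all(calls %in% c("A", "C", "G", "T")))
  expect_true(all(apply(calls, 1, function(x) length(unique(x))) >= 2))

  # private loci: minor allele confined to the recorded group
  priv <- !is.na(truth$snps$private_group)
  expect_gt(sum(priv), 0)
  for (i in which(priv)) {
    carriers <- lines$line_id[calls[i, ] == truth$snps$alt[i]]
    expect_equal(unique(lines$group[lines$line_id %in% carriers]),
                 truth$snps$private_group[i])
    expect_gte(length(carriers), 2)
  }
  # non-private loci span at least two groups
  for (i in which(!priv)[1:20]) {
    carriers <- lines$line_id[calls[i, ] == truth$snps$alt[i]]
    expect_gte(length(unique(lines$group[lines$line_id %in% carriers])), 2)
  }

  # SNPs land inside exons of the truth's gene models
  exonic <- truth$genes |>
    dplyr::select(chrom, exons) |>
    tidyr::unnest(exons)
  in_exon <- vapply(seq_len(nrow(truth$snps)), function(i) {
    any(exonic$chrom == truth$snps$chrom[i] &
          truth$snps$pos[i] >= exonic$start &
          truth$snps$pos[i] <= exonic$end)
  }, logical(1))
  expect_true(all(in_exon))
})

test_that("degenerate fractions behave as documented", {
  t0 <- simulate_population(small_cfg(group_private_snp_fraction = 0))
  expect_true(all(is.na(t0$snps$private_group)))

  t1 <- simulate_population(small_cfg(core_novel_fraction = 1))
  expect_true(all(t1$novel_presence$present))
})

test_that("error-free deep pileups make the caller recover the truth", {
  hits <- 0; total <- 0; fp <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_lines = 6, group_sizes = c(SSS = 3, NSS = 3),
                      n_genes = 10, n_snps = 60, n_invariant_sites = 60,
                      n_novel_transcripts = 5, n_background_transcripts = 5,
                      mean_depth = 10, error_rate = 0, seed = 1000 + s)
    truth <- simulate_population(cfg)
    bc <- simulate_basecounts(truth)
    gm <- discover_snps(bc, lines = truth$lines$line_id)
    got <- paste(gm$chrom, gm$pos)
    want_all <- paste(truth$snps$chrom, truth$snps$pos)
    fp <- fp + sum(!(got %in% want_all))
    # discoverable: each of the two alleles covered (>= 2 reads) in >= 2 lines
    depth_ok <- with(bc, tapply(
      count_A + count_C + count_G + count_T,
      list(paste(chrom, pos), line_id), sum))
    calls <- as.matrix(truth$snps[, truth$lines$line_id])
    discoverable <- vapply(seq_len(nrow(truth$snps)), function(i) {
      key <- paste(truth$snps$chrom[i], truth$snps$pos[i])
      d <- depth_ok[key, truth$lines$line_id]
      all(vapply(unique(calls[i, ]), function(a) {
        sum(calls[i, ] == a & !is.na(d) & d >= 2) >= 2
      }, logical(1)))
    }, logical(1))
    total <- total + sum(discoverable)
    hits <- hits + sum(want_all[discoverable] %in% got)
  }
  expect_equal(fp, 0)
  expect_gte(hits / total, 0.99)
})

test_that("zero-coverage loci propagate as missing calls", {
  cfg <- small_cfg(mean_depth = 0.2)
  truth <- simulate_population(cfg)
  bc <- simulate_basecounts(truth)
  zero <- rowSums(bc[, c("count_A", "count_C", "count_G", "count_T")]) == 0
  expect_gt(sum(zero), 0)
  calls <- call_line_genotype(count_matrix_for_test(bc))
  expect_true(all(is.na(calls$allele[zero])))
})

test_that("simulated FPKM tables encode the expression truth", {
  cfg <- small_cfg(fpkm_absent_rate = 0)
  truth <- simulate_population(cfg)
  fpkm <- simulate_fpkm_table(truth)
  expect_silent(validate_fpkm_table(fpkm))
  joined <- dplyr::inner_join(fpkm, truth$expression,
                              by = c("gene_id", "line_id"))
  # absent genes are the literal (0, 0, 0) record
  absent <- joined[joined$category == "NONE", ]
  expect_true(all(absent$fpkm == 0 & absent$conf_lo == 0 & absent$conf_hi == 0))
  # with no dropout the expression call recovers presence truth exactly
  expect_equal(expression_call(joined$conf_lo), joined$category != "NONE")
  # semi-quantitative categories match the truth levels
  expect_equal(as.character(semiquant_category(joined$fpkm, joined$conf_lo)),
               joined$category)

  # with dropout, some truly LOW cells lose their expression call
  fpkm_d <- simulate_fpkm_table(simulate_population(
    small_cfg(fpkm_absent_rate = 0.5)))
  joined_d <- dplyr::inner_join(fpkm_d,
                                simulate_population(
                                  small_cfg(fpkm_absent_rate = 0.5))$expression,
                                by = c("gene_id", "line_id"))
  low <- joined_d[joined_d$category == "LOW", ]
  expect_gt(sum(low$conf_lo == 0), 0)
})

test_that("alignment summaries make the novelty filter recover truth", {
  for (s in c(1, 2, 3)) {
    cfg <- small_cfg(seed = 300 + s)
    truth <- simulate_population(cfg)
    al <- simulate_alignment_summaries(truth)
    res <- filter_novel(al)
    expect_setequal(res$transcript_id[res$retained],
                    truth$transcripts$transcript_id[truth$transcripts$novel])
  }
  # all transcripts unaligned: all retained
  t_un <- simulate_population(small_cfg(novel_unaligned_fraction = 1,
                                        n_background_transcripts = 0))
  al_un <- simulate_alignment_summaries(t_un)
  expect_true(all(!al_un$aligned))
  expect_true(all(filter_novel(al_un)$retained))
})

test_that("read support reflects novel-transcript presence truth", {
  truth <- simulate_population(small_cfg())
  rs <- simulate_read_support(truth)
  joined <- dplyr::inner_join(rs, truth$novel_presence,
                              by = c("transcript_id", "line_id"))
  expect_true(all((joined$unique_reads >= 1) == joined$present))
})

test_that("GBS counts reproduce truth without error and degrade with it", {
  cfg <- small_cfg(error_rate = 0, gbs_site_fraction = 1)
  truth <- simulate_population(cfg)
  gbs <- simulate_gbs_counts(truth)
  calls <- call_gbs_genotype(count_matrix_for_test(gbs))
  covered <- rowSums(gbs[, c("count_A", "count_C", "count_G", "count_T")]) > 0
  truth_long <- truth$snps |>
    dplyr::select(chrom, pos, dplyr::all_of(truth$lines$line_id)) |>
    tidyr::pivot_longer(-c(chrom, pos), names_to = "line_id",
                        values_to = "true_allele")
  m <- dplyr::left_join(gbs, truth_long, by = c("line_id", "chrom", "pos"))
  expect_true(all(calls[covered] == m$true_allele[covered]))
  expect_true(all(is.na(calls[!covered])))

  # error 0.5 at mean depth 2: compare the missing fraction with the exact
  # expectation, enumerated over read compositions per Poisson depth
  cfg2 <- sim_config(n_lines = 6, group_sizes = c(SSS = 3, NSS = 3),
                     n_genes = 20, n_snps = 500, n_invariant_sites = 10,
                     n_novel_transcripts = 5, n_background_transcripts = 5,
                     mean_depth = 2, error_rate = 0.5, gbs_site_fraction = 1,
                     seed = 404)
  truth2 <- simulate_population(cfg2)
  gbs2 <- simulate_gbs_counts(truth2)
  calls2 <- call_gbs_genotype(count_matrix_for_test(gbs2))
  p_read <- c(0.5, 1 / 6, 1 / 6, 1 / 6)  # true allele vs each other base
  p_call_given_d <- function(d) {
    if (d == 0) return(0)
    comps <- expand.grid(rep(list(0:d), 4))
    comps <- comps[rowSums(comps) == d, ]
    probs <- apply(comps, 1, function(k) dmultinom(k, prob = p_read))
    sum(probs[apply(comps, 1, max) / d >= 0.70])
  }
  expected_missing <- sum(vapply(0:12, function(d) {
    dpois(d, 2) * (1 - p_call_given_d(d))
  }, numeric(1)))
  observed_missing <- mean(is.na(calls2))
  expect_lt(abs(observed_missing - expected_missing), 0.03)
})

test_that("simulate_study writes a loadable fixture set", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  truth <- simulate_study(cfg, dir)
  expect_true(file.exists(file.path(dir, "basecounts.tsv")))
  bc <- read_basecount_table(file.path(dir, "basecounts.tsv"))
  expect_equal(as.data.frame(bc),
               as.data.frame(simulate_basecounts(truth)))
  genes <- read_gff3_genes(file.path(dir, "genes.gff3"))
  expect_equal(genes$gene_id, truth$genes$gene_id)
  groups <- read_line_groups(file.path(dir, "line_groups.tsv"))
  expect_equal(groups$line_id, truth$lines$line_id)
})
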