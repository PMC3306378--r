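#' Configuration for a simulated inbred-line study panel
#'
#' Bundles and validates every parameter of the seeded simulator. The
#' defaults emulate the design of a 21-line maize seedling panel: three
#' Stiff Stalk Synthetic lines, eight Non-Stiff Stalk Synthetic, one
#' Iodent, five exotic and four other lines; roughly half the annotated
#' genes expressed in all lines, a quarter in a proper subset and a
#' quarter in none; and novel de novo assembled transcripts of which about
#' 43% are present in every line and 28% have no alignment to the
#' reference at all. Panel sizes (genes, SNPs, transcripts) are desk-scale.
#'
#' @param n_lines Number of inbred lines.
#' @param group_sizes Named integer vector, pedigree group -> line count;
#'   names from SSS, NSS, Iodent, Exotic, Other; must sum to `n_lines`.
#' @param n_genes Number of annotated gene models.
#' @param n_snps Number of true SNP loci (placed uniformly within exons).
#' @param n_invariant_sites Monomorphic exonic positions also covered by
#'   the pileups (the substrate for false SNP discoveries).
#' @param group_private_snp_fraction Fraction of SNP loci whose minor
#'   allele is confined to a single pedigree group.
#' @param n_novel_transcripts Truly novel transcripts (retained by the
#'   coverage/identity filter).
#' @param n_background_transcripts Assembled transcripts that are alleles/
#'   paralogs of reference sequence (removed by the filter).
#' @param core_novel_fraction Fraction of novel transcripts present in all
#'   lines.
#' @param group_private_novel_fraction Fraction of the dispensable novel
#'   transcripts confined to one group.
#' @param novel_unaligned_fraction Fraction of novel transcripts with no
#'   reference alignment at all.
#' @param mean_depth Mean sequencing depth per line per site (Poisson).
#' @param error_rate Per-base error probability; an erroneous read reports
#'   a uniformly chosen other nucleotide.
#' @param fpkm_absent_rate Fraction of truly low-expressed gene-by-line
#'   cells whose CI lower bound collapses to zero (sampling dropout of
#'   lowly expressed genes).
#' @param expressed_all_fraction,expressed_subset_fraction Fractions of
#'   genes expressed in all lines / in a proper subset (remainder: never).
#' @param gbs_site_fraction Fraction of SNP loci assayed by GBS.
#' @param n_chrom Number of chromosomes genes are laid out on.
#' @param seed Integer master seed; per-stage child seeds are derived from
#'   it by fixed offsets so each stage is independently reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_lines = 21,
                       group_sizes = c(SSS = 3, NSS = 8, Iodent = 1,
                                       Exotic = 5, Other = 4),
                       n_genes = 300,
                       n_snps = 3000,
                       n_invariant_sites = 3000,
                       group_private_snp_fraction = 0.3,
                       n_novel_transcripts = 150,
                       n_background_transcripts = 380,
                       core_novel_fraction = 0.43,
                       group_private_novel_fraction = 0.05,
                       novel_unaligned_fraction = 0.28,
                       mean_depth = 20,
                       error_rate = 0.005,
                       fpkm_absent_rate = 0.05,
                       expressed_all_fraction = 0.487,
                       expressed_subset_fraction = 0.279,
                       gbs_site_fraction = 0.5,
                       n_chrom = 2,
                       seed = 1) {
  cfg <- as.list(environment())
  for (p in c("group_private_snp_fraction", "core_novel_fraction",
              "group_private_novel_fraction", "novel_unaligned_fraction",
              "error_rate", "fpkm_absent_rate", "expressed_all_fraction",
              "expressed_subset_fraction", "gbs_site_fraction")) {
    assert_scalar_number(cfg[[p]], p, min = 0, max = 1)
  }
  if (cfg$expressed_all_fraction + cfg$expressed_subset_fraction > 1) {
    abort("Expression fractions must sum to at most 1.")
  }
  assert_scalar_number(n_lines, "n_lines", min = 2)
  assert_scalar_number(mean_depth, "mean_depth")
  if (mean_depth <= 0) abort("`mean_depth` must be positive.")
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% GROUP_LEVELS)) {
    abort(sprintf("`group_sizes` must be named with labels from: %s.",
                  paste(GROUP_LEVELS, collapse = ", ")))
  }
  if (sum(group_sizes) != n_lines) {
    abort("`group_sizes` must sum to `n_lines`.")
  }
  assert_scalar_number(seed, "seed")
  structure(cfg, class = "sim_config")
}

# fixed per-stage seed offsets so stages are independently reproducible
stage_seed <- function(config, stage) {
  offsets <- c(population = 1L, basecounts = 2L, fpkm = 3L,
               alignments = 4L, gbs = 5L, support = 6L)
  as.integer(config$seed) + offsets[[stage]]
}

#' Simulate the ground truth of a study panel
#'
#' Draws, deterministically for a given config (same seed, same truth):
#' lines partitioned into pedigree groups; gene models laid out with
#' 1-3 exons each; homozygous biallelic SNP loci placed uniformly within
#' exons, a configured fraction with the minor allele confined to one
#' group (of size >= 2) and the rest spanning at least two groups;
#' per-gene expression classes (expressed in all lines, in a random proper
#' subset, or never, with a LOW/MEDIUM/HIGH level for expressed genes);
#' and novel transcripts split into core (all lines) and dispensable
#' (a random nonempty proper subset, some confined to one group).
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list with elements `lines`, `genes`, `snps`
#'   (wide: `chrom`, `pos`, `ref`, `alt`, `private_group`, then one
#'   true-allele column per line), `invariant_sites`, `expression`
#'   (gene x line `category`), `transcripts` (id, length, novel flag) and
#'   `novel_presence` (transcript x line logical), plus the config.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config, "population"), {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    lines <- tibble(
      line_id = sprintf("%s_%02d", groups,
                        unlist(lapply(config$group_sizes, seq_len))),
      group = groups
    )
    line_ids <- lines$line_id

    genes <- sim_gene_models(config$n_genes, config$n_chrom)

    # candidate exonic positions
    exon_pos <- genes |>
      select("gene_id", "chrom", "exons") |>
      tidyr::unnest("exons") |>
      mutate(pos = purrr::map2(.data$start, .data$end, seq)) |>
      select("chrom", "pos") |>
      tidyr::unnest("pos")
    n_sites <- config$n_snps + config$n_invariant_sites
    if (nrow(exon_pos) < n_sites) {
      abort("Not enough exonic positions for the requested site counts.")
    }
    picked <- exon_pos[sample.int(nrow(exon_pos), n_sites), ]
    snp_sites <- picked[seq_len(config$n_snps), ]
    inv_sites <- picked[config$n_snps + seq_len(config$n_invariant_sites), ]

    ref <- sample(NUCLEOTIDES, config$n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(NUCLEOTIDES, r), 1),
                  character(1))

    eligible_groups <- names(config$group_sizes)[config$group_sizes >= 2]
    n_private <- round(config$group_private_snp_fraction * config$n_snps)
    if (n_private > 0 && length(eligible_groups) == 0L) {
      abort("Group-private SNPs need at least one group of size >= 2.")
    }
    carrier_sets <- vector("list", config$n_snps)
    for (i in seq_len(config$n_snps)) {
      if (i <= n_private) {
        g <- sample(eligible_groups, 1,
                    prob = config$group_sizes[eligible_groups])
        members <- line_ids[groups == g]
        k <- sample(2:length(members), 1)
        carrier_sets[[i]] <- sample(members, k)
      } else {
        # minor allele spans at least two groups: seed with one line from
        # each of two distinct groups, then add random others
        gs <- sample(unique(groups), 2)
        seed_lines <- c(sample(line_ids[groups == gs[1]], 1),
                        sample(line_ids[groups == gs[2]], 1))
        others <- setdiff(line_ids, seed_lines)
        k_extra <- sample(0:max(0, config$n_lines - 4), 1)
        carrier_sets[[i]] <- c(seed_lines, sample(others, k_extra))
      }
    }
    geno <- matrix(rep(ref, config$n_lines), ncol = config$n_lines,
                   dimnames = list(NULL, line_ids))
    for (i in seq_len(config$n_snps)) {
      geno[i, carrier_sets[[i]]] <- alt[i]
    }
    snps <- tibble(
      chrom = snp_sites$chrom, pos = snp_sites$pos,
      ref = ref, alt = alt,
      private_group = c(
        vapply(seq_len(n_private), function(i) {
          unique(lines$group[match(carrier_sets[[i]], line_ids)])
        }, character(1)),
        rep(NA_character_, config$n_snps - n_private)
      )
    )
    snps <- dplyr::bind_cols(snps, as_tibble(geno)) |>
      arrange(.data$chrom, .data$pos)
    invariant <- tibble(
      chrom = inv_sites$chrom, pos = inv_sites$pos,
      ref = sample(NUCLEOTIDES, config$n_invariant_sites, replace = TRUE)
    ) |>
      arrange(.data$chrom, .data$pos)

    expression <- sim_expression_truth(genes$gene_id, line_ids, config)

    novel <- sim_novel_truth(lines, config)

    structure(
      list(lines = lines, genes = genes, snps = snps,
           invariant_sites = invariant, expression = expression,
           transcripts = novel$transcripts,
           novel_presence = novel$presence,
           config = config),
      class = "sim_truth"
    )
  })
}

sim_gene_models <- function(n_genes, n_chrom) {
  chrom <- sprintf("chr%d", rep_len(seq_len(n_chrom), n_genes))
  out <- vector("list", n_genes)
  cursor <- setNames(rep(1L, n_chrom), sprintf("chr%d", seq_len(n_chrom)))
  for (i in seq_len(n_genes)) {
    ch <- chrom[i]
    start <- cursor[[ch]] + sample(5000:50000, 1)
    n_exons <- sample(1:3, 1)
    ex_len <- sample(200:1500, n_exons, replace = TRUE)
    intron <- if (n_exons > 1) sample(100:1000, n_exons - 1, replace = TRUE)
      else integer()
    ex_start <- start + c(0, cumsum(ex_len[-n_exons] + intron))
    ex_end <- ex_start + ex_len - 1L
    out[[i]] <- tibble(
      gene_id = sprintf("gene_%04d", i),
      chrom = ch, start = start, end = max(ex_end),
      strand = sample(c("+", "-"), 1),
      exons = list(tibble(start = as.integer(ex_start),
                          end = as.integer(ex_end))),
      exonic_length = sum(ex_len)
    )
    cursor[[ch]] <- max(ex_end)
  }
  bind_rows(out)
}

sim_expression_truth <- function(gene_ids, line_ids, config) {
  n_genes <- length(gene_ids)
  n_lines <- length(line_ids)
  cls <- sample(
    c("all", "subset", "never"), n_genes, replace = TRUE,
    prob = c(config$expressed_all_fraction, config$expressed_subset_fraction,
             1 - config$expressed_all_fraction -
               config$expressed_subset_fraction)
  )
  level <- sample(c("LOW", "MEDIUM", "HIGH"), n_genes, replace = TRUE,
                  prob = c(0.25, 0.60, 0.15))
  rows <- purrr::map(seq_len(n_genes), function(i) {
    expressed_in <- switch(
      cls[i],
      all = line_ids,
      never = character(),
      subset = sample(line_ids, sample.int(n_lines - 1L, 1))
    )
    tibble(
      gene_id = gene_ids[i], line_id = line_ids,
      category = ifelse(line_ids %in% expressed_in, level[i], "NONE")
    )
  })
  bind_rows(rows)
}

sim_novel_truth <- function(lines, config) {
  n_nov <- config$n_novel_transcripts
  n_bg <- config$n_background_transcripts
  ids <- sprintf("nov_%04d", seq_len(n_nov))
  bg_ids <- sprintf("bg_%04d", seq_len(n_bg))
  transcripts <- tibble(
    transcript_id = c(ids, bg_ids),
    length = sample(500:3000, n_nov + n_bg, replace = TRUE),
    novel = rep(c(TRUE, FALSE), c(n_nov, n_bg))
  )
  n_core <- round(config$core_novel_fraction * n_nov)
  n_disp <- n_nov - n_core
  n_private <- round(config$group_private_novel_fraction * n_disp)
  line_ids <- lines$line_id
  presence <- matrix(FALSE, n_nov, length(line_ids),
                     dimnames = list(ids, line_ids))
  presence[seq_len(n_core), ] <- TRUE
  disp_idx <- n_core + seq_len(n_disp)
  for (k in seq_along(disp_idx)) {
    i <- disp_idx[k]
    if (k <= n_private) {
      g <- sample(unique(lines$group), 1)
      members <- line_ids[lines$group == g]
      present_in <- sample(members, sample.int(length(members), 1))
    } else {
      present_in <- sample(line_ids,
                           sample.int(length(line_ids) - 1L, 1))
    }
    presence[i, present_in] <- TRUE
  }
  presence_tbl <- as_tibble(presence) |>
    mutate(transcript_id = ids) |>
    tidyr::pivot_longer(-"transcript_id", names_to = "line_id",
                        values_to = "present")
  list(transcripts = transcripts, presence = presence_tbl)
}

# depth + uniform substitution error model shared by RNA-seq and GBS counts
sim_counts_at <- function(true_allele, n, mean_depth, error_rate) {
  depth <- rpois(n, mean_depth)
  n_err <- rbinom(n, depth, error_rate)
  counts <- matrix(0, n, 4, dimnames = list(NULL, NUCLEOTIDES))
  ai <- match(true_allele, NUCLEOTIDES)
  counts[cbind(seq_len(n), ai)] <- depth - n_err
  has_err <- which(n_err > 0)
  for (i in has_err) {
    others <- setdiff(1:4, ai[i])
    err_alloc <- as.vector(stats::rmultinom(1, n_err[i], rep(1 / 3, 3)))
    counts[i, others] <- counts[i, others] + err_alloc
  }
  counts
}

#' Simulate base-count pileups from the truth
#'
#' For every line at every SNP locus and invariant site, depth is drawn
#' from Poisson(`mean_depth`); each read reports the line's true allele
#' with probability `1 - error_rate` and otherwise a uniformly chosen
#' other nucleotide. Zero-depth records are kept (all-zero counts), so the
#' caller observes missing data where coverage dropped out.
#'
#' @param truth A `sim_truth` from [simulate_population()].
#' @param config The same [sim_config()].
#' @return A base-count tibble (see [read_basecount_table()]).
#' @export
simulate_basecounts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  withr::with_seed(stage_seed(config, "basecounts"), {
    line_ids <- truth$lines$line_id
    snp_long <- truth$snps |>
      select("chrom", "pos", dplyr::all_of(line_ids)) |>
      tidyr::pivot_longer(dplyr::all_of(line_ids), names_to = "line_id",
                          values_to = "true_allele")
    inv_long <- truth$invariant_sites |>
      tidyr::expand_grid(line_id = line_ids) |>
      rename(true_allele = "ref")
    sites <- bind_rows(snp_long, inv_long)
    counts <- sim_counts_at(sites$true_allele, nrow(sites),
                            config$mean_depth, config$error_rate)
    tibble(
      line_id = sites$line_id, chrom = sites$chrom, pos = sites$pos,
      count_A = counts[, "A"], count_C = counts[, "C"],
      count_G = counts[, "G"], count_T = counts[, "T"]
    ) |>
      arrange(.data$line_id, .data$chrom, .data$pos)
  })
}

#' Simulate an FPKM table with CI bounds from the truth
#'
#' Unexpressed gene-by-line cells get the literal record (0, 0, 0). Truly
#' LOW cells draw FPKM uniformly in (0, 5); a `fpkm_absent_rate` fraction
#' of them additionally get a CI lower bound of zero, emulating the
#' sampling dropout by which very lowly expressed genes escape detection.
#' MEDIUM cells draw FPKM in \[5, 200\] and HIGH cells above 200; expressed
#' cells get `0 < conf_lo < fpkm < conf_hi`.
#'
#' @inheritParams simulate_basecounts
#' @return An FPKM tibble (see [read_fpkm_table()]).
#' @export
simulate_fpkm_table <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  withr::with_seed(stage_seed(config, "fpkm"), {
    ex <- truth$expression
    n <- nrow(ex)
    fpkm <- numeric(n)
    lo_frac <- runif(n, 0.2, 0.8)   # conf_lo = fpkm * lo_frac
    hi_frac <- runif(n, 1.2, 1.8)   # conf_hi = fpkm * hi_frac
    is_low <- ex$category == "LOW"
    is_med <- ex$category == "MEDIUM"
    is_high <- ex$category == "HIGH"
    fpkm[is_low] <- runif(sum(is_low), 0.01, 5 - 1e-6)
    fpkm[is_med] <- runif(sum(is_med), 5, 200)
    fpkm[is_high] <- runif(sum(is_high), 200 + 1e-6, 2000)
    conf_lo <- fpkm * lo_frac
    conf_hi <- fpkm * hi_frac
    dropout <- is_low & runif(n) < config$fpkm_absent_rate
    conf_lo[dropout] <- 0
    none <- ex$category == "NONE"
    fpkm[none] <- 0; conf_lo[none] <- 0; conf_hi[none] <- 0
    tibble(
      gene_id = ex$gene_id, line_id = ex$line_id,
      fpkm = fpkm, conf_lo = conf_lo, conf_hi = conf_hi
    )
  })
}

#' Simulate best-alignment summaries for assembled transcripts
#'
#' Novel transcripts either fail to align at all
#' (`novel_unaligned_fraction`) or align below the 85%/85% removal rule
#' (never both coverage and identity above 0.85). Background transcripts
#' (reference alleles/paralogs) align with both coverage and identity
#' strictly above 0.85 and are therefore removed by [filter_novel()], so
#' the filter's retained set equals the truth's novel set by construction.
#'
#' @inheritParams simulate_basecounts
#' @return An alignment-summary tibble (see [read_alignment_summary()]).
#' @export
simulate_alignment_summaries <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  withr::with_seed(stage_seed(config, "alignments"), {
    tr <- truth$transcripts
    n <- nrow(tr)
    aligned <- rep(TRUE, n)
    coverage <- numeric(n); identity <- numeric(n)
    nov <- tr$novel
    aligned[nov] <- runif(sum(nov)) >= config$novel_unaligned_fraction
    # novel + aligned: below cutoff on at least one axis
    na_idx <- which(nov & aligned)
    coverage[na_idx] <- runif(length(na_idx), 0.2, 1)
    identity[na_idx] <- runif(length(na_idx), 0.5, 1)
    both_high <- na_idx[coverage[na_idx] > 0.85 & identity[na_idx] > 0.85]
    identity[both_high] <- runif(length(both_high), 0.5, 0.849)
    bg_idx <- which(!nov)
    coverage[bg_idx] <- runif(length(bg_idx), 0.851, 1)
    identity[bg_idx] <- runif(length(bg_idx), 0.851, 1)
    coverage[!aligned] <- NA_real_
    identity[!aligned] <- NA_real_
    tibble(
      transcript_id = tr$transcript_id, aligned = aligned,
      coverage = coverage, identity = identity
    )
  })
}

#' Simulate per-line read support for novel transcripts
#'
#' Lines in which a transcript is truly present receive at least one
#' uniquely mapping read (1 + Poisson(5)) plus some multi-mapped reads;
#' absent lines receive zero unique reads but occasionally a few
#' multi-mapped reads, emulating cross-mapping from paralogous copies.
#'
#' @inheritParams simulate_basecounts
#' @return A read-support tibble (see [read_read_support()]).
#' @export
simulate_read_support <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  withr::with_seed(stage_seed(config, "support"), {
    pr <- truth$novel_presence
    n <- nrow(pr)
    unique_reads <- ifelse(pr$present, 1 + rpois(n, 5), 0)
    multi_reads <- ifelse(
      pr$present, rpois(n, 2),
      rbinom(n, 1, 0.15) * (1 + rpois(n, 2))
    )
    tibble(
      transcript_id = pr$transcript_id, line_id = pr$line_id,
      unique_reads = unique_reads, multi_reads = multi_reads
    )
  })
}

#' Simulate GBS per-site nucleotide counts
#'
#' Covers a random fraction (`gbs_site_fraction`) of the true SNP loci
#' across all lines, with the same Poisson-depth, uniform-substitution
#' count model as [simulate_basecounts()] — an independent genotyping of
#' the same panel, for concordance analysis.
#'
#' @inheritParams simulate_basecounts
#' @param mean_depth Mean GBS depth per site; defaults to the config's
#'   `mean_depth`.
#' @return A count tibble in base-count layout.
#' @export
simulate_gbs_counts <- function(truth, config = truth$config,
                                mean_depth = config$mean_depth) {
  stopifnot(inherits(truth, "sim_truth"))
  withr::with_seed(stage_seed(config, "gbs"), {
    line_ids <- truth$lines$line_id
    n_sites <- max(1L, round(config$gbs_site_fraction * nrow(truth$snps)))
    site_idx <- sort(sample.int(nrow(truth$snps), n_sites))
    sites <- truth$snps[site_idx, ] |>
      select("chrom", "pos", dplyr::all_of(line_ids)) |>
      tidyr::pivot_longer(dplyr::all_of(line_ids), names_to = "line_id",
                          values_to = "true_allele")
    counts <- sim_counts_at(sites$true_allele, nrow(sites),
                            mean_depth, config$error_rate)
    tibble(
      line_id = sites$line_id, chrom = sites$chrom, pos = sites$pos,
      count_A = counts[, "A"], count_C = counts[, "C"],
      count_G = counts[, "G"], count_T = counts[, "T"]
    ) |>
      arrange(.data$line_id, .data$chrom, .data$pos)
  })
}

#' Write a complete simulated study to a directory
#'
#' Materialises every fixture a downstream analysis needs — base counts,
#' GBS counts, FPKM table, gene models (GFF3), line groups, alignment
#' summaries, read support — plus the truth tables (TSV) for comparison.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the `sim_truth`.
#' @export
simulate_study <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_population(config)
  write_basecount_table(simulate_basecounts(truth, config),
                        file.path(outdir, "basecounts.tsv"))
  write_basecount_table(simulate_gbs_counts(truth, config),
                        file.path(outdir, "gbs_counts.tsv"))
  write_fpkm_table(simulate_fpkm_table(truth, config),
                   file.path(outdir, "fpkm.tsv"))
  write_gff3_genes(truth$genes, file.path(outdir, "genes.gff3"))
  readr::write_tsv(truth$lines, file.path(outdir, "line_groups.tsv"))
  write_alignment_summary(simulate_alignment_summaries(truth, config),
                          file.path(outdir, "alignments.tsv"))
  write_read_support(simulate_read_support(truth, config),
                     file.path(outdir, "read_support.tsv"))
  readr::write_tsv(truth$snps, file.path(outdir, "truth_snps.tsv"))
  readr::write_tsv(truth$expression, file.path(outdir, "truth_expression.tsv"))
  readr::write_tsv(truth$novel_presence,
                   file.path(outdir, "truth_novel_presence.tsv"))
  invisible(truth)
}
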