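#' Call a single line's genotype from base counts
#'
#' At one genomic position for one homozygous inbred line, a nucleotide is
#' accepted as an allele iff it is supported by at least `min_reads` of the
#' filtered reads and by strictly more than `min_frac` of them (defaults: 2
#' reads, 5.0%). If exactly one nucleotide passes, that nucleotide is the
#' genotype; if none or more than one pass, the genotype is missing — an
#' apparently heterozygous call in an inbred cannot be distinguished from a
#' collapsed paralog, so it is treated as missing data.
#'
#' @param counts Either a length-4 numeric vector of read counts in the
#'   order A, C, G, T, or a 4-column matrix (one row per position).
#' @param min_frac Strict lower bound on the allele's read fraction.
#' @param min_reads Minimum supporting read count.
#' @return A tibble with columns `allele` (nucleotide or NA) and
#'   `passing_alleles` (comma-separated nucleotides that met both rules),
#'   one row per input row.
#' @examples
#' call_line_genotype(c(10, 0, 0, 0))   # A
#' call_line_genotype(c(19, 1, 0, 0))   # A; C fails both rules
#' call_line_genotype(c(30, 2, 0, 0))   # missing: two alleles pass
#' @export
call_line_genotype <- function(counts, min_frac = 0.05, min_reads = 2) {
  if (is.null(dim(counts))) {
    counts <- matrix(as.numeric(counts), nrow = 1)
  }
  if (ncol(counts) != 4L) {
    abort("`counts` must have four columns (A, C, G, T).")
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort("Base counts must be nonnegative.")
  }
  total <- rowSums(counts)
  pass <- counts >= min_reads & counts > min_frac * total
  npass <- rowSums(pass)
  allele <- rep(NA_character_, nrow(counts))
  one <- npass == 1L
  if (any(one)) {
    allele[one] <- NUCLEOTIDES[max.col(pass[one, , drop = FALSE], "first")]
  }
  passing <- vapply(seq_len(nrow(counts)), function(i) {
    paste(NUCLEOTIDES[pass[i, ]], collapse = ",")
  }, character(1))
  tibble(allele = allele, passing_alleles = passing)
}

#' Confirm alleles across lines at one position
#'
#' An allele is confirmed at a position when at least `min_lines` distinct
#' inbred lines carry it as their (single, non-missing) genotype call.
#'
#' @param calls Character vector of per-line calls at one position
#'   (nucleotide or NA); at most one entry per line.
#' @param min_lines Minimum number of supporting lines (default 2).
#' @return Character vector of confirmed alleles, alphabetical.
#' @export
confirm_alleles <- function(calls, min_lines = 2) {
  assert_nucleotides(calls, "calls")
  tab <- table(calls[!is.na(calls)])
  out <- names(tab)[tab >= min_lines]
  if (is.null(out)) character(0) else sort(out)
}

new_genotype_matrix <- function(tbl, lines, unconfirmed = NULL) {
  attr(tbl, "lines") <- lines
  attr(tbl, "unconfirmed") <- unconfirmed %||%
    tibble(chrom = character(), pos = numeric(), line_id = character())
  class(tbl) <- c("genotype_matrix", class(tbl))
  tbl
}

#' Discover SNP loci across a panel of inbred lines
#'
#' The multi-sample caller: at every position with coverage, each line's
#' genotype is called with [call_line_genotype()]; alleles are then
#' confirmed across lines with [confirm_alleles()]; a position is emitted
#' as a SNP locus iff at least `min_alleles` (default 2) confirmed alleles
#' are present. With the default thresholds a biallelic SNP therefore needs
#' two lines supporting one allele and two other lines supporting the
#' alternative, so every locus has coverage in at least four lines.
#'
#' Per-line calls at emitted loci are retained as made, including calls for
#' alleles that themselves failed the two-line confirmation; those entries
#' are flagged in the `unconfirmed` attribute.
#'
#' @param basecounts A base-count table (see [read_basecount_table()]).
#' @param lines Ordered character vector of line ids defining the matrix
#'   columns; defaults to the sorted lines present in `basecounts`.
#' @param min_frac,min_reads Per-line call thresholds
#'   (see [call_line_genotype()]).
#' @param min_lines Lines required to confirm an allele.
#' @param min_alleles Confirmed alleles required to emit a locus.
#' @return A `genotype_matrix`: a tibble with `chrom`, `pos`,
#'   `confirmed_alleles` (comma-separated, alphabetical) and one call column
#'   per line (nucleotide or NA), sorted by (chrom, pos). Attributes:
#'   `lines` (column order) and `unconfirmed` (tibble of flagged entries).
#' @export
discover_snps <- function(basecounts, lines = NULL,
                          min_frac = 0.05, min_reads = 2,
                          min_lines = 2, min_alleles = 2) {
  bc <- validate_basecount_table(basecounts)
  lines <- lines %||% sort(unique(bc$line_id))
  extra <- setdiff(unique(bc$line_id), lines)
  if (length(extra) > 0L) {
    abort(sprintf("Lines in table but not in `lines`: %s.",
                  paste(extra, collapse = ", ")))
  }
  calls <- call_line_genotype(count_matrix(bc), min_frac, min_reads)
  bc <- bc |>
    mutate(allele = calls$allele) |>
    select("line_id", "chrom", "pos", "allele")

  per_pos <- bc |>
    filter(!is.na(.data$allele)) |>
    distinct(.data$chrom, .data$pos, .data$allele, .data$line_id) |>
    count(.data$chrom, .data$pos, .data$allele, name = "n_lines") |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      confirmed = list(sort(.data$allele[.data$n_lines >= min_lines])),
      .groups = "drop"
    ) |>
    filter(lengths(.data$confirmed) >= min_alleles)

  if (nrow(per_pos) == 0L) {
    empty <- tibble(chrom = character(), pos = numeric(),
                    confirmed_alleles = character())
    for (l in lines) empty[[l]] <- character()
    return(new_genotype_matrix(empty, lines))
  }

  loci <- per_pos |>
    mutate(confirmed_alleles = vapply(.data$confirmed, paste,
                                      character(1), collapse = ",")) |>
    select("chrom", "pos", "confirmed_alleles") |>
    arrange(.data$chrom, .data$pos)

  calls_at_loci <- bc |>
    dplyr::semi_join(loci, by = c("chrom", "pos"))
  wide <- calls_at_loci |>
    tidyr::pivot_wider(names_from = "line_id", values_from = "allele")
  for (l in setdiff(lines, names(wide))) wide[[l]] <- NA_character_
  out <- loci |>
    left_join(wide, by = c("chrom", "pos")) |>
    select("chrom", "pos", "confirmed_alleles", dplyr::all_of(lines))

  unconf <- calls_at_loci |>
    filter(!is.na(.data$allele)) |>
    left_join(loci, by = c("chrom", "pos")) |>
    filter(!purrr::map2_lgl(
      .data$allele, .data$confirmed_alleles,
      function(a, conf) a %in% strsplit(conf, ",", fixed = TRUE)[[1]]
    )) |>
    select("chrom", "pos", "line_id")

  new_genotype_matrix(out, lines, unconf)
}

#' @exportS3Method generics::tidy
tidy.genotype_matrix <- function(x, ...) {
  lines <- gm_lines(x)
  unconf <- attr(x, "unconfirmed")
  long <- as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(lines), names_to = "line_id",
                        values_to = "allele") |>
    left_join(
      unconf |> mutate(unconfirmed = TRUE),
      by = c("chrom", "pos", "line_id")
    ) |>
    mutate(unconfirmed = !is.na(.data$unconfirmed))
  long
}

#' @exportS3Method generics::glance
glance.genotype_matrix <- function(x, ...) {
  lines <- gm_lines(x)
  m <- as.matrix(as_tibble(x)[, lines, drop = FALSE])
  tibble(
    n_loci = nrow(x),
    n_lines = length(lines),
    n_missing = sum(is.na(m)),
    n_multiallelic = sum(lengths(strsplit(x$confirmed_alleles, ",")) > 2L),
    n_unconfirmed_calls = nrow(attr(x, "unconfirmed"))
  )
}

#' Per-gene SNP counts and density
#'
#' Assigns each SNP locus to every gene whose exon set contains its
#' position (RNA-seq reads, and hence RNA-seq SNPs, are exonic), then
#' reports the SNP count and the count per 100 bp of exonic gene length.
#' Loci falling in no gene's exons are tallied in the `n_unassigned`
#' attribute; a locus inside overlapping genes is counted once per gene.
#'
#' @param gm A genotype matrix from [discover_snps()].
#' @param genes Gene models from [read_gff3_genes()].
#' @param by Containment rule: `"exon"` (default) or `"span"` (whole gene
#'   span, introns included).
#' @return A tibble `gene_id`, `chrom`, `snp_count`, `exonic_length`,
#'   `snps_per_100bp`, one row per gene, with attribute `n_unassigned`.
#' @export
snp_gene_stats <- function(gm, genes, by = c("exon", "span")) {
  by <- match.arg(by)
  assert_cols(genes, c("gene_id", "chrom", "exons", "exonic_length"), "genes")
  loci <- as_tibble(gm)[, c("chrom", "pos")]
  assigned_any <- rep(FALSE, nrow(loci))
  counts <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    on_chrom <- loci$chrom == g$chrom
    if (by == "exon") {
      ex <- g$exons[[1]]
      hit <- on_chrom & vapply(loci$pos, function(p) {
        any(p >= ex$start & p <= ex$end)
      }, logical(1))
    } else {
      hit <- on_chrom & loci$pos >= g$start & loci$pos <= g$end
    }
    assigned_any[hit] <<- TRUE
    sum(hit)
  }, numeric(1))
  out <- tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    snp_count = counts,
    exonic_length = genes$exonic_length,
    snps_per_100bp = counts / (genes$exonic_length / 100)
  )
  attr(out, "n_unassigned") <- sum(!assigned_any)
  out
}

#' Gene, expressed-gene and SNP density in fixed genomic windows
#'
#' Bins the genome into consecutive windows of `window` bp (1-based
#' inclusive: window k spans `[(k-1)*window + 1, k*window]`). SNPs are
#' assigned by position and genes by midpoint. A gene counts as expressed
#' when at least `min_expressed_lines` lines have an FPKM 95% CI lower
#' bound above zero — the same number of lines required to call a SNP, so
#' the two densities are comparable.
#'
#' @param gm A genotype matrix from [discover_snps()].
#' @param genes Gene models.
#' @param fpkm An FPKM record tibble (see [read_fpkm_table()]).
#' @param window Window size in bp (default 1 Mb).
#' @param min_expressed_lines Lines with `conf_lo > 0` needed to count a
#'   gene as expressed (default 4).
#' @return A tibble `chrom`, `window_start`, `window_end`, `n_snps`,
#'   `n_genes`, `n_expressed_genes` covering every window containing a SNP
#'   or a gene midpoint.
#' @export
window_density <- function(gm, genes, fpkm, window = 1e6,
                           min_expressed_lines = 4) {
  assert_scalar_number(window, "window", min = 1)
  loci <- as_tibble(gm)[, c("chrom", "pos")]
  snp_w <- loci |>
    mutate(win = floor((.data$pos - 1) / window)) |>
    count(.data$chrom, .data$win, name = "n_snps")
  expressed_genes <- validate_fpkm_table(fpkm) |>
    group_by(.data$gene_id) |>
    summarise(n_expr = sum(.data$conf_lo > 0), .groups = "drop") |>
    filter(.data$n_expr >= min_expressed_lines) |>
    pull("gene_id")
  gene_w <- genes |>
    mutate(
      mid = floor((.data$start + .data$end) / 2),
      win = floor((.data$mid - 1) / window),
      expressed = .data$gene_id %in% expressed_genes
    ) |>
    group_by(.data$chrom, .data$win) |>
    summarise(n_genes = n(), n_expressed_genes = sum(.data$expressed),
              .groups = "drop")
  dplyr::full_join(snp_w, gene_w, by = c("chrom", "win")) |>
    mutate(
      across(c("n_snps", "n_genes", "n_expressed_genes"),
             ~ tidyr::replace_na(.x, 0)),
      window_start = .data$win * window + 1,
      window_end = (.data$win + 1) * window
    ) |>
    select("chrom", "window_start", "window_end", "n_snps", "n_genes",
           "n_expressed_genes") |>
    arrange(.data$chrom, .data$window_start)
}

#' Per-line SNP coverage statistics
#'
#' For each line: the percentage of SNP loci at which the line has at least
#' one read (of any nucleotide), and the percentage of SNP-containing genes
#' with at least one covered polymorphic locus in that line.
#'
#' @param basecounts The base-count table used for calling.
#' @param gm The genotype matrix from [discover_snps()].
#' @param genes Gene models.
#' @return A tibble `line_id`, `pct_snps_covered`, `pct_genes_covered`,
#'   ordered by `line_id`; percentages on the 0-100 scale.
#' @export
per_line_coverage_stats <- function(basecounts, gm, genes) {
  bc <- validate_basecount_table(basecounts)
  lines <- gm_lines(gm)
  loci <- as_tibble(gm)[, c("chrom", "pos")]
  n_loci <- nrow(loci)

  # map each locus to the genes containing it (exon rule)
  gene_hits <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    hit <- loci$chrom == g$chrom & vapply(loci$pos, function(p) {
      any(p >= ex$start & p <= ex$end)
    }, logical(1))
    if (any(hit)) tibble(gene_id = g$gene_id, locus = which(hit)) else NULL
  })
  gene_hits <- bind_rows(gene_hits)
  snp_genes <- unique(gene_hits$gene_id)

  cov <- bc |>
    mutate(depth = rowSums(count_matrix(bc))) |>
    filter(.data$depth > 0) |>
    dplyr::inner_join(loci |> mutate(locus = row_number()),
                      by = c("chrom", "pos"))
  purrr::map(lines, function(l) {
    covered <- unique(cov$locus[cov$line_id == l])
    genes_covered <- unique(gene_hits$gene_id[gene_hits$locus %in% covered])
    tibble(
      line_id = l,
      pct_snps_covered =
        if (n_loci == 0) NA_real_ else 100 * length(covered) / n_loci,
      pct_genes_covered =
        if (length(snp_genes) == 0) NA_real_
        else 100 * length(genes_covered) / length(snp_genes)
    )
  }) |>
    bind_rows() |>
    arrange(.data$line_id)
}
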