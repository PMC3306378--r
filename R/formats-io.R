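#' Read a per-line base-count pileup table
#'
#' The pipeline's sole input for SNP calling is a tab-separated table of
#' Phred-prefiltered read counts per nucleotide at each covered genomic
#' position for each inbred line. The expected header is
#' `line_id  chrom  pos  count_A  count_C  count_G  count_T`, with `pos`
#' 1-based and counts nonnegative integers.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per `(line_id, chrom, pos)` key. Duplicate
#'   keys are rejected.
#' @seealso [discover_snps()], [write_basecount_table()]
#' @export
read_basecount_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      line_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      count_A = readr::col_double(),
      count_C = readr::col_double(),
      count_G = readr::col_double(),
      count_T = readr::col_double()
    )
  )
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0L) {
    abort(sprintf(
      "Malformed base-count table row at line %d of %s.", prob$row[1] + 1L, path
    ))
  }
  validate_basecount_table(tbl)
}

#' @rdname read_basecount_table
#' @param tbl A base-count tibble.
#' @export
validate_basecount_table <- function(tbl) {
  assert_cols(tbl, c("line_id", "chrom", "pos",
                     "count_A", "count_C", "count_G", "count_T"), "tbl")
  counts <- count_matrix(tbl)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("Base counts must be nonnegative integers.")
  }
  if (any(is.na(tbl$pos)) || any(tbl$pos < 1) || any(tbl$pos != floor(tbl$pos))) {
    abort("`pos` must be a 1-based integer coordinate.")
  }
  key <- paste(tbl$line_id, tbl$chrom, tbl$pos)
  if (anyDuplicated(key)) {
    abort("Duplicate (line_id, chrom, pos) keys in base-count table.")
  }
  as_tibble(tbl)
}

#' @rdname read_basecount_table
#' @export
write_basecount_table <- function(tbl, path) {
  validate_basecount_table(tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read gene models from a GFF3 annotation
#'
#' Parses `gene`, `mRNA` and `exon` features (1-based inclusive coordinates)
#' and returns one record per gene. Exon structure is taken from the longest
#' annotated mRNA (summed exon length; ties broken by transcript id), since
#' RNA-seq derived SNPs are exonic and per-gene SNP density is normalised by
#' exonic length.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   a list-column `exons` (tibbles of sorted, non-overlapping `start`/`end`
#'   intervals), and `exonic_length`.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$ID <- as.character(df$ID)
  parent <- df$Parent
  df$parent1 <- vapply(
    seq_len(nrow(df)),
    function(i) {
      p <- parent[[i]]
      if (length(p) == 0L) NA_character_ else as.character(p[[1]])
    },
    character(1)
  )
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0L) {
    abort(sprintf("No gene features found in %s.", path))
  }
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gm <- mrnas[!is.na(mrnas$parent1) & mrnas$parent1 == g$ID, , drop = FALSE]
    if (nrow(gm) == 0L) {
      # no mRNA children: take exons parented directly on the gene,
      # or the gene span itself as a single exon
      ex <- exons[!is.na(exons$parent1) & exons$parent1 == g$ID, , drop = FALSE]
      if (nrow(ex) == 0L) {
        ex <- data.frame(start = g$start, end = g$end)
      }
    } else {
      mlen <- vapply(gm$ID, function(mid) {
        e <- exons[!is.na(exons$parent1) & exons$parent1 == mid, , drop = FALSE]
        sum(e$end - e$start + 1)
      }, numeric(1))
      best <- gm$ID[order(-mlen, gm$ID)][1]
      ex <- exons[!is.na(exons$parent1) & exons$parent1 == best, , drop = FALSE]
    }
    ex <- ex[order(ex$start), c("start", "end"), drop = FALSE]
    if (any(ex$start < g$start | ex$end > g$end)) {
      abort(sprintf("Exon outside gene span for gene %s.", g$ID))
    }
    if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      abort(sprintf("Overlapping exons for gene %s.", g$ID))
    }
    tibble(
      gene_id = g$ID, chrom = as.character(g$seqnames),
      start = as.integer(g$start), end = as.integer(g$end),
      strand = as.character(g$strand),
      exons = list(tibble(start = as.integer(ex$start), end = as.integer(ex$end))),
      exonic_length = sum(ex$end - ex$start + 1)
    )
  })
  bind_rows(out)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3_genes()]: each gene is written as a `gene` feature
#' with a single `mRNA` child carrying the exon structure.
#'
#' @param genes A gene-model tibble as returned by [read_gff3_genes()].
#' @param path Output path.
#' @export
write_gff3_genes <- function(genes, path) {
  assert_cols(genes, c("gene_id", "chrom", "start", "end", "strand", "exons"))
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(
      lines,
      paste(g$chrom, "pantx", "gene", g$start, g$end, ".", g$strand, ".",
            sprintf("ID=%s", g$gene_id), sep = "\t"),
      paste(g$chrom, "pantx", "mRNA", g$start, g$end, ".", g$strand, ".",
            sprintf("ID=%s;Parent=%s", mid, g$gene_id), sep = "\t")
    )
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        g$chrom, "pantx", "exon", ex$start[j], ex$end[j], ".", g$strand, ".",
        sprintf("ID=%s.e%d;Parent=%s", mid, j, mid), sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an FPKM table with 95% confidence-interval bounds
#'
#' Expects a TSV with columns `gene_id`, `line_id`, `fpkm`, `conf_lo`,
#' `conf_hi` (the Cufflinks-style 95% CI bounds). Records must satisfy
#' `0 <= conf_lo <= fpkm <= conf_hi`; `conf_lo` equal to zero marks a gene
#' not reliably detected as expressed in that line.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble of FPKM records.
#' @export
read_fpkm_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      line_id = readr::col_character(),
      fpkm = readr::col_double(),
      conf_lo = readr::col_double(),
      conf_hi = readr::col_double()
    )
  )
  validate_fpkm_table(tbl)
}

#' @rdname read_fpkm_table
#' @param tbl An FPKM tibble.
#' @export
validate_fpkm_table <- function(tbl) {
  assert_cols(tbl, c("gene_id", "line_id", "fpkm", "conf_lo", "conf_hi"), "tbl")
  with(tbl, {
    if (anyNA(fpkm) || anyNA(conf_lo) || anyNA(conf_hi)) {
      abort("FPKM records must not contain missing values.")
    }
    if (any(conf_lo < 0) || any(fpkm < 0)) {
      abort("FPKM values and CI bounds must be nonnegative.")
    }
    if (any(conf_lo > fpkm) || any(fpkm > conf_hi)) {
      abort("FPKM records must satisfy conf_lo <= fpkm <= conf_hi.")
    }
  })
  as_tibble(tbl)
}

#' @rdname read_fpkm_table
#' @export
write_fpkm_table <- function(tbl, path) {
  validate_fpkm_table(tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a line-to-pedigree-group assignment table
#'
#' TSV with columns `line_id` and `group`; groups are drawn from the fixed
#' vocabulary SSS, NSS, Iodent, Exotic, Other (Stiff Stalk Synthetic,
#' Non-Stiff Stalk Synthetic, ...). Every line must appear exactly once.
#'
#' @param path Path to a TSV file.
#' @export
read_line_groups <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    line_id = readr::col_character(), group = readr::col_character()
  ))
  validate_line_groups(tbl)
}

#' @rdname read_line_groups
#' @param tbl A line-group tibble.
#' @export
validate_line_groups <- function(tbl) {
  assert_cols(tbl, c("line_id", "group"), "tbl")
  if (anyDuplicated(tbl$line_id)) {
    abort("Each line must have exactly one group assignment.")
  }
  bad <- setdiff(unique(tbl$group), GROUP_LEVELS)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Unknown group label(s): %s. Allowed: %s.",
      paste(bad, collapse = ", "), paste(GROUP_LEVELS, collapse = ", ")
    ))
  }
  as_tibble(tbl)
}

#' Read and write transcript read-support tables
#'
#' TSV with columns `transcript_id`, `line_id`, `unique_reads`,
#' `multi_reads`: counts of reads mapping uniquely vs. to multiple locations
#' for each transcript in each line.
#'
#' @param path Path to a TSV file.
#' @export
read_read_support <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    line_id = readr::col_character(),
    unique_reads = readr::col_double(),
    multi_reads = readr::col_double()
  ))
  if (any(tbl$unique_reads < 0) || any(tbl$multi_reads < 0)) {
    abort("Read-support counts must be nonnegative.")
  }
  as_tibble(tbl)
}

#' @rdname read_read_support
#' @param tbl A read-support tibble.
#' @export
write_read_support <- function(tbl, path) {
  assert_cols(tbl, c("transcript_id", "line_id", "unique_reads", "multi_reads"))
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read and write transcript alignment summaries
#'
#' TSV with columns `transcript_id`, `aligned` (logical), `coverage`,
#' `identity` — the best alignment of each assembled transcript against the
#' reference. For unaligned transcripts `coverage`/`identity` are empty (NA).
#'
#' @param path Path to a TSV file.
#' @export
read_alignment_summary <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    aligned = readr::col_logical(),
    coverage = readr::col_double(),
    identity = readr::col_double()
  ))
  validate_alignment_summary(tbl)
}

#' @rdname read_alignment_summary
#' @param tbl An alignment-summary tibble.
#' @export
validate_alignment_summary <- function(tbl) {
  assert_cols(tbl, c("transcript_id", "aligned", "coverage", "identity"), "tbl")
  al <- tbl$aligned
  cv <- tbl$coverage[al]
  id <- tbl$identity[al]
  if (anyNA(cv) || anyNA(id) || any(cv < 0 | cv > 1) || any(id < 0 | id > 1)) {
    abort("Aligned transcripts need coverage and identity in [0, 1].")
  }
  if (any(!is.na(tbl$coverage[!al])) || any(!is.na(tbl$identity[!al]))) {
    abort("Unaligned transcripts must have NA coverage and identity.")
  }
  as_tibble(tbl)
}

#' @rdname read_alignment_summary
#' @export
write_alignment_summary <- function(tbl, path) {
  validate_alignment_summary(tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Write a genotype matrix as VCFv4.2
#'
#' Encodes SNP loci for a panel of homozygous inbred lines. REF is the
#' supplied reference nucleotide when available, otherwise the major allele
#' (most lines; alphabetical tie-break); the remaining confirmed alleles
#' become ALT in alphabetical order. Calls are rendered in homozygous
#' diploid style (`0/0`, `1/1`, ...) and missing data as `./.`. A call whose
#' allele is not among the locus's confirmed alleles (an unconfirmed
#' single-line allele) cannot be indexed and is rendered missing.
#'
#' @param gm A genotype matrix as returned by [discover_snps()] (columns
#'   `chrom`, `pos`, `confirmed_alleles`, then one column per line).
#' @param path Output path.
#' @param reference Optional tibble `chrom`, `pos`, `ref` giving reference
#'   nucleotides.
#' @export
write_vcf <- function(gm, path, reference = NULL) {
  assert_cols(gm, c("chrom", "pos", "confirmed_alleles"), "gm")
  lines <- gm_lines(gm)
  ord <- order(gm$chrom, gm$pos)
  if (!identical(ord, seq_len(nrow(gm)))) {
    abort("Loci must be sorted by (chrom, pos) before writing VCF.")
  }
  allele_sets <- strsplit(gm$confirmed_alleles, ",", fixed = TRUE)
  if (any(lengths(allele_sets) < 2L)) {
    abort("Every VCF locus must have at least two confirmed alleles.")
  }
  assert_nucleotides(unlist(allele_sets), "confirmed_alleles", allow_na = FALSE)
  calls <- as.matrix(gm[, lines, drop = FALSE])
  ref_lookup <- NULL
  if (!is.null(reference)) {
    assert_cols(reference, c("chrom", "pos", "ref"), "reference")
    ref_lookup <- setNames(reference$ref, paste(reference$chrom, reference$pos))
  }
  rows <- vapply(seq_len(nrow(gm)), function(i) {
    alleles <- sort(allele_sets[[i]])
    cr <- calls[i, ]
    ref <- NA_character_
    if (!is.null(ref_lookup)) {
      ref <- unname(ref_lookup[paste(gm$chrom[i], gm$pos[i])])
    }
    if (is.na(ref)) {
      # major allele among non-missing calls restricted to confirmed alleles
      tab <- table(factor(cr[cr %in% alleles], levels = alleles))
      ref <- names(tab)[order(-tab, names(tab))][1]
    }
    alt <- setdiff(alleles, ref)
    idx <- match(cr, c(ref, alt)) - 1L
    gt <- ifelse(is.na(idx), "./.", paste0(idx, "/", idx))
    paste(c(gm$chrom[i], gm$pos[i], ".", ref, paste(alt, collapse = ","),
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pantx",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", lines), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read inbred-line genotype calls back from a VCF
#'
#' Companion reader to [write_vcf()]: decodes homozygous-style `i/i` calls
#' into single nucleotides and `./.` into NA, returning the same wide layout
#' as [discover_snps()].
#'
#' @param path Path to a VCF file.
#' @return A wide genotype tibble: `chrom`, `pos`, `confirmed_alleles`, one
#'   column per sample.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  samples <- colnames(gt)
  alleles <- purrr::map2(fix$REF, fix$ALT, function(r, a) {
    c(r, if (!is.na(a) && nzchar(a)) strsplit(a, ",", fixed = TRUE)[[1]])
  })
  calls <- matrix(NA_character_, nrow(fix), length(samples),
                  dimnames = list(NULL, samples))
  for (i in seq_len(nrow(fix))) {
    idx <- suppressWarnings(as.integer(sub("[/|].*$", "", gt[i, ])))
    calls[i, ] <- alleles[[i]][idx + 1L]
  }
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    confirmed_alleles = vapply(alleles, function(a) paste(sort(a), collapse = ","),
                               character(1))
  )
  out <- dplyr::bind_cols(out, as_tibble(calls))
  attr(out, "lines") <- samples
  new_genotype_matrix(out, samples)
}

#' Write a phylogenetic tree in Newick format
#'
#' Thin, validating wrapper around [ape::write.tree()]: rejects duplicate
#' leaf labels and preserves branch lengths.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be an ape 'phylo' object.")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort("Duplicate leaf labels are not allowed in Newick output.")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
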