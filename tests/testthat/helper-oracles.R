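# Independently coded brute-force re-statements of the calling and
# classification rules, used as oracles against the vectorised
# implementations. Deliberately written as plain loops over the rule text.

NUCS <- c("A", "C", "G", "T")

oracle_line_call <- function(counts, min_frac = 0.05, min_reads = 2) {
  total <- sum(counts)
  passing <- character()
  for (k in 1:4) {
    if (counts[k] >= min_reads && total > 0 && counts[k] / total > min_frac) {
      passing <- c(passing, NUCS[k])
    }
  }
  if (length(passing) == 1) passing else NA_character_
}

oracle_gbs_call <- function(counts, min_frac = 0.70) {
  total <- sum(counts)
  if (total == 0) return(NA_character_)
  for (k in 1:4) {
    if (counts[k] / total >= min_frac) return(NUCS[k])
  }
  NA_character_
}

# exhaustive rule application: per-position loop over lines, then the
# two-line confirmation and two-allele locus rule
oracle_discover <- function(bc, lines) {
  pos_keys <- unique(bc[, c("chrom", "pos")])
  pos_keys <- pos_keys[order(pos_keys$chrom, pos_keys$pos), ]
  loci <- list()
  for (r in seq_len(nrow(pos_keys))) {
    ch <- pos_keys$chrom[r]; p <- pos_keys$pos[r]
    calls <- setNames(rep(NA_character_, length(lines)), lines)
    for (l in lines) {
      row <- bc[bc$line_id == l & bc$chrom == ch & bc$pos == p, ]
      if (nrow(row) == 1) {
        calls[l] <- oracle_line_call(as.numeric(
          row[c("count_A", "count_C", "count_G", "count_T")]))
      }
    }
    tab <- table(calls[!is.na(calls)])
    confirmed <- sort(names(tab)[tab >= 2])
    if (length(confirmed) >= 2) {
      loci[[length(loci) + 1]] <- c(
        list(chrom = ch, pos = p,
             confirmed_alleles = paste(confirmed, collapse = ",")),
        as.list(calls)
      )
    }
  }
  if (length(loci) == 0) return(NULL)
  do.call(rbind, lapply(loci, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

oracle_reference_concordance <- function(calls, reference) {
  n_comp <- 0; n_match <- 0
  for (i in seq_len(nrow(calls))) {
    hit <- reference[reference$chrom == calls$chrom[i] &
                       reference$pos == calls$pos[i], ]
    if (nrow(hit) == 1) {
      n_comp <- n_comp + 1
      if (hit$ref == calls$allele[i]) n_match <- n_match + 1
    }
  }
  list(n_compared = n_comp, n_matching = n_match, rate = n_match / n_comp)
}

oracle_cross_concordance <- function(a, b, lines) {
  n_shared <- 0; n_conc <- 0
  contr <- character()
  keys <- unique(rbind(a[, c("chrom", "pos")], b[, c("chrom", "pos")]))
  for (r in seq_len(nrow(keys))) {
    ra <- a[a$chrom == keys$chrom[r] & a$pos == keys$pos[r], , drop = FALSE]
    rb <- b[b$chrom == keys$chrom[r] & b$pos == keys$pos[r], , drop = FALSE]
    if (nrow(ra) == 0 || nrow(rb) == 0) next
    n_disc <- 0
    for (l in lines) {
      ca <- ra[[l]]; cb <- rb[[l]]
      if (!is.na(ca) && !is.na(cb)) {
        n_shared <- n_shared + 1
        if (ca == cb) n_conc <- n_conc + 1 else n_disc <- n_disc + 1
      }
    }
    if (n_disc > 2) contr <- c(contr, paste(keys$chrom[r], keys$pos[r]))
  }
  list(n_shared = n_shared, n_concordant = n_conc,
       contradiction_positions = contr)
}

oracle_filter_novel <- function(summaries, cov_cut = 0.85, id_cut = 0.85) {
  status <- character(nrow(summaries))
  for (i in seq_len(nrow(summaries))) {
    if (!summaries$aligned[i]) {
      status[i] <- "unaligned"
    } else if (summaries$coverage[i] > cov_cut && summaries$identity[i] > id_cut) {
      status[i] <- "removed"
    } else {
      status[i] <- "below_cutoff"
    }
  }
  status
}

oracle_classify_support <- function(support, n_lines, mode) {
  ids <- unique(support$transcript_id)
  out <- data.frame(transcript_id = ids, n_lines_supported = 0L,
                    category = "", stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    sub <- support[support$transcript_id == ids[k], ]
    n_sup <- 0
    for (i in seq_len(nrow(sub))) {
      reads <- if (mode == "unique") sub$unique_reads[i]
        else sub$unique_reads[i] + sub$multi_reads[i]
      if (reads >= 1) n_sup <- n_sup + 1
    }
    out$n_lines_supported[k] <- n_sup
    out$category[k] <- if (n_sup == n_lines) "CORE"
      else if (n_sup == 0) "NO_SUPPORT" else "DISPENSABLE"
  }
  out[order(out$transcript_id), ]
}

oracle_group_sets <- function(presence, groups) {
  ids <- sort(unique(presence$transcript_id))
  status <- character(length(ids))
  for (k in seq_along(ids)) {
    sub <- presence[presence$transcript_id == ids[k] & presence$present, ]
    gs <- unique(groups$group[match(sub$line_id, groups$line_id)])
    gs <- sort(gs[!is.na(gs)])
    status[k] <- if (length(gs) == 0) "absent"
      else if (length(gs) == 1) gs else "shared"
  }
  data.frame(transcript_id = ids, status = status, stringsAsFactors = FALSE)
}

# Rogers distance via the allele-frequency formula, not mismatch counting:
# per locus d = sqrt(0.5 * sum_a (p_a - q_a)^2) with 0/1 frequencies
oracle_rogers <- function(g1, g2) {
  ds <- c()
  for (i in seq_along(g1)) {
    if (is.na(g1[i]) || is.na(g2[i])) next
    p <- as.numeric(NUCS == g1[i])
    q <- as.numeric(NUCS == g2[i])
    ds <- c(ds, sqrt(0.5 * sum((p - q)^2)))
  }
  mean(ds)
}

count_matrix_for_test <- function(tbl) {
  as.matrix(tbl[, c("count_A", "count_C", "count_G", "count_T")])
}

# ---- random instance generators ----------------------------------------

# per position: a ref and alt allele, each line a homozygous carrier of one
# of them, with occasional error reads and dropped records, so generated
# tables exercise clean calls, missing data and borderline thresholds
random_basecount_table <- function(n_lines = 4, n_pos = 20, max_depth = 30,
                                   keep_prob = 0.85, error_prob = 0.05) {
  lines <- paste0("L", seq_len(n_lines))
  grid <- expand.grid(line_id = lines, pos = seq_len(n_pos),
                      stringsAsFactors = FALSE)
  ref <- sample(1:4, n_pos, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(1:4, r), 1), integer(1))
  grid <- grid[runif(nrow(grid)) < keep_prob, ]
  n <- nrow(grid)
  is_alt <- runif(n) < 0.4
  truth <- ifelse(is_alt, alt[grid$pos], ref[grid$pos])
  depth <- sample(0:max_depth, n, replace = TRUE)
  counts <- matrix(0L, n, 4)
  for (i in seq_len(n)) {
    if (depth[i] > 0) {
      reads <- ifelse(runif(depth[i]) < error_prob,
                      sample(1:4, depth[i], replace = TRUE), truth[i])
      counts[i, ] <- tabulate(reads, 4)
    }
  }
  tibble::tibble(
    line_id = grid$line_id, chrom = "chr1", pos = grid$pos,
    count_A = counts[, 1], count_C = counts[, 2],
    count_G = counts[, 3], count_T = counts[, 4]
  )
}

random_call_matrix <- function(lines, n_pos = 15, miss_prob = 0.3) {
  wide <- tibble::tibble(chrom = "chr1", pos = seq_len(n_pos))
  for (l in lines) {
    calls <- sample(NUCS, n_pos, replace = TRUE)
    calls[runif(n_pos) < miss_prob] <- NA
    wide[[l]] <- calls
  }
  attr(wide, "lines") <- lines
  wide
}

# additive distance matrix from a random binary tree with positive lengths
random_additive_case <- function(n_taxa) {
  tree <- ape::unroot(ape::rtree(n_taxa, br = NULL))
  tree$edge.length <- runif(nrow(tree$edge), 0.1, 2)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}
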