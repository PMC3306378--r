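#' Rogers distance between two homozygous genotype vectors
#'
#' The allele-frequency based Rogers distance, per locus
#' `d_l = sqrt(0.5 * sum_a (p_a - q_a)^2)` over allele frequencies, averaged
#' over loci. For homozygous inbred calls the per-line frequencies are 0/1
#' indicators, so `d_l` is 1 when the alleles differ and 0 when they match,
#' and the distance reduces to the mismatch proportion over compared loci.
#' Loci missing in either line are excluded (pairwise deletion).
#'
#' @param g1,g2 Character vectors of calls (nucleotide or NA) aligned on
#'   the same loci.
#' @param min_shared Minimum number of shared (pairwise non-missing) loci;
#'   below it the distance is undefined and `NA` is returned with a
#'   warning. Default 100.
#' @return A single number in \[0, 1\], with attribute `n_shared`, or `NA`.
#' @export
rogers_distance <- function(g1, g2, min_shared = 100) {
  if (length(g1) != length(g2)) {
    abort("Genotype vectors must be aligned on the same loci.")
  }
  assert_nucleotides(g1, "g1")
  assert_nucleotides(g2, "g2")
  shared <- !is.na(g1) & !is.na(g2)
  n <- sum(shared)
  if (n < min_shared) {
    warn(sprintf("Only %d shared loci (< min_shared = %d): distance undefined.",
                 n, min_shared))
    return(structure(NA_real_, n_shared = n))
  }
  structure(mean(g1[shared] != g2[shared]), n_shared = n)
}

#' Pairwise Rogers distance matrix for a panel
#'
#' @param gm A genotype matrix from [discover_snps()] (or any wide call
#'   tibble with line columns).
#' @param min_shared Passed to [rogers_distance()]; any pair with fewer
#'   shared loci aborts with a report of the offending pairs.
#' @return A `rogers_dist` object: list with `distance` (symmetric matrix,
#'   zero diagonal), `n_shared` (per-pair shared-locus counts) and `labels`.
#' @export
rogers_distance_matrix <- function(gm, min_shared = 100) {
  lines <- gm_lines(gm)
  if (length(lines) < 2L) abort("At least two lines are required.")
  m <- as.matrix(as_tibble(gm)[, lines, drop = FALSE])
  k <- length(lines)
  d <- matrix(0, k, k, dimnames = list(lines, lines))
  ns <- matrix(nrow(m), k, k, dimnames = list(lines, lines))
  bad <- character()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      dij <- suppressWarnings(rogers_distance(m[, i], m[, j], min_shared))
      ns[i, j] <- ns[j, i] <- attr(dij, "n_shared")
      if (is.na(dij)) {
        bad <- c(bad, sprintf("%s-%s (%d shared loci)", lines[i], lines[j],
                              attr(dij, "n_shared")))
      } else {
        d[i, j] <- d[j, i] <- as.numeric(dij)
      }
    }
  }
  if (length(bad) > 0L) {
    abort(paste0("Undefined Rogers distance for pair(s): ",
                 paste(bad, collapse = "; "), "."))
  }
  structure(list(distance = d, n_shared = ns, labels = lines),
            class = "rogers_dist")
}

#' @export
print.rogers_dist <- function(x, ...) {
  cat(sprintf("Rogers distance matrix: %d lines\n", length(x$labels)))
  print(round(x$distance, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rogers_dist <- function(x, ...) {
  labs <- x$labels
  pairs <- which(upper.tri(x$distance), arr.ind = TRUE)
  tibble(
    line_1 = labs[pairs[, 1]],
    line_2 = labs[pairs[, 2]],
    distance = x$distance[pairs],
    n_shared = x$n_shared[pairs]
  )
}

#' @exportS3Method generics::glance
glance.rogers_dist <- function(x, ...) {
  d <- x$distance[upper.tri(x$distance)]
  tibble(
    n_lines = length(x$labels),
    mean_distance = mean(d),
    min_distance = min(d),
    max_distance = max(d),
    min_shared_loci = min(x$n_shared[upper.tri(x$n_shared)])
  )
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomerative algorithm: iteratively join the pair
#' minimising `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with
#' branch lengths from the standard two-point formulas. Ties in Q are
#' broken by the lowest (row, column) index pair for determinism. Negative
#' branch lengths are handled by the Kuhner-Felsenstein convention: clamped
#' to zero with the deficit transferred to the sister branch, preserving
#' the path length between the joined nodes. On a matrix exactly additive
#' on a binary tree with positive branch lengths, that tree (topology and
#' lengths) is recovered.
#'
#' @param d A `rogers_dist` object, a `dist`, or a symmetric numeric matrix
#'   with row/column names; at least 3 taxa.
#' @return An unrooted [ape::phylo] tree whose tips are the input labels.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "rogers_dist")) d <- d$distance
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort("`d` must be a square distance matrix.")
  }
  n <- nrow(d)
  if (n < 3L) abort("Neighbor joining requires at least 3 taxa.")
  labs <- rownames(d) %||% paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0)) {
    abort("`d` must be symmetric with a zero diagonal.")
  }
  reps <- labs  # newick fragment per active node
  D <- d
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(D) > 2L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- unique(t(apply(hits, 1, sort)))
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_rep <- sprintf("(%s:%s,%s:%s)", reps[i], fmt(li), reps[j], fmt(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    reps <- c(reps[keep], new_rep)
    D <- D2
  }
  # join the final two active nodes with a single edge
  len <- max(D[1, 2], 0)
  if (startsWith(reps[2], "(")) {
    inner <- substr(reps[2], 2, nchar(reps[2]) - 1L)
    newick <- sprintf("(%s,%s:%s);", inner, reps[1], fmt(len))
  } else if (startsWith(reps[1], "(")) {
    inner <- substr(reps[1], 2, nchar(reps[1]) - 1L)
    newick <- sprintf("(%s,%s:%s);", inner, reps[2], fmt(len))
  } else {
    newick <- sprintf("(%s:%s,%s:0);", reps[1], fmt(len), reps[2])
  }
  ape::read.tree(text = newick)
}

#' Do a set of leaves form a connected subtree?
#'
#' Tests whether the lines of each pedigree group form a connected subtree
#' of an unrooted tree (i.e. some edge separates exactly that leaf set from
#' the rest). Groups of size 1, or covering all but one leaf, are trivially
#' connected.
#'
#' @param tree An unrooted [ape::phylo] tree.
#' @param groups A line-group tibble (`line_id`, `group`).
#' @return A tibble `group`, `n_lines`, `monophyletic`.
#' @export
group_monophyly <- function(tree, groups) {
  validate_line_groups(groups)
  tips <- tree$tip.label
  out <- groups |>
    group_by(.data$group) |>
    summarise(lines = list(.data$line_id), .groups = "drop") |>
    mutate(
      n_lines = lengths(.data$lines),
      monophyletic = purrr::map_lgl(.data$lines, function(l) {
        l <- intersect(l, tips)
        if (length(l) <= 1L || length(l) >= length(tips) - 1L) return(TRUE)
        out_leaf <- setdiff(tips, l)[1]
        rooted <- ape::root(tree, outgroup = out_leaf, resolve.root = TRUE)
        ape::is.monophyletic(rooted, l)
      })
    ) |>
    select("group", "n_lines", "monophyletic")
  out
}
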