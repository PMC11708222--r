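#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch with linear gap penalties.  A column scores as a match
#' whenever the two IUPAC base sets intersect (so an `R` aligned to a `G`
#' is a match), as a mismatch otherwise.  Traceback ties are broken
#' deterministically: diagonal, then up (gap in `b`), then left (gap in
#' `a`).
#'
#' @param a,b nucleotide strings (IUPAC alphabet).
#' @param match,mismatch,gap scores (defaults +1, -1, -2).
#' @return list of class `pairwise_alignment`: `gapped_a`, `gapped_b`
#'   (equal-length strings over the alphabet plus `-`) and `score`.
#' @export
global_align <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  sa <- strip_gaps(as_seq_string(a))
  sb <- strip_gaps(as_seq_string(b))
  if (!nchar(sa) || !nchar(sb)) stop("sequences must be non-empty", call. = FALSE)
  res <- .nw_align_bits(seq_bits(sa), seq_bits(sb),
                        as.integer(match), as.integer(mismatch), as.integer(gap))
  ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
  ga <- ifelse(res$ai > 0L, ca[pmax(res$ai, 1L)], "-")
  gb <- ifelse(res$bi > 0L, cb[pmax(res$bi, 1L)], "-")
  structure(list(gapped_a = paste(ga, collapse = ""),
                 gapped_b = paste(gb, collapse = ""),
                 score = res$score),
            class = "pairwise_alignment")
}

#' Uncorrected p-distance from a pairwise alignment
#'
#' The proportion of differing columns with no substitution-model
#' correction.  A column differs when the two IUPAC base sets are disjoint
#' or when exactly one row is a gap -- internal gap columns count as
#' differences.  Terminal overhangs (columns before the first or after the
#' last position where both rows have a base) are excluded so that length
#' differences at the ends do not inflate the distance.
#'
#' @param aln a `pairwise_alignment` from [global_align()].
#' @return distance in `[0, 1]`.
#' @export
p_distance <- function(aln) {
  ba <- seq_bits(aln$gapped_a)
  bb <- seq_bits(aln$gapped_b)
  both <- which(ba > 0L & bb > 0L)
  if (!length(both)) stop("alignment has no columns with both sequences present",
                          call. = FALSE)
  span <- both[1L]:both[length(both)]
  ba <- ba[span]
  bb <- bb[span]
  diff <- (ba == 0L | bb == 0L) | bitwAnd(ba, bb) == 0L
  sum(diff) / length(span)
}

#' Define an analysis region within a gene
#'
#' 1-based inclusive nucleotide bounds relative to position 1 of the
#' analyzed region; `numbering_offset` is the number of nucleotides between
#' the start codon and that position 1 (0 when numbering starts at the
#' start codon).
#'
#' @param start_nt,end_nt region bounds.
#' @param numbering_offset offset from the start codon (default 0).
#' @return object of class `region_spec`.
#' @export
region_spec <- function(start_nt, end_nt, numbering_offset = 0L) {
  start_nt <- as.integer(start_nt)
  end_nt <- as.integer(end_nt)
  if (start_nt > end_nt) stop("region start must be <= end", call. = FALSE)
  if (start_nt < 1L) stop("region start must be >= 1", call. = FALSE)
  structure(list(start_nt = start_nt, end_nt = end_nt,
                 numbering_offset = as.integer(numbering_offset)),
            class = "region_spec")
}

#' Pairwise p-distance matrix for a sequence panel
#'
#' Optionally restricts every sequence to a [region_spec()] (applied before
#' alignment), then computes all pairwise global alignments and their
#' p-distances.
#'
#' @param seqs `isolate_set` data frame (>= 3 sequences).
#' @param region optional [region_spec()].
#' @param match,mismatch,gap alignment scores passed to [global_align()].
#' @return symmetric numeric matrix with isolate ids as dimnames.
#' @export
build_distance_matrix <- function(seqs, region = NULL,
                                  match = 1L, mismatch = -1L, gap = -2L) {
  if (nrow(seqs) < 3L) stop("need at least 3 sequences", call. = FALSE)
  ss <- vapply(seqs$seq, strip_gaps, character(1), USE.NAMES = FALSE)
  if (!is.null(region)) {
    from <- region$numbering_offset + region$start_nt
    to <- region$numbering_offset + region$end_nt
    short <- which(nchar(ss) < to)
    if (length(short)) {
      stop("region [", from, ", ", to, "] extends past sequence '",
           seqs$id[short[1L]], "' (", nchar(ss[short[1L]]), " nt)", call. = FALSE)
    }
    ss <- substr(ss, from, to)
  }
  n <- length(ss)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- p_distance(global_align(ss[i], ss[j],
                                                    match, mismatch, gap))
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical agglomerative neighbor joining: at each step the pair
#' minimizing the Q criterion
#' `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`
#' is joined, with limb lengths from the standard three-point formulas.
#' Ties are broken by the lowest pair of current indices; negative limb
#' lengths are clamped to zero.  For an additive distance matrix the
#' generating tree is recovered exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal and labels as
#'   dimnames (>= 3 taxa).
#' @return an unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-9) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node carries a newick fragment built bottom-up
  frags <- paste0("x", seq_len(n))  # placeholder labels, restored at the end
  act <- d
  while (nrow(act) > 3L) {
    r <- nrow(act)
    rs <- rowSums(act)
    q <- (r - 2) * act - outer(rs, rs, `+`)
    diag(q) <- Inf
    # lowest-index pair among ties, scanning i < j in order
    best <- c(1L, 2L)
    bestq <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        if (q[i, j] < bestq - 1e-12) {
          bestq <- q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- 0.5 * act[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- act[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_d <- 0.5 * (act[i, ] + act[j, ] - act[i, j])
    frag <- sprintf("(%s:%.12g,%s:%.12g)", frags[i], li, frags[j], lj)
    keep <- setdiff(seq_len(r), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], new_d[keep]),
                 c(new_d[keep], 0))
    frags <- c(frags[keep], frag)
  }
  # final three-way join: limb lengths from the three-point equations
  l1 <- 0.5 * (act[1, 2] + act[1, 3] - act[2, 3])
  l2 <- 0.5 * (act[1, 2] + act[2, 3] - act[1, 3])
  l3 <- 0.5 * (act[1, 3] + act[2, 3] - act[1, 2])
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frags[1L], max(l1, 0), frags[2L], max(l2, 0), frags[3L], max(l3, 0))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[as.integer(sub("^x", "", tree$tip.label))]
  tree
}

# quote a label for Newick if it contains metacharacters
newick_label <- function(x) {
  needs <- grepl("[][(),:;'\"[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a tree to a Newick file
#'
#' Branch lengths are written with 6 decimal places; labels containing
#' Newick metacharacters or whitespace are single-quoted.  The output
#' re-parses (e.g. with `ape::read.tree`) to an isomorphic tree.
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @return the Newick string, invisibly.
#' @export
write_newick <- function(tree, path = NULL) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  tips <- newick_label(tree$tip.label)
  recurse <- function(node) {
    kid_edges <- children[[as.character(node)]]
    parts <- vapply(kid_edges, function(e) {
      child <- tree$edge[e, 2L]
      sub <- if (child <= n_tip) tips[child] else recurse(child)
      if (!is.null(tree$edge.length)) {
        sprintf("%s:%.6f", sub, tree$edge.length[e])
      } else sub
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(recurse(root), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}

#' Score concordance of a tree with external clade labels
#'
#' For each clade label carried by at least two leaves, tests whether the
#' unrooted tree has an edge separating exactly those leaves from all other
#' labeled leaves (i.e. whether the label's members form a clan); unlabeled
#' leaves may fall on either side.  Returns the fraction of multi-member
#' labels that pass; a per-clade report is attached as attribute `report`.
#'
#' @param tree a `phylo` object.
#' @param clades named character vector mapping leaf id to clade label.
#' @return fraction in `[0, 1]`, with a `report` data frame attribute
#'   (columns `clade`, `size`, `monophyletic`).
#' @export
clade_concordance <- function(tree, clades) {
  tips <- tree$tip.label
  labeled <- intersect(tips, names(clades))
  lab <- clades[labeled]
  counts <- table(lab)
  test_labels <- names(counts)[counts >= 2L]
  if (!length(test_labels)) stop("nothing to test: no clade label has >= 2 leaves",
                                 call. = FALSE)
  labeled_idx <- match(labeled, tips)
  parts <- ape::prop.part(tree)  # tip-index sets, one per internal node
  part_sets <- lapply(parts, function(p) sort(intersect(p, labeled_idx)))
  comp_sets <- lapply(parts, function(p) sort(setdiff(labeled_idx, p)))
  all_sets <- c(part_sets, comp_sets)
  ok <- vapply(test_labels, function(cl) {
    members <- sort(labeled_idx[lab == cl])
    if (length(members) == length(labeled_idx)) return(TRUE)  # trivial split
    any(vapply(all_sets, function(s) identical(s, members), logical(1)))
  }, logical(1))
  report <- data.frame(clade = test_labels,
                       size = as.integer(counts[test_labels]),
                       monophyletic = unname(ok),
                       stringsAsFactors = FALSE)
  structure(mean(ok), report = report)
}

#' Write a square PHYLIP distance matrix
#' @param d symmetric labeled matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
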