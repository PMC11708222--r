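test_that("global alignment is optimal against exhaustive enumeration", {
  a <- global_align("ACGT", "ACGT")
  expect_equal(a$score, 4L)
  expect_equal(a$gapped_a, "ACGT")
  a <- global_align("ACGT", "AGT")
  expect_equal(a$gapped_b, "A-GT")
  expect_equal(a$score, 3L - 2L)
  a <- global_align("A", "T")
  expect_equal(a$score, -1L)
  expect_equal(nchar(a$gapped_a), 1L)
  set.seed(405)
  for (i in 1:20) {
    s1 <- random_dna(sample(1:6, 1))
    s2 <- random_dna(sample(1:6, 1))
    aln <- global_align(s1, s2)
    expect_equal(aln$score, brute_align_score(s1, s2),
                 info = paste(s1, s2))
    # removing gaps recovers the inputs; no gap/gap column
    expect_equal(gsub("-", "", aln$gapped_a), s1)
    expect_equal(gsub("-", "", aln$gapped_b), s2)
    cols <- cbind(strsplit(aln$gapped_a, "")[[1]], strsplit(aln$gapped_b, "")[[1]])
    expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
  }
})

paln <- function(a, b) structure(list(gapped_a = a, gapped_b = b, score = 0L),
                                 class = "pairwise_alignment")

test_that("p-distance counts disjoint columns and internal gaps", {
  expect_equal(p_distance(paln("ACGTACGTAC", "ACGTACGTAC")), 0)
  expect_equal(p_distance(paln("ACGTACGTAC", "TCGTACGTAC")), 0.1)
  expect_equal(p_distance(paln("A", "R")), 0)  # compatible sets
  expect_equal(p_distance(paln("ACG-ACGTAC", "ACGTACGTAC")), 0.1)  # internal gap
  # terminal overhangs excluded
  expect_equal(p_distance(paln("ACGTACGT---", "ACGTACGTTTT")), 0)
  expect_equal(p_distance(paln("AC", "AC")), 0)
  expect_error(p_distance(paln("--", "AA")), "no columns")
  # row swap invariance on random alignments
  set.seed(406)
  for (i in 1:5) {
    x <- global_align(random_dna(40), random_dna(40))
    expect_equal(p_distance(x), p_distance(paln(x$gapped_b, x$gapped_a)))
    expect_gte(p_distance(x), 0)
    expect_lte(p_distance(x), 1)
  }
})

test_that("distance matrices are symmetric with region extraction applied first", {
  seqs <- allelegeo:::isolate_set(c("a", "b", "c"), rep(random_dna(1950), 3))
  d <- build_distance_matrix(seqs, region = region_spec(819, 1904))
  expect_equal(unname(d), matrix(0, 3, 3))
  expect_equal(region_spec(819, 1904)$end_nt - region_spec(819, 1904)$start_nt + 1L,
               1086L)
  set.seed(407)
  seqs <- allelegeo:::isolate_set(letters[1:4],
                                  vapply(1:4, function(i) random_dna(80), ""))
  d <- build_distance_matrix(seqs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  short <- allelegeo:::isolate_set(c("a", "b", "tiny"),
                                   c(random_dna(2000), random_dna(2000), random_dna(100)))
  expect_error(build_distance_matrix(short, region = region_spec(819, 1904)), "tiny")
  expect_error(build_distance_matrix(seqs[1:2, ]), "at least 3")
})

test_that("neighbor joining solves 3 taxa in closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-9)
  # limbs solve the three-point equations: a = (dAB + dAC - dBC)/2 = 2
  a_edge <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(a_edge, 2)
})

test_that("neighbor joining recovers the additive 4-taxon split exactly", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 9, 10,
                3, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4, 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(d)
  pd <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(pd, d, tolerance = 1e-9)  # split AB|CD with exact lengths
  # the AB cherry exists: leaves A and B share a parent
  pa <- tr$edge[match(match(c("A", "B"), tr$tip.label), tr$edge[, 2]), 1]
  expect_equal(pa[1], pa[2])
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbor joining reconstructs random additive trees of 4-8 taxa", {
  set.seed(408)
  for (n in 4:8) {
    case <- random_additive_case(n)
    rec <- neighbor_joining(case$d)
    expect_equal(ape::dist.topo(ape::unroot(case$tree), rec), 0,
                 ignore_attr = TRUE)
    pd <- ape::cophenetic.phylo(rec)
    pd <- pd[rownames(case$d), colnames(case$d)]
    expect_equal(pd, case$d, tolerance = 1e-8)
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(409)
  case <- random_additive_case(7)
  ours <- neighbor_joining(case$d)
  apes <- ape::nj(case$d)
  expect_equal(ape::dist.topo(ours, apes), 0, ignore_attr = TRUE)
})

test_that("equal distances give a deterministic tie-broken tree", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- write_newick(neighbor_joining(d))
  t2 <- write_newick(neighbor_joining(d))
  expect_identical(t1, t2)
  # internal branch collapses to length 0
  internal <- neighbor_joining(d)$edge.length[
    neighbor_joining(d)$edge[, 2] > 4]
  expect_equal(internal, 0, tolerance = 1e-12)
})

test_that("Newick serialization round-trips and quotes awkward labels", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  nwk <- write_newick(tr)
  expect_match(nwk, "^\\(.*A:.*B:.*C:.*\\);$")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)

  tr$tip.label[1] <- "a b"
  expect_match(write_newick(tr), "'a b'", fixed = TRUE)
  back <- ape::read.tree(text = write_newick(tr))
  expect_true("'a b'" %in% back$tip.label)  # quoting keeps the label one token

  set.seed(410)
  case <- random_additive_case(6)
  back <- ape::read.tree(text = write_newick(case$tree))
  expect_equal(ape::dist.topo(back, ape::unroot(case$tree)), 0, ignore_attr = TRUE)
})

test_that("clade concordance tests clans of the unrooted tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(as.numeric(clade_concordance(tr, c(A = "x", C = "x", B = "y", D = "y"))),
               0)
  expect_equal(as.numeric(clade_concordance(tr, c(A = "x", B = "x", C = "y", D = "y"))),
               1)
  expect_equal(as.numeric(clade_concordance(tr, c(A = "x", B = "x", C = "x", D = "x"))),
               1)  # trivial split: all leaves
  # unlabeled leaves are ignored
  expect_equal(as.numeric(clade_concordance(tr, c(A = "x", B = "x", C = "y"))), 1)
  expect_error(clade_concordance(tr, c(A = "x", B = "y")), "nothing to test")
})
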