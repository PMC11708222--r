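test_that("IUPAC compatibility is set intersection, symmetric, strict on input", {
  expect_true(iupac_compatible("R", "G"))
  expect_true(iupac_compatible("R", "A"))
  expect_false(iupac_compatible("R", "T"))
  expect_false(iupac_compatible("Y", "R"))
  for (x in c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")) {
    expect_true(iupac_compatible("N", x))
    expect_equal(iupac_compatible(x, "W"), iupac_compatible("W", x))
  }
  expect_error(iupac_compatible("X", "A"), "non-IUPAC")
  expect_error(iupac_compatible("A", "-"), "non-IUPAC")
})

test_that("probes are the codon plus symmetric flanks, bounded by the CDS", {
  panel <- cached_panel()
  site223 <- panel$sites[[2L]]
  pr <- build_probe(panel, site223)
  expect_equal(nchar(pr$probe), 15L)
  expect_equal(pr$var_start, 7L)  # codon occupies window positions 7-9
  expect_equal(pr$probe, substr(panel$reference_cds, 3 * 223 - 8, 3 * 223 + 6))
  expect_error(build_probe(panel, site_marker("1", 1L, "M")), "boundary")
})

test_that("probe scanning finds IUPAC-compatible matches at shifted offsets", {
  panel <- cached_panel()
  ref <- panel$reference_cds
  pr <- build_probe(panel, panel$sites[[2L]])
  expect_equal(scan_for_probe(ref, pr), pr$ref_start)
  # a 10-nt insertion upstream shifts the unique match by +10
  ins <- paste0(substr(ref, 1, 50), "GATTACAGAT", substr(ref, 51, nchar(ref)))
  expect_equal(scan_for_probe(ins, pr), pr$ref_start + 10L)
  expect_length(scan_for_probe(random_dna(300), pr), 0L)
})

test_that("probe scanning agrees with a brute-force scan oracle", {
  set.seed(401)
  for (i in 1:15) {
    s <- paste0(random_dna(60), "RYK", random_dna(20))
    p <- substr(s, 31, 41)
    var_pos <- if (i %% 2 == 0) 5:7 else integer(0)
    probe <- if (length(var_pos)) {
      structure(list(site_id = "x", probe = p, var_start = 5L, ref_start = 31L),
                class = "site_probe")
    } else p
    expect_equal(scan_for_probe(s, probe), brute_scan(s, p, var_pos))
  }
})

test_that("site calls expand ambiguity codes into amino-acid sets", {
  panel <- cached_panel()
  ref <- panel$reference_cds
  site223 <- panel$sites[[2L]]
  cl <- call_site(ref, panel, site223)
  expect_equal(cl$aa_calls, "G")
  expect_equal(cl$status, "called")

  # GRT at codon 223 expands to {GAT, GGT} -> {D, G}
  het <- ref
  substr(het, 3 * 223 - 2, 3 * 223) <- "GRT"
  cl <- call_site(het, panel, site223)
  expect_equal(cl$aa_calls, c("D", "G"))
  expect_equal(cl$status, "het")

  # mutate the flanks away -> not_found
  broken <- ref
  substr(broken, 3 * 223 - 8, 3 * 223 - 3) <- "AAAAAA"
  substr(broken, 3 * 223 + 1, 3 * 223 + 6) <- "TTTTTT"
  expect_equal(call_site(broken, panel, site223)$status, "not_found")

  # a second copy of the probe region -> multiple_hits, untypable
  pr <- build_probe(panel, site223)
  dup <- paste0(ref, pr$probe)
  expect_equal(call_site(dup, panel, site223)$status, "multiple_hits")
  expect_false(type_isolate(dup, panel)$typable)

  # an amino acid outside the configured alleles is reported verbatim
  novel <- ref
  substr(novel, 3 * 223 - 2, 3 * 223) <- "TGG"  # Trp
  cl <- call_site(novel, panel, site223)
  expect_equal(cl$aa_calls, "W")
  expect_equal(cl$status, "novel")
  expect_match(type_isolate(novel, panel)$key, "223W")
})

test_that("deletion calling measures the anchor gap and surviving repeat", {
  panel <- cached_panel()
  ref <- panel$reference_cds
  fl <- call_deletion(ref, panel)
  expect_equal(fl$state, "full_length")
  expect_equal(fl$observed_gap_nt, 0L)
  expect_equal(fl$repeat_copies, 2L)

  del <- plant_genotype(ref, "189A-223G-405L-475L-Δ", panel)
  expect_equal(nchar(ref) - nchar(del), 108L)
  dc <- call_deletion(del, panel)
  expect_equal(dc$state, "deleted")
  expect_equal(dc$observed_gap_nt, 108L)
  expect_equal(dc$repeat_copies, 1L)

  scrambled <- ref
  bs <- 3 * (524 - 1) + 1
  substr(scrambled, bs - 15, bs - 1) <- paste(rep("A", 15), collapse = "")
  expect_equal(call_deletion(scrambled, panel)$state, "undetermined")
})

test_that("ORF translation reports truncation and frameshift", {
  r <- translate_orf("ATGAAATAA", "ATGAAATAA")
  expect_equal(r$protein_len, 2L)
  expect_true(r$stop_found)
  expect_false(r$frameshifted)

  ref <- cached_panel()$reference_cds
  # single-nucleotide deletion inside codon 138 -> truncation after 148 residues
  mut <- paste0(substr(ref, 1, 412), substr(ref, 414, nchar(ref)))
  r <- translate_orf(mut, ref)
  expect_equal(r$protein_len, 148L)
  expect_true(r$frameshifted)
  expect_equal(r$first_indel_codon, 138L)
  expect_equal(r$net_indel_nt, -1L)

  nostop <- "ATGAAACCC"
  r <- translate_orf(nostop, nostop)
  expect_false(r$stop_found)
  expect_equal(r$protein_len, 3L)
  expect_error(translate_orf("AT", "ATG"), "shorter than one codon")

  # intact reference: no frameshift, stop at the final codon
  r <- translate_orf(ref, ref)
  expect_false(r$frameshifted)
  expect_equal(r$protein_len, nchar(ref) / 3 - 1)
})

test_that("composite keys reproduce the canonical allele-group labels", {
  panel <- cached_panel()
  ref <- panel$reference_cds
  expect_equal(type_isolate(ref, panel)$key, "189A-223G-405L-475L-FL")
  acd <- plant_genotype(ref, "189A-223S-405S-475L-FL", panel)
  expect_equal(type_isolate(acd, panel)$key, "189A-223S-405S-475L-FL")
  het <- plant_genotype(ref, "189A/T-223D/G-405L-475H/L-FL", panel)
  g <- type_isolate(het, panel)
  expect_equal(g$key, "189A/T-223D/G-405L-475H/L-FL")
  expect_true(g$typable)
  # deterministic and idempotent
  expect_identical(g$key, type_isolate(het, panel)$key)
})

test_that("site calls are invariant to indels outside probe windows", {
  panel <- cached_panel()
  ref <- panel$reference_cds
  base_key <- type_isolate(ref, panel)$key
  prot <- allelegeo:::protected_positions(panel)
  open <- setdiff(seq_len(nchar(ref)), prot)
  # insertion points where the left and right neighbours are both open
  ins_ok <- open[open > 3 & (open - 1) %in% open]
  runs <- split(open, cumsum(c(1, diff(open) != 1)))
  set.seed(402)
  for (i in 1:8) {
    p <- sample(ins_ok, 1)
    n_ins <- sample(1:30, 1)
    mutated <- paste0(substr(ref, 1, p - 1), random_dna(n_ins),
                      substr(ref, p, nchar(ref)))
    expect_identical(type_isolate(mutated, panel)$key, base_key)
    # deletion fully inside an open run
    long_runs <- runs[lengths(runs) >= 12]
    run <- long_runs[[sample(length(long_runs), 1)]]
    n_del <- sample(1:min(30, length(run) - 2), 1)
    from <- run[1] + 1
    mutated <- paste0(substr(ref, 1, from - 1), substr(ref, from + n_del, nchar(ref)))
    expect_identical(type_isolate(mutated, panel)$key, base_key)
  }
})

test_that("IUPAC union of two homozygous codons calls both alleles", {
  panel <- cached_panel()
  ref <- panel$reference_cds
  set.seed(403)
  for (site in panel$sites) {
    alleles <- names(site$allele_map)
    pair <- sample(alleles, 2L)
    at <- 3 * site$codon_index - 2
    ref_codon <- substr(ref, at, at + 2)
    c1 <- allelegeo:::choose_site_codon(ref_codon, pair[1L])
    c2 <- allelegeo:::choose_site_codon(ref_codon, pair[2L])
    s1 <- ref; substr(s1, at, at + 2) <- c1
    s2 <- ref; substr(s2, at, at + 2) <- c2
    expect_equal(call_site(s1, panel, site)$aa_calls, pair[1L])
    expect_equal(call_site(s2, panel, site)$aa_calls, pair[2L])
    u <- ref; substr(u, at, at + 2) <- allelegeo:::iupac_union(c1, c2)
    expect_true(all(pair %in% call_site(u, panel, site)$aa_calls))
  }
})

test_that("SNP counting uses disjoint base sets and honours masks", {
  s <- random_dna(200)
  expect_equal(count_snp_differences(s, s), 0L)
  mut <- s
  substr(mut, 50, 50) <- if (substr(s, 50, 50) == "A") "C" else "A"
  substr(mut, 120, 120) <- if (substr(s, 120, 120) == "G") "T" else "G"
  expect_equal(count_snp_differences(s, mut), 2L)
  expect_equal(count_snp_differences(s, mut, mask = c(40, 60)), 1L)
  # an ambiguity code overlapping the base contributes 0
  amb <- s
  substr(amb, 10, 10) <- "N"
  expect_equal(count_snp_differences(s, amb), 0L)
  # unequal lengths are aligned first; gap columns are excluded
  indel <- paste0(substr(s, 1, 99), substr(s, 103, 200))
  expect_equal(count_snp_differences(s, indel), 0L)
})
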