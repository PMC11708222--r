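# Independent oracles and small builders shared across test files.

# Exhaustive global-alignment score: enumerates every monotone alignment
# path recursively (no dynamic programming), for sequences of a few nt.
brute_align_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0L)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      col <- if (iupac_compatible(ca[i], cb[j])) match else mismatch
      best <- max(best, col + rec(i + 1L, j + 1L))
    }
    if (i <= length(ca)) best <- max(best, gap + rec(i + 1L, j))
    if (j <= length(cb)) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# Brute-force probe scan: nested loops over offsets and positions.
brute_scan <- function(seq, probe_str, var_pos = integer(0)) {
  n <- nchar(seq); L <- nchar(probe_str)
  hits <- integer(0)
  for (off in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      if (k %in% var_pos) next
      if (!iupac_compatible(substr(seq, off + k - 1L, off + k - 1L),
                            substr(probe_str, k, k))) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# A random unrooted tree with positive branch lengths and its (additive)
# patristic distance matrix.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- round(runif(nrow(tr$edge), 0.1, 1), 3)
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

textConnection_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_panel <- function() {
  ref <- make_reference()
  marker_panel(ref, allelegeo:::ho5_sites(), deletion_marker(524, 559, 8),
               panel_id = "HO-5site-test")
}

# cached across tests within a file run
.cache <- new.env()
cached_panel <- function() {
  if (is.null(.cache$panel)) .cache$panel <- test_panel()
  .cache$panel
}

# small fast simulation used by several tests
small_sim_spec <- function(seed = 11, background_sub_rate = 0, n_members = 3L,
                           groups = NULL) {
  if (is.null(groups)) {
    groups <- allelegeo:::default_sim_groups()[1:3]
    for (i in seq_along(groups)) groups[[i]]$n_members <- n_members
  }
  sim_spec(groups = groups, background_sub_rate = background_sub_rate, seed = seed)
}
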