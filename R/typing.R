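# Anchor probe length (nt) used on both sides of the deletable block.
DEL_ANCHOR_LEN <- 15L

#' Build the search probe for a diagnostic site
#'
#' The probe is the reference window `[3c - 2 - f, 3c + f]` around codon `c`
#' with flank `f`; the three codon positions are the variable slot, left
#' unconstrained during the scan so that any allele (including heterozygous
#' ambiguity codes) at the site still matches.
#'
#' @param panel a [marker_panel()].
#' @param site a [site_marker()] belonging to the panel.
#' @return object of class `site_probe` with fields `probe` (the window),
#'   `var_start` (1-based offset of the codon inside the window) and
#'   `site_id`.
#' @export
build_probe <- function(panel, site) {
  c3 <- 3L * site$codon_index
  from <- c3 - 2L - site$flank_nt
  to <- c3 + site$flank_nt
  if (from < 1L || to > nchar(panel$reference_cds)) {
    stop("site '", site$site_id,
         "': probe window extends past the reference CDS boundary", call. = FALSE)
  }
  structure(list(site_id = site$site_id,
                 probe = substr(panel$reference_cds, from, to),
                 var_start = site$flank_nt + 1L,
                 ref_start = from),
            class = "site_probe")
}

#' Scan a sequence for an IUPAC-compatible probe match
#'
#' Slides the probe along the sequence and reports every start position
#' (1-based) at which all constrained probe positions are
#' [iupac_compatible()] with the sequence.  For a `site_probe` the three
#' codon positions are unconstrained; a plain character probe is fully
#' constrained.  Matching is by ambiguity-set intersection, so heterozygous
#' positions encoded as IUPAC codes still match, and the search is
#' coordinate-free: indels elsewhere in the sequence only shift the reported
#' offset.
#'
#' @param seq nucleotide string.
#' @param probe a `site_probe` from [build_probe()] or a plain string.
#' @return integer vector of 1-based match start positions (possibly empty).
#' @export
scan_for_probe <- function(seq, probe) {
  var_pos <- integer(0)
  if (inherits(probe, "site_probe")) {
    var_pos <- probe$var_start + 0:2
    probe <- probe$probe
  }
  sb <- seq_bits(seq)
  pb <- seq_bits(probe)
  L <- length(pb)
  n_off <- length(sb) - L + 1L
  if (n_off < 1L) return(integer(0))
  keep <- setdiff(seq_len(L), var_pos)
  ok <- rep(TRUE, n_off)
  for (j in keep) {
    ok <- ok & bitwAnd(sb[j:(j + n_off - 1L)], pb[j]) > 0L
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

#' Call the genotype at one diagnostic site
#'
#' Locates the site's probe in the (gap-stripped) isolate sequence; a unique
#' match is required.  The three observed codon characters are expanded over
#' their IUPAC base sets into concrete codons and translated with the
#' standard genetic code; the resulting amino-acid set is the call.  One
#' amino acid gives status `called` (or `novel` when it is outside the
#' site's configured alleles); two or more give `het`; no probe match gives
#' `not_found` and multiple matches `multiple_hits` (the isolate is then
#' untypable rather than silently mistyped).
#'
#' @param seq nucleotide string or single-row `isolate_set`.
#' @param panel a [marker_panel()].
#' @param site a [site_marker()] from the panel.
#' @return list of class `site_call`: `site_id`, `aa_calls` (sorted), `status`.
#' @export
call_site <- function(seq, panel, site) {
  s <- strip_gaps(as_seq_string(seq))
  probe <- build_probe(panel, site)
  hits <- scan_for_probe(s, probe)
  if (length(hits) == 0L) {
    return(site_call(site$site_id, character(0), "not_found"))
  }
  if (length(hits) > 1L) {
    return(site_call(site$site_id, character(0), "multiple_hits"))
  }
  at <- hits[1L] + probe$var_start - 1L
  aas <- codon_aas(substr(s, at, at + 2L))
  status <- if (length(aas) >= 2L) {
    "het"
  } else if (aas %in% names(site$allele_map)) "called" else "novel"
  site_call(site$site_id, aas, status)
}

site_call <- function(site_id, aa_calls, status) {
  structure(list(site_id = site_id, aa_calls = aa_calls, status = status),
            class = "site_call")
}

as_seq_string <- function(seq) {
  if (inherits(seq, "isolate_set") || is.data.frame(seq)) seq$seq[1L] else as.character(seq)[1L]
}

strip_gaps <- function(s) gsub("-", "", s, fixed = TRUE)

#' Call the deletion state of the repeat-flanked block
#'
#' Two anchor probes are taken from the reference: one immediately upstream
#' of the deletable block and one immediately downstream of the second
#' repeat copy.  Both are located in the isolate sequence by IUPAC-aware
#' scanning; the difference between the expected and observed number of
#' nucleotides between them is the gap.  A gap of zero is `full_length`; a
#' gap equal to the block length (3 x block codons; 108 nt for a 36-codon
#' block) is `deleted`; missing or ambiguous anchors, or any other gap, give
#' `undetermined`.  As a consistency check the number of copies of the
#' direct repeat found between the anchors is reported (two expected in a
#' full-length allele, one in a deleted allele); it does not affect the
#' state.  A heterozygous deletion (one full-length and one deleted allele)
#' cannot be encoded by a single IUPAC string and surfaces as `undetermined`.
#'
#' @param seq nucleotide string or single-row `isolate_set`.
#' @param panel a [marker_panel()] with a deletion marker.
#' @return list of class `deletion_call`: `state`, `observed_gap_nt`,
#'   `repeat_copies`.
#' @export
call_deletion <- function(seq, panel) {
  del <- panel$deletion
  if (is.null(del)) stop("panel has no deletion marker", call. = FALSE)
  s <- strip_gaps(as_seq_string(seq))
  ref <- panel$reference_cds
  bs <- 3L * (del$start_codon - 1L) + 1L   # first nt of the block
  be <- 3L * del$end_codon                 # last nt of the block
  rl <- del$repeat_len_nt
  block_nt <- deletion_block_nt(del)

  up_anchor <- substr(ref, bs - DEL_ANCHOR_LEN, bs - 1L)
  down_anchor <- substr(ref, be + rl + 1L, be + rl + DEL_ANCHOR_LEN)
  up_hits <- scan_for_probe(s, up_anchor)
  down_hits <- scan_for_probe(s, down_anchor)
  if (length(up_hits) != 1L || length(down_hits) != 1L) {
    return(deletion_call("undetermined", NA_integer_, NA_integer_))
  }
  between_start <- up_hits + DEL_ANCHOR_LEN
  between_end <- down_hits - 1L
  observed_between <- between_end - between_start + 1L
  expected_between <- block_nt + rl
  gap <- expected_between - observed_between

  repeat_seq <- substr(ref, bs, bs + rl - 1L)
  copies <- if (observed_between >= rl) {
    length(scan_for_probe(substr(s, between_start, between_end), repeat_seq))
  } else 0L

  state <- if (gap == 0L) "full_length" else if (gap == block_nt) "deleted" else "undetermined"
  deletion_call(state, as.integer(gap), as.integer(copies))
}

deletion_call <- function(state, observed_gap_nt, repeat_copies) {
  structure(list(state = state, observed_gap_nt = observed_gap_nt,
                 repeat_copies = repeat_copies),
            class = "deletion_call")
}

#' Translate an open reading frame and detect frameshift truncation
#'
#' Translates the sequence codon by codon with the standard genetic code
#' until the first stop codon (ambiguity codes translate to their amino-acid
#' set; a codon counts as a stop only when every expansion is a stop).  The
#' sequence is then globally aligned to the reference to locate insertions
#' and deletions; the ORF is frameshifted when the running net indel length
#' is not a multiple of 3 at any point before the stop.
#'
#' @param seq nucleotide string or single-row `isolate_set`, starting at the
#'   start codon.
#' @param reference reference CDS string.
#' @return list of class `orf_report`: `protein_len` (residues before the
#'   first stop), `stop_found`, `net_indel_nt` (net indel up to the stop),
#'   `frameshifted`, `first_indel_codon` (1-based reference codon of the
#'   first indel, or NA).
#' @export
translate_orf <- function(seq, reference) {
  s <- strip_gaps(as_seq_string(seq))
  if (nchar(s) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  n_codons <- nchar(s) %/% 3L
  protein_len <- n_codons
  stop_found <- FALSE
  for (i in seq_len(n_codons)) {
    aas <- codon_aas(substr(s, 3L * i - 2L, 3L * i))
    if (all(aas == "*")) {
      protein_len <- i - 1L
      stop_found <- TRUE
      break
    }
  }
  stop_end_nt <- if (stop_found) 3L * protein_len + 3L else nchar(s)

  aln <- global_align(reference, s)
  ra <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1L]]
  sa <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1L]]
  ref_pos <- 0L
  seq_pos <- 0L
  net <- 0L
  frameshifted <- FALSE
  first_indel_codon <- NA_integer_
  for (k in seq_along(ra)) {
    if (ra[k] != "-") ref_pos <- ref_pos + 1L
    if (sa[k] != "-") seq_pos <- seq_pos + 1L
    if (ra[k] == "-") {            # insertion relative to the reference
      net <- net + 1L
      if (is.na(first_indel_codon)) first_indel_codon <- (ref_pos %/% 3L) + 1L
    } else if (sa[k] == "-") {     # deletion relative to the reference
      net <- net - 1L
      if (is.na(first_indel_codon)) first_indel_codon <- ((ref_pos - 1L) %/% 3L) + 1L
    }
    if (net %% 3L != 0L) frameshifted <- TRUE
    if (seq_pos >= stop_end_nt) break
  }
  structure(list(protein_len = protein_len, stop_found = stop_found,
                 net_indel_nt = net, frameshifted = frameshifted,
                 first_indel_codon = first_indel_codon),
            class = "orf_report")
}

#' Type one isolate against a marker panel
#'
#' Runs [call_site()] for every panel site in order, [call_deletion()] when
#' the panel defines a deletion block, and [translate_orf()] against the
#' panel reference, then assembles the canonical composite genotype key:
#' site calls in panel order (heterozygous alleles sorted alphabetically and
#' joined by `/`), followed by the deletion state suffix `FL` (full length)
#' or `\u0394` (deleted).  Sites with no probe match are keyed `?` and sites
#' with multiple probe matches `!`; either makes the isolate untypable.
#' Isolates share an allele group exactly when their keys are identical.
#'
#' @param seq nucleotide string or single-row `isolate_set`.
#' @param panel a [marker_panel()].
#' @param id optional isolate id carried into the result.
#' @return list of class `composite_genotype` with fields `id`,
#'   `site_calls`, `deletion_call`, `orf`, `key`, `typable`.
#' @export
type_isolate <- function(seq, panel, id = NULL) {
  if (is.null(id) && (inherits(seq, "isolate_set") || is.data.frame(seq))) id <- seq$id[1L]
  s <- strip_gaps(as_seq_string(seq))
  calls <- lapply(panel$sites, function(site) call_site(s, panel, site))
  del <- if (!is.null(panel$deletion)) call_deletion(s, panel) else NULL
  orf <- translate_orf(s, panel$reference_cds)
  parts <- vapply(calls, function(cl) {
    tag <- switch(cl$status, not_found = "?", multiple_hits = "!",
                  paste(cl$aa_calls, collapse = "/"))
    paste0(cl$site_id, tag)
  }, character(1))
  if (!is.null(del)) {
    suffix <- switch(del$state, full_length = "FL", deleted = "\u0394", "?")
    parts <- c(parts, suffix)
  }
  typable <- !any(vapply(calls, function(cl) cl$status %in% c("not_found", "multiple_hits"),
                         logical(1)))
  structure(list(id = id, site_calls = calls, deletion_call = del, orf = orf,
                 key = paste(parts, collapse = "-"), typable = typable),
            class = "composite_genotype")
}

#' Type every isolate in a panel of sequences
#'
#' @param seqs `isolate_set` data frame.
#' @param panel a [marker_panel()].
#' @return named list of `composite_genotype` objects, one per isolate.
#' @export
type_panel <- function(seqs, panel) {
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    type_isolate(seqs$seq[i], panel, id = seqs$id[i])
  })
  setNames(out, seqs$id)
}

#' Tabulate composite genotypes
#'
#' One row per isolate: the per-site calls, deletion state, ORF columns and
#' the composite key.  Panels without a deletion marker report `n/a` for the
#' deletion state.
#'
#' @param genotypes named list from [type_panel()].
#' @return data frame.
#' @export
call_table <- function(genotypes) {
  if (!length(genotypes)) {
    return(data.frame(id = character(0), key = character(0), typable = logical(0)))
  }
  site_ids <- vapply(genotypes[[1L]]$site_calls, `[[`, character(1), "site_id")
  rows <- lapply(genotypes, function(g) {
    site_vals <- vapply(g$site_calls, function(cl) {
      if (length(cl$aa_calls)) paste(cl$aa_calls, collapse = "/") else cl$status
    }, character(1))
    df <- as.data.frame(as.list(setNames(site_vals, paste0("site_", site_ids))),
                        stringsAsFactors = FALSE)
    df$deletion <- if (is.null(g$deletion_call)) "n/a" else g$deletion_call$state
    df$protein_len <- g$orf$protein_len
    df$frameshifted <- g$orf$frameshifted
    df$first_indel_codon <- g$orf$first_indel_codon
    df$key <- g$key
    df$typable <- g$typable
    cbind(data.frame(id = g$id, stringsAsFactors = FALSE), df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count SNP differences between two sequences
#'
#' Sequences of equal length are compared column by column; otherwise they
#' are globally aligned first.  A column counts as a difference when the two
#' IUPAC base sets are disjoint; gap columns are excluded, as is an optional
#' masked interval (1-based, in the coordinates of `a`).
#'
#' @param a,b nucleotide strings or single-row `isolate_set`s.
#' @param mask optional `c(start, end)` interval in `a` coordinates to skip.
#' @return integer count.
#' @export
count_snp_differences <- function(a, b, mask = NULL) {
  sa <- strip_gaps(as_seq_string(a))
  sb <- strip_gaps(as_seq_string(b))
  if (nchar(sa) == nchar(sb)) {
    ga <- sa; gb <- sb
  } else {
    aln <- global_align(sa, sb)
    ga <- aln$gapped_a; gb <- aln$gapped_b
  }
  ba <- seq_bits(ga)
  bb <- seq_bits(gb)
  both <- ba > 0L & bb > 0L
  if (!any(both)) stop("sequences have no aligned overlap", call. = FALSE)
  apos <- cumsum(ba > 0L)   # a-coordinate of each column
  keep <- both
  if (!is.null(mask)) keep <- keep & !(apos >= mask[1L] & apos <= mask[2L] & ba > 0L)
  sum(keep & bitwAnd(ba, bb) == 0L)
}
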