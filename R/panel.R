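#' Define a diagnostic codon site
#'
#' A site is typed by searching for a short probe -- the reference sequence
#' surrounding the codon -- rather than by fixed coordinates, so indels
#' elsewhere in an isolate's sequence do not shift the call.  The probe is
#' the codon plus `flank_nt` reference nucleotides on each side; its total
#' length `2 * flank_nt + 3` must lie in 7..16 nucleotides.
#'
#' @param site_id short label used in composite genotype keys (convention:
#'   the residue number, e.g. `"223"`).
#' @param codon_index 1-based codon number in the reference CDS.
#' @param alleles amino-acid letters expected at this site; calls outside
#'   this set are flagged `novel` but still reported verbatim.
#' @param flank_nt flanking nucleotides per side (default 6, a 15-nt probe).
#' @return object of class `site_marker`.
#' @export
site_marker <- function(site_id, codon_index, alleles, flank_nt = 6L) {
  flank_nt <- as.integer(flank_nt)
  wlen <- 2L * flank_nt + 3L
  if (wlen < 7L || wlen > 16L) {
    stop(sprintf("site '%s': probe window %d nt outside the allowed 7-16 nt range",
                 site_id, wlen), call. = FALSE)
  }
  alleles <- unique(toupper(alleles))
  allele_map <- setNames(lapply(alleles, codons_for_aa), alleles)
  empty <- lengths(allele_map) == 0L
  if (any(empty)) {
    stop("site '", site_id, "': no codon encodes amino acid '",
         alleles[empty][1L], "'", call. = FALSE)
  }
  structure(list(site_id = as.character(site_id),
                 codon_index = as.integer(codon_index),
                 flank_nt = flank_nt, allele_map = allele_map),
            class = "site_marker")
}

#' Define a repeat-flanked deletion region
#'
#' Describes an internal block of codons (`start_codon`..`end_codon`,
#' inclusive) that can be cleanly excised by recombination between two
#' direct repeats of `repeat_len_nt` nucleotides.  The first repeat copy
#' occupies the first `repeat_len_nt` nucleotides of the block and the
#' second copy the `repeat_len_nt` nucleotides immediately after it, so that
#' recombination retaining a single copy removes exactly the block.
#'
#' @param start_codon,end_codon 1-based inclusive codon bounds.
#' @param repeat_len_nt direct repeat length in nucleotides (default 8).
#' @return object of class `deletion_marker`.
#' @export
deletion_marker <- function(start_codon, end_codon, repeat_len_nt = 8L) {
  start_codon <- as.integer(start_codon)
  end_codon <- as.integer(end_codon)
  if (end_codon < start_codon) stop("end_codon must be >= start_codon", call. = FALSE)
  structure(list(start_codon = start_codon, end_codon = end_codon,
                 repeat_len_nt = as.integer(repeat_len_nt)),
            class = "deletion_marker")
}

# nt length of the deletable block
deletion_block_nt <- function(del) 3L * (del$end_codon - del$start_codon + 1L)

#' Assemble a marker panel
#'
#' Binds a reference CDS to an ordered list of diagnostic sites and an
#' optional deletion region.  The site order given here is the order used in
#' composite genotype keys and in all tabular output.
#'
#' @param reference_cds reference coding sequence (A/C/G/T, length divisible
#'   by 3, starting with ATG).
#' @param sites list of [site_marker()] objects, in reporting order.
#' @param deletion optional [deletion_marker()].
#' @param panel_id panel label.
#' @param numbering_offset nucleotides between the start codon and position
#'   1 of the analyzed region (0 when the region is the whole CDS).
#' @return object of class `marker_panel`.
#' @export
marker_panel <- function(reference_cds, sites, deletion = NULL,
                         panel_id = "panel", numbering_offset = 0L) {
  reference_cds <- toupper(chartr("uU", "tT", reference_cds))
  n <- nchar(reference_cds)
  if (n %% 3L != 0L) stop("reference CDS length must be divisible by 3", call. = FALSE)
  if (substr(reference_cds, 1L, 3L) != "ATG") {
    stop("reference CDS must start with ATG", call. = FALSE)
  }
  seq_bits(reference_cds)  # validates the alphabet
  n_codons <- n %/% 3L
  for (s in sites) {
    if (!inherits(s, "site_marker")) stop("sites must be site_marker objects", call. = FALSE)
    if (s$codon_index < 1L || s$codon_index > n_codons) {
      stop("site '", s$site_id, "': codon ", s$codon_index,
           " outside the reference CDS (", n_codons, " codons)", call. = FALSE)
    }
  }
  if (!is.null(deletion)) {
    if (!inherits(deletion, "deletion_marker")) {
      stop("deletion must be a deletion_marker", call. = FALSE)
    }
    if (3L * deletion$end_codon + deletion$repeat_len_nt + DEL_ANCHOR_LEN > n) {
      stop("deletion region too close to the end of the CDS for anchor probes",
           call. = FALSE)
    }
    if (3L * (deletion$start_codon - 1L) < DEL_ANCHOR_LEN) {
      stop("deletion region too close to the start of the CDS for anchor probes",
           call. = FALSE)
    }
  }
  structure(list(panel_id = as.character(panel_id),
                 reference_cds = reference_cds,
                 sites = sites, deletion = deletion,
                 numbering_offset = as.integer(numbering_offset)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel '%s': %d-codon reference, %d site(s)%s\n",
              x$panel_id, nchar(x$reference_cds) %/% 3L, length(x$sites),
              if (is.null(x$deletion)) "" else
                sprintf(", deletion %d-%d (repeat %d nt)",
                        x$deletion$start_codon, x$deletion$end_codon,
                        x$deletion$repeat_len_nt)))
  invisible(x)
}

#' Read a marker-panel configuration
#'
#' The configuration is a YAML (or JSON) document naming a reference CDS
#' FASTA (resolved relative to the config file), the ordered diagnostic
#' sites, and an optional deletion block:
#'
#' ```yaml
#' panel_id: HO-5site
#' reference_fasta: ho5_synthetic_reference.fasta
#' sites:
#'   - {site_id: "189", codon: 189, flank_nt: 6, alleles: [A, T, S]}
#' deletion: {start_codon: 524, end_codon: 559, repeat_len_nt: 8}
#' ```
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return a validated [marker_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$reference_fasta)) stop("panel config must name reference_fasta", call. = FALSE)
  ref_path <- cfg$reference_fasta
  if (!file.exists(ref_path)) ref_path <- file.path(dirname(path), cfg$reference_fasta)
  ref <- read_fasta(ref_path)
  sites <- lapply(cfg$sites, function(s) {
    site_marker(s$site_id, s$codon, s$alleles,
                flank_nt = if (is.null(s$flank_nt)) 6L else s$flank_nt)
  })
  del <- if (!is.null(cfg$deletion)) {
    d <- cfg$deletion
    deletion_marker(d$start_codon, d$end_codon,
                    if (is.null(d$repeat_len_nt)) 8L else d$repeat_len_nt)
  }
  marker_panel(ref$seq[1L], sites, del,
               panel_id = if (is.null(cfg$panel_id)) "panel" else cfg$panel_id,
               numbering_offset = if (is.null(cfg$numbering_offset)) 0L else cfg$numbering_offset)
}

# Default site set of the shipped 5-region panel: four single-residue sites
# plus the 36-codon deletable block at residues 524-559.
ho5_sites <- function(flank_nt = 6L) {
  list(site_marker("189", 189L, c("A", "T", "S"), flank_nt),
       site_marker("223", 223L, c("G", "D", "S"), flank_nt),
       site_marker("405", 405L, c("L", "S"), flank_nt),
       site_marker("475", 475L, c("L", "H"), flank_nt))
}

#' The shipped default 5-region marker panel
#'
#' Loads the packaged `HO-5site` panel: diagnostic codons 189, 223, 405 and
#' 475 plus the deletable 36-codon block at residues 524-559 flanked by an
#' 8-nt direct repeat, on a packaged synthetic reference CDS of 586 codons
#' (the reference is synthetic -- generated by [make_reference()] -- not a
#' deposited gene sequence).
#'
#' @return a [marker_panel()].
#' @export
ho5_panel <- function() {
  read_panel(system.file("extdata", "ho5_panel.yaml", package = "allelegeo",
                         mustWork = TRUE))
}
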