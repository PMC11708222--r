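STOP_CODONS <- c("TAA", "TAG", "TGA")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

NONSTOP_CODONS <- {
  all3 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                          c("A", "C", "G", "T"), paste0))
  sort(setdiff(all3, STOP_CODONS))
}

# Fixed direct-repeat sequence written at both ends of the deletable block.
# "CA"-led codons can never create a stop at either insertion point.
SIM_REPEAT <- "CAGGTCCA"

# Panel geometry shared by the generator and the shipped default panel.
SIM_SITE_CODONS <- c(`189` = 189L, `223` = 223L, `405` = 405L, `475` = 475L)
SIM_SITE_REF <- c(`189` = "GCT", `223` = "GGT", `405` = "CTT", `475` = "CTG")
SIM_DEL_START <- 524L
SIM_DEL_END <- 559L
SIM_FRAMESHIFT_CODON <- 138L

#' Generate the synthetic reference CDS
#'
#' Builds a random coding sequence of `n_codons` codons that starts with
#' ATG, ends with a stop, and has no internal in-frame stop, with three
#' engineered features: (1) identical 8-nt direct repeats at the boundaries
#' of the 36-codon deletable block (residues 524-559) -- the first copy is
#' the first 8 nt of the block, the second the 8 nt immediately after it,
#' so recombination keeping one copy excises exactly the block; (2) the
#' region around codon 138 is arranged so that a single-nucleotide deletion
#' inside codon 138 shifts the frame onto a stop right after residue 148,
#' reproducing a naturally observed truncation architecture; (3) reference
#' alleles at the four diagnostic codons (A189, G223, L405, L475).  The
#' construction is deterministic for a given seed; probes, anchors and the
#' repeat are verified unique so that probe scans cannot be ambiguous.
#'
#' @param n_codons reference length in codons (default 586; must leave room
#'   for the deletion block and its downstream anchor).
#' @param seed RNG seed for the random background codons (default 42; the
#'   packaged reference uses this default).
#' @return reference CDS string.
#' @export
make_reference <- function(n_codons = 586L, seed = 42L) {
  n_codons <- as.integer(n_codons)
  min_needed <- ceiling((3L * SIM_DEL_END + nchar(SIM_REPEAT) + DEL_ANCHOR_LEN) / 3) + 1L
  if (n_codons < min_needed) {
    stop("n_codons too small for the deletion region: need at least ", min_needed,
         call. = FALSE)
  }
  for (attempt in 0:49) {
    ref <- with_seed(seed + attempt * 100003L, build_reference_once(n_codons))
    if (reference_valid(ref)) return(ref)
  }
  stop("could not build a valid reference; try a different seed", call. = FALSE)
}

build_reference_once <- function(n_codons) {
  codons <- sample(NONSTOP_CODONS, n_codons, replace = TRUE)
  codons[1L] <- "ATG"
  codons[n_codons] <- "TAA"
  codons[SIM_SITE_CODONS] <- SIM_SITE_REF
  # frameshift engineering around codon 138: deleting the middle nucleotide
  # of ACG shifts the frame; codon 149 ATA followed by AGG puts the shifted
  # frame's first stop (TAA) right after residue 148.
  codons[137L] <- "GAT"
  codons[138L] <- "ACG"
  codons[149L] <- "ATA"
  codons[150L] <- "AGG"
  # shifted-frame windows for codons 139..148 must not be stops
  nxt <- "A"  # first nt of codon 149
  for (m in 148:139) {
    repeat {
      cand <- codons[m]
      if (!(paste0(substr(cand, 2L, 3L), nxt) %in% STOP_CODONS)) break
      codons[m] <- sample(NONSTOP_CODONS, 1L)
    }
    nxt <- substr(codons[m], 1L, 1L)
  }
  s <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1L]]
  bs <- 3L * (SIM_DEL_START - 1L) + 1L
  be <- 3L * SIM_DEL_END
  rep_chars <- strsplit(SIM_REPEAT, "", fixed = TRUE)[[1L]]
  s[bs:(bs + 7L)] <- rep_chars
  s[(be + 1L):(be + 8L)] <- rep_chars
  paste(s, collapse = "")
}

# check engineered properties that random background could have broken
reference_valid <- function(ref) {
  n_codons <- nchar(ref) %/% 3L
  codons <- substring(ref, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  if (any(codons[-n_codons] %in% STOP_CODONS)) return(FALSE)
  if (count_fixed(ref, SIM_REPEAT) != 2L) return(FALSE)
  bs <- 3L * (SIM_DEL_START - 1L) + 1L
  be <- 3L * SIM_DEL_END
  probes <- c(vapply(SIM_SITE_CODONS, function(ci) {
    substr(ref, 3L * ci - 2L - 6L, 3L * ci + 6L)
  }, character(1)),
  substr(ref, bs - DEL_ANCHOR_LEN, bs - 1L),
  substr(ref, be + 9L, be + 8L + DEL_ANCHOR_LEN))
  if (any(vapply(probes, function(p) count_fixed(ref, p), integer(1)) != 1L)) {
    return(FALSE)
  }
  # the engineered truncation: 1-nt deletion inside codon 138 -> 148 residues
  mutant <- paste0(substr(ref, 1L, 3L * SIM_FRAMESHIFT_CODON - 2L),
                   substr(ref, 3L * SIM_FRAMESHIFT_CODON, nchar(ref)))
  first_stop_codon(mutant) == 149L
}

count_fixed <- function(s, pattern) {
  hits <- gregexpr(pattern, s, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) 0L else length(hits)
}

first_stop_codon <- function(s) {
  n <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit)) hit[1L] else NA_integer_
}

# Substitution alternatives at position p that do not create an in-frame
# stop codon (frame 0 of the full-length sequence).  Planted variation is
# kept nonsense-free so open reading frames stay intact except where a
# truncation is engineered deliberately.
safe_alts <- function(chars, p) {
  base0 <- 3L * ((p - 1L) %/% 3L)
  codon <- chars[(base0 + 1L):(base0 + 3L)]
  pos <- p - base0
  alts <- setdiff(c("A", "C", "G", "T"), chars[p])
  keep <- vapply(alts, function(a) {
    codon[pos] <- a
    !(paste(codon, collapse = "") %in% STOP_CODONS)
  }, logical(1))
  alts[keep]
}

# hamming distance between equal-length codon strings
codon_hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# Pick the codon(s) realizing the requested allele(s) at a site.  Homozygous:
# the codon of that amino acid with fewest changes from the reference codon,
# ties broken alphabetically.  Heterozygous: the codon pair whose position-
# wise IUPAC union expands back to exactly the two amino acids (preferring
# minimal total change, then alphabetical order); the union is returned.
choose_site_codon <- function(ref_codon, alleles) {
  if (length(alleles) == 1L) {
    cands <- codons_for_aa(alleles)
    if (!length(cands)) stop("no codon encodes amino acid '", alleles, "'", call. = FALSE)
    dist <- vapply(cands, codon_hamming, integer(1), b = ref_codon)
    return(cands[order(dist, cands)][1L])
  }
  if (length(alleles) != 2L) stop("a site carries one or two alleles", call. = FALSE)
  c1s <- codons_for_aa(alleles[1L])
  c2s <- codons_for_aa(alleles[2L])
  if (!length(c1s) || !length(c2s)) {
    stop("no codon encodes amino acid '",
         alleles[c(!length(c1s), !length(c2s))][1L], "'", call. = FALSE)
  }
  grid <- expand.grid(c1 = c1s, c2 = c2s, stringsAsFactors = FALSE)
  grid$union <- mapply(iupac_union, grid$c1, grid$c2)
  grid$exact <- vapply(grid$union, function(u) {
    identical(codon_aas(u), sort(unique(alleles)))
  }, logical(1))
  grid$dist <- vapply(grid$c1, codon_hamming, integer(1), b = ref_codon) +
    vapply(grid$c2, codon_hamming, integer(1), b = ref_codon)
  grid <- grid[order(!grid$exact, grid$dist, grid$c1, grid$c2), , drop = FALSE]
  grid$union[1L]
}

# Parse a composite genotype key like "189A/T-223G-405L-475L-FL" against a
# panel; returns list(alleles = named list, deleted = logical).
parse_genotype <- function(genotype, panel) {
  tokens <- strsplit(genotype, "-", fixed = TRUE)[[1L]]
  deleted <- FALSE
  if (tokens[length(tokens)] %in% c("FL", "\u0394")) {
    deleted <- tokens[length(tokens)] == "\u0394"
    tokens <- tokens[-length(tokens)]
  }
  site_ids <- vapply(panel$sites, `[[`, character(1), "site_id")
  if (length(tokens) != length(site_ids)) {
    stop("genotype '", genotype, "' does not match the panel's ", length(site_ids),
         " sites", call. = FALSE)
  }
  alleles <- vector("list", length(site_ids))
  names(alleles) <- site_ids
  for (k in seq_along(tokens)) {
    if (!startsWith(tokens[k], site_ids[k])) {
      stop("genotype token '", tokens[k], "' does not start with site id '",
           site_ids[k], "'", call. = FALSE)
    }
    aa <- substring(tokens[k], nchar(site_ids[k]) + 1L)
    alleles[[k]] <- strsplit(aa, "/", fixed = TRUE)[[1L]]
  }
  list(alleles = alleles, deleted = deleted)
}

#' Plant a composite genotype onto the reference sequence
#'
#' Replaces the codon at each diagnostic site with a codon encoding the
#' requested allele (minimal nucleotide change from the reference codon,
#' ties broken alphabetically); heterozygous sites are written as the
#' position-wise IUPAC union of the two allele codons, choosing a codon
#' pair whose union decodes back to exactly the two amino acids.  A deleted
#' genotype excises the 36-codon block (the surviving repeat copy is the one
#' after the block, which reads identically at the junction).
#'
#' @param reference reference CDS string.
#' @param genotype composite key string, e.g. `"189A-223G-405L-475L-FL"`.
#' @param panel the [marker_panel()] the genotype refers to.
#' @return nucleotide string (IUPAC codes at heterozygous sites).
#' @export
plant_genotype <- function(reference, genotype, panel) {
  gt <- parse_genotype(genotype, panel)
  s <- strsplit(reference, "", fixed = TRUE)[[1L]]
  for (site in panel$sites) {
    at <- 3L * site$codon_index - 2L
    ref_codon <- substr(reference, at, at + 2L)
    codon <- choose_site_codon(ref_codon, gt$alleles[[site$site_id]])
    s[at:(at + 2L)] <- strsplit(codon, "", fixed = TRUE)[[1L]]
  }
  if (gt$deleted) {
    if (is.null(panel$deletion)) stop("genotype requests a deletion but the panel has none",
                                      call. = FALSE)
    bs <- 3L * (panel$deletion$start_codon - 1L) + 1L
    be <- 3L * panel$deletion$end_codon
    s <- s[-(bs:be)]
  }
  paste(s, collapse = "")
}

# Reference positions that the generator must never mutate: probe windows,
# deletion anchors + repeats + block, start/stop codons, and the engineered
# frameshift region (codons 136-151).
protected_positions <- function(panel) {
  n <- nchar(panel$reference_cds)
  prot <- c(1:3, (n - 2L):n, (3L * 136L - 2L):(3L * 151L))
  for (site in panel$sites) {
    pr <- build_probe(panel, site)
    prot <- c(prot, pr$ref_start:(pr$ref_start + nchar(pr$probe) - 1L))
  }
  if (!is.null(panel$deletion)) {
    bs <- 3L * (panel$deletion$start_codon - 1L) + 1L
    be <- 3L * panel$deletion$end_codon
    rl <- panel$deletion$repeat_len_nt
    prot <- c(prot, (bs - DEL_ANCHOR_LEN):(be + rl + DEL_ANCHOR_LEN))
  }
  sort(unique(prot))
}

default_sim_groups <- function() {
  list(
    list(genotype = "189A-223G-405L-475L-FL", n_members = 10L,
         centroid = c(39.74, -104.99), dispersion_km = 1500,
         origin_class = "Nature", niche = "oak bark"),
    list(genotype = "189A-223S-405S-475L-FL", n_members = 10L,
         centroid = c(38.6, -92.2), dispersion_km = 4000,
         origin_class = "Nature", niche = "oak bark"),
    list(genotype = "189A/T-223D/G-405L-475H/L-FL", n_members = 10L,
         centroid = c(46.2, 6.1), dispersion_km = 3000,
         origin_class = "Domesticated", niche = "wine must"),
    list(genotype = "189T-223G-405L-475H-FL", n_members = 10L,
         centroid = c(32.73, 35.05), dispersion_km = 2500,
         origin_class = "Nature", niche = "soil"),
    list(genotype = "189A-223D-405L-475L-Δ", n_members = 10L,
         centroid = c(-1.8, -78.5), dispersion_km = 600,
         origin_class = "Nature", niche = "tree bark"))
}

#' Specify a synthetic panel simulation
#'
#' The defaults emulate the structure of a natural-isolate marker-gene
#' survey: five allele groups of ten isolates each (including one group
#' heterozygous at three sites and one carrying the 36-codon deletion plus
#' the codon-138 frameshift), group-private backbone substitutions so that
#' groups behave as clades, rare background substitutions outside all probe
#' windows, and sampling locations scattered around each group's centroid.
#'
#' @param n_codons reference length (default 586 codons).
#' @param groups list of group specifications: `genotype` (composite key
#'   string, or NULL to draw one at random), `n_members`, `centroid`
#'   (`c(lat, lon)`), `dispersion_km`, `origin_class`, `niche`.
#' @param het_prob probability that a site of a randomly drawn genotype is
#'   heterozygous (explicit genotype strings are used verbatim).
#' @param background_sub_rate per-nucleotide substitution probability
#'   outside probe windows and anchors (default 0.002).
#' @param clade_subs_per_group group-private backbone substitutions giving
#'   each allele group its own clade signature (default 8).
#' @param frameshift list of `list(group, codon)`: every member of that
#'   group receives a single-nucleotide deletion in that codon.  The default
#'   `"auto"` gives every group whose genotype carries the deletion the
#'   codon-138 frameshift as well, mirroring how the truncation and the
#'   block deletion co-occur on natural loss-of-function alleles; `NULL`
#'   plants none.
#' @param seed RNG seed for the simulation.
#' @param reference_seed seed for [make_reference()] (default 42, matching
#'   the packaged reference).
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_codons = 586L, groups = default_sim_groups(),
                     het_prob = 0.3, background_sub_rate = 0.002,
                     clade_subs_per_group = 8L,
                     frameshift = "auto",
                     seed = 1L, reference_seed = 42L) {
  if (het_prob < 0 || het_prob > 1) stop("het_prob must be in [0, 1]", call. = FALSE)
  if (background_sub_rate < 0 || background_sub_rate > 1) {
    stop("background_sub_rate must be in [0, 1]", call. = FALSE)
  }
  for (g in groups) {
    if (is.null(g$n_members) || g$n_members < 1L) {
      stop("every group needs n_members >= 1", call. = FALSE)
    }
  }
  if (!is.null(frameshift) && !identical(frameshift, "auto")) {
    for (f in frameshift) {
      if (f$group < 1L || f$group > length(groups)) {
        stop("frameshift group index out of range", call. = FALSE)
      }
    }
  }
  structure(list(n_codons = as.integer(n_codons), groups = groups,
                 het_prob = het_prob, background_sub_rate = background_sub_rate,
                 clade_subs_per_group = as.integer(clade_subs_per_group),
                 frameshift = frameshift, seed = as.integer(seed),
                 reference_seed = as.integer(reference_seed)),
            class = "sim_spec")
}

random_genotype <- function(panel, het_prob) {
  parts <- vapply(panel$sites, function(site) {
    alleles <- names(site$allele_map)
    aa <- if (length(alleles) >= 2L && runif(1) < het_prob) {
      paste(sort(sample(alleles, 2L)), collapse = "/")
    } else sample(alleles, 1L)
    paste0(site$site_id, aa)
  }, character(1))
  del <- if (!is.null(panel$deletion) && runif(1) < 0.15) "\u0394" else "FL"
  paste(c(parts, del), collapse = "-")
}

#' Simulate a sequence panel with planted ground truth
#'
#' Generates the reference and panel, plants each group's composite
#' genotype, adds group-private clade substitutions and per-member
#' background substitutions (both restricted to positions outside every
#' probe window, anchor and engineered region), applies any requested
#' frameshift deletions, and samples member coordinates around each group
#' centroid by drawing a random bearing and a half-normal great-circle
#' distance (so the scatter is correct on the sphere at any latitude).
#' Members are assigned round-robin to `ceiling(n/2)` named sampling sites
#' per group, so some locations carry several isolates.  Output is fully
#' deterministic for a fixed spec.
#'
#' @param spec a [sim_spec()].
#' @param out_dir optional directory; when given, writes `sequences.fasta`,
#'   `metadata.tsv`, `ground_truth.tsv`, `reference.fasta` and `panel.yaml`.
#' @return list with `sequences` (`isolate_set`), `metadata`
#'   (`isolate_meta`), `truth` (data frame), `panel`, `reference`.
#' @export
simulate_panel <- function(spec = sim_spec(), out_dir = NULL) {
  reference <- make_reference(spec$n_codons, seed = spec$reference_seed)
  panel <- marker_panel(reference, ho5_sites(),
                        deletion_marker(SIM_DEL_START, SIM_DEL_END, nchar(SIM_REPEAT)),
                        panel_id = "HO-5site-sim")
  unprot <- setdiff(seq_len(nchar(reference)), protected_positions(panel))
  bases <- c("A", "C", "G", "T")
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  bs <- 3L * (SIM_DEL_START - 1L) + 1L
  be <- 3L * SIM_DEL_END

  out <- with_seed(spec$seed, {
    genotypes <- vapply(spec$groups, function(g) {
      if (is.null(g$genotype)) random_genotype(panel, spec$het_prob) else g$genotype
    }, character(1))
    n_groups <- length(spec$groups)
    clade_pos <- if (spec$clade_subs_per_group > 0L) {
      split(sample(unprot, spec$clade_subs_per_group * n_groups),
            rep(seq_len(n_groups), each = spec$clade_subs_per_group))
    } else {
      rep(list(integer(0)), n_groups)
    }
    clade_alt <- lapply(clade_pos, function(pos) {
      vapply(pos, function(p) {
        alts <- safe_alts(ref_chars, p)
        if (length(alts)) sample(alts, 1L) else ref_chars[p]
      }, character(1))
    })
    fs <- spec$frameshift
    if (identical(fs, "auto")) {
      del_groups <- which(vapply(genotypes, function(g) {
        parse_genotype(g, panel)$deleted
      }, logical(1)))
      fs <- lapply(del_groups, function(g) list(group = g, codon = SIM_FRAMESHIFT_CODON))
    }
    fs_groups <- vapply(fs, `[[`, numeric(1), "group")
    fs_codons <- vapply(fs, `[[`, numeric(1), "codon")

    seq_rows <- list(); meta_rows <- list(); truth_rows <- list()
    idx <- 0L
    for (g in seq_len(n_groups)) {
      grp <- spec$groups[[g]]
      gt <- parse_genotype(genotypes[g], panel)
      # plant the diagnostic codons in full-length coordinates; the block
      # excision is deferred until after substitutions are placed
      planted <- ref_chars
      for (site in panel$sites) {
        at <- 3L * site$codon_index - 2L
        codon <- choose_site_codon(substr(reference, at, at + 2L),
                                   gt$alleles[[site$site_id]])
        planted[at:(at + 2L)] <- strsplit(codon, "", fixed = TRUE)[[1L]]
      }
      n_sites <- max(1L, ceiling(grp$n_members / 2))
      site_pts <- lapply(seq_len(n_sites), function(j) {
        bearing <- runif(1, 0, 360)
        dist_km <- abs(rnorm(1, 0, grp$dispersion_km))
        p <- geosphere::destPoint(c(grp$centroid[2L], grp$centroid[1L]),
                                  bearing, dist_km * 1000, r = EARTH_RADIUS_KM * 1000)
        c(lat = round(p[1L, 2L], 4), lon = round(p[1L, 1L], 4))
      })
      for (m in seq_len(grp$n_members)) {
        idx <- idx + 1L
        id <- sprintf("iso%03d", idx)
        s <- planted
        s[clade_pos[[g]]] <- clade_alt[[g]]
        open <- setdiff(unprot, clade_pos[[g]])
        hit <- open[runif(length(open)) < spec$background_sub_rate]
        subs <- character(0)
        for (p in hit) {
          alts <- safe_alts(s, p)
          if (!length(alts)) next
          alt <- sample(alts, 1L)
          subs <- c(subs, paste0(p, s[p], ">", alt))
          s[p] <- alt
        }
        drop_idx <- integer(0)
        if (gt$deleted) drop_idx <- bs:be
        frameshift <- g %in% fs_groups
        if (frameshift) {
          fc <- fs_codons[match(g, fs_groups)]
          drop_idx <- c(drop_idx, 3L * fc - 1L)  # middle nucleotide of the codon
        }
        if (length(drop_idx)) s <- s[-drop_idx]
        site_j <- ((m - 1L) %% n_sites) + 1L
        pt <- site_pts[[site_j]]
        seq_rows[[idx]] <- isolate_set(id, paste(s, collapse = ""),
                                       sprintf("synthetic group %d", g))
        meta_rows[[idx]] <- data.frame(
          id = id, origin_class = grp$origin_class, niche = grp$niche,
          clade = sprintf("grp%d", g),
          location_name = sprintf("g%d_site%d", g, site_j),
          lat = pt[["lat"]], lon = pt[["lon"]], ho_deleted = FALSE,
          stringsAsFactors = FALSE)
        truth_rows[[idx]] <- data.frame(
          id = id, key = genotypes[g], group = g,
          lat = pt[["lat"]], lon = pt[["lon"]],
          location_name = sprintf("g%d_site%d", g, site_j),
          background_subs = paste(subs, collapse = ","),
          frameshift = frameshift, stringsAsFactors = FALSE)
      }
    }
    sequences <- do.call(rbind, seq_rows)
    class(sequences) <- c("isolate_set", "data.frame")
    metadata <- do.call(rbind, meta_rows)
    class(metadata) <- c("isolate_meta", "data.frame")
    list(sequences = sequences, metadata = metadata,
         truth = do.call(rbind, truth_rows))
  })
  out$panel <- panel
  out$reference <- reference
  out$spec <- spec
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$sequences, file.path(out_dir, "sequences.fasta"))
    write_metadata(out$metadata, file.path(out_dir, "metadata.tsv"))
    write.table(out$truth, file.path(out_dir, "ground_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(isolate_set("reference", reference, "synthetic reference CDS"),
                file.path(out_dir, "reference.fasta"))
    write_panel_yaml(panel, file.path(out_dir, "panel.yaml"), "reference.fasta")
  }
  out
}

write_panel_yaml <- function(panel, path, reference_fasta) {
  cfg <- list(
    panel_id = panel$panel_id,
    reference_fasta = reference_fasta,
    numbering_offset = panel$numbering_offset,
    sites = lapply(panel$sites, function(s) {
      list(site_id = s$site_id, codon = s$codon_index, flank_nt = s$flank_nt,
           alleles = as.list(names(s$allele_map)))
    }))
  if (!is.null(panel$deletion)) {
    cfg$deletion <- list(start_codon = panel$deletion$start_codon,
                         end_codon = panel$deletion$end_codon,
                         repeat_len_nt = panel$deletion$repeat_len_nt)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
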