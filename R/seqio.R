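SEQ_ALPHABET <- c(names(IUPAC_BITS), "-")

#' Read a multi-FASTA panel of coding sequences
#'
#' Sequences are uppercased and `U` is normalized to `T`.  The record id is
#' the first whitespace-delimited token of the header; the remainder is kept
#' as the description.  Alignment gap characters (`-`) are accepted on input
#' and stripped later by the typing functions.
#'
#' @param path FASTA file.
#' @return a data frame of class `isolate_set` with columns `id`, `seq`,
#'   `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- chartr("uU", "tT", as.character(set))
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    if (!length(chars)) stop("empty sequence for record '", ids[i], "'", call. = FALSE)
    bad <- which(!chars %in% SEQ_ALPHABET)
    if (length(bad)) {
      stop(sprintf("record '%s': non-IUPAC character '%s' at position %d",
                   ids[i], chars[bad[1L]], bad[1L]), call. = FALSE)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  isolate_set(ids, unname(seqs), desc)
}

isolate_set <- function(id, seq, description = "") {
  out <- data.frame(id = as.character(id), seq = as.character(seq),
                    description = as.character(description),
                    stringsAsFactors = FALSE)
  class(out) <- c("isolate_set", "data.frame")
  out
}

#' Write an isolate sequence set to FASTA
#'
#' @param seqs an `isolate_set` data frame (see [read_fasta()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  headers <- ifelse(nzchar(seqs$description),
                    paste(seqs$id, seqs$description), seqs$id)
  set <- Biostrings::BStringSet(setNames(seqs$seq, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

META_COLUMNS <- c("id", "origin_class", "niche", "clade", "location_name",
                  "lat", "lon", "ho_deleted")

#' Read an isolate metadata table
#'
#' Tab-separated with a header row; lines starting with `#` are skipped.
#' The only required column is `id`.  Recognized optional columns are
#' `origin_class`, `niche`, `clade`, `location_name`, `lat`, `lon` and
#' `ho_deleted` (isolates whose marker gene was deliberately deleted during
#' strain construction).  Unknown columns raise a warning and are dropped.
#' Missing coordinates stay missing -- they are never coerced to zero -- and
#' a record must carry either both coordinates or neither.
#'
#' @param path TSV file.
#' @return data frame of class `isolate_meta` with the columns above.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   quote = "", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  if (!"id" %in% names(df)) stop("metadata must have an 'id' column", call. = FALSE)
  unknown <- setdiff(names(df), META_COLUMNS)
  if (length(unknown)) {
    warning("ignoring unknown metadata column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  for (col in setdiff(META_COLUMNS, names(df))) df[[col]] <- rep(NA_character_, nrow(df))
  df <- df[, META_COLUMNS, drop = FALSE]
  df$lat <- suppressWarnings(as.numeric(ifelse(df$lat == "", NA, df$lat)))
  df$lon <- suppressWarnings(as.numeric(ifelse(df$lon == "", NA, df$lon)))
  bad_lat <- which(!is.na(df$lat) & (df$lat < -90 | df$lat > 90))
  if (length(bad_lat)) {
    stop(sprintf("latitude out of range [-90, 90] for id '%s': %s",
                 df$id[bad_lat[1L]], df$lat[bad_lat[1L]]), call. = FALSE)
  }
  bad_lon <- which(!is.na(df$lon) & (df$lon < -180 | df$lon > 180))
  if (length(bad_lon)) {
    stop(sprintf("longitude out of range [-180, 180] for id '%s': %s",
                 df$id[bad_lon[1L]], df$lon[bad_lon[1L]]), call. = FALSE)
  }
  one_sided <- which(is.na(df$lat) != is.na(df$lon))
  if (length(one_sided)) {
    stop("id '", df$id[one_sided[1L]],
         "' has only one of lat/lon; provide both or neither", call. = FALSE)
  }
  df$ho_deleted <- !is.na(df$ho_deleted) &
    toupper(df$ho_deleted) %in% c("TRUE", "T", "1", "YES")
  if (anyDuplicated(df$id)) {
    stop("duplicate metadata id: ", df$id[duplicated(df$id)][1L], call. = FALSE)
  }
  class(df) <- c("isolate_meta", "data.frame")
  df
}

#' Write an isolate metadata table
#' @param meta `isolate_meta` data frame.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta[, META_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Split sequence ids into annotated and unannotated
#'
#' Every sequence id either has a metadata row or is reported as
#' unannotated; the two sets partition the panel.
#'
#' @param seqs `isolate_set`.
#' @param meta `isolate_meta`.
#' @return list with character vectors `annotated` and `unannotated`.
#' @export
match_metadata <- function(seqs, meta) {
  ann <- intersect(seqs$id, meta$id)
  list(annotated = ann, unannotated = setdiff(seqs$id, ann))
}
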