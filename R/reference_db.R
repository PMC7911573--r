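# UNITE-style reference database: read, validate, index, round-trip.

#' Read a UNITE-style reference FASTA into a tidy database
#'
#' Each FASTA header must carry a record identifier and a seven-rank
#' QIIME-style lineage (`k__...;p__...;...;s__...`), separated by whitespace
#' (the QIIME release layout) or by `|`. Sequences are upper-cased and `U`
#' is normalised to `T`; the alphabet is validated against the 15-letter
#' IUPAC code.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param dialect `"whitespace"` (default) splits the header on the first
#'   whitespace run; `"pipe"` splits on `|` and takes the first field as the
#'   record id. In both dialects the lineage is located by its `k__...`
#'   signature, so headers with extra fields parse fine.
#' @param tokens Unidentified-label tokens, see [is_identified_label()].
#' @return A `ref_db` tibble with columns `record_id`, `sequence`, and the
#'   seven rank columns `kingdom` ... `species`.
#' @export
read_reference_fasta <- function(path, dialect = c("whitespace", "pipe"),
                                 tokens = default_unidentified_tokens()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("database file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(seqs)
  ids <- vapply(headers, function(h) {
    if (dialect == "pipe" && grepl("|", h, fixed = TRUE)) {
      strsplit(h, "|", fixed = TRUE)[[1]][1]
    } else {
      strsplit(trimws(h), "[ \t]+")[[1]][1]
    }
  }, character(1), USE.NAMES = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate record id(s): ", paste(head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  sequences <- chartr("u", "U", toupper(as.character(seqs)))
  sequences <- chartr("U", "T", sequences)
  bad <- purrr::imap(sequences, function(s, i) invalid_iupac_letters(s))
  offenders <- which(lengths(bad) > 0L)
  if (length(offenders) > 0L) {
    stop("non-IUPAC letters in record(s): ",
         paste(sprintf("%s [%s]", ids[offenders],
                       vapply(bad[offenders], paste, "", collapse = "")),
               collapse = "; "),
         call. = FALSE)
  }
  if (any(nchar(sequences) == 0L)) {
    stop("empty sequence(s) for record(s): ",
         paste(ids[nchar(sequences) == 0L], collapse = ", "), call. = FALSE)
  }
  lineages <- purrr::map(headers, parse_lineage, tokens = tokens)
  ranks <- purrr::map_dfr(lineages, function(l) {
    setNames(as.list(l$label), l$rank)
  })
  db <- dplyr::bind_cols(
    tibble(record_id = ids, sequence = unname(sequences)),
    ranks
  )
  attr(db, "dialect") <- dialect
  attr(db, "unidentified_tokens") <- tokens
  class(db) <- c("ref_db", class(db))
  db
}

#' Write a reference database back to FASTA
#'
#' Inverse of [read_reference_fasta()]: headers are
#' `record_id<sep>k__...;...;s__...` with the separator matching `dialect`.
#'
#' @param db A `ref_db` tibble.
#' @param path Output FASTA path.
#' @param dialect Header dialect, as in [read_reference_fasta()].
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path,
                                  dialect = c("whitespace", "pipe")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "pipe") "|" else " "
  lineage <- apply(as.matrix(db[TAXONOMIC_RANKS]), 1L, format_lineage)
  headers <- paste0(db$record_id, sep, lineage)
  x <- Biostrings::DNAStringSet(db$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' Record ids annotated with a given label at a given rank
#'
#' Only identified labels are matched: querying an unidentified token (or a
#' species label lacking a binomial epithet) returns an empty set, because
#' unidentified labels are deliberately not indexed as taxa.
#'
#' @param db A `ref_db` tibble.
#' @param rank One of the seven canonical ranks.
#' @param label Taxon label to look up (exact match).
#' @param tokens Unidentified-label tokens.
#' @return Character vector of record ids (possibly empty).
#' @export
taxon_members <- function(db, rank, label,
                          tokens = db_tokens(db)) {
  if (!(is.character(rank) && length(rank) == 1L && rank %in% TAXONOMIC_RANKS)) {
    stop("unknown rank: ", paste(rank, collapse = ", "),
         " (must be one of ", paste(TAXONOMIC_RANKS, collapse = ", "), ")",
         call. = FALSE)
  }
  lab <- db[[rank]]
  keep <- lab == label & is_identified_label(lab, rank, tokens)
  db$record_id[keep]
}

db_tokens <- function(db) {
  attr(db, "unidentified_tokens") %||% default_unidentified_tokens()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-rank identified flags for a reference database
#'
#' @param db A `ref_db` tibble.
#' @param tokens Unidentified-label tokens.
#' @return A tibble `record_id` + one logical column per rank.
#' @export
identified_flags <- function(db, tokens = db_tokens(db)) {
  out <- tibble(record_id = db$record_id)
  for (r in TAXONOMIC_RANKS) {
    out[[r]] <- is_identified_label(db[[r]], r, tokens)
  }
  out
}

#' Summarise a reference database
#'
#' @param db A `ref_db` tibble.
#' @return A tibble of per-phylum record counts (unidentified phyla pooled
#'   under `"unidentified"`), with sequence-length summaries.
#' @export
ref_db_summary <- function(db) {
  db |>
    dplyr::mutate(
      phylum_bucket = dplyr::if_else(
        is_identified_label(.data$phylum, "phylum", db_tokens(db)),
        .data$phylum, "unidentified"
      ),
      len = nchar(.data$sequence)
    ) |>
    dplyr::count(.data$phylum_bucket, name = "n_records") |>
    dplyr::arrange(dplyr::desc(.data$n_records))
}

#' Dump a reference database as TSV
#'
#' Writes `record_id`, the seven rank columns and sequence length.
#'
#' @param db A `ref_db` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_db_tsv <- function(db, path) {
  db |>
    dplyr::mutate(length = nchar(.data$sequence)) |>
    dplyr::select("record_id", dplyr::all_of(TAXONOMIC_RANKS), "length") |>
    readr::write_tsv(path)
  invisible(path)
}
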