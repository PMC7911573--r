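# Seven-rank QIIME/UNITE lineage handling.

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")
RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
SUBKINGDOM_RANKS <- TAXONOMIC_RANKS[-1]

#' Canonical taxonomic ranks
#'
#' The seven ranks carried by UNITE-style lineage strings, in order:
#' kingdom, phylum, class, order, family, genus, species.
#'
#' @return Character vector of length seven.
#' @export
taxonomic_ranks <- function() TAXONOMIC_RANKS

default_unidentified_tokens <- function() "unidentified"

#' Is a rank label "identified"?
#'
#' A label counts as unidentified when it is empty, matches one of the
#' unidentified tokens (case-insensitive; `"unidentified"` by default), or —
#' at species rank only — lacks a binomial epithet (ends in `_sp` or `_sp.`).
#' `Incertae_sedis` is a formal placement and is *not* treated as
#' unidentified unless added to `tokens`.
#'
#' @param label Character vector of rank labels (without the `x__` prefix).
#' @param rank Single rank name; only `"species"` changes behaviour.
#' @param tokens Labels treated as unidentified (case-insensitive).
#' @return Logical vector: `TRUE` where the label is identified.
#' @export
is_identified_label <- function(label, rank = "genus",
                                tokens = default_unidentified_tokens()) {
  stopifnot(length(rank) == 1L, rank %in% TAXONOMIC_RANKS)
  lab <- trimws(as.character(label))
  unident <- is.na(lab) | lab == "" | tolower(lab) %in% tolower(tokens)
  if (rank == "species") {
    unident <- unident | grepl("_sp\\.?$", lab, ignore.case = TRUE)
  }
  !unident
}

#' Parse a UNITE-style seven-rank lineage string
#'
#' Accepts a header (or header fragment) containing a lineage of the form
#' `k__Fungi;p__Ascomycota;c__...;o__...;f__...;g__...;s__...` and returns a
#' one-row-per-rank tibble with identified flags.
#'
#' @param header_text A single header or lineage string.
#' @param tokens Unidentified-label tokens, see [is_identified_label()].
#' @return A tibble with columns `rank`, `label`, `identified` (7 rows).
#' @examples
#' parse_lineage("k__Fungi;p__Basidiomycota;c__Agaricomycetes;o__Cantharellales;f__Tulasnellaceae;g__Tulasnella;s__Tulasnella_calospora")
#' @export
parse_lineage <- function(header_text, tokens = default_unidentified_tokens()) {
  stopifnot(is.character(header_text), length(header_text) == 1L)
  lineage <- extract_lineage_string(header_text)
  if (is.na(lineage)) {
    stop("no `k__...;...;s__...` lineage found in header: ", header_text,
         call. = FALSE)
  }
  fields <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  if (length(fields) != 7L) {
    stop("expected 7 `;`-separated rank fields, found ", length(fields),
         " in header: ", header_text, call. = FALSE)
  }
  prefixes <- substr(fields, 1L, 3L)
  if (!identical(prefixes, RANK_PREFIXES)) {
    stop("rank prefixes missing or out of order (need k__,p__,c__,o__,f__,",
         "g__,s__) in header: ", header_text, call. = FALSE)
  }
  labels <- trimws(substring(fields, 4L))
  tibble(
    rank = TAXONOMIC_RANKS,
    label = labels,
    identified = vapply(
      seq_along(labels),
      function(i) is_identified_label(labels[i], TAXONOMIC_RANKS[i], tokens),
      logical(1)
    )
  )
}

# Locate the lineage substring inside a free-form header. Tolerates both
# ">ID k__...;..." (whitespace) and ">ID|acc|k__...;..." (pipe) dialects.
extract_lineage_string <- function(header_text) {
  m <- regmatches(
    header_text,
    regexpr("k__[^;]*;p__[^;]*;c__[^;]*;o__[^;]*;f__[^;]*;g__[^;]*;s__[^ \t|]*",
            header_text)
  )
  if (length(m) == 0L) NA_character_ else m
}

# Format rank labels back into a lineage string.
format_lineage <- function(labels) {
  stopifnot(length(labels) == 7L)
  paste0(RANK_PREFIXES, labels, collapse = ";")
}
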