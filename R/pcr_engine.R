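# The amplification engine: IUPAC-aware binding-site search under the
# mismatch-acceptance rules, convergent-pair assembly, length filtering.

#' Mismatch profile of a primer binding region against a template window
#'
#' Position `i` (0-based from the primer 5' end) is a mismatch iff the
#' primer and template symbols are IUPAC-incompatible. Reports the mismatch
#' count, the longest run of consecutive mismatches, and whether any
#' mismatch falls within the protected 3'-terminal window.
#'
#' @param binding_region Primer binding region, 5'->3'.
#' @param window Template window in primer orientation, same length.
#' @param protected_3prime_bases Width of the protected 3' window.
#' @param ambiguity_mode See [iupac_compatible()].
#' @return A list of class `mismatch_profile` with elements `positions`
#'   (0-based offsets), `count`, `longest_run`, `hits_3prime_window`.
#' @export
mismatch_profile <- function(binding_region, window,
                             protected_3prime_bases = 2L,
                             ambiguity_mode = c("intersect", "strict")) {
  p <- seq_chars(binding_region)
  w <- seq_chars(window)
  if (length(p) != length(w)) {
    stop("binding region (", length(p), " nt) and window (", length(w),
         " nt) differ in length", call. = FALSE)
  }
  m <- compat_matrix(match.arg(ambiguity_mode))
  mism <- !m[cbind(p, w)]
  profile_from_logical(mism, protected_3prime_bases)
}

# Build a mismatch_profile from a logical mismatch vector (internal fast path).
profile_from_logical <- function(mism, protected_3prime_bases) {
  n <- length(mism)
  positions <- which(mism) - 1L
  longest <- 0L
  if (any(mism)) {
    r <- rle(mism)
    longest <- max(r$lengths[r$values])
  }
  structure(
    list(
      positions = positions,
      count = length(positions),
      longest_run = as.integer(longest),
      hits_3prime_window = any(positions >= n - protected_3prime_bases)
    ),
    class = "mismatch_profile"
  )
}

#' Is a binding site accepted under the mismatch rules?
#'
#' A site is accepted iff its mismatch count is within the budget, it has no
#' run of `forbid_consecutive_run` or more successive mismatches, and no
#' mismatch falls in the protected 3'-terminal window.
#'
#' @param profile A [mismatch_profile()] (computed with the same protected
#'   window width as `params`).
#' @param params A [pcr_params()] object.
#' @return Logical scalar.
#' @export
site_accepted <- function(profile, params = pcr_params()) {
  profile$count <= params$max_mismatches &&
    profile$longest_run < params$forbid_consecutive_run &&
    !profile$hits_3prime_window
}

# Find accepted binding windows of `binding` on `subject_chars` (plus-strand
# orientation of the scan). `orient` = "forward" matches the binding region
# directly; "reverse" matches its reverse complement and computes the profile
# in primer orientation. Returns a tibble of 0-based half-open sites with
# profiles. Uses Biostrings::matchPattern for candidate generation, then the
# package's own profile/acceptance rules.
scan_sites <- function(subject, subject_chars, binding, orient, params) {
  n <- nchar(binding)
  L <- length(subject_chars)
  if (L < n) return(empty_sites())
  pattern <- if (orient == "forward") binding else revcomp(binding)
  fixed <- if (params$ambiguity_mode == "strict") "pattern" else FALSE
  hits <- Biostrings::matchPattern(
    pattern, subject,
    max.mismatch = params$max_mismatches, with.indels = FALSE, fixed = fixed
  )
  if (length(hits) == 0L) return(empty_sites())
  starts <- Biostrings::start(hits)   # 1-based
  m <- compat_matrix(params$ambiguity_mode)
  pchars <- seq_chars(binding)
  keep <- logical(length(starts))
  profs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    wchars <- subject_chars[s:(s + n - 1L)]
    if (orient == "reverse") {
      wchars <- rev(unname(.RC_MAP[wchars]))
    }
    mism <- !m[cbind(pchars, wchars)]
    prof <- profile_from_logical(mism, params$protected_3prime_bases)
    profs[[i]] <- prof
    keep[i] <- site_accepted(prof, params)
  }
  if (!any(keep)) return(empty_sites())
  tibble(
    start = starts[keep] - 1L,           # 0-based
    end = starts[keep] - 1L + n,         # half-open
    profile = profs[keep]
  )
}

empty_sites <- function() tibble(start = integer(), end = integer(),
                                 profile = list())

# Oriented template window for a site, in primer orientation (5'->3' of the
# primer), used for Tm estimation.
oriented_window <- function(subject_chars, start0, end0, orient) {
  w <- subject_chars[(start0 + 1L):end0]
  if (orient == "reverse") w <- rev(unname(.RC_MAP[w]))
  paste(w, collapse = "")
}

#' Find in silico amplicons of a primer pair in one sequence
#'
#' Scans the plus strand for accepted forward-primer windows and, downstream,
#' accepted windows matching the reverse complement of the reverse primer's
#' binding region; every convergent combination whose amplicon satisfies the
#' length bounds is reported. With `scan_both_strands` the reverse strand is
#' scanned the same way. Coordinates are 0-based half-open on the plus strand
#' of the sequence as stored.
#'
#' @param sequence IUPAC DNA string (or a one-row `ref_db` slice).
#' @param pair A [primer_pair()].
#' @param params A [pcr_params()].
#' @param record_id Identifier copied into the output.
#' @return A tibble with one row per accepted amplification event: strand,
#'   site and amplicon coordinates, amplicon length, per-primer mismatch
#'   summaries and melting temperatures.
#' @export
find_amplicons <- function(sequence, pair, params = pcr_params(),
                           record_id = NA_character_) {
  stopifnot(inherits(pair, "primer_pair"), inherits(params, "pcr_params"))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  fwd_b <- pair$forward$binding_region
  rev_b <- pair$reverse$binding_region
  if (L < nchar(fwd_b) || L < nchar(rev_b)) return(empty_hits())

  strands <- if (params$scan_both_strands) c("+", "-") else "+"
  out <- purrr::map(strands, function(strand) {
    seq_str <- if (strand == "+") sequence else revcomp(sequence)
    subject <- Biostrings::DNAString(seq_str)
    chars <- seq_chars(seq_str)
    fwd_sites <- scan_sites(subject, chars, fwd_b, "forward", params)
    if (nrow(fwd_sites) == 0L) return(empty_hits())
    rev_sites <- scan_sites(subject, chars, rev_b, "reverse", params)
    if (nrow(rev_sites) == 0L) return(empty_hits())
    combos <- tidyr::expand_grid(f = seq_len(nrow(fwd_sites)),
                                 r = seq_len(nrow(rev_sites)))
    rows <- purrr::pmap(combos, function(f, r) {
      fs <- fwd_sites$start[f]; fe <- fwd_sites$end[f]
      rs <- rev_sites$start[r]; re <- rev_sites$end[r]
      if (rs < fe) return(NULL)                     # convergent order only
      if (params$include_primers) {
        as0 <- fs; ae0 <- re
      } else {
        as0 <- fe; ae0 <- rs
      }
      len <- ae0 - as0
      if (len < params$min_amplicon_length ||
          len > params$max_amplicon_length) return(NULL)
      fp <- fwd_sites$profile[[f]]; rp <- rev_sites$profile[[r]]
      tm_f <- melting_temperature(fwd_b, oriented_window(chars, fs, fe, "forward"))
      tm_r <- melting_temperature(rev_b, oriented_window(chars, rs, re, "reverse"))
      # map scan coordinates back to the stored plus strand
      map0 <- function(s, e) if (strand == "+") c(s, e) else c(L - e, L - s)
      fwd_c <- map0(fs, fe); rev_c <- map0(rs, re); amp_c <- map0(as0, ae0)
      tibble(
        record_id = record_id, strand = strand,
        fwd_start = fwd_c[1], fwd_end = fwd_c[2],
        rev_start = rev_c[1], rev_end = rev_c[2],
        amplicon_start = amp_c[1], amplicon_end = amp_c[2],
        amplicon_length = len,
        fwd_mismatches = fp$count, rev_mismatches = rp$count,
        fwd_mismatch_positions = paste(fp$positions, collapse = ","),
        rev_mismatch_positions = paste(rp$positions, collapse = ","),
        fwd_longest_run = fp$longest_run, rev_longest_run = rp$longest_run,
        tm_fwd = tm_f, tm_rev = tm_r
      )
    })
    dplyr::bind_rows(rows)
  })
  hits <- dplyr::bind_rows(out)
  if (nrow(hits) == 0L) return(empty_hits())
  dplyr::arrange(hits, .data$strand, .data$fwd_start)
}

empty_hits <- function() {
  tibble(
    record_id = character(), strand = character(),
    fwd_start = integer(), fwd_end = integer(),
    rev_start = integer(), rev_end = integer(),
    amplicon_start = integer(), amplicon_end = integer(),
    amplicon_length = integer(),
    fwd_mismatches = integer(), rev_mismatches = integer(),
    fwd_mismatch_positions = character(), rev_mismatch_positions = character(),
    fwd_longest_run = integer(), rev_longest_run = integer(),
    tm_fwd = double(), tm_rev = double()
  )
}

#' Run in silico PCR over a whole reference database
#'
#' @param db A `ref_db` tibble from [read_reference_fasta()] (any tibble
#'   with `record_id` and `sequence` columns works).
#' @param pairs A named list of [primer_pair()] objects (default: the two
#'   ITS fusion pairs).
#' @param params A [pcr_params()].
#' @return A tibble of hits with a leading `pair` column.
#' @export
amplify <- function(db, pairs = default_primer_pairs(),
                    params = pcr_params()) {
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  if (is.null(names(pairs)) || any(names(pairs) == "")) {
    names(pairs) <- purrr::map_chr(pairs, "barcode")
  }
  purrr::imap(pairs, function(pair, label) {
    hits <- purrr::map2(
      db$record_id, db$sequence,
      function(id, s) find_amplicons(s, pair, params, record_id = id)
    )
    dplyr::bind_rows(hits) |>
      dplyr::mutate(pair = label, .before = 1L)
  }) |>
    dplyr::bind_rows()
}

#' Deterministic representative hit per record
#'
#' When a single hit per record is needed, picks (fewest total mismatches,
#' then shorter amplicon, then leftmost forward site, then plus strand).
#'
#' @param hits A hit tibble from [amplify()] or [find_amplicons()].
#' @return One row per (`pair`, if present) x `record_id`.
#' @export
representative_hits <- function(hits) {
  grp <- intersect(c("pair", "record_id"), names(hits))
  hits |>
    dplyr::mutate(.total_mm = .data$fwd_mismatches + .data$rev_mismatches) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(.data$.total_mm, .data$amplicon_length, .data$fwd_start,
                   .data$strand, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".total_mm")
}

#' Write a hit table as TSV
#'
#' Fixed column order matching the engine's per-hit schema.
#'
#' @param hits A hit tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c(
    intersect("pair", names(hits)),
    "record_id", "strand", "fwd_start", "fwd_end", "rev_start", "rev_end",
    "amplicon_start", "amplicon_end", "amplicon_length",
    "fwd_mismatches", "rev_mismatches",
    "fwd_mismatch_positions", "rev_mismatch_positions", "tm_fwd", "tm_rev"
  )
  readr::write_tsv(dplyr::select(hits, dplyr::all_of(cols)), path)
  invisible(path)
}
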