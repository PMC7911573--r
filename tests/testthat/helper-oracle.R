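# Independent brute-force oracle for the amplification engine. Implemented
# from first principles (own IUPAC tables, exhaustive all-window scan, plain
# character vectors) so it shares no code path with the package engine.

OR_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
OR_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
             W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
             N = "N")

or_chars <- function(s) strsplit(toupper(s), "")[[1]]
or_revcomp <- function(s) paste(rev(unname(OR_COMP[or_chars(s)])), collapse = "")

or_mismatch <- function(pchar, tchar, strict = FALSE) {
  if (strict && !(tchar %in% c("A", "C", "G", "T"))) return(TRUE)
  length(intersect(OR_SETS[[pchar]], OR_SETS[[tchar]])) == 0L
}

# all windows of `primer` (already oriented 5'->3' along the scanned strand
# for orient "forward"; for "reverse" the window is flipped back into primer
# orientation before comparing) that pass the acceptance rules
or_scan <- function(seq_chars_v, primer, orient, params) {
  p <- or_chars(primer)
  n <- length(p)
  L <- length(seq_chars_v)
  out <- list()
  if (L < n) return(out)
  strict <- params$ambiguity_mode == "strict"
  for (s in 1:(L - n + 1L)) {
    w <- seq_chars_v[s:(s + n - 1L)]
    if (orient == "reverse") w <- rev(unname(OR_COMP[w]))
    mism <- vapply(seq_len(n), function(i) or_mismatch(p[i], w[i], strict),
                   logical(1))
    count <- sum(mism)
    if (count > params$max_mismatches) next
    run <- 0L
    if (count > 0L) {
      r <- rle(mism)
      run <- max(r$lengths[r$values])
    }
    if (run >= params$forbid_consecutive_run) next
    pos0 <- which(mism) - 1L
    if (any(pos0 >= n - params$protected_3prime_bases)) next
    out[[length(out) + 1L]] <- list(start = s - 1L, end = s - 1L + n,
                                    count = count)
  }
  out
}

# exhaustive enumeration of accepted (forward, reverse) site combinations
oracle_find_amplicons <- function(sequence, pair, params) {
  fwd_b <- pair$forward$binding_region
  rev_b <- pair$reverse$binding_region
  strands <- if (params$scan_both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    s <- if (strand == "+") toupper(sequence) else or_revcomp(sequence)
    ch <- or_chars(s)
    L <- length(ch)
    fs <- or_scan(ch, fwd_b, "forward", params)
    # reverse sites: windows matching revcomp(rev binding); the profile is
    # taken in primer orientation inside or_scan
    rs <- or_scan(ch, rev_b, "reverse", params)
    for (f in fs) {
      for (r in rs) {
        if (r$start < f$end) next
        if (params$include_primers) {
          a0 <- f$start; a1 <- r$end
        } else {
          a0 <- f$end; a1 <- r$start
        }
        len <- a1 - a0
        if (len < params$min_amplicon_length ||
            len > params$max_amplicon_length) next
        map0 <- function(x, y) if (strand == "+") c(x, y) else c(L - y, L - x)
        fc <- map0(f$start, f$end); rc <- map0(r$start, r$end)
        ac <- map0(a0, a1)
        rows[[length(rows) + 1L]] <- data.frame(
          strand = strand,
          fwd_start = fc[1], fwd_end = fc[2],
          rev_start = rc[1], rev_end = rc[2],
          amplicon_start = ac[1], amplicon_end = ac[2],
          amplicon_length = len,
          fwd_mismatches = f$count, rev_mismatches = r$count
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      strand = character(), fwd_start = integer(), fwd_end = integer(),
      rev_start = integer(), rev_end = integer(),
      amplicon_start = integer(), amplicon_end = integer(),
      amplicon_length = integer(),
      fwd_mismatches = integer(), rev_mismatches = integer()
    ))
  }
  out <- do.call(rbind, rows)
  out[order(out$strand, out$fwd_start, out$rev_start), , drop = FALSE]
}

or_cols <- c("strand", "fwd_start", "fwd_end", "rev_start", "rev_end",
             "amplicon_start", "amplicon_end", "amplicon_length",
             "fwd_mismatches", "rev_mismatches")

expect_engine_equals_oracle <- function(sequence, pair, params) {
  eng <- find_amplicons(sequence, pair, params)
  eng <- as.data.frame(eng[or_cols])
  eng <- eng[order(eng$strand, eng$fwd_start, eng$rev_start), , drop = FALSE]
  ora <- oracle_find_amplicons(sequence, pair, params)[or_cols]
  rownames(eng) <- rownames(ora) <- NULL
  expect_equal(eng, ora)
}
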