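# Primer model: fusion primers with non-binding adapter/tag tails and the
# 3' binding region that is actually matched against the template.

FORWARD_TAIL <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"          # 33 nt
REVERSE_TAIL <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"         # 34 nt

#' Construct a primer
#'
#' A primer is its full printed (fusion) sequence split into a non-binding
#' 5' `tail` (sequencing adapter, optionally plus a sample tag) and the 3'
#' `binding_region` assumed to anneal to the template. The concatenation
#' `tail + binding_region` must reproduce `printed_sequence` exactly.
#'
#' @param name Primer name.
#' @param printed_sequence Full 5'->3' IUPAC sequence including the tail.
#' @param tail The 5' non-binding portion (may be `""`).
#' @param role `"forward"` or `"reverse"`.
#' @param binding_region Optional override; defaults to
#'   `printed_sequence` minus `tail`.
#' @return A list of class `primer`.
#' @export
primer <- function(name, printed_sequence, tail = "",
                   role = c("forward", "reverse"),
                   binding_region = NULL) {
  role <- match.arg(role)
  printed_sequence <- toupper(printed_sequence)
  tail <- toupper(tail)
  if (is.null(binding_region)) {
    if (!startsWith(printed_sequence, tail)) {
      stop("tail is not a prefix of the printed sequence for primer ", name,
           call. = FALSE)
    }
    binding_region <- substring(printed_sequence, nchar(tail) + 1L)
  } else {
    binding_region <- toupper(binding_region)
    if (paste0(tail, binding_region) != printed_sequence) {
      # a sample tag may sit between adapter tail and binding region:
      # fold it into the tail so the concatenation invariant holds
      if (startsWith(printed_sequence, tail) &&
          endsWith(printed_sequence, binding_region)) {
        tail <- substring(printed_sequence, 1L,
                          nchar(printed_sequence) - nchar(binding_region))
      } else {
        stop("printed_sequence != tail + binding_region for primer ", name,
             call. = FALSE)
      }
    }
  }
  for (s in c(printed_sequence, binding_region)) {
    bad <- invalid_iupac_letters(s)
    if (length(bad) > 0L) {
      stop("non-IUPAC letters in primer ", name, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (nchar(binding_region) < 15L) {
    stop("binding region of primer ", name, " is shorter than 15 nt",
         call. = FALSE)
  }
  structure(
    list(name = name, printed_sequence = printed_sequence, tail = tail,
         binding_region = binding_region, role = role),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s (%s)\n  tail:    %s\n  binding: %s (%d nt)\n",
              x$name, x$role, ifelse(nchar(x$tail) > 0, x$tail, "<none>"),
              x$binding_region, nchar(x$binding_region)))
  invisible(x)
}

#' Construct a primer pair
#'
#' @param barcode Label for the amplified region (e.g. `"ITS1"`, `"ITS2"`).
#' @param forward,reverse [primer()] objects with matching roles.
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(barcode, forward, reverse) {
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"))
  if (forward$role != "forward") stop("forward primer has role ", forward$role,
                                      call. = FALSE)
  if (reverse$role != "reverse") stop("reverse primer has role ", reverse$role,
                                      call. = FALSE)
  structure(list(barcode = barcode, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n", x$barcode))
  print(x$forward); print(x$reverse)
  invisible(x)
}

#' The two fungal ITS fusion-primer pairs evaluated by the package
#'
#' Returns the ITS1 pair (ITS1Fngs / ITS2) and the ITS2 pair
#' (ITS3tagmix1-5 / ITS4ngs) with their published fusion sequences. The
#' Illumina adapter tails (33 nt forward, 34 nt reverse) do not anneal to
#' the template and are excluded from matching; for ITS3tagmix1-5 the 9-nt
#' sample tag following the adapter is likewise assigned to the tail, so its
#' default binding region is the 18-nt ITS3-ngs core `CATCGATGAAGAACGCAG`.
#' All binding regions can be overridden via [primer()].
#'
#' @return Named list with elements `ITS1` and `ITS2`, each a [primer_pair()].
#' @examples
#' pairs <- default_primer_pairs()
#' pairs$ITS1$forward$binding_region  # "GGTCATTTAGAGGAAGTAA"
#' @export
default_primer_pairs <- function() {
  its1f <- primer(
    "ITS1Fngs",
    paste0(FORWARD_TAIL, "GGTCATTTAGAGGAAGTAA"),
    tail = FORWARD_TAIL, role = "forward"
  )
  its2 <- primer(
    "ITS2",
    paste0(REVERSE_TAIL, "GCTGCGTTCTTCATCGATGC"),
    tail = REVERSE_TAIL, role = "reverse"
  )
  its3 <- primer(
    "ITS3tagmix1-5",
    paste0(FORWARD_TAIL, "TAGACTCGTCATCGATGAAGAACGCAG"),
    tail = FORWARD_TAIL, role = "forward",
    binding_region = "CATCGATGAAGAACGCAG"
  )
  its4 <- primer(
    "ITS4ngs",
    paste0(REVERSE_TAIL, "TTCCTSCGCTTATTGATATGC"),
    tail = REVERSE_TAIL, role = "reverse"
  )
  list(
    ITS1 = primer_pair("ITS1", its1f, its2),
    ITS2 = primer_pair("ITS2", its3, its4)
  )
}

#' In silico PCR parameters
#'
#' Encodes the site-acceptance rules and amplicon constraints: at most
#' `max_mismatches` per primer, no run of `forbid_consecutive_run` or more
#' successive mismatches, and no mismatch within the `protected_3prime_bases`
#' 3'-terminal bases of either primer.
#'
#' @param max_mismatches Maximum mismatches allowed per primer (default 3).
#' @param forbid_consecutive_run Reject a site containing a run of at least
#'   this many successive mismatches (default 3).
#' @param protected_3prime_bases Reject any mismatch within this many bases
#'   of the primer 3' end (default 2).
#' @param min_amplicon_length,max_amplicon_length Length bounds in nt applied
#'   to the amplicon as defined by `include_primers` (defaults 50 and 900).
#' @param include_primers If `FALSE` (default) the amplicon is the
#'   inter-primer region; if `TRUE` it spans both binding sites.
#' @param scan_both_strands Scan the reverse strand too (default `TRUE`).
#' @param ambiguity_mode Template ambiguity handling, see
#'   [iupac_compatible()].
#' @return A list of class `pcr_params`.
#' @export
pcr_params <- function(max_mismatches = 3L,
                       forbid_consecutive_run = 3L,
                       protected_3prime_bases = 2L,
                       min_amplicon_length = 50L,
                       max_amplicon_length = 900L,
                       include_primers = FALSE,
                       scan_both_strands = TRUE,
                       ambiguity_mode = c("intersect", "strict")) {
  ambiguity_mode <- match.arg(ambiguity_mode)
  stopifnot(
    max_mismatches >= 0L, forbid_consecutive_run >= 1L,
    protected_3prime_bases >= 0L,
    min_amplicon_length >= 0L,
    min_amplicon_length <= max_amplicon_length
  )
  structure(
    list(
      max_mismatches = as.integer(max_mismatches),
      forbid_consecutive_run = as.integer(forbid_consecutive_run),
      protected_3prime_bases = as.integer(protected_3prime_bases),
      min_amplicon_length = as.integer(min_amplicon_length),
      max_amplicon_length = as.integer(max_amplicon_length),
      include_primers = isTRUE(include_primers),
      scan_both_strands = isTRUE(scan_both_strands),
      ambiguity_mode = ambiguity_mode
    ),
    class = "pcr_params"
  )
}

#' Read primer definitions from a YAML config
#'
#' The file holds a list of blocks with fields `name`, `printed_sequence`,
#' `tail`, `role`, optional `binding_region`, grouped per pair under
#' `barcode`. The concatenation invariant is validated on load.
#'
#' @param path YAML file path.
#' @return Named list of [primer_pair()] objects.
#' @export
read_primer_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pairs <- purrr::map(cfg$pairs, function(p) {
    primer_pair(
      p$barcode,
      primer(p$forward$name, p$forward$printed_sequence,
             tail = p$forward$tail %||% "", role = "forward",
             binding_region = p$forward$binding_region),
      primer(p$reverse$name, p$reverse$printed_sequence,
             tail = p$reverse$tail %||% "", role = "reverse",
             binding_region = p$reverse$binding_region)
    )
  })
  setNames(pairs, purrr::map_chr(pairs, "barcode"))
}
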