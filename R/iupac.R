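#' @keywords internal
"_PACKAGE"

## Usethis-style package-level imports live here.
#' @importFrom rlang .data .env
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm setNames t.test
#' @importFrom utils head modifyList
NULL

# IUPAC nucleotide code -> set of concrete bases
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

# 15x15 logical matrix: TRUE iff the two codes' base sets intersect
.iupac_compat_matrix <- local({
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  for (a in IUPAC_LETTERS) {
    for (b in IUPAC_LETTERS) {
      m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
    }
  }
  m
})

# Strict variant: any template (column) ambiguity code is incompatible with
# everything; concrete template bases behave as usual.
.iupac_compat_matrix_strict <- local({
  m <- .iupac_compat_matrix
  m[, setdiff(IUPAC_LETTERS, c("A", "C", "G", "T"))] <- FALSE
  m
})

compat_matrix <- function(ambiguity_mode = c("intersect", "strict")) {
  ambiguity_mode <- match.arg(ambiguity_mode)
  if (ambiguity_mode == "strict") .iupac_compat_matrix_strict else .iupac_compat_matrix
}

#' Are two IUPAC nucleotide symbols compatible?
#'
#' Two symbols are compatible when the base sets they denote intersect, e.g.
#' `S` (= C or G) is compatible with `C` but not with `A`; `N` is compatible
#' with everything. This is the matching rule used throughout the
#' amplification engine, so a degenerate primer base never counts as a
#' mismatch against a template base it could anneal to.
#'
#' @param primer_base,target_base Single IUPAC nucleotide symbols
#'   (vectorised; recycled to common length).
#' @param ambiguity_mode `"intersect"` (default) applies set intersection on
#'   both sides; `"strict"` counts any ambiguity code in the *target* as a
#'   mismatch regardless of the primer base.
#' @return Logical vector.
#' @examples
#' iupac_compatible("S", "C")  # TRUE
#' iupac_compatible("S", "A")  # FALSE
#' iupac_compatible("N", c("A", "C", "G", "T"))  # all TRUE
#' @export
iupac_compatible <- function(primer_base, target_base,
                             ambiguity_mode = c("intersect", "strict")) {
  p <- toupper(as.character(primer_base))
  t <- toupper(as.character(target_base))
  bad <- setdiff(unique(c(p, t)), IUPAC_LETTERS)
  if (length(bad) > 0L) {
    stop("non-IUPAC nucleotide symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- compat_matrix(ambiguity_mode)
  unname(m[cbind(p, t)])
}

# Split a DNA string into a character vector of single upper-case letters.
seq_chars <- function(x) {
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

.RC_MAP <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse-complement an IUPAC DNA string
#'
#' @param x Character vector of IUPAC DNA strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(unname(.RC_MAP[seq_chars(s)])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Validate a DNA string against the IUPAC alphabet; returns offending letters.
invalid_iupac_letters <- function(x) {
  setdiff(unique(seq_chars(x)), IUPAC_LETTERS)
}
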