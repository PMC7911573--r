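# Nearest-neighbor duplex melting temperature.
#
# Perfectly matched stacks use the unified NN parameter set (SantaLucia &
# Hicks 2004); each mismatched position removes its flanking stacks'
# stabilisation and adds a fixed enthalpic penalty, which makes Tm strictly
# decrease with every added mismatch. Conditions are fixed: 50 mM monovalent
# salt, 0.25 uM total oligo, entropic salt correction 0.368*(N-1)*ln[Na+].

# dH kcal/mol, dS cal/(mol*K), keyed by the 5'->3' top-strand dimer of a
# Watson-Crick stack.
.NN_DH <- c(
  AA = -7.6, TT = -7.6, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.NN_DS <- c(
  AA = -21.3, TT = -21.3, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
.NN_INIT_DH <- 0.2;  .NN_INIT_DS <- -5.7
.NN_TERM_AT_DH <- 2.2; .NN_TERM_AT_DS <- 6.9
.MISMATCH_DH_PENALTY <- 3.0   # kcal/mol per mismatched pair

.GAS_CONSTANT <- 1.987        # cal/(mol*K)

#' Melting temperature of a primer:template duplex
#'
#' Nearest-neighbor Tm estimate for the duplex formed by a primer binding
#' region annealed to a template window (in primer orientation). Matched
#' positions contribute unified NN stack parameters; a degenerate primer
#' base is resolved to the base complementary to the template. Stacks
#' involving a mismatched position contribute nothing, and each mismatch
#' adds a fixed destabilising enthalpy penalty, so Tm strictly decreases
#' with every additional mismatch in an otherwise fixed window. Conditions:
#' 50 mM monovalent salt, 0.25 uM total oligo.
#'
#' @param binding_region Primer binding region, 5'->3' IUPAC DNA.
#' @param window Template window of equal length, in primer orientation.
#'   Ambiguity codes in the window are resolved to a primer-compatible base
#'   when possible, otherwise the position counts as mismatched.
#' @param ambiguity_mode See [iupac_compatible()].
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temperature("GCTGCGTTCTTCATCGATGC", "GCTGCGTTCTTCATCGATGC")
#' @export
melting_temperature <- function(binding_region, window,
                                ambiguity_mode = c("intersect", "strict")) {
  ambiguity_mode <- match.arg(ambiguity_mode)
  p <- seq_chars(binding_region)
  w <- seq_chars(window)
  if (length(p) != length(w)) {
    stop("binding region and window differ in length", call. = FALSE)
  }
  n <- length(p)
  m <- compat_matrix(ambiguity_mode)
  matched <- m[cbind(p, w)]

  # concrete top (primer) strand of the duplex: at matched positions the
  # primer base resolved against the template; elsewhere any concrete
  # representative (its stacks carry no parameters anyway)
  top <- character(n)
  for (i in seq_len(n)) {
    pset <- IUPAC_SETS[[p[i]]]
    wset <- IUPAC_SETS[[w[i]]]
    if (matched[i]) {
      # window is written in primer orientation, so the resolved primer base
      # is any member of the set intersection
      top[i] <- intersect(pset, wset)[1]
    } else {
      top[i] <- pset[1]
    }
  }

  dh <- .NN_INIT_DH
  ds <- .NN_INIT_DS
  for (i in seq_len(n - 1L)) {
    if (matched[i] && matched[i + 1L]) {
      dimer <- paste0(top[i], top[i + 1L])
      dh <- dh + .NN_DH[[dimer]]
      ds <- ds + .NN_DS[[dimer]]
    }
  }
  for (i in c(1L, n)) {
    if (matched[i] && top[i] %in% c("A", "T")) {
      dh <- dh + .NN_TERM_AT_DH
      ds <- ds + .NN_TERM_AT_DS
    }
  }
  dh <- dh + .MISMATCH_DH_PENALTY * sum(!matched)

  na_molar <- 0.05
  ct <- 0.25e-6
  ds_corr <- ds + 0.368 * (n - 1L) * log(na_molar)
  1000 * dh / (ds_corr + .GAS_CONSTANT * log(ct / 4)) - 273.15
}

#' Recommended annealing temperature
#'
#' The conventional PCR guidance of annealing about 5 degrees C below the
#' primer melting temperature.
#'
#' @param tm Melting temperature(s) in degrees Celsius.
#' @return `tm - 5`.
#' @examples
#' recommended_annealing(60)  # 55
#' @export
recommended_annealing <- function(tm) {
  stopifnot(is.numeric(tm), all(is.finite(tm)))
  tm - 5.0
}
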