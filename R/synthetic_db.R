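# Synthetic UNITE-like database generator with planted primer binding sites
# and a machine-readable truth table. Every record carries one planted
# region per primer pair; whether the region amplifies is decided by design
# (exact per-taxon fractions), so the generator's truth table is exact, not
# probabilistic.

FAILURE_PLANS <- c("exceed-count", "consecutive-run", "3prime-hit",
                   "missing-site")

#' Specify a synthetic reference database
#'
#' @param taxa A data frame with one row per taxon: the seven rank columns
#'   (`kingdom` ... `species`; use `"unidentified"` tokens for designed
#'   unidentified lineages), `n_records`, per-pair amplifiable fractions
#'   `its1_fraction` / `its2_fraction` in `[0, 1]`, and per-pair failure
#'   plans `its1_plan` / `its2_plan` (one of `"exceed-count"`,
#'   `"consecutive-run"`, `"3prime-hit"`, `"missing-site"`) applied to the
#'   records designed not to amplify.
#' @param insert_len A data frame with columns `pair` (`"ITS1"`, `"ITS2"`),
#'   `mean`, `sd`: the normal distribution (truncated at the amplicon
#'   length bounds) of planted inter-primer insert lengths, in nt.
#' @param unidentified_species_fraction Fraction of each taxon's records
#'   whose species label is rewritten to `"unidentified"` (nested planting
#'   of unidentified labels at deeper structure is done via `taxa`
#'   templates).
#' @param flank_len Length of the random flanks (nt).
#' @param spacer_len Length of the random spacer between the two planted
#'   regions (nt).
#' @param design_budget Mismatch budget the truth labels are designed
#'   against (default 3): amplifiable records carry 0..`design_budget`
#'   planted benign mismatches on the forward primer, cycling
#'   deterministically so coverage grows stepwise with the allowed budget.
#' @param params [pcr_params()] supplying the length bounds and acceptance
#'   rule constants the planting respects.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(taxa, insert_len,
                           unidentified_species_fraction = 0,
                           flank_len = 60L, spacer_len = 20L,
                           design_budget = 3L,
                           params = pcr_params()) {
  taxa <- as_tibble(taxa)
  need <- c(TAXONOMIC_RANKS, "n_records", "its1_fraction", "its2_fraction",
            "its1_plan", "its2_plan")
  missing_cols <- setdiff(need, names(taxa))
  if (length(missing_cols) > 0L) {
    stop("taxa is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fr <- c(taxa$its1_fraction, taxa$its2_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("amplifiable fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(taxa$n_records < 1L)) stop("n_records must be >= 1", call. = FALSE)
  if (!all(c(taxa$its1_plan, taxa$its2_plan) %in% FAILURE_PLANS)) {
    stop("failure plans must be one of: ",
         paste(FAILURE_PLANS, collapse = ", "), call. = FALSE)
  }
  insert_len <- as_tibble(insert_len)
  stopifnot(all(c("pair", "mean", "sd") %in% names(insert_len)),
            all(c("ITS1", "ITS2") %in% insert_len$pair),
            all(insert_len$sd >= 0))
  if (unidentified_species_fraction < 0 || unidentified_species_fraction > 1) {
    stop("unidentified_species_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      taxa = taxa, insert_len = insert_len,
      unidentified_species_fraction = unidentified_species_fraction,
      flank_len = as.integer(flank_len),
      spacer_len = as.integer(spacer_len),
      design_budget = as.integer(design_budget),
      params = params
    ),
    class = "synthetic_spec"
  )
}

#' Canned synthetic spec with a designed ITS1-vs-ITS2 coverage bias
#'
#' A fixed specification qualitatively mirroring known contrasts between the
#' two ITS barcodes: a Tulasnellaceae-like family amplified by the ITS1 pair
#' only (48% vs 0%), an Aspergillus-like genus biased towards ITS1 (89% vs
#' 56%) opposed to a Penicillium-like genus biased towards ITS2 (68% vs
#' 92%), further ITS2-favoured taxa (>90% vs 43-70%) and ITS1-favoured taxa
#' (>90% vs 20-59%), filler taxa spreading records over 11 phyla plus
#' unidentified-lineage records, and ITS2-analogue inserts 100 nt longer
#' than ITS1-analogue ones on average.
#'
#' @return A [synthetic_spec()].
#' @export
its_bias_spec <- function() {
  lin <- function(p, c, o, f, g, s) {
    tibble(kingdom = "Fungi", phylum = p, class = c, order = o,
           family = f, genus = g, species = s)
  }
  u <- "unidentified"
  focal <- dplyr::bind_rows(
    lin("Basidiomycota", "Agaricomycetes", "Cantharellales",
        "Tulasnellaceae", "Tulasnella", "Tulasnella_calospora") |>
      dplyr::mutate(n_records = 100L, its1_fraction = 0.48,
                    its2_fraction = 0.00,
                    its1_plan = "3prime-hit", its2_plan = "3prime-hit"),
    lin("Ascomycota", "Eurotiomycetes", "Eurotiales",
        "Trichocomaceae", "Aspergillus", "Aspergillus_fumigatus") |>
      dplyr::mutate(n_records = 100L, its1_fraction = 0.89,
                    its2_fraction = 0.56,
                    its1_plan = "exceed-count", its2_plan = "consecutive-run"),
    lin("Ascomycota", "Eurotiomycetes", "Eurotiales",
        "Aspergillaceae", "Penicillium", "Penicillium_chrysogenum") |>
      dplyr::mutate(n_records = 100L, its1_fraction = 0.68,
                    its2_fraction = 0.92,
                    its1_plan = "missing-site", its2_plan = "exceed-count"),
    lin("Ascomycota", "Dothideomycetes", "Dothideales",
        "Dothioraceae", "Aureobasidium", "Aureobasidium_pullulans") |>
      dplyr::mutate(n_records = 50L, its1_fraction = 0.50,
                    its2_fraction = 0.92,
                    its1_plan = "consecutive-run", its2_plan = "3prime-hit"),
    lin("Ascomycota", "Dothideomycetes", "Botryosphaeriales",
        "Botryosphaeriaceae", "Botryosphaeria", "Botryosphaeria_dothidea") |>
      dplyr::mutate(n_records = 50L, its1_fraction = 0.44,
                    its2_fraction = 0.96,
                    its1_plan = "exceed-count", its2_plan = "missing-site"),
    lin("Mucoromycota", "Mucoromycetes", "Mucorales",
        "Mucoraceae", "Mucor", "Mucor_circinelloides") |>
      dplyr::mutate(n_records = 50L, its1_fraction = 0.70,
                    its2_fraction = 0.90,
                    its1_plan = "3prime-hit", its2_plan = "exceed-count"),
    lin("Ascomycota", "Saccharomycetes", "Saccharomycetales",
        "Saccharomycetaceae", "Saccharomyces", "Saccharomyces_cerevisiae") |>
      dplyr::mutate(n_records = 50L, its1_fraction = 0.66,
                    its2_fraction = 0.98,
                    its1_plan = "missing-site", its2_plan = "consecutive-run"),
    lin("Basidiomycota", "Pucciniomycetes", "Pucciniales",
        "Pucciniaceae", "Puccinia", "Puccinia_graminis") |>
      dplyr::mutate(n_records = 50L, its1_fraction = 0.92,
                    its2_fraction = 0.40,
                    its1_plan = "exceed-count", its2_plan = "3prime-hit"),
    lin("Ascomycota", "Sordariomycetes", "Hypocreales",
        "Ophiocordycipitaceae", "Ophiocordyceps", "Ophiocordyceps_sinensis") |>
      dplyr::mutate(n_records = 50L, its1_fraction = 0.94,
                    its2_fraction = 0.58,
                    its1_plan = "consecutive-run", its2_plan = "missing-site"),
    lin("Microsporidia", u, u, u, u, u) |>
      dplyr::mutate(n_records = 50L, its1_fraction = 0.96,
                    its2_fraction = 0.20,
                    its1_plan = "3prime-hit", its2_plan = "exceed-count"),
    lin("Ascomycota", "Archaeorhizomycetes", "Archaeorhizomycetales",
        "Archaeorhizomycetaceae", "Archaeorhizomyces",
        "Archaeorhizomyces_finlayi") |>
      dplyr::mutate(n_records = 50L, its1_fraction = 0.90,
                    its2_fraction = 0.30,
                    its1_plan = "missing-site", its2_plan = "consecutive-run"),
    lin("Basidiomycota", "Agaricomycetes", "Agaricales",
        "Mycenaceae", "Mycena", "Mycena_galericulata") |>
      dplyr::mutate(n_records = 50L, its1_fraction = 0.98,
                    its2_fraction = 0.52,
                    its1_plan = "exceed-count", its2_plan = "3prime-hit")
  )
  filler_phyla <- c("Chytridiomycota", "Glomeromycota", "Rozellomycota",
                    "Zoopagomycota", "Olpidiomycota", "Neocallimastigomycota",
                    "Blastocladiomycota", "Entorrhizomycota")
  filler <- purrr::map_dfr(filler_phyla, function(p) {
    lin(p, paste0(p, "_class"), paste0(p, "_order"), paste0(p, "_family"),
        paste0(p, "_genus"), paste0(p, "_genus_sp")) |>
      dplyr::mutate(n_records = 15L, its1_fraction = 0.8,
                    its2_fraction = 0.6,
                    its1_plan = "exceed-count", its2_plan = "exceed-count")
  })
  unidentified_fillers <- dplyr::bind_rows(
    lin(u, u, u, u, u, u) |>
      dplyr::mutate(n_records = 20L, its1_fraction = 0.5,
                    its2_fraction = 0.5,
                    its1_plan = "missing-site", its2_plan = "missing-site"),
    lin("Ascomycota", u, u, u, u, u) |>
      dplyr::mutate(n_records = 20L, its1_fraction = 0.75,
                    its2_fraction = 0.75,
                    its1_plan = "3prime-hit", its2_plan = "3prime-hit")
  )
  synthetic_spec(
    taxa = dplyr::bind_rows(focal, filler, unidentified_fillers),
    insert_len = tibble(pair = c("ITS1", "ITS2"),
                        mean = c(250, 350), sd = c(40, 60)),
    unidentified_species_fraction = 0.2
  )
}

# ---- internal planting helpers ----------------------------------------

.ALPHABET <- c("A", "C", "G", "T")

# concrete instance of an IUPAC binding region (ambiguity resolved randomly)
concrete_instance <- function(binding_chars) {
  vapply(binding_chars, function(b) {
    s <- IUPAC_SETS[[b]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1), USE.NAMES = FALSE)
}

# a base incompatible with the given primer base (never exists for N; the
# generator's primers contain no N)
incompatible_base <- function(primer_base) {
  pool <- setdiff(.ALPHABET, IUPAC_SETS[[primer_base]])
  if (length(pool) == 0L) stop("cannot plant a mismatch against N",
                               call. = FALSE)
  sample(pool, 1L)
}

has_run3 <- function(pos0) {
  if (length(pos0) < 3L) return(FALSE)
  p <- sort(pos0)
  any(diff(p, lag = 2L) == 2L)
}

# sample k benign mismatch positions (0-based): outside the protected 3'
# window, no run of >= forbid_run
sample_benign_positions <- function(k, n, protected, forbid_run) {
  if (k == 0L) return(integer())
  allowed <- 0:(n - protected - 1L)
  repeat {
    pos <- sort(sample(allowed, k))
    if (!has_run3(pos) || forbid_run > 3L) return(pos)
  }
}

# positions violating acceptance per failure plan (0-based)
plan_positions <- function(plan, n, protected, budget) {
  switch(
    plan,
    "exceed-count" = {
      repeat {
        pos <- sort(sample(0:(n - protected - 1L), budget + 1L))
        if (!has_run3(pos)) return(pos)
      }
    },
    "consecutive-run" = {
      start <- sample(0:(n - protected - 3L), 1L)
      start + 0:2
    },
    "3prime-hit" = sample((n - protected):(n - 1L), 1L),
    "missing-site" = integer()
  )
}

# random ACGT segment screened to contain no window within `budget`
# mismatches of any pattern in `patterns` (a DNAStringSet)
screened_segment <- function(len, patterns, budget) {
  if (len == 0L) return("")
  repeat {
    s <- paste(sample(.ALPHABET, len, replace = TRUE), collapse = "")
    subj <- Biostrings::DNAString(s)
    clean <- TRUE
    for (i in seq_along(patterns)) {
      if (Biostrings::countPattern(patterns[[i]], subj,
                                   max.mismatch = budget,
                                   fixed = FALSE) > 0L) {
        clean <- FALSE
        break
      }
    }
    if (clean) return(s)
  }
}

# planted forward site: concrete instance with mismatches at pos0
plant_site <- function(binding_chars, pos0) {
  site <- concrete_instance(binding_chars)
  for (p in pos0) site[p + 1L] <- incompatible_base(binding_chars[p + 1L])
  paste(site, collapse = "")
}

draw_insert_len <- function(mean, sd, lo, hi) {
  repeat {
    x <- as.integer(round(rnorm(1L, mean, sd)))
    if (x >= lo && x <= hi) return(x)
  }
}

# ---- generator ---------------------------------------------------------

#' Generate a synthetic reference database with truth labels
#'
#' Deterministic given `seed`. Each record is assembled as
#' `flank + ITS2-analogue region + spacer + ITS1-analogue region + flank`,
#' where each region is a planted forward binding site, an insert of drawn
#' length, and the reverse complement of a planted reverse binding site.
#' Records designed to amplify carry 0-3 benign forward-primer mismatches
#' (scattered, outside the protected 3' window, cycling 0,1,2,3 so coverage
#' grows stepwise with the allowed mismatch budget); records designed not
#' to amplify get their taxon's failure plan planted on the forward site.
#' Mismatched template bases are IUPAC-incompatible with the primer base by
#' construction, and all random flanks/inserts/spacers are rejection-sampled
#' to contain no binding site within the design budget for any primer in
#' either orientation.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @param pairs Primer pairs to plant (default [default_primer_pairs()]).
#' @return A list of class `synthetic_db` with elements `db` (a `ref_db`
#'   tibble) and `truth` (per record: lineage, and per pair the
#'   `should_amplify` flag, planted forward-mismatch positions, failure
#'   plan, and planted insert length).
#' @export
generate_reference_db <- function(spec, seed = 1L,
                                  pairs = default_primer_pairs()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(as.integer(seed), generate_impl(spec, pairs))
}

generate_impl <- function(spec, pairs) {
  params <- spec$params
  budget <- spec$design_budget
  protected <- params$protected_3prime_bases

  f1 <- seq_chars(pairs$ITS1$forward$binding_region)
  r1 <- seq_chars(pairs$ITS1$reverse$binding_region)
  f2 <- seq_chars(pairs$ITS2$forward$binding_region)
  r2 <- seq_chars(pairs$ITS2$reverse$binding_region)
  screen_patterns <- Biostrings::DNAStringSet(c(
    pairs$ITS1$forward$binding_region, pairs$ITS1$reverse$binding_region,
    pairs$ITS2$forward$binding_region, pairs$ITS2$reverse$binding_region,
    revcomp(pairs$ITS1$forward$binding_region),
    revcomp(pairs$ITS1$reverse$binding_region),
    revcomp(pairs$ITS2$forward$binding_region),
    revcomp(pairs$ITS2$reverse$binding_region)
  ))

  ins1 <- spec$insert_len[spec$insert_len$pair == "ITS1", ]
  ins2 <- spec$insert_len[spec$insert_len$pair == "ITS2", ]
  lo <- params$min_amplicon_length
  hi <- params$max_amplicon_length

  n_amplifiable <- function(frac, n, taxon, pair) {
    k <- frac * n
    if (abs(k - round(k)) > 1e-9) {
      warning(sprintf(
        "taxon %s, pair %s: fraction %.3f of %d records is not an integer; rounding to %d",
        taxon, pair, frac, n, round(k)), call. = FALSE)
    }
    as.integer(round(k))
  }

  records <- vector("list", nrow(spec$taxa))
  truths <- vector("list", nrow(spec$taxa))
  for (t in seq_len(nrow(spec$taxa))) {
    tx <- spec$taxa[t, ]
    n <- tx$n_records
    k1 <- n_amplifiable(tx$its1_fraction, n, tx$genus, "ITS1")
    k2 <- n_amplifiable(tx$its2_fraction, n, tx$genus, "ITS2")
    amp1 <- seq_len(n) %in% sample(n, k1)
    amp2 <- seq_len(n) %in% sample(n, k2)
    # benign loads cycle 0..budget over each pair's amplifiable records
    load1 <- load2 <- rep(NA_integer_, n)
    load1[amp1] <- (seq_len(k1) - 1L) %% (budget + 1L)
    load2[amp2] <- (seq_len(k2) - 1L) %% (budget + 1L)
    n_unident_sp <- as.integer(round(spec$unidentified_species_fraction * n))
    species_unident <- seq_len(n) %in% sample(n, n_unident_sp)

    rec_rows <- vector("list", n)
    truth_rows <- vector("list", n)
    for (j in seq_len(n)) {
      # per-pair forward-site mismatch positions
      mk_region <- function(fwd_chars, rev_chars, amp, load, plan, ins) {
        if (amp) {
          pos <- sample_benign_positions(load, length(fwd_chars), protected,
                                         params$forbid_consecutive_run)
          fwd_site <- plant_site(fwd_chars, pos)
          used_plan <- NA_character_
        } else if (plan == "missing-site") {
          pos <- integer()
          fwd_site <- screened_segment(length(fwd_chars), screen_patterns,
                                       budget)
          used_plan <- plan
        } else {
          pos <- plan_positions(plan, length(fwd_chars), protected, budget)
          fwd_site <- plant_site(fwd_chars, pos)
          used_plan <- plan
        }
        ilen <- draw_insert_len(ins$mean, ins$sd, lo, hi)
        insert <- screened_segment(ilen, screen_patterns, budget)
        rev_site <- revcomp(paste(concrete_instance(rev_chars), collapse = ""))
        list(
          seq = paste0(fwd_site, insert, rev_site),
          pos = pos, plan = used_plan, insert_len = ilen
        )
      }
      reg1 <- mk_region(f1, r1, amp1[j], load1[j], tx$its1_plan, ins1)
      reg2 <- mk_region(f2, r2, amp2[j], load2[j], tx$its2_plan, ins2)
      flank1 <- screened_segment(spec$flank_len, screen_patterns, budget)
      flank2 <- screened_segment(spec$flank_len, screen_patterns, budget)
      spacer <- screened_segment(spec$spacer_len, screen_patterns, budget)
      # ITS2-analogue region first: keeps the forward-primer core embedded
      # in the ITS1 reverse site (the biological ITS3/ITS2-primer overlap)
      # from ever seeing a downstream reverse site
      seq <- paste0(flank1, reg2$seq, spacer, reg1$seq, flank2)

      id <- sprintf("SH%02d%04d.97", t, j)
      species_label <- if (species_unident[j]) "unidentified" else tx$species
      rec_rows[[j]] <- tibble(
        record_id = id, sequence = seq,
        kingdom = tx$kingdom, phylum = tx$phylum, class = tx$class,
        order = tx$order, family = tx$family, genus = tx$genus,
        species = species_label
      )
      truth_rows[[j]] <- tibble(
        record_id = id,
        kingdom = tx$kingdom, phylum = tx$phylum, class = tx$class,
        order = tx$order, family = tx$family, genus = tx$genus,
        species = species_label,
        its1_should_amplify = amp1[j],
        its1_fwd_mismatch_positions = paste(reg1$pos, collapse = ","),
        its1_plan = reg1$plan,
        its1_insert_len = reg1$insert_len,
        its2_should_amplify = amp2[j],
        its2_fwd_mismatch_positions = paste(reg2$pos, collapse = ","),
        its2_plan = reg2$plan,
        its2_insert_len = reg2$insert_len
      )
    }
    records[[t]] <- dplyr::bind_rows(rec_rows)
    truths[[t]] <- dplyr::bind_rows(truth_rows)
  }

  db <- dplyr::bind_rows(records)
  attr(db, "dialect") <- "whitespace"
  attr(db, "unidentified_tokens") <- default_unidentified_tokens()
  class(db) <- c("ref_db", class(db))
  structure(list(db = db, truth = dplyr::bind_rows(truths)),
            class = "synthetic_db")
}

#' Designed coverage fractions of a synthetic database
#'
#' Truth-table summary: per taxon (at a chosen rank) and pair, the designed
#' fraction of records that should amplify at the design budget.
#'
#' @param truth The `truth` tibble from [generate_reference_db()].
#' @param rank Rank at which to group (default `"genus"`).
#' @return A tibble with `taxon_label`, per-pair designed counts and
#'   percentages.
#' @export
truth_coverage <- function(truth, rank = "genus") {
  stopifnot(rank %in% TAXONOMIC_RANKS)
  truth |>
    dplyr::group_by(taxon_label = .data[[rank]]) |>
    dplyr::summarise(
      total_records = dplyr::n(),
      its1_amplified = sum(.data$its1_should_amplify),
      its2_amplified = sum(.data$its2_should_amplify),
      its1_percent = 100 * mean(.data$its1_should_amplify),
      its2_percent = 100 * mean(.data$its2_should_amplify),
      .groups = "drop"
    )
}

#' Write synthetic outputs: FASTA, truth TSV and the spec echo
#'
#' @param gen A `synthetic_db` from [generate_reference_db()].
#' @param dir Output directory (created if needed).
#' @param spec The [synthetic_spec()] used (echoed as YAML for provenance);
#'   omit to skip the echo.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(gen, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "synthetic_db.fasta")
  truth <- file.path(dir, "truth_table.tsv")
  write_reference_fasta(gen$db, fasta)
  readr::write_tsv(gen$truth, truth)
  paths <- c(fasta = fasta, truth = truth)
  if (!is.null(spec)) {
    spec_path <- file.path(dir, "synthetic_spec.yaml")
    yaml::write_yaml(
      list(
        taxa = as.data.frame(spec$taxa),
        insert_len = as.data.frame(spec$insert_len),
        unidentified_species_fraction = spec$unidentified_species_fraction,
        flank_len = spec$flank_len, spacer_len = spec$spacer_len,
        design_budget = spec$design_budget,
        params = unclass(spec$params)
      ),
      spec_path
    )
    paths <- c(paths, spec = spec_path)
  }
  invisible(paths)
}
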