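# Run orchestration: config round-trip, the amplify/summarize/synth stages,
# and provenance logging. The thin command-line wrapper in inst/cli/itspcr
# dispatches straight into these functions.

#' Build a run configuration
#'
#' @param database Path to the reference FASTA (`NULL` when the run starts
#'   from [run_synth()] output).
#' @param primers `"default"` for [default_primer_pairs()], or a path to a
#'   YAML primer config for [read_primer_config()].
#' @param params A [pcr_params()].
#' @param taxa Data frame of focal taxa (`rank`, `label`) for the coverage
#'   summary, or `NULL` to summarise every identified taxon at a rank.
#' @param out_dir Output directory.
#' @param universe `"amplified"` or `"all"`, see [unidentified_counts()].
#' @param seed Seed used by stages that draw random numbers.
#' @return A list of class `run_config`.
#' @export
run_config <- function(database = NULL, primers = "default",
                       params = pcr_params(), taxa = NULL,
                       out_dir = "itspcr_out",
                       universe = c("amplified", "all"), seed = 1L) {
  universe <- match.arg(universe)
  structure(
    list(database = database, primers = primers, params = params,
         taxa = if (!is.null(taxa)) as_tibble(taxa) else NULL,
         out_dir = out_dir, universe = universe, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' The round-trip is lossless: `read_run_config(write_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  x$taxa <- if (!is.null(x$taxa)) as.data.frame(x$taxa)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    database = x$database,
    primers = x$primers %||% "default",
    params = do.call(pcr_params, x$params %||% list()),
    taxa = if (!is.null(x$taxa)) dplyr::bind_rows(x$taxa),
    out_dir = x$out_dir %||% "itspcr_out",
    universe = x$universe %||% "amplified",
    seed = x$seed %||% 1L
  )
}

resolve_pairs <- function(config) {
  if (identical(config$primers, "default")) default_primer_pairs()
  else read_primer_config(config$primers)
}

log_msg <- function(..., log_file = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
}

#' Generate stage: synthetic database + truth table
#'
#' Delegates to [generate_reference_db()] and writes FASTA, truth TSV and
#' the spec echo into `out_dir`.
#'
#' @param spec A [synthetic_spec()] (default [its_bias_spec()]).
#' @param config A [run_config()] supplying `out_dir` and `seed`.
#' @return The `synthetic_db` object, invisibly; files on disk.
#' @export
run_synth <- function(spec = its_bias_spec(), config = run_config()) {
  gen <- generate_reference_db(spec, seed = config$seed)
  paths <- write_synthetic(gen, config$out_dir, spec = spec)
  log_msg("synth: wrote ", nrow(gen$db), " records to ", paths[["fasta"]])
  invisible(gen)
}

#' Amplification stage
#'
#' Reads the database, runs [amplify()] for every configured pair, writes a
#' per-pair hit TSV plus a run log recording parameters, database size and
#' per-pair amplified-record counts.
#'
#' @param config A [run_config()] with a readable `database` path.
#' @param db Optionally, an already-loaded `ref_db` (skips reading).
#' @return The combined hit tibble, invisibly; files on disk.
#' @export
run_amplify <- function(config, db = NULL) {
  if (is.null(db)) {
    if (is.null(config$database) || !file.exists(config$database)) {
      stop("database not readable: ", config$database %||% "<unset>",
           call. = FALSE)
    }
    db <- read_reference_fasta(config$database)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(config$out_dir, "run.log")
  pairs <- resolve_pairs(config)
  p <- config$params
  log_msg("amplify: ", nrow(db), " records; max_mismatches=", p$max_mismatches,
          " forbid_run=", p$forbid_consecutive_run,
          " protected_3prime=", p$protected_3prime_bases,
          " len=[", p$min_amplicon_length, ",", p$max_amplicon_length, "]",
          log_file = log_file)
  hits <- amplify(db, pairs, p)
  for (label in names(pairs)) {
    sub <- dplyr::filter(hits, .data$pair == label)
    path <- file.path(config$out_dir, paste0("hits_", label, ".tsv"))
    write_hits_tsv(sub, path)
    log_msg("amplify: pair ", label, ": ",
            length(amplified_record_set(sub)), " amplified records (",
            nrow(sub), " hits) -> ", path, log_file = log_file)
  }
  write_provenance(config, db, file.path(config$out_dir, "provenance.yaml"))
  invisible(hits)
}

#' Summary stage
#'
#' Emits the four summary tables per primer pair — per-taxon coverage,
#' unidentified counts, phylum representation, amplicon lengths — plus a
#' cross-pair coverage comparison (per-taxon percentage difference) and the
#' between-pair length t-test.
#'
#' @param config A [run_config()].
#' @param db A `ref_db` tibble.
#' @param hits Hit tibble from [run_amplify()] / [amplify()].
#' @return Named list of the summary tibbles, invisibly; TSVs on disk.
#' @export
run_summarize <- function(config, db, hits) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(config$out_dir, "run.log")
  pairs <- unique(hits$pair)
  if (nrow(hits) == 0L) {
    log_msg("summarize: empty hit table; summaries will be all zero",
            log_file = log_file)
    pairs <- names(resolve_pairs(config))
  }
  taxa <- config$taxa
  if (is.null(taxa)) {
    taxa <- db |>
      dplyr::filter(is_identified_label(.data$genus, "genus", db_tokens(db))) |>
      dplyr::distinct(label = .data$genus) |>
      dplyr::mutate(rank = "genus", .before = 1L)
  }
  per_pair <- purrr::map(setNames(pairs, pairs), function(label) {
    sub <- dplyr::filter(hits, .data$pair == label)
    list(
      coverage = coverage_by_taxon(db, sub, taxa),
      unidentified = unidentified_counts(db, sub, universe = config$universe),
      representation = phylum_representation(db, sub,
                                             universe = config$universe),
      lengths = representative_hits(sub) |>
        dplyr::select("record_id", "amplicon_length")
    )
  })
  out <- list(per_pair = per_pair)
  for (label in pairs) {
    for (tbl in c("coverage", "unidentified", "representation", "lengths")) {
      readr::write_tsv(per_pair[[label]][[tbl]],
                       file.path(config$out_dir,
                                 paste0(tbl, "_", label, ".tsv")))
    }
  }
  if (all(c("ITS1", "ITS2") %in% pairs)) {
    cmp <- coverage_comparison(per_pair$ITS1$coverage,
                               per_pair$ITS2$coverage)
    readr::write_tsv(cmp, file.path(config$out_dir,
                                    "coverage_comparison.tsv"))
    out$comparison <- cmp
    la <- per_pair$ITS1$lengths$amplicon_length
    lb <- per_pair$ITS2$lengths$amplicon_length
    if (length(la) >= 2L && length(lb) >= 2L) {
      lc <- length_comparison(la, lb, labels = c("ITS1", "ITS2"))
      readr::write_tsv(tidy(lc), file.path(config$out_dir,
                                           "length_comparison.tsv"))
      out$length_test <- lc
      log_msg(sprintf(
        "summarize: length t-test ITS1 (mean %.1f nt) vs ITS2 (mean %.1f nt): p = %.3g",
        lc$groups$mean[1], lc$groups$mean[2], lc$p_value),
        log_file = log_file)
    }
  }
  invisible(out)
}

#' Full pipeline: synthesise (optionally), amplify, summarise
#'
#' @param config A [run_config()]; when `config$database` is `NULL` the run
#'   starts by generating `spec` with [run_synth()].
#' @param spec Synthetic spec used when no database path is configured.
#' @return Named list with `db`, `hits` and the summaries, invisibly.
#' @export
run_all <- function(config = run_config(), spec = its_bias_spec()) {
  if (is.null(config$database)) {
    gen <- run_synth(spec, config)
    db <- gen$db
  } else {
    db <- read_reference_fasta(config$database)
  }
  hits <- run_amplify(config, db = db)
  summaries <- run_summarize(config, db, hits)
  invisible(list(db = db, hits = hits, summaries = summaries))
}

# machine-readable provenance: config, package version, input checksum
write_provenance <- function(config, db, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  x$taxa <- if (!is.null(x$taxa)) as.data.frame(x$taxa)
  checksum <- sum(utils::head(
    as.integer(charToRaw(paste(db$record_id, collapse = ""))), 1e6))
  yaml::write_yaml(
    list(
      config = x,
      package_version = as.character(utils::packageVersion("itspcr")),
      n_records = nrow(db),
      record_id_checksum = checksum
    ),
    path
  )
  invisible(path)
}
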