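# Programmatic fixtures shared across test files.

ACGT <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(ACGT, n, replace = TRUE), collapse = "")

# a sequence with exact binding sites for the given pair around an insert
make_template <- function(pair, insert_len = 200L, flank = 30L) {
  paste0(rand_dna(flank), pair$forward$binding_region, rand_dna(insert_len),
         revcomp(pair$reverse$binding_region), rand_dna(flank))
}

# small in-memory reference db: `n` records per (phylum, class, ...) lineage
# row; sequences carry exact ITS1-pair sites so every record amplifies
make_toy_db <- function(lineages, n_per = 2L, insert_len = 150L,
                        pair = default_primer_pairs()$ITS1, seed = 99L) {
  withr::with_seed(seed, {
    rows <- list()
    k <- 0L
    for (i in seq_len(nrow(lineages))) {
      for (j in seq_len(n_per)) {
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          record_id = sprintf("TOY%04d", k),
          sequence = make_template(pair, insert_len),
          kingdom = "Fungi",
          phylum = lineages$phylum[i],
          class = lineages$class[i], order = lineages$order[i],
          family = lineages$family[i], genus = lineages$genus[i],
          species = lineages$species[i]
        )
      }
    }
    db <- dplyr::bind_rows(rows)
    class(db) <- c("ref_db", class(db))
    db
  })
}

toy_lineages <- function() {
  tibble::tibble(
    phylum = c("Ascomycota", "Ascomycota", "Basidiomycota", "unidentified"),
    class = c("Eurotiomycetes", "unidentified", "Agaricomycetes",
              "unidentified"),
    order = c("Eurotiales", "unidentified", "Cantharellales", "unidentified"),
    family = c("Trichocomaceae", "unidentified", "Tulasnellaceae",
               "unidentified"),
    genus = c("Aspergillus", "unidentified", "Tulasnella", "unidentified"),
    species = c("Aspergillus_fumigatus", "unidentified",
                "Tulasnella_calospora", "unidentified")
  )
}

# write a ref_db-shaped tibble to a FASTA file in the whitespace dialect
write_toy_fasta <- function(db, path = tempfile(fileext = ".fasta")) {
  write_reference_fasta(db, path)
  path
}

# The full designed-bias synthetic run is expensive (~1 min); generate and
# amplify it once per session and share across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached_bias_run <- function(seed = 42L) {
  key <- paste0("bias_", seed)
  if (is.null(.fixture_cache[[key]])) {
    spec <- its_bias_spec()
    gen <- generate_reference_db(spec, seed = seed)
    hits <- amplify(gen$db, default_primer_pairs(), pcr_params())
    .fixture_cache[[key]] <- list(spec = spec, gen = gen, hits = hits)
  }
  .fixture_cache[[key]]
}

# small synthetic spec for fast unit tests
small_spec <- function() {
  taxa <- tibble::tibble(
    kingdom = "Fungi",
    phylum = c("Ascomycota", "Basidiomycota", "Mucoromycota"),
    class = c("Eurotiomycetes", "Agaricomycetes", "Mucoromycetes"),
    order = c("Eurotiales", "Cantharellales", "Mucorales"),
    family = c("Trichocomaceae", "Tulasnellaceae", "Mucoraceae"),
    genus = c("Aspergillus", "Tulasnella", "Mucor"),
    species = c("Aspergillus_fumigatus", "Tulasnella_calospora",
                "Mucor_circinelloides"),
    n_records = c(10L, 10L, 10L),
    its1_fraction = c(0.7, 0.5, 1.0),
    its2_fraction = c(0.4, 0.0, 0.8),
    its1_plan = c("exceed-count", "3prime-hit", "missing-site"),
    its2_plan = c("consecutive-run", "3prime-hit", "exceed-count")
  )
  synthetic_spec(
    taxa = taxa,
    insert_len = tibble::tibble(pair = c("ITS1", "ITS2"),
                                mean = c(150, 250), sd = c(20, 30)),
    unidentified_species_fraction = 0.2,
    flank_len = 40L, spacer_len = 15L
  )
}

cached_small_run <- function(seed = 7L) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_cache[[key]])) {
    gen <- generate_reference_db(small_spec(), seed = seed)
    hits <- amplify(gen$db, default_primer_pairs(), pcr_params())
    .fixture_cache[[key]] <- list(gen = gen, hits = hits)
  }
  .fixture_cache[[key]]
}
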