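test_that("generation is deterministic given a seed and fractions are exact", {
  spec <- small_spec()
  g1 <- generate_reference_db(spec, seed = 7)
  g2 <- generate_reference_db(spec, seed = 7)
  expect_identical(g1$db$sequence, g2$db$sequence)
  expect_identical(g1$truth, g2$truth)

  # byte-identical files too
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic(g1, d1, spec = spec)
  write_synthetic(g2, d2, spec = spec)
  for (f in c("synthetic_db.fasta", "truth_table.tsv", "synthetic_spec.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # designed amplifiable counts are exact per taxon and pair
  tc <- truth_coverage(g1$truth, rank = "genus")
  expect_equal(tc$its1_amplified[tc$taxon_label == "Aspergillus"], 7L)
  expect_equal(tc$its2_amplified[tc$taxon_label == "Tulasnella"], 0L)
  expect_equal(tc$its1_amplified[tc$taxon_label == "Mucor"], 10L)

  # a different seed preserves all truth fractions but changes sequences
  g3 <- generate_reference_db(spec, seed = 8)
  expect_equal(truth_coverage(g3$truth, "genus")[c("its1_amplified",
                                                   "its2_amplified")],
               tc[c("its1_amplified", "its2_amplified")])
  expect_false(identical(g1$db$sequence, g3$db$sequence))
})

test_that("generated FASTA parses back through the reference reader unchanged", {
  run <- cached_small_run()
  path <- tempfile(fileext = ".fasta")
  write_reference_fasta(run$gen$db, path)
  db2 <- read_reference_fasta(path)
  expect_equal(db2$record_id, run$gen$db$record_id)
  expect_equal(db2$sequence, run$gen$db$sequence)
  expect_equal(db2$species, run$gen$db$species)
})

test_that("truth labels are exact at the design budget: planted records amplify iff designed", {
  run <- cached_small_run()
  for (p in c("ITS1", "ITS2")) {
    amp <- amplified_record_set(run$hits[run$hits$pair == p, ])
    should <- run$gen$truth$record_id[run$gen$truth[[
      paste0(tolower(p), "_should_amplify")]]]
    expect_setequal(amp, should)
  }
})

test_that("failure plans defeat the matching acceptance rule at any budget up to the design budget", {
  run <- cached_small_run()
  gen <- run$gen
  pairs <- default_primer_pairs()
  # 3prime-hit Tulasnella records must stay unamplified even at k = 3
  tula <- gen$truth[gen$truth$genus == "Tulasnella" &
                      !gen$truth$its2_should_amplify, ]
  expect_gt(nrow(tula), 0L)
  seqs <- gen$db$sequence[match(tula$record_id, gen$db$record_id)]
  for (k in 0:3) {
    params_k <- pcr_params(max_mismatches = k)
    n_hits <- sum(vapply(seqs, function(s) {
      nrow(find_amplicons(s, pairs$ITS2, params_k))
    }, integer(1)))
    expect_equal(n_hits, 0L)
  }
  # exceed-count Aspergillus ITS1 failures carry 4 mismatches: rejected at
  # the design budget but recovered at k = 4
  asp <- gen$truth[gen$truth$genus == "Aspergillus" &
                     !gen$truth$its1_should_amplify, ]
  seqs <- gen$db$sequence[match(asp$record_id, gen$db$record_id)]
  n3 <- sum(vapply(seqs, function(s)
    nrow(find_amplicons(s, pairs$ITS1, pcr_params(max_mismatches = 3))),
    integer(1)))
  n4 <- sum(vapply(seqs, function(s)
    nrow(find_amplicons(s, pairs$ITS1, pcr_params(max_mismatches = 4))),
    integer(1)))
  expect_equal(n3, 0L)
  expect_equal(n4, nrow(asp))
})

test_that("planted insert lengths are reproduced exactly in the hits", {
  run <- cached_small_run()
  h1 <- representative_hits(run$hits[run$hits$pair == "ITS1", ])
  joined <- dplyr::inner_join(h1, run$gen$truth, by = "record_id")
  expect_equal(joined$amplicon_length, joined$its1_insert_len)
})

test_that("spec validation rejects malformed inputs", {
  spec <- small_spec()
  bad <- spec$taxa
  bad$its1_fraction[1] <- 1.5
  expect_error(synthetic_spec(bad, spec$insert_len), "fractions")
  bad <- spec$taxa
  bad$its2_plan[1] <- "typo-plan"
  expect_error(synthetic_spec(bad, spec$insert_len), "plans")
  expect_error(synthetic_spec(spec$taxa[, -1], spec$insert_len), "missing")
  expect_error(synthetic_spec(spec$taxa, spec$insert_len,
                              unidentified_species_fraction = 2), "fraction")
  # unsatisfiable fraction for tiny n: rounded with a warning
  tiny <- spec$taxa[1, ]
  tiny$n_records <- 3L
  tiny$its1_fraction <- 0.5
  tiny$its2_fraction <- 0
  expect_warning(generate_reference_db(
    synthetic_spec(tiny, spec$insert_len), seed = 1), "rounding")
})

test_that("the designed-bias spec encodes the documented contrasts", {
  spec <- its_bias_spec()
  tx <- spec$taxa
  tula <- tx[tx$family == "Tulasnellaceae", ]
  expect_equal(tula$its2_fraction, 0)
  expect_gt(tula$its1_fraction, 0)
  asp <- tx[tx$genus == "Aspergillus", ]
  pen <- tx[tx$genus == "Penicillium", ]
  expect_equal(c(asp$its1_fraction, asp$its2_fraction), c(0.89, 0.56))
  expect_equal(c(pen$its1_fraction, pen$its2_fraction), c(0.68, 0.92))
  # ITS2-analogue inserts longer on average
  il <- spec$insert_len
  expect_gt(il$mean[il$pair == "ITS2"], il$mean[il$pair == "ITS1"])
  # 11 phyla plus the unidentified bucket
  expect_gte(length(setdiff(unique(tx$phylum), "unidentified")), 11L)
})
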