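test_that("IUPAC compatibility is set intersection, with a strict template mode", {
  expect_true(iupac_compatible("S", "C"))
  expect_true(iupac_compatible("S", "G"))
  expect_false(iupac_compatible("S", "A"))
  expect_true(all(iupac_compatible("N", c("A", "C", "G", "T", "R", "N"))))
  expect_true(iupac_compatible("R", "D"))   # {A,G} meets {A,G,T}
  expect_false(iupac_compatible("R", "Y"))
  expect_error(iupac_compatible("S", "X"), "non-IUPAC")
  # strict mode: template ambiguity always mismatches
  expect_false(iupac_compatible("A", "N", ambiguity_mode = "strict"))
  expect_true(iupac_compatible("S", "C", ambiguity_mode = "strict"))
})

test_that("mismatch profiles report positions, runs and 3'-window hits", {
  p20 <- strrep("A", 20)
  prof <- mismatch_profile(p20, p20)
  expect_equal(prof$count, 0L)
  expect_equal(prof$longest_run, 0L)
  expect_false(prof$hits_3prime_window)

  # degenerate S matches G: no mismatch anywhere
  prof <- mismatch_profile("TTCCTSCGCTTATTGATATGC", "TTCCTGCGCTTATTGATATGC")
  expect_equal(prof$count, 0L)

  # planted run at offsets 3,4,5
  w <- seq_chars(p20); w[4:6] <- "C"
  prof <- mismatch_profile(p20, paste(w, collapse = ""))
  expect_equal(prof$positions, c(3L, 4L, 5L))
  expect_equal(prof$longest_run, 3L)

  # 21-mer with single terminal mismatch hits the protected window
  p21 <- strrep("A", 21)
  w <- seq_chars(p21); w[21] <- "G"
  prof <- mismatch_profile(p21, paste(w, collapse = ""),
                           protected_3prime_bases = 2L)
  expect_equal(prof$positions, 20L)
  expect_true(prof$hits_3prime_window)

  expect_error(mismatch_profile("ACGT", "ACG"), "length")
})

test_that("site acceptance enforces budget, run and 3'-protection rules", {
  params <- pcr_params()
  mk <- function(pos, n = 20L) {
    mism <- rep(FALSE, n); mism[pos + 1L] <- TRUE
    itspcr:::profile_from_logical(mism, params$protected_3prime_bases)
  }
  expect_false(site_accepted(mk(c(1, 5, 9, 13)), params))   # count 4 > 3
  expect_false(site_accepted(mk(c(2, 3, 4)), params))       # run of 3
  expect_false(site_accepted(mk(19), params))               # 3' terminal
  expect_false(site_accepted(mk(18), params))               # 3' window
  expect_true(site_accepted(mk(c(1, 8)), params))
  expect_true(site_accepted(mk(integer()), params))
})

test_that("acceptance rules are exact over all mismatch sets of size <= 3 on a 20-mer", {
  # each rule checked independently against its own direct predicate,
  # exhaustively: C(20,0)+C(20,1)+C(20,2)+C(20,3) = 1351 position sets
  n <- 20L
  params <- pcr_params()
  sets <- list(integer())
  for (k in 1:3) {
    cmb <- utils::combn(0:(n - 1L), k)
    sets <- c(sets, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  ok <- vapply(sets, function(pos) {
    mism <- rep(FALSE, n); mism[pos + 1L] <- TRUE
    prof <- itspcr:::profile_from_logical(mism, params$protected_3prime_bases)
    no_run3 <- !any(diff(sort(pos), lag = 2) == 2)
    no_3prime <- !any(pos >= n - 2L)
    site_accepted(prof, params) == (no_run3 && no_3prime)
  }, logical(1))
  expect_true(all(ok))

  # the count rule needs size-4 violations: scattered, clean of other rules
  withr::with_seed(11, {
    for (i in 1:50) {
      pos <- sort(sample(seq(0L, n - 3L, by = 2L), 4L))
      mism <- rep(FALSE, n); mism[pos + 1L] <- TRUE
      prof <- itspcr:::profile_from_logical(mism, 2L)
      expect_false(site_accepted(prof, params))
      expect_true(site_accepted(prof, pcr_params(max_mismatches = 4L)))
    }
  })
})

test_that("constructed template yields exactly one hit with exact coordinates", {
  withr::with_seed(21, {
    pair <- default_primer_pairs()$ITS1
    s <- make_template(pair, insert_len = 200L, flank = 30L)
    h <- find_amplicons(s, pair, pcr_params())
    expect_equal(nrow(h), 1L)
    expect_equal(h$strand, "+")
    expect_equal(h$fwd_start, 30L)
    expect_equal(h$amplicon_length, 200L)
    expect_equal(h$fwd_mismatches + h$rev_mismatches, 0L)
    expect_engine_equals_oracle(s, pair, pcr_params())

    # over-long insert: filtered by the length bound
    s_long <- make_template(pair, insert_len = 950L)
    expect_equal(nrow(find_amplicons(s_long, pair, pcr_params())), 0L)

    # forward site alone is not enough
    s_fwd_only <- paste0(rand_dna(30), pair$forward$binding_region,
                         rand_dna(200))
    expect_equal(nrow(find_amplicons(s_fwd_only, pair, pcr_params())), 0L)

    # sequence shorter than the binding region: empty, not an error
    expect_equal(nrow(find_amplicons("ACGT", pair, pcr_params())), 0L)
  })
})

test_that("reverse-complementing the template mirrors every hit onto the other strand", {
  withr::with_seed(31, {
    pairs <- default_primer_pairs()
    for (pair in pairs) {
      s <- make_template(pair, insert_len = 180L)
      h_fwd <- find_amplicons(s, pair, pcr_params())
      h_rev <- find_amplicons(revcomp(s), pair, pcr_params())
      expect_equal(nrow(h_fwd), nrow(h_rev))
      expect_setequal(h_rev$strand, "-")
      expect_equal(sort(h_rev$amplicon_length), sort(h_fwd$amplicon_length))
      expect_equal(sort(h_rev$fwd_mismatches), sort(h_fwd$fwd_mismatches))
      # coordinates mirror: start' = L - end
      L <- nchar(s)
      expect_equal(sort(L - h_rev$fwd_end), sort(h_fwd$fwd_start))
    }
  })
})

test_that("hit sets grow monotonically with the mismatch budget and k=0 means exact matching", {
  withr::with_seed(41, {
    pair <- default_primer_pairs()$ITS2
    fwd <- seq_chars(pair$forward$binding_region)
    key <- function(h) paste(h$strand, h$fwd_start, h$rev_start)
    for (i in 1:10) {
      # plant 0-2 benign mismatches in the forward site
      nmm <- sample(0:2, 1)
      site <- fwd
      if (nmm > 0) {
        pos <- sample(seq_len(length(fwd) - 2L), nmm)
        for (p in pos) site[p] <- setdiff(ACGT, OR_SETS[[fwd[p]]])[1]
      }
      s <- paste0(rand_dna(25), paste(site, collapse = ""), rand_dna(150),
                  revcomp(pair$reverse$binding_region), rand_dna(25))
      prev <- character()
      for (k in 0:3) {
        h <- find_amplicons(s, pair, pcr_params(max_mismatches = k))
        if (k == 0) {
          expect_true(all(h$fwd_mismatches == 0L & h$rev_mismatches == 0L))
        }
        expect_true(all(prev %in% key(h)))
        prev <- key(h)
      }
    }
  })
})

test_that("degenerate primer bases amplify every compatible template variant", {
  # ITS4ngs carries S = {C,G}: both concrete templates must amplify with
  # zero recorded mismatches
  pair <- default_primer_pairs()$ITS2
  withr::with_seed(51, {
    rev_site <- seq_chars(pair$reverse$binding_region)
    s_pos <- which(rev_site == "S")
    for (base in c("C", "G")) {
      inst <- rev_site; inst[s_pos] <- base
      s <- paste0(rand_dna(20), pair$forward$binding_region, rand_dna(120),
                  revcomp(paste(inst, collapse = "")), rand_dna(20))
      h <- find_amplicons(s, pair, pcr_params())
      expect_equal(nrow(h), 1L)
      expect_equal(h$rev_mismatches, 0L)
    }
  })
})

test_that("representative hit selection is deterministic under the tie-break rules", {
  pair <- default_primer_pairs()$ITS1
  withr::with_seed(61, {
    # two forward sites upstream of one reverse site: two hits, one record
    s <- paste0(rand_dna(10), pair$forward$binding_region, rand_dna(60),
                pair$forward$binding_region, rand_dna(100),
                revcomp(pair$reverse$binding_region), rand_dna(10))
    h <- find_amplicons(s, pair, pcr_params(), record_id = "r")
    expect_equal(nrow(h), 2L)
    rep <- representative_hits(h)
    expect_equal(nrow(rep), 1L)
    # equal mismatches: the shorter amplicon wins
    expect_equal(rep$amplicon_length, min(h$amplicon_length))
    expect_equal(amplified_record_set(h), "r")
  })
})
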