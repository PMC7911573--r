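mk_hits <- function(ids) {
  h <- itspcr:::empty_hits()
  if (length(ids) == 0L) return(h)
  dplyr::bind_rows(h, tibble::tibble(
    record_id = ids, strand = "+", fwd_start = 0L, fwd_end = 19L,
    rev_start = 100L, rev_end = 120L, amplicon_start = 19L,
    amplicon_end = 100L, amplicon_length = 81L,
    fwd_mismatches = 0L, rev_mismatches = 0L,
    fwd_mismatch_positions = "", rev_mismatch_positions = "",
    fwd_longest_run = 0L, rev_longest_run = 0L,
    tm_fwd = 50, tm_rev = 50
  ))
}

test_that("amplified records are deduplicated across hits", {
  expect_setequal(amplified_record_set(mk_hits(c("a", "b", "a"))), c("a", "b"))
  expect_length(amplified_record_set(mk_hits(character())), 0L)
  expect_equal(amplified_record_set(mk_hits("x")), "x")
})

test_that("coverage percentages follow amplified/total per taxon", {
  db <- make_toy_db(toy_lineages(), n_per = 5L)   # 20 records
  # the 5 Ascomycota records with unidentified class (not Aspergillus)
  asco_unident <- db$record_id[db$phylum == "Ascomycota" &
                                 db$class == "unidentified"]
  tula <- taxon_members(db, "family", "Tulasnellaceae")    # 5 records
  hits <- mk_hits(c(asco_unident, tula))
  cov <- coverage_by_taxon(db, hits, tibble::tibble(
    rank = c("phylum", "family", "genus", "genus"),
    label = c("Ascomycota", "Tulasnellaceae", "Aspergillus", "Ghost")
  ))
  expect_equal(cov$percent[1], 50)
  expect_equal(cov$percent[2], 100)
  expect_equal(cov$percent[3], 0)          # no Aspergillus record amplified
  expect_equal(cov$total_records[4], 0L)   # absent taxon flagged by NA
  expect_true(is.na(cov$percent[4]))
  expect_true(all(cov$amplified_records <= cov$total_records))
  expect_error(coverage_by_taxon(db, hits,
                                 tibble::tibble(rank = "clade", label = "x")),
               "rank")
})

test_that("unidentified counts are per-rank, independent, over amplified records", {
  db <- make_toy_db(toy_lineages(), n_per = 2L)
  # amplify one fully identified and one fully unidentified-below-kingdom
  # record plus one unidentified-below-phylum record
  ids <- c(taxon_members(db, "genus", "Aspergillus")[1],
           db$record_id[db$phylum == "unidentified"][1],
           db$record_id[db$class == "unidentified" &
                          db$phylum == "Ascomycota"][1])
  u <- unidentified_counts(db, mk_hits(ids))
  expect_equal(as.character(u$rank),
               c("phylum", "class", "order", "family", "genus", "species"))
  expect_equal(u$n_unidentified, c(1L, 2L, 2L, 2L, 2L, 2L))
  # a record unidentified at family counts again at genus and species
  expect_true(all(diff(u$n_unidentified) >= 0))

  u_all <- unidentified_counts(db, mk_hits(character()), universe = "all")
  expect_equal(u_all$n_unidentified[1], 2L)   # both unidentified-phylum records
  u_amp <- unidentified_counts(db, mk_hits(character()))
  expect_equal(u_amp$n_unidentified, rep(0L, 6))
})

test_that("phylum representation lists zero-hit phyla and partitions the amplified set", {
  db <- make_toy_db(toy_lineages(), n_per = 3L)
  ids <- c(taxon_members(db, "phylum", "Ascomycota")[1:4],
           db$record_id[db$phylum == "unidentified"][1])
  rep <- phylum_representation(db, mk_hits(ids))
  expect_setequal(rep$phylum,
                  c("Ascomycota", "Basidiomycota", "unidentified"))
  expect_equal(rep$n_amplified[rep$phylum == "Ascomycota"], 4L)
  expect_equal(rep$n_amplified[rep$phylum == "Basidiomycota"], 0L)
  expect_equal(sum(rep$n_amplified), length(ids))   # partition property

  rep0 <- phylum_representation(db, mk_hits(character()))
  expect_true(all(rep0$n_amplified == 0L))
})

test_that("length comparison reproduces the Welch t-test computed from first principles", {
  withr::with_seed(91, {
    a <- rnorm(20, 250, 10)
    b <- rnorm(20, 400, 10)
  })
  lc <- length_comparison(a, b, labels = c("ITS1", "ITS2"))
  # independent oracle: Welch statistic from the closed-form definition
  se2 <- var(a) / length(a) + var(b) / length(b)
  t_manual <- (mean(a) - mean(b)) / sqrt(se2)
  df_manual <- se2^2 / ((var(a) / 20)^2 / 19 + (var(b) / 20)^2 / 19)
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  expect_equal(lc$t_statistic, t_manual, tolerance = 1e-10)
  expect_equal(lc$df, df_manual, tolerance = 1e-10)
  expect_equal(lc$p_value, p_manual, tolerance = 1e-10)
  expect_lt(lc$p_value, 0.001)

  # symmetry: swapping groups negates t, preserves p
  lc_sw <- length_comparison(b, a)
  expect_equal(lc_sw$t_statistic, -lc$t_statistic)
  expect_equal(lc_sw$p_value, lc$p_value)

  # identical degenerate samples: t = 0, p = 1
  lc_id <- length_comparison(c(5, 5, 5), c(5, 5, 5))
  expect_equal(lc_id$t_statistic, 0)
  expect_equal(lc_id$p_value, 1)

  expect_error(length_comparison(1, c(1, 2)), "at least two")
})

test_that("tidy and glance expose the comparison as one-row tibbles", {
  lc <- length_comparison(c(100, 110, 120), c(200, 210, 220),
                          labels = c("ITS1", "ITS2"))
  td <- tidy(lc)
  expect_equal(nrow(td), 1L)
  expect_equal(td$mean_diff, -100)
  gl <- glance(lc)
  expect_named(gl, c("t_statistic", "df", "p_value"))
})

test_that("coverage comparison reports signed per-taxon differences", {
  db <- make_toy_db(toy_lineages(), n_per = 4L)
  taxa <- tibble::tibble(rank = c("phylum", "family"),
                         label = c("Ascomycota", "Tulasnellaceae"))
  asco <- taxon_members(db, "phylum", "Ascomycota")
  tula <- taxon_members(db, "family", "Tulasnellaceae")
  cov1 <- coverage_by_taxon(db, mk_hits(c(asco, tula[1:2])), taxa)
  cov2 <- coverage_by_taxon(db, mk_hits(tula), taxa)
  cmp <- coverage_comparison(cov1, cov2)
  expect_equal(cmp$percent_diff, c(100, -50))
  expect_equal(cmp$sign, c(1, -1))
})

test_that("plot builders return ggplot objects", {
  db <- make_toy_db(toy_lineages(), n_per = 2L)
  hits <- mk_hits(db$record_id[1:3])
  cov <- coverage_by_taxon(db, hits,
                           tibble::tibble(rank = "phylum",
                                          label = c("Ascomycota",
                                                    "Basidiomycota")))
  expect_s3_class(plot_coverage(cov), "ggplot")
  expect_s3_class(ggplot2::autoplot(cov), "ggplot")
  expect_s3_class(plot_unidentified(unidentified_counts(db, hits)), "ggplot")
  expect_s3_class(plot_phylum_representation(phylum_representation(db, hits)),
                  "ggplot")
})
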