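# Per-taxon coverage, unidentified-taxon counts, phylum representation,
# amplicon-length comparison.

#' Records amplified at least once
#'
#' Deduplicates a hit table to the set of record ids with one or more
#' accepted amplicons, so a record is counted once regardless of hit
#' multiplicity.
#'
#' @param hits A hit tibble from [amplify()] / [find_amplicons()].
#' @return Character vector of unique record ids.
#' @export
amplified_record_set <- function(hits) {
  if (nrow(hits) == 0L) return(character())
  unique(hits$record_id)
}

#' Per-taxon amplification coverage
#'
#' For each requested (rank, label) taxon: the number of database records
#' carrying that identified label, how many of them were amplified, and the
#' coverage percentage (denominator = all records annotated to the taxon in
#' the database). A requested taxon absent from the database yields a row
#' with `total_records` 0 and `percent` `NA`.
#'
#' @param db A `ref_db` tibble.
#' @param hits Hit tibble (one primer pair; pre-filter if `hits` holds
#'   several pairs).
#' @param taxa A data frame with columns `rank` and `label`.
#' @return A tibble with `taxon_label`, `rank`, `total_records`,
#'   `amplified_records`, `percent`, rows in input order.
#' @export
coverage_by_taxon <- function(db, hits, taxa) {
  stopifnot(all(c("rank", "label") %in% names(taxa)))
  amp <- amplified_record_set(hits)
  rows <- purrr::map2(taxa$rank, taxa$label, function(rank, label) {
    members <- taxon_members(db, rank, label)
    total <- length(members)
    n_amp <- length(intersect(members, amp))
    tibble(
      taxon_label = label, rank = rank,
      total_records = total, amplified_records = n_amp,
      percent = if (total > 0L) 100 * n_amp / total else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coverage_table", class(out))
  out
}

#' Unidentified-taxon counts per rank among amplified records
#'
#' For each of the six sub-kingdom ranks (phylum ... species), counts the
#' distinct records whose lineage is unidentified at that rank. Counting is
#' independent per rank: a record unidentified at family also counts at
#' genus and species if those are unidentified too.
#'
#' @param db A `ref_db` tibble.
#' @param hits Hit tibble for one primer pair.
#' @param universe `"amplified"` (default) restricts to amplified records;
#'   `"all"` counts over the whole database regardless of amplification.
#' @return A tibble with `rank` (ordered factor levels phylum..species) and
#'   `n_unidentified`.
#' @export
unidentified_counts <- function(db, hits, universe = c("amplified", "all")) {
  universe <- match.arg(universe)
  sub <- if (universe == "amplified") {
    dplyr::filter(db, .data$record_id %in% amplified_record_set(hits))
  } else {
    db
  }
  tokens <- db_tokens(db)
  counts <- vapply(SUBKINGDOM_RANKS, function(r) {
    sum(!is_identified_label(sub[[r]], r, tokens))
  }, integer(1))
  tibble(
    rank = factor(SUBKINGDOM_RANKS, levels = SUBKINGDOM_RANKS),
    n_unidentified = unname(counts)
  )
}

#' Per-phylum representation of amplified records
#'
#' Counts amplified records per phylum; phyla present in the database but
#' with zero amplified records are still listed, and records with an
#' unidentified phylum are pooled into an `"unidentified"` bucket, so the
#' counts partition the amplified record set.
#'
#' @inheritParams unidentified_counts
#' @return A tibble with `phylum` and `n_amplified`.
#' @export
phylum_representation <- function(db, hits, universe = c("amplified", "all")) {
  universe <- match.arg(universe)
  tokens <- db_tokens(db)
  bucket <- dplyr::if_else(
    is_identified_label(db$phylum, "phylum", tokens), db$phylum, "unidentified"
  )
  levels <- unique(bucket)
  sub <- if (universe == "amplified") {
    db$record_id %in% amplified_record_set(hits)
  } else {
    rep(TRUE, nrow(db))
  }
  counts <- table(factor(bucket[sub], levels = levels))
  tibble(phylum = levels, n_amplified = as.integer(counts))
}

#' Compare two amplicon-length samples (Welch two-tailed t-test)
#'
#' @param lengths_a,lengths_b Numeric vectors of amplicon lengths (nt), at
#'   least two values each and nonzero variance in at least one group.
#' @param labels Length-2 character vector naming the groups.
#' @return A `length_comparison` object (list with per-group `n`, `mean`,
#'   `sd`, plus `t_statistic`, `df`, `p_value`). Degenerate equal-constant
#'   samples return `t = 0`, `p = 1`.
#' @seealso [generics::tidy()] and [generics::glance()] methods.
#' @export
length_comparison <- function(lengths_a, lengths_b,
                              labels = c("a", "b")) {
  stopifnot(length(labels) == 2L)
  if (length(lengths_a) < 2L || length(lengths_b) < 2L) {
    stop("need at least two lengths per group", call. = FALSE)
  }
  summ <- tibble(
    group = labels,
    n = c(length(lengths_a), length(lengths_b)),
    mean = c(mean(lengths_a), mean(lengths_b)),
    sd = c(stats::sd(lengths_a), stats::sd(lengths_b))
  )
  if (all(summ$sd == 0)) {
    if (summ$mean[1] == summ$mean[2]) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = 1)
    } else {
      stop("both groups have zero variance with different means; ",
           "t-test undefined", call. = FALSE)
    }
  } else {
    ht <- t.test(lengths_a, lengths_b, var.equal = FALSE,
                 alternative = "two.sided")
    tt <- list(statistic = ht$statistic, parameter = ht$parameter,
               p.value = ht$p.value)
  }
  structure(
    list(
      groups = summ,
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value
    ),
    class = "length_comparison"
  )
}

#' @export
print.length_comparison <- function(x, ...) {
  cat("Amplicon length comparison (Welch two-tailed t-test)\n")
  print(x$groups)
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Tidy an amplicon-length comparison
#'
#' @param x A `length_comparison` object.
#' @param ... Unused.
#' @return One-row tibble with group means, their difference, `t_statistic`,
#'   `df` and two-tailed `p_value`.
#' @method tidy length_comparison
#' @export
tidy.length_comparison <- function(x, ...) {
  tibble(
    group_a = x$groups$group[1], group_b = x$groups$group[2],
    mean_a = x$groups$mean[1], mean_b = x$groups$mean[2],
    mean_diff = x$groups$mean[1] - x$groups$mean[2],
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value
  )
}

#' @rdname tidy.length_comparison
#' @method glance length_comparison
#' @export
glance.length_comparison <- function(x, ...) {
  tibble(t_statistic = x$t_statistic, df = x$df, p_value = x$p_value)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' ITS1-vs-ITS2 coverage comparison table
#'
#' Joins two per-taxon coverage tables (one per primer pair) and reports the
#' per-taxon percentage-point difference.
#'
#' @param cov_a,cov_b [coverage_by_taxon()] tables for the two pairs.
#' @param labels Length-2 labels used as column suffixes.
#' @return A tibble with per-pair percentages and `percent_diff`
#'   (`a - b`) plus its `sign`.
#' @export
coverage_comparison <- function(cov_a, cov_b, labels = c("ITS1", "ITS2")) {
  a <- dplyr::select(cov_a, "taxon_label", "rank", "total_records", "percent")
  b <- dplyr::select(cov_b, "taxon_label", "rank", "percent")
  out <- dplyr::inner_join(a, b, by = c("taxon_label", "rank"),
                           suffix = paste0("_", labels))
  pa <- paste0("percent_", labels[1]); pb <- paste0("percent_", labels[2])
  out$percent_diff <- out[[pa]] - out[[pb]]
  out$sign <- sign(out$percent_diff)
  out
}

#' Round percentages for comparison against printed integers
#'
#' Half-up rounding (so 89.5 -> 90), matching how printed whole-number
#' percentages are compared.
#'
#' @param x Numeric vector of percentages.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
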