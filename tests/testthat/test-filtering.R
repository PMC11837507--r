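make_counts <- function(rows, frac_ids) {
  m <- do.call(rbind, rows)
  colnames(m) <- frac_ids
  m
}

test_that("ASV filter removes taxa failing both conditions (permissive rule)", {
  nf <- 25
  rows <- list(
    low_both = c(rep(10, 19), rep(0, nf - 19)),          # 190 total, 19 fracs
    high_count_low_spread = c(5000, 4000, 1000, rep(0, nf - 3)),
    low_count_high_spread = c(rep(1, 21), rep(0, nf - 21)),
    zero = rep(0, nf)
  )
  m <- taxon_matrix(make_counts(rows, paste0("F", 1:nf)),
                    setNames(sprintf("d__B;p__P;c__C;o__O;f__F;g__G%d", 1:4),
                             names(rows)))
  kept <- filter_asvs(m)
  expect_setequal(rownames(kept$counts),
                  c("high_count_low_spread", "low_count_high_spread"))
  rep <- attr(kept, "filter_report")
  expect_equal(rep$removed, 2L)

  strict <- suppressWarnings(filter_asvs(m, rule = "either"))
  expect_equal(nrow(strict$counts), 0L)
})

test_that("ASV with 199 total in 19 fractions is removed, monotone in thresholds", {
  nf <- 25
  edge <- c(rep(10, 18), 19, rep(0, nf - 19))  # total 199, 19 fractions
  keepme <- c(rep(11, 19), rep(0, nf - 19))    # total 209, 19 fractions
  m <- taxon_matrix(make_counts(list(edge = edge, keepme = keepme),
                                paste0("F", 1:nf)),
                    setNames(sprintf("d__B;p__P;c__C;o__O;f__F;g__G%d", 1:2),
                             c("edge", "keepme")))
  kept <- filter_asvs(m)
  expect_identical(rownames(kept$counts), "keepme")
  # relaxing a threshold never removes a previously retained taxon
  relaxed <- filter_asvs(m, min_total = 150, min_fractions = 10)
  expect_true(all(rownames(kept$counts) %in% rownames(relaxed$counts)))
})

test_that("genus aggregation sums member ASVs and keys on the full lineage", {
  frac <- paste0("F", 1:2)
  counts <- make_counts(list(a1 = c(3, 4), a2 = c(1, 0), b = c(2, 2),
                             c1 = c(5, 5), c2 = c(7, 1)), frac)
  tax <- c(
    a1 = "d__B;p__P;c__C;o__O;f__F1;g__Shared",
    a2 = "d__B;p__P;c__C;o__O;f__F1;g__Shared",
    b  = "d__B;p__P;c__C;o__O;f__Oxalobacteraceae",   # unresolved genus
    c1 = "d__B;p__P;c__C;o__O;f__F2;g__Shared",       # same name, other family
    c2 = "d__B;p__P;c__C;o__O;f__F2;g__Shared"
  )
  m <- taxon_matrix(counts, tax)
  g <- aggregate_to_genus(m)
  expect_equal(nrow(g$counts), 3L)
  expect_equal(unname(g$counts[match("Shared", rownames(g$counts)), ]),
               c(4, 4))
  expect_true("Oxalobacteraceae gen." %in% rownames(g$counts))
  # same terminal name under different families stays distinct
  expect_equal(sum(startsWith(rownames(g$counts), "Shared")), 2L)
  # aggregation conserves totals
  expect_equal(sum(g$counts), sum(m$counts))
  expect_setequal(g$provenance[["Shared"]], c("a1", "a2"))
})

test_that("genus filters apply the abundance and per-site prevalence rules", {
  samples <- toy_samples(n_plots = 7, sites = c("Valley", "Ridge"))
  design <- validate_design(samples)
  fr <- toy_fractions(samples, densities = c(1.68, 1.70, 1.72),
                      total_copies = 1e5)
  fr <- as_qsip_fractions(fr)
  tubes <- unique(fr$tube_id)
  nfr <- nrow(fr)

  # genus "everywhere": large counts in all fractions
  # genus "rare": tiny relative abundance everywhere (mean relabund ~ 5e-5)
  # genus "valley_only": present in all Valley plots, 2 Ridge plots
  everywhere <- rep(1000, nfr)
  rare <- rep(0.15, nfr)  # 0.15/ ~3000 per fraction => ~5e-5
  ridge_plots_present <- c(1, 2)
  is_valley <- grepl("Valley", fr$tube_id)
  plot_of <- as.integer(sub(".*_P(\\d+)_.*", "\\1", fr$tube_id))
  valley_only <- ifelse(is_valley | plot_of %in% ridge_plots_present, 2000, 0)
  counts <- rbind(everywhere = everywhere, rare = rare,
                  valley_only = valley_only)
  colnames(counts) <- fr$fraction_id
  g <- structure(list(counts = counts,
                      taxonomy = setNames(paste0("k;p;c;o;f;g", 1:3),
                                          rownames(counts)),
                      provenance = as.list(rownames(counts))),
                 class = "genus_table")

  out <- filter_genera(g, design, fr, min_relabund = 1e-4,
                       min_samples_per_site = 5)
  expect_setequal(rownames(out$counts), "everywhere")
  rep <- attr(out, "filter_report")
  expect_equal(rep$removed[rep$rule == "mean_relabund<1e-04"], 1L)
  expect_equal(rep$removed[grepl("plots_per_site", rep$rule)], 1L)

  # genus present in exactly 5 of 7 plots at both sites is retained
  five_plots <- ifelse(plot_of <= 5, 500, 0)
  g2 <- g
  g2$counts <- rbind(g$counts, five = five_plots)
  g2$taxonomy <- c(g$taxonomy, five = "k;p;c;o;f;g5")
  g2$provenance <- c(g$provenance, list(five = "five"))
  out2 <- filter_genera(g2, design, fr, min_relabund = 1e-4,
                        min_samples_per_site = 5)
  expect_true("five" %in% rownames(out2$counts))
})
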