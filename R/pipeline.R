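# The central model object: qsip_fit() runs the full estimation chain
# (window -> ASV filter -> genus aggregation -> genus filters -> WAD ->
# tube correction -> EAF -> percent N) and returns a classed fit.

#' Fit the qSIP enrichment model to a gradient experiment
#'
#' Runs the complete estimation chain on the four experiment tables and
#' returns a fitted object holding per-(genus, sample) 15N excess atom
#' fractions (relative N assimilation rates) and percent N assimilated.
#'
#' @param fractions A \code{qsip_fractions} table ([read_fraction_table()]).
#' @param counts A \code{taxon_matrix} ([read_taxon_counts()]).
#' @param samples Sample metadata data frame ([read_sample_table()]) or a
#'   \code{study_design}.
#' @param window Analyzed density window, g/mL (default 1.67--1.74).
#' @param asv_min_total,asv_min_fractions,asv_rule ASV filter settings, see
#'   [filter_asvs()].
#' @param min_relabund,min_samples_per_site Genus filter settings, see
#'   [filter_genera()].
#' @param n_ref Reference genera for the tube correction (default 50).
#' @param tube_rank Reference ranking for [tube_correction()]:
#'   \code{"signed"} (default) or \code{"abs"}.
#' @param constants [isotope_constants()].
#' @return Object of class \code{qsip_fit} with components
#'   \code{enrichment} (per genus and labeled sample), \code{wads},
#'   \code{shifts} (tube-corrected), \code{design}, \code{filter_report},
#'   \code{window}, \code{constants}.
#' @examples
#' sim <- simulate_study(sim_config(n_taxa = 20, seq_depth = 500, seed = 7))
#' fit <- qsip_fit(sim$fractions, sim$counts, sim$samples,
#'                 asv_min_total = 10, asv_min_fractions = 3,
#'                 min_samples_per_site = 1, n_ref = 10)
#' print(fit)
#' @export
qsip_fit <- function(fractions, counts, samples,
                     window = c(1.67, 1.74),
                     asv_min_total = 200, asv_min_fractions = 20,
                     asv_rule = c("both", "either"),
                     min_relabund = 1e-4, min_samples_per_site = 5,
                     n_ref = 50, tube_rank = c("signed", "abs"),
                     constants = isotope_constants()) {
  tube_rank <- match.arg(tube_rank)
  asv_rule <- match.arg(asv_rule)
  design <- if (inherits(samples, "study_design")) samples
            else validate_design(samples)
  fr <- select_fractions(fractions, window)
  m <- filter_asvs(counts, asv_min_total, asv_min_fractions, asv_rule)
  rep_asv <- attr(m, "filter_report")
  g <- aggregate_to_genus(m)
  n_genera_pre <- nrow(g$counts)
  g <- filter_genera(g, design, fr, min_relabund, min_samples_per_site)
  rep_gen <- attr(g, "filter_report")
  wads <- wad_table(g, fr)
  shifts <- tube_correction(wad_shifts(wads, design), n_ref, rank = tube_rank)
  enr <- enrichment_table(wads, shifts, design, constants)
  structure(list(
    enrichment = enr,
    wads = wads,
    shifts = shifts,
    design = design,
    filter_report = rbind(rep_asv[names(rep_gen)[1:3]], rep_gen),
    n_genera_pre_filter = n_genera_pre,
    n_genera = length(unique(enr$genus)),
    window = window,
    n_ref = n_ref,
    constants = constants,
    call = match.call()
  ), class = "qsip_fit")
}

#' Run the qSIP pipeline from files on disk
#'
#' Thin orchestration over [qsip_fit()]: reads \code{fractions.tsv},
#' \code{counts.tsv}, \code{taxonomy.tsv} and \code{samples.tsv} from a
#' directory, fits, and optionally writes the result tables
#' (\code{eaf.tsv}, \code{wad.tsv}, \code{wad_shifts.tsv},
#' \code{filter_report.tsv}).
#'
#' @param dir Input directory containing the four tables.
#' @param out Optional output directory for result tables.
#' @param ... Passed to [qsip_fit()].
#' @return The \code{qsip_fit} object, invisibly when \code{out} is given.
#' @export
run_qsip <- function(dir, out = NULL, ...) {
  fractions <- read_fraction_table(file.path(dir, "fractions.tsv"))
  counts <- read_taxon_counts(file.path(dir, "counts.tsv"),
                              file.path(dir, "taxonomy.tsv"))
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  fit <- qsip_fit(fractions, counts, samples, ...)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_tsv_commented(fit$enrichment, file.path(out, "eaf.tsv"))
    write_tsv_commented(fit$wads, file.path(out, "wad.tsv"))
    write_tsv_commented(fit$shifts, file.path(out, "wad_shifts.tsv"))
    write_tsv_commented(fit$filter_report, file.path(out, "filter_report.tsv"))
    return(invisible(fit))
  }
  fit
}

#' Genus-level medians across replicate plots
#'
#' The genus-level summary used for method comparison: the median of the
#' plot-level values within each method (optionally within each site).
#'
#' @param fit A \code{qsip_fit}.
#' @param metric \code{"eaf"} or \code{"pct_n"}.
#' @param by_site Keep sites separate (default \code{FALSE}: pool both sites'
#'   plots, as in a combined-sites comparison).
#' @return Data frame with \code{genus} (and \code{site}) and one column per
#'   method (\code{field}, \code{lab}) of median values.
#' @export
genus_medians <- function(fit, metric = c("eaf", "pct_n"), by_site = FALSE) {
  metric <- match.arg(metric)
  e <- fit$enrichment
  v <- e[[metric]]
  grp <- if (by_site) interaction(e$genus, e$site, e$method, drop = FALSE)
         else interaction(e$genus, e$method, drop = FALSE)
  med <- tapply(v, grp, stats::median, na.rm = TRUE)
  if (by_site) {
    keys <- expand.grid(genus = unique(e$genus), site = unique(e$site),
                        stringsAsFactors = FALSE)
    keys$field <- as.numeric(med[paste(keys$genus, keys$site, "field", sep = ".")])
    keys$lab <- as.numeric(med[paste(keys$genus, keys$site, "lab", sep = ".")])
  } else {
    keys <- data.frame(genus = unique(e$genus), stringsAsFactors = FALSE)
    keys$field <- as.numeric(med[paste(keys$genus, "field", sep = ".")])
    keys$lab <- as.numeric(med[paste(keys$genus, "lab", sep = ".")])
  }
  keys
}

#' Compare field and lab methods with Passing-Bablok regression
#'
#' Regresses genus-median field values on lab values with
#' [passing_bablok()]; the slope CI excluding 1 flags a proportional
#' difference between methods, the intercept CI excluding 0 a constant one.
#'
#' @param fit A \code{qsip_fit}.
#' @param metric \code{"eaf"} or \code{"pct_n"}.
#' @param by_site Fit each site separately as well as both sites pooled.
#' @param pb_method,boot,conf.level,seed Passed to [passing_bablok()].
#' @return A \code{pb_fit} (or, with \code{by_site = TRUE}, a named list of
#'   \code{pb_fit}s: one per site plus \code{"both"}).
#' @export
compare_methods <- function(fit, metric = c("eaf", "pct_n"), by_site = FALSE,
                            pb_method = c("equivariant", "classical"),
                            boot = 1999, conf.level = 0.95, seed = NULL) {
  metric <- match.arg(metric)
  pb_method <- match.arg(pb_method)
  one <- function(md) {
    ok <- stats::complete.cases(md$lab, md$field)
    passing_bablok(md$lab[ok], md$field[ok], method = pb_method, boot = boot,
                   conf.level = conf.level, seed = seed)
  }
  if (!by_site) return(one(genus_medians(fit, metric, by_site = FALSE)))
  md <- genus_medians(fit, metric, by_site = TRUE)
  fits <- lapply(split(md, md$site), one)
  fits$both <- one(genus_medians(fit, metric, by_site = FALSE))
  fits
}

#' Per-genus field-vs-lab tests
#'
#' One-way ANOVA (field vs lab, n = plots per method) for every genus within
#' each site, with conventional significance tiers.
#'
#' @param fit A \code{qsip_fit}.
#' @param metric \code{"eaf"} or \code{"pct_n"}.
#' @return Data frame: \code{genus}, \code{site}, \code{F}, \code{p},
#'   \code{tier}.
#' @export
genus_method_tests <- function(fit, metric = c("eaf", "pct_n")) {
  metric <- match.arg(metric)
  e <- fit$enrichment
  res <- list()
  for (s in unique(e$site)) {
    es <- e[e$site == s, , drop = FALSE]
    for (g in unique(es$genus)) {
      a <- es[[metric]][es$genus == g & es$method == "field"]
      b <- es[[metric]][es$genus == g & es$method == "lab"]
      t <- tryCatch(genus_group_test(a, b), error = function(err) NULL)
      if (is.null(t)) next
      res[[length(res) + 1L]] <- data.frame(
        genus = g, site = s, F = t$statistic, p = t$p.value, tier = t$tier,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.qsip_fit <- function(x, ...) {
  e <- x$enrichment
  cat("qSIP 15N enrichment fit\n")
  cat("  genera: ", x$n_genera, " (", x$n_genera_pre_filter,
      " before genus filters)\n", sep = "")
  cat("  labeled samples:", length(unique(e$sample_id)),
      " sites:", paste(unique(e$site), collapse = ", "), "\n")
  for (m in sort(unique(e$method))) {
    cat(sprintf("  median EAF (%s): %.4f\n", m,
                stats::median(e$eaf[e$method == m], na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.qsip_fit <- function(object, ...) {
  e <- object$enrichment
  agg <- stats::aggregate(e[c("eaf", "pct_n")],
                          by = list(site = e$site, method = e$method),
                          FUN = function(v) stats::median(v, na.rm = TRUE))
  out <- list(fit = object, by_group = agg,
              filter_report = object$filter_report,
              tube_offsets = attr(object$shifts, "tube_offsets"))
  class(out) <- "summary.qsip_fit"
  out
}

#' @export
print.summary.qsip_fit <- function(x, ...) {
  print(x$fit)
  cat("\nmedian EAF / pct N by site and method:\n")
  print(x$by_group, row.names = FALSE)
  cat("\nfilter report:\n")
  print(x$filter_report, row.names = FALSE)
  invisible(x)
}

#' @export
coef.qsip_fit <- function(object, metric = "eaf", ...) {
  md <- genus_medians(object, metric, by_site = FALSE)
  m <- as.matrix(md[c("field", "lab")])
  rownames(m) <- md$genus
  m
}

#' @export
plot.qsip_fit <- function(x, metric = "eaf", ...) {
  md <- genus_medians(x, metric, by_site = FALSE)
  graphics::plot(md$lab, md$field, xlab = paste("lab median", metric),
                 ylab = paste("field median", metric), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
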