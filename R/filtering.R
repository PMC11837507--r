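# ASV-level quality filtering, genus-level aggregation, and genus-level
# abundance/prevalence filtering.

#' Filter low-quality ASVs
#'
#' Removes amplicon sequence variants with low support across the whole data
#' set. Under the default (permissive) rule an ASV is removed only when it
#' BOTH occurs fewer than \code{min_total} times in total AND is present in
#' fewer than \code{min_fractions} fractions; the strict rule removes an ASV
#' failing either condition.
#'
#' @param m A \code{taxon_matrix} of raw (unnormalized) counts.
#' @param min_total Minimum total count across all fractions (default 200).
#' @param min_fractions Minimum number of fractions with a nonzero count
#'   (default 20).
#' @param rule \code{"both"} (default: removal requires both conditions) or
#'   \code{"either"}.
#' @return The filtered \code{taxon_matrix}, with a \code{filter_report}
#'   attribute (data frame: rule, removed, retained).
#' @export
filter_asvs <- function(m, min_total = 200, min_fractions = 20,
                        rule = c("both", "either")) {
  stopifnot(inherits(m, "taxon_matrix"))
  rule <- match.arg(rule)
  total <- rowSums(m$counts)
  prev <- rowSums(m$counts > 0)
  low_total <- total < min_total
  low_prev <- prev < min_fractions
  remove <- if (rule == "both") low_total & low_prev else low_total | low_prev
  if (all(remove)) warning("all ASVs removed by filter")
  out <- taxon_matrix(m$counts[!remove, , drop = FALSE],
                      m$taxonomy[!remove])
  attr(out, "filter_report") <- data.frame(
    rule = paste0("asv_", rule, "_total<", min_total, "_fractions<", min_fractions),
    removed = sum(remove), retained = sum(!remove),
    stringsAsFactors = FALSE
  )
  out
}

# internal: split a taxonomy string into trimmed ranks
parse_ranks <- function(s) {
  r <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  r[!is.na(r)]
}

# internal: is a rank label an unresolved placeholder?
rank_unresolved <- function(r) {
  r == "" | grepl("^[a-z]__$", r) | is.na(r) |
    tolower(sub("^[a-z]__", "", r)) %in% c("uncultured", "unclassified", "na")
}

#' Aggregate ASVs to genus-level taxa
#'
#' ASVs sharing an identical six-rank taxonomy prefix
#' (domain;phylum;class;order;family;genus) are summed into one genus-level
#' taxon. ASVs not resolved to genus are labeled by the finest resolved rank
#' followed by \code{"gen."} (e.g. \code{"Oxalobacteraceae gen."}); identity
#' is still keyed on the full rank prefix, so two unresolved genera under
#' different families stay distinct.
#'
#' @param m A \code{taxon_matrix} (usually after [filter_asvs()]).
#' @return A \code{genus_table}: list with \code{counts} (genus x fraction),
#'   \code{taxonomy} (genus label -> six-rank key) and \code{provenance}
#'   (genus label -> contributing ASV ids).
#' @export
aggregate_to_genus <- function(m) {
  stopifnot(inherits(m, "taxon_matrix"))
  n <- nrow(m$counts)
  keys <- character(n)
  labels <- character(n)
  for (i in seq_len(n)) {
    ranks <- parse_ranks(m$taxonomy[i])
    if (length(ranks) < 1L || all(rank_unresolved(ranks))) {
      stop("malformed or empty taxonomy for ASV ", rownames(m$counts)[i])
    }
    ranks6 <- ranks[seq_len(min(6L, length(ranks)))]
    unres <- rank_unresolved(ranks6)
    keys[i] <- paste(ranks6, collapse = ";")
    if (length(ranks6) == 6L && !unres[6L]) {
      labels[i] <- sub("^[a-z]__", "", ranks6[6L])
    } else {
      finest <- max(which(!unres))
      labels[i] <- paste(sub("^[a-z]__", "", ranks6[finest]), "gen.")
    }
  }
  ukeys <- unique(keys)
  idx <- match(keys, ukeys)
  counts <- rowsum(m$counts, group = idx, reorder = TRUE)
  # one label per key; disambiguate label collisions across distinct keys
  lab_of_key <- labels[match(ukeys, keys)]
  lab_of_key <- make.unique(lab_of_key, sep = " ")
  rownames(counts) <- lab_of_key
  prov <- split(rownames(m$counts), lab_of_key[idx])
  structure(list(counts = counts,
                 taxonomy = stats::setNames(ukeys, lab_of_key),
                 provenance = prov[lab_of_key]),
            class = "genus_table")
}

#' @export
print.genus_table <- function(x, ...) {
  cat("genus_table:", nrow(x$counts), "genera x", ncol(x$counts), "fractions\n")
  invisible(x)
}

#' Filter genera by abundance and prevalence
#'
#' Removes genera whose mean copies-weighted relative abundance across all
#' samples falls below \code{min_relabund}, and genera detected in fewer than
#' \code{min_samples_per_site} replicate plots at either site. A genus counts
#' as present in a plot when it has at least one read in at least one analyzed
#' fraction of any of that plot's tubes.
#'
#' @param g A \code{genus_table}.
#' @param design A \code{study_design} from [validate_design()].
#' @param fractions A \code{qsip_fractions} table (already windowed if the
#'   analysis restricts densities) giving fraction-to-tube mapping and qPCR
#'   totals used for copies-weighted relative abundance.
#' @param min_relabund Mean relative abundance threshold (default 1e-4).
#' @param min_samples_per_site Minimum plots per site with the genus detected
#'   (default 5).
#' @return The filtered \code{genus_table} with a \code{filter_report}
#'   attribute counting removals by rule.
#' @export
filter_genera <- function(g, design, fractions, min_relabund = 1e-4,
                          min_samples_per_site = 5) {
  stopifnot(inherits(g, "genus_table"), inherits(design, "study_design"))
  frac <- as.data.frame(fractions)
  common <- intersect(colnames(g$counts), frac$fraction_id)
  frac <- frac[match(common, frac$fraction_id), , drop = FALSE]
  cnt <- g$counts[, common, drop = FALSE]

  # relative abundance per sample: genus copies / total copies, copies-weighted
  tubes <- unique(frac$tube_id)
  ra <- matrix(NA_real_, nrow(cnt), length(tubes),
               dimnames = list(rownames(cnt), tubes))
  present <- ra
  for (j in seq_along(tubes)) {
    sel <- frac$tube_id == tubes[j]
    f_k <- frac$total_copies[sel]
    sub <- cnt[, sel, drop = FALSE]
    csum <- colSums(sub)
    p <- sweep(sub, 2L, ifelse(csum > 0, csum, 1), "/")
    copies <- p %*% f_k
    tot <- sum(f_k)
    ra[, j] <- if (tot > 0) copies / tot else 0
    present[, j] <- as.numeric(rowSums(sub) > 0)
  }
  mean_ra <- rowMeans(ra)
  low_ab <- mean_ra < min_relabund

  # prevalence per site, counting plots (a plot is covered by any of its tubes)
  meta <- design$samples
  tube_meta <- meta[match(frac$sample_id[match(tubes, frac$tube_id)],
                          meta$sample_id), , drop = FALSE]
  sites <- unique(meta$site)
  low_prev <- rep(FALSE, nrow(cnt))
  for (s in sites) {
    tsel <- which(tube_meta$site == s)
    if (length(tsel) == 0L) next
    plots <- tube_meta$plot[tsel]
    det <- present[, tsel, drop = FALSE]
    nplots <- vapply(seq_len(nrow(det)), function(i) {
      length(unique(plots[det[i, ] > 0]))
    }, numeric(1L))
    low_prev <- low_prev | (nplots < min_samples_per_site)
  }

  remove <- low_ab | low_prev
  keep <- !remove
  out <- structure(list(counts = g$counts[keep, , drop = FALSE],
                        taxonomy = g$taxonomy[keep],
                        provenance = g$provenance[keep]),
                   class = "genus_table")
  attr(out, "filter_report") <- data.frame(
    rule = c(paste0("mean_relabund<", min_relabund),
             paste0("plots_per_site<", min_samples_per_site),
             "either"),
    removed = c(sum(low_ab), sum(low_prev), sum(remove)),
    retained = nrow(out$counts),
    stringsAsFactors = FALSE
  )
  attr(out, "mean_relabund") <- mean_ra[keep]
  out
}
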