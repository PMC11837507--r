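# Weighted average buoyant density (WAD) per genus and tube, natural-abundance
# (light) WADs from pre-incubation controls, and tube-level density correction.

#' Restrict a fraction table to the analyzed density window
#'
#' Keeps fractions whose buoyant density lies inside the closed window
#' (default 1.67--1.74 g/mL, the range with enough DNA for sequencing in a
#' typical CsCl gradient). Tubes left with fewer than 3 fractions are flagged
#' unusable and dropped with a warning.
#'
#' @param fractions A \code{qsip_fractions} table.
#' @param window Numeric length-2, closed density interval in g/mL.
#' @return The windowed \code{qsip_fractions} table; unusable tube ids are
#'   recorded in the \code{unusable_tubes} attribute.
#' @export
select_fractions <- function(fractions, window = c(1.67, 1.74)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  df <- as.data.frame(fractions)
  keep <- df$density >= window[1] & df$density <= window[2]
  df <- df[keep, , drop = FALSE]
  n_by_tube <- table(df$tube_id)
  bad <- names(n_by_tube)[n_by_tube < 3L]
  if (length(bad) > 0L) {
    warning("tube(s) with < 3 fractions in window flagged unusable: ",
            paste(bad, collapse = ", "))
    df <- df[!(df$tube_id %in% bad), , drop = FALSE]
  }
  rownames(df) <- NULL
  out <- as_qsip_fractions(df)
  attr(out, "unusable_tubes") <- bad
  out
}

#' Per-fraction 16S copies of one taxon
#'
#' Distributes a fraction's total qPCR copies to a taxon according to its
#' relative sequence abundance in that fraction: \code{y_k = p_k * f_k}.
#'
#' @param rel_abund Relative abundances in `[0, 1]`, one per fraction.
#' @param total_copies Total 16S copies per fraction (same length).
#' @return Numeric vector of taxon copies per fraction.
#' @export
taxon_fraction_copies <- function(rel_abund, total_copies) {
  if (length(rel_abund) != length(total_copies)) {
    stop("rel_abund and total_copies must have the same length")
  }
  if (any(rel_abund < 0 | rel_abund > 1, na.rm = TRUE)) {
    stop("rel_abund must lie in [0, 1]")
  }
  rel_abund * total_copies
}

#' Weighted average density
#'
#' The abundance-weighted mean buoyant density of a taxon's DNA:
#' \code{W = sum(density_k * copies_k) / sum(copies_k)}.
#'
#' @param copies Taxon 16S copies per fraction.
#' @param densities Fraction buoyant densities (g/mL), same length.
#' @return The WAD in g/mL, or \code{NA} when no copies were recovered.
#' @export
weighted_average_density <- function(copies, densities) {
  if (length(copies) != length(densities)) {
    stop("copies and densities must have the same length")
  }
  tot <- sum(copies)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(densities * copies) / tot
}

#' Per-genus, per-tube WAD table
#'
#' Computes, for every genus and tube, the weighted average density, the total
#' copies recovered, and the number of fractions the genus was detected in.
#'
#' @param g A \code{genus_table}.
#' @param fractions A (windowed) \code{qsip_fractions} table.
#' @return Data frame with columns \code{genus}, \code{tube_id},
#'   \code{sample_id}, \code{wad}, \code{copies_recovered},
#'   \code{n_fractions_detected}, \code{rel_abund} (genus copies over total
#'   copies in the tube's analyzed fractions). \code{wad} is \code{NA} where
#'   the genus is absent from the tube.
#' @export
wad_table <- function(g, fractions) {
  stopifnot(inherits(g, "genus_table"))
  frac <- as.data.frame(fractions)
  common <- intersect(colnames(g$counts), frac$fraction_id)
  frac <- frac[match(common, frac$fraction_id), , drop = FALSE]
  cnt <- g$counts[, common, drop = FALSE]
  tubes <- unique(frac$tube_id)
  res <- vector("list", length(tubes))
  for (j in seq_along(tubes)) {
    sel <- frac$tube_id == tubes[j]
    x <- frac$density[sel]
    f_k <- frac$total_copies[sel]
    sub <- cnt[, sel, drop = FALSE]
    csum <- colSums(sub)
    p <- sweep(sub, 2L, ifelse(csum > 0, csum, 1), "/")
    y <- sweep(p, 2L, f_k, "*")           # genus x fraction copies
    copies <- rowSums(y)
    wad <- as.numeric(y %*% x) / ifelse(copies > 0, copies, NA_real_)
    tot <- sum(f_k)
    res[[j]] <- data.frame(
      genus = rownames(cnt),
      tube_id = tubes[j],
      sample_id = frac$sample_id[sel][1L],
      wad = wad,
      copies_recovered = copies,
      n_fractions_detected = rowSums(sub > 0),
      rel_abund = if (tot > 0) copies / tot else 0,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Natural-abundance (light) WAD per genus
#'
#' Averages each genus's WAD over the unlabeled (pre-incubation) tubes where
#' it was detected; this is the natural-abundance reference density from which
#' genomic GC content is inferred.
#'
#' @param wads A WAD table from [wad_table()].
#' @param design A \code{study_design}.
#' @return Data frame: \code{genus}, \code{w_light_mean}, \code{n_tubes}.
#'   Genera absent from all unlabeled tubes get \code{NA} and should be
#'   dropped from enrichment estimation.
#' @export
light_wad <- function(wads, design) {
  unl <- design$samples$sample_id[design$samples$label == "unlabeled"]
  w <- wads[wads$sample_id %in% unl & !is.na(wads$wad), , drop = FALSE]
  genera <- unique(wads$genus)
  mn <- tapply(w$wad, factor(w$genus, levels = genera), mean)
  nt <- tapply(rep(1, nrow(w)), factor(w$genus, levels = genera), sum)
  data.frame(genus = genera,
             w_light_mean = as.numeric(mn),
             n_tubes = ifelse(is.na(as.numeric(nt)), 0L, as.numeric(nt)),
             stringsAsFactors = FALSE)
}

#' Raw WAD shifts of labeled tubes
#'
#' For every labeled tube, the per-genus shift in WAD relative to the
#' unlabeled control tube of the same plot:
#' \code{raw_dwad = wad(labeled) - wad(control)}.
#'
#' @param wads WAD table from [wad_table()].
#' @param design A \code{study_design}.
#' @return Data frame: \code{genus}, \code{tube_id}, \code{sample_id},
#'   \code{site}, \code{method}, \code{plot}, \code{w_light_plot},
#'   \code{raw_dwad} (NA where either WAD is undefined).
#' @export
wad_shifts <- function(wads, design) {
  pair <- design$pairing
  key <- function(g, s) paste(g, s, sep = "\r")
  wkey <- stats::setNames(wads$wad, key(wads$genus, wads$sample_id))
  res <- vector("list", nrow(pair))
  genera <- unique(wads$genus)
  for (i in seq_len(nrow(pair))) {
    w_lab <- wkey[key(genera, pair$sample_id[i])]
    w_ctl <- wkey[key(genera, pair$control_id[i])]
    tube <- unique(wads$tube_id[wads$sample_id == pair$sample_id[i]])
    res[[i]] <- data.frame(
      genus = genera,
      tube_id = tube[1L],
      sample_id = pair$sample_id[i],
      site = pair$site[i],
      method = pair$method[i],
      plot = pair$plot[i],
      w_light_plot = unname(w_ctl),
      raw_dwad = unname(w_lab - w_ctl),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tube-level density correction of WAD shifts
#'
#' CsCl gradients differ slightly tube to tube, shifting every taxon's
#' apparent density in a tube by a common offset. The correction uses the
#' \code{n_ref} genera with the smallest mean raw WAD shift (ranked globally
#' across all labeled tubes) as internal unenriched references; each labeled
#' tube's offset is the median raw shift of the reference genera in that
#' tube, and corrected shifts are \code{raw - offset}.
#'
#' Ranking is by the signed mean shift (default): isotope incorporation can
#' only increase density, so the least-shifted genera are the unenriched
#' floor. Ranking by absolute shift is available but confounds the floor with
#' the study-average tube offset: when the labeled tubes' offsets do not
#' average to exactly zero, the genera closest to zero apparent shift are the
#' ones whose true enrichment cancels that common offset, and anchoring on
#' them biases every corrected shift by it. The signed ranking is invariant
#' to a common offset.
#'
#' With \code{scope = "loo"} (default) the reference set for each tube is
#' ranked on the mean shift over the \emph{other} labeled tubes. Ranking on
#' all tubes at once ("global") selects genera partly for their negative
#' noise in the very tubes being corrected, which biases every offset
#' downward by a constant; leaving the target tube out decorrelates the
#' selection from the median it feeds.
#'
#' @param shifts Data frame from [wad_shifts()].
#' @param n_ref Number of reference genera (default 50); \code{0} disables
#'   the correction (all offsets 0), appropriate when tubes are known to
#'   share one calibration.
#' @param rank \code{"signed"} (default) or \code{"abs"} reference ranking.
#' @param scope \code{"loo"} (leave-one-tube-out ranking, default) or
#'   \code{"global"} (one reference set for all tubes).
#' @return \code{shifts} with added columns \code{tube_offset} and
#'   \code{corrected_dwad}, plus attributes \code{reference_genera} (the
#'   globally ranked set, for reporting) and \code{tube_offsets}.
#' @export
tube_correction <- function(shifts, n_ref = 50, rank = c("signed", "abs"),
                            scope = c("loo", "global")) {
  rank <- match.arg(rank)
  scope <- match.arg(scope)
  tubes <- unique(shifts$tube_id)
  if (n_ref == 0L) {
    shifts$tube_offset <- 0
    shifts$corrected_dwad <- shifts$raw_dwad
    attr(shifts, "reference_genera") <- character(0)
    attr(shifts, "tube_offsets") <- stats::setNames(numeric(length(tubes)),
                                                    tubes)
    return(shifts)
  }
  rank_refs <- function(sub) {
    mu <- tapply(sub$raw_dwad, sub$genus, function(v) mean(v, na.rm = TRUE))
    mu <- mu[!is.na(mu)]
    key <- if (rank == "abs") abs(mu) else mu
    names(sort(key))[seq_len(min(n_ref, length(mu)))]
  }
  global_ref <- rank_refs(shifts)
  if (length(global_ref) < n_ref) {
    warning("only ", length(global_ref), " genera with defined shifts; ",
            "using all of them as references (n_ref = ", n_ref, ")")
  }
  offsets <- stats::setNames(numeric(length(tubes)), tubes)
  for (tb in tubes) {
    ref <- if (scope == "global" || length(tubes) < 3L) {
      global_ref
    } else {
      rank_refs(shifts[shifts$tube_id != tb, , drop = FALSE])
    }
    v <- shifts$raw_dwad[shifts$tube_id == tb & shifts$genus %in% ref]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      warning("tube ", tb, ": no reference genera detected; offset set to 0")
      offsets[tb] <- 0
    } else {
      offsets[tb] <- stats::median(v)
    }
  }
  shifts$tube_offset <- unname(offsets[shifts$tube_id])
  shifts$corrected_dwad <- shifts$raw_dwad - shifts$tube_offset
  attr(shifts, "reference_genera") <- global_ref
  attr(shifts, "tube_offsets") <- offsets
  shifts
}
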