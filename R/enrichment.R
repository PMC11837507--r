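# Conversion of corrected WAD shifts to 15N excess atom fraction (EAF, the
# relative N assimilation rate) and abundance-weighted percent N assimilated.

#' Isotope and DNA physical constants
#'
#' Constants of the qSIP formula chain linking buoyant density, genomic GC
#' content, nucleotide molecular weight and 15N incorporation. Defaults follow
#' the standard qSIP methodology; all are overridable for sensitivity work.
#'
#' @param gc_slope Density change per unit GC content (g/mL).
#' @param gc_intercept Density of GC = 0 DNA (g/mL).
#' @param mw_light_slope,mw_light_intercept Mean nucleotide molecular weight
#'   (g/mol) of unlabeled DNA as a linear function of GC.
#' @param heavy_max_slope,heavy_max_intercept Additional molecular weight
#'   (g/mol) at full 15N substitution, linear in GC.
#' @param nat_abund_15n Natural abundance atom fraction of 15N.
#' @return Object of class \code{isotope_constants}.
#' @export
isotope_constants <- function(gc_slope = 0.083506,
                              gc_intercept = 1.646057,
                              mw_light_slope = 0.496,
                              mw_light_intercept = 307.691,
                              heavy_max_slope = 0.5024,
                              heavy_max_intercept = 3.517,
                              nat_abund_15n = 0.003663) {
  c0 <- list(gc_slope = gc_slope, gc_intercept = gc_intercept,
             mw_light_slope = mw_light_slope,
             mw_light_intercept = mw_light_intercept,
             heavy_max_slope = heavy_max_slope,
             heavy_max_intercept = heavy_max_intercept,
             nat_abund_15n = nat_abund_15n)
  if (any(unlist(c0) <= 0)) stop("all isotope constants must be positive")
  structure(c0, class = "isotope_constants")
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("isotope_constants (15N qSIP):\n")
  for (nm in names(x)) cat(sprintf("  %-19s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' GC content from natural-abundance WAD
#'
#' Inverts the linear GC-density relationship:
#' \code{GC = (w_light - gc_intercept) / gc_slope}. Values outside `[0, 1]`
#' are clipped with a warning.
#'
#' @param w_light Natural-abundance (light) WAD in g/mL.
#' @param constants An [isotope_constants()] object.
#' @return GC content as a proportion in `[0, 1]`.
#' @export
gc_from_light_wad <- function(w_light, constants = isotope_constants()) {
  gc <- (w_light - constants$gc_intercept) / constants$gc_slope
  out <- gc < -1e-9 | gc > 1 + 1e-9   # beyond numerical dust
  if (any(out, na.rm = TRUE)) {
    warning(sum(out, na.rm = TRUE), " GC value(s) outside [0, 1] clipped")
  }
  pmin(pmax(gc, 0), 1)
}

#' Nucleotide molecular weights from GC content
#'
#' @param gc GC content, proportion in `[0, 1]`.
#' @param constants An [isotope_constants()] object.
#' @return List with \code{m_light} (unlabeled mean nucleotide weight, g/mol)
#'   and \code{m_heavy_max} (weight at full 15N substitution).
#' @export
molecular_weights <- function(gc, constants = isotope_constants()) {
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("gc must lie in [0, 1]")
  m_light <- constants$mw_light_slope * gc + constants$mw_light_intercept
  m_heavy_max <- m_light + constants$heavy_max_slope * gc +
    constants$heavy_max_intercept
  list(m_light = m_light, m_heavy_max = m_heavy_max)
}

#' 15N excess atom fraction from a WAD shift
#'
#' Converts the post-incubation shift in weighted average density to the
#' excess atom fraction of 15N in the taxon's DNA. The observed molecular
#' weight scales with density, \code{m_lab = m_light * w_lab / w_light}; the
#' EAF is the achieved fraction of the maximum possible weight gain, scaled by
#' one minus the natural 15N abundance:
#' \code{eaf = (m_lab - m_light) / (m_heavy_max - m_light) * (1 - nat_abund)}.
#'
#' @param w_lab Labeled (tube-corrected) WAD, g/mL.
#' @param w_light Natural-abundance WAD, g/mL.
#' @param gc GC content proportion.
#' @param constants An [isotope_constants()] object.
#' @return Raw EAF; negative values pass through (see [clamp_negative()]).
#' @export
eaf_15n <- function(w_lab, w_light, gc, constants = isotope_constants()) {
  if (any(w_light <= 0, na.rm = TRUE)) stop("w_light must be positive")
  mw <- molecular_weights(gc, constants)
  m_lab <- mw$m_light * (w_lab / w_light)
  (m_lab - mw$m_light) / (mw$m_heavy_max - mw$m_light) *
    (1 - constants$nat_abund_15n)
}

#' Inverse of the EAF formula chain
#'
#' Labeled WAD that would produce a given EAF at a given light WAD and GC;
#' used by the forward simulator and for self-consistency checks.
#'
#' @inheritParams eaf_15n
#' @param eaf Target excess atom fraction.
#' @return The labeled WAD \code{w_lab} in g/mL.
#' @export
wad_for_eaf <- function(eaf, w_light, gc, constants = isotope_constants()) {
  mw <- molecular_weights(gc, constants)
  m_lab <- mw$m_light + eaf / (1 - constants$nat_abund_15n) *
    (mw$m_heavy_max - mw$m_light)
  w_light * m_lab / mw$m_light
}

#' Replace negative EAF estimates with zero
#'
#' Negative estimated EAFs arise from measurement noise around zero
#' enrichment and are replaced with zero before downstream analysis.
#'
#' @param eaf Numeric vector of raw EAF estimates.
#' @return Clamped vector; the number of clamped values is recorded in the
#'   \code{n_clamped} attribute.
#' @export
clamp_negative <- function(eaf) {
  n <- sum(eaf < 0, na.rm = TRUE)
  out <- pmax(eaf, 0)
  attr(out, "n_clamped") <- n
  out
}

#' Percent of community N assimilation per genus
#'
#' Each genus's abundance-weighted share of total community 15N assimilation:
#' \code{P_i = (RA_i * E_i) / sum_j(RA_j * E_j)}.
#'
#' @param eafs Per-genus EAF values (clamped, >= 0).
#' @param rel_abunds Per-genus relative abundances (>= 0), aligned.
#' @return Proportions summing to 1; all zeros (with a warning) when every
#'   product is zero.
#' @export
percent_n_assimilated <- function(eafs, rel_abunds) {
  if (length(eafs) != length(rel_abunds)) {
    stop("eafs and rel_abunds must have the same length")
  }
  if (any(rel_abunds < 0, na.rm = TRUE)) stop("rel_abunds must be >= 0")
  prod <- eafs * rel_abunds
  tot <- sum(prod, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) {
    warning("all abundance x EAF products are zero; percent N undefined, ",
            "returning zeros")
    return(rep(0, length(eafs)))
  }
  prod / tot
}

#' Per-sample enrichment table
#'
#' Assembles the genus-level enrichment results for every labeled sample:
#' GC content (from the genus's mean natural-abundance WAD), light and
#' corrected labeled WADs, raw and clamped 15N EAF, relative abundance in the
#' labeled sample, and percent N assimilated within the sample.
#'
#' @param wads WAD table from [wad_table()].
#' @param shifts Corrected shift table from [tube_correction()].
#' @param design A \code{study_design}.
#' @param constants An [isotope_constants()] object.
#' @return Data frame with one row per (genus, labeled sample): columns
#'   \code{genus}, \code{site}, \code{method}, \code{plot}, \code{gc},
#'   \code{w_light}, \code{w_lab}, \code{eaf_raw}, \code{eaf},
#'   \code{rel_abund}, \code{pct_n}.
#' @export
enrichment_table <- function(wads, shifts, design,
                             constants = isotope_constants()) {
  lw <- light_wad(wads, design)
  dropped <- lw$genus[lw$n_tubes == 0]
  if (length(dropped) > 0L) {
    message(length(dropped),
            " genus/genera absent from all unlabeled tubes dropped from EAF")
  }
  gc_of <- stats::setNames(gc_from_light_wad(lw$w_light_mean, constants),
                           lw$genus)
  ra_of <- stats::setNames(wads$rel_abund,
                           paste(wads$genus, wads$sample_id, sep = "\r"))
  out <- shifts[!(shifts$genus %in% dropped), , drop = FALSE]
  out$gc <- unname(gc_of[out$genus])
  out$w_light <- out$w_light_plot
  out$w_lab <- out$w_light_plot + out$corrected_dwad
  out$eaf_raw <- eaf_15n(out$w_lab, out$w_light, out$gc, constants)
  out$eaf <- as.numeric(clamp_negative(out$eaf_raw))
  out$rel_abund <- unname(ra_of[paste(out$genus, out$sample_id, sep = "\r")])
  out$pct_n <- NA_real_
  for (sid in unique(out$sample_id)) {
    sel <- which(out$sample_id == sid)
    ok <- sel[!is.na(out$eaf[sel]) & !is.na(out$rel_abund[sel])]
    if (length(ok) > 0L) {
      out$pct_n[ok] <- suppressWarnings(
        percent_n_assimilated(out$eaf[ok], out$rel_abund[ok]))
    }
  }
  cols <- c("genus", "site", "method", "plot", "sample_id", "tube_id",
            "gc", "w_light", "w_lab", "raw_dwad", "tube_offset",
            "corrected_dwad", "eaf_raw", "eaf", "rel_abund", "pct_n")
  out <- out[cols]
  rownames(out) <- NULL
  out
}
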