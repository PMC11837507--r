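# Forward simulator of the whole gradient experiment: taxa with known GC,
# abundance and true 15N enrichment; tubes with density offsets; qPCR and
# multinomial sequencing noise. Emits pipeline-ready tables plus the truth.

#' Simulation configuration
#'
#' Parameters of the forward model. Defaults emulate the design of a paired
#' field/lab 15N rhizosphere experiment: 2 sites x 7 replicate plots x
#' (1 pre-incubation control + field and lab labeled samples), 25 fractions
#' per tube spanning 1.61--1.78 g/mL with the 1.67--1.74 g/mL window
#' sequenced, and a linear lab-to-field EAF map with slope 0.81 and intercept
#' 0.01.
#'
#' @param n_taxa Number of simulated taxa (default 300).
#' @param gc_range,gc_shape Genomic GC content drawn from
#'   Beta(\code{gc_shape[1]}, \code{gc_shape[2]}) scaled to \code{gc_range}.
#'   The default range `[0.45, 0.65]` spans realistic soil prokaryote GC and
#'   keeps every taxon's DNA (light or labeled) well inside the analyzed
#'   density window, so enrichment is identifiable for all taxa.
#' @param abund_sdlog Log-SD of the lognormal baseline abundance profile
#'   (normalized to proportions).
#' @param eaf_pi0 Zero-inflation: probability a taxon assimilated no label.
#' @param eaf_shape,eaf_max Positive lab EAFs drawn from
#'   Beta(\code{eaf_shape}) scaled to `[0, eaf_max]`.
#' @param map_slope,map_intercept,map_noise_sd Lab-to-field EAF map:
#'   \code{field = slope * lab + intercept + N(0, sd)}, clamped at 0.
#' @param n_plots Replicate plots per site (default 7).
#' @param sites Site names (default Valley, Ridge).
#' @param fractions_per_tube Number of gradient fractions (default 25).
#' @param density_range Full gradient density span, g/mL.
#' @param analysis_window Density window that gets sequenced, g/mL.
#' @param kernel_sd Within-taxon Gaussian density spread, g/mL (diffusion and
#'   mixing in the gradient; default 0.006 makes a taxon span 3--6 fractions).
#' @param tube_offset_sd SD of the per-tube density calibration offset, g/mL.
#' @param qpcr_cv Coefficient of variation of multiplicative lognormal qPCR
#'   noise on fraction totals.
#' @param seq_depth Sequencing reads per fraction (multinomial); \code{Inf}
#'   yields exact expected proportions (scaled to 1e6) for noise-free runs.
#' @param copies_scale Total 16S copies per tube before qPCR noise.
#' @param constants [isotope_constants()] used by the forward model (the same
#'   chain the estimator inverts).
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_taxa = 300,
                       gc_range = c(0.45, 0.65), gc_shape = c(2, 2),
                       abund_sdlog = 1.2,
                       eaf_pi0 = 0.1, eaf_shape = c(1.8, 5.4), eaf_max = 0.6,
                       map_slope = 0.81, map_intercept = 0.01,
                       map_noise_sd = 0.01,
                       n_plots = 7, sites = c("Valley", "Ridge"),
                       fractions_per_tube = 25,
                       density_range = c(1.61, 1.78),
                       analysis_window = c(1.67, 1.74),
                       kernel_sd = 0.006, tube_offset_sd = 0.002,
                       qpcr_cv = 0.1, seq_depth = 10000,
                       copies_scale = 5e8,
                       constants = isotope_constants(),
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_taxa >= 1, kernel_sd > 0, seq_depth > 0, copies_scale > 0,
            qpcr_cv >= 0, tube_offset_sd >= 0,
            density_range[1] < density_range[2],
            analysis_window[1] < analysis_window[2])
  structure(cfg, class = "sim_config")
}

#' Draw the per-taxon truth of a simulated study
#'
#' Draws GC content, baseline relative abundances, true lab EAFs (a
#' zero-inflated scaled Beta), and field EAFs via the configured linear map
#' with taxon-level noise, clamped at zero.
#'
#' @param cfg A [sim_config()].
#' @return Data frame of class \code{sim_truth}: \code{taxon_id},
#'   \code{taxonomy}, \code{gc}, \code{abundance}, \code{eaf_lab},
#'   \code{eaf_field}, with the config attached as attribute \code{config}.
#' @export
simulate_taxa <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_taxa
  gc <- cfg$gc_range[1] +
    diff(cfg$gc_range) * stats::rbeta(n, cfg$gc_shape[1], cfg$gc_shape[2])
  ab <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$abund_sdlog)
  ab <- ab / sum(ab)
  zero <- stats::runif(n) < cfg$eaf_pi0
  eaf_lab <- ifelse(zero, 0,
                    cfg$eaf_max * stats::rbeta(n, cfg$eaf_shape[1],
                                               cfg$eaf_shape[2]))
  eaf_field <- pmax(0, cfg$map_slope * eaf_lab + cfg$map_intercept +
                      stats::rnorm(n, 0, cfg$map_noise_sd))
  id <- sprintf("ASV%04d", seq_len(n))
  taxonomy <- sprintf(
    "d__Bacteria;p__SimPhylum%d;c__SimClass%d;o__SimOrder%d;f__SimFamily%d;g__SimGenus%04d",
    seq_len(n) %% 8L + 1L, seq_len(n) %% 16L + 1L, seq_len(n) %% 32L + 1L,
    seq_len(n) %% 64L + 1L, seq_len(n))
  out <- data.frame(taxon_id = id, taxonomy = taxonomy, gc = gc,
                    abundance = ab, eaf_lab = eaf_lab,
                    eaf_field = eaf_field, stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  class(out) <- c("sim_truth", "data.frame")
  out
}

# internal: one tube. Uses the current RNG stream (no reseeding).
# Returns list(fractions = data.frame rows, counts = taxa x fractions matrix).
simulate_tube <- function(truth, site, method, label, tube_id, sample_id,
                          cfg, tube_offset = 0) {
  n <- nrow(truth)
  w_light <- cfg$constants$gc_slope * truth$gc + cfg$constants$gc_intercept
  eaf <- if (label == "unlabeled") {
    rep(0, n)
  } else if (method == "lab") truth$eaf_lab else truth$eaf_field
  center <- wad_for_eaf(eaf, w_light, truth$gc, cfg$constants) + tube_offset

  edges <- seq(cfg$density_range[1], cfg$density_range[2],
               length.out = cfg$fractions_per_tube + 1L)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  # kernel mass per taxon per bin: Gaussian integrated over bin edges
  z <- outer(center, edges, function(w, e) stats::pnorm((e - w) / cfg$kernel_sd))
  mass <- truth$abundance * t(diff(t(z)))    # taxa x bins

  f_k <- cfg$copies_scale * colSums(mass)
  if (cfg$qpcr_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$qpcr_cv^2))
    f_k <- f_k * stats::rlnorm(length(f_k), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
  }
  in_window <- mids >= cfg$analysis_window[1] & mids <= cfg$analysis_window[2]
  counts <- matrix(0, n, cfg$fractions_per_tube)
  for (k in which(in_window)) {
    m_k <- mass[, k]
    tot <- sum(m_k)
    if (tot <= 0) next
    q <- m_k / tot
    counts[, k] <- if (is.finite(cfg$seq_depth)) {
      stats::rmultinom(1L, cfg$seq_depth, q)[, 1L]
    } else {
      q * 1e6
    }
  }
  fraction_id <- sprintf("%s_F%02d", tube_id, seq_len(cfg$fractions_per_tube))
  colnames(counts) <- fraction_id
  rownames(counts) <- truth$taxon_id
  list(
    fractions = data.frame(tube_id = tube_id, sample_id = sample_id,
                           fraction_id = fraction_id, density = mids,
                           total_copies = f_k, stringsAsFactors = FALSE),
    counts = counts
  )
}

#' Simulate a full paired field/lab qSIP study
#'
#' Generates the complete 2-site x 7-plot x (control + field + lab) design:
#' for every tube, fraction densities, qPCR totals with lognormal noise, and
#' multinomial sequencing counts over the analyzed window. Fractions outside
#' the window are generated (with qPCR totals) but receive no reads,
#' mirroring a study that only sequences the high-DNA window.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, writes
#'   \code{fractions.tsv}, \code{counts.tsv}, \code{taxonomy.tsv},
#'   \code{samples.tsv} and \code{truth.tsv}. Refuses a non-empty directory
#'   unless \code{force = TRUE}.
#' @param force Overwrite an existing non-empty directory.
#' @return List of class \code{qsip_sim}: \code{fractions}
#'   (\code{qsip_fractions}), \code{counts} (\code{taxon_matrix}),
#'   \code{samples}, \code{design}, \code{truth}, \code{tube_offsets},
#'   \code{config}.
#' @export
simulate_study <- function(cfg = sim_config(), dir = NULL, force = FALSE) {
  truth <- simulate_taxa(cfg)   # seeds the stream; later draws follow it

  samples <- expand.grid(plot = seq_len(cfg$n_plots), site = cfg$sites,
                         stringsAsFactors = FALSE)
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(samples))) {
    s <- samples$site[i]; p <- samples$plot[i]
    base <- sprintf("%s_P%d", s, p)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = c(paste0(base, "_pre"), paste0(base, "_field"),
                    paste0(base, "_lab")),
      site = s, method = c("none", "field", "lab"), plot = p,
      label = c("unlabeled", "labeled", "labeled"), stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  design <- validate_design(meta)

  tube_ids <- paste0("T_", meta$sample_id)
  offsets <- stats::setNames(
    stats::rnorm(nrow(meta), 0, cfg$tube_offset_sd), tube_ids)

  frac_list <- vector("list", nrow(meta))
  count_list <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    tb <- simulate_tube(truth, meta$site[i], meta$method[i], meta$label[i],
                        tube_ids[i], meta$sample_id[i], cfg,
                        tube_offset = offsets[tube_ids[i]])
    frac_list[[i]] <- tb$fractions
    count_list[[i]] <- tb$counts
  }
  fractions <- as_qsip_fractions(do.call(rbind, frac_list))
  counts <- do.call(cbind, count_list)
  tm <- taxon_matrix(counts, stats::setNames(truth$taxonomy, truth$taxon_id))

  out <- structure(list(fractions = fractions, counts = tm, samples = meta,
                        design = design, truth = truth,
                        tube_offsets = offsets, config = cfg),
                   class = "qsip_sim")
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
      stop("output directory ", dir, " is not empty (use force = TRUE)")
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fraction_table(fractions, file.path(dir, "fractions.tsv"),
                         seed = cfg$seed)
    write_taxon_counts(tm, file.path(dir, "counts.tsv"),
                       file.path(dir, "taxonomy.tsv"), seed = cfg$seed)
    write_sample_table(meta, file.path(dir, "samples.tsv"), seed = cfg$seed)
    tdf <- as.data.frame(truth)
    tdf$tube_offset_sd <- cfg$tube_offset_sd
    write_tsv_commented(tdf, file.path(dir, "truth.tsv"), seed = cfg$seed)
  }
  out
}

#' @export
print.qsip_sim <- function(x, ...) {
  cat("qsip_sim:", nrow(x$truth), "taxa,",
      length(unique(x$fractions$tube_id)), "tubes,",
      nrow(x$fractions), "fractions (seed", x$config$seed, ")\n")
  invisible(x)
}
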