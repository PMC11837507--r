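# Readers, writers and validation for the four tabular inputs of a qSIP
# experiment: gradient fractions, taxon counts, taxonomy, sample metadata.

#' Read a gradient fraction table
#'
#' Reads the per-tube fraction table of a density-gradient experiment: one row
#' per ultracentrifuge fraction, carrying the refractometer buoyant density
#' (g/mL) and the total 16S rRNA gene copies measured by qPCR.
#'
#' @param path Path to a delimited text file with header columns
#'   \code{tube_id}, \code{sample_id}, \code{fraction_id}, \code{density},
#'   \code{total_copies}. Lines starting with \code{#} are ignored.
#' @param sep Field separator. \code{NULL} (default) auto-detects tab vs comma
#'   from the header line; pass \code{"\t"} or \code{","} to override.
#' @return A \code{qsip_fractions} data frame, sorted by tube then ascending
#'   density, validated (densities in (1.5, 2.0) g/mL, copies >= 0, unique
#'   fraction ids, >= 3 fractions per tube, strictly increasing densities
#'   within tube).
#' @seealso [write_fraction_table()], [select_fractions()]
#' @export
read_fraction_table <- function(path, sep = NULL) {
  df <- read_delim_auto(path, sep)
  need <- c("tube_id", "sample_id", "fraction_id", "density", "total_copies")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("fraction table is missing column(s): ", paste(miss, collapse = ", "))
  }
  as_qsip_fractions(df[need])
}

#' Construct a validated fraction table from a data frame
#'
#' @param df Data frame with columns \code{tube_id}, \code{sample_id},
#'   \code{fraction_id}, \code{density}, \code{total_copies}.
#' @return A \code{qsip_fractions} data frame (see [read_fraction_table()]).
#' @export
as_qsip_fractions <- function(df) {
  df$tube_id <- as.character(df$tube_id)
  df$sample_id <- as.character(df$sample_id)
  df$fraction_id <- as.character(df$fraction_id)
  df$density <- as.numeric(df$density)
  df$total_copies <- as.numeric(df$total_copies)

  bad <- which(!is.finite(df$density) | df$density <= 1.5 | df$density >= 2.0)
  if (length(bad) > 0L) {
    stop("fraction table row(s) ", paste(bad, collapse = ", "),
         ": density outside (1.5, 2.0) g/mL")
  }
  bad <- which(!is.finite(df$total_copies) | df$total_copies < 0)
  if (length(bad) > 0L) {
    stop("fraction table row(s) ", paste(bad, collapse = ", "),
         ": total_copies must be non-negative")
  }
  if (anyDuplicated(df$fraction_id)) {
    stop("duplicate fraction_id: ",
         paste(unique(df$fraction_id[duplicated(df$fraction_id)]), collapse = ", "))
  }
  df <- df[order(df$tube_id, df$density), , drop = FALSE]
  rownames(df) <- NULL
  for (tb in unique(df$tube_id)) {
    d <- df$density[df$tube_id == tb]
    if (length(d) < 3L) {
      stop("tube ", tb, " has fewer than 3 fractions")
    }
    if (any(diff(d) <= 0)) {
      stop("tube ", tb, " has non-increasing (tied) densities after sorting")
    }
    sid <- unique(df$sample_id[df$tube_id == tb])
    if (length(sid) != 1L) {
      stop("tube ", tb, " maps to more than one sample_id")
    }
  }
  class(df) <- c("qsip_fractions", "data.frame")
  df
}

#' Read a taxon-by-fraction count matrix with taxonomy
#'
#' @param path Path to a delimited file whose first column is \code{taxon_id}
#'   and remaining columns are fraction ids holding non-negative counts.
#' @param taxonomy_path Path to a two-column delimited file \code{taxon_id},
#'   \code{taxonomy} (semicolon-delimited rank string).
#' @param sep Separator override as in [read_fraction_table()].
#' @return A \code{taxon_matrix}: list with \code{counts} (numeric matrix,
#'   taxa x fractions) and \code{taxonomy} (named character vector).
#' @export
read_taxon_counts <- function(path, taxonomy_path, sep = NULL) {
  df <- read_delim_auto(path, sep)
  if (names(df)[1L] != "taxon_id") {
    stop("counts table must have 'taxon_id' as its first column")
  }
  tax <- read_delim_auto(taxonomy_path, sep)
  if (!all(c("taxon_id", "taxonomy") %in% names(tax))) {
    stop("taxonomy table must have columns taxon_id, taxonomy")
  }
  ids <- as.character(df$taxon_id)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "double"
  rownames(counts) <- ids
  taxonomy <- stats::setNames(as.character(tax$taxonomy), as.character(tax$taxon_id))
  taxon_matrix(counts, taxonomy)
}

#' Construct a validated taxon count matrix
#'
#' @param counts Numeric matrix, taxa in rows (rownames = taxon ids),
#'   fractions in columns (colnames = fraction ids).
#' @param taxonomy Named character vector mapping taxon id to a
#'   semicolon-delimited taxonomy string.
#' @return An object of class \code{taxon_matrix}.
#' @export
taxon_matrix <- function(counts, taxonomy) {
  if (nrow(counts) > 0L && is.null(rownames(counts))) {
    stop("counts matrix needs taxon row names")
  }
  if (is.null(colnames(counts))) {
    stop("counts matrix needs fraction column names")
  }
  if (nrow(counts) == 0L && is.null(rownames(counts))) {
    rownames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate taxon id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  missing_tax <- setdiff(rownames(counts), names(taxonomy))
  if (length(missing_tax) > 0L) {
    stop("taxa without taxonomy: ", paste(missing_tax, collapse = ", "))
  }
  structure(list(counts = counts,
                 taxonomy = taxonomy[rownames(counts)]),
            class = "taxon_matrix")
}

#' @export
print.taxon_matrix <- function(x, ...) {
  cat("taxon_matrix:", nrow(x$counts), "taxa x", ncol(x$counts), "fractions\n")
  invisible(x)
}

#' Read sample metadata
#'
#' @param path Delimited file with columns \code{sample_id}, \code{site},
#'   \code{method}, \code{plot}, \code{label}.
#' @param sep Separator override.
#' @return Data frame of sample metadata (method in \{field, lab\} or NA for
#'   unlabeled controls; label in \{unlabeled, labeled\}).
#' @export
read_sample_table <- function(path, sep = NULL) {
  df <- read_delim_auto(path, sep)
  need <- c("sample_id", "site", "method", "plot", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  df$site <- as.character(df$site)
  df$method <- as.character(df$method)
  df$plot <- as.integer(df$plot)
  df$label <- as.character(df$label)
  df
}

#' Validate the paired study design
#'
#' Checks that every labeled (post-incubation) sample has exactly one
#' unlabeled (pre-incubation, natural-abundance) control in the same
#' (site, plot), and builds the pairing used throughout the analysis. The one
#' pre-incubation extract of a plot serves as the control for both the field
#' and the lab labeled samples of that plot.
#'
#' @param samples Data frame as returned by [read_sample_table()].
#' @return A \code{study_design}: list with \code{samples} and \code{pairing}
#'   (data frame: labeled sample id, its control sample id, site, method, plot).
#' @export
validate_design <- function(samples) {
  samples <- samples[order(samples$site, samples$plot, samples$label,
                           samples$method, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in metadata")
  }
  if (!all(samples$label %in% c("unlabeled", "labeled"))) {
    stop("label must be 'unlabeled' or 'labeled'")
  }
  lab <- samples[samples$label == "labeled", , drop = FALSE]
  if (!all(lab$method %in% c("field", "lab"))) {
    stop("labeled samples must have method 'field' or 'lab'")
  }
  unl <- samples[samples$label == "unlabeled", , drop = FALSE]

  key <- function(d) paste(d$site, d$plot, sep = "\r")
  dup_ctl <- unique(key(unl)[duplicated(key(unl))])
  if (length(dup_ctl) > 0L) {
    stop("more than one unlabeled control for (site, plot): ",
         paste(gsub("\r", ", plot ", dup_ctl), collapse = "; "),
         " (pairing would be ambiguous)")
  }
  dup_lab <- paste(key(lab), lab$method)[duplicated(paste(key(lab), lab$method))]
  if (length(dup_lab) > 0L) {
    stop("more than one labeled sample for the same (site, plot, method)")
  }
  ctl_of <- stats::setNames(unl$sample_id, key(unl))
  missing_ctl <- !(key(lab) %in% names(ctl_of))
  if (any(missing_ctl)) {
    bad <- unique(gsub("\r", ", plot ", key(lab)[missing_ctl]))
    stop("labeled sample(s) without a same-plot unlabeled control: site ",
         paste(bad, collapse = "; site "))
  }
  pairing <- data.frame(
    sample_id = lab$sample_id,
    control_id = unname(ctl_of[key(lab)]),
    site = lab$site,
    method = lab$method,
    plot = lab$plot,
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, pairing = pairing), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", nrow(x$samples), "samples,",
      nrow(x$pairing), "labeled/control pairs\n")
  cat("  sites:", paste(unique(x$samples$site), collapse = ", "), "\n")
  invisible(x)
}

# ---- writers -----------------------------------------------------------

#' Write pipeline tables
#'
#' Writers for the package's tab-separated formats. Each file starts with a
#' comment line recording the package version (and seed when given), which the
#' readers skip.
#'
#' @param x Object to write (fraction table, sample data frame, or
#'   \code{taxon_matrix}).
#' @param path Output file path.
#' @param seed Optional integer recorded in the header comment.
#' @return \code{path}, invisibly.
#' @export
write_fraction_table <- function(x, path, seed = NULL) {
  write_tsv_commented(as.data.frame(x), path, seed)
}

#' @rdname write_fraction_table
#' @export
write_sample_table <- function(x, path, seed = NULL) {
  write_tsv_commented(as.data.frame(x), path, seed)
}

#' @rdname write_fraction_table
#' @param taxonomy_path Where to write the taxonomy companion table.
#' @export
write_taxon_counts <- function(x, path, taxonomy_path, seed = NULL) {
  stopifnot(inherits(x, "taxon_matrix"))
  df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, path, seed)
  tax <- data.frame(taxon_id = names(x$taxonomy), taxonomy = unname(x$taxonomy),
                    stringsAsFactors = FALSE)
  write_tsv_commented(tax, taxonomy_path, seed)
  invisible(path)
}

# internal: sniff separator from the first non-comment line
read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    con <- file(path, "r")
    on.exit(close(con))
    repeat {
      ln <- readLines(con, n = 1L)
      if (length(ln) == 0L) stop("empty file: ", path)
      if (!startsWith(ln, "#")) break
    }
    sep <- if (grepl("\t", ln)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"")
}

write_tsv_commented <- function(df, path, seed = NULL) {
  hdr <- paste0("# qsipn ", as.character(utils::packageVersion("qsipn")),
                if (!is.null(seed)) paste0(" seed=", seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
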