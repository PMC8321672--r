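#' iBAQ pulldown intensity matrix
#'
#' Proteins x samples, where each sample is one (probe, time point) RNA
#' affinity pulldown. Missing intensities stay `NA` until
#' [ibaq_preprocess()], so "not quantified" is distinguishable from a
#' measured zero.
#'
#' @param values numeric matrix, rows = proteins (rownames required),
#'   columns = samples.
#' @param probe,timepoint character vectors labelling each column.
#' @param contaminant logical per-protein flag (default: rownames matching
#'   `contaminant_patterns`).
#' @param contaminant_patterns regexes marking contaminant/confounding
#'   proteins (keratins and ribosomal proteins by default).
#' @return object of class `ibaq_matrix`.
#' @export
ibaq_matrix <- function(values, probe, timepoint, contaminant = NULL,
                        contaminant_patterns = c("(?i)^krt", "(?i)keratin",
                                                 "(?i)^rp[ls]",
                                                 "(?i)ribosomal")) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)),
            length(probe) == ncol(values),
            length(timepoint) == ncol(values))
  if (any(values < 0, na.rm = TRUE)) stop("iBAQ values must be >= 0")
  if (is.null(contaminant)) {
    contaminant <- Reduce(`|`, lapply(contaminant_patterns, function(p)
      grepl(p, rownames(values), perl = TRUE)))
  }
  names(contaminant) <- rownames(values)
  colnames(values) <- paste(probe, timepoint, sep = ".")
  structure(list(values = values, probe = probe, timepoint = timepoint,
                 contaminant = contaminant, processed = FALSE),
            class = "ibaq_matrix")
}

#' @export
print.ibaq_matrix <- function(x, ...) {
  cat(sprintf(
    "<ibaq_matrix> %d proteins x %d samples (%d probes x %d timepoints)%s, %d contaminant-flagged\n",
    nrow(x$values), ncol(x$values), length(unique(x$probe)),
    length(unique(x$timepoint)),
    if (x$processed) ", preprocessed" else "", sum(x$contaminant)))
  invisible(x)
}

#' Preprocess an iBAQ matrix
#'
#' Missing intensities are set to 0, contaminant-flagged proteins removed,
#' values transformed as `log10(x + 1)`, and every sample column centered to
#' mean 0.
#'
#' @param m an [ibaq_matrix()].
#' @return the processed `ibaq_matrix` (`processed = TRUE`).
#' @export
ibaq_preprocess <- function(m) {
  stopifnot(inherits(m, "ibaq_matrix"))
  v <- m$values
  if (any(colSums(!is.na(v)) == 0)) {
    stop("sample column(s) entirely missing: ",
         paste(colnames(v)[colSums(!is.na(v)) == 0], collapse = ", "))
  }
  v[is.na(v)] <- 0
  v <- v[!m$contaminant, , drop = FALSE]
  v <- log10(v + 1)
  v <- sweep(v, 2, colMeans(v), "-")
  structure(list(values = v, probe = m$probe, timepoint = m$timepoint,
                 contaminant = rep(FALSE, nrow(v)), processed = TRUE),
            class = "ibaq_matrix")
}

#' Per-protein fold enrichment of one probe versus the others
#'
#' On the de-logged normalized scale (`10^y` of the centered log values),
#' the fold change of each probe versus the mean of the other probes at the
#' same time point; a protein is flagged enriched when the fold change
#' exceeds `fold` (strict). Bead-only control columns are excluded from the
#' "other probes" mean by default.
#'
#' @param m a preprocessed [ibaq_matrix()].
#' @param fold enrichment threshold (default 10).
#' @param bead_probe name of the bead-only control probe (excluded from the
#'   comparison mean), or `NULL` to include every probe.
#' @return data frame with `protein`, `probe`, `timepoint`, `fc` (linear),
#'   `log2_fc`, `enriched`.
#' @export
fold_enrichment <- function(m, fold = 10, bead_probe = "bead") {
  stopifnot(inherits(m, "ibaq_matrix"), m$processed)
  probes <- unique(m$probe)
  if (!is.null(bead_probe)) probes <- setdiff(probes, bead_probe)
  if (length(probes) < 2L) stop("need at least 2 probes per timepoint")
  out <- list()
  for (tp in unique(m$timepoint)) {
    cols <- which(m$timepoint == tp & m$probe %in% probes)
    u <- 10^m$values[, cols, drop = FALSE]       # de-logged normalized
    for (ci in seq_along(cols)) {
      others <- rowMeans(u[, -ci, drop = FALSE])
      fc <- u[, ci] / others                     # Inf when others == 0
      fc[u[, ci] == 0 & others == 0] <- NA_real_
      out[[length(out) + 1L]] <- data.frame(
        protein = rownames(u), probe = m$probe[cols[ci]], timepoint = tp,
        fc = unname(fc), log2_fc = unname(log2(fc)),
        enriched = unname(!is.na(fc) & fc > fold), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

# linear fold-change core: value of one probe vs mean of the others
fc_linear <- function(values, probe_idx) {
  others <- mean(values[-probe_idx])
  v <- values[probe_idx]
  if (others == 0) {
    if (v == 0) NA_real_ else Inf
  } else {
    v / others
  }
}

#' Enriched-protein sets per time point
#'
#' @param fe a [fold_enrichment()] table.
#' @return named list (per time point) of character vectors of proteins
#'   enriched on at least one probe.
#' @export
enriched_sets <- function(fe) {
  lapply(split(fe, fe$timepoint), function(d)
    sort(unique(d$protein[d$enriched])))
}

#' Differentiation-specific and persistent enriched proteins
#'
#' `specific` = proteins enriched at any post-differentiation time point
#' (e.g. day 2 or day 4) but not at baseline; `persistent` = proteins
#' enriched at every tested time point including baseline.
#'
#' @param sets named list of per-timepoint enriched protein sets (as from
#'   [enriched_sets()]).
#' @param baseline name of the baseline time point (default first element).
#' @return list with `specific` and `persistent` character vectors.
#' @export
differentiation_specific <- function(sets, baseline = names(sets)[1L]) {
  stopifnot(baseline %in% names(sets))
  post <- sets[setdiff(names(sets), baseline)]
  specific <- setdiff(sort(unique(unlist(post))), sets[[baseline]])
  persistent <- sort(Reduce(intersect, sets))
  list(specific = specific, persistent = persistent)
}

#' Read an iBAQ TSV table
#'
#' Layout: first column protein id, remaining columns named
#' `<probe>.<timepoint>`; empty cells are missing.
#'
#' @param path TSV file.
#' @param ... passed to [ibaq_matrix()].
#' @return an [ibaq_matrix()].
#' @export
read_ibaq <- function(path, ...) {
  d <- utils::read.delim(path, check.names = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  rownames(vals) <- d[[1]]
  parts <- strsplit(colnames(vals), ".", fixed = TRUE)
  ibaq_matrix(vals,
              probe = vapply(parts, `[[`, character(1), 1L),
              timepoint = vapply(parts, `[[`, character(1), 2L), ...)
}
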