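## Plain-text interchange: headered TSV for matrices, CSV for tables, all
## floating point at 17 significant digits so write/read round-trips are
## exact at double precision.

fmtNum <- function(x) formatC(x, digits = 17, format = "g")

writeMatrixTsv <- function(m, path) {
  df <- as.data.frame(apply(m, 2L, fmtNum))
  if (is.null(colnames(m))) names(df) <- sprintf("V%d", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readMatrixTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a cohort to disk
#'
#' Writes one headered TSV per subject (T rows x N ROI columns), a
#' phenotype CSV (`subject_id`, `site_id`, `label`) and a `manifest.csv`
#' listing every subject's file. Round-trips through [readCohort()].
#'
#' @param cohort list of [RoiTimeSeries-class].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pheno <- data.frame(subject_id = subjectId(cohort),
                      site_id = siteId(cohort),
                      label = subjectLabel(cohort),
                      file = paste0(subjectId(cohort), ".tsv"))
  for (s in cohort)
    writeMatrixTsv(tsData(s), file.path(dir, paste0(subjectId(s), ".tsv")))
  utils::write.csv(pheno[, c("subject_id", "site_id", "label")],
                   file.path(dir, "phenotype.csv"), row.names = FALSE)
  utils::write.csv(pheno, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a cohort from a manifest
#'
#' Validates on the way in: duplicate subject ids, missing files, labels
#' outside patient/control, inconsistent ROI counts and zero-variance ROI
#' columns are rejected with the offending subjects named.
#'
#' @param manifest path to a `manifest.csv` written by [writeCohort()].
#' @return List of [RoiTimeSeries-class] in manifest order.
#' @export
readCohort <- function(manifest) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "site_id", "label", "file")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(mf$subject_id))
    stop("duplicate subject ids: ",
         paste(unique(mf$subject_id[duplicated(mf$subject_id)]),
               collapse = ", "))
  bad <- !mf$label %in% c("patient", "control")
  if (any(bad))
    stop("invalid labels for: ", paste(mf$subject_id[bad], collapse = ", "))
  base <- dirname(manifest)
  nRois <- NULL
  out <- vector("list", nrow(mf))
  for (k in seq_len(nrow(mf))) {
    path <- file.path(base, mf$file[k])
    if (!file.exists(path)) stop("missing time-series file: ", path)
    d <- readMatrixTsv(path)
    if (is.null(nRois)) nRois <- ncol(d)
    if (ncol(d) != nRois)
      stop("subject ", mf$subject_id[k], ": wrong ROI count (", ncol(d),
           " vs ", nRois, ")")
    v <- apply(d, 2L, stats::var)
    if (any(v == 0))
      stop("subject ", mf$subject_id[k], " rejected: zero-variance ROI ",
           paste(which(v == 0), collapse = ", "))
    out[[k]] <- new("RoiTimeSeries", data = d, subjectId = mf$subject_id[k],
                    siteId = mf$site_id[k], label = mf$label[k])
  }
  out
}

#' Write / read a connectivity matrix as headered TSV
#' @param m a [ConnectivityMatrix-class].
#' @param path file path.
#' @export
writeConnectivity <- function(m, path) {
  v <- m@values
  colnames(v) <- if (is.null(colnames(v)))
    sprintf("ROI%03d", seq_len(ncol(v))) else colnames(v)
  writeMatrixTsv(v, path)
  invisible(path)
}

#' @rdname writeConnectivity
#' @param layer,subjectId tags for the reconstructed object.
#' @export
readConnectivity <- function(path, layer = "LOFC", subjectId = "unknown") {
  new("ConnectivityMatrix", values = unname(readMatrixTsv(path)),
      layer = layer, subjectId = subjectId)
}

#' Write a selection result as CSV
#'
#' One row per edge: index, ROI pair, p-value, selected flag, fold id.
#'
#' @param sel a [SelectionResult-class].
#' @param nRois number of ROIs (to reconstruct the pair labels).
#' @param path file path.
#' @export
writeSelection <- function(sel, nRois, path) {
  pairs <- edgePairs(nRois)
  df <- data.frame(edge = seq_along(sel@pValues), roi_i = pairs[, "i"],
                   roi_j = pairs[, "j"], p_value = fmtNum(sel@pValues),
                   selected = seq_along(sel@pValues) %in% sel@selected,
                   layer = sel@layer, fold = sel@foldId)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a cross-validation report
#'
#' The per-fold CSV has one row per held-out site; a configuration header
#' is stored in comment lines.
#'
#' @param report a [CvReport-class].
#' @param path file path.
#' @export
writeCvReport <- function(report, path) {
  cfg <- report@configuration
  hdr <- sprintf("# layers=%s classifier=%s pThreshold=%s seed=%s",
                 paste(cfg$layers, collapse = "+"), cfg$classifier,
                 cfg$pThreshold, cfg$seed)
  pf <- report@perFold
  pf$accuracy <- fmtNum(pf$accuracy)
  pf$accuracy_best <- fmtNum(pf$accuracy_best)
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.csv(pf, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeCvReport
#' @export
readCvReport <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^# ", "", lines[1])
  kv <- strsplit(strsplit(hdr, " ")[[1]], "=")
  cfg <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  cfg$layers <- strsplit(cfg$layers, "+", fixed = TRUE)[[1]]
  cfg$pThreshold <- as.numeric(cfg$pThreshold)
  cfg$seed <- as.integer(cfg$seed)
  pf <- utils::read.csv(textConnection(lines[-1]))
  pf$accuracy <- as.numeric(pf$accuracy)
  pf$accuracy_best <- as.numeric(pf$accuracy_best)
  new("CvReport", configuration = cfg, perFold = pf,
      meanSd = summarizeFolds(pf))
}

#' Summary table across configurations
#'
#' Builds the study-style summary: one row per layer configuration, one
#' column per classifier/threshold/reporting-sense combination, entries
#' formatted "mean +/- sd" in percent, recomputed from the per-fold rows.
#'
#' @param reports list of [CvReport-class].
#' @param path optional CSV path to write to.
#' @return data.frame, invisibly if written.
#' @export
cvSummaryTable <- function(reports, path = NULL) {
  rows <- lapply(reports, function(r) {
    cfg <- r@configuration
    ms <- summarizeFolds(r@perFold)  # recomputed, not copied
    out <- data.frame(
      configuration = paste(cfg$layers, collapse = "+"),
      column = sprintf("%s_p%s_test", cfg$classifier, cfg$pThreshold),
      value = sprintf("%.2f ± %.2f", ms["mean"], ms["sd"]))
    if (cfg$classifier == "dann")
      out <- rbind(out, data.frame(
        configuration = out$configuration[1],
        column = sprintf("dann_p%s_best_test", cfg$pThreshold),
        value = sprintf("%.2f ± %.2f", ms["mean_best"], ms["sd_best"])))
    out
  })
  long <- do.call(rbind, rows)
  wide <- stats::reshape(long, idvar = "configuration",
                         timevar = "column", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  if (!is.null(path)) {
    utils::write.csv(wide, path, row.names = FALSE)
    return(invisible(wide))
  }
  wide
}
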