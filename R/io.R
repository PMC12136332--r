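## Delimiter auto-detection for matrix files: tab wins if present in the
## first data line, else comma, else whitespace.
detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

readMatrixFile <- function(path, subjectId) {
  if (!file.exists(path))
    stop(sprintf("subject %s: matrix file not found: %s", subjectId, path))
  sep <- detectSep(path)
  nf <- utils::count.fields(path, sep = sep)
  if (length(unique(nf)) > 1)
    stop(sprintf("subject %s: ragged matrix in %s (rows have %s fields)",
                 subjectId, path, paste(unique(nf), collapse = "/")))
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          colClasses = "character")
  m <- suppressWarnings(apply(as.matrix(df), c(1, 2), as.numeric))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("subject %s: non-numeric entry at row %d, column %d of %s",
                 subjectId, bad[1], bad[2], path))
  }
  unname(m)
}

#' Write a cohort to delimited text files plus a manifest
#'
#' One tab-delimited matrix per subject (rows = regions, columns = time
#' points, no header) and a `manifest.csv` with columns `subject_id`,
#' `label`, `path` (paths relative to the manifest). When a [SimSpec-class]
#' is supplied it is echoed to `simspec.json` alongside.
#'
#' @param cohort a [RoiTimeSeriesSet-class].
#' @param dir output directory (created if needed).
#' @param spec optional [SimSpec-class] that generated the cohort.
#' @return path of the manifest, invisibly.
#' @export
writeCohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("%s.tsv", subjectIds(cohort))
  for (i in seq_len(nSubjects(cohort)))
    utils::write.table(cohort@series[[i]], file.path(dir, paths[i]),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  manifest <- data.frame(subject_id = subjectIds(cohort),
                         label = as.character(groupLabels(cohort)),
                         path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(spec))
    jsonlite::write_json(
      list(n_regions = spec@nRegions, n_timepoints = spec@nTimepoints,
           n_per_group = spec@nPerGroup,
           effect_edges = if (nrow(spec@effectEdges)) spec@effectEdges else
             matrix(integer(0), ncol = 2),
           effect_size = spec@effectSize, n_states = spec@nStates,
           switch_prob = spec@switchProb, noise_sd = spec@noiseSd,
           seed = spec@seed),
      file.path(dir, "simspec.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a cohort from a manifest of delimited matrix files
#'
#' @param manifestPath CSV with columns `subject_id`, `label`
#'   (`NC`/`eMCI`), `path` (relative to the manifest or absolute).
#' @return a [RoiTimeSeriesSet-class].
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop("manifest not found: ", manifestPath)
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns subject_id, label, path")
  badLab <- setdiff(unique(man$label), GROUP_LEVELS)
  if (length(badLab))
    stop(sprintf("unknown label(s) in manifest: %s",
                 paste(badLab, collapse = ", ")))
  base <- dirname(manifestPath)
  series <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    readMatrixFile(p, man$subject_id[i])
  })
  names(series) <- man$subject_id
  new("RoiTimeSeriesSet", series = series,
      labels = factor(man$label, levels = GROUP_LEVELS),
      subjectIds = man$subject_id)
}
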