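#' Construct a StrokeCase from in-memory volumes
#'
#' @param case_id identifier string.
#' @param volumes named list of six 3D arrays (names from
#'   [pmfesnModalities()]), all the same shape.
#' @param mrs integer outcome label 0..4.
#' @param clinical optional list of clinical covariates (carried, never used
#'   by the model).
#' @return A [StrokeCase-class].
#' @export
strokeCase <- function(case_id, volumes, mrs, clinical = list()) {
  new("StrokeCase", caseId = as.character(case_id),
      volumes = volumes[pmfesnModalities()],
      mrs = as.integer(mrs), clinical = clinical)
}

#' Construct a StrokeDataset from a list of cases
#'
#' @param cases list of [StrokeCase-class] objects (order preserved).
#' @return A [StrokeDataset-class].
#' @export
strokeDataset <- function(cases = list()) new("StrokeDataset", cases = cases)

#' Load one case from six NIfTI files
#'
#' Reads the six co-registered parameter maps of a single case. The maps are
#' assumed preprocessed (skull-stripped, co-registered); voxel data are kept
#' as read.
#'
#' @param modality_paths named character vector or list mapping each of the
#'   six canonical modality names to a .nii/.nii.gz path.
#' @param mrs integer label 0..4.
#' @param case_id identifier; defaults to the basename stem of the ADC file.
#' @param clinical optional clinical covariate list.
#' @return A [StrokeCase-class].
#' @export
loadCase <- function(modality_paths, mrs, case_id = NULL, clinical = list()) {
  mods <- pmfesnModalities()
  missing <- setdiff(mods, names(modality_paths))
  if (length(missing))
    stop("missing modality path(s): ", paste(missing, collapse = ", "))
  paths <- vapply(mods, function(m) as.character(modality_paths[[m]]), "")
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("file(s) not found: ", paste(absent, collapse = ", "))
  vols <- lapply(paths, function(p) {
    v <- RNifti::readNifti(p)
    a <- array(as.numeric(v), dim = dim(v))
    if (length(dim(a)) != 3L)
      stop("not a 3D volume: ", p)
    a
  })
  names(vols) <- mods
  if (is.null(case_id)) {
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(paths[["ADC"]]))
    case_id <- sub("_?ADC$", "", case_id)
  }
  strokeCase(case_id, vols, mrs, clinical)
}

#' Discover a case's modality files in a directory
#'
#' Convenience for challenge-style layouts where each map's filename contains
#' the modality name (e.g. `..._ADC.nii.gz`, `..._Tmax.nii.gz`): matches each
#' canonical modality by case-sensitive substring and loads the case. A
#' manifest (see [loadDataset()]) overrides this when layouts differ.
#'
#' @param dir directory holding exactly one NIfTI file per modality.
#' @param mrs integer label 0..4.
#' @param case_id identifier; defaults to the directory name.
#' @return A [StrokeCase-class].
#' @export
discoverCase <- function(dir, mrs, case_id = basename(normalizePath(dir))) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  paths <- vapply(pmfesnModalities(), function(m) {
    hit <- files[grepl(m, basename(files), fixed = TRUE)]
    if (m == "TTP")  # Tmax also contains no "TTP", but guard the converse
      hit <- hit[!grepl("Tmax", basename(hit), fixed = TRUE)]
    if (length(hit) == 0L)
      stop("no file matching modality ", m, " in ", dir)
    if (length(hit) > 1L)
      stop("ambiguous files for modality ", m, ": ",
           paste(basename(hit), collapse = ", "))
    hit
  }, "")
  loadCase(paths, mrs = mrs, case_id = case_id)
}

#' Load a dataset from a CSV manifest
#'
#' The manifest has one row per case with columns `case_id`, `adc`, `mtt`,
#' `ttp`, `tmax`, `cbv`, `cbf`, `mrs` (and optionally `tss_minutes`,
#' `ttt_minutes`, `tici_grade`). Relative paths are resolved against the
#' manifest's directory. Case order follows manifest order.
#'
#' @param manifest path to the CSV manifest, or a data.frame with the same
#'   columns.
#' @param base_dir directory against which relative paths are resolved;
#'   defaults to the manifest's directory (or `.` for a data.frame input).
#' @return A [StrokeDataset-class].
#' @export
loadDataset <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else if (is.null(base_dir)) base_dir <- "."
  cols <- c("case_id", "adc", "mtt", "ttp", "tmax", "cbv", "cbf", "mrs")
  missing <- setdiff(cols, names(manifest))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$case_id))
    stop("duplicate case_id in manifest: ",
         paste(unique(manifest$case_id[duplicated(manifest$case_id)]),
               collapse = ", "))
  mods <- pmfesnModalities()
  lower <- c("adc", "mtt", "ttp", "tmax", "cbv", "cbf")
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    paths <- vapply(lower, function(m) {
      p <- as.character(row[[m]])
      if (file.exists(p)) p else file.path(base_dir, p)
    }, "")
    names(paths) <- mods
    clin <- list()
    for (cc in c("tss_minutes", "ttt_minutes", "tici_grade"))
      if (cc %in% names(row) && !is.na(row[[cc]])) clin[[cc]] <- row[[cc]]
    tryCatch(
      loadCase(paths, mrs = row$mrs, case_id = row$case_id, clinical = clin),
      error = function(e)
        stop("case '", row$case_id, "': ", conditionMessage(e), call. = FALSE))
  })
  strokeDataset(cases)
}

#' Write a StrokeDataset as NIfTI volumes plus a CSV manifest
#'
#' Produces the on-disk layout that [loadDataset()] reads back, so synthetic
#' data exercise the real I/O path.
#'
#' @param dataset a [StrokeDataset-class].
#' @param dir output directory (created if needed).
#' @param gzip write .nii.gz (default) or plain .nii.
#' @return Invisibly, the manifest path.
#' @export
writeDataset <- function(dataset, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  mods <- pmfesnModalities()
  rows <- lapply(cases(dataset), function(cs) {
    paths <- vapply(mods, function(m) {
      fn <- paste0(cs@caseId, "_", m, ext)
      RNifti::writeNifti(RNifti::asNifti(cs@volumes[[m]]), file.path(dir, fn))
      fn
    }, "")
    data.frame(case_id = cs@caseId,
               adc = paths["ADC"], mtt = paths["MTT"], ttp = paths["TTP"],
               tmax = paths["Tmax"], cbv = paths["CBV"], cbf = paths["CBF"],
               mrs = cs@mrs, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Write an evaluation report to disk
#'
#' Serializes the metrics (JSON) and the confusion matrix (CSV) side by side:
#' `<prefix>.json` and `<prefix>_confusion.csv`. The pair is human-diffable
#' and read back losslessly by [readReport()].
#'
#' @param report an [EvaluationReport-class].
#' @param prefix output path prefix (directories are created).
#' @return Invisibly, the JSON path.
#' @export
writeReport <- function(report, prefix) {
  validObject(report)
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  cm <- report@confusion
  utils::write.csv(as.data.frame(cm), paste0(prefix, "_confusion.csv"))
  payload <- list(
    per_class = report@perClass,
    macro = as.list(report@macro),
    mae_macro = report@maeMacro,
    mcc = report@mcc,
    folds = report@folds,
    scores = report@scores,
    classes = colnames(cm)
  )
  jsonlite::write_json(payload, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(paste0(prefix, ".json"))
}

#' Read an evaluation report written by [writeReport()]
#'
#' @param prefix the path prefix used when writing.
#' @return An [EvaluationReport-class]; round-trips written reports exactly.
#' @export
readReport <- function(prefix) {
  cmdf <- utils::read.csv(paste0(prefix, "_confusion.csv"),
                          row.names = 1L, check.names = FALSE)
  cm <- as.matrix(cmdf)
  storage.mode(cm) <- "integer"
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  per_class <- as.data.frame(js$per_class)
  per_class$class <- as.integer(per_class$class)
  folds <- as.data.frame(js$folds)
  if (nrow(folds)) {
    folds$true <- as.integer(folds$true)
    folds$pred <- as.integer(folds$pred)
    folds$tie <- as.logical(folds$tie)
  } else {
    folds <- emptyFoldsFrame()
  }
  scores <- js$scores
  if (is.null(dim(scores)))
    scores <- matrix(numeric(0), 0L, ncol(cm),
                     dimnames = list(NULL, colnames(cm)))
  else colnames(scores) <- colnames(cm)
  new("EvaluationReport", confusion = cm, perClass = per_class,
      macro = unlist(js$macro)[c("precision", "recall", "f1")],
      maeMacro = js$mae_macro, mcc = js$mcc, folds = folds, scores = scores)
}

emptyFoldsFrame <- function() {
  data.frame(case_id = character(0), true = integer(0), pred = integer(0),
             tie = logical(0), stringsAsFactors = FALSE)
}
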