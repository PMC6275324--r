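# Case data model, NIfTI I/O, dataset manifests and fold construction.
#
# All volumes of a case live on one pre-registered voxel grid (no world-space
# resampling is performed here); masks are stored as unsigned 8-bit NIfTI,
# parameter maps as 32-bit float. Axial slices are the third dimension.

#' Construct and validate a perfusion case
#'
#' @param case_id character identifier
#' @param cbv,ttd 3D arrays: cerebral blood volume and time-to-drain maps
#'   (arbitrary units)
#' @param core_mask,core_penumbra_mask,lesion_mask binary 3D arrays; the
#'   follow-up `lesion_mask` may be `NULL` at prediction time
#' @param t_onset_to_imaging,t_imaging_to_treatment times in hours, >= 0
#' @param geometry optional NIfTI geometry template (kept for round trips)
#' @return an object of class `perfusion_case`
#' @details Real clinical cases can violate the nesting
#'   `S_c <= S_l <= S_cp` (follow-up lesions are occasionally smaller than
#'   the admission core); such cases are kept and flagged via the
#'   `nesting_ok` field rather than rejected.
#' @export
perfusion_case <- function(case_id, cbv, ttd, core_mask, core_penumbra_mask,
                           lesion_mask = NULL, t_onset_to_imaging,
                           t_imaging_to_treatment, geometry = NULL) {
  vols <- list(cbv = cbv, ttd = ttd, core_mask = core_mask,
               core_penumbra_mask = core_penumbra_mask)
  if (!is.null(lesion_mask)) vols$lesion_mask <- lesion_mask
  d0 <- dim(cbv)
  if (length(d0) != 3L) stop("cbv must be a 3D array")
  for (nm in names(vols)) {
    if (!all(dim(vols[[nm]]) == d0))
      stop("volume '", nm, "' has extent ",
           paste(dim(vols[[nm]]), collapse = "x"),
           " but the case grid is ", paste(d0, collapse = "x"))
  }
  for (nm in c("core_mask", "core_penumbra_mask",
               if (!is.null(lesion_mask)) "lesion_mask")) {
    if (!all(vols[[nm]] %in% c(0, 1)))
      stop("mask '", nm, "' contains values outside {0,1}")
  }
  if (t_onset_to_imaging < 0 || t_imaging_to_treatment < 0)
    stop("times must be non-negative")
  nesting_ok <- all(core_mask <= core_penumbra_mask) &&
    (is.null(lesion_mask) ||
       (all(core_mask <= lesion_mask) && all(lesion_mask <= core_penumbra_mask)))
  if (!nesting_ok)
    message("case ", case_id,
            ": masks violate core <= lesion <= core+penumbra nesting; ",
            "kept and flagged")
  structure(list(case_id = as.character(case_id), cbv = cbv, ttd = ttd,
                 core_mask = core_mask,
                 core_penumbra_mask = core_penumbra_mask,
                 lesion_mask = lesion_mask,
                 t_onset_to_imaging = as.numeric(t_onset_to_imaging),
                 t_imaging_to_treatment = as.numeric(t_imaging_to_treatment),
                 geometry = geometry, nesting_ok = nesting_ok),
            class = "perfusion_case")
}

#' @export
print.perfusion_case <- function(x, ...) {
  cat("<perfusion_case>", x$case_id, "grid",
      paste(dim(x$cbv), collapse = "x"),
      sprintf("t_onset->imaging %.2fh t_imaging->treatment %.2fh",
              x$t_onset_to_imaging, x$t_imaging_to_treatment),
      if (!x$nesting_ok) "[nesting violated]" else "", "\n")
  invisible(x)
}

#' Read a case from NIfTI files
#'
#' Mask volumes stored as floats or label values (e.g. 0/255) are binarized
#' at > 0.5.
#'
#' @param paths named character vector/list with entries `cbv`, `ttd`,
#'   `core`, `core_penumbra`, and optionally `lesion`
#' @param times numeric length-2: onset-to-imaging and imaging-to-treatment
#'   hours
#' @param case_id identifier; defaults to the CBV file stem
#' @param require_lesion error when the follow-up lesion mask is missing
#'   (training needs it; prediction does not)
#' @return a [perfusion_case()]
#' @export
read_case <- function(paths, times, case_id = NULL, require_lesion = FALSE) {
  paths <- as.list(paths)
  need <- c("cbv", "ttd", "core", "core_penumbra")
  if (!all(need %in% names(paths)))
    stop("paths must name ", paste(need, collapse = ", "))
  has_lesion <- !is.null(paths$lesion) && !is.na(paths$lesion) &&
    nzchar(paths$lesion)
  if (require_lesion && !has_lesion)
    stop("missing follow-up lesion mask for case '", case_id,
         "' (required at training time)")
  rd <- function(p) RNifti::readNifti(p)
  cbv <- rd(paths$cbv)
  geometry <- cbv
  d0 <- dim(cbv)
  load_vol <- function(nm, binarize) {
    v <- rd(paths[[nm]])
    if (!all(dim(v)[1:3] == d0))
      stop("volume '", nm, "' (", paths[[nm]], ") has extent ",
           paste(dim(v), collapse = "x"), " but cbv is ",
           paste(d0, collapse = "x"))
    a <- array(as.numeric(v), dim = d0)
    if (binarize) a <- (a > 0.5) * 1
    a
  }
  perfusion_case(
    case_id = case_id %||% sub("\\.nii(\\.gz)?$", "", basename(paths$cbv)),
    cbv = array(as.numeric(cbv), dim = d0),
    ttd = load_vol("ttd", FALSE),
    core_mask = load_vol("core", TRUE),
    core_penumbra_mask = load_vol("core_penumbra", TRUE),
    lesion_mask = if (has_lesion) load_vol("lesion", TRUE),
    t_onset_to_imaging = times[[1]],
    t_imaging_to_treatment = times[[2]],
    geometry = geometry)
}

#' Write a volume to NIfTI
#'
#' @param volume 3D numeric array (finite values only)
#' @param path output file (`.nii` or `.nii.gz`)
#' @param reference optional NIfTI image or [perfusion_case()] whose
#'   affine/geometry is copied
#' @param datatype NIfTI storage type: `"float"` for maps/probabilities,
#'   `"uint8"` for binary masks
#' @return the path, invisibly
#' @export
write_volume <- function(volume, path, reference = NULL,
                         datatype = c("float", "uint8")) {
  datatype <- match.arg(datatype)
  if (!all(is.finite(volume)))
    stop("volume contains non-finite values and cannot be written")
  ref <- if (inherits(reference, "perfusion_case")) reference$geometry
         else reference
  img <- if (!is.null(ref)) RNifti::asNifti(array(volume, dim = dim(volume)),
                                            reference = ref)
         else RNifti::asNifti(array(volume, dim = dim(volume)))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write / read a dataset manifest
#'
#' A manifest is a flat CSV with one record per case: `case_id`, the five
#' volume paths (relative to the manifest directory) and the two times in
#' hours.
#'
#' @param manifest data frame with columns `case_id`, `cbv`, `ttd`, `core`,
#'   `core_penumbra`, `lesion`, `t_onset_to_imaging`, `t_imaging_to_treatment`
#' @param path CSV file path
#' @return the manifest data frame
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "cbv", "ttd", "core", "core_penumbra", "lesion",
            "t_onset_to_imaging", "t_imaging_to_treatment")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}

#' Load all cases listed in a manifest
#'
#' @param manifest a data frame from [read_manifest()]
#' @param dir directory volume paths are relative to (defaults to the
#'   manifest's own directory)
#' @param require_lesion passed to [read_case()]
#' @return list of [perfusion_case()] objects named by `case_id`
#' @export
load_cases <- function(manifest, dir = attr(manifest, "dir"),
                       require_lesion = FALSE) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    resolve <- function(p) if (is.na(p) || !nzchar(p)) p
                           else if (startsWith(p, "/")) p else file.path(dir, p)
    read_case(list(cbv = resolve(row$cbv), ttd = resolve(row$ttd),
                   core = resolve(row$core),
                   core_penumbra = resolve(row$core_penumbra),
                   lesion = resolve(row$lesion)),
              times = c(row$t_onset_to_imaging, row$t_imaging_to_treatment),
              case_id = row$case_id, require_lesion = require_lesion)
  })
  names(out) <- manifest$case_id
  out
}

#' Deterministic balanced k-fold assignment
#'
#' Cases are shuffled with the given seed (after sorting, so the assignment
#' is invariant to input order) and dealt round-robin; fold sizes differ by
#' at most one, e.g. 29 cases in 5 folds gives sizes 6,6,6,6,5.
#'
#' @param case_ids character vector of case identifiers
#' @param k number of folds (>= 2)
#' @param seed integer seed
#' @param validation_fraction fraction of each training split later held out
#'   for validation-based model selection
#' @return a `dataset_split` data frame with columns `case_id`, `fold`
#'   (0-based)
#' @export
make_folds <- function(case_ids, k, seed = 1L, validation_fraction = 0.25) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (anyDuplicated(case_ids)) stop("case_ids must be unique")
  if (length(case_ids) < k)
    stop("cannot build ", k, " folds from ", length(case_ids), " cases")
  ids <- sort(as.character(case_ids))
  set.seed(seed)
  ids <- sample(ids)
  out <- data.frame(case_id = ids,
                    fold = rep(seq_len(k) - 1L, length.out = length(ids)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$case_id), ]
  rownames(out) <- NULL
  attr(out, "validation_fraction") <- validation_fraction
  class(out) <- c("dataset_split", "data.frame")
  out
}
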