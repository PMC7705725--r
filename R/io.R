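# Readers/writers for the pipeline's interchange formats: NIfTI volumes,
# CSV landmark/curve/profile tables, JSON transforms and dendrograms,
# CSV LFP/speed traces, YAML run configs.

#' Read and write brain volumes as NIfTI
#'
#' Volumes are stored with isotropic pixdim equal to `voxel_pitch`; axis
#' order on disk matches the in-memory (AP, DV, ML) convention.
#'
#' @param volume A `brain_volume`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param subject_id Identifier attached on read.
#' @return `read_brain_volume`: a `brain_volume`.
#' @export
write_brain_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- rep(volume$voxel_pitch, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_brain_volume
#' @export
read_brain_volume <- function(path, subject_id = basename(path)) {
  img <- RNifti::readNifti(path)
  pitch <- RNifti::pixdim(img)[1]
  new_brain_volume(array(as.numeric(img), dim = dim(img)),
                   if (isTRUE(pitch > 0)) pitch else 1,
                   subject_id, "file")
}

#' Read and write landmark sets as CSV
#'
#' Columns: `name`, `ap`, `dv`, `ml`, `space`.
#'
#' @param landmarks A [landmark_set()].
#' @param path CSV file path.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = rownames(landmarks$points),
                   landmarks$points, space = landmarks$space)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  landmark_set(as.matrix(df[, c("ap", "dv", "ml")]), names = df$name,
               space = df$space[1])
}

#' Read and write rigid transforms as JSON
#'
#' Rotation stored row-major plus a translation vector.
#'
#' @param transform A `rigid_transform`.
#' @param path JSON file path.
#' @export
write_rigid_transform <- function(transform, path) {
  jsonlite::write_json(list(rotation = as.vector(t(transform$rotation)),
                            translation = transform$translation),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_rigid_transform
#' @export
read_rigid_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}

#' Write a similarity result as CSV tables
#'
#' Writes `sbar.csv` (averaged matrix with ids), `slices.csv` (slice
#' metadata) and `s_slices.csv` (long form: `i`, `j`, `slice`, `value`).
#'
#' @param result A [masked_slicewise_similarity()] result.
#' @param dir Output directory (created if needed).
#' @export
write_similarity <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(result$S_bar),
                   file.path(dir, "sbar.csv"), row.names = TRUE)
  utils::write.csv(result$slice_info, file.path(dir, "slices.csv"),
                   row.names = FALSE)
  n <- length(result$ids)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  long <- do.call(rbind, lapply(seq_len(dim(result$S_slices)[3]), function(e)
    data.frame(i = result$ids[pairs[, 1]], j = result$ids[pairs[, 2]],
               slice = e, value = result$S_slices[, , e][pairs])))
  utils::write.csv(long, file.path(dir, "s_slices.csv"), row.names = FALSE)
  invisible(dir)
}

# Newick serialization of the merge tree, heights as branch lengths.
dendrogram_to_newick <- function(dendrogram) {
  h <- dendrogram$height
  lab <- dendrogram$labels
  node <- function(code, parent_h) {
    if (code < 0)
      return(sprintf("%s:%g", lab[-code], parent_h))
    left <- node(dendrogram$merge[code, 1], h[code])
    right <- node(dendrogram$merge[code, 2], h[code])
    sprintf("(%s,%s):%g", left, right, max(parent_h - h[code], 0))
  }
  top <- nrow(dendrogram$merge)
  paste0("(", node(dendrogram$merge[top, 1], h[top]), ",",
         node(dendrogram$merge[top, 2], h[top]), ");")
}

#' Write a dendrogram as JSON (merge list) and Newick
#'
#' @param dendrogram A [linkage_single()] result.
#' @param path Output path without extension; writes `<path>.json` and
#'   `<path>.nwk`.
#' @export
write_dendrogram <- function(dendrogram, path) {
  jsonlite::write_json(list(merge = dendrogram$merge,
                            height = dendrogram$height,
                            labels = dendrogram$labels,
                            method = dendrogram$method),
                       paste0(path, ".json"), digits = NA)
  writeLines(dendrogram_to_newick(dendrogram), paste0(path, ".nwk"))
  invisible(path)
}

#' Write nearest-control profiles and group summaries as tidy CSV
#'
#' @param profile A [nearest_control_profile()] result.
#' @param dir Output directory.
#' @export
write_profiles <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(seq_along(profile$ids), function(s)
    data.frame(subject = profile$ids[s],
               slice = seq_len(ncol(profile$values)),
               ap = profile$slice_info$ap, side = profile$slice_info$side,
               value = profile$values[s, ])))
  utils::write.csv(long, file.path(dir, "profiles.csv"), row.names = FALSE)
  utils::write.csv(summarize_groups(profile),
                   file.path(dir, "profile_summary.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read and write LFP and speed traces as CSV
#'
#' LFP in wide form (`time`, `ch1`...`chN`); speed as (`time`, `speed`).
#'
#' @param lfp An `lfp_record`; `speed` a `speed_trace`.
#' @param path CSV file path.
#' @export
write_lfp_csv <- function(lfp, path) {
  df <- data.frame(time = (seq_len(ncol(lfp$data)) - 1) / lfp$fs,
                   t(lfp$data))
  names(df) <- c("time", paste0("ch", seq_len(nrow(lfp$data))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  df <- utils::read.csv(path)
  fs <- 1 / stats::median(diff(df$time))
  new_lfp_record(t(as.matrix(df[, -1, drop = FALSE])), round(fs))
}

#' @rdname write_lfp_csv
#' @param speed A `speed_trace`.
#' @export
write_speed_csv <- function(speed, path) {
  utils::write.csv(data.frame(time = (seq_along(speed$values) - 1) / speed$fs,
                              speed = speed$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_speed_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(values = df$speed,
                 fs = round(1 / stats::median(diff(df$time)))),
            class = "speed_trace")
}

#' Write a phase-offset matrix as CSV
#'
#' Writes the full matrix plus a tidy pair list (`ch_i`, `ch_j`,
#' `offset_rad`, `resultant`).
#'
#' @param offsets A [pairwise_theta_offsets()] result.
#' @param dir Output directory.
#' @export
write_offsets <- function(offsets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(offsets$offsets, file.path(dir, "offsets.csv"),
                   row.names = FALSE)
  n <- nrow(offsets$offsets)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  utils::write.csv(data.frame(ch_i = pairs[, 1], ch_j = pairs[, 2],
                              offset_rad = offsets$offsets[pairs],
                              resultant = offsets$resultant[pairs]),
                   file.path(dir, "offset_pairs.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a run configuration from YAML or JSON
#'
#' The file may override any [cohort_config()] argument under `cohort:` and
#' any top-level [run_config()] field.
#'
#' @param path YAML (or JSON) file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cohort_args <- raw$cohort %||% list()
  cohort <- do.call(cohort_config, cohort_args)
  extra <- raw[setdiff(names(raw), "cohort")]
  do.call(run_config, c(list(cohort = cohort), extra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
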