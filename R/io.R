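## File interfaces: PDB structures (via bio3d), feature/discrete trajectory
## CSV round-trips with JSON manifests, and model serialization.

#' Read a PDB file into structure frames
#'
#' Parses single- or multi-model PDB files (via bio3d) into a list of
#' [structure_frame()] objects. Both OP1/O1P and OP2/O2P phosphate-oxygen
#' spellings are accepted and preserved. Truncated ATOM/HETATM records raise
#' an error citing the offending line.
#'
#' @param path PDB file path.
#' @return List of [structure_frame()] objects, one per model.
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  short <- which(rec & nchar(lines) < 54)
  if (length(short)) {
    stop("truncated ATOM record at line ", short[1], " of ", path)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  elem <- ifelse(is.na(elem) | elem == "", substr(trimws(at$elety), 1, 1),
                 trimws(elem))
  n_models <- nrow(pdb$xyz)
  lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    structure_frame(data.frame(
      name = trimws(at$elety), elem = elem, resid = trimws(at$resid),
      resno = at$resno, chain = ifelse(is.na(at$chain), "A", at$chain),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), time = (m - 1))
  })
}

#' Write structure frames to a PDB file
#'
#' @param frames a [structure_frame()] or list of them (written as models).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frames, path) {
  if (inherits(frames, "StructureFrame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    if (length(frames) > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(fr))) {
      nm <- fr$name[i]
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      writeLines(sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, nm_fmt, substr(fr$resid[i], 1, 3), substr(fr$chain[i], 1, 1),
        fr$resno[i], fr$x[i], fr$y[i], fr$z[i], 1, 0, fr$elem[i]), con)
    }
    if (length(frames) > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write / read feature trajectories as CSV plus a JSON manifest
#'
#' One CSV per trajectory (header row of feature names) and one
#' `manifest.json` recording the frame stride, feature names and file list;
#' `read_features(write_features(x))` round-trips the data.
#'
#' @param ftrajs list of [feature_trajectory()] objects.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_features <- function(ftrajs, dir) {
  ftrajs <- as_traj_list(ftrajs, "FeatureTrajectory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(ftrajs))
  for (i in seq_along(ftrajs)) {
    id <- if (is.null(ftrajs[[i]]$id)) sprintf("traj%03d", i) else ftrajs[[i]]$id
    files[i] <- paste0(id, ".csv")
    utils::write.csv(as.data.frame(ftrajs[[i]]$data),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- list(kind = "features",
                   frame_stride_ns = ftrajs[[1]]$frame_stride,
                   feature_names = ftrajs[[1]]$feature_names,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' @rdname write_features
#' @export
read_features <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(manifest$files, function(f) {
    mat <- as.matrix(utils::read.csv(file.path(dir, f), check.names = FALSE))
    feature_trajectory(mat, frame_stride = manifest$frame_stride_ns,
                       feature_names = manifest$feature_names,
                       id = sub("\\.csv$", "", f))
  })
}

#' Write / read discrete trajectories (one integer per line) with a manifest
#'
#' @param dtrajs list of [discrete_trajectory()] objects.
#' @param dir output directory.
#' @return The manifest path, invisibly.
#' @export
write_dtrajs <- function(dtrajs, dir) {
  dtrajs <- as_traj_list(dtrajs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dtrajs))
  for (i in seq_along(dtrajs)) {
    id <- if (is.null(dtrajs[[i]]$id)) sprintf("traj%03d", i) else dtrajs[[i]]$id
    files[i] <- paste0(id, ".txt")
    writeLines(as.character(dtrajs[[i]]$labels), file.path(dir, files[i]))
  }
  manifest <- list(kind = "dtrajs",
                   frame_stride_ns = dtrajs[[1]]$frame_stride,
                   n_states = dtrajs[[1]]$n_states, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' @rdname write_dtrajs
#' @export
read_dtrajs <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(manifest$files, function(f) {
    discrete_trajectory(as.integer(readLines(file.path(dir, f))),
                        frame_stride = manifest$frame_stride_ns,
                        n_states = manifest$n_states,
                        id = sub("\\.txt$", "", f))
  })
}

#' Serialize / restore a transition model as JSON
#'
#' Matrices are stored row-major with dimensions; `read_model(write_model(m))`
#' reproduces the model to full double precision.
#'
#' @param model a `TransitionModel`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(class = "TransitionModel",
              counts = as.vector(t(model$counts)),
              tpm = as.vector(t(model$tpm)),
              n_states = nrow(model$tpm),
              pi = model$pi, eigenvalues = model$eigenvalues,
              lag_frames = model$lag_frames, lag_ns = model$lag_ns,
              state_map = model$state_map, reversible = model$reversible)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- obj$n_states
  structure(list(counts = matrix(obj$counts, k, k, byrow = TRUE),
                 tpm = matrix(obj$tpm, k, k, byrow = TRUE),
                 pi = obj$pi, eigenvalues = obj$eigenvalues,
                 lag_frames = obj$lag_frames, lag_ns = obj$lag_ns,
                 state_map = obj$state_map, reversible = obj$reversible),
            class = "TransitionModel")
}
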