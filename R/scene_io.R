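## Scene I/O.
##
## Canonical on-disk form is a long tabular CSV with header
## frame,agent,marker,x,y,z  (frame 0-based, coordinates in mm). A JSON
## manifest {scene_id, emotion, path} indexes multi-scene datasets. C3D is
## part of the format enum for completeness but no C3D reader library is
## available in this build, so it raises an informative error.

#' Read a dyadic scene from disk
#'
#' @param path file path.
#' @param format \code{"tabular"} (canonical long CSV) or \code{"c3d"}
#'   (unsupported in this build; errors).
#' @param fps sampling rate of the recording in Hz (the tabular dialect does
#'   not embed it); default 100.
#' @param emotion,scene_id optional labels attached to the scene (the
#'   manifest normally supplies them).
#' @param max_gap longest run of missing samples (frames) that is repaired
#'   by linear interpolation; longer gaps are errors. Default 5.
#' @param markers a \code{\link{marker_set}}; its alias table maps external
#'   marker labels onto the canonical 15.
#' @return A \code{\link{scene}}.
#' @export
read_scene <- function(path, format = c("tabular", "c3d"), fps = 100,
                       emotion = NA_character_, scene_id = NULL,
                       max_gap = 5, markers = marker_set()) {
  format <- match.arg(format)
  if (format == "c3d")
    stop_dyadkin(paste0("C3D input is not supported in this build (no C3D ",
                        "reader available); convert to the tabular dialect"))
  if (!file.exists(path)) stop_dyadkin("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "agent", "marker", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_dyadkin("tabular scene needs columns %s", paste(need, collapse = ","))
  agents_present <- sort(unique(df$agent))
  if (length(agents_present) != 2L)
    stop_dyadkin("agent count must be 2, file has %d agent id(s)",
                 length(agents_present))
  df$marker <- resolve_markers(as.character(df$marker), markers)
  frames <- sort(unique(df$frame))
  nf <- length(frames)
  frame_idx <- match(df$frame, frames)
  build_agent <- function(id) {
    sub <- df[df$agent == id, , drop = FALSE]
    labs <- unique(sub$marker)
    missing <- setdiff(markers$names, labs)
    if (length(missing))
      stop_dyadkin("agent %s: missing marker label(s): %s", id,
                   paste(missing, collapse = ", "))
    a <- array(NA_real_, c(nf, 15L, 3L),
               dimnames = list(NULL, markers$names, c("x", "y", "z")))
    fi <- frame_idx[df$agent == id]
    mi <- match(sub$marker, markers$names)
    a[cbind(fi, mi, 1L)] <- sub$x
    a[cbind(fi, mi, 2L)] <- sub$y
    a[cbind(fi, mi, 3L)] <- sub$z
    fill_gaps(a, max_gap = max_gap, agent = id)
  }
  a1 <- build_agent(agents_present[1])
  a2 <- build_agent(agents_present[2])
  scene(a1, a2, fps = fps, emotion = emotion,
        scene_id = scene_id %||% tools::file_path_sans_ext(basename(path)),
        markers = markers)
}

# Linear interpolation of interior missing-sample runs of length <= max_gap.
fill_gaps <- function(a, max_gap, agent = "?") {
  nf <- dim(a)[1]
  for (m in seq_len(dim(a)[2])) for (k in 1:3) {
    v <- a[, m, k]
    bad <- !is.finite(v)
    if (!any(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      glen <- r$lengths[j]
      interior <- starts[j] > 1L && ends[j] < nf
      if (glen > max_gap || !interior)
        stop_dyadkin(
          "agent %s, marker '%s': unrecoverable missing samples (gap of %d frame(s)%s, max_gap = %d)",
          agent, dimnames(a)[[2]][m], glen,
          if (interior) "" else " at series edge", max_gap)
    }
    ok <- which(!bad)
    a[, m, k] <- stats::approx(ok, v[ok], xout = seq_len(nf))$y
  }
  a
}

#' Write a scene in the canonical tabular dialect
#'
#' Round-trips through \code{\link{read_scene}} to within 1e-6 mm.
#'
#' @param sc a \code{dyad_scene}.
#' @param path output CSV path.
#' @export
write_scene <- function(sc, path) {
  validate_scene(sc)
  nf <- n_frames(sc)
  rows <- lapply(1:2, function(i) {
    a <- sc$agents[[i]]
    data.frame(frame = rep(seq_len(nf) - 1L, times = 15L),
               agent = i,
               marker = rep(sc$markers$names, each = nf),
               x = as.vector(a[, , 1]),
               y = as.vector(a[, , 2]),
               z = as.vector(a[, , 3]))
  })
  df <- do.call(rbind, rows)
  ## fixed-precision writer: 1e-4 mm resolution, well inside the 1e-6 contract
  ## would fail; use full precision via format with 15 significant digits
  df$x <- formatC(df$x, format = "g", digits = 15)
  df$y <- formatC(df$y, format = "g", digits = 15)
  df$z <- formatC(df$z, format = "g", digits = 15)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_dyadkin("cannot write scene to '%s'", path)
  invisible(path)
}

#' Write / read a dataset of scenes with a JSON manifest
#'
#' \code{write_dataset} writes one CSV per scene plus \code{manifest.json}
#' listing \code{scene_id}, \code{emotion} and relative \code{path};
#' \code{read_dataset} reads it back.
#'
#' @param scenes list of \code{dyad_scene}.
#' @param dir dataset directory (created if needed).
#' @param ... passed to \code{\link{read_scene}}.
#' @return \code{write_dataset}: the manifest path, invisibly.
#'   \code{read_dataset}: a list of scenes.
#' @export
write_dataset <- function(scenes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    scene_id = vapply(scenes, function(s) s$scene_id, character(1)),
    emotion = vapply(scenes, function(s) s$emotion, character(1)),
    path = paste0(vapply(scenes, function(s) s$scene_id, character(1)), ".csv"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$scene_id))
    stop_dyadkin("duplicate scene ids in dataset")
  for (i in seq_along(scenes))
    write_scene(scenes[[i]], file.path(dir, manifest$path[i]))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(mp)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, ...) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop_dyadkin("no manifest.json in '%s'", dir)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_scene(file.path(dir, manifest$path[i]),
               emotion = manifest$emotion[i],
               scene_id = manifest$scene_id[i], ...)
  })
}
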