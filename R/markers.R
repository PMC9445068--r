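## Marker-set vocabulary for the 15-marker point-light body model.

#' Canonical 15-marker set of a point-light agent
#'
#' The body model places one marker on the head, sternum and sacrum and one
#' on each shoulder, elbow, wrist, hip, knee and ankle. Feature extraction
#' uses the 13 anatomical landmarks (sternum and sacrum excluded); the six
#' left/right pairs drive the posture-symmetry feature.
#'
#' @param aliases optional named character vector mapping external labels
#'   (as found in a file) onto the canonical labels, e.g.
#'   \code{c(LSHO = "l_shoulder")}.
#' @return An object of class \code{marker_set}: a list with \code{names}
#'   (15 canonical labels), \code{anatomical_13}, \code{pairs} (6x2 matrix of
#'   left/right labels) and \code{aliases}.
#' @examples
#' ms <- marker_set()
#' length(ms$names)          # 15
#' length(ms$anatomical_13)  # 13
#' @export
marker_set <- function(aliases = NULL) {
  sides <- c("shoulder", "elbow", "wrist", "hip", "knee", "ankle")
  names15 <- c("head", "sternum", "sacrum",
               paste0("l_", sides), paste0("r_", sides))
  ## interleave for a stable anatomical reading order
  names15 <- c("head", "sternum", "sacrum",
               as.vector(rbind(paste0("l_", sides), paste0("r_", sides))))
  stopifnot(length(names15) == 15L, !anyDuplicated(names15))
  pairs <- cbind(left = paste0("l_", sides), right = paste0("r_", sides))
  rownames(pairs) <- sides
  anatomical <- setdiff(names15, c("sternum", "sacrum"))
  if (!is.null(aliases)) {
    stopifnot(is.character(aliases), !is.null(names(aliases)),
              all(aliases %in% names15))
  }
  structure(list(names = names15, anatomical_13 = anatomical,
                 pairs = pairs, aliases = aliases),
            class = "marker_set")
}

# Resolve external labels to canonical labels via the alias table.
resolve_markers <- function(labels, ms = marker_set()) {
  out <- labels
  if (!is.null(ms$aliases)) {
    hit <- labels %in% names(ms$aliases)
    out[hit] <- unname(ms$aliases[labels[hit]])
  }
  out
}
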