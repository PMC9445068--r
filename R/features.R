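## Scene-collection feature table.

#' Feature name constants
#'
#' @return Character vectors of the 8 intrapersonal, 12 interpersonal, or
#'   all 20 feature names.
#' @export
intrapersonal_features <- function() {
  c("VEL", "ACC", "VM", "VOL", "VOL_STD", "SM", "LA", "LC")
}

#' @rdname intrapersonal_features
#' @export
interpersonal_features <- function() {
  c("IPD", "IPD_STD", "PS", "IPO", "IPO_BAL",
    "DC_VEL", "DC_ACC", "DC_VOL", "DC_LC",
    "SYNC_VEL", "SYNC_ACC", "ME_BAL")
}

#' @rdname intrapersonal_features
#' @export
all_features <- function() c(intrapersonal_features(), interpersonal_features())

#' Extract the 20-feature table from a scene collection
#'
#' One row per scene with columns \code{scene_id}, \code{emotion} and the 20
#' named feature scalars.
#'
#' @param scenes list of \code{\link{scene}} objects.
#' @param cone_half_angle facing cone half-angle for the orientation
#'   features, degrees.
#' @return A data frame (48 x 22 for the default dataset).
#' @export
extract_features <- function(scenes, cone_half_angle = 45) {
  rows <- lapply(scenes, function(sc) {
    v <- c(reduce_intrapersonal(sc),
           reduce_interpersonal(sc, cone_half_angle))
    cbind(data.frame(scene_id = sc$scene_id, emotion = sc$emotion,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
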