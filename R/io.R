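# Plain-text serialisation of pipeline inputs and outputs: STL meshes are
# handled in mesh.R; pressure trials travel as a long CSV plus a JSON
# sidecar; variable tables and results as CSV.

#' Write a pressure trial to CSV + JSON sidecar
#'
#' Frames are stored long (frame, row, col, kpa; zero cells omitted); grid
#' shape, pitch, frame interval and markers go to `<prefix>.json`.
#'
#' @param seq A [pressure_sequence()].
#' @param prefix Output path prefix; writes `<prefix>.csv`, `<prefix>.json`.
#' @export
write_pressure_trial <- function(seq, prefix) {
  d <- dim(seq$frames)
  idx <- which(seq$frames != 0, arr.ind = TRUE)
  df <- data.frame(frame = idx[, 3], row = idx[, 1], col = idx[, 2],
                   kpa = seq$frames[idx])
  df <- df[order(df$frame, df$col, df$row), ]
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(nrow = d[1], ncol = d[2], nframes = d[3],
               pitch = seq$pitch, dt = seq$dt)
  if (!is.null(seq$markers))
    side$markers <- data.frame(marker = rownames(seq$markers),
                               x = seq$markers[, 1], y = seq$markers[, 2])
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a pressure trial written by [write_pressure_trial()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [pressure_sequence()].
#' @export
read_pressure_trial <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, ".csv"))
  frames <- array(0, c(side$nrow, side$ncol, side$nframes))
  frames[cbind(df$row, df$col, df$frame)] <- df$kpa
  markers <- NULL
  if (!is.null(side$markers)) {
    markers <- as.matrix(side$markers[, c("x", "y")])
    rownames(markers) <- side$markers$marker
  }
  pressure_sequence(frames, side$pitch, side$dt, markers)
}

#' Write the per-foot 84-variable vector as a long CSV
#'
#' One row per variable: name, value, units, flag for undefined entries.
#'
#' @param vars Named 84-vector from [foot_3d_variables()].
#' @param path Output CSV path.
#' @export
write_3d_variables <- function(vars, path) {
  nm <- names(vars)
  units <- ifelse(startsWith(nm, "Hg_"), "mm",
                  ifelse(startsWith(nm, "HgR_"), "ratio", "deg"))
  utils::write.csv(
    data.frame(variable = nm, value = as.numeric(vars), units = units,
               flag = ifelse(is.na(vars), "undefined", "")),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a region mask as a labelled CSV grid
#'
#' @param mask A [plantar_angle_masks()] result.
#' @param path Output CSV path.
#' @export
write_region_mask <- function(mask, path) {
  utils::write.table(mask$labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
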