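#' Feature trajectory container
#'
#' A feature trajectory is the pipeline's universal per-frame record: the
#' two hinge angles describing the protein's domain motion, the distance
#' between the ligand and the binding site, the minimum protein-ligand
#' heavy-atom distance, and the ligand centre-of-mass position in the
#' protein-aligned frame. Frames are evenly spaced in time.
#'
#' @param df data frame with columns `opening_deg`, `twisting_deg`,
#'   `site_distance_A`, `min_dist_A`, `lig_x`, `lig_y`, `lig_z`.
#' @param dt_ps frame spacing in picoseconds (default 20).
#' @return object of class `feature_trajectory` (a data frame with a
#'   `dt_ps` attribute).
#' @export
feature_trajectory <- function(df, dt_ps = 20) {
  req <- c("opening_deg", "twisting_deg", "site_distance_A", "min_dist_A",
           "lig_x", "lig_y", "lig_z")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("feature trajectory is missing columns: %s",
          paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req, drop = FALSE]
  if (nrow(df) > 0) {
    if (any(df$site_distance_A < 0) || any(df$min_dist_A < 0))
      stopf("distances must be nonnegative")
    bad <- abs(df$opening_deg) > 180 | abs(df$twisting_deg) > 180
    if (any(bad))
      stopf("angles must lie in (-180, 180]; offending frame %d",
            which(bad)[1])
  }
  attr(df, "dt_ps") <- dt_ps
  class(df) <- c("feature_trajectory", "data.frame")
  df
}

#' @export
print.feature_trajectory <- function(x, ...) {
  cat(sprintf("<feature_trajectory> %d frames, dt = %g ps\n",
              nrow(x), attr(x, "dt_ps")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Write / read a feature trajectory as tab-delimited text
#'
#' One frame per row, a header line naming the columns, and a leading
#' `frame` index column. The frame spacing is stored in a `# dt_ps=` comment
#' on the first line.
#'
#' @param traj a [feature_trajectory()].
#' @param path file path.
#' @export
write_feature_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_ps=%g", attr(traj, "dt_ps") %||% 20), con)
  df <- cbind(frame = seq_len(nrow(traj)), as.data.frame(traj))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_trajectory
#' @export
read_feature_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  dt <- 20
  if (grepl("^# dt_ps=", first))
    dt <- as.numeric(sub("^# dt_ps=", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  df$frame <- NULL
  feature_trajectory(df, dt_ps = dt)
}

#' Write / read integer label sequences as one-integer-per-line text
#' @param labels integer vector.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) as.integer(readLines(path))
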