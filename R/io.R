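# CSV dialects for the measurement modalities. Headers are part of the
# contract; readers fail with the offending file and column named.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("malformed CSV ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("CSV ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read and write the package's CSV formats
#'
#' Droplet footprint-area series are `time_min,area_um2`; polarized
#' fluorescence series are `time_min,I_par,I_perp`; sperm trajectories are
#' long-format `track_id,time_s,x_um,y_um`; survival panels are
#' `V0_nL,motility_30min_pct,motility_postthaw_pct,velocity_um_s`; simulated
#' droplet trajectories are written as
#' `time_min,S_um2,V_nL,C_mol_per_m3,eta_cP`.
#'
#' @param path File path.
#' @param df,tr Object to write.
#' @return Readers return data frames (`read_trajectories_csv` returns a
#'   list of per-track data frames); writers return the path invisibly.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
read_area_series <- function(path) {
  read_csv_checked(path, c("time_min", "area_um2"))
}

#' @rdname csv_io
#' @export
read_fp_series <- function(path) {
  read_csv_checked(path, c("time_min", "I_par", "I_perp"))
}

#' @rdname csv_io
#' @export
read_survival_records <- function(path) {
  read_csv_checked(path, c("V0_nL", "motility_30min_pct",
                           "motility_postthaw_pct", "velocity_um_s"))
}

#' @rdname csv_io
#' @export
read_trajectories_csv <- function(path) {
  df <- read_csv_checked(path, c("track_id", "time_s", "x_um", "y_um"))
  split(df[, c("track_id", "time_s", "x_um", "y_um")], df$track_id)
}

#' @rdname csv_io
#' @export
write_trajectories_csv <- function(tr, path) {
  df <- do.call(rbind, tr)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
write_droplet_trajectory <- function(tr, path) {
  stopifnot(inherits(tr, "droplet_trajectory"))
  out <- data.frame(time_min = tr$time_min, S_um2 = tr$S_um2,
                    V_nL = tr$V_nL, C_mol_per_m3 = tr$C_mol_m3,
                    eta_cP = tr$eta_cP)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
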