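# Trial serialization: a directory of tidy CSV files (time_s, channel,
# value) plus a JSON metadata sidecar.

tidy_csv <- function(time, mat, path) {
  df <- do.call(rbind, lapply(colnames(mat), function(ch)
    data.frame(time_s = time, channel = ch, value = signif(mat[, ch], 9))))
  utils::write.csv(df, path, row.names = FALSE)
}

untidy_csv <- function(path, key_map = NULL) {
  if (!file.exists(path)) stop("missing trial file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "channel", "value")
  if (!all(need %in% names(df)))
    stop("malformed trial file ", path, ": expected columns ",
         paste(need, collapse = ", "))
  if (!is.null(key_map)) {
    hit <- df$channel %in% names(key_map)
    df$channel[hit] <- key_map[df$channel[hit]]
  }
  channels <- unique(df$channel)
  time <- sort(unique(df$time_s))
  mat <- matrix(NA_real_, length(time), length(channels),
                dimnames = list(NULL, channels))
  for (ch in channels) {
    sub <- df[df$channel == ch, ]
    mat[match(sub$time_s, time), ch] <- sub$value
  }
  if (any(is.na(mat))) stop("malformed trial file ", path,
                            ": channels do not share the time base")
  list(time = time, mat = mat)
}

#' Write a gait trial to a directory of CSV files
#'
#' One tidy CSV (`time_s`, `channel`, `value`) per signal category
#' (`angles.csv`, `moments.csv`, `grf.csv`, `emg.csv`) plus a JSON sidecar
#' (`meta.json`) with the sampling rate, participant, condition, events
#' and gas data.  Values are serialized at 9 significant digits.
#'
#' @param trial a `gait_trial`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tidy_csv(trial$time, trial$joint_angles, file.path(dir, "angles.csv"))
  tidy_csv(trial$time, trial$joint_moments, file.path(dir, "moments.csv"))
  grf <- cbind(ipsi = trial$grf_ipsi, contra = trial$grf_contra)
  tidy_csv(trial$time, grf, file.path(dir, "grf.csv"))
  tidy_csv(trial$time, trial$emg, file.path(dir, "emg.csv"))
  meta <- list(fs = trial$fs, n_strides = trial$n_strides,
               samples_per_stride = trial$samples_per_stride,
               participant = unclass(trial$participant),
               condition = unclass(trial$condition),
               events = trial$events, gas = trial$gas)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a gait trial from a directory of CSV files
#'
#' Inverse of [write_trial()].  A key map (named character vector, file
#' channel name to package channel name) lets foreign channel labels be
#' ingested.
#'
#' @param dir trial directory.
#' @param key_map optional channel renaming map.
#' @return a `gait_trial`.
#' @export
read_trial <- function(dir, key_map = NULL) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing trial file: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ang <- untidy_csv(file.path(dir, "angles.csv"), key_map)
  mom <- untidy_csv(file.path(dir, "moments.csv"), key_map)
  grf <- untidy_csv(file.path(dir, "grf.csv"), key_map)
  emg <- untidy_csv(file.path(dir, "emg.csv"), key_map)
  need_ang <- c("hip", "knee", "ankle")
  if (!all(need_ang %in% colnames(ang$mat)))
    stop("angles.csv is missing joints: ",
         paste(setdiff(need_ang, colnames(ang$mat)), collapse = ", "))
  miss_emg <- setdiff(emg_channels(), colnames(emg$mat))
  if (length(miss_emg) > 0)
    stop("emg.csv is missing muscle channels: ",
         paste(miss_emg, collapse = ", "))
  participant <- do.call(participant_spec, c(
    meta$participant[c("id", "body_mass", "stride_period",
                       "stance_fraction")],
    list(template_scales = unlist(meta$participant$template_scales),
         mvc = unlist(meta$participant$mvc))))
  condition <- condition_spec(meta$condition$grade_deg,
                              meta$condition$shoe_deg,
                              meta$condition$speed)
  out <- list(fs = meta$fs, time = ang$time,
              joint_angles = ang$mat[, need_ang],
              joint_moments = mom$mat[, need_ang],
              grf_ipsi = grf$mat[, "ipsi"], grf_contra = grf$mat[, "contra"],
              emg = emg$mat[, emg_channels()],
              condition = condition, participant = participant,
              n_strides = meta$n_strides,
              samples_per_stride = meta$samples_per_stride,
              events = lapply(meta$events, as.integer),
              gas = meta$gas)
  class(out) <- "gait_trial"
  out
}
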