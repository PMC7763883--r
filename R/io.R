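#' Write / read an ECG record as CSV
#'
#' Columns `time_s`, `voltage_mV`. Metadata and the sampling rate travel in
#' `#`-prefixed header comment lines so a round trip is lossless.
#'
#' @param rec an [ecg_record()].
#' @param path output file.
#' @export
write_record_csv <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rs=%g subject=%s state=%s session=%s",
                     rec$rs, rec$subject, rec$state, rec$session), con)
  tt <- (seq_along(rec$samples) - 1) / rec$rs
  utils::write.csv(data.frame(time_s = tt, voltage_mV = rec$samples),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record_csv
#' @param path input file written by [write_record_csv()].
#' @return `read_record_csv`: an [ecg_record()] (without ground truth).
#' @export
read_record_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- c(rs = NA, subject = NA, state = NA, session = NA)
  if (startsWith(hdr, "#")) {
    kv <- strsplit(trimws(sub("^#", "", hdr)), " ")[[1]]
    for (pair in strsplit(kv, "=")) meta[pair[1]] <- pair[2]
  }
  d <- utils::read.csv(path, comment.char = "#")
  rs <- as.numeric(meta[["rs"]])
  if (is.na(rs)) {
    dt <- diff(d$time_s[1:2])
    rs <- 1 / dt
  }
  ecg_record(d$voltage_mV, rs, subject = meta[["subject"]],
             state = meta[["state"]],
             session = suppressWarnings(as.integer(meta[["session"]])))
}

#' Write R-peak annotations as CSV
#'
#' Columns `sample_index` (0-based) and `label` (always `"R"`).
#'
#' @param ann an [r_peak_annotation()].
#' @param path output file.
#' @export
write_annotation_csv <- function(ann, path) {
  stopifnot(inherits(ann, "r_peak_annotation"))
  utils::write.csv(data.frame(sample_index = ann$indices - 1L, label = "R"),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write per-cycle fiducials as CSV
#'
#' One row per accepted cycle with 0-based sample indices (within the
#' fixed-window segment) of Pls, P peak, Rls, R, Rrs, T peak and Trs. P and
#' QRS sections are half-open (`[Pls, Rls)`, `[Rls, Rrs)`); the T section is
#' closed at Trs.
#'
#' @param fiducials list of `fiducial_set` objects.
#' @param path output file.
#' @export
write_fiducials_csv <- function(fiducials, path) {
  rows <- lapply(seq_along(fiducials), function(i) {
    f <- fiducials[[i]]
    data.frame(cycle_id = i, Pls = f$pls - 1L, Ppeak = f$p_peak - 1L,
               Rls = f$rls - 1L, R = f$r_peak - 1L, Rrs = f$rrs - 1L,
               Tpeak = f$t_peak - 1L, Trs = f$trs - 1L)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a normalized cycle matrix as CSV with a JSON sidecar
#'
#' One row per cycle with leading `subject`, `state`, `session`, `cycle`
#' columns followed by the samples. The sidecar (`<path>.json`) records the
#' normalization mode, sampling rate and band (requires the jsonlite
#' package).
#'
#' @param set a [cycle_set()].
#' @param path output CSV path.
#' @param spec optional [normalization_spec()] recorded in the sidecar.
#' @export
write_cycles_csv <- function(set, path, spec = NULL) {
  stopifnot(inherits(set, "cycle_set"))
  d <- cbind(set$meta, as.data.frame(set$cycles))
  utils::write.csv(d, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(mode = set$mode, rs = set$rs,
                 n_cycles = nrow(set$cycles), cycle_length = ncol(set$cycles))
    if (!is.null(spec))
      side <- c(side, list(tn_p = spec$tn_p, tn_t = spec$tn_t,
                           band = spec$band))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
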