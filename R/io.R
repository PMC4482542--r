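#' Write a trial series table to CSV
#'
#' Tidy per-trial format with header
#' `subject_id,t,phase,probe,value`; `phase` is `training`/`retention`,
#' `probe` is `zEC`, `vEC` or empty.
#'
#' @param series A `trial_series` data frame (or a `decay_cohort`, which is
#'   converted first).
#' @param path Output file path.
#' @export
write_trial_series <- function(series, path) {
  if (inherits(series, "decay_cohort")) series <- as.data.frame(series)
  stopifnot(all(c("subject_id", "t", "phase", "probe", "value") %in%
                  names(series)))
  utils::write.csv(series[, c("subject_id", "t", "phase", "probe", "value")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial series table from CSV
#' @param path CSV path as written by [write_trial_series()].
#' @return A `trial_series` data frame.
#' @export
read_trial_series <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character",
                                        t = "integer", phase = "character",
                                        probe = "character",
                                        value = "numeric"))
  out$probe[!nzchar(out$probe) | is.na(out$probe)] <- NA_character_
  class(out) <- c("trial_series", "data.frame")
  out
}

#' Write a population or drift specification as YAML
#' @param spec A [population_spec()] or [drift_generative_spec()].
#' @param path Output YAML path.
#' @export
write_spec_yaml <- function(spec, path) {
  cls <- class(spec)[1L]
  yaml::write_yaml(c(list(spec_class = cls), unclass(spec)), path)
  invisible(path)
}

#' Read a specification written by [write_spec_yaml()]
#' @param path YAML path.
#' @return The reconstructed spec object.
#' @export
read_spec_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cls <- raw$spec_class
  raw$spec_class <- NULL
  ctor <- switch(cls,
                 population_spec = population_spec,
                 drift_generative_spec = drift_generative_spec,
                 arma_spec = arma_spec,
                 stop("unknown spec class: ", cls))
  do.call(ctor, raw[names(raw) %in% names(formals(ctor))])
}

#' Write a vEC sequence (CSV of degrees + YAML sidecar)
#'
#' The sequence itself is a single-column CSV of clamp directions in
#' degrees; generation settings and acceptance bookkeeping go to
#' `<path>.yaml`.
#'
#' @param seq A `vec_sequence`.
#' @param path CSV output path.
#' @export
write_vec_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "vec_sequence"))
  utils::write.csv(data.frame(angle_deg = seq$angles), path,
                   row.names = FALSE)
  yaml::write_yaml(list(sd_target = seq$sd_target,
                        accepted = seq$accepted,
                        attempts = seq$attempts,
                        criteria = unclass(seq$criteria)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a vEC sequence written by [write_vec_sequence()]
#' @param path CSV path.
#' @return A `vec_sequence`.
#' @export
read_vec_sequence <- function(path) {
  angles <- utils::read.csv(path)$angle_deg
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  criteria <- if (!is.null(meta$criteria))
    do.call(rejection_criteria, meta$criteria) else rejection_criteria()
  structure(list(angles = angles,
                 sd_target = meta$sd_target %||% NA_real_,
                 pattern = binary_error_pattern(angles, criteria),
                 accepted = meta$accepted %||% NA,
                 attempts = meta$attempts %||% NA_integer_,
                 criteria = criteria),
            class = "vec_sequence")
}
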