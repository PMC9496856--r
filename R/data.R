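## Longitudinal containers: a trajectory is one subject's visit series with
## optional latent paths and per-interval impact records; a pe_data object
## is a validated collection of trajectories sharing a covariate dimension.

#' Construct a single-subject trajectory
#'
#' @param subject_id Identifier (coerced to character).
#' @param times Strictly increasing numeric visit times t0..tn.
#' @param y Observed scores aligned with \code{times}.
#' @param z Optional covariate matrix, one row per visit.
#' @param latent Optional data frame with columns \code{d} (non-negative,
#'   non-decreasing) and \code{m}, one row per visit.
#' @param impacts Optional data frame with columns \code{n_neg}, \code{n_pos},
#'   \code{delta_neg}, \code{delta_pos}, one row per interval (so
#'   \code{length(times) - 1} rows).
#' @return A list of class \code{"pe_trajectory"}.
#' @export
pe_trajectory <- function(subject_id, times, y, z = NULL, latent = NULL,
                          impacts = NULL) {
  times <- as.numeric(times)
  y <- as.numeric(y)
  n1 <- length(times)
  if (n1 < 1L) stop("trajectory needs at least one visit")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(y) != n1) stop("y and times must have equal length")
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (nrow(z) != n1) stop("z must have one row per visit")
    storage.mode(z) <- "double"
  }
  if (!is.null(latent)) {
    latent <- as.data.frame(latent)
    if (!all(c("d", "m") %in% names(latent)) || nrow(latent) != n1)
      stop("latent must have columns d, m with one row per visit")
    if (any(latent$d < 0)) stop("latent degradation d must be non-negative")
    if (any(diff(latent$d) < 0)) stop("latent degradation d must be non-decreasing")
  }
  if (!is.null(impacts)) {
    impacts <- as.data.frame(impacts)
    need <- c("n_neg", "n_pos", "delta_neg", "delta_pos")
    if (!all(need %in% names(impacts)) || nrow(impacts) != n1 - 1L)
      stop("impacts must have columns n_neg, n_pos, delta_neg, delta_pos, one row per interval")
    if (any(impacts$delta_neg < 0) || any(impacts$delta_pos < 0))
      stop("cumulative impacts must be non-negative")
    if (any(impacts$delta_neg[impacts$n_neg == 0] != 0) ||
        any(impacts$delta_pos[impacts$n_pos == 0] != 0))
      stop("cumulative impact must be zero when the impact count is zero")
  }
  structure(list(subject_id = as.character(subject_id), times = times, y = y,
                 z = z, latent = latent, impacts = impacts),
            class = "pe_trajectory")
}

#' Bundle trajectories into a dataset
#'
#' @param trajectories List of [pe_trajectory()] objects.
#' @param preset Optional [pe_setting()] the data were generated from.
#' @param seed Optional integer seed the data were generated with.
#' @return A list of class \code{"pe_data"}.
#' @export
pe_data <- function(trajectories, preset = NULL, seed = NULL) {
  if (!length(trajectories)) stop("dataset must contain at least one trajectory")
  if (!all(vapply(trajectories, inherits, logical(1), "pe_trajectory")))
    stop("trajectories must be pe_trajectory objects")
  p <- unique(vapply(trajectories,
                     function(tr) if (is.null(tr$z)) 0L else ncol(tr$z),
                     integer(1)))
  if (length(p) != 1L)
    stop("all trajectories must share the covariate dimension")
  ids <- vapply(trajectories, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicated subject ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(trajectories = trajectories, preset = preset, seed = seed),
            class = "pe_data")
}

#' @export
length.pe_data <- function(x) length(x$trajectories)

#' @export
print.pe_data <- function(x, ...) {
  ns <- vapply(x$trajectories, function(tr) length(tr$times), integer(1))
  cat(sprintf("Longitudinal dataset: %d subjects, %d observations (%s visits/subject)\n",
              length(x$trajectories), sum(ns),
              if (min(ns) == max(ns)) min(ns) else paste0(min(ns), "-", max(ns))))
  if (!is.null(x$preset))
    cat(sprintf("  generated from synthetic setting %d (seed %s)\n",
                x$preset$setting_id, format(x$seed)))
  has <- c(latent = any(vapply(x$trajectories, function(t) !is.null(t$latent), logical(1))),
           impacts = any(vapply(x$trajectories, function(t) !is.null(t$impacts), logical(1))))
  if (any(has)) cat("  carries:", paste(names(has)[has], collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a dataset to a long table
#'
#' One row per (subject, visit); covariates become columns \code{z_1..z_p};
#' per-interval impact records are aligned to the interval's right endpoint
#' (so they are \code{NA} on each subject's first row).
#'
#' @param x A [pe_data()] object.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data frame.
#' @export
as.data.frame.pe_data <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- lapply(x$trajectories, function(tr) {
    df <- data.frame(subject_id = tr$subject_id, time = tr$times, y = tr$y,
                     stringsAsFactors = FALSE)
    if (!is.null(tr$z))
      for (j in seq_len(ncol(tr$z))) df[[paste0("z_", j)]] <- tr$z[, j]
    if (!is.null(tr$impacts)) {
      for (nm in c("n_neg", "n_pos", "delta_neg", "delta_pos"))
        df[[nm]] <- c(NA, tr$impacts[[nm]])
    }
    df
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## full-precision numeric formatting so CSV round-trips are lossless
.fmt_num <- function(x) {
  s <- vapply(x, function(v) if (is.na(v)) NA_character_ else sprintf("%.17g", v),
              character(1))
  s
}

.write_csv17 <- function(df, path) {
  out <- df
  for (nm in names(out)) if (is.numeric(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write a dataset as longitudinal CSV
#'
#' Comma-separated, UTF-8, header row, full float precision. Optionally
#' writes a latent-state sidecar table (one row per visit with the latent
#' degradation/emotion path and the per-interval impact record) used for
#' testing and display.
#'
#' @param data A [pe_data()] object.
#' @param path Output CSV path.
#' @param latent_path Optional path for the latent sidecar CSV.
#' @return \code{data}, invisibly.
#' @export
write_longitudinal <- function(data, path, latent_path = NULL) {
  stopifnot(inherits(data, "pe_data"))
  .write_csv17(as.data.frame(data), path)
  if (!is.null(latent_path)) {
    side <- lapply(data$trajectories, function(tr) {
      if (is.null(tr$latent)) return(NULL)
      df <- data.frame(subject_id = tr$subject_id, time = tr$times,
                       d = tr$latent$d, m = tr$latent$m,
                       stringsAsFactors = FALSE)
      if (!is.null(tr$impacts))
        for (nm in c("n_pos", "n_neg", "delta_pos", "delta_neg"))
          df[[nm]] <- c(NA, tr$impacts[[nm]])
      df
    })
    side <- do.call(rbind, c(side, list(make.row.names = FALSE)))
    if (!is.null(side)) .write_csv17(side, latent_path)
  }
  invisible(data)
}

#' Read a longitudinal CSV into a dataset
#'
#' Expects a header row naming at least \code{subject_id}, \code{time},
#' \code{y}; optional covariate columns \code{z_1..z_p} and per-interval
#' impact columns \code{n_neg}, \code{n_pos}, \code{delta_neg},
#' \code{delta_pos} (empty on each subject's first row). Rows are sorted by
#' time within subject; duplicate (subject, time) pairs are an error.
#'
#' @param path CSV path.
#' @return A [pe_data()] object.
#' @export
read_longitudinal <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time", "y")
  if (!all(need %in% names(df)))
    stop("missing required columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  for (nm in setdiff(names(df), "subject_id")) {
    v <- df[[nm]]
    if (is.character(v)) {
      suppress <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      bad <- which(!is.na(v) & v != "" & is.na(suppress))
      if (length(bad))
        stop("non-numeric value in column '", nm, "' at row ",
             paste(bad, collapse = ", "))
      df[[nm]] <- suppress
    }
  }
  dup <- duplicated(df[c("subject_id", "time")])
  if (any(dup))
    stop("duplicated (subject_id, time) pairs: ",
         paste(unique(paste0(df$subject_id[dup], "@", df$time[dup])), collapse = ", "))
  zcols <- grep("^z_[0-9]+$", names(df), value = TRUE)
  zcols <- zcols[order(as.integer(sub("^z_", "", zcols)))]
  icols <- c("n_neg", "n_pos", "delta_neg", "delta_pos")
  has_imp <- all(icols %in% names(df))
  trs <- lapply(split(df, df$subject_id), function(sub) {
    sub <- sub[order(sub$time), , drop = FALSE]
    z <- if (length(zcols)) as.matrix(sub[zcols]) else NULL
    impacts <- NULL
    if (has_imp && nrow(sub) > 1L) {
      imp <- sub[-1L, icols, drop = FALSE]
      if (!anyNA(imp)) impacts <- imp
    }
    pe_trajectory(sub$subject_id[1L], sub$time, sub$y, z = z, impacts = impacts)
  })
  names(trs) <- NULL
  pe_data(trs)
}

#' Clamp scores to the instrument range
#'
#' Post-hoc clamping of emitted scores to a bounded instrument range such as
#' the 0-30 MMSE scale. Off by default in the simulator: the observation
#' model is an unbounded Gaussian and inference assumes it; clamping exists
#' for display-realistic fixtures only.
#'
#' @param y Numeric scores.
#' @param lo,hi Range bounds, \code{lo < hi}.
#' @return Clamped scores.
#' @examples
#' clip_score(c(-2, 15, 31.2)) # 0 15 30
#' @export
clip_score <- function(y, lo = 0, hi = 30) {
  if (lo >= hi) stop("lo must be below hi")
  pmin(pmax(y, lo), hi)
}
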