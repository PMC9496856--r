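## Base-graphics diagnostics: trace and density panels for fits, trajectory
## panels with impact shading for datasets, prediction-band panels for
## forecasts. Purely presentational.

#' @export
plot.pe_fit <- function(x, type = c("trace", "density"), pars = NULL, ...) {
  type <- match.arg(type)
  draws <- x$draws
  if (is.null(pars)) pars <- colnames(draws[[1]])
  nc <- ceiling(sqrt(length(pars)))
  nr <- ceiling(length(pars) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(3, 3, 2, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(length(draws), "Dark 3")
  for (p in pars) {
    if (type == "trace") {
      m <- sapply(draws, function(ch) as.numeric(ch[, p]))
      graphics::matplot(m, type = "l", lty = 1, col = cols, xlab = "iteration",
                        ylab = p, main = p, ...)
    } else {
      dens <- lapply(draws, function(ch) stats::density(as.numeric(ch[, p])))
      xl <- range(sapply(dens, function(d) range(d$x)))
      yl <- c(0, max(sapply(dens, function(d) max(d$y))))
      graphics::plot(NA, xlim = xl, ylim = yl, xlab = p, ylab = "density",
                     main = p, ...)
      for (k in seq_along(dens)) graphics::lines(dens[[k]], col = cols[k])
    }
  }
  invisible(x)
}

#' @export
plot.pe_data <- function(x, subjects = seq_len(min(4L, length(x$trajectories))),
                         show_impacts = TRUE, show_latent = TRUE, ...) {
  trs <- x$trajectories[subjects]
  nc <- ceiling(sqrt(length(trs)))
  nr <- ceiling(length(trs) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(3, 3, 2, 3), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  for (tr in trs) {
    graphics::plot(tr$times, tr$y, type = "b", pch = 16, xlab = "time",
                   ylab = "score", main = tr$subject_id, ...)
    if (show_impacts && !is.null(tr$impacts)) {
      usr <- graphics::par("usr")
      for (j in seq_len(nrow(tr$impacts))) {
        net <- tr$impacts$delta_pos[j] - tr$impacts$delta_neg[j]
        if (net == 0) next
        graphics::rect(tr$times[j], usr[3], tr$times[j + 1L], usr[4],
                       col = grDevices::adjustcolor(
                         if (net > 0) "pink" else "lightblue", 0.4),
                       border = NA)
      }
      graphics::points(tr$times, tr$y, type = "b", pch = 16)
    }
    if (show_latent && !is.null(tr$latent)) {
      sc <- max(tr$latent$d, 1)
      graphics::lines(tr$times, tr$latent$d / sc * diff(range(tr$y)) + min(tr$y),
                      col = "blue", lty = 2)
      graphics::axis(4, col.axis = "blue",
                     at = pretty(range(tr$y)),
                     labels = signif((pretty(range(tr$y)) - min(tr$y)) /
                                       diff(range(tr$y)) * sc, 2))
      graphics::mtext("latent D", side = 4, line = 2, col = "blue", cex = 0.7)
    }
  }
  invisible(x)
}

#' @export
plot.pe_forecasts <- function(x, data = NULL,
                              subjects = unique(x$subject_id), ...) {
  subjects <- subjects[subjects %in% x$subject_id]
  nc <- ceiling(sqrt(length(subjects)))
  nr <- ceiling(length(subjects) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(3, 3, 2, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  ids <- if (!is.null(data))
    vapply(data$trajectories, `[[`, character(1), "subject_id") else character(0)
  for (sid in subjects) {
    fx <- x[x$subject_id == sid, , drop = FALSE]
    yl <- range(fx$q05, fx$q95)
    tr <- NULL
    if (!is.null(data) && sid %in% ids) {
      tr <- data$trajectories[[match(sid, ids)]]
      yl <- range(yl, tr$y)
    }
    graphics::plot(NA, xlim = range(fx$target_time, if (!is.null(tr)) tr$times),
                   ylim = yl, xlab = "time", ylab = "score", main = sid, ...)
    graphics::polygon(c(fx$target_time, rev(fx$target_time)),
                      c(fx$q05, rev(fx$q95)),
                      col = grDevices::adjustcolor("red", 0.25), border = NA)
    graphics::lines(fx$target_time, fx$predictive_mean, col = "red", type = "b",
                    pch = 1)
    if (!is.null(tr)) graphics::lines(tr$times, tr$y, type = "b", pch = 16)
  }
  invisible(x)
}

#' Write diagnostic plots to image files
#'
#' Dispatches on the object class: a fit yields per-parameter trace and
#' density panels, a dataset yields trajectory panels with impact shading
#' and the latent degradation overlay, forecasts yield prediction-band
#' panels.
#'
#' @param x A [pe_fit()], [pe_data()] or \code{"pe_forecasts"} object.
#' @param path Output PNG path; for fits, a \code{_trace}/\code{_density}
#'   pair derived from it.
#' @param data Observed data to overlay on forecast plots.
#' @param width,height Device size in pixels.
#' @return Character vector of files written, invisibly.
#' @export
pe_plot_diagnostics <- function(x, path, data = NULL, width = 1200,
                                height = 900) {
  if ((is.data.frame(x) && nrow(x) == 0) ||
      (inherits(x, "pe_data") && !length(x$trajectories))) {
    warning("empty input: no plots written")
    return(invisible(character(0)))
  }
  files <- character(0)
  dev <- function(f) grDevices::png(f, width = width, height = height)
  if (inherits(x, "pe_fit")) {
    f1 <- sub("(\\.[a-zA-Z]+)?$", "_trace.png", path)
    f2 <- sub("(\\.[a-zA-Z]+)?$", "_density.png", path)
    dev(f1); plot(x, type = "trace"); grDevices::dev.off()
    dev(f2); plot(x, type = "density"); grDevices::dev.off()
    files <- c(f1, f2)
  } else if (inherits(x, "pe_forecasts")) {
    dev(path); plot(x, data = data); grDevices::dev.off()
    files <- path
  } else if (inherits(x, "pe_data")) {
    dev(path); plot(x); grDevices::dev.off()
    files <- path
  } else stop("no diagnostic plot defined for this object")
  invisible(files)
}
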