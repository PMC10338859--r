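#' Equilibrium response of an association trace
#'
#' Estimates the equilibrium (plateau) response Req of one association
#' trace as the mean response over the final `tail_fraction` of time points.
#' The tail is checked for plateau: when the fitted tail slope exceeds 1% of
#' Req per 10% of trace duration (relative), the trace is flagged
#' non-plateau and Req is instead taken as the asymptote R_inf of a
#' single-exponential fit R(t) = R_inf (1 - exp(-k t)).
#'
#' @param trace data.frame with `time_s` and `response` for a single
#'   concentration (and replicate).
#' @param tail_fraction fraction of the time points used as tail.
#' @param slope_tolerance relative plateau tolerance (default 0.01 = 1% of
#'   Req per 10% of trace duration).
#' @return list: `req`, `non_plateau` (flag), `tail_points`.
#' @export
equilibrium_response <- function(trace, tail_fraction = 0.1,
                                 slope_tolerance = 0.01) {
  stopifnot(all(c("time_s", "response") %in% names(trace)))
  trace <- trace[order(trace$time_s), , drop = FALSE]
  n <- nrow(trace)
  n_tail <- max(5L, ceiling(tail_fraction * n))
  if (n < 5L || n_tail > n) stop("fewer than 5 tail points")
  tl <- trace[(n - n_tail + 1L):n, , drop = FALSE]
  req <- mean(tl$response)
  if (req == 0 && all(trace$response == 0)) {
    return(list(req = 0, non_plateau = FALSE, tail_points = n_tail))
  }
  duration <- max(trace$time_s) - min(trace$time_s)
  slope <- unname(stats::coef(stats::lm(response ~ time_s, data = tl))[2])
  ## response change per 10% of trace duration, relative to Req
  drift <- abs(slope) * 0.1 * duration / max(abs(req), .Machine$double.eps)
  non_plateau <- drift > slope_tolerance
  if (non_plateau) {
    fit <- minpack.lm::nlsLM(
      response ~ rinf * (1 - exp(-k * time_s)), data = trace,
      start = list(rinf = max(trace$response),
                   k = 2 / max(max(trace$time_s), 1)),
      lower = c(0, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    req <- unname(stats::coef(fit)[["rinf"]])
  }
  list(req = req, non_plateau = non_plateau, tail_points = n_tail)
}

#' Per-concentration equilibrium responses of a trace set
#'
#' Applies [equilibrium_response()] to each (replicate, concentration)
#' trace of a BLI dataset.
#'
#' @param traces data.frame with replicate, concentration_M, time_s,
#'   response (e.g. from [simulate_bli_dataset()] or [read_bli_csv()]).
#' @param ... passed to [equilibrium_response()].
#' @return data.frame: replicate, concentration_M, req, non_plateau.
#' @export
equilibrium_points <- function(traces, ...) {
  keys <- unique(traces[c("replicate", "concentration_M")])
  keys <- keys[order(keys$replicate, keys$concentration_M), , drop = FALSE]
  res <- lapply(seq_len(nrow(keys)), function(i) {
    tr <- traces[traces$replicate == keys$replicate[i] &
                   traces$concentration_M == keys$concentration_M[i], ]
    er <- equilibrium_response(tr, ...)
    data.frame(replicate = keys$replicate[i],
               concentration_M = keys$concentration_M[i],
               req = er$req, non_plateau = er$non_plateau)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fit a 1:1 equilibrium binding isotherm
#'
#' Nonlinear least-squares fit of the Langmuir 1:1 isotherm
#' \deqn{R_{eq}(C) = R_{max}\, C / (C + K_d)} to (concentration, Req)
#' points. Initialisation: Rmax0 = max(Req), Kd0 = concentration at
#' half-maximal response (linearly interpolated). A fit is flagged
#' low-confidence when the data do not constrain it: the isotherm is not
#' sampled past half-saturation (max Req < 0.5 * fitted Rmax), the responses
#' carry no curvature (fully saturated ladder), or the Kd standard error
#' exceeds the estimate.
#'
#' @param points data.frame with `concentration_M` and `req` (>= 3 distinct
#'   concentrations).
#' @return list of class `equilibrium_fit`: `kd`, `rmax`, `kd_se`,
#'   `rmax_se`, `rss`, `low_confidence`, `points` (with fitted and
#'   normalised responses), `fit` (the `nls` object or `NULL`).
#' @export
fit_equilibrium_kd <- function(points) {
  stopifnot(all(c("concentration_M", "req") %in% names(points)))
  pts <- points[order(points$concentration_M), , drop = FALSE]
  if (length(unique(pts$concentration_M)) < 3) {
    stop("need >= 3 distinct concentrations")
  }
  rmax0 <- max(pts$req)
  saturated <- rmax0 > 0 &&
    (max(pts$req) - min(pts$req)) / rmax0 < 1e-6
  ## interpolated concentration at half-max
  kd0 <- tryCatch(
    stats::approx(pts$req, pts$concentration_M, xout = rmax0 / 2,
                  ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(pts$concentration_M)

  fit <- tryCatch(
    minpack.lm::nlsLM(req ~ rmax * concentration_M / (concentration_M + kd),
                      data = pts,
                      start = list(rmax = max(rmax0, .Machine$double.eps),
                                   kd = kd0),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(kd = NA_real_, rmax = rmax0, kd_se = NA_real_,
                rmax_se = NA_real_, rss = NA_real_, low_confidence = TRUE,
                points = pts, fit = NULL)
    class(out) <- "equilibrium_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(rmax = NA_real_, kd = NA_real_))
  rss <- sum(stats::residuals(fit)^2)
  pts$fitted <- stats::fitted(fit)
  pts$normalised <- if (cf[["rmax"]] > 0) pts$req / cf[["rmax"]] else NA_real_
  low_confidence <- saturated ||
    max(pts$req) < 0.5 * cf[["rmax"]] ||
    (is.finite(se[["kd"]]) && cf[["kd"]] > 0 && se[["kd"]] > cf[["kd"]]) ||
    !is.finite(se[["kd"]])
  out <- list(kd = unname(cf[["kd"]]), rmax = unname(cf[["rmax"]]),
              kd_se = unname(se[["kd"]]), rmax_se = unname(se[["rmax"]]),
              rss = rss, low_confidence = low_confidence,
              points = pts, fit = fit)
  class(out) <- "equilibrium_fit"
  out
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  cat(sprintf("1:1 equilibrium fit: Kd = %.4g M (SE %.2g), Rmax = %.4g (SE %.2g)%s\n",
              x$kd, x$kd_se, x$rmax, x$rmax_se,
              if (x$low_confidence) "  [low confidence]" else ""))
  invisible(x)
}

#' Fit per-replicate Kds for a BLI dataset
#'
#' Convenience wrapper: per replicate, extract equilibrium responses and fit
#' the 1:1 isotherm; returns one Kd per replicate (the analysis the
#' replicate mean +/- SD summaries are built from).
#'
#' @param traces BLI traces data.frame (replicate, concentration_M, time_s,
#'   response).
#' @param ... passed to [equilibrium_points()].
#' @return data.frame: replicate, kd, rmax, low_confidence.
#' @export
fit_bli_replicates <- function(traces, ...) {
  pts <- equilibrium_points(traces, ...)
  reps <- sort(unique(pts$replicate))
  out <- lapply(reps, function(r) {
    f <- fit_equilibrium_kd(pts[pts$replicate == r, ])
    data.frame(replicate = r, kd = f$kd, rmax = f$rmax,
               low_confidence = f$low_confidence)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare affinities between two groups of replicate Kds
#'
#' Reports mean +/- SD per group and a two-tailed unpaired (Student's,
#' equal-variance) t test. Degenerate cases are handled explicitly: when
#' the pooled within-group variance is zero the test statistic is undefined,
#' and p is reported as 1 for identical group means or as below the machine
#' floor (with `degenerate = TRUE`) for different means.
#'
#' @param kd_a,kd_b numeric vectors of replicate Kds (>= 2 each).
#' @return data.frame: mean_a, sd_a, n_a, mean_b, sd_b, n_b, difference,
#'   p_value, degenerate.
#' @export
compare_affinities <- function(kd_a, kd_b) {
  if (length(kd_a) < 2 || length(kd_b) < 2) {
    stop("need >= 2 replicates per group")
  }
  pooled_var <- (stats::var(kd_a) * (length(kd_a) - 1) +
                   stats::var(kd_b) * (length(kd_b) - 1)) /
    (length(kd_a) + length(kd_b) - 2)
  degenerate <- pooled_var == 0
  if (degenerate) {
    p <- if (mean(kd_a) == mean(kd_b)) 1 else .Machine$double.xmin
  } else {
    p <- stats::t.test(kd_a, kd_b, var.equal = TRUE)$p.value
  }
  data.frame(mean_a = mean(kd_a), sd_a = stats::sd(kd_a), n_a = length(kd_a),
             mean_b = mean(kd_b), sd_b = stats::sd(kd_b), n_b = length(kd_b),
             difference = mean(kd_a) - mean(kd_b),
             p_value = p, degenerate = degenerate)
}

#' Read/write BLI traces as CSV
#'
#' Plain CSV with columns replicate, concentration_M, time_s, response.
#'
#' @param traces BLI traces data.frame.
#' @param path CSV file.
#' @return `read_bli_csv`: the traces data.frame; `write_bli_csv`:
#'   invisibly, `path`.
#' @export
write_bli_csv <- function(traces, path) {
  utils::write.csv(traces[c("replicate", "concentration_M", "time_s",
                            "response")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bli_csv
#' @export
read_bli_csv <- function(path) {
  utils::read.csv(path)
}
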