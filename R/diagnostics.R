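#' Visual predictive check
#'
#' Simulates `n_reps` complete studies from a parameter set (simulation
#' truth or fitted values) and summarizes, per arm, observation kind and
#' sampling time, the median and a central prediction interval of the
#' simulated individual observations (inter-individual variability plus
#' residual error included). Observed values, when supplied, are attached
#' and the fraction falling inside the interval is reported.
#'
#' @param truth parameter list as in [species_truth()] (or the
#'   corresponding fitted values).
#' @param design the [make_design()] the observations follow.
#' @param observed optional observation table to overlay.
#' @param n_reps number of simulated replicate studies.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param level coverage of the prediction interval (default 0.95).
#' @return An object of class `oltt_vpc`: a tibble with `arm`, `kind`,
#'   `time`, `lo`, `med`, `hi`, `n_obs`, `n_inside`, plus attributes
#'   `n_reps`, `seed`, `level` and `coverage` (overall observed fraction
#'   inside the band, `NA` without observations).
#' @export
vpc <- function(truth, design, observed = NULL, n_reps = 1000, seed = 1,
                level = 0.95) {
  if (n_reps < 1) stop("vpc: 'n_reps' must be >= 1", call. = FALSE)
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  sims <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s <- simulate_study(design, truth, seed = seed + r)
    sims[[r]] <- s[s$kind %in% c("pk", "tag"),
                   c("arm", "kind", "time", "value")]
  }
  pool <- do.call(rbind, sims)
  key <- paste(pool$arm, pool$kind, pool$time, sep = "\r")
  grp <- split(seq_len(nrow(pool)), key)
  qs <- t(vapply(grp, function(ix) quantile(pool$value[ix], probs = probs,
                                            names = FALSE), numeric(3)))
  first <- vapply(grp, `[`, integer(1), 1L)
  res <- tibble::tibble(arm = pool$arm[first], kind = pool$kind[first],
                        time = pool$time[first],
                        lo = qs[, 1], med = qs[, 2], hi = qs[, 3],
                        n_obs = 0L, n_inside = 0L)
  res <- res[order(res$kind, res$arm, res$time), ]
  if (!is.null(observed)) {
    obs <- observed[observed$kind %in% c("pk", "tag"), , drop = FALSE]
    idx <- match(paste(obs$arm, obs$kind, obs$time, sep = "\r"),
                 paste(res$arm, res$kind, res$time, sep = "\r"))
    keep <- !is.na(idx)
    inside <- obs$value[keep] >= res$lo[idx[keep]] &
      obs$value[keep] <= res$hi[idx[keep]]
    res$n_obs <- as.integer(tabulate(idx[keep], nbins = nrow(res)))
    res$n_inside <- as.integer(tabulate(idx[keep][inside],
                                        nbins = nrow(res)))
  }
  structure(res, class = c("oltt_vpc", class(res)),
            n_reps = n_reps, seed = seed, level = level,
            coverage = if (is.null(observed)) NA_real_ else
              sum(res$n_inside) / max(1L, sum(res$n_obs)))
}

#' Goodness-of-fit table
#'
#' Per-observation population predictions (PRED, random effects at zero),
#' individual predictions (IPRED, empirical-Bayes random effects),
#' residuals, and individual weighted residuals
#' `(obs - IPRED) / (sigma * IPRED)` — the proportional-error
#' standardization used here as a practical stand-in for conditional
#' weighted residuals.
#'
#' @param fit an `oltt_fit`.
#' @param data the observation table the fit was run on.
#' @return tibble with `subject`, `arm`, `kind`, `time`, `obs`, `pred`,
#'   `ipred`, `res`, `wres`.
#' @export
gof_table <- function(fit, data) {
  st <- fit$stages[[length(fit$stages)]]
  obj <- st$obj
  par_hat <- obj$env$last.par.best
  rep_i <- obj$report(par_hat)
  par0 <- par_hat
  if (!is.null(st$inp$random)) par0[names(par0) == "eta"] <- 0
  rep_p <- obj$report(par0)
  rows <- st$inp$obs_rows
  kind <- data$kind[rows]
  sig <- ifelse(kind == "tag", fit$resid_hat[["tag"]], fit$resid_hat[["pk"]])
  obs <- data$value[rows]
  ipred <- rep_i$pred
  tibble::tibble(
    subject = data$subject[rows],
    arm = if ("arm" %in% names(data)) data$arm[rows] else NA_character_,
    kind = kind,
    time = data$time[rows],
    obs = obs,
    pred = rep_p$pred,
    ipred = ipred,
    res = obs - ipred,
    wres = (obs - ipred) / (sig * ipred)
  )
}

#' Plot a visual predictive check
#'
#' One panel per arm: simulated median (solid), prediction-interval bounds
#' (dashed) and observed points, for the requested observation kind.
#'
#' @param v an `oltt_vpc`.
#' @param observed optional observation table for the overlay points.
#' @param kind `"tag"` or `"pk"`.
#' @param path optional file path; when given the figure is written there
#'   (format from the extension, e.g. `.pdf`) and the path returned.
#' @return the ggplot object (invisibly, when written to file).
#' @export
plot_vpc <- function(v, observed = NULL, kind = "tag", path = NULL) {
  d <- v[v$kind == kind, , drop = FALSE]
  if (nrow(d) == 0L) {
    warning("plot_vpc: empty result; nothing to plot", call. = FALSE)
    return(invisible(NULL))
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = time)) +
    ggplot2::geom_line(ggplot2::aes(y = med), colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = lo), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = hi), linetype = "dashed") +
    ggplot2::facet_wrap(~arm, scales = "free_y") +
    ggplot2::labs(x = "time (h)",
                  y = if (kind == "tag") "plasma TAG (mg/dL)"
                      else "free concentration (umol/L)")
  if (!is.null(observed)) {
    o <- observed[observed$kind == kind, , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = o, ggplot2::aes(x = time, y = value), alpha = 0.4, size = 0.8)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 6)
    return(invisible(p))
  }
  p
}

#' Plot goodness-of-fit diagnostics
#'
#' Observed vs population and individual predictions, and weighted
#' residuals vs time, per observation kind.
#'
#' @param g a [gof_table()] result.
#' @param path optional file path, as in [plot_vpc()].
#' @export
plot_gof <- function(g, path = NULL) {
  if (nrow(g) == 0L) {
    warning("plot_gof: empty result; nothing to plot", call. = FALSE)
    return(invisible(NULL))
  }
  long <- rbind(
    data.frame(x = g$pred, y = g$obs, panel = "obs vs PRED", kind = g$kind),
    data.frame(x = g$ipred, y = g$obs, panel = "obs vs IPRED", kind = g$kind),
    data.frame(x = g$time, y = g$wres, panel = "WRES vs time", kind = g$kind))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(kind ~ panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 9, height = 6)
    return(invisible(p))
  }
  p
}
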