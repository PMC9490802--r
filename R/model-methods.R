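## S3 methods for fitted state-flux models.

#' @export
print.state_flux_model <- function(x, ...) {
  cat("Bayesian negative-binomial multilevel flux model\n")
  cat("  ", x$n_obs, " intervals, ", length(x$predictor_names),
      " phase predictors, ", length(x$group_levels), " pores\n", sep = "")
  cat("  ", x$chains, " chains x ", x$iter, " iterations (",
      x$warmup, " warmup); acceptance ",
      paste(sprintf("%.2f", x$acceptance), collapse = "/"), "\n",
      sep = "")
  cv <- check_convergence(x)
  cat(sprintf("  max split-Rhat %.4f, min ESS %.0f\n", cv$worst_rhat,
              cv$min_ess))
  cat("Posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.state_flux_model <- function(object, ...) {
  keep <- c("alpha", paste0("b_", object$predictor_names))
  colMeans(object$draws[, keep, drop = FALSE])
}

#' @export
summary.state_flux_model <- function(object, probs = c(0.025, 0.975),
                                     ...) {
  d <- object$draws
  qs <- t(apply(d, 2L, stats::quantile, probs = probs))
  tab <- data.frame(parameter = colnames(d), mean = colMeans(d),
                    sd = apply(d, 2L, stats::sd), qs,
                    row.names = NULL, check.names = FALSE)
  names(tab)[4:5] <- paste0("q", probs * 100)
  tab <- merge(tab, object$diagnostics, by = "parameter", sort = FALSE)
  structure(list(table = tab, acceptance = object$acceptance,
                 chains = object$chains, iter = object$iter,
                 warmup = object$warmup),
            class = "summary.state_flux_model")
}

#' @export
print.summary.state_flux_model <- function(x, ...) {
  cat("Posterior summary (", x$chains, " chains x ", x$iter - x$warmup,
      " retained draws)\n", sep = "")
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Posterior linear predictor / expected counts for new intervals
#'
#' @param object a [state_flux_model].
#' @param newdata data.frame with the predictor columns (default: the
#'   covariate means of the training data).
#' @param group_effect group deviation `u` on the log scale (default 0,
#'   a typical pore).
#' @param type `"response"` (expected counts per flux window) or
#'   `"link"`.
#' @param ... unused.
#' @return data.frame with posterior `mean`, `lo95`, `hi95` per row of
#'   `newdata`.
#' @export
predict.state_flux_model <- function(object, newdata = NULL,
                                     group_effect = 0,
                                     type = c("response", "link"), ...) {
  type <- match.arg(type)
  xm <- if (is.null(newdata)) {
    matrix(object$covariate_means, 1L,
           dimnames = list(NULL, object$predictor_names))
  } else {
    miss <- setdiff(object$predictor_names, names(newdata))
    if (length(miss))
      stop("newdata lacks predictor(s): ", paste(miss, collapse = ", "))
    as.matrix(newdata[object$predictor_names])
  }
  a <- object$draws[, "alpha"]
  B <- object$draws[, paste0("b_", object$predictor_names),
                    drop = FALSE]
  eta <- outer(a, rep(1, nrow(xm))) + B %*% t(xm) + group_effect
  val <- if (type == "response") exp(eta) else eta
  data.frame(mean = colMeans(val),
             lo95 = apply(val, 2L, stats::quantile, 0.025),
             hi95 = apply(val, 2L, stats::quantile, 0.975))
}

#' Predicted water flux per residue gating state
#'
#' For each requested state the residue is fixed fully in that state
#' (its phase fraction set to 1), the other residues are held at the
#' covariate policy, and the group effect is fixed; the posterior of
#' `mu = exp(linear predictor)` is summarised as waters per flux window
#' (5 ns under the default scheme) with a 95% credible interval.
#'
#' @param object a [state_flux_model] fitted on a dataset carrying a
#'   residue map ([assemble_dataset()]).
#' @param residue residue id(s), e.g. `"r206"`; default all residues.
#' @param state state label(s) of that residue; default all states.
#' @param covariate_policy `"mean"` holds other residues at their
#'   dataset-mean phase fractions; `"reference"` puts them fully in their
#'   reference states.
#' @param group_effect group deviation on the log scale (default 0).
#' @return data.frame of class `state_flux_prediction`: `residue`,
#'   `state`, `mean`, `lo95`, `hi95` (waters per flux window).
#' @export
predict_state_flux <- function(object, residue = NULL, state = NULL,
                               covariate_policy = c("mean", "reference"),
                               group_effect = 0) {
  covariate_policy <- match.arg(covariate_policy)
  rmap <- object$residue_map
  if (is.null(rmap))
    stop("fit carries no residue/state map; refit on an assembled dataset")
  if (is.null(residue)) residue <- names(rmap)
  bad <- setdiff(residue, names(rmap))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  base <- if (covariate_policy == "mean") object$covariate_means
          else stats::setNames(rep(0, length(object$predictor_names)),
                               object$predictor_names)
  rows <- list()
  for (r in residue) {
    states <- if (is.null(state)) rmap[[r]]$states else state
    bad <- setdiff(states, rmap[[r]]$states)
    if (length(bad))
      stop("unknown state(s) for ", r, ": ", paste(bad, collapse = ", "))
    own_cols <- stats::na.omit(rmap[[r]]$columns)
    for (s in states) {
      x <- base
      x[own_cols] <- 0                       # residue fully out of ...
      col <- rmap[[r]]$columns[[s]]
      if (!is.na(col)) x[col] <- 1           # ... all but the target state
      rows[[paste(r, s)]] <- data.frame(
        residue = r, state = s,
        predict(object, as.data.frame(as.list(x), check.names = FALSE),
                group_effect = group_effect))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("state_flux_prediction", "data.frame")
  out
}

#' @export
plot.state_flux_model <- function(x, ...) {
  pred <- predict_state_flux(x)
  lab <- paste(pred$residue, pred$state, sep = ":")
  n <- nrow(pred)
  op <- graphics::par(mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_len(n), pred$mean, ylim = range(0, pred$hi95),
                 xaxt = "n", xlab = "", pch = 19, col = "magenta4",
                 ylab = "waters per flux window",
                 main = "Predicted flux per gating state (95% CI)", ...)
  graphics::arrows(seq_len(n), pred$lo95, seq_len(n), pred$hi95,
                   angle = 90, code = 3, length = 0.03, col = "magenta4")
  graphics::axis(1, at = seq_len(n), labels = lab, las = 2, cex.axis = 0.7)
  invisible(pred)
}

#' Posterior-predictive simulation of flux counts
#'
#' Draws counts from the fitted negative-binomial likelihood on supplied
#' covariates, one posterior draw per simulated dataset.
#'
#' @param object a [state_flux_model].
#' @param nsim number of simulated replicate count vectors.
#' @param seed optional seed.
#' @param newdata predictor data.frame plus (optionally) a `pore_id`
#'   column matched against the fitted group levels; default: a single
#'   covariate-mean row.
#' @param ... unused.
#' @return matrix (rows of `newdata` x `nsim`) of simulated counts.
#' @export
simulate.state_flux_model <- function(object, nsim = 1, seed = NULL,
                                      newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata))
    newdata <- as.data.frame(as.list(object$covariate_means),
                             check.names = FALSE)
  xm <- as.matrix(newdata[object$predictor_names])
  u <- rep(0, nrow(xm))
  if (!is.null(newdata$pore_id) && length(object$group_levels)) {
    ucols <- paste0("u[", newdata$pore_id, "]")
    ok <- ucols %in% colnames(object$draws)
    if (!all(ok)) stop("unknown pore id(s) in newdata")
  }
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  out <- matrix(NA_real_, nrow(xm), nsim)
  for (s in seq_len(nsim)) {
    dr <- object$draws[idx[s], ]
    eta <- dr[["alpha"]] +
      drop(xm %*% dr[paste0("b_", object$predictor_names)])
    if (!is.null(newdata$pore_id) && length(object$group_levels))
      eta <- eta + dr[paste0("u[", newdata$pore_id, "]")]
    out[, s] <- stats::rnbinom(nrow(xm), size = dr[["phi"]],
                               mu = exp(eta))
  }
  out
}

#' Residuals of a state-flux model fit
#'
#' Pearson residuals `(y - mu) / sqrt(mu + mu^2/phi)` at the posterior
#' means, computed against a supplied dataset (the object does not store
#' its training data).
#'
#' @param object a [state_flux_model].
#' @param data the dataset the model was fitted on (or comparable).
#' @param type `"pearson"` or `"response"`.
#' @param ... unused.
#' @return numeric vector, one residual per row of `data`.
#' @export
residuals.state_flux_model <- function(object, data,
                                       type = c("pearson", "response"),
                                       ...) {
  type <- match.arg(type)
  if (missing(data))
    stop("supply the dataset: the fit object stores no training data")
  mu <- posterior_mean_mu(object, data)
  y <- data$flux_count
  r <- y - mu
  if (type == "pearson") {
    phi <- mean(object$draws[, "phi"])
    r <- r / sqrt(mu + mu^2 / phi)
  }
  r
}

#' Posterior-mean expected counts on a dataset
#'
#' @param object a [state_flux_model].
#' @param data the (training) dataset with predictor and `pore_id`
#'   columns.
#' @return numeric vector of posterior-mean `mu` per row.
#' @export
posterior_mean_mu <- function(object, data) {
  xm <- as.matrix(data[object$predictor_names])
  a <- object$draws[, "alpha"]
  B <- object$draws[, paste0("b_", object$predictor_names), drop = FALSE]
  eta <- outer(a, rep(1, nrow(xm))) + B %*% t(xm)
  if (!is.null(data$pore_id) && length(object$group_levels)) {
    U <- object$draws[, paste0("u[", data$pore_id, "]"), drop = FALSE]
    eta <- eta + U
  }
  colMeans(exp(eta))
}

#' Relative water permeability of variants
#'
#' Per-pore mean permeation events per `window_ns` over the analysis
#' range, variant means with SEM across pores, and ratios to the
#' reference variant with delta-method propagated uncertainty.
#'
#' @param series list of [flux_series]; each must carry a `variant`
#'   field in `pore_id` metadata, or supply `variants`.
#' @param variants character vector, one variant label per series.
#' @param analysis_range length-2 ns range counted.
#' @param window_ns normalisation window (default 100 ns).
#' @param reference reference variant label (default `"wt"`).
#' @param mode `"total"` or `"net"` counting.
#' @return data.frame `variant`, `mean_per_window`, `sem`, `n_pores`,
#'   `ratio_to_ref`, `ratio_sem`.
#' @export
relative_flux <- function(series, variants = NULL,
                          analysis_range = c(1000, 3000),
                          window_ns = 100, reference = "wt",
                          mode = c("total", "net")) {
  mode <- match.arg(mode)
  if (is.null(variants))
    variants <- vapply(series, function(s)
      strsplit(as.character(s$pore_id), "[._]")[[1L]][1L], "")
  if (!reference %in% variants)
    stop("reference variant '", reference, "' absent")
  starts <- seq(analysis_range[1L], analysis_range[2L] - window_ns,
                by = window_ns)
  win <- cbind(starts, starts + window_ns)
  per_pore <- vapply(series, function(s)
    mean(flux_in_windows(s, win, mode = mode)), 0)
  vs <- sort(unique(variants))
  agg <- data.frame(
    variant = vs,
    mean_per_window = vapply(vs, function(v)
      mean(per_pore[variants == v]), 0),
    sem = vapply(vs, function(v) {
      x <- per_pore[variants == v]
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    }, 0),
    n_pores = vapply(vs, function(v) sum(variants == v), 0L),
    row.names = NULL)
  ref <- agg[agg$variant == reference, ]
  agg$ratio_to_ref <- agg$mean_per_window / ref$mean_per_window
  agg$ratio_sem <- agg$ratio_to_ref *
    sqrt((agg$sem / agg$mean_per_window)^2 +
           (ref$sem / ref$mean_per_window)^2)
  agg
}
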