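## Paired property/flux interval scheme and assembly of the model input
## table: phase-percentage predictors (k-1 per residue) plus flux counts.

#' Paired property/flux interval scheme
#'
#' Each pair consists of a property window `[t, t + property_len)` during
#' which residue states are summarised, and a flux window
#' `[t + lag, t + lag + flux_len)` in which crossings are counted; with
#' the defaults (5 ns windows, 3 ns lag) the windows overlap by 2 ns so
#' that conformation precedes transport. Pairs advance by `stride` while
#' the property window fits inside the analysis range; a trailing flux
#' window is clipped at the range end. The default stride of 10/3 ns
#' yields exactly 599 pairs over a 2000 ns analysis range.
#'
#' @param property_len,flux_len window lengths in ns.
#' @param lag ns between property and flux window starts; must satisfy
#'   `0 < lag < property_len`.
#' @param stride ns between consecutive pairs.
#' @param analysis_start,analysis_end analysed time range in ns (default
#'   1000-3000: the first microsecond of each simulation is treated as
#'   equilibration).
#' @return object of class `interval_scheme`.
#' @export
interval_scheme <- function(property_len = 5, flux_len = 5, lag = 3,
                            stride = 10 / 3, analysis_start = 1000,
                            analysis_end = 3000) {
  if (stride <= 0) stop("stride must be positive")
  if (lag <= 0 || lag >= property_len)
    stop("lag must lie strictly between 0 and property_len")
  structure(list(property_len = property_len, flux_len = flux_len,
                 lag = lag, stride = stride,
                 analysis_start = analysis_start,
                 analysis_end = analysis_end),
            class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat("<interval_scheme> property ", x$property_len, " ns, flux ",
      x$flux_len, " ns, lag ", x$lag, " ns (overlap ",
      x$property_len - x$lag, " ns), stride ",
      format(x$stride, digits = 6), " ns over [",
      x$analysis_start, ", ", x$analysis_end, ") ns: ",
      nrow(build_windows(x)), " pairs\n", sep = "")
  invisible(x)
}

#' Paired windows of a scheme
#'
#' @param scheme an [interval_scheme].
#' @return data.frame with half-open windows in ns: `t_start`,
#'   `property_start`, `property_end`, `flux_start`, `flux_end` (clipped
#'   at the analysis end).
#' @export
build_windows <- function(scheme) {
  span <- scheme$analysis_end - scheme$analysis_start
  # one paired block spans lag + flux_len ns (8 by default)
  if (span < max(scheme$property_len, scheme$lag + scheme$flux_len))
    return(data.frame(t_start = numeric(), property_start = numeric(),
                      property_end = numeric(), flux_start = numeric(),
                      flux_end = numeric()))
  n <- floor((span - scheme$property_len) / scheme$stride + 1e-9) + 1L
  t0 <- scheme$analysis_start + (seq_len(n) - 1L) * scheme$stride
  data.frame(t_start = t0,
             property_start = t0,
             property_end = t0 + scheme$property_len,
             flux_start = t0 + scheme$lag,
             flux_end = pmin(t0 + scheme$lag + scheme$flux_len,
                             scheme$analysis_end))
}

#' Phase fractions of a state trace in one window
#'
#' Fraction of frames within the half-open window per state; fractions
#' over all states (including the reference) sum to 1.
#'
#' @param trace a [state_trace].
#' @param window length-2 numeric `(start_ns, end_ns)`.
#' @return named fractions, one per state level.
#' @export
phase_fractions <- function(trace, window) {
  f <- phase_fractions_windows(trace, matrix(window, 1L))
  stats::setNames(as.numeric(f), colnames(f))
}

## Vectorised phase fractions over many windows via per-state cumulative
## counts: O(n_frames x n_states) regardless of window count.
phase_fractions_windows <- function(trace, windows) {
  t0 <- trace$time_start_ns
  dt <- trace$frame_period_ps / 1000
  nfr <- length(trace$states)
  # first frame index with time >= start; last with time < end (half-open)
  lo <- pmax(1L, as.integer(ceiling((windows[, 1L] - t0) / dt - 1e-9)) + 1L)
  hi <- pmin(nfr, as.integer(ceiling((windows[, 2L] - t0) / dt - 1e-9)))
  if (any(hi < lo)) stop("window with zero frames in trace time base")
  levs <- levels(trace$states)
  out <- matrix(0, nrow(windows), length(levs),
                dimnames = list(NULL, levs))
  si <- as.integer(trace$states)
  for (s in seq_along(levs)) {
    cs <- c(0L, cumsum(si == s))
    out[, s] <- cs[hi + 1L] - cs[lo]
  }
  out / (hi - lo + 1L)
}

#' Assemble the interval dataset
#'
#' Builds one row per pore per paired window: the phase fractions of every
#' registry residue over the property window (reference-state columns
#' dropped, the k-1 encoding) and the flux count over the flux window.
#' Predictor columns are named `<residue>.<state>`.
#'
#' @param traces list over pores; each element a named list of
#'   [state_trace] objects, one per residue definition.
#' @param flux list over pores of [flux_series] (or event tables), in the
#'   same order.
#' @param scheme an [interval_scheme].
#' @param registry the gating registry the traces were classified with;
#'   used for state order and reference states.
#' @param pore_meta optional data.frame (one row per pore) with columns
#'   such as `pore_id`, `variant`, `replica`, `chain`.
#' @param flux_mode `"total"` (default, bidirectional event count) or
#'   `"net"`.
#' @param drop_reference set `FALSE` to keep reference-state columns
#'   (diagnostic mode; predictor columns per residue then sum to 1).
#' @return data.frame of class `flux_dataset` with attributes
#'   `predictors` (column names) and `residue_map`.
#' @export
assemble_dataset <- function(traces, flux, scheme,
                             registry = gating_registry(),
                             pore_meta = NULL,
                             flux_mode = c("total", "net"),
                             drop_reference = TRUE) {
  flux_mode <- match.arg(flux_mode)
  n_pores <- length(traces)
  if (length(flux) != n_pores)
    stop("traces and flux series disagree on pore count")
  if (is.null(pore_meta))
    pore_meta <- data.frame(pore_id = paste0("pore", seq_len(n_pores)),
                            variant = "wt", replica = 1L,
                            chain = LETTERS[(seq_len(n_pores) - 1L) %% 4L
                                            + 1L])
  win <- build_windows(scheme)
  if (!nrow(win)) stop("analysis range admits no paired window")
  rows <- vector("list", n_pores)
  for (p in seq_len(n_pores)) {
    tr_p <- traces[[p]]
    miss <- setdiff(names(registry), names(tr_p))
    if (length(miss))
      stop("pore ", pore_meta$pore_id[p], " lacks state trace(s) for: ",
           paste(miss, collapse = ", "))
    pred <- interval_predictors(tr_p, win, registry, drop_reference)
    y <- flux_in_windows(flux[[p]],
                         as.matrix(win[c("flux_start", "flux_end")]),
                         mode = flux_mode, allow_overlap = TRUE)
    rows[[p]] <- data.frame(pore_meta[p, , drop = FALSE],
                            interval = seq_len(nrow(win)),
                            t_start_ns = win$t_start, pred,
                            flux_count = y, row.names = NULL,
                            check.names = FALSE)
  }
  ds <- do.call(rbind, rows)
  meta_cols <- c(names(pore_meta), "interval", "t_start_ns", "flux_count")
  attr(ds, "predictors") <- setdiff(names(ds), meta_cols)
  attr(ds, "residue_map") <- residue_map_of(registry, drop_reference)
  attr(ds, "scheme") <- scheme
  class(ds) <- c("flux_dataset", "data.frame")
  ds
}

## Phase-percentage predictor matrix of one pore over the paired windows
## (property windows), k-1 encoded unless drop_reference = FALSE.
interval_predictors <- function(tr_p, win, registry, drop_reference) {
  pred <- list()
  for (rid in names(registry)) {
    def <- registry[[rid]]
    fr <- phase_fractions_windows(tr_p[[rid]],
                                  as.matrix(win[c("property_start",
                                                  "property_end")]))
    keep <- if (drop_reference) setdiff(def$labels, def$reference)
            else def$labels
    fr <- fr[, keep, drop = FALSE]
    colnames(fr) <- paste0(rid, ".", keep)
    pred[[rid]] <- fr
  }
  do.call(cbind, pred)
}

## residue_map attribute shared by assemble_dataset and the simulator.
residue_map_of <- function(registry, drop_reference = TRUE) {
  lapply(registry, function(d)
    list(states = d$labels, reference = d$reference,
         columns = stats::setNames(
           ifelse(d$labels == d$reference & drop_reference, NA,
                  paste0(d$id, ".", d$labels)), d$labels)))
}

#' Write / read the interval dataset CSV
#'
#' The CSV is the sole input of the statistics layer.
#'
#' @param ds a `flux_dataset`.
#' @param path file path.
#' @return `path` (write) or the dataset with its attributes (read).
#' @export
write_dataset_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  ds <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- intersect(c("pore_id", "variant", "replica", "chain",
                           "interval", "t_start_ns", "flux_count"),
                         names(ds))
  attr(ds, "predictors") <- setdiff(names(ds), meta_cols)
  class(ds) <- c("flux_dataset", "data.frame")
  ds
}
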