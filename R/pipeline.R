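#' Read one epoch from a CSV file
#'
#' Rows are time points, columns are channels; a header row is optional and
#' auto-detected.
#'
#' @param path CSV file path.
#' @param sampling_rate_hz optional sampling rate to attach.
#' @param epoch_index epoch label.
#' @return An \code{\link{epoch_series}}.
#' @export
read_epoch_csv <- function(path, sampling_rate_hz = NULL, epoch_index = 0L) {
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, ",")[[1L]]))))
  df <- utils::read.csv(path, header = has_header)
  epoch_series(as.matrix(df), sampling_rate_hz = sampling_rate_hz,
               epoch_index = epoch_index)
}

#' Read a multi-epoch manifest
#'
#' A manifest is a YAML or JSON file with fields \code{epochs} (file names in
#' epoch order, relative to the manifest's directory) and optional
#' \code{sampling_rate_hz}. Epoch files may have different numbers of
#' channels.
#'
#' @param path manifest file path (\code{.yaml}/\code{.yml}/\code{.json}).
#' @return List of \code{\link{epoch_series}} in manifest order.
#' @export
read_manifest <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$epochs)) stop("manifest has no 'epochs' field")
  base <- dirname(path)
  fs <- spec$sampling_rate_hz
  lapply(seq_along(spec$epochs), function(i) {
    read_epoch_csv(file.path(base, spec$epochs[[i]]),
                   sampling_rate_hz = fs, epoch_index = i)
  })
}

#' Epoch-wise FS-ratio traces with scan profiles
#'
#' Runs the full per-epoch analysis over a multi-epoch recording whose
#' dimension may change from epoch to epoch: center (optionally pre-whiten),
#' estimate the spectral matrix, compute the FS-ratio for every requested
#' band (with a stationary-bootstrap CI when \code{n_replicates > 0}), and
#' optionally the scan profile. Epochs that fail (degenerate input) are
#' skipped with a warning, leaving \code{NA} gaps in the traces.
#'
#' @param epochs list of \code{\link{epoch_series}} or a manifest path
#'   (see \code{\link{read_manifest}}).
#' @param bands list of \code{\link{frequency_band}} objects (named or
#'   labelled).
#' @param config list of options: \code{kernel} (default
#'   \code{"epanechnikov"}), \code{h} (default \code{\link{default_bandwidth}}
#'   per epoch), \code{n_replicates} (bootstrap replicates per epoch and
#'   band; 0 = no CIs, the default), \code{block_length} (\code{"auto"} or a
#'   number), \code{seed} (default 1), \code{ci_level} (default 0.95),
#'   \code{prewhiten} (default \code{FALSE}), \code{scan} (compute scan
#'   profiles, default \code{TRUE}), \code{scan_delta} (default 0.01),
#'   \code{scan_Q} (default 49), \code{verbose} (default \code{FALSE}).
#' @return Object of class \code{"fs_epoch_run"}: list with \code{traces}
#'   (one \code{"fsratio_trace"} per band: \code{band},
#'   \code{epoch_values}, \code{ci_lower}, \code{ci_upper},
#'   \code{epoch_dims}), \code{profiles} (per-epoch \code{lambdas} matrix and
#'   \code{grid}, or \code{NULL}), \code{epoch_dims}, \code{config}.
#' @export
run_epochs <- function(epochs, bands, config = list()) {
  if (is.character(epochs)) epochs <- read_manifest(epochs)
  stopifnot(is.list(epochs), length(epochs) >= 1L, is.list(bands),
            length(bands) >= 1L)
  cfg <- utils::modifyList(
    list(kernel = "epanechnikov", h = NULL, n_replicates = 0L,
         block_length = "auto", seed = 1L, ci_level = 0.95,
         prewhiten = FALSE, scan = TRUE, scan_delta = 0.01, scan_Q = 49L,
         verbose = FALSE),
    config)
  n_ep <- length(epochs)
  labels <- band_labels(bands)
  vals <- matrix(NA_real_, n_ep, length(bands),
                 dimnames = list(NULL, labels))
  los <- his <- vals
  dims <- integer(n_ep)
  lam_mat <- NULL
  lam_grid <- NULL
  for (i in seq_len(n_ep)) {
    e <- epochs[[i]]
    dims[i] <- e$n_comp
    ok <- tryCatch({
      if (cfg$prewhiten) e <- prewhiten(e)
      est <- spectral_estimate(e, kernel = cfg$kernel, h = cfg$h)
      for (b in seq_along(bands)) {
        if (cfg$n_replicates > 0L) {
          ci <- fsratio_bootstrap_ci(
            e, bands[[b]], n_replicates = cfg$n_replicates,
            block_length = cfg$block_length,
            seed = replicate_seed(cfg$seed, i * length(bands) + b),
            ci_level = cfg$ci_level, kernel = cfg$kernel, h = cfg$h)
          vals[i, b] <- ci$estimate
          los[i, b] <- ci$lower
          his[i, b] <- ci$upper
        } else {
          vals[i, b] <- fs_ratio(est, bands[[b]])
        }
      }
      if (cfg$scan) {
        prof <- scan_profile(est, delta = cfg$scan_delta, Q = cfg$scan_Q)
        if (is.null(lam_mat)) {
          lam_grid <- prof$grid
          lam_mat <- matrix(NA_real_, n_ep, length(prof$grid))
        }
        lam_mat[i, ] <- prof$lambdas
      }
      TRUE
    }, error = function(err) {
      warning("epoch ", i, " skipped: ", conditionMessage(err))
      FALSE
    })
    if (cfg$verbose && ok) {
      message(sprintf("epoch %d: d = %d, T = %d", i, e$n_comp, e$n_time))
    }
  }
  traces <- lapply(seq_along(bands), function(b) {
    structure(
      list(band = bands[[b]], epoch_values = unname(vals[, b]),
           ci_lower = unname(los[, b]), ci_upper = unname(his[, b]),
           epoch_dims = dims),
      class = "fsratio_trace")
  })
  names(traces) <- labels
  structure(
    list(traces = traces,
         profiles = if (cfg$scan) list(grid = lam_grid, lambdas = lam_mat),
         epoch_dims = dims, config = cfg),
    class = "fs_epoch_run"
  )
}

band_labels <- function(bands) {
  lb <- vapply(seq_along(bands), function(b) {
    if (!is.null(bands[[b]]$label)) bands[[b]]$label
    else if (!is.null(names(bands)) && nzchar(names(bands)[b])) names(bands)[b]
    else sprintf("band%d", b)
  }, character(1L))
  make.unique(lb)
}

#' Per-group numerical summary of an FS-ratio trace
#'
#' Summarizes a trace over groups of epochs (e.g. pre/post an intervention):
#' mean, median and SD of the per-epoch FS-ratios, plus a group-level
#' interval taken as the 2.5\% and 97.5\% quantiles of the pooled per-epoch
#' bootstrap CI endpoints (when the trace carries CIs; otherwise quantiles of
#' the epoch values themselves).
#'
#' @param trace an \code{"fsratio_trace"} from \code{\link{run_epochs}}.
#' @param groups named list of epoch index vectors; indices must be disjoint
#'   and non-empty.
#' @return Data frame with one row per group: \code{group}, \code{band},
#'   \code{n}, \code{mean}, \code{median}, \code{sd}, \code{ci_lower},
#'   \code{ci_upper}.
#' @export
group_summary <- function(trace, groups) {
  stopifnot(inherits(trace, "fsratio_trace"), is.list(groups),
            length(groups) >= 1L)
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  all_idx <- unlist(groups)
  if (anyDuplicated(all_idx)) stop("groups must be disjoint")
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) == 0L) stop("group '", g, "' is empty")
    v <- trace$epoch_values[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop("group '", g, "' has no usable epochs")
    ends <- c(trace$ci_lower[idx], trace$ci_upper[idx])
    ends <- ends[!is.na(ends)]
    if (length(ends) == 0L) ends <- v
    data.frame(
      group = g,
      band = if (is.null(trace$band$label)) NA_character_ else trace$band$label,
      n = length(v), mean = mean(v), median = stats::median(v),
      sd = stats::sd(v),
      ci_lower = unname(stats::quantile(ends, 0.025)),
      ci_upper = unname(stats::quantile(ends, 0.975)))
  })
  do.call(rbind, rows)
}

#' Rank bands by between-group change and within-group variation
#'
#' For two epoch groups (e.g. pre/post), ranks the analyzed bands by
#' (i) the absolute difference of group means of the FS-ratio trace
#' (between-group change) and (ii) the mean within-group standard deviation
#' (within-group variation). Ties break by band label order.
#'
#' @param traces named list of \code{"fsratio_trace"} objects
#'   (from \code{\link{run_epochs}}).
#' @param groups named list of exactly two epoch index vectors.
#' @return Data frame with columns \code{band}, \code{between_change},
#'   \code{within_sd}, \code{rank_change}, \code{rank_within}, ordered by
#'   decreasing between-group change.
#' @export
consistency_ranking <- function(traces, groups) {
  stopifnot(is.list(traces), length(traces) >= 2L, length(groups) == 2L)
  labs <- names(traces)
  if (is.null(labs)) labs <- paste0("band", seq_along(traces))
  rows <- lapply(seq_along(traces), function(b) {
    sm <- group_summary(traces[[b]], groups)
    data.frame(band = labs[b],
               between_change = abs(sm$mean[1L] - sm$mean[2L]),
               within_sd = mean(sm$sd))
  })
  df <- do.call(rbind, rows)
  ord <- order(-df$between_change, df$band)
  df <- df[ord, , drop = FALSE]
  df$rank_change <- rank(-df$between_change, ties.method = "first")
  df$rank_within <- rank(-df$within_sd, ties.method = "first")
  rownames(df) <- NULL
  df
}

#' Write an FS-ratio trace as CSV
#'
#' Columns: \code{epoch}, \code{d}, \code{rhat}, \code{lo}, \code{hi}.
#'
#' @param trace an \code{"fsratio_trace"}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fsratio_trace"))
  df <- data.frame(epoch = seq_along(trace$epoch_values),
                   d = trace$epoch_dims, rhat = trace$epoch_values,
                   lo = trace$ci_lower, hi = trace$ci_upper)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a scan profile as CSV
#'
#' Columns: \code{a_j_normalized}, \code{lambda_hat}.
#'
#' @param profile a \code{\link{scan_profile}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "scan_profile"))
  utils::write.csv(
    data.frame(a_j_normalized = profile$grid, lambda_hat = profile$lambdas),
    path, row.names = FALSE)
  invisible(path)
}
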