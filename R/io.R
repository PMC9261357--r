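# Plain-text serialization: observation tables and interval datasets as TSV
# (header line, "inf" for unbounded edges), manifests as JSON.

#' Write and read observation tables
#'
#' An observation table has one row per scored observation with columns
#' `trial_id`, `design`, `time`, `n_live`, `n_dead`, `n_censored` —
#' the per-timepoint counts recorded in a lifespan experiment. Readers
#' validate counts and the within-trial time ordering.
#'
#' @param trials List of trials from [run_trial_set()] (or a single trial).
#' @param path File path.
#' @return `write_observations` invisibly returns `path`;
#'   `read_observations` returns the validated data.frame;
#'   `observations_table` returns the table without writing.
#' @export
write_observations <- function(trials, path) {
  tab <- observations_table(trials)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
observations_table <- function(trials) {
  if (inherits(trials, c("tlm_trial", "rsm_trial"))) trials <- list(trials)
  rows <- lapply(seq_along(trials), function(i) {
    trial <- trials[[i]]
    obs <- trial$observations
    data.frame(trial_id = i,
               design = if (inherits(trial, "tlm_trial")) "TLM" else "RSM",
               obs)
  })
  do.call(rbind, rows)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("trial_id", "design", "time", "n_live", "n_dead", "n_censored")
  if (!all(need %in% names(tab))) {
    stop("observation table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  counts <- as.matrix(tab[c("n_live", "n_dead", "n_censored")])
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or missing counts at line(s) ",
         paste(unique(bad[, 1] + 1L), collapse = ", "), call. = FALSE)
  }
  mono <- tapply(tab$time, tab$trial_id, function(t) all(diff(t) > 0))
  if (!all(mono)) {
    stop("observation times must be strictly increasing within a trial",
         call. = FALSE)
  }
  tab
}

#' Fit every trial of an observation table
#'
#' Rebuilds per-trial interval datasets from a (possibly deserialized)
#' observation table and applies one analysis treatment. For TLM tables,
#' deaths at an observation are assigned the interval since the previous
#' observation (or taken as exact times under `"km_right"`); RSM tables
#' yield current-status intervals and are refused under `"km_right"`.
#'
#' @param table A data.frame as returned by [read_observations()].
#' @param analysis As in [fit_trials()].
#' @return A data.frame with one row per trial.
#' @export
fit_observation_table <- function(table,
                                  analysis = c("logistic", "km_right",
                                               "npmle_interval")) {
  analysis <- match.arg(analysis)
  if (!nrow(table)) stop("empty observation table", call. = FALSE)
  rows <- lapply(split(table, table$trial_id), function(tt) {
    design <- tt$design[1]
    dat <- table_to_intervals(tt, design, analysis)
    if (analysis == "logistic") {
      f <- fit_logistic_mle(dat)
      data.frame(trial_id = tt$trial_id[1], analysis = analysis,
                 median = f$median, mean = f$mean, q95 = f$q95,
                 converged = f$converged)
    } else {
      curve <- if (analysis == "km_right") km_right_censored(dat) else
        npmle_interval(dat)
      s <- curve_summaries(curve)
      data.frame(trial_id = tt$trial_id[1], analysis = analysis,
                 median = s$median, mean = s$mean, q95 = s$q95,
                 converged = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

table_to_intervals <- function(tt, design, analysis) {
  if (design == "RSM") {
    if (analysis == "km_right") {
      stop("right-censored Kaplan-Meier cannot analyze RSM current-status ",
           "data (each animal is observed once; no exact death times exist)",
           call. = FALSE)
    }
    left <- c(rep(0, nrow(tt)), tt$time)
    right <- c(tt$time, rep(Inf, nrow(tt)))
    w <- c(tt$n_dead, tt$n_live)
  } else {
    dead <- tt$n_dead > 0
    if (!any(dead)) stop("TLM trial with no deaths", call. = FALSE)
    t_prev <- c(-Inf, tt$time[-nrow(tt)])
    left <- if (analysis == "km_right") tt$time[dead] else t_prev[dead]
    right <- tt$time[dead]
    w <- tt$n_dead[dead]
    cens <- tt$n_censored > 0
    if (any(cens)) {
      left <- c(left, tt$time[cens])
      right <- c(right, rep(Inf, sum(cens)))
      w <- c(w, tt$n_censored[cens])
    }
  }
  keep <- w > 0
  interval_data(left[keep], right[keep], w[keep])
}

#' Write and read interval datasets
#'
#' TSV with columns `left`, `right`, `weight`; unbounded edges are written
#' as `inf` / `-inf`.
#'
#' @param data An [interval_data()] object.
#' @param path File path.
#' @return `write_intervals` invisibly returns `path`; `read_intervals`
#'   returns an [interval_data()].
#' @export
write_intervals <- function(data, path) {
  data <- as_interval_data(data)
  out <- data.frame(left = format_edge(data$left),
                    right = format_edge(data$right),
                    weight = data$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
  if (!all(c("left", "right", "weight") %in% names(tab))) {
    stop("interval table must have columns left, right, weight", call. = FALSE)
  }
  interval_data(parse_edge(tab$left), parse_edge(tab$right), tab$weight)
}

format_edge <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE)
  out[is.infinite(x) & x > 0] <- "inf"
  out[is.infinite(x) & x < 0] <- "-inf"
  out
}

parse_edge <- function(x) {
  x <- tolower(trimws(x))
  out <- suppressWarnings(as.numeric(x))
  out[x %in% c("inf", "+inf", "infinity")] <- Inf
  out[x == "-inf"] <- -Inf
  if (any(is.na(out))) stop("unparseable interval edge", call. = FALSE)
  out
}

#' Write a reproducibility manifest
#'
#' JSON record sufficient to regenerate an output file exactly: the
#' configuration used, the master seed, and the package version.
#'
#' @param path Output path for the manifest.
#' @param config Named list echoing the simulation configuration.
#' @param master_seed Integer seed used.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, config, master_seed) {
  manifest <- list(
    package = "wormspan",
    version = as.character(utils::packageVersion("wormspan")),
    master_seed = master_seed,
    config = config,
    rng = "L'Ecuyer-CMRG per-trial substreams")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
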