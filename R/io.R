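# Plain-text interchange formats: every writer emits a "# key: value"
# header (always including the package version and, when known, the seed)
# followed by a delimited table; readers preserve unknown header keys.

.pkg_version <- function() {
  as.character(utils::packageVersion("sifir"))
}

.write_header <- function(con, type, meta) {
  writeLines(sprintf("# sifir_%s v%s", type, .pkg_version()), con)
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.null(v) || length(v) != 1 || is.list(v)) next
    writeLines(sprintf("# %s: %s", k, format(v, digits = 15)), con)
  }
}

.read_header <- function(lines) {
  hdr <- grep("^#", lines)
  meta <- list()
  for (i in hdr[-1]) {
    kv <- sub("^#\\s*", "", lines[i])
    sep <- regexpr(":", kv, fixed = TRUE)
    if (sep < 0) next
    key <- trimws(substr(kv, 1, sep - 1))
    val <- trimws(substr(kv, sep + 1, nchar(kv)))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  list(meta = meta, n_header = length(hdr))
}

#' Write / read a decay histogram as delimited text
#'
#' Two columns (channel index, counts) after a `# key: value` metadata
#' header. `channel_width_ps` is required on reading; unknown header keys
#' are preserved in the histogram's metadata.
#'
#' @param hist a [decay_histogram()].
#' @param path file path.
#' @return `write_decay` the path invisibly; `read_decay` a
#'   [decay_histogram()].
#' @export
write_decay <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- hist$metadata
  meta$channel_width_ps <- hist$channel_width * 1e3
  meta$kind <- hist$kind
  .write_header(con, "decay", meta)
  writeLines("channel\tcounts", con)
  writeLines(sprintf("%d\t%.17g", seq_along(hist$counts), hist$counts),
             con)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  lines <- readLines(path)
  h <- .read_header(lines)
  if (is.null(h$meta$channel_width_ps))
    stop("format error in ", path,
         ": missing required header key channel_width_ps")
  body <- lines[-seq_len(h$n_header)]
  body <- body[nzchar(body)]
  if (length(body) && grepl("^channel", body[1])) body <- body[-1]
  parts <- strsplit(body, "[\t ]+")
  counts <- as.numeric(vapply(parts, `[`, "", 2))
  bad <- which(is.na(counts) | counts < 0)
  if (length(bad))
    stop("format error in ", path, " line ",
         h$n_header + 1 + bad[1], ": counts must be non-negative numbers")
  kind <- if (identical(h$meta$kind, "irf")) "irf" else "decay"
  meta <- h$meta
  meta$channel_width_ps <- NULL
  meta$kind <- NULL
  decay_histogram(counts, h$meta$channel_width_ps / 1e3, kind = kind,
                  metadata = c(list(channel_width_ps = h$meta$channel_width_ps),
                               meta))
}

#' Write / read a single-molecule intensity trace
#'
#' Columns frame, intensity and (when available) the ground-truth state,
#' after a metadata header carrying `frame_time_s`.
#'
#' @param trace an `intensity_trace`.
#' @param path file path.
#' @return `write_trace` the path invisibly; `read_trace` an
#'   `intensity_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, "trace", list(frame_time_s = trace$frame_time,
                                   seed = trace$seed))
  has_truth <- !is.null(trace$truth_state)
  if (has_truth) {
    writeLines("frame\tintensity\ttruth_state", con)
    writeLines(sprintf("%d\t%.6g\t%s", seq_along(trace$intensities),
                       trace$intensities,
                       ifelse(is.na(trace$truth_state), "NA",
                              as.character(trace$truth_state))), con)
  } else {
    writeLines("frame\tintensity", con)
    writeLines(sprintf("%d\t%.6g", seq_along(trace$intensities),
                       trace$intensities), con)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  h <- .read_header(lines)
  if (is.null(h$meta$frame_time_s))
    stop("format error in ", path, ": missing header key frame_time_s")
  body <- lines[-seq_len(h$n_header)]
  body <- body[nzchar(body)]
  has_truth <- grepl("truth_state", body[1])
  body <- body[-1]
  parts <- strsplit(body, "\t")
  intens <- as.numeric(vapply(parts, `[`, "", 2))
  truth <- NULL
  if (has_truth) {
    tv <- vapply(parts, `[`, "", 3)
    truth <- factor(ifelse(tv == "NA", NA, tv),
                    levels = c("open", "closed"))
  }
  structure(list(intensities = intens, frame_time = h$meta$frame_time_s,
                 truth_state = truth, truth_frac_closed = NULL,
                 bleach_frame = NA_integer_, config = NULL,
                 seed = if (!is.null(h$meta$seed)) h$meta$seed else NA),
            class = "intensity_trace")
}

#' Write / read a profile dataset as a directory of decay files
#'
#' One decay file per (position, experiment, replicate), named
#' `decay_pos<P>_exp<E>_rep<R>.txt` (`pos` = `ctrl` for the control rows),
#' plus a `manifest.tsv` mapping file to position, experiment and
#' replicate.
#'
#' @param dataset a `profile_dataset` in decays mode.
#' @param dir output directory (created if missing).
#' @return `write_profile_dataset` the directory invisibly;
#'   `read_profile_dataset` a `profile_dataset`.
#' @export
write_profile_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "profile_dataset"))
  if (dataset$mode != "decays")
    stop("only decays-mode datasets can be written as decay files")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- dataset$table
  files <- sprintf("decay_pos%s_exp%d_rep%d.txt",
                   ifelse(is.na(tab$position), "ctrl",
                          sprintf("%02d", tab$position)),
                   tab$experiment, tab$replicate)
  for (i in seq_len(nrow(tab)))
    write_decay(dataset$decays[[i]], file.path(dir, files[i]))
  write_decay(dataset$irf, file.path(dir, "irf.txt"))
  con <- file(file.path(dir, "manifest.tsv"), "w")
  on.exit(close(con))
  .write_header(con, "manifest", list(seed = dataset$seed,
                                      n_experiments = dataset$config$n_experiments))
  writeLines("file\tposition\texperiment\treplicate", con)
  writeLines(sprintf("%s\t%s\t%d\t%d", files,
                     ifelse(is.na(tab$position), "NA", tab$position),
                     tab$experiment, tab$replicate), con)
  invisible(dir)
}

#' @rdname write_profile_dataset
#' @export
read_profile_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", dir)
  lines <- readLines(mf)
  h <- .read_header(lines)
  body <- lines[-seq_len(h$n_header)]
  body <- body[nzchar(body)][-1]
  parts <- strsplit(body, "\t")
  tab <- data.frame(
    position = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2))),
    experiment = as.integer(vapply(parts, `[`, "", 3)),
    replicate = as.integer(vapply(parts, `[`, "", 4)))
  files <- vapply(parts, `[`, "", 1)
  decays <- lapply(files, function(f) read_decay(file.path(dir, f)))
  irf <- read_decay(file.path(dir, "irf.txt"))
  positions <- sort(unique(tab$position[!is.na(tab$position)]))
  structure(list(table = tab, decays = decays, irf = irf,
                 instrument = NULL,
                 config = list(positions = positions,
                               n_experiments = length(unique(tab$experiment)),
                               n_decays_total = max(tab$replicate)),
                 mode = "decays", truth = NULL,
                 seed = if (!is.null(h$meta$seed)) h$meta$seed else NA),
            class = "profile_dataset")
}

#' Write a reconvolution fit report
#'
#' Key:value summary fields plus one row per component (tau_ns, alpha,
#' f_intensity), mirroring the layout of standard TCSPC fit tables.
#'
#' @param fit a `decay_fit`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "decay_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  gof <- goodness_of_fit(fit)
  .write_header(con, "fit_report", list(
    n_components = fit$n_components,
    chi2_reduced = fit$chi2_reduced,
    runs_test_p = gof$residual_randomness_p,
    background = fit$background,
    irf_shift_ns = fit$irf_shift,
    tau_amp_ns = amplitude_weighted_lifetime(fit),
    tau_int_ns = intensity_weighted_lifetime(fit),
    weighting = fit$weighting,
    collapsed_components = fit$collapsed))
  writeLines("component\ttau_ns\talpha\tf_intensity", con)
  f <- fractional_intensities(fit)
  writeLines(sprintf("%d\t%.6g\t%.6g\t%.6g", seq_len(fit$n_components),
                     fit$lifetimes, fit$amplitudes, f), con)
  invisible(path)
}

#' Molar absorption coefficient of Cy3 at 550 nm
#'
#' 150000 per molar per cm, the standard value used to compute dye
#' concentrations from absorbance.
#' @export
epsilon_cy3_550 <- 150000

#' Dye concentration by Beer-Lambert
#'
#' `c = A / (epsilon * l)`. Absorbance above 0.1 triggers an inner-filter
#' warning (quantitative fluorescence work keeps Cy3 absorbance at or
#' below 0.1).
#'
#' @param absorbance measured absorbance (dimensionless, >= 0).
#' @param epsilon molar absorption coefficient in 1/(M cm); default
#'   [epsilon_cy3_550].
#' @param path_length cuvette path length in cm (default 1).
#' @return concentration in mol/L.
#' @export
beer_lambert_concentration <- function(absorbance,
                                       epsilon = epsilon_cy3_550,
                                       path_length = 1) {
  if (epsilon <= 0 || path_length <= 0)
    stop("epsilon and path_length must be positive")
  if (any(absorbance < 0)) stop("absorbance must be >= 0")
  if (any(absorbance > 0.1))
    warning("absorbance > 0.1: inner-filter effects likely")
  absorbance / (epsilon * path_length)
}
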