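#' @include AllClasses.R
NULL

#' Write / read spectrometer frame streams as CSV
#'
#' Plain-text interchange with one frame per row: a \code{time_s} column
#' followed by one \code{I_<wavelength>} column per channel (RFU). The
#' dialect is fixed (comma separator, `.` decimal, header mandatory) so
#' golden files stay bit-stable. \code{readFrames()} validates the grid
#' declared by the header and reports malformed rows with their line
#' numbers.
#'
#' @param frames a [SpectralFrames] object.
#' @param path CSV file path.
#' @return \code{writeFrames()} returns \code{path} invisibly;
#'   \code{readFrames()} returns a [SpectralFrames].
#' @export
writeFrames <- function(frames, path) {
  stopifnot(is(frames, "SpectralFrames"))
  mat <- intensityMatrix(frames)
  df <- cbind(time_s = frameTimes(frames), as.data.frame(t(mat)))
  names(df) <- c("time_s", sprintf("I_%.1f", wavelengths(frames)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFrames
#' @export
readFrames <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty frames file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "time_s" || !all(grepl("^I_", header[-1])))
    stop("malformed frames header: expected time_s, I_<wavelength>, ...")
  wl <- as.numeric(sub("^I_", "", header[-1]))
  if (anyNA(wl) || any(diff(wl) <= 0))
    stop("header wavelengths must be numeric and strictly increasing")
  ncols <- length(header)
  n <- length(lines) - 1
  if (n == 0)
    return(SpectralFrames(matrix(0, length(wl), 0), wl, numeric(0)))
  vals <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(vals) != ncols)
  if (length(bad))
    stop("malformed frame row at line ", bad[1] + 1, ": expected ",
         ncols, " fields, found ", lengths(vals)[bad[1]])
  num <- suppressWarnings(as.numeric(unlist(vals)))
  if (anyNA(num)) {
    flat <- which(is.na(num))[1]
    stop("non-numeric cell at line ", (flat - 1) %/% ncols + 2,
         ", field ", (flat - 1) %% ncols + 1)
  }
  m <- matrix(num, nrow = ncols)
  SpectralFrames(m[-1, , drop = FALSE], wl, m[1, ])
}

#' Write / read droplet trains as JSONL
#'
#' One droplet record per line (streaming-friendly ground truth for later
#' scoring).
#'
#' @param train a [DropletTrain].
#' @param path JSONL file path.
#' @return \code{writeTrain()} returns \code{path} invisibly;
#'   \code{readTrain()} returns a [DropletTrain] (the generating config is
#'   not serialised).
#' @export
writeTrain <- function(train, path) {
  stopifnot(is(train, "DropletTrain"))
  df <- as.data.frame(train)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df)))
    writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  invisible(path)
}

#' @rdname writeTrain
#' @export
readTrain <- function(path) {
  lines <- readLines(path)
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed record at line ", i,
                                             ": ", conditionMessage(e)))
    as.data.frame(lapply(rec, function(v) if (is.null(v)) NA else v))
  })
  df <- do.call(rbind, rows)
  df$hyphal_exit_time <- as.numeric(df$hyphal_exit_time)
  new("DropletTrain", do.call(DataFrame, as.list(df)))
}

# known keys per run-config section: each section maps onto one
# constructor's formals
.config_sections <- function() list(
  sim = names(formals(simConfig)),
  detector = names(formals(detectorModel)),
  filter = names(formals(filterSettings)),
  criteria = names(formals(peakCriteria)),
  gate = names(formals(gate)),
  timing = names(formals(timingModel)),
  pulse = names(formals(pulseSettings)))

#' Validate, read and write run configurations
#'
#' A run configuration is a named list with sections \code{sim},
#' \code{detector}, \code{filter}, \code{criteria}, \code{gate},
#' \code{timing} and \code{pulse} (each holding arguments of the matching
#' constructor) plus an optional top-level \code{seed}. Unknown sections or
#' keys are rejected -- a typo never silently becomes a default.
#' Configurations round-trip losslessly through YAML.
#'
#' @param config a run-configuration list.
#' @param path YAML file path.
#' @return \code{validateRunConfig()} returns the config invisibly (or
#'   errors); \code{readRunConfig()} the validated list;
#'   \code{writeRunConfig()} the path invisibly; \code{buildRunObjects()}
#'   a list of constructed S4 settings objects.
#' @export
validateRunConfig <- function(config) {
  schema <- .config_sections()
  known_top <- c(names(schema), "seed")
  extra <- setdiff(names(config), known_top)
  if (length(extra))
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "))
  for (sec in intersect(names(config), names(schema))) {
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  invisible(config)
}

#' @rdname validateRunConfig
#' @export
readRunConfig <- function(path) {
  validateRunConfig(yaml::read_yaml(path))
}

#' @rdname validateRunConfig
#' @export
writeRunConfig <- function(config, path) {
  validateRunConfig(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname validateRunConfig
#' @export
buildRunObjects <- function(config) {
  validateRunConfig(config)
  build <- function(fun, args) do.call(fun, args %||% list())
  `%||%` <- function(a, b) if (is.null(a)) b else a
  list(sim = build(simConfig, config$sim),
       detector = build(detectorModel, config$detector),
       filter = build(filterSettings, config$filter),
       criteria = build(peakCriteria, config$criteria),
       gate = build(gate, config$gate),
       timing = build(timingModel, config$timing),
       pulse = build(pulseSettings, config$pulse),
       seed = if (is.null(config$seed)) 1L else as.integer(config$seed))
}

#' Generate canonical seeded fixtures
#'
#' Writes the experiment-shaped test inputs to \code{dir}:
#' \describe{
#'   \item{calibration_5_50uM}{two frame streams of fluorescein standard
#'     droplets (5 and 50 uM) for gate calibration, plus their truth
#'     files.}
#'   \item{mixed_pos_neg}{one stream mixing fluorescein positives with
#'     dye-only negatives, plus truth.}
#'   \item{mutant_library}{a short incubated mutant-library session
#'     stream, plus truth.}
#'   \item{efficiency_grid}{the 7 x 20 sorter characterization grid, 10
#'     attempts per cell, as CSV.}
#' }
#' Identical name and seed always produce identical files.
#'
#' @param name fixture name.
#' @param dir output directory.
#' @param seed integer seed.
#' @param n droplets per population (streams) -- the calibration design
#'   records 500 peaks per concentration; smaller values keep files small.
#' @return character vector of written paths.
#' @export
makeFixture <- function(name = c("calibration_5_50uM", "mixed_pos_neg",
                                 "mutant_library", "efficiency_grid"),
                        dir = ".", seed = 1L, n = 500) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown fixture name '", name[1], "'; valid names: ",
         "calibration_5_50uM, mixed_pos_neg, mutant_library, efficiency_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- detectorModel()
  paths <- character()
  stream_files <- function(train, stem, s) {
    fr <- synthesizeFrames(train, det, seed = s)
    f1 <- file.path(dir, paste0(stem, "_frames.csv"))
    f2 <- file.path(dir, paste0(stem, "_truth.jsonl"))
    writeFrames(fr, f1)
    writeTrain(train, f2)
    c(f1, f2)
  }
  if (name == "calibration_5_50uM") {
    for (conc in c(5, 50)) {
      tr <- simulateMixedTrain(n, posFraction = 1, posUM = conc,
                               seed = seed + conc)
      paths <- c(paths, stream_files(tr, sprintf("calibration_%duM", conc),
                                     seed + conc))
    }
  } else if (name == "mixed_pos_neg") {
    tr <- simulateMixedTrain(n, posFraction = 0.1, posUM = 5, seed = seed)
    paths <- stream_files(tr, "mixed_pos_neg", seed)
  } else if (name == "mutant_library") {
    cfg <- simConfig(sessionLength = (n + 1) / 7, seed = seed)
    tr <- simulateDropletTrain(cfg)
    paths <- stream_files(tr, "mutant_library", seed)
  } else {
    g <- efficiencyGrid(seed = seed)
    f <- file.path(dir, "efficiency_grid.csv")
    write.csv(g, f, row.names = FALSE, quote = FALSE)
    paths <- f
  }
  paths
}
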