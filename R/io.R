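#' Write feature codes as bitstring text
#'
#' One line per code: a 32-character 0/1 string, a space, and the class label
#' (\code{NA} for unlabelled test codes).
#'
#' @param codes list of \code{\link{feature_code}} objects or 0/1 vectors.
#' @param path output file.
#' @param classes optional class labels (overrides labels carried by codes).
#' @export
write_codes <- function(codes, path, classes = NULL) {
  cls <- codes_classes(codes, classes)
  lines <- vapply(seq_along(cls), function(i) {
    bits <- as_bits(codes_to_list(codes)[[i]])
    paste(paste(bits, collapse = ""), cls[i])
  }, character(1))
  writeLines(lines, path)
}

#' Read feature codes from bitstring text
#'
#' @param path file written by \code{\link{write_codes}}.
#' @return List of \code{\link{feature_code}} objects.
#' @export
read_codes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    bits <- as.integer(strsplit(parts[1], "")[[1]])
    cls <- if (length(parts) > 1 && parts[2] != "NA") parts[2] else NA_character_
    feature_code(bits, cls)
  })
}

#' Write a crossbar conductance matrix as delimited text
#'
#' Tab-separated, 6 rows x 32 columns, preceded by comment lines recording
#' the conductance bounds and units.
#'
#' @param xbar a \code{\link{crossbar}}.
#' @param path output file.
#' @export
write_crossbar <- function(xbar, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# crossbar conductances, units nA/V, g_min=%g g_max=%g",
                     xbar$params$g_min, xbar$params$g_max), con)
  utils::write.table(xbar$G, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
}

#' Read a crossbar conductance matrix written by \code{\link{write_crossbar}}
#'
#' @param path input file.
#' @param params a \code{\link{device_params}}.
#' @param config a \code{\link{learning_config}}; dimensions are taken from
#'   the file.
#' @return A \code{\link{crossbar}}.
#' @export
read_crossbar <- function(path, params = device_params(),
                          config = learning_config()) {
  G <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(G) <- NULL
  config$n_post <- nrow(G)
  config$n_pre <- ncol(G)
  xb <- init_crossbar(config, params)
  if (any(G < params$g_min - 1e-9) || any(G > params$g_max + 1e-9))
    stop("stored conductances violate the device bounds")
  xb$G <- G
  xb
}

#' Write a pulse-train table (pulse index, conductance)
#'
#' @param g conductance sequence from \code{\link{pulse_train}}.
#' @param path output file.
#' @export
write_pulse_train <- function(g, path) {
  utils::write.table(data.frame(pulse = seq_along(g), conductance = g),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Write integrator traces (time, six voltages) as delimited text
#'
#' @param trial result of \code{\link{run_trial}}.
#' @param path output file.
#' @export
write_traces <- function(trial, path) {
  df <- data.frame(time = trial$time, trial$traces)
  names(df) <- c("time", paste0("neuron", seq_len(ncol(trial$traces))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Serialize a parameter set to a key-value YAML file
#'
#' Round-trips \code{\link{device_params}}, \code{\link{learning_config}},
#' \code{\link{neuron_params}} and the generator configs losslessly.
#'
#' @param x a parameter object (classed list).
#' @param path output file.
#' @export
write_config <- function(x, path) {
  yaml::write_yaml(c(list(.class = class(x)[1]), unclass(x)), path,
                   precision = 15)
}

#' Read a parameter set written by \code{\link{write_config}}
#'
#' @param path input file.
#' @return The parameter object with its original class.
#' @export
read_config <- function(path) {
  v <- yaml::read_yaml(path)
  cls <- v$.class
  v$.class <- NULL
  v <- lapply(v, function(f) if (is.list(f)) unlist(f) else f)
  structure(v, class = cls)
}
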