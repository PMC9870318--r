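.trace_schema_version <- "1.0"

#' Write and read trace containers
#'
#' The internal trace container is a directory holding `traces.csv` (long
#' format: `neuron_id`, `protocol`, `step`, `time_ms`, `command`,
#' `response`) and a JSON manifest with the schema version, per-protocol
#' mode and declared units. Doubles are written with 17 significant digits,
#' so `read_traces(write_traces(x))` reproduces `x` to full float
#' precision. Units are validated on read — a container whose declared
#' units do not match its protocol mode is rejected with the offending
#' protocol named, never silently converted.
#'
#' @param sims Long sweep tibble (as from [simulate_neuron()], with or
#'   without `neuron_id`).
#' @param path Directory to create/write.
#' @param protocols Named protocol list describing the sweeps ("rmp" traces
#'   are treated as current clamp).
#' @return `write_traces()`: the path, invisibly. `read_traces()`: the sweep
#'   tibble.
#' @export
write_traces <- function(sims, path, protocols = default_protocols()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!"neuron_id" %in% names(sims))
    sims <- mutate(sims, neuron_id = "neuron", .before = 1)
  cols <- c("neuron_id", "protocol", "step", "time_ms", "command", "response")
  miss <- setdiff(setdiff(cols, "neuron_id"), names(sims))
  if (length(miss))
    abort(paste0("sweep table lacks columns: ", paste(miss, collapse = ", ")))
  sims <- sims[cols]
  proto_meta <- purrr::imap(protocols, function(pr, nm) {
    u <- expected_units(pr$mode)
    list(mode = pr$mode, holding = pr$holding,
         step_onset = pr$step_onset, step_duration = pr$step_duration,
         post_window = pr$post_window,
         units = list(command = u$command, response = u$response,
                      time = "ms"))
  })
  proto_meta$rmp <- list(mode = "current_clamp",
                         units = list(command = "pA", response = "mV",
                                      time = "ms"))
  manifest <- list(schema_version = .trace_schema_version,
                   n_neurons = dplyr::n_distinct(sims$neuron_id),
                   protocols = proto_meta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # doubles as 17 significant digits: exact binary round trip through strtod
  out <- sims
  for (cn in c("step", "time_ms", "command", "response"))
    out[[cn]] <- sprintf("%.17g", sims[[cn]])
  utils::write.csv(out, file.path(path, "traces.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  mf <- file.path(path, "manifest.json")
  tf <- file.path(path, "traces.csv")
  if (!file.exists(mf) || !file.exists(tf))
    abort("not a trace container: missing manifest.json or traces.csv")
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$schema_version, .trace_schema_version))
    abort(sprintf("schema version mismatch: file has %s, reader expects %s",
                  manifest$schema_version %||% "<none>",
                  .trace_schema_version))
  for (nm in names(manifest$protocols)) {
    p <- manifest$protocols[[nm]]
    exp <- expected_units(p$mode)
    got <- p$units
    if (!identical(got$response, exp$response) ||
        !identical(got$command, exp$command))
      abort(sprintf(
        "unit mismatch in protocol '%s': declared %s/%s, %s requires %s/%s",
        nm, got$command %||% "<none>", got$response %||% "<none>",
        p$mode, exp$command, exp$response))
  }
  sims <- as_tibble(utils::read.csv(
    tf, colClasses = c(neuron_id = "character", protocol = "character",
                       step = "numeric", time_ms = "numeric",
                       command = "numeric", response = "numeric")))
  known <- names(manifest$protocols)
  bad <- setdiff(unique(sims$protocol), known)
  if (length(bad))
    abort(paste0("traces reference undeclared protocol(s): ",
                 paste(bad, collapse = ", ")))
  sims
}

#' Feature table round trip
#'
#' One row per neuron, one column per named feature; missing values are
#' written as explicit `NA` cells.
#'
#' @param features Feature tibble.
#' @param path TSV path.
#' @return The path (write) or the tibble (read).
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}

#' Match sweeps to a protocol by their command waveform
#'
#' Assigns each sweep its protocol and step amplitude by comparing the
#' command waveform's step plateau against the protocols' amplitude lists,
#' tolerant to small command dither. Unmatched sweeps are kept and reported
#' (`matched = FALSE`), never silently dropped.
#'
#' @param sweeps Tibble with `sweep_id`, `time_ms`, `command` (and anything
#'   else); one sweep per `sweep_id`.
#' @param protocols Named protocol list to match against.
#' @param tol Amplitude tolerance (pA or mV).
#' @return Tibble `sweep_id`, `protocol`, `step`, `matched`.
#' @export
match_protocol <- function(sweeps, protocols = default_protocols(), tol = 2) {
  purrr::map(split(sweeps, sweeps$sweep_id), function(sw) {
    base <- median(head(sw$command, 20))
    dev <- sw$command - base
    amp_max <- max(abs(dev))
    amp <- if (amp_max < tol / 2) 0 else
      median(dev[abs(dev) > amp_max / 2])
    hit <- NULL
    for (nm in names(protocols)) {
      d <- abs(protocols[[nm]]$amplitudes - amp)
      if (min(d) <= tol) {
        hit <- tibble(protocol = nm,
                      step = protocols[[nm]]$amplitudes[which.min(d)])
        break
      }
    }
    if (is.null(hit)) {
      tibble(sweep_id = sw$sweep_id[1], protocol = NA_character_,
             step = NA_real_, matched = FALSE)
    } else {
      tibble(sweep_id = sw$sweep_id[1], protocol = hit$protocol,
             step = hit$step, matched = TRUE)
    }
  }) |>
    purrr::list_rbind()
}
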