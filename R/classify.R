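#' Recording-quality exclusion criteria
#'
#' A neuron is excluded when its resting membrane potential is more positive
#' than -50 mV (strict inequality: exactly -50 mV is kept) or when it fired
#' no spike at any depolarizing step of the excitability protocol.
#'
#' @param features Per-neuron feature tibble from [extract_features()]
#'   (needs `rmp` and `max_evoked`).
#' @param rmp_cutoff Exclusion cutoff (mV).
#' @return The input with logical `excluded` and character
#'   `exclusion_reason` columns.
#' @export
apply_exclusion <- function(features, rmp_cutoff = -50) {
  features |>
    mutate(
      .rmp_bad = !is.na(.data$rmp) & .data$rmp > rmp_cutoff,
      .silent = is.na(.data$max_evoked) | .data$max_evoked == 0,
      excluded = .data$.rmp_bad | .data$.silent,
      exclusion_reason = dplyr::case_when(
        .data$.rmp_bad ~ sprintf("RMP more positive than %g mV", rmp_cutoff),
        .data$.silent ~ "no spikes in excitability protocol",
        TRUE ~ NA_character_)) |>
    select(-".rmp_bad", -".silent")
}

#' Rule-based neuron-type classification
#'
#' Applies the visual-classification rules for the four intrinsic phenotypes,
#' in fixed order, to each non-excluded neuron:
#'
#' 1. **Others** — no spikes at any excitability step below
#'    `others_current_threshold` (default +30 pA) *and* at most
#'    `others_max_spikes` evoked spikes (default 1) at any step: a cell that
#'    only fires a single late spike at larger current injections.
#' 2. **Type II** — at least one rebound spike after the -80 pA step.
#'    Rebound spiking is exclusive to Type II, so this rule precedes the sag
#'    rule; a rebound neuron without sag is still Type II (flagged in the
#'    rationale).
#' 3. **Type I** — voltage sag at -80 pA of at least `sag_threshold` mV
#'    (default 3 mV; the sag/no-sag boundary is a tunable threshold since
#'    sag presence is judged visually at the rig).
#' 4. **Type III** — otherwise (no sag, no rebound).
#'
#' @param features Feature tibble from [extract_features()], with exclusion
#'   columns from [apply_exclusion()] (added here when absent).
#' @param sag_threshold Sag-presence threshold (mV) at -80 pA.
#' @param others_current_threshold Step (pA) below which an "Others" neuron
#'   must be silent.
#' @param others_max_spikes Maximum evoked spikes per step for "Others".
#' @return The input tibble with `label` (`"I"`, `"II"`, `"III"`,
#'   `"Others"`, `"Excluded"`) and `rationale` columns.
#' @export
classify_neurons <- function(features, sag_threshold = 3,
                             others_current_threshold = 30,
                             others_max_spikes = 1) {
  if (!"excluded" %in% names(features))
    features <- apply_exclusion(features)
  need <- c("sag_80", "rebound_80", "max_evoked", "min_firing_step")
  miss <- setdiff(need, names(features))
  if (length(miss))
    abort(paste0("classification requires features: ",
                 paste(miss, collapse = ", ")))

  classify_one <- function(excluded, reason, sag, reb, maxev, minstep) {
    if (isTRUE(excluded))
      return(c("Excluded", reason))
    bad <- c(sag = sag, rebound = reb, max_evoked = maxev)
    if (any(is.na(bad)))
      abort(paste0("required features missing: ",
                   paste(names(bad)[is.na(bad)], collapse = ", ")))
    if (minstep >= others_current_threshold && maxev <= others_max_spikes)
      return(c("Others", sprintf(
        "silent below %g pA, at most %g spike(s) per step",
        others_current_threshold, others_max_spikes)))
    if (reb >= 1)
      return(c("II", if (sag >= sag_threshold)
        "rebound spikes with sag" else "rebound spikes without sag"))
    if (sag >= sag_threshold)
      return(c("I", sprintf("sag %.1f mV >= %g mV, no rebound",
                            sag, sag_threshold)))
    c("III", "no sag, no rebound")
  }
  res <- purrr::pmap(
    list(features$excluded, features$exclusion_reason, features$sag_80,
         features$rebound_80, features$max_evoked,
         features$min_firing_step),
    classify_one)
  features |>
    mutate(label = purrr::map_chr(res, 1),
           rationale = purrr::map_chr(res, 2))
}

#' Per-type proportions of classified neurons
#'
#' Percentages are computed over the non-excluded neurons and reported to
#' two decimals; they sum to 100 up to rounding.
#'
#' @param labels Character vector of labels, or a tibble with a `label`
#'   column. `"Excluded"` entries are dropped from the denominator.
#' @return Tibble with `label`, `n`, `pct` for the four types, plus the
#'   total in `attr(, "total")`.
#' @examples
#' proportions_by_type(rep(c("I", "II", "III", "Others"), c(67, 25, 28, 13)))
#' @export
proportions_by_type <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- labels[labels != "Excluded"]
  total <- length(labels)
  out <- tibble(label = .phenotypes) |>
    mutate(n = purrr::map_int(.data$label, ~ sum(labels == .x)),
           pct = if (total > 0) round(100 * .data$n / total, 2) else 0)
  attr(out, "total") <- total
  out
}
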