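#' Phenotype parameter templates
#'
#' Returns the ground-truth model parameters for one of the four intrinsic
#' phenotypes. The templates encode the qualitative contrasts that define the
#' types in slice recordings of VTA-projecting BNST neurons:
#'
#' * **Type I** — voltage sag (moderate Ih, half-activation ~ -85 mV), no
#'   rebound current, regular firing.
#' * **Type II** — sag plus a low-threshold inactivating current (`g_t`) that
#'   is de-inactivated by hyperpolarization and fires a rebound burst on
#'   release; highest input resistance, earliest depolarization block.
#' * **Type III** — essentially no Ih (`g_h` below any sag-producing level),
#'   no rebound.
#' * **Others** — late-firing cells: a slowly inactivating K current (`g_d`)
#'   suppresses firing below ~ +30 pA and keeps evoked spiking to a single
#'   late spike; large capacitance, hyperpolarized resting potential, and a
#'   large Ih that only activates below ~ -100 mV, so it produces a large
#'   clamp current at -140 mV without any current-clamp sag.
#'
#' Units: capacitance pF, conductances nS, voltages mV, times ms,
#' currents pA.
#'
#' @param phenotype One of `"I"`, `"II"`, `"III"`, `"Others"`.
#' @return Named numeric vector of model parameters.
#' @export
phenotype_template <- function(phenotype) {
  phenotype <- match.arg(phenotype, .phenotypes)
  shared <- c(
    e_h = -40, e_t = 120, e_k = -90,
    tm_half = -50, tm_slope = 5,
    th_half = -80, th_slope = 4, tau_th_gate = 100,
    da_half = -65, da_slope = 5,
    db_half = -55, db_slope = 6, tau_db = 2000,
    v_spike = 40, tau_filt = 5)
  own <- switch(phenotype,
    I = c(c_m = 80, g_l = 1.8, e_l = -65,
          g_h = 1.6, h_half = -85, h_slope = 6, tau_h = 90,
          g_t = 0, g_d = 0,
          theta0 = -55, d_theta = 10, tau_theta = 70,
          v_reset = -58, t_ref = 4, b_w = 25, tau_w = 200, v_block = -25),
    II = c(c_m = 60, g_l = 1.0, e_l = -63,
           g_h = 0.5, h_half = -95, h_slope = 6, tau_h = 120,
           g_t = 4, g_d = 0,
           theta0 = -55, d_theta = 5, tau_theta = 150,
           v_reset = -56, t_ref = 4, b_w = 15, tau_w = 200, v_block = -30),
    III = c(c_m = 75, g_l = 1.6, e_l = -66,
            g_h = 0.05, h_half = -85, h_slope = 6, tau_h = 120,
            g_t = 0, g_d = 0,
            theta0 = -55, d_theta = 13, tau_theta = 65,
            v_reset = -58, t_ref = 4, b_w = 20, tau_w = 200, v_block = -22),
    Others = c(c_m = 110, g_l = 2.5, e_l = -74,
               g_h = 4.0, h_half = -110, h_slope = 8, tau_h = 150,
               g_t = 0, g_d = 8,
               theta0 = -55, d_theta = 3, tau_theta = 300,
               v_reset = -58, t_ref = 2.5, b_w = 30, tau_w = 600,
               v_block = -15))
  c(own, shared)
}

# parameters receiving multiplicative lognormal jitter
.jitter_lognormal <- c("c_m", "g_l", "g_h", "g_t", "g_d")
# cap keeping a jittered Type III below any sag-producing Ih level
.gh_sag_free_cap <- 0.3

#' Generate a synthetic cohort with ground-truth labels
#'
#' Draws `n_per_type` neurons per phenotype from the templates of
#' [phenotype_template()], applying per-neuron parameter jitter:
#' multiplicative lognormal (sd `jitter` on the log scale) on capacitance and
#' all conductances, additive Gaussian (sd `15 * jitter` mV) on the leak
#' reversal. Jitter is clipped so that it never flips a template constraint
#' (a Type III neuron never acquires a sag-producing Ih; zero conductances
#' stay zero). Each neuron also receives a recording position along the
#' rostro-caudal axis (mm from bregma).
#'
#' @param n_per_type Named or positional integer vector of counts for
#'   Types I, II, III, Others.
#' @param jitter Lognormal sd of the multiplicative parameter jitter.
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return A tibble with one row per neuron: `neuron_id`, `phenotype`
#'   (ground truth), `ap_position` and one column per model parameter.
#' @examples
#' cohort <- make_cohort(c(2, 2, 2, 2), jitter = 0.1, seed = 1)
#' @export
make_cohort <- function(n_per_type = c(I = 30, II = 30, III = 30, Others = 30),
                        jitter = 0.1, seed = 1) {
  if (length(n_per_type) != 4) abort("`n_per_type` must have four counts")
  if (any(n_per_type < 0)) abort("`n_per_type` counts must be non-negative")
  if (jitter < 0) abort("`jitter` must be non-negative")
  n_per_type <- setNames(as.integer(n_per_type), .phenotypes)

  set.seed(as.integer(seed))
  rows <- purrr::map(.phenotypes, function(ph) {
    n <- n_per_type[[ph]]
    if (n == 0) return(NULL)
    tmpl <- phenotype_template(ph)
    purrr::map(seq_len(n), function(i) {
      p <- tmpl
      if (jitter > 0) {
        p[.jitter_lognormal] <- p[.jitter_lognormal] *
          rlnorm(length(.jitter_lognormal), 0, jitter)
        p["e_l"] <- p["e_l"] + rnorm(1, 0, 15 * jitter)
      }
      if (ph == "III") p["g_h"] <- min(p["g_h"], .gh_sag_free_cap)
      pos <- sample(c(0.26, 0.14, 0.02, -0.10), 1,
                    prob = c(0.15, 0.35, 0.35, 0.15))
      c(list(phenotype = ph, ap_position = pos), as.list(p))
    })
  })
  cohort <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(cohort) == 0) {
    return(tibble(neuron_id = character(), phenotype = character(),
                  ap_position = numeric()))
  }
  cohort |>
    mutate(neuron_id = sprintf("n%03d", dplyr::row_number()),
           .before = 1)
}

# one cohort row -> named parameter vector for the integrator
cohort_params <- function(row) {
  stopifnot(nrow(row) == 1)
  p <- row |> select(-dplyr::any_of(c("neuron_id", "phenotype", "ap_position")))
  unlist(p)
}
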