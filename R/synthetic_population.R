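#' @title Conditions and markers known to the synthetic generator
#' @description Experimental conditions emulated by the generator:
#' untreated control, siRNA depletion of BRCA1 or BARD1, the SUV4-20H1/2
#' inhibitor A-196 (blocks H4K20me2 restoration on replicated chromatin),
#' and a BRCA1-mutant line.
#' @keywords internal
#' @name qibc_conditions
QIBC_CONDITIONS <- c("control", "siBRCA1", "siBARD1", "A196", "BRCA1mut")
QIBC_MARKERS <- c("53BP1", "gammaH2AX", "RAD51", "BRCA1")
QIBC_PHASES <- c("G1", "S", "G2")

#' Focus-formation model parameters
#'
#' Parameterizes the expected number of ionizing-radiation-induced foci per
#' cell as a function of DNA content. The genome of a cell with DNA content
#' \eqn{c \in [2, 4]} N-equivalents splits into unreplicated chromatin
#' (\eqn{4 - c} N) and replicated chromatin (\eqn{2(c - 2)} N: template plus
#' nascent copy). Each unreplicated N contributes `base_rate_per_N` expected
#' foci; each replicated N contributes a fraction `1 - decline_strength` of
#' that, modeling the suppression of focus formation (53BP1 in particular)
#' on post-replicative chromatin. `decline_strength = 0` gives strict
#' proportionality to DNA content, the behavior of gammaH2AX.
#'
#' Condition modifiers multiply the base rate, the decline strength, and the
#' replicated-chromatin term: BRCA1/BARD1 depletion attenuates (halves) the
#' decline without abolishing it; A-196 depresses 53BP1 focus formation
#' preferentially on replicated chromatin, leaving a residual signal.
#'
#' @param marker focus marker channel, one of `"53BP1"`, `"gammaH2AX"`,
#'   `"RAD51"`, `"BRCA1"`.
#' @param condition experimental condition (see `QIBC_CONDITIONS`).
#' @param base_rate_per_N expected foci per genome equivalent on
#'   unreplicated chromatin; default 5 (about 10 foci in a G1 cell,
#'   an early-timepoint load after ~0.5 Gy).
#' @param decline_strength fraction in `[0, 1]` by which the per-N focus
#'   propensity falls from unreplicated to fully replicated chromatin.
#'   Default: 0.6 for 53BP1, 0 otherwise.
#' @param condition_modifiers named list of per-condition multipliers, each
#'   a list with elements `rate`, `decline`, `replicated`.
#' @return an object of class `focus_model_params`.
#' @seealso [expected_focus_count()]
#' @export
focus_model_params <- function(marker = c("53BP1", "gammaH2AX", "RAD51", "BRCA1"),
                               condition = "control",
                               base_rate_per_N = 5,
                               decline_strength = NULL,
                               condition_modifiers = NULL) {
  marker <- match.arg(marker)
  condition <- match.arg(condition, QIBC_CONDITIONS)
  assert_scalar_number(base_rate_per_N, "base_rate_per_N", positive = TRUE)
  if (is.null(decline_strength))
    decline_strength <- if (marker == "53BP1") 0.6 else 0
  assert_scalar_number(decline_strength, "decline_strength")
  if (decline_strength < 0 || decline_strength > 1)
    stopf("'decline_strength' must lie in [0, 1]")
  if (is.null(condition_modifiers))
    condition_modifiers <- default_condition_modifiers(marker)
  mod <- condition_modifiers[[condition]] %||%
    list(rate = 1, decline = 1, replicated = 1)
  mod$rate <- mod$rate %||% 1
  mod$decline <- mod$decline %||% 1
  mod$replicated <- mod$replicated %||% 1
  if (mod$rate <= 0 || mod$replicated <= 0)
    stopf("condition multipliers must keep all rates strictly positive")
  structure(
    list(marker = marker, condition = condition,
         base_rate_per_N = base_rate_per_N,
         decline_strength = decline_strength,
         condition_modifiers = condition_modifiers,
         rate_eff = base_rate_per_N * mod$rate,
         decline_eff = min(decline_strength * mod$decline, 1),
         replicated_eff = mod$replicated),
    class = "focus_model_params")
}

# BRCA1-BARD1 loss halves the decline (present but weaker); A-196 halves
# the replicated-chromatin contribution of 53BP1 (reduced, never abolished).
default_condition_modifiers <- function(marker) {
  base <- list(rate = 1, decline = 1, replicated = 1)
  mods <- list(control = base, siBRCA1 = base, siBARD1 = base,
               A196 = base, BRCA1mut = base)
  mods$siBRCA1$decline <- 0.5
  mods$siBARD1$decline <- 0.5
  mods$BRCA1mut$decline <- 0.5
  if (marker == "53BP1") mods$A196$replicated <- 0.5
  mods
}

#' Expected focus count for a cell
#'
#' Evaluates the focus-rate model
#' \deqn{\lambda(c) = r \left[(4 - c) + 2 m (1 - d)(c - 2)\right]}
#' where \eqn{c} is DNA content in N-equivalents (clamped to `[2, 4]`),
#' \eqn{r} the effective per-N rate, \eqn{d} the effective decline strength
#' and \eqn{m} the replicated-chromatin condition multiplier. At `d = 0`,
#' `m = 1` this reduces to \eqn{\lambda = r c}: strict proportionality to
#' DNA content, so a 4N cell carries exactly twice the expected foci of a
#' 2N cell. At `d > 0` the expectation declines monotonically with the
#' replicated fraction: \eqn{\lambda(4N)/\lambda(2N) = 2 m (1 - d)}.
#'
#' @param state a `data.frame` with a `dna_content` column (as returned by
#'   [sample_population()]) or a numeric vector of DNA contents in
#'   N-equivalents.
#' @param params a [focus_model_params()] object.
#' @return numeric vector of expected focus counts (Poisson means).
#' @export
expected_focus_count <- function(state, params) {
  if (!inherits(params, "focus_model_params"))
    stopf("'params' must be a focus_model_params object")
  dna <- if (is.data.frame(state)) state$dna_content else state
  if (!is.numeric(dna) || anyNA(dna))
    stopf("DNA content must be numeric and non-missing")
  c_ <- pmin(pmax(dna, 2), 4)
  r <- params$rate_eff
  d <- params$decline_eff
  m <- params$replicated_eff
  r * ((4 - c_) + 2 * m * (1 - d) * (c_ - 2))
}

#' Sample a synthetic asynchronous cell population
#'
#' Draws per-cell cell-cycle states emulating an asynchronous U-2 OS-like
#' population: phases multinomial with the given fractions, S-phase progress
#' uniform on `[0, 1]`, DNA content walking from 2N to 4N through S, an
#' EdU-positive S-phase arc, Cyclin A accumulating through S into G2, and
#' H4K20me2 per unit DNA maximal in G1, diluted through replication and
#' partially restored in G2. All marker levels carry lognormal
#' multiplicative noise.
#'
#' @param n_cells number of cells (>= 1).
#' @param phase_fractions numeric simplex over `c(G1, S, G2)` (named or in
#'   that order); must sum to 1 within 1e-9.
#' @param condition experimental condition label attached to every cell.
#' @param seed integer seed; identical seeds give identical populations.
#' @param marker_cv coefficient of variation of the lognormal marker noise
#'   (default 0.15).
#' @param dna_cv coefficient of variation of the measured DNA content
#'   around its cell-cycle expectation (default 0.05, the tight spread of a
#'   well-stained DAPI profile).
#' @return a `data.frame` with one row per cell: `cell_id`, `phase`,
#'   `s_progress`, `dna_content` (noisy, in N-equivalents, kept inside
#'   (1.5, 5)), `dna_content_true` (noiseless), `edu_level`,
#'   `cyclinA_level`, `h4k20me2_level` (arbitrary units), `condition`.
#' @export
sample_population <- function(n_cells,
                              phase_fractions = c(G1 = 0.5, S = 0.3, G2 = 0.2),
                              condition = "control",
                              seed = 1L,
                              marker_cv = 0.15,
                              dna_cv = 0.05) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != round(n_cells))
    stopf("'n_cells' must be a positive integer")
  fr <- as.numeric(phase_fractions)
  if (length(fr) != 3L || any(!is.finite(fr)) || any(fr < 0) ||
      abs(sum(fr) - 1) > 1e-9)
    stopf("'phase_fractions' must be 3 non-negative numbers summing to 1")
  if (!is.null(names(phase_fractions))) {
    if (!setequal(names(phase_fractions), QIBC_PHASES))
      stopf("named 'phase_fractions' must use names G1, S, G2")
    fr <- as.numeric(phase_fractions[QIBC_PHASES])
  }
  condition <- match.arg(condition, QIBC_CONDITIONS)
  set.seed(as.integer(seed))
  n <- as.integer(n_cells)
  phase <- sample(QIBC_PHASES, n, replace = TRUE, prob = fr)
  s_progress <- ifelse(phase == "S", runif(n), ifelse(phase == "G2", 1, 0))
  dna_true <- 2 + 2 * s_progress * (phase == "S") + 2 * (phase == "G2")
  dna <- pmin(pmax(dna_true * rlnorm_cv(n, dna_cv), 1.55), 4.9)

  edu_mean <- ifelse(phase == "S", 10, 1)
  edu <- edu_mean * rlnorm_cv(n, marker_cv)

  cycA_mean <- ifelse(phase == "G1", 1,
                      ifelse(phase == "S", 1 + 4 * s_progress, 6))
  cycA <- cycA_mean * rlnorm_cv(n, marker_cv)

  # H4K20me2 per N: 1.0 in G1, diluted to 0.35 at the end of S by
  # incorporation of unmethylated H4, partially restored (0.6) in G2
  me2_per_N <- ifelse(phase == "G1", 1,
                      ifelse(phase == "S", 1 - 0.65 * s_progress, 0.6))
  me2 <- me2_per_N * dna * rlnorm_cv(n, marker_cv)

  data.frame(cell_id = seq_len(n),
             phase = phase,
             s_progress = s_progress,
             dna_content = dna,
             dna_content_true = dna_true,
             edu_level = edu,
             cyclinA_level = cycA,
             h4k20me2_level = me2,
             condition = condition,
             stringsAsFactors = FALSE)
}
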