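#' Evaluate the 19 reaction rates
#'
#' Evaluates every rate law of the model at a given state. Negative state
#' entries (which a stiff solver may step into transiently) are clamped to
#' zero before evaluation, so the rate vector is always defined and
#' non-negative. `r13` is the constant specific death rate `k13A`.
#'
#' The NADH-coupled reductions use ping-pong kinetics with the constants in
#' their printed per-reaction arrangement: for r11 and r14 the `kA` constant
#' multiplies NADH and `kB` the carbon substrate; for r19 `kA` multiplies
#' butyryl-CoA and `kB` NADH, with butanol as competitive inhibitor (`kC`).
#'
#' @param state Named state vector over [abe_species()] (mM).
#' @param params An [abe_parameters] set (complete; a missing constant raises
#'   an error naming the reaction).
#' @return Named numeric vector `r1` ... `r19` of specific rates (h^-1).
#' @export
#' @examples
#' compute_rates(abe_initial("shinto"), abe_fit("A"))
compute_rates <- function(state, params) {
  validate_complete(params)
  state <- state[abe_species()]
  if (any(!is.finite(state))) abort("State concentrations must be finite.")
  s <- pmax(as.numeric(state), 0)
  p <- function(rx, const) params[[const]][match(rx, params$reaction)]
  G <- s[1]; F6P <- s[2]; G3P <- s[3]; Pyr <- s[4]; Lac <- s[5]
  ACoA <- s[6]; Ac <- s[8]; AACoA <- s[10]; AcAc <- s[11]
  BCoA <- s[12]; Buty <- s[13]; BuOH <- s[15]; NADH <- s[16]

  r <- c(
    r1  = glucose_uptake_rate(p("r1", "V"), p("r1", "kA"), p("r1", "kB"),
                              p("r1", "kC"), G, BuOH),
    r2  = mm_rate(p("r2", "V"), p("r2", "kA"), F6P),
    r3  = mm_rate(p("r3", "V"), p("r3", "kA"), G3P),
    r4  = mm_rate(p("r4", "V"), p("r4", "kA"), Lac),
    r5  = mm_rate(p("r5", "V"), p("r5", "kA"), Pyr),
    r6  = mm_rate(p("r6", "V"), p("r6", "kA"), Pyr),
    r7  = mm_rate(p("r7", "V"), p("r7", "kA"), Ac),
    r8  = dual_mm_rate(p("r8", "V"), p("r8", "kA"), p("r8", "kB"), Ac, AACoA),
    r9  = mm_rate(p("r9", "V"), p("r9", "kA"), ACoA),
    r10 = mm_rate(p("r10", "V"), p("r10", "kA"), ACoA),
    r11 = ping_pong_rate(p("r11", "V"), K1 = p("r11", "kB"),
                         K2 = p("r11", "kA"), S1 = ACoA, S2 = NADH),
    r12 = growth_rate(p("r12", "V"), p("r12", "kA"), p("r12", "kB"),
                      ACoA, BuOH),
    r13 = p("r13", "kA"),
    r14 = ping_pong_rate(p("r14", "V"), K1 = p("r14", "kB"),
                         K2 = p("r14", "kA"), S1 = AACoA, S2 = NADH),
    r15 = dual_mm_rate(p("r15", "V"), p("r15", "kA"), p("r15", "kB"),
                       Buty, AACoA),
    r16 = mm_rate(p("r16", "V"), p("r16", "kA"), AcAc),
    r17 = butyrate_uptake_rate(p("r17", "V"), p("r17", "kA"),
                               p("r17", "kB"), Buty),
    r18 = mm_rate(p("r18", "V"), p("r18", "kA"), BCoA),
    r19 = ping_pong_inhibited_rate(p("r19", "V"), K1 = p("r19", "kA"),
                                   K2 = p("r19", "kB"), Ki = p("r19", "kC"),
                                   S1 = BCoA, S2 = NADH, I = BuOH)
  )
  r
}

#' Right-hand side of the batch balance equations
#'
#' Computes dC/dt = N r(C) X, where N is [abe_stoichiometry()], r the rate
#' vector of [compute_rates()] and X the biomass entry of the state. The
#' system is autonomous; `t` is accepted for solver compatibility only.
#'
#' This is the reference R implementation; [simulate_batch()] uses an
#' identical compiled version for speed (their agreement is tested).
#'
#' @param t Time (h), unused.
#' @param state Named state vector (mM).
#' @param params An [abe_parameters] set.
#' @param clamp_nadh If `TRUE`, hold NADH constant (zero its derivative),
#'   emulating a clamped intracellular redox level.
#' @return Named vector of derivatives (mM/h).
#' @export
abe_rhs <- function(t, state, params, clamp_nadh = FALSE) {
  r <- compute_rates(state, params)
  X <- max(state[["X"]], 0)
  d <- as.vector(abe_stoichiometry() %*% r) * X
  names(d) <- abe_species()
  if (isTRUE(clamp_nadh)) d[["NADH"]] <- 0
  d
}
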