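#' Rate-law families
#'
#' The four enzyme-kinetic rate families used by the 19 reactions of the
#' model, plus the two bespoke inhibited forms (glucose uptake and growth).
#' All rates are specific rates in h^-1 (per unit biomass); constants are in
#' mM.
#'
#' * `mm_rate()`: single-substrate Michaelis-Menten, `V*S/(Km+S)`.
#' * `dual_mm_rate()`: product of two Michaelis-Menten factors,
#'   `V * S1/(KA+S1) * S2/(KB+S2)`; used for the CoA-transferase
#'   re-assimilation of acetate (r8) and butyrate (r15).
#' * `ping_pong_rate()`: two-substrate ping-pong bi-bi kinetics
#'   `V*S1*S2 / (K1*S1 + K2*S2 + S1*S2)`; `V` is approached only when both
#'   substrates saturate. Used for the NADH-coupled reductions r11 and r14
#'   (with the constants passed in the per-reaction printed arrangement).
#' * `ping_pong_inhibited_rate()`: ping-pong kinetics with a competitive
#'   inhibitor scaling the `S1*S2` denominator term by `(1 + I/Ki)`;
#'   butanol inhibits the butanol-forming reduction r19 this way.
#'
#' @param V Maximum specific rate (h^-1), positive.
#' @param Km,K1,K2,KA,KB Saturation constants (mM), positive.
#' @param Ki Inhibitor dissociation constant (mM), positive.
#' @param S,S1,S2 Substrate concentrations (mM), non-negative.
#' @param I Inhibitor concentration (mM), non-negative.
#' @return Numeric rate (h^-1). The ping-pong forms return 0 at
#'   `S1 = S2 = 0` (the limit value), not an error.
#' @export
#' @examples
#' mm_rate(10, 5, 5)                        # half saturation -> V/2
#' ping_pong_rate(1, 1, 1, 1, 1)            # 1/3
#' ping_pong_inhibited_rate(1, 1, 1, 1, 1, 1, 1)  # 1/4
mm_rate <- function(V, Km, S) {
  check_rate_args(V = V, Km = Km)
  check_nonneg(S = S)
  V * S / (Km + S)
}

#' @rdname mm_rate
#' @export
dual_mm_rate <- function(V, KA, KB, S1, S2) {
  check_rate_args(V = V, KA = KA, KB = KB)
  check_nonneg(S1 = S1, S2 = S2)
  V * (S1 / (KA + S1)) * (S2 / (KB + S2))
}

#' @rdname mm_rate
#' @export
ping_pong_rate <- function(V, K1, K2, S1, S2) {
  check_rate_args(V = V, K1 = K1, K2 = K2)
  check_nonneg(S1 = S1, S2 = S2)
  den <- K1 * S1 + K2 * S2 + S1 * S2
  ifelse(den == 0, 0, V * S1 * S2 / den)
}

#' @rdname mm_rate
#' @export
ping_pong_inhibited_rate <- function(V, K1, K2, Ki, S1, S2, I) {
  check_rate_args(V = V, K1 = K1, K2 = K2, Ki = Ki)
  check_nonneg(S1 = S1, S2 = S2, I = I)
  den <- K1 * S1 + K2 * S2 + S1 * S2 * (1 + I / Ki)
  ifelse(den == 0, 0, V * S1 * S2 / den)
}

#' Glucose uptake with substrate and butanol inhibition
#'
#' The glucose consumption law combines saturable uptake with a
#' substrate-inhibition term and non-competitive butanol inhibition:
#'
#' `r1 = V * G / ( kA * (1 + G/kC) + G * (1 + BuOH/kB) )`
#'
#' The printed grouping of the three constants is typographically ambiguous;
#' this pairing -- the small constant `kC` with glucose (strong substrate
#' inhibition at high sugar) and the ~90 mM constant `kB` with butanol
#' (inhibition on the physiological toxicity scale) -- is the one reading
#' that is biophysically consistent and reproduces the published response
#' surfaces. It is implemented only here, so a corrected grouping would be a
#' one-line change invisible to callers.
#'
#' @param V Maximum specific uptake rate (h^-1).
#' @param kA Saturation constant (mM).
#' @param kB Butanol inhibition constant (mM).
#' @param kC Substrate (glucose) inhibition constant (mM).
#' @param G Glucose (mM). @param BuOH Butanol (mM).
#' @return Specific uptake rate (h^-1).
#' @export
glucose_uptake_rate <- function(V, kA, kB, kC, G, BuOH) {
  check_rate_args(V = V, kA = kA, kB = kB, kC = kC)
  check_nonneg(G = G, BuOH = BuOH)
  V * G / (kA * (1 + G / kC) + G * (1 + BuOH / kB))
}

# growth on acetyl-CoA with non-competitive butanol inhibition (r12)
growth_rate <- function(V, kA, kB, ACoA, BuOH) {
  V * ACoA / ((kA + ACoA) * (1 + BuOH / kB))
}

# butyrate re-uptake to butyryl-CoA (r17), transcribed grouping
# V*Buty/(kA*(1 + kB/Buty) + Buty), evaluated in polynomial form so the
# Buty -> 0 limit (rate 0) needs no special case
butyrate_uptake_rate <- function(V, kA, kB, Buty) {
  den <- kA * Buty + kA * kB + Buty^2
  ifelse(den == 0, 0, V * Buty^2 / den)
}

check_rate_args <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(paste0("`", nm, "` must be finite and positive."))
    }
  }
  invisible(NULL)
}

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      abort(paste0("`", nm, "` must be finite and non-negative."))
    }
  }
  invisible(NULL)
}
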