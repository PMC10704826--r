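# Independent arithmetic oracle: the 19 rate laws written out directly as
# plain formulas over a named parameter list, kept deliberately separate from
# the package's rate-law functions.
oracle_flat_params <- function(params = abe_fit("A")) {
  pv <- as.list(param_vector(params))
  pv
}

oracle_rates <- function(state, p) {
  s <- pmax(as.numeric(state[abe_species()]), 0)
  G <- s[1]; F6P <- s[2]; G3P <- s[3]; Pyr <- s[4]; Lac <- s[5]
  ACoA <- s[6]; Ac <- s[8]; AACoA <- s[10]; AcAc <- s[11]
  BCoA <- s[12]; Buty <- s[13]; BuOH <- s[15]; NADH <- s[16]
  with(p, c(
    V1 * G / (k1A * (1 + G / k1C) + G * (1 + BuOH / k1B)),
    V2 * F6P / (k2A + F6P),
    V3 * G3P / (k3A + G3P),
    V4 * Lac / (k4A + Lac),
    V5 * Pyr / (k5A + Pyr),
    V6 * Pyr / (k6A + Pyr),
    V7 * Ac / (k7A + Ac),
    V8 * Ac / (k8A + Ac) * AACoA / (k8B + AACoA),
    V9 * ACoA / (k9A + ACoA),
    V10 * ACoA / (k10A + ACoA),
    if (ACoA + NADH == 0) 0 else
      V11 * ACoA * NADH / (ACoA * NADH + k11A * NADH + k11B * ACoA),
    V12 * ACoA / ((k12A + ACoA) * (1 + BuOH / k12B)),
    k13A,
    if (AACoA + NADH == 0) 0 else
      V14 * AACoA * NADH / (AACoA * NADH + k14A * NADH + k14B * AACoA),
    V15 * Buty / (k15A + Buty) * AACoA / (k15B + AACoA),
    V16 * AcAc / (k16A + AcAc),
    if (Buty == 0) 0 else
      V17 * Buty^2 / (k17A * Buty + k17A * k17B + Buty^2),
    V18 * BCoA / (k18A + BCoA),
    if (BCoA + NADH == 0) 0 else
      V19 * BCoA * NADH / (k19A * BCoA + k19B * NADH +
                             BCoA * NADH * (1 + BuOH / k19C))
  ))
}

# Hand-encoded substrate/product sets of each reaction arrow in the network
# diagram (consumed species -> produced species), used to cross-validate the
# stoichiometric matrix column supports.
network_adjacency <- function() {
  list(
    r1  = list(sub = "G",                 prod = "F6P"),
    r2  = list(sub = "F6P",               prod = "G3P"),
    r3  = list(sub = "G3P",               prod = c("Pyr", "NADH")),
    r4  = list(sub = "Lac",               prod = "Pyr"),
    r5  = list(sub = "Pyr",               prod = "Lac"),
    r6  = list(sub = "Pyr",               prod = "ACoA"),
    r7  = list(sub = "Ac",                prod = "ACoA"),
    r8  = list(sub = c("Ac", "AACoA"),    prod = c("AcAc", "ACoA")),
    r9  = list(sub = "ACoA",              prod = "Ac"),
    r10 = list(sub = "ACoA",              prod = "AACoA"),
    r11 = list(sub = c("ACoA", "NADH"),   prod = "EtOH"),
    r12 = list(sub = "ACoA",              prod = "X"),
    r13 = list(sub = "X",                 prod = character(0)),
    r14 = list(sub = c("AACoA", "NADH"),  prod = "BCoA"),
    r15 = list(sub = c("Buty", "AACoA"),  prod = c("AcAc", "BCoA")),
    r16 = list(sub = "AcAc",              prod = "An"),
    r17 = list(sub = "Buty",              prod = "BCoA"),
    r18 = list(sub = "BCoA",              prod = "Buty"),
    r19 = list(sub = c("BCoA", "NADH"),   prod = "BuOH")
  )
}

# random admissible state on mixed scales, for property tests
random_state <- function() {
  abe_state(.base = setNames(runif(16, 0, 100) * 10^runif(16, -3, 0),
                             abe_species()))
}
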