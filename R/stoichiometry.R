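#' Stoichiometric matrix of the ABE network
#'
#' The fixed 16 x 19 integer coefficient matrix N of the balance equations
#' dC/dt = N r X, rows in canonical species order ([abe_species()]), columns
#' r1..r19. Coefficients follow the pathway topology together with the
#' published redox bookkeeping (one glucose yields two glycolytic NADH; one
#' butanol consumes four NADH; one butanol per glucose through the direct
#' "hot channel").
#'
#' @return Integer matrix with dimnames `(species, reaction)`.
#' @export
#' @examples
#' N <- abe_stoichiometry()
#' N["G", ]      # glucose is only consumed, by r1
abe_stoichiometry <- function() {
  .abe_stoich
}

# Column-by-column transcription; the enzyme abbreviations are the pathway
# labels of the network diagram.
.abe_stoich <- local({
  sp <- c("G", "F6P", "G3P", "Pyr", "Lac", "ACoA", "X", "Ac",
          "EtOH", "AACoA", "AcAc", "BCoA", "Buty", "An", "BuOH", "NADH")
  N <- matrix(0L, 16L, 19L, dimnames = list(sp, paste0("r", 1:19)))
  set <- function(rx, ...) {
    v <- c(...)
    N[names(v), rx] <<- as.integer(v)
  }
  set("r1",  G = -1, F6P = 1)                    # PTS uptake / PFK feed
  set("r2",  F6P = -1, G3P = 2)                  # PFK+aldolase: 2 trioses
  set("r3",  G3P = -1, Pyr = 1, NADH = 1)        # GAPDH..PK: glycolytic NADH
  set("r4",  Lac = -1, Pyr = 1)                  # LDH, lactate re-uptake
  set("r5",  Pyr = -1, Lac = 1)                  # LDH, lactate formation
  set("r6",  Pyr = -1, ACoA = 1)                 # PFOR
  set("r7",  Ac = -1, ACoA = 1)                  # AK/PTA, acetate re-uptake
  set("r8",  Ac = -1, AACoA = -1, AcAc = 1, ACoA = 1)   # CoAT (acetate)
  set("r9",  ACoA = -1, Ac = 1)                  # PTA/AK, acetate formation
  set("r10", ACoA = -2, AACoA = 1)               # thiolase condensation
  set("r11", ACoA = -1, EtOH = 1, NADH = -2)     # AYDH+ADH, 2 reductions
  set("r12", ACoA = -1, X = 1)                   # growth
  set("r13", X = -1)                             # cell death
  set("r14", AACoA = -1, BCoA = 1, NADH = -2)    # BHBD+ECH+BCD
  set("r15", Buty = -1, AACoA = -1, AcAc = 1, BCoA = 1) # CoAT (butyrate)
  set("r16", AcAc = -1, An = 1)                  # acetoacetate decarboxylase
  set("r17", Buty = -1, BCoA = 1)                # BK/PTB, butyrate re-uptake
  set("r18", BCoA = -1, Buty = 1)                # PTB/BK, butyrate formation
  set("r19", BCoA = -1, BuOH = 1, NADH = -2)     # BYDH+BDH, 2 reductions
  N
})
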