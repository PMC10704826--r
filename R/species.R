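#' Canonical species catalogue
#'
#' The model balances 16 species. Their names and order are fixed and shared
#' by state vectors, the rows of the stoichiometric matrix, trajectory columns
#' and every file format the package reads or writes.
#'
#' The catalogue is, in order: glucose (`G`), fructose-6-phosphate (`F6P`),
#' glyceraldehyde-3-phosphate (`G3P`), pyruvate (`Pyr`), lactate (`Lac`),
#' acetyl-CoA (`ACoA`), biomass (`X`), acetate (`Ac`), ethanol (`EtOH`),
#' acetoacetyl-CoA (`AACoA`), the acetoacetate/acetone-precursor pool
#' (`AcAc`), butyryl-CoA (`BCoA`), butyrate (`Buty`), acetone (`An`),
#' butanol (`BuOH`) and the reduced cofactor `NADH`. All concentrations,
#' including biomass, are expressed in mM.
#'
#' @return Character vector of the 16 canonical species names.
#' @export
#' @examples
#' abe_species()
abe_species <- function() {
  c("G", "F6P", "G3P", "Pyr", "Lac", "ACoA", "X", "Ac",
    "EtOH", "AACoA", "AcAc", "BCoA", "Buty", "An", "BuOH", "NADH")
}

# default trace concentration for species whose inoculum level is not part of
# a published initial condition; NADH defaults to the middle of the reported
# physiological range (0.039-8.49 mM)
.default_trace <- 1e-3
.default_nadh <- 2

#' Build a state vector
#'
#' Returns a named concentration vector over the canonical species order
#' ([abe_species()]). Species not mentioned default to a 10^-3 mM trace,
#' except NADH which defaults to 2 mM (mid physiological range); both defaults
#' are overridable simply by naming the species.
#'
#' @param ... Named concentrations in mM, e.g. `G = 70.6, X = 0.2`.
#' @param .base Optional state vector to start from instead of the defaults.
#' @return Named numeric vector of length 16 in canonical order.
#' @export
#' @examples
#' abe_state(G = 70.6, X = 0.2, Ac = 40.12)
abe_state <- function(..., .base = NULL) {
  sp <- abe_species()
  if (is.null(.base)) {
    state <- setNames(rep(.default_trace, 16L), sp)
    state["NADH"] <- .default_nadh
  } else {
    state <- validate_state(.base)
  }
  upd <- c(...)
  if (length(upd)) {
    bad <- setdiff(names(upd), sp)
    if (length(bad)) {
      abort(paste0("Unknown species: ", paste(bad, collapse = ", ")))
    }
    state[names(upd)] <- as.numeric(upd)
  }
  validate_state(state)
}

validate_state <- function(state) {
  sp <- abe_species()
  if (is.null(names(state)) || !setequal(names(state), sp)) {
    abort("A state vector must be named over the 16 canonical species.")
  }
  state <- state[sp]
  if (any(!is.finite(state))) abort("State concentrations must be finite.")
  if (any(state < 0)) abort("State concentrations must be non-negative.")
  state
}

#' Published initial conditions
#'
#' Packaged batch initial conditions used for the two parameter fits:
#' `"shinto"` (glucose 70.6 mM, biomass 0.20 mM, acetate 40.12 mM, butyrate
#' 2.12 mM, acetone 2.58 mM, butanol 4.46 mM) and `"alshorgani"` (glucose
#' 277.78 mM, i.e. 50 g/L; only glucose is published for this culture, so
#' biomass and the remaining species take the package defaults and the
#' fixture is in that sense partly synthetic).
#'
#' Species not listed above start at the [abe_state()] defaults: 10^-3 mM
#' traces and 2 mM NADH, all overridable.
#'
#' @param name `"shinto"` or `"alshorgani"`.
#' @return Named numeric state vector (see [abe_state()]).
#' @export
#' @examples
#' abe_initial("shinto")[c("G", "X", "Ac")]
abe_initial <- function(name = c("shinto", "alshorgani")) {
  name <- match.arg(name)
  switch(name,
    shinto = abe_state(G = 70.6, X = 0.20, Ac = 40.12, Buty = 2.12,
                       An = 2.58, BuOH = 4.46),
    alshorgani = abe_state(G = 277.78, X = 0.20)
  )
}
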