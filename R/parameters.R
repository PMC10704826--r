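# Which kinetic constants each reaction requires. V is the maximum specific
# rate (h^-1); kA/kB/kC are concentration constants (mM). r13 is a constant
# specific death rate and carries only kA.
.param_schema <- list(
  r1  = c("V", "kA", "kB", "kC"),
  r2  = c("V", "kA"), r3 = c("V", "kA"), r4 = c("V", "kA"),
  r5  = c("V", "kA"), r6 = c("V", "kA"), r7 = c("V", "kA"),
  r8  = c("V", "kA", "kB"),
  r9  = c("V", "kA"), r10 = c("V", "kA"),
  r11 = c("V", "kA", "kB"),
  r12 = c("V", "kA", "kB"),
  r13 = c("kA"),
  r14 = c("V", "kA", "kB"),
  r15 = c("V", "kA", "kB"),
  r16 = c("V", "kA"),
  r17 = c("V", "kA", "kB"),
  r18 = c("V", "kA"),
  r19 = c("V", "kA", "kB", "kC")
)

.reaction_ids <- paste0("r", 1:19)

#' Kinetic parameter sets
#'
#' A parameter set is a tibble with one row per reaction (`r1` ... `r19`) and
#' columns `reaction`, `V`, `kA`, `kB`, `kC`, mirroring the layout of the
#' published parameter table. Cells that a reaction's rate law does not use
#' are `NA` (absent by omission, never zero-filled). The set's provenance is
#' kept in the `label` attribute.
#'
#' `abe_parameters()` validates and normalises such a tibble; [abe_fit()]
#' returns the two packaged fits.
#'
#' @param tbl Data frame with columns `reaction`, `V`, `kA`, `kB`, `kC`.
#' @param label Provenance label stored on the result.
#' @return A `tbl_df` of class `abe_parameters`.
#' @export
abe_parameters <- function(tbl, label = "unlabelled") {
  tbl <- as_tibble(tbl)
  need <- c("reaction", "V", "kA", "kB", "kC")
  if (!all(need %in% names(tbl))) {
    abort(paste0("Parameter table needs columns: ", paste(need, collapse = ", ")))
  }
  if (!setequal(tbl$reaction, .reaction_ids) || nrow(tbl) != 19L) {
    abort("Parameter table must have exactly one row per reaction r1..r19.")
  }
  tbl <- tbl[match(.reaction_ids, tbl$reaction), need]
  for (col in c("V", "kA", "kB", "kC")) {
    tbl[[col]] <- as.numeric(tbl[[col]])
    bad <- !is.na(tbl[[col]]) & tbl[[col]] <= 0
    if (any(bad)) {
      abort(paste0("Non-positive ", col, " for ", paste(tbl$reaction[bad], collapse = ", ")))
    }
  }
  structure(tbl, label = label, class = c("abe_parameters", class(tbl)))
}

#' @export
print.abe_parameters <- function(x, ...) {
  cat("<abe_parameters> ", attr(x, "label"), "\n", sep = "")
  NextMethod()
}

# error if a constant required by a rate law is missing; names the reaction
validate_complete <- function(params) {
  for (rx in .reaction_ids) {
    row <- params[params$reaction == rx, ]
    for (const in .param_schema[[rx]]) {
      if (is.na(row[[const]])) {
        abort(paste0("Parameter set '", attr(params, "label"),
                     "' is missing ", const, " for reaction ", rx, "."))
      }
    }
  }
  invisible(params)
}

#' Packaged parameter fits
#'
#' The two published parameter sets for the NADH-modulated ABE model:
#' fit A (calibrated against the Shinto batch culture of
#' *C. saccharoperbutylacetonicum* N1-4) and fit B (calibrated against the
#' Al-Shorgani batch culture of *C. acetobutylicum*). Values are transcribed
#' cell by cell from the published table; empty cells are `NA`.
#'
#' Two caveats carried over from the source table: fit A lists a third
#' constant `kC = 2.56` for reactions r16 and r18 although their rate laws
#' use only `V` and `kA` -- the values are stored for fidelity but never
#' evaluated; and fit B prints no `V` for r16/r18, so simulating fit B
#' requires supplying those two rates (see [set_params()]).
#'
#' @param fit `"A"` or `"B"`.
#' @return An [abe_parameters] tibble.
#' @export
#' @examples
#' abe_fit("A")
abe_fit <- function(fit = c("A", "B")) {
  fit <- match.arg(fit)
  A <- tibble(
    reaction = .reaction_ids,
    V  = c(9.89, 41.10, 148.27, 14.23, 6.22e-2, 166.00, 5.40e-3, 144.91,
           2.18, 100.23, 7.63e-1, 6.35, NA, 44.43, 3.55, 44.76, 91.59,
           4.84, 26.27),
    kA = c(11.54, 4.0e-4, 4.91e-2, 154.19, 494.70, 0.31, 111.61, 0.85,
           85.45, 3.63e-1, 46.31, 0.11, 5.06e-2, 7.42e-1, 4.30, 2.43e-1,
           2.85, 12.66, 6.0e-1),
    kB = c(89.50, NA, NA, NA, NA, NA, NA, 12.77, NA, NA, 26.27, 144.58,
           NA, 2.40, 53.62, NA, 2.36, NA, 28.45),
    kC = c(2.56, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
           2.56, NA, 2.56, 105.51)
  )
  B <- tibble(
    reaction = .reaction_ids,
    V  = c(7.30, 44.84, 144.84, 24.61, 2.06e-3, 178.808, 1.14e-4, 106.84,
           5.96, 83.61, 15.95, 16.16, NA, 9.00, 91.37, NA, 15.60, NA, 14.61),
    kA = c(42.40, 3.20e-5, 16.93, 172.78, 502.49, 2.53, 92.65, 1.51e-2,
           65.19, 0.49, 37.62, 1.05, 5.77e-4, 4.51, 26.79, 1.09, 23.78,
           17.35, 1.82),
    kB = c(62.98, NA, NA, NA, NA, NA, NA, 19.88, NA, NA, 46.45, 155.71,
           NA, 1.29, 46.78, NA, 14.96, NA, 32.49),
    kC = c(5.11, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
           NA, NA, NA, 81.06)
  )
  params <- abe_parameters(if (fit == "A") A else B,
                           label = paste0("fit_", fit))
  if (fit == "A") {
    rlang::inform(
      "fit A stores kC for r16/r18 as published; the rate laws do not use it.",
      .frequency = "once", .frequency_id = "abekin_fitA_kC")
  }
  params
}

#' Packaged fixtures by name
#'
#' Single lookup for the published inputs: `"fit_A"` / `"fit_B"` return
#' [abe_fit()] parameter sets, `"shinto_initial"` / `"alshorgani_initial"`
#' return [abe_initial()] state vectors.
#'
#' @param name Fixture name.
#' @return A parameter set or a state vector, by name.
#' @export
abe_fixture <- function(name = c("fit_A", "fit_B", "shinto_initial",
                                 "alshorgani_initial")) {
  name <- match.arg(name)
  switch(name,
    fit_A = abe_fit("A"),
    fit_B = abe_fit("B"),
    shinto_initial = abe_initial("shinto"),
    alshorgani_initial = abe_initial("alshorgani")
  )
}

#' Flatten and modify parameter sets
#'
#' `param_vector()` flattens a parameter set to a named numeric vector with
#' entries such as `V1`, `k1A`, `k19C` (absent cells are dropped);
#' `set_params()` writes such named values back into a copy of the set. The
#' flat names are the handles used by the estimation and sensitivity modules.
#'
#' @param params An [abe_parameters] set.
#' @param values Named numeric vector, e.g. `c(V1 = 10, k14B = 2.5)`.
#' @return `param_vector()`: named numeric vector. `set_params()`: a new
#'   [abe_parameters] set.
#' @export
param_vector <- function(params) {
  out <- numeric(0)
  for (i in seq_len(19L)) {
    rx <- params$reaction[i]
    n <- sub("r", "", rx)
    for (const in c("V", "kA", "kB", "kC")) {
      val <- params[[const]][i]
      if (!is.na(val)) {
        nm <- if (const == "V") paste0("V", n) else
          paste0("k", n, sub("k", "", const))
        out[nm] <- val
      }
    }
  }
  out
}

#' @rdname param_vector
#' @export
set_params <- function(params, values) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    abort("`values` must be a fully named numeric vector.")
  }
  for (nm in names(values)) {
    m <- regmatches(nm, regexec("^(V|k)([0-9]+)([ABC]?)$", nm))[[1]]
    if (length(m) == 0L || (m[2] == "k" && !nzchar(m[4])) ||
        (m[2] == "V" && nzchar(m[4]))) {
      abort(paste0("Unrecognised parameter name: ", nm))
    }
    rx <- paste0("r", m[3])
    if (!rx %in% .reaction_ids) abort(paste0("Unrecognised reaction in: ", nm))
    col <- if (m[2] == "V") "V" else paste0("k", m[4])
    params[params$reaction == rx, col] <- as.numeric(values[[nm]])
  }
  abe_parameters(params, label = attr(params, "label"))
}

# 77-slot numeric layout shared with the compiled right-hand side:
# slots (i-1)*4 + 1..4 hold V,kA,kB,kC of reaction i (NA -> NaN, never read),
# slot 77 is the clamp-NADH flag.
pack_params <- function(params, clamp_nadh = FALSE) {
  validate_complete(params)
  p <- rep(NaN, 77)
  for (i in seq_len(19L)) {
    p[(i - 1) * 4 + 1:4] <- c(params$V[i], params$kA[i],
                              params$kB[i], params$kC[i])
  }
  p[77] <- as.numeric(isTRUE(clamp_nadh))
  p
}
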