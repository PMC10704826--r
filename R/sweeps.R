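#' Butanol/acetone selectivity
#'
#' The dimensionless endpoint ratio butanol/acetone (mol/mol). Undefined
#' (returned as `NA`) when acetone does not exceed `eps`.
#'
#' @param butanol,acetone Endpoint concentrations (mM), vectorised.
#' @param eps Acetone threshold below which the ratio is undefined
#'   (default 1e-6 mM).
#' @return Numeric selectivity, `NA` where undefined.
#' @export
#' @examples
#' selectivity(6, 3)   # 2
selectivity <- function(butanol, acetone, eps = 1e-6) {
  ifelse(acetone > eps, butanol / acetone, NA_real_)
}

#' Sweep initial glucose, NADH and acetate
#'
#' Simulates a batch to `t_end` for every combination of the supplied
#' initial-concentration levels, overriding the corresponding entries of
#' `base_initial` (all other initials are kept), and records endpoint
#' butanol, acetone and their selectivity. An axis left `NULL` stays at its
#' base value. The NADH axis is applied as an initial concentration -- NADH
#' is a balanced dynamic state -- unless `clamp_nadh = TRUE`, which holds it
#' constant over the run (the alternative reading of an externally imposed
#' redox level).
#'
#' Individual simulation failures are flagged (`ok = FALSE`) and the sweep
#' continues.
#'
#' @param params An [abe_parameters] set.
#' @param base_initial Base state vector (defaults to the Shinto initial
#'   condition).
#' @param glucose,nadh,acetate Numeric axes of initial concentrations (mM),
#'   or `NULL`.
#' @param t_end Batch horizon (h).
#' @param endpoint `"end"` records concentrations at `t_end`; `"peak"`
#'   records each solvent's maximum over the trajectory.
#' @param clamp_nadh Hold NADH constant during each run.
#' @param ... Passed to [simulate_batch()].
#' @return A tibble of class `abe_sweep`: columns `glucose_mM`, `nadh_mM`,
#'   `acetate_mM`, `butanol_mM`, `acetone_mM`, `selectivity`, `ok`.
#' @export
#' @examples
#' run_sweep(abe_fit("A"), glucose = c(50, 70), nadh = 2, t_end = 60)
run_sweep <- function(params, base_initial = abe_initial("shinto"),
                      glucose = NULL, nadh = NULL, acetate = NULL,
                      t_end = 60, endpoint = c("end", "peak"),
                      clamp_nadh = FALSE, ...) {
  endpoint <- match.arg(endpoint)
  base_initial <- validate_state(base_initial)
  axes <- list(G = glucose, NADH = nadh, Ac = acetate)
  for (ax in names(axes)) {
    if (is.null(axes[[ax]])) axes[[ax]] <- base_initial[[ax]]
    if (any(axes[[ax]] < 0)) abort("Sweep levels must be non-negative.")
    axes[[ax]] <- sort(unique(as.numeric(axes[[ax]])))
  }
  grid <- tidyr::expand_grid(glucose_mM = axes$G, nadh_mM = axes$NADH,
                             acetate_mM = axes$Ac)
  cells <- purrr::pmap_dfr(grid, function(glucose_mM, nadh_mM, acetate_mM) {
    init <- abe_state(G = glucose_mM, NADH = nadh_mM, Ac = acetate_mM,
                      .base = base_initial)
    res <- tryCatch({
      if (endpoint == "end") {
        s <- endpoint_state(init, params, t_end = t_end,
                            clamp_nadh = clamp_nadh, ...)
        c(bu = s[["BuOH"]], an = s[["An"]])
      } else {
        traj <- simulate_batch(init, params, t_end = t_end,
                               clamp_nadh = clamp_nadh, ...)
        c(bu = max(traj$BuOH), an = max(traj$An))
      }
    }, abekin_solver_error = function(e) c(bu = NA_real_, an = NA_real_))
    tibble(butanol_mM = res[["bu"]], acetone_mM = res[["an"]],
           selectivity = selectivity(res[["bu"]], res[["an"]]),
           ok = !is.na(res[["bu"]]))
  })
  out <- dplyr::bind_cols(grid, cells)
  structure(out, t_end = t_end, params = params, base_initial = base_initial,
            clamp_nadh = clamp_nadh,
            class = c("abe_sweep", class(out)))
}

#' Locate an extremum on a sweep grid
#'
#' Finds the maximum or minimum of an endpoint quantity over the (optionally
#' pre-filtered) grid cells, skipping failed or undefined cells. Ties break
#' towards the lowest axis values in axis order (glucose, then NADH, then
#' acetate).
#'
#' @param grid An `abe_sweep` (or any tibble with the sweep columns),
#'   possibly filtered to a slice of interest.
#' @param quantity One of `"selectivity"`, `"butanol_mM"`, `"acetone_mM"`.
#' @param kind `"max"` or `"min"`.
#' @return One-row tibble: the extremal cell.
#' @export
locate_extremum <- function(grid, quantity = c("selectivity", "butanol_mM",
                                               "acetone_mM"),
                            kind = c("max", "min")) {
  quantity <- match.arg(quantity)
  kind <- match.arg(kind)
  ok <- grid[!is.na(grid[[quantity]]) & (grid$ok %||% TRUE), , drop = FALSE]
  if (nrow(ok) == 0L) {
    abort("No admissible cells: all failed or undefined.",
          class = "abekin_no_extremum")
  }
  target <- if (kind == "max") max(ok[[quantity]]) else min(ok[[quantity]])
  hits <- ok[ok[[quantity]] == target, , drop = FALSE]
  hits <- hits[order(hits$glucose_mM, hits$nadh_mM, hits$acetate_mM), ,
               drop = FALSE]
  as_tibble(hits[1L, , drop = FALSE])
}
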