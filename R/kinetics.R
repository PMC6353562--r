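# Mechanically coupled SNAREpin release-time kinetics.

#' Kinetics parameters for coupled SNAREpins
#'
#' Membranes are rigid on the length scale of a fusion pore, so the
#' SNAREpins under one vesicle are mechanically coupled: each added pin
#' contributes its remaining mechanical work (`dE_kBT`, in units of kBT)
#' toward the bilayer fusion barrier (`barrier_kBT`), multiplying the
#' Arrhenius escape rate. Two conventions are offered for the per-pin
#' speed-up factor: the exact exponential `exp(dE_kBT)`, and its
#' order-of-magnitude rounding `10^round(log10(exp(dE_kBT)))` (for the
#' default 5 kBT: `exp(5) = 148.4`, rounded to `10^2`).
#'
#' @param t1_s fusion time of a single SNAREpin, seconds (default 1).
#' @param dE_kBT mechanical work per pin toward the barrier, kBT (default 5).
#' @param barrier_kBT bilayer fusion barrier, kBT (default 25).
#' @param convention `"order_of_magnitude"` (default) or
#'   `"exact_exponential"`.
#' @return an object of class `kinetics_params`.
#' @export
kinetics_params <- function(t1_s = 1, dE_kBT = 5, barrier_kBT = 25,
                            convention = c("order_of_magnitude",
                                           "exact_exponential")) {
  convention <- match.arg(convention)
  if (t1_s <= 0 || dE_kBT < 0 || barrier_kBT <= 0)
    stop("kinetics parameters must be positive (dE_kBT >= 0)")
  structure(list(t1_s = t1_s, dE_kBT = dE_kBT, barrier_kBT = barrier_kBT,
                 convention = convention),
            class = "kinetics_params")
}

#' Per-added-pin waiting-time reduction factor
#'
#' @param params a [kinetics_params()].
#' @return the multiplicative speed-up per added SNAREpin (1 when
#'   `dE_kBT = 0`).
#' @export
coupling_factor <- function(params = kinetics_params()) {
  stopifnot(inherits(params, "kinetics_params"))
  f <- exp(params$dE_kBT)
  if (params$convention == "order_of_magnitude" && params$dE_kBT > 0)
    f <- 10^round(log10(f))
  f
}

#' Release time for n mechanically coupled SNAREpins
#'
#' `t(n) = t1 / f^(n - 1)` with `f` the [coupling_factor()]: one pin takes
#' `t1_s` (about a second for physiological barriers), and every further
#' pin divides the waiting time by `f`.
#'
#' @param n_pins integer number of SNAREpins (>= 1); vectorized.
#' @param params a [kinetics_params()].
#' @return release time(s) in seconds.
#' @export
release_time <- function(n_pins, params = kinetics_params()) {
  if (any(n_pins < 1) || any(n_pins != round(n_pins)))
    stop("`n_pins` must be a positive integer")
  params$t1_s / coupling_factor(params)^(n_pins - 1)
}

#' Release-time table with work bookkeeping
#'
#' Tabulates `t(n)` together with the accumulated mechanical work
#' `n * dE_kBT` and whether it reaches the fusion barrier (reported for
#' orientation, not used as a fusion criterion).
#'
#' @param n_max largest pin count tabulated.
#' @param params a [kinetics_params()].
#' @return data.frame with `n_pins`, `time_s`, `work_kBT`,
#'   `work_reaches_barrier`.
#' @export
release_time_table <- function(n_max = 6, params = kinetics_params()) {
  n <- seq_len(n_max)
  data.frame(n_pins = n, time_s = release_time(n, params),
             work_kBT = n * params$dE_kBT,
             work_reaches_barrier = n * params$dE_kBT >= params$barrier_kBT)
}
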