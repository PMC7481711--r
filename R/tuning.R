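# Calibration procedures: PIP titration to a target tidal volume, joint
# PIP + restrictor equalization for mismatched pairs, and independent
# adjustment of one patient's tidal volume.
#
# All procedures target the steady-cycle tidal volume and use plain bisection
# on responses that are strictly monotone over the search bracket (tidal
# volume increases with PIP and decreases with the patient's own inline
# restrictor resistance). Bisection stops when the response is within `f_tol`
# of the target; the clinical acceptance band (`tol`, default 10 ml) is
# checked afterwards and reported via `converged`.

# bisection to f(x) == target for monotone f; `increasing` gives the direction.
# Checks the endpoints first so boundary solutions (e.g. restrictor fully
# open) return exactly.
.bisect <- function(f, lower, upper, target, f_tol = 0.25, increasing = TRUE,
                    max_iter = 60L, what = "response") {
  sgn <- if (increasing) 1 else -1
  f_lo <- f(lower)
  if (sgn * (f_lo - target) >= -f_tol) {
    # target at or below the achievable range: boundary solution
    if (abs(f_lo - target) <= f_tol || sgn * (f_lo - target) > 0) {
      return(list(x = lower, fx = f_lo, iterations = 1L,
                  converged = abs(f_lo - target) <= f_tol))
    }
  }
  f_hi <- f(upper)
  if (sgn * (f_hi - target) < -f_tol) {
    stop(sprintf("target %s %.3f unreachable in bracket [%g, %g] (achieved %.3f to %.3f)",
                 what, target, lower, upper, f_lo, f_hi))
  }
  it <- 2L
  x_lo <- lower; x_hi <- upper
  repeat {
    mid <- (x_lo + x_hi) / 2
    fm <- f(mid)
    it <- it + 1L
    if (abs(fm - target) <= f_tol || it >= max_iter) {
      return(list(x = mid, fx = fm, iterations = it,
                  converged = abs(fm - target) <= f_tol))
    }
    if (sgn * (fm - target) < 0) x_lo <- mid else x_hi <- mid
  }
}

.tune_result <- function(pip, r_v1, r_v2, vt1, vt2, iterations, converged,
                         target = NA_real_) {
  structure(list(pip = unname(pip), r_v1 = unname(r_v1), r_v2 = unname(r_v2),
                 vt1 = unname(vt1), vt2 = unname(vt2),
                 iterations = iterations, converged = converged,
                 target = unname(target)),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf(paste0("Tuned settings: PIP %.3f cmH2O, R_V1 %.3f, R_V2 %.3f cmH2O/L/s\n",
                     "Achieved tidal volumes: %.1f / %.1f ml (target %s; %s after %d evaluations)\n"),
              x$pip, x$r_v1, x$r_v2, x$vt1, x$vt2,
              ifelse(is.na(x$target), "-", format(x$target)),
              ifelse(x$converged, "converged", "NOT converged"), x$iterations))
  invisible(x)
}

#' Titrate PIP to a target tidal volume
#'
#' Bisects PIP over `[peep + 0.1, pip_max]` until patient 1's steady-cycle
#' tidal volume is within `f_tol` of `target_vt`; `converged` reports the
#' clinical band `tol`.
#'
#' @param lung1,lung2 [lung_model()]s; `lung2` defaults to `lung1` (matched
#'   pair) and is ignored for topology "single".
#' @param topology "standard", "modified" or "single".
#' @param target_vt target tidal volume, ml.
#' @param tol clinical acceptance band, ml.
#' @param settings base [ventilator_settings()]; its `pip` is replaced by the
#'   titrated value.
#' @param splitter a [splitter_config()]; its topology field is overridden by
#'   `topology`.
#' @param pip_max upper search bound for PIP, cmH2O.
#' @param f_tol inner bisection tolerance on tidal volume, ml.
#' @return A `tune_result`.
#' @export
tune_pip <- function(lung1, lung2 = lung1,
                     topology = c("standard", "modified", "single"),
                     target_vt = 490, tol = 10,
                     settings = ventilator_settings(),
                     splitter = NULL, pip_max = 60, f_tol = 0.25) {
  topology <- match.arg(topology)
  if (is.null(splitter)) splitter <- splitter_config(topology)
  splitter$topology <- topology
  net <- build_splitter(lung1, lung2, splitter)
  with_pip <- function(pip) ventilator_settings(pip, settings$peep,
                                                settings$rr, settings$ie)
  f <- function(pip) .steady_vts(net, with_pip(pip))[1]
  res <- .bisect(f, settings$peep + 0.1, pip_max, target_vt, f_tol = f_tol,
                 increasing = TRUE, what = "tidal volume (ml)")
  vts <- .steady_vts(net, with_pip(res$x))
  .tune_result(pip = res$x, r_v1 = splitter$r_v1, r_v2 = splitter$r_v2,
               vt1 = vts[1], vt2 = if (length(vts) > 1) vts[2] else NA_real_,
               iterations = res$iterations,
               converged = abs(vts[1] - target_vt) <= tol, target = target_vt)
}

#' Equalize tidal volumes for a mismatched pair on the modified splitter
#'
#' Two-stage calibration: first PIP is raised (restrictors fully open) until
#' the lower-compliance patient (patient 2) reaches the target tidal volume;
#' then the restrictor in patient 1's inspiration arm is increased until
#' patient 1 also reaches the target. Because the one-way expiration valves
#' decouple the patients, stage 2 barely moves patient 2; the outer loop
#' repeats stage 1 only if it did (at most `max_outer` passes).
#'
#' @param lung1,lung2 [lung_model()]s; patient 2 must not have the higher
#'   compliance.
#' @param target_vt target tidal volume for both patients, ml.
#' @param tol clinical acceptance band, ml.
#' @param settings base [ventilator_settings()].
#' @param splitter a [splitter_config()] (topology forced to "modified";
#'   `r_v2` held at 0).
#' @param r_v_max upper search bound for the restrictor, cmH2O/L/s.
#' @param pip_max upper search bound for PIP, cmH2O.
#' @param f_tol inner bisection tolerance, ml.
#' @param max_outer maximum number of stage-1/stage-2 passes.
#' @return A `tune_result`.
#' @export
tune_modified <- function(lung1, lung2, target_vt = 490, tol = 10,
                          settings = ventilator_settings(),
                          splitter = splitter_config("modified"),
                          r_v_max = 100, pip_max = 60, f_tol = 0.25,
                          max_outer = 3L) {
  if (lung2$c_l > lung1$c_l) {
    stop("patient 2 must be the lower-compliance patient; swap the pair")
  }
  splitter$topology <- "modified"
  splitter$r_v2 <- 0
  with_pip <- function(pip) ventilator_settings(pip, settings$peep,
                                                settings$rr, settings$ie)
  vts_at <- function(pip, r_v1) {
    splitter$r_v1 <- r_v1
    .steady_vts(build_modified(lung1, lung2, splitter), with_pip(pip))
  }
  r_v1 <- 0
  iters <- 0L
  pip <- settings$pip
  for (pass in seq_len(max_outer)) {
    s1 <- .bisect(function(p) vts_at(p, r_v1)[2],
                  settings$peep + 0.1, pip_max, target_vt, f_tol = f_tol,
                  increasing = TRUE, what = "patient-2 tidal volume (ml)")
    pip <- s1$x
    s2 <- .bisect(function(rv) vts_at(pip, rv)[1],
                  0, r_v_max, target_vt, f_tol = f_tol,
                  increasing = FALSE, what = "patient-1 tidal volume (ml)")
    r_v1 <- s2$x
    iters <- iters + s1$iterations + s2$iterations
    vts <- vts_at(pip, r_v1)
    if (abs(vts[2] - target_vt) <= tol) break
  }
  conv <- all(abs(vts - target_vt) <= tol)
  if (!conv) warning("tidal-volume equalization did not converge to the ",
                     tol, " ml band")
  .tune_result(pip = pip, r_v1 = r_v1, r_v2 = 0, vt1 = vts[1], vt2 = vts[2],
               iterations = iters, converged = conv, target = target_vt)
}

#' Independently adjust patient 2's tidal volume on the modified splitter
#'
#' Starting from the configuration given by `settings` with both restrictors
#' fully open (the baseline), changes patient 2's tidal volume by
#' `delta_fraction` while holding patient 1's at its baseline value. For a
#' decrease, PIP is held and patient 2's restrictor is raised. For an
#' increase, PIP is raised until patient 2 reaches the target and then
#' patient 1's restrictor is raised to bring patient 1 back to baseline.
#'
#' @param lung1,lung2 [lung_model()]s (the pair; identical lungs in the
#'   reference scenario).
#' @param delta_fraction fractional change for patient 2, in (-1, 1); e.g.
#'   -0.3 for a 30% reduction.
#' @param settings [ventilator_settings()] defining the baseline (its `pip`
#'   is the baseline PIP).
#' @param splitter a [splitter_config()] (topology forced to "modified").
#' @param tol acceptance band on the adjusted/maintained tidal volumes, ml.
#' @param r_v_max,pip_max search bounds.
#' @param f_tol inner bisection tolerance, ml.
#' @return A `tune_result`; `target` is patient 2's target tidal volume and
#'   the baseline volumes are attached as attribute `baseline`.
#' @export
adjust_patient2 <- function(lung1, lung2 = lung1, delta_fraction,
                            settings = ventilator_settings(pip = 18.5),
                            splitter = splitter_config("modified"),
                            tol = 1, r_v_max = 100, pip_max = 60,
                            f_tol = 0.25) {
  if (abs(delta_fraction) >= 1) stop("|delta_fraction| must be < 1")
  splitter$topology <- "modified"
  with_pip <- function(pip) ventilator_settings(pip, settings$peep,
                                                settings$rr, settings$ie)
  vts_at <- function(pip, r_v1, r_v2) {
    splitter$r_v1 <- r_v1
    splitter$r_v2 <- r_v2
    .steady_vts(build_modified(lung1, lung2, splitter), with_pip(pip))
  }
  baseline <- vts_at(settings$pip, 0, 0)
  target2 <- (1 + delta_fraction) * baseline[2]
  if (delta_fraction == 0) {
    res <- .tune_result(settings$pip, 0, 0, baseline[1], baseline[2],
                        iterations = 1L, converged = TRUE, target = target2)
  } else if (delta_fraction < 0) {
    s <- .bisect(function(rv) vts_at(settings$pip, 0, rv)[2],
                 0, r_v_max, target2, f_tol = f_tol, increasing = FALSE,
                 what = "patient-2 tidal volume (ml)")
    vts <- vts_at(settings$pip, 0, s$x)
    conv <- abs(vts[2] - target2) <= tol && abs(vts[1] - baseline[1]) <= tol
    res <- .tune_result(settings$pip, 0, s$x, vts[1], vts[2],
                        iterations = s$iterations, converged = conv,
                        target = target2)
  } else {
    s1 <- .bisect(function(p) vts_at(p, 0, 0)[2],
                  settings$peep + 0.1, pip_max, target2, f_tol = f_tol,
                  increasing = TRUE, what = "patient-2 tidal volume (ml)")
    s2 <- .bisect(function(rv) vts_at(s1$x, rv, 0)[1],
                  0, r_v_max, baseline[1], f_tol = f_tol, increasing = FALSE,
                  what = "patient-1 tidal volume (ml)")
    vts <- vts_at(s1$x, s2$x, 0)
    conv <- abs(vts[2] - target2) <= tol && abs(vts[1] - baseline[1]) <= tol
    res <- .tune_result(s1$x, s2$x, 0, vts[1], vts[2],
                        iterations = s1$iterations + s2$iterations,
                        converged = conv, target = target2)
  }
  attr(res, "baseline") <- baseline
  res
}
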