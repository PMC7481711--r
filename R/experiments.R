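# Scripted reproduction of the four study scenarios: validation with matched
# pairs, the standard splitter with mismatched pairs, tidal-volume
# equalization with the modified splitter, and independent adjustment of one
# patient. Each function simulates the reference configurations and reports
# achieved tidal volumes next to the closed-form single-branch prediction.

# reference configurations for matched pairs (PIP titrated to ~490 ml)
.VALIDATION_ROWS <- data.frame(
  pair = c("A-A", "B-B", "C-C", "D-D"),
  lung1 = c("A", "B", "C", "D"), lung2 = c("A", "B", "C", "D"),
  pip = c(15, 17, 18.5, 20.5), stringsAsFactors = FALSE)

# mismatched pairs on the standard splitter (PIP set for patient 1's ~490 ml)
.MISMATCH_ROWS <- data.frame(
  pair = c("A-A", "A-B", "A-C", "A-D", "B-C", "B-D", "C-D"),
  lung1 = c("A", "A", "A", "A", "B", "B", "C"),
  lung2 = c("A", "B", "C", "D", "C", "D", "D"),
  pip = c(15, 15, 15, 15, 17, 17, 18.5), stringsAsFactors = FALSE)

# reference (PIP, patient-1 restrictor) settings for the modified splitter
.EQUALIZE_ROWS <- data.frame(
  pair = c("A-A", "A-B", "A-C", "A-D", "B-C", "B-D", "C-D"),
  lung1 = c("A", "A", "A", "A", "B", "B", "C"),
  lung2 = c("A", "B", "C", "D", "C", "D", "D"),
  pip = c(15, 17, 18.33, 20.33, 18.5, 20.3, 20.3),
  r_v1 = c(0, 7, 11.67, 18, 6.67, 11.94, 8.67), stringsAsFactors = FALSE)

# independent-adjustment reference rows (matched moderate-ARDS pair)
.ADJUST_ROWS <- data.frame(
  label = c("C-C", "C-C(-)", "C-C(+)"),
  r_v1 = c(0, 0, 16.67), r_v2 = c(0, 16.67, 0),
  pip = c(18.5, 18.5, 22.67), stringsAsFactors = FALSE)

.with_pip <- function(settings, pip) {
  ventilator_settings(pip, settings$peep, settings$rr, settings$ie)
}

#' Validation: matched pairs on the standard splitter
#'
#' Simulates the four matched pairs A-A through D-D at their reference PIPs
#' and reports both tidal volumes, achieved PEEP and the closed-form
#' single-branch prediction. Optionally re-derives each PIP from scratch with
#' [tune_pip()].
#'
#' @param settings base [ventilator_settings()] (PEEP, RR, I:E).
#' @param splitter a [splitter_config()].
#' @param tune also run [tune_pip()] per pair and report the recovered PIP.
#' @param ... passed to [steady_state_summary()].
#' @return A data.frame, one row per pair.
#' @export
run_validation <- function(settings = ventilator_settings(),
                           splitter = splitter_config("standard"),
                           tune = TRUE, ...) {
  rows <- .VALIDATION_ROWS
  out <- lapply(seq_len(nrow(rows)), function(i) {
    l1 <- lung_preset(rows$lung1[i]); l2 <- lung_preset(rows$lung2[i])
    s <- .with_pip(settings, rows$pip[i])
    net <- build_standard(l1, l2, splitter)
    summ <- steady_state_summary(net, s, ...)
    res <- data.frame(pair = rows$pair[i], pip = rows$pip[i],
                      vt1_ml = summ$vt1_ml, vt2_ml = summ$vt2_ml,
                      peep1 = summ$peep1, peep2 = summ$peep2,
                      vt_oracle_ml = oracle_vt(l1, s, splitter),
                      steady_cycle = attr(summ, "steady_cycle"))
    res$resid_ml <- res$vt1_ml - res$vt_oracle_ml
    if (tune) {
      tr <- tune_pip(l1, l2, "standard", settings = settings,
                     splitter = splitter)
      res$pip_tuned <- tr$pip
      res$vt1_tuned_ml <- tr$vt1
    }
    res
  })
  do.call(rbind, out)
}

#' Mismatched pairs on the standard splitter
#'
#' Simulates the mismatched pairs at the PIP that ventilates patient 1
#' correctly and reports patient 2's tidal-volume deficit in ml and percent.
#'
#' @inheritParams run_validation
#' @return A data.frame, one row per pair, with `deficit_ml` and `deficit_pct`
#'   (patient 2 relative to patient 1) and closed-form predictions for both
#'   patients.
#' @export
run_standard_mismatch <- function(settings = ventilator_settings(),
                                  splitter = splitter_config("standard"),
                                  ...) {
  rows <- .MISMATCH_ROWS
  out <- lapply(seq_len(nrow(rows)), function(i) {
    l1 <- lung_preset(rows$lung1[i]); l2 <- lung_preset(rows$lung2[i])
    s <- .with_pip(settings, rows$pip[i])
    summ <- steady_state_summary(build_standard(l1, l2, splitter), s, ...)
    data.frame(pair = rows$pair[i], pip = rows$pip[i],
               vt1_ml = summ$vt1_ml, vt2_ml = summ$vt2_ml,
               deficit_ml = summ$vt1_ml - summ$vt2_ml,
               deficit_pct = 100 * (summ$vt1_ml - summ$vt2_ml) / summ$vt1_ml,
               peep1 = summ$peep1, peep2 = summ$peep2,
               vt1_oracle_ml = oracle_vt(l1, s, splitter),
               vt2_oracle_ml = oracle_vt(l2, s, splitter))
  })
  do.call(rbind, out)
}

#' Tidal-volume equalization on the modified splitter
#'
#' Simulates each mismatched pair at its reference (PIP, patient-1 restrictor)
#' setting and reports both achieved tidal volumes; optionally re-derives the
#' settings from scratch with [tune_modified()].
#'
#' @inheritParams run_validation
#' @param tune also run [tune_modified()] per mismatched pair.
#' @return A data.frame, one row per pair.
#' @export
run_modified_equalize <- function(settings = ventilator_settings(),
                                  splitter = splitter_config("modified"),
                                  tune = TRUE, ...) {
  rows <- .EQUALIZE_ROWS
  out <- lapply(seq_len(nrow(rows)), function(i) {
    l1 <- lung_preset(rows$lung1[i]); l2 <- lung_preset(rows$lung2[i])
    s <- .with_pip(settings, rows$pip[i])
    spl <- splitter
    spl$r_v1 <- rows$r_v1[i]; spl$r_v2 <- 0
    summ <- steady_state_summary(build_modified(l1, l2, spl), s, ...)
    res <- data.frame(pair = rows$pair[i], pip = rows$pip[i],
                      r_v1 = rows$r_v1[i],
                      vt1_ml = summ$vt1_ml, vt2_ml = summ$vt2_ml,
                      peep1 = summ$peep1, peep2 = summ$peep2,
                      vt1_oracle_ml = oracle_vt(l1, s, spl, r_v = rows$r_v1[i]),
                      vt2_oracle_ml = oracle_vt(l2, s, spl))
    if (tune) {
      tr <- tune_modified(l1, l2, settings = settings, splitter = splitter)
      res$pip_tuned <- tr$pip
      res$r_v1_tuned <- tr$r_v1
      res$vt1_tuned_ml <- tr$vt1
      res$vt2_tuned_ml <- tr$vt2
      res$tuned_converged <- tr$converged
    }
    res
  })
  do.call(rbind, out)
}

#' Independent adjustment of one patient's tidal volume
#'
#' Simulates the three reference rows for the matched moderate-ARDS pair
#' (baseline, patient 2 reduced, patient 2 increased) at their printed
#' restrictor/PIP settings, and optionally re-derives the -30% and +30%
#' adjustments from scratch with [adjust_patient2()].
#'
#' @inheritParams run_validation
#' @param adjust also run [adjust_patient2()] for delta -0.30 and +0.30.
#' @param delta fractional adjustment magnitude used when `adjust = TRUE`.
#' @return A data.frame, one row per configuration; re-derived rows carry
#'   label suffix "tuned".
#' @export
run_independent_adjust <- function(settings = ventilator_settings(pip = 18.5),
                                   splitter = splitter_config("modified"),
                                   adjust = TRUE, delta = 0.30, ...) {
  lc <- lung_preset("C")
  rows <- .ADJUST_ROWS
  out <- lapply(seq_len(nrow(rows)), function(i) {
    s <- .with_pip(settings, rows$pip[i])
    spl <- splitter
    spl$r_v1 <- rows$r_v1[i]; spl$r_v2 <- rows$r_v2[i]
    summ <- steady_state_summary(build_modified(lc, lc, spl), s, ...)
    data.frame(label = rows$label[i], pip = rows$pip[i],
               r_v1 = rows$r_v1[i], r_v2 = rows$r_v2[i],
               vt1_ml = summ$vt1_ml, vt2_ml = summ$vt2_ml,
               peep1 = summ$peep1, peep2 = summ$peep2)
  })
  out <- do.call(rbind, out)
  if (adjust) {
    for (d in c(-delta, delta)) {
      tr <- adjust_patient2(lc, lc, delta_fraction = d, settings = settings,
                            splitter = splitter)
      out <- rbind(out, data.frame(
        label = sprintf("C-C(%+.0f%%) tuned", 100 * d),
        pip = tr$pip, r_v1 = tr$r_v1, r_v2 = tr$r_v2,
        vt1_ml = tr$vt1, vt2_ml = tr$vt2, peep1 = NA, peep2 = NA))
    }
  }
  rownames(out) <- NULL
  out
}
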