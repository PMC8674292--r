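# Assay arithmetic: ECL protein lowering, efficiency-corrected qPCR
# abundance, transwell apparent permeability, and the unbound
# brain-to-plasma partition coefficient.

#' Percent protein lowering from ECL duplicate signals
#'
#' Per animal: ratio = mean(target duplicates) / mean(normaliser
#' duplicates) x 1000; fold change = ratio / grand mean of the vehicle
#' group's ratios; percent lowering = (1 - fold change) x 100. The vehicle
#' group's mean lowering is therefore 0 by construction. In `wbc = TRUE`
#' mode (white blood cells, no normaliser measured) raw target means are
#' used in place of ratios, against the vehicle grand target mean.
#'
#' @param records data.frame: animal_id, group, target (numeric signal),
#'   normaliser; duplicates as repeated rows per animal.
#' @param vehicle Vehicle group label (default "vehicle").
#' @param wbc Normaliser-free variant (default `FALSE`).
#' @return list(per_animal = data.frame(animal_id, group, ratio, fold,
#'   lowering_pct, excluded, reason), per_group = data.frame(group, n,
#'   mean_lowering, sem)).
#' @export
ecl_lowering <- function(records, vehicle = "vehicle", wbc = FALSE) {
  if (!any(records$group == vehicle)) stop("no vehicle animals")
  per <- do.call(rbind, lapply(split(records, records$animal_id), function(a) {
    tgt <- mean(a$target)
    nrm <- if (wbc) NA_real_ else mean(a$normaliser)
    excluded <- !wbc && (is.na(nrm) || nrm == 0)
    data.frame(animal_id = a$animal_id[1], group = a$group[1],
               ratio = if (wbc) tgt else if (excluded) NA_real_ else 1000 * tgt / nrm,
               excluded = excluded,
               reason = if (excluded) "zero or missing normaliser mean" else "",
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  grand <- mean(per$ratio[per$group == vehicle & !per$excluded])
  per$fold <- per$ratio / grand
  per$lowering_pct <- (1 - per$fold) * 100
  grp <- do.call(rbind, lapply(split(per[!per$excluded, ], per$group[!per$excluded]),
    function(g) {
      data.frame(group = g$group[1], n = nrow(g),
                 mean_lowering = mean(g$lowering_pct),
                 sem = stats::sd(g$lowering_pct) / sqrt(nrow(g)),
                 stringsAsFactors = FALSE)
    }))
  rownames(grp) <- NULL
  list(per_animal = per, per_group = grp)
}

#' Efficiency-corrected qPCR abundance and percent of vehicle
#'
#' Abundance of each amplicon is `(1 + E)^(-Ct)`; the target is normalised
#' to the housekeeping amplicon, and each sample's normalised abundance is
#' expressed as a percent of the vehicle group's mean — the
#' efficiency-generalised form of the 2^-ddCt method.
#'
#' @param records data.frame: sample_id, group, target_ct, norm_ct.
#' @param e_target,e_norm Amplification efficiencies in (0, 1.2].
#' @param vehicle Vehicle group label.
#' @return The records with abundance_target, abundance_norm, normalised,
#'   percent_of_vehicle appended.
#' @export
qpcr_percent <- function(records, e_target, e_norm, vehicle = "vehicle") {
  for (e in c(e_target, e_norm)) {
    if (is.na(e) || e <= 0 || e > 1.2) stop("efficiency outside (0, 1.2]: ", e)
  }
  records$abundance_target <- (1 + e_target)^(-records$target_ct)
  records$abundance_norm <- (1 + e_norm)^(-records$norm_ct)
  records$normalised <- records$abundance_target / records$abundance_norm
  vm <- mean(records$normalised[records$group == vehicle])
  records$percent_of_vehicle <- 100 * records$normalised / vm
  records
}

#' Estimate qPCR amplification efficiency from a dilution series
#'
#' E = 10^(-1/slope) - 1, with slope the least-squares slope of Ct vs
#' log10(input amount). A perfect doubling assay has slope -1/log10(2)
#' (about -3.32) and E = 1.
#'
#' @param ct Ct values.
#' @param input Input amounts (same length).
#' @return Efficiency E.
#' @export
estimate_efficiency <- function(ct, input) {
  stopifnot(length(ct) == length(input), length(ct) >= 2)
  slope <- stats::coef(stats::lm(ct ~ log10(input)))[[2]]
  10^(-1 / slope) - 1
}

#' Apparent permeability from a receiver concentration time course
#'
#' `Papp = (dCr/dt) * Vr / (A * C0)` with dCr/dt the least-squares slope of
#' receiver concentration (uM) vs time (s) — a difference quotient when
#' only two timepoints exist — Vr the receiver volume (cm^3), A the insert
#' area (cm^2; 1.13 for a 12-well format), C0 the measured donor
#' concentration at time zero (uM). Result in cm/s.
#'
#' @param times Timepoints in seconds (>= 2).
#' @param receiver_conc Receiver concentrations (uM) at `times`.
#' @param vr Receiver volume (cm^3).
#' @param area Insert area (cm^2), default 1.13.
#' @param c0 Donor concentration at time zero (uM), > 0.
#' @return Papp in cm/s.
#' @export
papp <- function(times, receiver_conc, vr, area = 1.13, c0) {
  if (length(times) < 2) stop("need >= 2 receiver timepoints")
  if (c0 <= 0) stop("C0 must be positive")
  stopifnot(length(times) == length(receiver_conc))
  slope <- if (length(times) == 2) {
    diff(receiver_conc) / diff(times)
  } else {
    stats::coef(stats::lm(receiver_conc ~ times))[[2]]
  }
  slope * vr / (area * c0)
}

#' Efflux metrics from directional permeabilities
#'
#' Returns both forms: `as_printed`, the difference
#' `Papp(B->A) - Papp(A->B)` exactly as the source arithmetic defines the
#' net efflux ratio, and `conventional_ratio`, the quotient
#' `Papp(B->A) / Papp(A->B)` customary in transporter assays (`NA` when
#' the denominator is zero). Neither is privileged; both are labelled.
#'
#' @param papp_ab Apical-to-basolateral Papp (cm/s).
#' @param papp_ba Basolateral-to-apical Papp (cm/s).
#' @return list(as_printed, conventional_ratio).
#' @export
efflux_metrics <- function(papp_ab, papp_ba) {
  stopifnot(papp_ab >= 0, papp_ba >= 0)
  list(as_printed = papp_ba - papp_ab,
       conventional_ratio = if (papp_ab == 0) NA_real_ else papp_ba / papp_ab)
}

#' Unbound brain-to-plasma partition coefficient
#'
#' `Kp,uu = Cbrain * fu,b / (Cplasma * fu,p)`: the ratio of unbound brain
#' to unbound plasma drug concentration. 1 means free drug equilibrates
#' across the blood-brain barrier.
#'
#' @param c_brain,c_plasma Total concentrations (same units), > 0.
#' @param fu_brain,fu_plasma Unbound fractions in \[0, 1\].
#' @return Dimensionless Kp,uu.
#' @export
kpuu <- function(c_brain, c_plasma, fu_brain, fu_plasma) {
  stopifnot(c_brain > 0, c_plasma > 0,
            fu_brain >= 0, fu_brain <= 1, fu_plasma >= 0, fu_plasma <= 1)
  if (c_plasma * fu_plasma == 0) stop("zero unbound plasma term")
  c_brain * fu_brain / (c_plasma * fu_plasma)
}
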