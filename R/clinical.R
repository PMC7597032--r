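# Clinical neuropathy scoring and patient grouping.

#' Construct a clinical record
#'
#' @param mnsi_history Michigan Neuropathy Screening Instrument, patient
#'   history questionnaire score (max 15).
#' @param mnsi_physical MNSI physical-assessment score (max 10).
#' @param mdns Michigan Diabetes Neuropathy Score.
#' @param vpt_hallux,vpt_malleolus Vibration perception thresholds, Volt
#'   (max 40).
#' @param age Years. @param bmi kg/m^2. @param yod Years of disease.
#' @param diagnosis `"type1"` or `"LADA"`.
#' @return Object of class `clinical_record`.
#' @export
clinical_record <- function(mnsi_history, mnsi_physical, mdns,
                            vpt_hallux, vpt_malleolus,
                            age = NA_real_, bmi = NA_real_, yod = NA_real_,
                            diagnosis = c("type1", "LADA")) {
  diagnosis <- match.arg(diagnosis)
  chk <- function(x, max, what) {
    if (is.na(x) || x < 0 || x > max)
      stop(what, " must lie in [0, ", max, "]")
    x
  }
  structure(list(
    mnsi_history = chk(mnsi_history, 15, "MNSI history score"),
    mnsi_physical = chk(mnsi_physical, 10, "MNSI physical score"),
    mdns = chk(mdns, 46, "Michigan Diabetes Neuropathy Score"),
    vpt_hallux = chk(vpt_hallux, 40, "VPT at hallux"),
    vpt_malleolus = chk(vpt_malleolus, 40, "VPT at malleolus"),
    age = age, bmi = bmi, yod = yod, diagnosis = diagnosis),
    class = "clinical_record")
}

#' Composite neuropathy variable NS-VPT
#'
#' Sum of four contributions, each divided by its full-scale value: MNSI
#' history (/15), MNSI physical assessment (/10), VPT at hallux (/40) and
#' VPT at malleolus (/40). Expressed in relative units, range `[0, 4]`.
#'
#' @param rec A [clinical_record()].
#' @return NS-VPT in relative units.
#' @export
ns_vpt <- function(rec) {
  rec$mnsi_history / 15 + rec$mnsi_physical / 10 +
    rec$vpt_hallux / 40 + rec$vpt_malleolus / 40
}

#' Assign a patient to the N / D / LADA group
#'
#' A LADA diagnosis maps to LADA. Otherwise the patient is neuropathic (N)
#' when at least two of the three conditions hold, with strict inequalities:
#' MNSI > 2, Michigan Diabetes Neuropathy Score > 7, VPT > 25 Volt; else D.
#' The MNSI criterion uses the physical-assessment score by convention
#' (switchable to the history score).
#'
#' @param rec A [clinical_record()].
#' @param vpt VPT used by the rule, Volt; defaults to the hallux VPT.
#' @param mnsi_component Which MNSI sub-score the `> 2` cut-off refers to.
#' @return `"N"`, `"D"` or `"LADA"`.
#' @export
classify_group <- function(rec, vpt = rec$vpt_hallux,
                           mnsi_component = c("physical", "history")) {
  mnsi_component <- match.arg(mnsi_component)
  if (rec$diagnosis == "LADA") return("LADA")
  mnsi <- if (mnsi_component == "physical") rec$mnsi_physical else
    rec$mnsi_history
  if (any(is.na(c(mnsi, rec$mdns, vpt)))) stop("missing grouping criterion")
  hits <- sum(mnsi > 2, rec$mdns > 7, vpt > 25)
  if (hits >= 2) "N" else "D"
}

#' Score and group a cohort of clinical records
#'
#' @param records List of [clinical_record()] objects (optionally named).
#' @param ... Passed to [classify_group()].
#' @return data.frame with one row per patient: the raw scores, `NSVPT` and
#'   the assigned `group`.
#' @export
score_cohort <- function(records, ...) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(patient = if (!is.null(names(records))) names(records)[i] else
      paste0("pt", i),
      mnsi_history = r$mnsi_history, mnsi_physical = r$mnsi_physical,
      mdns = r$mdns, vpt_hallux = r$vpt_hallux,
      vpt_malleolus = r$vpt_malleolus, age = r$age, bmi = r$bmi,
      yod = r$yod, diagnosis = r$diagnosis,
      NSVPT = ns_vpt(r), group = classify_group(r, ...))
  })
  do.call(rbind, rows)
}
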