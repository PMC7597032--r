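# Controlled vocabularies and the canonical variable registry.

#' Bone labels understood by the pipeline
#'
#' Controlled vocabulary for mesh labels: calcaneus (CAL), talus (TAL),
#' navicular (NAV), cuboid (CUB), cuneiforms (CN1-CN3), metatarsals (M1-M5),
#' phalanges (P1-P5) and the segmented ground (GROUND).
#'
#' @format Character vector of length 20.
#' @export
BONE_LABELS <- c("CAL", "TAL", "NAV", "CUB", "CN1", "CN2", "CN3",
                 paste0("M", 1:5), paste0("P", 1:5), "GROUND")

# the ten forefoot bones carrying angle + height variables
forefoot_bones <- function() c(paste0("M", 1:5), paste0("P", 1:5))

# the five metatarsophalangeal pairs carrying relative orientation variables
mtp_pairs <- function() paste0("M", 1:5, "P", 1:5)

# midfoot bones carrying height variables only (longitudinal arch proxies)
midfoot_bones <- function() c("CUB", "NAV")

#' Canonical names of the 84 skeletal ("3D") variables
#'
#' Naming scheme is `<measure>_<bone(s)>`: absolute inclinations `I3`/`IL`/
#' `IF`/`IT` for the ten forefoot bones, relative orientations `R3`/`RL`/
#' `RF`/`RT` for the five metatarsophalangeal pairs, absolute minimum heights
#' `Hg` and foot-length-normalised heights `HgR` for the ten forefoot bones
#' plus cuboid and navicular.
#'
#' @return Character vector of length 84, in fixed canonical order.
#' @export
variable_names_3d <- function() {
  fb <- forefoot_bones()
  pr <- mtp_pairs()
  c(paste0("I3_", fb), paste0("IL_", fb), paste0("IF_", fb), paste0("IT_", fb),
    paste0("R3_", pr), paste0("RL_", pr), paste0("RF_", pr), paste0("RT_", pr),
    paste0("Hg_", fb), paste0("HgR_", fb),
    paste0("Hg_", midfoot_bones()), paste0("HgR_", midfoot_bones()))
}

#' Names of the 12 regional loading (LOAD) variables
#'
#' Three metrics (peak pressure `PP`, pressure-time integral `PTI`,
#' contact-time-normalised integral `PTIN`) in each of the four forefoot
#' regions: hallux `HLX`, first metatarsal `MET1`, central metatarsals
#' `MET24`, fifth metatarsal `MET5`.
#'
#' @return Character vector of length 12.
#' @export
variable_names_load <- function() {
  as.vector(t(outer(c("PP", "PTI", "PTIN"), load_regions(), paste, sep = "_")))
}

# the four forefoot pressure regions, medial to lateral reading order
load_regions <- function() c("HLX", "MET1", "MET24", "MET5")

variable_names_func <- function() c("CT", "AI")
variable_names_biol <- function() c("AGE", "BMI")
variable_names_clin <- function() c("YOD", "NSVPT")

#' All 102 analysis variable names grouped by family
#'
#' @return Named list with elements `threeD` (84), `load` (12), `func` (2),
#'   `biol` (2), `clin` (2).
#' @export
variable_registry <- function() {
  list(threeD = variable_names_3d(),
       load   = variable_names_load(),
       func   = variable_names_func(),
       biol   = variable_names_biol(),
       clin   = variable_names_clin())
}

#' Families of 3D variables used in correlation summaries
#'
#' Partition of the 84 skeletal variables into the six reporting families:
#' angles per projection plane (lateral, transverse, frontal, 3D; 15 each)
#' and minimum heights of the forefoot (20) and midfoot (4).
#'
#' @return Named list of character vectors partitioning [variable_names_3d()].
#' @export
variable_families_3d <- function() {
  fb <- forefoot_bones()
  pr <- mtp_pairs()
  list(
    lateral_angles    = c(paste0("IL_", fb), paste0("RL_", pr)),
    transverse_angles = c(paste0("IT_", fb), paste0("RT_", pr)),
    frontal_angles    = c(paste0("IF_", fb), paste0("RF_", pr)),
    threeD_angles     = c(paste0("I3_", fb), paste0("R3_", pr)),
    forefoot_heights  = c(paste0("Hg_", fb), paste0("HgR_", fb)),
    midfoot_heights   = c(paste0("Hg_", midfoot_bones()),
                          paste0("HgR_", midfoot_bones()))
  )
}
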