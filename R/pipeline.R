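# End-to-end orchestration: simulate or load a study, run every stage, and
# write a reproducible report bundle.

#' Pipeline configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; every random stage derives from it.
#' @param n Named group sizes for the synthetic study.
#' @param contact_threshold Contact threshold, kPa.
#' @param sector_fractions Plantar-angle sector fractions (medial, central,
#'   lateral); must be positive and sum to 1.
#' @param toe_offset Posterior offset of the toe line from the hallux
#'   marker, mm.
#' @param per_sensor_pti Use the per-sensor PTI convention.
#' @param area_weighted Area-weighted bone PCA.
#' @param alpha Significance level of the correlation screen.
#' @param p_adjust `"none"` or `"BH"`.
#' @param n_vertices Vertex budget per synthetic bone.
#' @return Validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(out_dir = tempfile("footload_run_"), seed = 1L,
                            n = c(N = 7, D = 8, LADA = 1),
                            contact_threshold = 10,
                            sector_fractions = c(0.30, 0.51, 0.19),
                            toe_offset = 15, per_sensor_pti = FALSE,
                            area_weighted = FALSE, alpha = 0.05,
                            p_adjust = "none", n_vertices = 500) {
  if (any(sector_fractions <= 0) || abs(sum(sector_fractions) - 1) > 1e-9)
    stop("validation: sector fractions must be positive and sum to 1")
  if (alpha <= 0 || alpha >= 1)
    stop("validation: alpha must lie in (0, 1)")
  if (seed >= 2^31 || seed < 0) stop("validation: seed out of range")
  structure(list(out_dir = out_dir, seed = as.integer(seed), n = n,
                 contact_threshold = contact_threshold,
                 sector_fractions = sector_fractions,
                 toe_offset = toe_offset, per_sensor_pti = per_sensor_pti,
                 area_weighted = area_weighted, alpha = alpha,
                 p_adjust = p_adjust, n_vertices = n_vertices),
            class = "pipeline_config")
}

#' Simulate a full study: one foot scan + five pressure trials + clinical
#' record per patient
#'
#' Per-patient inputs are generated with seeded variation: bone poses are
#' jittered around the default foot, and the second-phalanx dorsiflexion is
#' linked to the central-metatarsal pressure amplitude so the study carries
#' a real skeletal-to-load relationship for the correlation screen to find.
#'
#' @param n Named group sizes.
#' @param seed Master seed.
#' @param n_vertices Vertex budget per bone.
#' @param link_slope kPa of central-metatarsal amplitude per degree of
#'   planted second-phalanx 3D inclination.
#' @param link_noise_sd SD (kPa) of the amplitude noise around the link.
#' @return List of per-patient entries: `group`, `foot` (from
#'   [make_foot()]), `gait` (from [make_pressure_trials()]) and `clinical`.
#' @export
simulate_study <- function(n = c(N = 7, D = 8, LADA = 1), seed = 1L,
                           n_vertices = 500, link_slope = 6,
                           link_noise_sd = 45) {
  groups <- rep(names(n), n)
  cohort <- make_cohort(default_cohort_spec(n = n, links = list()),
                        seed = seed)
  study <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    pseed <- (seed + 7919L * i) %% .Machine$integer.max
    set.seed(pseed)
    target_i3p2 <- stats::rnorm(1, 5.7, 8.9)
    fspec <- default_foot_spec(n_vertices = n_vertices)
    fspec$bones$P2$rotation[2] <- -target_i3p2
    foot <- make_foot(fspec, seed = pseed + 1L)
    realized <- foot$truth[["I3_P2"]]
    gspec <- default_gait_spec()
    set.seed(pseed + 2L)
    scale <- pmax(0.3, stats::rnorm(length(gspec$amplitudes), 1, 0.15))
    gspec$amplitudes <- gspec$amplitudes * scale
    gspec$amplitudes[["MET24"]] <-
      max(50, 418 + link_slope * (realized - 5.7) +
            stats::rnorm(1, 0, link_noise_sd))
    gait <- make_pressure_trials(gspec, seed = pseed + 3L)
    study[[i]] <- list(patient = sprintf("pt%02d", i), group = groups[i],
                       foot = foot, gait = gait,
                       clinical = cohort$records[[i]])
  }
  study
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Measures every patient's 84 skeletal variables from the meshes, the 12
#' LOAD and 2 FUNC variables from the pressure trials, scores the clinical
#' records, assembles the variable table, and runs the exhaustive
#' correlation screen (per group: 1512 inter, 3486 intra-3D and 66
#' intra-LOAD pairs), family summaries and N-vs-D t-tests. All results are
#' written as CSV next to a JSON copy of the configuration; reruns with the
#' same configuration and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param study Optional pre-built study (from [simulate_study()] or loaded
#'   from disk); by default one is simulated from the config.
#' @return Invisibly, a list with the variable `table`, `correlations`,
#'   `summary`, `ttests` and the bundle `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(study))
    study <- simulate_study(config$n, config$seed,
                            n_vertices = config$n_vertices)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (entry in study) {
    vars <- tryCatch(
      foot_3d_variables(entry$foot$meshes,
                        area_weighted = config$area_weighted),
      error = function(e) stop("geometry stage failed for ", entry$patient,
                               ": ", conditionMessage(e)))
    press <- tryCatch(
      analyze_pressure_trials(entry$gait$trials,
                              threshold = config$contact_threshold,
                              fractions = config$sector_fractions,
                              toe_offset = config$toe_offset,
                              per_sensor_pti = config$per_sensor_pti),
      error = function(e) stop("pressure stage failed for ", entry$patient,
                               ": ", conditionMessage(e)))
    cl <- entry$clinical
    row <- c(as.list(vars[variable_names_3d()]),
             as.list(press$load),
             CT = unname(press$func["CT"]), AI = unname(press$func["AI"]),
             AGE = cl$age, BMI = cl$bmi, YOD = cl$yod, NSVPT = ns_vpt(cl))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(patient = entry$patient,
                       group = classify_group(cl)),
            as.data.frame(row, check.names = FALSE))
  }
  table <- do.call(rbind, rows)
  groups <- intersect(c("ALL", "N", "D"), c("ALL", unique(table$group)))
  cors <- do.call(rbind, lapply(groups, function(g)
    if (identical(g, "ALL") || sum(table$group == g) > 0)
      correlate_all(table, g, alpha = config$alpha,
                    p_adjust = config$p_adjust)))
  summ <- summarize_correlations(cors)
  tt <- do.call(rbind, lapply(unlist(variable_registry()), function(v) {
    r <- group_ttest(table, v)
    data.frame(variable = v, t = r$t, p = r$p, df = r$df,
               n_N = r$n[1], n_D = r$n[2], flag = r$flag)
  }))
  clin <- do.call(rbind, lapply(study, function(e)
    score_cohort(stats::setNames(list(e$clinical), e$patient))))
  paths <- c(
    variables = file.path(config$out_dir, "variables.csv"),
    correlations = file.path(config$out_dir, "correlations.csv"),
    summary = file.path(config$out_dir, "summary_families.csv"),
    r2_summary = file.path(config$out_dir, "summary_r2.csv"),
    ttests = file.path(config$out_dir, "ttests_n_vs_d.csv"),
    clinical = file.path(config$out_dir, "clinical.csv"),
    config = file.path(config$out_dir, "config.json"))
  utils::write.csv(table, paths["variables"], row.names = FALSE)
  utils::write.csv(cors, paths["correlations"], row.names = FALSE)
  utils::write.csv(summ$families, paths["summary"], row.names = FALSE)
  utils::write.csv(summ$r2_significant, paths["r2_summary"],
                   row.names = FALSE)
  utils::write.csv(tt, paths["ttests"], row.names = FALSE)
  utils::write.csv(clin, paths["clinical"], row.names = FALSE)
  jsonlite::write_json(
    c(unclass(config),
      list(package_version = as.character(utils::packageVersion("footload")))),
    paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(list(table = table, correlations = cors, summary = summ,
                 ttests = tt, paths = paths))
}
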