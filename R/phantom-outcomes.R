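#' Damage-to-deficit outcome model
#'
#' Generative model linking structure-level lesion burden to longitudinal
#' functional outcomes. For parameter p of subject s at day t (>= 0):
#'
#' `value = baseline_p * (1 - D) + noise`, with deficit
#' `D = sum_k beta[p, k] * PoS[s, k] / 100 * 2^(-t / halflife_p)`
#' and `noise ~ N(0, noise_sd_p)`. Timepoints with `t < 0` are pre-stroke
#' and carry no deficit. Positive betas therefore depress the outcome in
#' proportion to the percent of structure k lesioned, with exponential
#' recovery at the per-parameter half-life; negative betas model parameters
#' that increase after stroke (e.g. stance percent).
#'
#' The modified Rankin Scale is generated separately: a latent deficit
#' score (the mRS row's `D` plus noise) is thresholded onto the 0-6 integer
#' scale via `mrs_thresholds`.
#'
#' @param baseline Tibble `parameter`, `limb`, `baseline`, `units`.
#' @param beta Tibble `parameter`, `structure_id`, `beta` (deficit per unit
#'   PoS fraction).
#' @param noise_sd Tibble `parameter`, `noise_sd` (>= 0, outcome units;
#'   latent-score units for mRS).
#' @param halflife Tibble `parameter`, `halflife_days` (> 0).
#' @param mrs_thresholds Increasing latent-score cut points mapping the
#'   latent deficit onto mRS grades 0-6 (6 values).
#' @return An `outcome_model` list.
#' @export
outcome_model <- function(baseline, beta, noise_sd, halflife,
                          mrs_thresholds = c(0.05, 0.15, 0.3, 0.5, 0.7,
                                             0.95)) {
  baseline <- tibble::as_tibble(baseline)
  beta <- tibble::as_tibble(beta)
  noise_sd <- tibble::as_tibble(noise_sd)
  halflife <- tibble::as_tibble(halflife)
  stopifnot(all(c("parameter", "limb", "baseline", "units") %in%
                  names(baseline)),
            all(c("parameter", "structure_id", "beta") %in% names(beta)),
            all(c("parameter", "noise_sd") %in% names(noise_sd)),
            all(c("parameter", "halflife_days") %in% names(halflife)))
  if (any(noise_sd$noise_sd < 0)) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (any(halflife$halflife_days <= 0)) {
    stop("half-lives must be > 0", call. = FALSE)
  }
  if (length(mrs_thresholds) != 6 || is.unsorted(mrs_thresholds)) {
    stop("`mrs_thresholds` must be 6 nondecreasing cut points",
         call. = FALSE)
  }
  structure(list(baseline = baseline, beta = beta, noise_sd = noise_sd,
                 halflife = halflife, mrs_thresholds = mrs_thresholds),
            class = "outcome_model")
}

# healthy means echo typical porcine gait/open-field magnitudes
default_baseline_table <- function() {
  tibble::tribble(
    ~parameter,           ~limb, ~baseline, ~units,
    "velocity",           "LF",  198.78,    "cm/s",
    "cadence",            "LF",  133.01,    "strides/min",
    "stride_length",      "LF",  89.01,     "cm",
    "step_length",        "LF",  44.36,     "cm",
    "swing_percent",      "LF",  51.93,     "%",
    "stance_percent",     "LF",  48.06,     "%",
    "distance_traveled",  NA,    75.70,     "m",
    "movement_duration",  NA,    230.55,    "s",
    "mrs",                NA,    0,         "score"
  )
}

#' Default outcome model for a phantom atlas
#'
#' Deficit coefficients target motor-associated structures (putamen,
#' globus pallidus, primary somatosensory cortex) most strongly, with
#' weaker loadings on the temporal/visual structures that the infarct also
#' covers but that do not drive gait; `stance_percent` carries a negative
#' beta (it rises after stroke). Noise defaults to 10% of each baseline,
#' and deficits recover with a 7-day half-life.
#'
#' @param atlas A phantom [label_atlas()]; betas attach to its ipsilateral
#'   structure labels by name.
#' @param ipsilateral Hemisphere carrying the lesion.
#' @param noise_frac Noise SD as a fraction of baseline (mRS latent noise
#'   uses `noise_frac` directly).
#' @return An [outcome_model()].
#' @export
default_outcome_model <- function(atlas, ipsilateral = "right",
                                  noise_frac = 0.10) {
  lk <- atlas$lookup
  id_of <- function(nm) {
    hit <- lk$label_id[lk$name == paste0(nm, "_", ipsilateral)]
    if (length(hit) != 1) NA_integer_ else hit
  }
  motor <- c(putamen = 0.55, globus_pallidus = 0.45,
             primary_somatosensory_cortex = 0.40)
  weak <- c(claustrum = 0.05, superior_temporal_gyrus = 0.05)
  loadings <- c(motor, weak)
  ids <- vapply(names(loadings), id_of, integer(1))
  keep <- !is.na(ids)
  loadings <- loadings[keep]; ids <- ids[keep]

  gait <- c("velocity", "cadence", "stride_length", "step_length",
            "swing_percent")
  beta <- purrr::map_dfr(c(gait, "stance_percent", "distance_traveled",
                           "movement_duration", "mrs"), function(p) {
    scale <- switch(p, stance_percent = -0.7, mrs = 1.6, 1)
    tibble::tibble(parameter = p, structure_id = ids,
                   beta = unname(loadings) * scale)
  })
  baseline <- default_baseline_table()
  outcome_model(
    baseline = baseline,
    beta = beta,
    noise_sd = tibble::tibble(
      parameter = baseline$parameter,
      noise_sd = ifelse(baseline$parameter == "mrs", noise_frac,
                        noise_frac * abs(baseline$baseline))),
    halflife = tibble::tibble(parameter = baseline$parameter,
                              halflife_days = 7)
  )
}

#' Sample per-subject structure lesion burden for a cohort
#'
#' Draws a plausible joint distribution of per-structure PoS across stroked
#' subjects without building volumes: each structure has a lesion incidence
#' probability and a mean coverage, and a subject's PoS in a lesioned
#' structure is Beta-distributed around that mean with a subject-level
#' severity multiplier (so severely infarcted subjects are damaged across
#' structures, mimicking a territorial infarct). Control subjects have PoS
#' 0 everywhere.
#'
#' @param structures Tibble `structure_id`, `mean_pos` (percent),
#'   `incidence` (probability in \[0, 1\]). Defaults echo a territorial
#'   MCA infarct over the ipsilateral labels of `atlas`.
#' @param n_stroked,n_control Cohort sizes (defaults 7 and 5).
#' @param atlas Optional phantom atlas used to build default `structures`.
#' @param ipsilateral Hemisphere of the infarct for the defaults.
#' @param severity_range Range of the uniform subject-level severity
#'   multiplier; `c(1, 1)` makes per-structure coverage independent across
#'   structures (no territorial coupling).
#' @param seed Integer RNG seed.
#' @return Tibble `subject_id`, `group` (`"MCAO"`/`"control"`),
#'   `structure_id`, `pos_percent`.
#' @export
sample_cohort_pos <- function(structures = NULL, n_stroked = 7,
                              n_control = 5, atlas = NULL,
                              ipsilateral = "right",
                              severity_range = c(0.6, 1.4), seed = 1L) {
  if (is.null(structures)) {
    if (is.null(atlas)) {
      stop("supply `structures` or an `atlas` to derive them from",
           call. = FALSE)
    }
    lk <- atlas$lookup
    ips <- lk[lk$hemisphere == ipsilateral & !lk$is_ventricle &
                !lk$is_cerebellum, ]
    n <- nrow(ips)
    # severity falls off across structures; proximal structures always hit
    structures <- tibble::tibble(
      structure_id = ips$label_id,
      mean_pos = pmax(60 * exp(-(seq_len(n) - 1) / 4), 5),
      incidence = pmin(1, 1.05 * exp(-(seq_len(n) - 1) / 8))
    )
  }
  structures <- tibble::as_tibble(structures)
  stopifnot(all(c("structure_id", "mean_pos", "incidence") %in%
                  names(structures)))
  withr::with_seed(seed, {
    stroked <- purrr::map_dfr(seq_len(n_stroked), function(s) {
      severity <- stats::runif(1, severity_range[1], severity_range[2])
      hit <- stats::runif(nrow(structures)) < structures$incidence
      mu <- pmin(structures$mean_pos * severity, 95) / 100
      shape_sum <- 8
      pos <- ifelse(hit,
                    100 * stats::rbeta(nrow(structures), mu * shape_sum,
                                       (1 - mu) * shape_sum),
                    0)
      tibble::tibble(subject_id = sprintf("mcao%02d", s), group = "MCAO",
                     structure_id = structures$structure_id,
                     pos_percent = pos)
    })
    control <- purrr::map_dfr(seq_len(n_control), function(s) {
      tibble::tibble(subject_id = sprintf("ctrl%02d", s), group = "control",
                     structure_id = structures$structure_id,
                     pos_percent = 0)
    })
    dplyr::bind_rows(stroked, control)
  })
}

#' Generate longitudinal outcome tables from structure damage
#'
#' Applies an [outcome_model()] to per-subject PoS records, producing the
#' tidy longitudinal table the statistical modules consume. Values follow
#' the damage-to-deficit model documented in [outcome_model()]; mRS rows
#' are integers 0-6 from thresholding the latent deficit.
#'
#' @param cohort_pos Tibble `subject_id`, `group`, `structure_id`,
#'   `pos_percent` (see [sample_cohort_pos()] or [structure_overlap()]
#'   output reshaped accordingly). Subjects outside the stroked group must
#'   carry PoS 0.
#' @param model An [outcome_model()].
#' @param timepoints Numeric days; negative values are pre-stroke.
#' @param seed Integer RNG seed.
#' @return Tibble `subject_id`, `group`, `timepoint_day`, `limb`,
#'   `parameter`, `value`, `units`.
#' @export
generate_outcomes <- function(cohort_pos, model,
                              timepoints = c(-3, 2, 8, 15, 27),
                              seed = 1L) {
  stopifnot(inherits(model, "outcome_model"))
  cohort_pos <- tibble::as_tibble(cohort_pos)
  stopifnot(all(c("subject_id", "group", "structure_id", "pos_percent") %in%
                  names(cohort_pos)))
  known <- unique(cohort_pos$structure_id)
  bad <- setdiff(unique(model$beta$structure_id), known)
  if (length(bad)) {
    stop("outcome model references structure ids absent from `cohort_pos`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  subjects <- dplyr::distinct(cohort_pos, .data$subject_id, .data$group)

  # per subject x parameter raw (undecayed) deficit: sum_k beta * PoS / 100
  raw_deficit <- model$beta |>
    dplyr::inner_join(cohort_pos, by = "structure_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$subject_id, .data$parameter) |>
    dplyr::summarise(deficit0 = sum(.data$beta * .data$pos_percent / 100),
                     .groups = "drop")

  grid <- tidyr::expand_grid(subjects, model$baseline,
                             timepoint_day = timepoints) |>
    dplyr::left_join(raw_deficit, by = c("subject_id", "parameter")) |>
    dplyr::left_join(model$halflife, by = "parameter") |>
    dplyr::left_join(model$noise_sd, by = "parameter") |>
    dplyr::mutate(
      deficit0 = dplyr::coalesce(.data$deficit0, 0),
      decay = ifelse(.data$timepoint_day < 0, 0,
                     2^(-.data$timepoint_day / .data$halflife_days)),
      deficit = .data$deficit0 * .data$decay
    )

  withr::with_seed(seed, {
    noise <- stats::rnorm(nrow(grid), 0, grid$noise_sd)
    grid$value <- ifelse(
      grid$parameter == "mrs",
      pmin(findInterval(grid$deficit + noise, model$mrs_thresholds), 6),
      grid$baseline * (1 - grid$deficit) + noise
    )
  })
  out <- grid[, c("subject_id", "group", "timepoint_day", "limb",
                  "parameter", "value", "units")]
  dplyr::arrange(out, .data$subject_id, .data$timepoint_day,
                 .data$parameter)
}
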