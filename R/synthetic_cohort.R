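# Synthetic CT-exam cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# weight distribution given by a five-class truncated-normal mixture, a
# linear-Gaussian dose model in standardized predictors with published effect
# magnitudes, categorical protocol structure with rare levels, per-field
# missingness, decoy predictors unrelated to dose, and a ~1% contamination of
# injected dose outliers (mixed systemic + sporadic).

WEIGHT_BREAKS <- c(56.5, 79.5, 102.5, 136.5)
WEIGHT_CLASSES <- c("S", "M", "L", "XL", "XXL")
WEIGHT_PROPS <- c(10.65, 45.73, 33.38, 8.98, 1.26) / 100
WEIGHT_MEANS <- c(50.52, 68.72, 88.98, 113.69, 156.19)
WEIGHT_SDS <- c(4.90, 6.55, 6.49, 8.95, 26.81)

DEFAULT_COEFFICIENTS <- c(
  tube_current = 3.49, kvp = 1.73, weight = 1.15,
  collimator_width = 0.66, reference_mas = 0.37
)

RANGE_LEVELS <- c(
  "ABDOMEN_PELVIS", "CHEST_ROUTINE", "CHEST_PE", "ABDOMEN_MULTI",
  "CAP_TRAUMA", "SPINE_LUMBAR", "CARDIAC_CTA", "AORTA_CTA",
  "RENAL_STONE", "LIVER_TRIPHASE", "EXTREMITY", "PEDIATRIC_BODY"
)
RANGE_PROBS <- c(.26, .22, .14, .10, .08, .06, .05, .04, .03, .013, .0045, .0025)
RANGE_OFFSETS <- c(0.3, -0.4, 0.2, 0.4, 0.3, 0.2, -0.3, -0.2, -0.4, 0.4, -0.3, -0.4)
SYSTEMIC_LEVEL <- "LIVER_TRIPHASE"

SCANNER_LEVELS <- c("GE_LIGHTSPEED", "GE_DISCOVERY", "SIEMENS_DEFINITION",
                    "SIEMENS_SENSATION", "PHILIPS_BRILLIANCE", "PHILIPS_ICT")
SCANNER_PROBS <- c(.28, .22, .18, .14, .11, .07)
SCANNER_OFFSETS <- c(0.2, -0.1, 0.3, -0.3, 0.1, -0.2)

MODULATION_LEVELS <- c("NONE", "ANGULAR", "LONGITUDINAL", "COMBINED")
MODULATION_PROBS <- c(.15, .30, .25, .30)
MODULATION_OFFSETS <- c(0.2, -0.1, 0.0, -0.1)

#' Configuration for the synthetic CT-exam cohort
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' Defaults encode the study conditions the generator emulates: the five
#' standardized effect magnitudes of the dose model (tube current 3.49,
#' kVp 1.73, weight 1.15, collimator width 0.66, reference mAs 0.37, in
#' mGy per SD of the predictor), a 1% outlier contamination, and a weight
#' distribution following the five published size classes.
#'
#' @param n_exams number of exam records to generate.
#' @param true_coefficients named numeric vector of standardized effect sizes
#'   (mGy per SD) for the numeric dose predictors.
#' @param noise_sd SD (mGy) of the Gaussian dose noise.
#' @param outlier_fraction fraction of records injected as dose outliers.
#' @param outlier_inflation upper multiplicative dose-inflation factor for
#'   injected outliers (> 1); per-exam factors are drawn uniformly between a
#'   lower factor and this value, because real overexposures vary in magnitude.
#' @param systemic_share share of the outlier budget concentrated in one
#'   designated protocol level (a systemic protocol misconfiguration); the rest
#'   are sporadic, scattered uniformly over the cohort.
#' @param symmetric_contamination if `TRUE`, half of the sporadic outliers are
#'   deflated (dose divided by the factor) instead of inflated.
#' @param missing_rate_per_field per-field probability that a value is missing.
#' @param n_categories optional named integer vector overriding the number of
#'   levels of the categorical fields (`gender` cannot be overridden); when a
#'   field is overridden its levels get geometrically decaying frequencies with
#'   `rare_category_mass` spread over trailing rare levels.
#' @param rare_category_mass total probability mass placed on rare trailing
#'   levels when `n_categories` overrides a field.
#' @param head_fraction fraction of head exams (downstream analysis retains
#'   body exams only).
#' @param intercept baseline body CTDIvol (mGy) at average predictor values.
#' @param head_intercept baseline head CTDIvol (mGy).
#' @param dose_floor small positive lower bound applied to generated doses.
#' @param seed integer RNG seed; the same config yields an identical cohort.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_exams = 500, seed = 1)
#' cohort <- generate_cohort(cfg)
synthetic_config <- function(n_exams = 20000,
                             true_coefficients = DEFAULT_COEFFICIENTS,
                             noise_sd = 1.5,
                             outlier_fraction = 0.01,
                             outlier_inflation = 3,
                             systemic_share = 0.6,
                             symmetric_contamination = FALSE,
                             missing_rate_per_field = 0.02,
                             n_categories = NULL,
                             rare_category_mass = 0.01,
                             head_fraction = 0.08,
                             intercept = 15,
                             head_intercept = 45,
                             dose_floor = 0.2,
                             seed = 1) {
  stop_if(!is_count(n_exams), "n_exams must be a positive integer")
  stop_if(!is.numeric(true_coefficients) || is.null(names(true_coefficients)) ||
            any(!is.finite(true_coefficients)),
          "true_coefficients must be a named, finite numeric vector")
  stop_if(!is_prop(outlier_fraction, open_hi = TRUE),
          "outlier_fraction must be in [0, 1)")
  stop_if(!is_prop(missing_rate_per_field, open_hi = TRUE),
          "missing_rate_per_field must be in [0, 1)")
  stop_if(!is.numeric(outlier_inflation) || !is.finite(outlier_inflation) ||
            outlier_inflation <= 1,
          "outlier_inflation must be a finite factor > 1")
  stop_if(!is_prop(systemic_share), "systemic_share must be in [0, 1]")
  stop_if(!is.numeric(noise_sd) || !is.finite(noise_sd) || noise_sd < 0,
          "noise_sd must be finite and >= 0")
  stop_if(!is_prop(head_fraction, open_hi = TRUE), "head_fraction must be in [0, 1)")
  stop_if(!is.numeric(intercept) || !is.finite(intercept) ||
            !is.numeric(head_intercept) || !is.finite(head_intercept),
          "intercepts must be finite")
  stop_if(!is.numeric(dose_floor) || !is.finite(dose_floor) || dose_floor <= 0,
          "dose_floor must be a small positive value")
  stop_if(!is_prop(rare_category_mass, open_hi = TRUE),
          "rare_category_mass must be in [0, 1)")
  if (!is.null(n_categories)) {
    stop_if(is.null(names(n_categories)) || any(n_categories < 2),
            "n_categories must be a named vector of counts >= 2")
  }
  structure(list(
    n_exams = as.integer(n_exams),
    true_coefficients = true_coefficients,
    noise_sd = noise_sd,
    outlier_fraction = outlier_fraction,
    outlier_inflation = outlier_inflation,
    systemic_share = systemic_share,
    symmetric_contamination = isTRUE(symmetric_contamination),
    missing_rate_per_field = missing_rate_per_field,
    n_categories = n_categories,
    rare_category_mass = rare_category_mass,
    head_fraction = head_fraction,
    intercept = intercept,
    head_intercept = head_intercept,
    dose_floor = dose_floor,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Patient weight class
#'
#' Assigns a weight (kg) to the five size classes S/M/L/XL/XXL, with breaks at
#' 56.5, 79.5, 102.5 and 136.5 kg. The lower bound of each class is inclusive,
#' the upper bound exclusive (56.5 kg is M, 79.5 kg is L).
#'
#' @param weight_kg positive numeric vector of weights in kg (NA allowed).
#' @return character vector of class labels.
#' @export
#' @examples
#' weight_class(c(50, 56.5, 79.5, 156.19))
weight_class <- function(weight_kg) {
  stop_if(any(weight_kg <= 0, na.rm = TRUE), "weights must be positive")
  idx <- findInterval(weight_kg, WEIGHT_BREAKS) + 1L
  WEIGHT_CLASSES[idx]
}

# Sample from N(mean, sd) truncated to (lo, hi) by inverse-CDF.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

# Levels/probs/offsets for a categorical field, honoring n_categories overrides.
categorical_spec <- function(field, config) {
  builtin <- switch(field,
    range_name = list(levels = RANGE_LEVELS, probs = RANGE_PROBS,
                      offsets = RANGE_OFFSETS),
    scanner_type = list(levels = SCANNER_LEVELS, probs = SCANNER_PROBS,
                        offsets = SCANNER_OFFSETS),
    modulation_type = list(levels = MODULATION_LEVELS, probs = MODULATION_PROBS,
                           offsets = MODULATION_OFFSETS)
  )
  k <- config$n_categories[[field]]
  if (is.null(k)) return(builtin)
  k <- as.integer(k)
  n_rare <- max(0L, min(k - 2L, 2L))
  n_main <- k - n_rare
  main <- 0.65^(seq_len(n_main) - 1)
  main <- main / sum(main) * (1 - config$rare_category_mass * (n_rare > 0))
  rare <- if (n_rare > 0) {
    r <- 0.5^(seq_len(n_rare) - 1)
    r / sum(r) * config$rare_category_mass
  } else numeric(0)
  list(
    levels = sprintf("%s_L%02d", toupper(field), seq_len(k)),
    probs = c(main, rare),
    offsets = 0.4 * sin(seq_len(k)) # small, fixed, mixed-sign pattern
  )
}

# Pick the level used for systemic contamination: the one whose frequency is
# closest to the targeted within-level contamination support (~1.3%).
systemic_level_of <- function(spec) {
  if (SYSTEMIC_LEVEL %in% spec$levels) return(SYSTEMIC_LEVEL)
  spec$levels[which.min(abs(spec$probs - 0.013))]
}

#' Generate a synthetic CT-exam cohort
#'
#' Draws `n_exams` per-acquisition records: numeric predictors (tube current,
#' kVp, patient weight, collimator width, reference mAs) that drive the dose,
#' decoy predictors independent of dose (age, pitch factor, scan length,
#' number of scans), categorical fields (gender, scanner type, protocol range
#' name, modulation type) with small additive dose offsets, Gaussian dose
#' noise, per-field missingness, and injected dose outliers. The CTDIvol of a
#' body exam is
#' `intercept + sum_j beta_j * z(x_j) + categorical offsets + noise`,
#' floored at `dose_floor`, where `z()` standardizes by the cohort mean and SD.
#'
#' Injected outliers have their dose multiplied by a per-exam factor and are
#' marked in the simulator-only truth column `is_injected_outlier`. The
#' contamination is mixed: a `systemic_share` of the budget is concentrated in
#' one designated protocol level (factors uniform on
#' `[1.5, outlier_inflation]`), the remainder is sporadic (factors uniform on
#' `[1.25, outlier_inflation]`).
#'
#' @param config a [synthetic_config()] object.
#' @return a data.frame with one row per acquisition: `exam_id`,
#'   `body_region`, numeric and categorical predictors, `ctdi_vol` (mGy), and
#'   the truth flag `is_injected_outlier`. Missing values are `NA`.
#' @export
generate_cohort <- function(config) {
  stop_if(!inherits(config, "synthetic_config"),
          "config must be created by synthetic_config()")
  set.seed(config$seed)
  n <- config$n_exams

  # weight: five-class truncated-normal mixture
  cls <- sample.int(5L, n, replace = TRUE, prob = WEIGHT_PROPS)
  lo <- c(1, WEIGHT_BREAKS)[cls]
  hi <- c(WEIGHT_BREAKS, Inf)[cls]
  weight <- rtruncnorm(n, WEIGHT_MEANS[cls], WEIGHT_SDS[cls], lo, hi)

  num <- data.frame(
    tube_current = rlnorm(n, log(200), 0.4),
    kvp = sample(c(80, 100, 120, 140), n, replace = TRUE,
                 prob = c(.08, .17, .65, .10)),
    weight = weight,
    collimator_width = sample(c(19.2, 28.8, 38.4, 40.0), n, replace = TRUE,
                              prob = c(.15, .25, .40, .20)),
    reference_mas = rlnorm(n, log(150), 0.35),
    # decoys: generated independent of dose
    age = pmin(pmax(rnorm(n, 60.6, 17.1), 1), 100),
    pitch_factor = runif(n, 0.6, 1.5),
    scan_length = pmax(rnorm(n, 40, 10), 5),
    n_scans = 1 + rpois(n, 0.8)
  )

  gender <- ifelse(runif(n) < 0.541, "F", "M")
  cat_fields <- c("scanner_type", "range_name", "modulation_type")
  cat_specs <- lapply(setNames(cat_fields, cat_fields), categorical_spec,
                      config = config)
  cats <- data.frame(gender = gender, stringsAsFactors = FALSE)
  cat_offset <- ifelse(gender == "F", 0.1, -0.1)
  for (f in cat_fields) {
    sp <- cat_specs[[f]]
    idx <- sample.int(length(sp$levels), n, replace = TRUE, prob = sp$probs)
    cats[[f]] <- sp$levels[idx]
    cat_offset <- cat_offset + sp$offsets[idx]
  }

  body_region <- ifelse(runif(n) < config$head_fraction, "head", "body")

  beta <- config$true_coefficients
  missing_beta <- setdiff(names(beta), names(num))
  stop_if(length(missing_beta) > 0,
          "unknown predictors in true_coefficients: ",
          paste(missing_beta, collapse = ", "))
  z <- vapply(names(beta),
              function(p) as.numeric(scale(num[[p]])), numeric(n))
  base <- ifelse(body_region == "head", config$head_intercept, config$intercept)
  dose <- base + drop(z %*% beta) + cat_offset + rnorm(n, 0, config$noise_sd)
  dose <- pmax(dose, config$dose_floor)

  # injected outliers: systemic (one protocol level) + sporadic
  is_outlier <- logical(n)
  n_out <- round(config$outlier_fraction * n)
  if (n_out > 0) {
    sys_level <- systemic_level_of(cat_specs$range_name)
    n_sys <- round(config$systemic_share * n_out)
    members <- which(cats$range_name == sys_level)
    sys_idx <- if (length(members) <= n_sys) members else
      sample(members, n_sys)
    spor_pool <- setdiff(seq_len(n), sys_idx)
    n_spor <- n_out - length(sys_idx)
    spor_idx <- if (n_spor > 0) sample(spor_pool, n_spor) else integer(0)

    f_sys <- runif(length(sys_idx), 1.5, config$outlier_inflation)
    f_spor <- runif(length(spor_idx), 1.25, config$outlier_inflation)
    if (config$symmetric_contamination && length(spor_idx) > 1) {
      flip <- seq_along(spor_idx) %% 2 == 0
      f_spor[flip] <- 1 / f_spor[flip]
    }
    dose[sys_idx] <- dose[sys_idx] * f_sys
    dose[spor_idx] <- dose[spor_idx] * f_spor
    is_outlier[c(sys_idx, spor_idx)] <- TRUE
  }

  records <- cbind(
    data.frame(exam_id = sprintf("EX%07d", seq_len(n)),
               body_region = body_region, stringsAsFactors = FALSE),
    num, cats,
    data.frame(ctdi_vol = dose, is_injected_outlier = is_outlier)
  )

  # per-field missingness (response and weight included, so the record
  # filters have work to do; ids, region and truth flags stay complete)
  maskable <- setdiff(names(records),
                      c("exam_id", "body_region", "is_injected_outlier"))
  if (config$missing_rate_per_field > 0) {
    for (f in maskable) {
      records[[f]][runif(n) < config$missing_rate_per_field] <- NA
    }
  }
  records
}

#' Write / read a cohort table
#'
#' The main table is written as a plain CSV with one row per acquisition and
#' missing values as empty cells, matching a de-identified scanner export; the
#' simulator-only truth flags go to a separate sidecar CSV so the main table
#' looks like real data.
#'
#' @param records cohort data.frame from [generate_cohort()] (or user data).
#' @param path path of the main CSV.
#' @param truth_path optional path of the sidecar truth CSV
#'   (`exam_id,is_injected_outlier`); used only when the truth column exists.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, truth_path = NULL) {
  main <- records[setdiff(names(records), "is_injected_outlier")]
  write.csv(main, path, row.names = FALSE, na = "")
  if (!is.null(truth_path) && "is_injected_outlier" %in% names(records)) {
    write.csv(records[c("exam_id", "is_injected_outlier")], truth_path,
              row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, truth_path = NULL) {
  records <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!is.null(truth_path)) {
    truth <- read.csv(truth_path, stringsAsFactors = FALSE)
    records$is_injected_outlier <-
      as.logical(truth$is_injected_outlier[match(records$exam_id, truth$exam_id)])
  }
  records
}
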