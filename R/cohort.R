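# Synthetic multi-omics case-control cohorts.
#
# Real cohorts of this shape (post-harmonization Parkinson's disease data)
# are access controlled, so the package generates cohorts with the same
# post-preprocessing statistical structure: standardized continuous features
# in modality blocks (genetic-like, transcriptomic-like), a small
# clinico-demographic block with two binary columns and a dominant
# smell-test-like predictor, class-conditional Gaussian means, and
# equicorrelation within each modality block.

#' Specify a synthetic cohort
#'
#' @param n_cases,n_controls Number of case (label 1) and control (label 0)
#'   samples; each must be at least 1.
#' @param n_genetic,n_transcriptomic,n_clinical Feature-block sizes. Defaults
#'   mirror a harmonized multi-omics Parkinson's cohort: 72 genetic-like
#'   features (variant dosages + polygenic risk score analogues), 596
#'   transcriptomic-like features, 5 clinico-demographic columns (age, family
#'   history, ancestry flag, sex, smell-test score). `n_clinical` must be 5.
#' @param informative_fraction Fraction of the genetic + transcriptomic
#'   features carrying a true class effect, in (0, 1].
#' @param effect_scale Mean absolute standardized class-mean difference of
#'   the informative features (nonnegative). The smell-test column carries
#'   `2.5 * effect_scale`, the largest single-feature effect.
#' @param block_correlation Equicorrelation within each omics modality block,
#'   in \[0, 1).
#' @param seed Integer seed; the cohort is bitwise reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases, n_controls,
                        n_genetic = 72L, n_transcriptomic = 596L,
                        n_clinical = 5L,
                        informative_fraction = 0.1,
                        effect_scale = 0.4,
                        block_correlation = 0.1,
                        seed = 1L) {
  spec <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
               n_genetic = as.integer(n_genetic),
               n_transcriptomic = as.integer(n_transcriptomic),
               n_clinical = as.integer(n_clinical),
               informative_fraction = informative_fraction,
               effect_scale = effect_scale,
               block_correlation = block_correlation,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid cohort spec field `%s`: %s", field, why), call. = FALSE)
  }
  chk(spec$n_cases >= 1L, "n_cases", "must be >= 1")
  chk(spec$n_controls >= 1L, "n_controls", "must be >= 1")
  chk(spec$n_genetic >= 0L, "n_genetic", "must be >= 0")
  chk(spec$n_transcriptomic >= 0L, "n_transcriptomic", "must be >= 0")
  chk(spec$n_clinical == 5L, "n_clinical", "the clinico-demographic block has exactly 5 columns")
  chk(is.numeric(spec$informative_fraction) &&
        spec$informative_fraction > 0 && spec$informative_fraction <= 1,
      "informative_fraction", "must lie in (0, 1]")
  chk(is.numeric(spec$effect_scale) && spec$effect_scale >= 0,
      "effect_scale", "must be nonnegative")
  chk(is.numeric(spec$block_correlation) &&
        spec$block_correlation >= 0 && spec$block_correlation < 1,
      "block_correlation", "must lie in [0, 1)")
  chk(is.finite(spec$seed), "seed", "must be a finite integer")
  invisible(spec)
}

#' Specify a distribution shift for an external cohort
#'
#' Describes how an external (out-of-distribution) cohort differs from the
#' source generative law: a location shift of the informative features
#' (covariate shift) and a multiplicative attenuation of all class effects
#' (a drug-treatment analogue — treated external patients separate less).
#'
#' @param mean_shift Nonnegative offset added to every informative continuous
#'   feature, all samples.
#' @param effect_attenuation Multiplier in \[0, 1\] applied to all class
#'   effects. `effect_attenuation = 1` with `mean_shift = 0` reproduces the
#'   source law exactly (bitwise, for the same seed and label counts).
#' @param label_ratio_override Optional `c(n_cases, n_controls)` for the
#'   external cohort; defaults to the source spec's counts.
#' @return A `shift_spec` list.
#' @export
shift_spec <- function(mean_shift = 0, effect_attenuation = 1,
                       label_ratio_override = NULL) {
  if (!is.numeric(mean_shift) || mean_shift < 0)
    stop("invalid shift field `mean_shift`: must be nonnegative", call. = FALSE)
  if (!is.numeric(effect_attenuation) || effect_attenuation < 0 || effect_attenuation > 1)
    stop("invalid shift field `effect_attenuation`: must lie in [0, 1]", call. = FALSE)
  if (!is.null(label_ratio_override)) {
    if (length(label_ratio_override) != 2L || any(label_ratio_override < 1))
      stop("invalid shift field `label_ratio_override`: need c(n_cases, n_controls) >= 1",
           call. = FALSE)
    label_ratio_override <- as.integer(label_ratio_override)
  }
  structure(list(mean_shift = mean_shift,
                 effect_attenuation = effect_attenuation,
                 label_ratio_override = label_ratio_override),
            class = "shift_spec")
}

# Construct + validate the labeled cohort container.
labeled_cohort <- function(features, labels, feature_meta, cohort_tag = "cohort",
                           provenance = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop("labels length must equal the feature-matrix row count", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (anyNA(features) || any(!is.finite(features)))
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  if (nrow(feature_meta) != ncol(features))
    stop("feature_meta must have one row per feature column", call. = FALSE)
  colnames(features) <- feature_meta$name
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("S%04d", seq_len(nrow(features)))
  structure(list(features = features, labels = labels,
                 feature_meta = feature_meta, cohort_tag = cohort_tag,
                 provenance = provenance),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("<labeled_cohort '%s': %d samples (%d cases / %d controls) x %d features>\n",
              x$cohort_tag, nrow(x$features), sum(x$labels == 1L),
              sum(x$labels == 0L), ncol(x$features)))
  tab <- table(x$feature_meta$modality)
  cat("  features:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / features of a cohort
#' @param cohort A `labeled_cohort`.
#' @return Integer count.
#' @export
n_samples <- function(cohort) nrow(cohort$features)

#' @rdname n_samples
#' @export
n_features <- function(cohort) ncol(cohort$features)

# The shared generative core. External cohorts reuse it with attenuated
# effects / shifted means; identical arguments give bitwise-identical output.
generate_core <- function(spec, n_cases, n_controls, attenuation = 1,
                          mean_shift = 0, cohort_tag = "internal") {
  n <- n_cases + n_controls
  labels <- c(rep(1L, n_cases), rep(0L, n_controls))
  pbar <- n_cases / n
  p_omics <- spec$n_genetic + spec$n_transcriptomic

  meta <- tibble::tibble(
    name = c(sprintf("gen_%03d", seq_len(spec$n_genetic)),
             sprintf("tx_%03d", seq_len(spec$n_transcriptomic)),
             "age", "family_history", "ashkenazi", "sex", "upsit"),
    modality = c(rep("genetic", spec$n_genetic),
                 rep("transcriptomic", spec$n_transcriptomic),
                 rep("clinical", 5L)),
    kind = c(rep("continuous", p_omics),
             "continuous", "binary", "binary", "binary", "continuous")
  )

  # Structural stream: which omics features are informative, and effect signs.
  # Independent of sample counts so internal and external cohorts share the
  # same informative set.
  n_inf <- max(1L, round(spec$informative_fraction * p_omics))
  structure_draw <- with_seed(derive_seed(spec$seed, "structure"), {
    idx <- sort(sample.int(p_omics, n_inf))
    signs <- sample(c(-1, 1), n_inf, replace = TRUE)
    list(idx = idx, signs = signs)
  })

  # True standardized class-mean differences (case minus control).
  delta <- numeric(p_omics)
  delta[structure_draw$idx] <- structure_draw$signs * spec$effect_scale * attenuation
  es <- spec$effect_scale * attenuation
  delta_age <- 0.3 * es      # cases slightly older
  delta_upsit <- -2.5 * es   # smell score markedly lower in cases
  # log-odds shifts for the binary clinical columns (case vs control)
  lo_fh <- 1.2 * es
  lo_aj <- 0.8 * es
  lo_sex <- 0.5 * es         # male excess among cases

  sample_seed <- derive_seed(spec$seed, "samples", n_cases, n_controls)
  X <- with_seed(sample_seed, {
    rho <- spec$block_correlation
    draw_block <- function(p) {
      if (p == 0L) return(matrix(numeric(0), n, 0L))
      f <- rnorm(n)
      z <- matrix(rnorm(n * p), n, p)
      sqrt(rho) * f + sqrt(1 - rho) * z
    }
    Xg <- draw_block(spec$n_genetic)
    Xt <- draw_block(spec$n_transcriptomic)
    age <- rnorm(n)
    upsit <- rnorm(n)
    u_fh <- runif(n)
    u_aj <- runif(n)
    u_sex <- runif(n)
    Xo <- cbind(Xg, Xt)
    if (p_omics > 0L)
      Xo <- Xo + tcrossprod(labels - pbar, delta)
    age <- age + delta_age * (labels - pbar)
    upsit <- upsit + delta_upsit * (labels - pbar)
    prate <- function(base, shift) stats::plogis(stats::qlogis(base) + shift * labels)
    fh <- as.numeric(u_fh < prate(0.10, lo_fh))
    aj <- as.numeric(u_aj < prate(0.05, lo_aj))
    sex <- as.numeric(u_sex < prate(0.50, lo_sex))
    cbind(Xo, age, fh, aj, sex, upsit)
  })

  if (mean_shift != 0) {
    inf_cont <- c(structure_draw$idx, p_omics + 1L, p_omics + 5L)  # omics + age + upsit
    X[, inf_cont] <- X[, inf_cont] + mean_shift
  }

  meta$effect <- c(delta, delta_age, lo_fh, lo_aj, lo_sex, delta_upsit)
  meta$informative <- meta$effect != 0

  labeled_cohort(X, labels, meta, cohort_tag = cohort_tag,
                 provenance = list(spec = unclass(spec),
                                   attenuation = attenuation,
                                   mean_shift = mean_shift,
                                   n_cases = n_cases, n_controls = n_controls))
}

#' Generate a synthetic training cohort
#'
#' Draws a class-conditional Gaussian cohort per the spec: standardized
#' continuous features with equicorrelated modality blocks, a sparse effect
#' vector separating class means, and a 5-column clinico-demographic block
#' (continuous age-like and smell-test-like columns, binary family-history,
#' ancestry and sex columns with class-dependent rates). Deterministic and
#' bitwise reproducible for a fixed spec.
#'
#' @param spec A [cohort_spec()].
#' @param cohort_tag Free-text tag stored on the cohort.
#' @return A `labeled_cohort`: `features` (n x p matrix), `labels` (0/1),
#'   `feature_meta` (name, modality, kind, true effect, informative flag),
#'   `cohort_tag`, `provenance`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(30, 70, n_genetic = 10,
#'                                   n_transcriptomic = 20, seed = 1))
#' dim(co$features)
generate_cohort <- function(spec, cohort_tag = "internal") {
  validate_cohort_spec(spec)
  generate_core(spec, spec$n_cases, spec$n_controls, cohort_tag = cohort_tag)
}

#' Generate a distribution-shifted external cohort
#'
#' Same feature space and informative-feature set as [generate_cohort()] on
#' the same spec, with class effects multiplied by `shift$effect_attenuation`,
#' informative continuous features offset by `shift$mean_shift`, and label
#' counts taken from `shift$label_ratio_override` when given. With the
#' identity shift and no override, the output equals [generate_cohort()]
#' bitwise.
#'
#' @param spec A [cohort_spec()] (the source cohort's spec).
#' @param shift A [shift_spec()].
#' @return A `labeled_cohort` tagged "external".
#' @export
generate_external_cohort <- function(spec, shift = shift_spec()) {
  validate_cohort_spec(spec)
  if (!inherits(shift, "shift_spec")) stop("`shift` must be a shift_spec", call. = FALSE)
  counts <- if (is.null(shift$label_ratio_override))
    c(spec$n_cases, spec$n_controls) else shift$label_ratio_override
  generate_core(spec, counts[1L], counts[2L],
                attenuation = shift$effect_attenuation,
                mean_shift = shift$mean_shift, cohort_tag = "external")
}

# Row subset of a cohort (keeps metadata).
subset_cohort <- function(cohort, idx, tag = cohort$cohort_tag) {
  labeled_cohort(cohort$features[idx, , drop = FALSE], cohort$labels[idx],
                 cohort$feature_meta, cohort_tag = tag,
                 provenance = cohort$provenance)
}
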