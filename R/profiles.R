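#' Reference table of the seven commercial tea products
#'
#' Canonical per-product metadata used throughout the package: abbreviation,
#' species, flowering stage at harvest, and the published per-product bud
#' counts for the two acquisition campaigns (morphological-feature plates and
#' colour plates used for the network). Three products are harvested in full
#' bloom and four at the fetal (pre-bloom) stage.
#'
#' @return data.frame with columns `id`, `name`, `abbrev`, `species`,
#'   `stage`, `shape_count`, `dnn_count`.
#' @examples
#' sum(chrysanthemum_classes()$shape_count)
#' @export
chrysanthemum_classes <- function() {
  data.frame(
    id = 1:7,
    name = c("Hangbaiju", "Huangshangongju", "Kunlunxueju", "Hangtaiju",
             "Kunlunmiju", "Huaiju", "Dabieshantaiju"),
    abbrev = c("HB", "HG", "KX", "HT", "KM", "HJ", "DT"),
    species = c("C. morifolium", "C. morifolium", "C. tinctoria",
                "C. morifolium", "C. tinctoria", "C. morifolium",
                "C. morifolium"),
    stage = c("bloom", "bloom", "bloom", "fetal", "fetal", "fetal", "fetal"),
    shape_count = c(203L, 144L, 332L, 348L, 517L, 435L, 364L),
    dnn_count = c(148L, 97L, 185L, 258L, 373L, 270L, 250L),
    stringsAsFactors = FALSE
  )
}

#' Class profile for the synthetic bud generator
#'
#' A class profile defines the sampling distribution over [shape_spec()]
#' parameters plus colour and surface texture for one product class. Bloom
#' products are drawn larger with a stronger petal frill (open petals), fetal
#' products smaller and smoother, mirroring the size/irregularity contrast
#' between harvest stages.
#'
#' @param name class label.
#' @param stage `"bloom"` or `"fetal"`.
#' @param family shape family drawn for instances (default `"bud"`).
#' @param scale_px,elongation,frill_amplitude,frill_count 2-vector sampling
#'   ranges (uniform; `frill_count` integer-uniform).
#' @param perturb_max total amplitude budget for smooth random harmonics.
#' @param color mean RGB (0..255) of the bud surface on colour plates.
#' @param color_jitter per-channel Gaussian SD of instance colour.
#' @param texture_strength multiplicative surface texture amplitude (>= 0).
#' @return Object of class `class_profile`.
#' @export
class_profile <- function(name, stage = c("bloom", "fetal"), family = "bud",
                          scale_px, elongation = c(1, 1.25),
                          frill_amplitude = c(0.05, 0.15),
                          frill_count = c(6L, 10L), perturb_max = 0.04,
                          color = c(180, 150, 90), color_jitter = 6,
                          texture_strength = 0.06) {
  stage <- match.arg(stage)
  rng_ok <- function(r) length(r) %in% c(1L, 2L) && !anyNA(r) &&
    (length(r) == 1L || r[2] >= r[1])
  if (!rng_ok(scale_px) || !rng_ok(elongation) || !rng_ok(frill_amplitude) ||
      !rng_ok(frill_count))
    stopf("sampling ranges must be ordered 2-vectors")
  if (texture_strength < 0) stopf("texture_strength must be >= 0")
  structure(list(name = name, stage = stage, family = family,
                 scale_px = scale_px, elongation = elongation,
                 frill_amplitude = frill_amplitude,
                 frill_count = frill_count, perturb_max = perturb_max,
                 color = color, color_jitter = color_jitter,
                 texture_strength = texture_strength),
            class = "class_profile")
}

#' Default synthetic profiles for the seven products
#'
#' Sampling ranges are chosen so that relative mean sizes follow the
#' published per-product ordering (HG largest, KM/HJ smallest, KX and HT of
#' similar size despite different stages) and so that bloom classes carry a
#' visibly stronger petal frill than fetal ones. Colours are plausible dried
#' chrysanthemum tones, all darker than white paper in luma.
#'
#' @return Named list of seven [class_profile()] objects (order of
#'   [chrysanthemum_classes()]).
#' @export
default_class_profiles <- function() {
  p <- list(
    class_profile("HB", "bloom", scale_px = c(30, 38),
                  frill_amplitude = c(0.10, 0.18), frill_count = c(8L, 12L),
                  elongation = c(1, 1.25), color = c(195, 175, 110)),
    class_profile("HG", "bloom", scale_px = c(40, 48),
                  frill_amplitude = c(0.08, 0.16), frill_count = c(8L, 12L),
                  elongation = c(1, 1.2), color = c(205, 150, 60)),
    class_profile("KX", "bloom", scale_px = c(22, 28),
                  frill_amplitude = c(0.10, 0.20), frill_count = c(7L, 11L),
                  elongation = c(1, 1.3), color = c(170, 100, 40)),
    class_profile("HT", "fetal", scale_px = c(19, 25),
                  frill_amplitude = c(0.02, 0.08), frill_count = c(5L, 9L),
                  elongation = c(1, 1.3), color = c(185, 170, 115)),
    class_profile("KM", "fetal", scale_px = c(12, 16),
                  frill_amplitude = c(0.02, 0.06), frill_count = c(5L, 9L),
                  elongation = c(1, 1.2), color = c(150, 110, 55)),
    class_profile("HJ", "fetal", scale_px = c(11, 15),
                  frill_amplitude = c(0.02, 0.08), frill_count = c(5L, 9L),
                  elongation = c(1, 1.35), color = c(175, 135, 75)),
    class_profile("DT", "fetal", scale_px = c(17, 22),
                  frill_amplitude = c(0.02, 0.08), frill_count = c(5L, 9L),
                  elongation = c(1, 1.3), color = c(130, 95, 45))
  )
  names(p) <- vapply(p, `[[`, "", "name")
  p
}

#' Profiles whose classes differ only in colour
#'
#' All seven classes share one shape distribution; only the mean colour
#' differs. Shape descriptors carry no class signal on data drawn from these
#' profiles, while raw-image models retain the colour signal -- the substrate
#' for the shape-vs-colour contrast experiments.
#'
#' @param stage_split if `TRUE` keep the canonical 3 bloom / 4 fetal stage
#'   labelling; stages are label-only (shapes stay identical).
#' @return Named list of seven [class_profile()] objects.
#' @export
color_only_profiles <- function(stage_split = TRUE) {
  cls <- chrysanthemum_classes()
  cols <- list(c(200, 60, 50), c(60, 140, 60), c(70, 90, 190),
               c(200, 160, 40), c(150, 70, 160), c(60, 170, 170),
               c(120, 85, 45))
  p <- lapply(1:7, function(i) {
    class_profile(cls$abbrev[i],
                  stage = if (stage_split) cls$stage[i] else "bloom",
                  scale_px = c(20, 30), frill_amplitude = c(0.05, 0.15),
                  frill_count = c(6L, 10L), elongation = c(1, 1.25),
                  color = cols[[i]], color_jitter = 8,
                  texture_strength = 0.05)
  })
  names(p) <- cls$abbrev
  p
}

# Draw one shape_spec from a profile (centre left unset); consumes RNG.
sample_shape_spec <- function(profile) {
  fam <- profile$family
  amp <- runif_range(profile$frill_amplitude)
  kk <- profile$frill_count
  k <- if (length(kk) == 2L) sample(seq(kk[1], kk[2]), 1L) else kk
  perturb <- NULL
  if (fam == "bud" && profile$perturb_max > 0) {
    perturb <- list(amp = runif(3, 0, profile$perturb_max / 3),
                    phase = runif(3, 0, 2 * pi))
  }
  shape_spec(family = fam,
             scale_px = runif_range(profile$scale_px),
             elongation = runif_range(profile$elongation),
             frill_amplitude = if (fam == "bud") amp else 0,
             frill_count = if (fam == "bud") k else 0L,
             rotation_rad = runif(1, 0, 2 * pi),
             perturb = perturb)
}
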