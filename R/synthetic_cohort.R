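# Seeded synthetic cohort: bags of slice instances with planted key slices,
# a clinical/dosimetric table, and a high-dimensional sparse-signal
# radiomics-style table. This is first-class, tested code: it defines the
# study conditions under which the MIL machinery is validated.

# Table-1-style generating values: six categorical features carry no class
# signal (their marginals are realistic for a thoracic radiotherapy cohort);
# five dosimetric features get positive mean shifts in the positive class.
.clin_categorical <- list(
  age_ge65       = 0.44,
  smoking        = 0.42,
  chemotherapy   = 0.66,
  histology_scc  = 0.39,
  t_stage_34     = 0.35,
  n_stage_23     = 0.69
)
.dosim_names <- c("lung_v5", "lung_v10", "lung_v20", "lung_v30", "lung_dmean")
.dosim_mean  <- c(43.75, 31.15, 20.09, 13.17, 10.82)
.dosim_sd    <- c(13.65, 10.25,  7.38,  5.22,  3.40)
.dosim_shift <- c(2.68, 2.19, 1.77, 1.34, 0.81)

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients.
#' @param prevalence fraction of positive (symptomatic) patients, in (0,1).
#' @param volume_shape integer (height, width, depth) of each volume.
#' @param key_slice_range integer (min, max) count of planted key slices per
#'   positive patient; min must be >= 1.
#' @param lesion_effect additive intensity shift (volume units) applied inside
#'   the planted lesion patch.
#' @param clinical_effect_sizes named numeric, per-dosimetric-feature mean
#'   shift (feature units) added in the positive class. Defaults mirror the
#'   observed positive-minus-negative differences of lung V5/V10/V20/V30 and
#'   mean lung dose in a screened radiotherapy cohort.
#' @param n_radiomics number of radiomics-style columns.
#' @param n_radiomics_informative number of radiomics columns carrying signal.
#' @param radiomics_effect additive class shift (in units of the column SD)
#'   for informative radiomics columns.
#' @param noise_sd voxel noise standard deviation (volume units).
#' @param intensity_anchors named `c(low, high)` intensities of the constant
#'   anchor structures present in every volume (the analog of air and dense
#'   tissue in a real scan); they pin the per-volume min and max so min-max
#'   normalization maps all patients identically and the class signal stays
#'   local to the planted slices.
#' @param seed integer global seed; all sub-generators derive named streams
#'   from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 120L,
                          prevalence = 0.4,
                          volume_shape = c(32L, 32L, 16L),
                          key_slice_range = c(1L, 2L),
                          lesion_effect = 50,
                          clinical_effect_sizes = stats::setNames(.dosim_shift, .dosim_names),
                          n_radiomics = 758L,
                          n_radiomics_informative = 15L,
                          radiomics_effect = 0.8,
                          noise_sd = 10,
                          intensity_anchors = c(low = 0, high = 300),
                          seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort_domain("`prevalence` must lie strictly in (0, 1)")
  }
  if (length(volume_shape) != 3L || any(volume_shape < 1)) {
    abort_domain("`volume_shape` must be three positive counts (H, W, S)")
  }
  if (length(key_slice_range) != 2L || key_slice_range[1] < 1 ||
      key_slice_range[2] < key_slice_range[1] ||
      key_slice_range[2] > volume_shape[3]) {
    abort_domain("`key_slice_range` must satisfy 1 <= min <= max <= depth")
  }
  n_radiomics <- check_count(n_radiomics, "n_radiomics")
  n_radiomics_informative <- check_count(n_radiomics_informative,
                                         "n_radiomics_informative", min = 0L)
  if (n_radiomics_informative > n_radiomics) {
    abort_domain("`n_radiomics_informative` cannot exceed `n_radiomics`")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort_domain("`noise_sd` must be >= 0")
  structure(list(
    n_patients = n_patients, prevalence = prevalence,
    volume_shape = as.integer(volume_shape),
    key_slice_range = as.integer(key_slice_range),
    lesion_effect = lesion_effect,
    clinical_effect_sizes = clinical_effect_sizes,
    n_radiomics = n_radiomics,
    n_radiomics_informative = n_radiomics_informative,
    radiomics_effect = radiomics_effect,
    noise_sd = noise_sd, intensity_anchors = intensity_anchors,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Bag label from instance labels (MIL constraint)
#'
#' A bag is negative iff every instance in it is negative.
#'
#' @param instance_labels nonempty vector of 0/1 instance labels.
#' @return integer 0 or 1.
#' @export
bag_label_from_instances <- function(instance_labels) {
  if (length(instance_labels) == 0L) {
    abort_domain("bag label is undefined for an empty instance set")
  }
  if (!all(instance_labels %in% c(0, 1))) {
    abort_domain("instance labels must be 0/1")
  }
  as.integer(any(instance_labels == 1))
}

#' Plant bright lesion patches on selected slices
#'
#' Adds `effect` inside a compact elliptical patch on each listed slice,
#' returning a new volume; the input is untouched. The planted signal is
#' confined to the listed slices, matching the slice-as-instance premise.
#'
#' @param volume 3D array (H, W, S).
#' @param indices slice indices (1-based, along the third axis).
#' @param effect additive intensity shift.
#' @param centers optional list of (h, w) centers, one per index; defaults to
#'   the slice center.
#' @param radii (rh, rw) ellipse radii in voxels; default `dim/6`.
#' @return a new volume array.
#' @export
plant_key_slices <- function(volume, indices, effect, centers = NULL,
                             radii = NULL) {
  d <- dim(volume)
  stopifnot(length(d) == 3L)
  if (length(indices) && (any(indices < 1) || any(indices > d[3]))) {
    abort_domain("slice index out of depth range")
  }
  if (is.null(radii)) radii <- pmax(1, d[1:2] / 6)
  out <- volume
  for (j in seq_along(indices)) {
    ctr <- if (is.null(centers)) (d[1:2] + 1) / 2 else centers[[j]]
    hh <- ((seq_len(d[1]) - ctr[1]) / radii[1])^2
    ww <- ((seq_len(d[2]) - ctr[2]) / radii[2])^2
    mask <- outer(hh, ww, `+`) <= 1
    sl <- out[, , indices[j]]
    sl[mask] <- sl[mask] + effect
    out[, , indices[j]] <- sl
  }
  out
}

#' Generate a synthetic weakly-labelled cohort
#'
#' Emits `n_patients` volumes with planted key slices in positive patients,
#' a clinical table (six null categorical features, five shifted dosimetric
#' features), a sparse-signal radiomics-style table, and full ground truth
#' (instance labels, bag labels, key-slice indices). Bit-identical given the
#' same config.
#'
#' @param config a [cohort_config()].
#' @return list with `volumes` (list of 3D arrays), `clinical` (data.frame),
#'   `radiomics` (data.frame), `ground_truth` (list).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_domain("`config` must come from cohort_config()")
  }
  n <- config$n_patients
  shp <- config$volume_shape
  depth <- shp[3]
  ids <- sprintf("P%04d", seq_len(n))

  bag_labels <- with_stream(config$seed, "labels",
                            rbinom(n, 1L, config$prevalence))

  # key slice placement
  key_idx <- with_stream(config$seed, "slices", {
    lapply(seq_len(n), function(i) {
      if (bag_labels[i] == 0L) return(integer(0))
      m <- if (config$key_slice_range[1] == config$key_slice_range[2]) {
        config$key_slice_range[1]
      } else {
        sample(seq(config$key_slice_range[1], config$key_slice_range[2]), 1L)
      }
      sort(sample.int(depth, m))
    })
  })
  centers <- with_stream(config$seed, "lesion-geometry", {
    lapply(seq_len(n), function(i) {
      lapply(seq_along(key_idx[[i]]), function(j) {
        c(runif(1, shp[1] / 4, 3 * shp[1] / 4),
          runif(1, shp[2] / 4, 3 * shp[2] / 4))
      })
    })
  })

  volumes <- with_stream(config$seed, "volumes", {
    lapply(seq_len(n), function(i) {
      v <- array(100 + rnorm(prod(shp), sd = config$noise_sd), dim = shp)
      # intensity anchors: every scan contains a known-dark and a known-bright
      # structure (air / dense tissue in real CT), so the min-max mapping is
      # identical across patients and the class signal stays confined to the
      # planted key slices rather than leaking through the normalization
      v[1:2, 1:2, ] <- config$intensity_anchors[["low"]]
      v[shp[1] - 1:0, shp[2] - 1:0, ] <- config$intensity_anchors[["high"]]
      if (length(key_idx[[i]])) {
        v <- plant_key_slices(v, key_idx[[i]], config$lesion_effect,
                              centers = centers[[i]])
      }
      v
    })
  })

  clinical <- with_stream(config$seed, "clinical", {
    df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    # categorical features are uninformative by construction: the target
    # marginal is allocated proportionally within each class and permuted
    # (a randomization-balanced null), so the class association is zero by
    # design rather than merely zero in expectation
    for (nm in names(.clin_categorical)) {
      q <- .clin_categorical[[nm]]
      col <- integer(n)
      for (cls in c(0L, 1L)) {
        idx <- which(bag_labels == cls)
        ones <- round(q * length(idx))
        col[idx] <- sample(rep(c(1L, 0L), c(ones, length(idx) - ones)))
      }
      df[[nm]] <- col
    }
    shifts <- config$clinical_effect_sizes
    for (j in seq_along(.dosim_names)) {
      nm <- .dosim_names[j]
      mu <- .dosim_mean[j] + ifelse(bag_labels == 1L,
                                    if (nm %in% names(shifts)) shifts[[nm]] else 0,
                                    0)
      df[[nm]] <- rnorm(n, mean = mu, sd = .dosim_sd[j])
    }
    df
  })

  radiomics <- with_stream(config$seed, "radiomics", {
    p <- config$n_radiomics
    mat <- matrix(rnorm(n * p), n, p)
    nz <- seq_len(config$n_radiomics_informative)
    if (length(nz)) {
      mat[, nz] <- mat[, nz] +
        outer(as.numeric(bag_labels == 1L), rep(config$radiomics_effect, length(nz)))
    }
    nms <- if (p == 758L) enumerate_radiomics_space() else sprintf("rf_%04d", seq_len(p))
    df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    df[nms] <- as.data.frame(mat)
    df
  })

  instance_labels <- lapply(seq_len(n), function(i) {
    v <- integer(depth)
    v[key_idx[[i]]] <- 1L
    v
  })
  # the stored bag label always equals the MIL aggregation of instance labels
  stopifnot(vapply(instance_labels, bag_label_from_instances, integer(1)) ==
              bag_labels)

  list(
    volumes = stats::setNames(volumes, ids),
    clinical = clinical,
    radiomics = radiomics,
    ground_truth = list(
      patient_ids = ids,
      bag_labels = stats::setNames(as.integer(bag_labels), ids),
      instance_labels = stats::setNames(instance_labels, ids),
      key_slice_indices = stats::setNames(key_idx, ids)
    ),
    config = config
  )
}
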