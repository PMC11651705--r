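# Biomarker primitives: GH assay harmonization, short acute octreotide test
# (sAOT) classification, IGF-1 standard-deviation scores, tumor geometry.

#' Default GH assay calibration registry
#'
#' Affine calibrations mapping each automated GH immunoassay onto the
#' reference immunoassay scale (Immulite i2000), so that the 2.7 ng/mL
#' responder cutoff is applied on a single harmonized scale. Each entry is
#' `harmonized = slope * raw + intercept`; the reference assay is the
#' identity.
#'
#' @return A data frame with columns `assay_id`, `slope`, `intercept`.
#' @examples
#' gh_calibrations()
#' @export
gh_calibrations <- function() {
  data.frame(
    assay_id = c("Immulite i2000", "Liason XL", "DxI 800", "Cobas 8000"),
    slope = c(1, 1.272, 1.387, 1.089),
    intercept = c(0, 0.023, 0.356, 0.082),
    stringsAsFactors = FALSE
  )
}

#' Read or validate an assay calibration registry
#'
#' @param path Path to a CSV file with columns `assay_id`, `slope`,
#'   `intercept`. Slopes must be strictly positive.
#' @return The validated calibration data frame.
#' @export
read_gh_calibrations <- function(path) {
  cal <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_gh_calibrations(cal)
}

validate_gh_calibrations <- function(cal) {
  needed <- c("assay_id", "slope", "intercept")
  if (!all(needed %in% names(cal))) {
    stop("calibration registry needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(!is.finite(cal$slope)) || any(cal$slope <= 0)) {
    stop("calibration slopes must be finite and strictly positive")
  }
  cal
}

#' Harmonize a GH measurement onto the reference assay scale
#'
#' Applies the affine calibration registered for `assay_id`. The reference
#' assay returns the input unchanged. All downstream cutoffs (notably the
#' 2.7 ng/mL sAOT responder cutoff) are defined on the harmonized scale, so
#' raw assay values must pass through this map before classification.
#'
#' @param raw_value GH concentration in ng/mL as reported by the assay
#'   (non-negative; vectorized).
#' @param assay_id Assay identifier present in `calibrations`.
#' @param calibrations Calibration registry, see [gh_calibrations()].
#' @return Harmonized GH in ng/mL.
#' @examples
#' harmonize_gh(1.0, "Liason XL")   # 1.272 * 1 + 0.023 = 1.295
#' harmonize_gh(2.5, "Immulite i2000")  # identity
#' @export
harmonize_gh <- function(raw_value, assay_id, calibrations = gh_calibrations()) {
  calibrations <- validate_gh_calibrations(calibrations)
  if (any(raw_value < 0, na.rm = TRUE)) stop("raw GH values must be >= 0")
  idx <- match(assay_id, calibrations$assay_id)
  if (anyNA(idx)) {
    stop("unknown assay_id: ",
         paste(unique(assay_id[is.na(idx)]), collapse = ", "))
  }
  calibrations$slope[idx] * raw_value + calibrations$intercept[idx]
}

#' Invert a GH harmonization
#'
#' Maps a harmonized GH value back to the raw scale of `assay_id`.
#' @inheritParams harmonize_gh
#' @param value Harmonized GH in ng/mL.
#' @return Raw-scale GH in ng/mL.
#' @export
unharmonize_gh <- function(value, assay_id, calibrations = gh_calibrations()) {
  calibrations <- validate_gh_calibrations(calibrations)
  idx <- match(assay_id, calibrations$assay_id)
  if (anyNA(idx)) stop("unknown assay_id")
  (value - calibrations$intercept[idx]) / calibrations$slope[idx]
}

#' sAOT response classes
#' @export
saot_classes <- c("RESPONDER", "PARTIAL_RESPONDER", "NON_RESPONDER")

#' Classify the short acute octreotide test
#'
#' GH is measured before and 2 h after 100 ug subcutaneous octreotide; strong
#' suppression predicts response to first-generation somatostatin receptor
#' ligands (fgSRLs). Classification on harmonized values:
#' \itemize{
#'   \item `GH_2h < 2.7` ng/mL: `RESPONDER` (the GH_2h result prevails over a
#'     discordant percent drop);
#'   \item `GH_2h >= 2.7` and drop `> 50`\%: `PARTIAL_RESPONDER`;
#'   \item `GH_2h >= 2.7` and drop `<= 50`\%: `NON_RESPONDER`.
#' }
#' The exact 2.7 boundary goes to the percent-drop branch and the exact 50\%
#' drop to `NON_RESPONDER` (cutoff exactness favors the non-responder path).
#'
#' @param gh_basal Basal GH, ng/mL, harmonized; must be > 0 for a valid test.
#' @param gh_2h GH 2 h post-octreotide, ng/mL, harmonized, >= 0.
#' @param cutoff_gh2h Responder cutoff on the harmonized scale (ng/mL).
#' @param cutoff_drop Percent-drop boundary.
#' @return An object of class `saot_result`: list with `gh_basal`, `gh_2h`,
#'   `pct_drop`, `saot_class`.
#' @examples
#' classify_saot(4.6, 1.3)    # RESPONDER
#' classify_saot(10, 4)       # PARTIAL_RESPONDER (60% drop)
#' classify_saot(4.0, 2.8)    # NON_RESPONDER (30% drop)
#' @export
classify_saot <- function(gh_basal, gh_2h, cutoff_gh2h = 2.7, cutoff_drop = 50) {
  if (length(gh_basal) != 1L || length(gh_2h) != 1L) {
    stop("classify_saot takes scalar GH values; vectorize externally")
  }
  if (gh_basal < 0 || gh_2h < 0) stop("GH values must be >= 0")
  if (gh_basal == 0) stop("invalid sAOT: basal GH is zero")
  pct_drop <- 100 * (gh_basal - gh_2h) / gh_basal
  cls <- if (gh_2h < cutoff_gh2h) {
    "RESPONDER"
  } else if (pct_drop > cutoff_drop) {
    "PARTIAL_RESPONDER"
  } else {
    "NON_RESPONDER"
  }
  structure(
    list(gh_basal = gh_basal, gh_2h = gh_2h, pct_drop = pct_drop,
         saot_class = cls),
    class = "saot_result"
  )
}

#' @export
print.saot_result <- function(x, ...) {
  cat(sprintf("sAOT: basal %.2f ng/mL, 2h %.2f ng/mL (drop %.1f%%) -> %s\n",
              x$gh_basal, x$gh_2h, x$pct_drop, x$saot_class))
  invisible(x)
}

#' Synthetic IGF-1 reference table
#'
#' A self-consistent log-normal IGF-1 reference: per sex and age band
#' (tiling 18-80 y), the location and scale of log IGF-1 (ng/mL) in a
#' healthy population. The published SDS calculator's internal tables are
#' not public, so this synthetic table parameterizes the same pluggable
#' model; any table with the same columns can be supplied instead. IGF-1
#' declines with age; women run slightly lower here.
#'
#' @return Data frame with columns `sex` ("M"/"F"), `age_low`, `age_high`,
#'   `location` (mean of log IGF-1), `scale` (sd of log IGF-1).
#' @export
igf1_reference_default <- function() {
  bands <- data.frame(
    age_low = c(18, 30, 40, 50, 60, 70),
    age_high = c(30, 40, 50, 60, 70, 80)
  )
  med_m <- c(260, 220, 190, 165, 145, 130)  # ng/mL, declining with age
  out <- rbind(
    data.frame(sex = "M", bands, location = log(med_m), scale = 0.25),
    data.frame(sex = "F", bands, location = log(0.92 * med_m), scale = 0.25)
  )
  rownames(out) <- NULL
  out
}

igf1_lookup_band <- function(age, sex, ref) {
  hit <- ref$sex == sex &
    age >= ref$age_low &
    (age < ref$age_high | (age == ref$age_high & ref$age_high == max(ref$age_high)))
  i <- which(hit)
  if (length(i) == 0L) {
    stop(sprintf("no IGF-1 reference band covers sex=%s age=%s", sex, age))
  }
  i[1L]
}

#' IGF-1 standard-deviation score
#'
#' Converts an absolute IGF-1 concentration into an age- and sex-adjusted
#' standard-deviation score (SDS) under a log-normal reference model:
#' `(log(igf1) - location) / scale` for the matching (sex, age band).
#' Normalized IGF1-SDS defines hormonal control of acromegaly.
#'
#' @param igf1 IGF-1, ng/mL, > 0 (vectorized).
#' @param age Age in years, within the reference coverage (vectorized).
#' @param sex "M" or "F" (vectorized).
#' @param ref Reference table, see [igf1_reference_default()].
#' @return IGF1-SDS (dimensionless).
#' @export
igf1_sds <- function(igf1, age, sex, ref = igf1_reference_default()) {
  if (any(ref$scale <= 0)) stop("reference scale must be > 0")
  n <- max(length(igf1), length(age), length(sex))
  igf1 <- rep_len(igf1, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (any(igf1 <= 0)) stop("IGF-1 must be > 0")
  vapply(seq_len(n), function(k) {
    i <- igf1_lookup_band(age[k], sex[k], ref)
    (log(igf1[k]) - ref$location[i]) / ref$scale[i]
  }, numeric(1))
}

#' Absolute IGF-1 from an SDS (inverse of [igf1_sds()])
#'
#' @inheritParams igf1_sds
#' @param sds IGF1-SDS value(s).
#' @return IGF-1 in ng/mL.
#' @export
igf1_from_sds <- function(sds, age, sex, ref = igf1_reference_default()) {
  n <- max(length(sds), length(age), length(sex))
  sds <- rep_len(sds, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  vapply(seq_len(n), function(k) {
    i <- igf1_lookup_band(age[k], sex[k], ref)
    exp(ref$location[i] + ref$scale[i] * sds[k])
  }, numeric(1))
}

#' Ellipsoid tumor volume
#'
#' Di Chiro-Nelson estimate from three orthogonal axes measured on MRI:
#' `volume = height * length * width * pi / 6` (mm^3).
#'
#' @param height,length,width Axes in mm, >= 0 (vectorized).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 10, 10)  # 523.6 mm^3
#' @export
tumor_volume <- function(height, length, width) {
  if (any(c(height, length, width) < 0)) stop("tumor axes must be >= 0")
  height * length * width * pi / 6
}

#' Assemble a tumor geometry record
#'
#' @inheritParams tumor_volume
#' @param t2_class T2-weighted MRI signal class relative to normal pituitary
#'   or temporal gray matter: "HYPOINTENSE", "ISOINTENSE" or "HYPERINTENSE".
#'   Hypointensity predicts good fgSRL response.
#' @param knosp_grade Knosp grade 0-4 of cavernous sinus invasion.
#' @return List of class `tumor_geometry` with axes, `largest_diameter`,
#'   `volume`, `t2_class`, `knosp_grade`.
#' @export
tumor_geometry <- function(height, length, width,
                           t2_class = c("HYPOINTENSE", "ISOINTENSE", "HYPERINTENSE"),
                           knosp_grade = 0L) {
  t2_class <- match.arg(t2_class)
  if (!(knosp_grade %in% 0:4)) stop("knosp_grade must be an integer 0-4")
  structure(
    list(height = height, length = length, width = width,
         largest_diameter = max(height, length, width),
         volume = tumor_volume(height, length, width),
         t2_class = t2_class, knosp_grade = as.integer(knosp_grade)),
    class = "tumor_geometry"
  )
}
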