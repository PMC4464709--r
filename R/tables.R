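.extdata <- function(file) {
  path <- system.file("extdata", file, package = "atriarecon")
  if (path == "") path <- file.path("inst", "extdata", file) # pre-install
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled phantom-study volume table
#'
#' Worked-example fixture: measured LA phantom volumes for the five shapes
#' (oval large 54 ml, oval small 51 ml, oblique oval 61 ml, sphere 55 ml,
#' curved 70 ml) under the three slice-orientation strategies (codes A1-E3;
#' rows 1/2/3 = aligned+perpendicular / aligned+tilted / misaligned), by
#' both the non-model-based reconstruction and the bi-plane area-length
#' method, against water-displacement reference volumes. Used to reproduce
#' the agreement statistics of the validation study as regression fixtures.
#'
#' @return a tibble with `shape`, `strategy`, `method`, `volume_ml`,
#'   `reference_ml`.
#' @export
phantom_study_table <- function() as_tibble(.extdata("phantom_study_volumes.csv"))

#' Bundled high-resolution 3D reference volume table
#'
#' Phantom volumes measured on the self-navigated high-resolution 3D
#' acquisition against the water-displacement reference.
#'
#' @return a tibble with `shape`, `volume_ml`, `reference_ml`.
#' @export
phantom_hr_table <- function() as_tibble(.extdata("phantom_hr_volumes.csv"))

#' Bundled patient LA volume comparison table
#'
#' Mid-diastolic LA volumes of three patients: sparse-cine reconstruction
#' versus the high-resolution 3D reference.
#'
#' @return a tibble with `patient`, `cine_ml`, `reference_ml`.
#' @export
patient_volume_table <- function() as_tibble(.extdata("patient_la_volumes.csv"))

#' Bundled patient LA function table
#'
#' Worked-example fixture for the functional indices: per patient the three
#' landmark volumes (`v_max`, `v_min`, `v_pre_a`; `NA` pre-contraction
#' volume encodes absent atrial contraction), the LV stroke volume, and the
#' printed derived indices used as regression values.
#'
#' @return a tibble, one row per patient.
#' @export
patient_function_table <- function() as_tibble(.extdata("patient_la_function.csv"))
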