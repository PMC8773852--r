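#' Standard 12-lead ECG lead order
#'
#' The fixed lead ordering used throughout the package: the three standard
#' limb leads, the three augmented limb leads, then the six precordial leads.
#' Genomes, branch indices and synthetic signals all follow this order.
#'
#' @return Character vector of 12 lead names.
#' @export
#' @examples
#' ecg_lead_names()
ecg_lead_names <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Diagnostic class labels
#'
#' Healthy control plus the six location-based myocardial infarction
#' subcategories (anterior, antero-septal, antero-lateral, inferior,
#' infero-lateral, and the catch-all "other MI").
#'
#' @return Character vector of 7 class labels.
#' @export
mi_class_labels <- function() {
  c("HC", "AMI", "ASMI", "ALMI", "IMI", "ILMI", "OMI")
}

# Anatomical aspect -> leads map (standard lead/territory correspondence).
.aspect_leads <- list(
  anterior    = c("V3", "V4"),
  septal      = c("V1", "V2"),
  lateral     = c("I", "aVL", "V5", "V6"),
  inferior    = c("II", "III", "aVF"),
  endocardial = c("aVR")
)

#' Anatomical lead map for MI subcategories
#'
#' Maps each MI subcategory to the ECG leads overlying its infarct
#' territory: anterior (V3, V4), septal (V1, V2), lateral (I, aVL, V5, V6),
#' inferior (II, III, aVF). Compound locations take the union of their
#' aspects. OMI is a catch-all with no fixed territory and maps to an empty
#' set here (the synthetic generator draws a random 2-lead subset for it);
#' HC maps to the empty set.
#'
#' @return Named list, one character vector of lead names per class label.
#' @export
#' @examples
#' mi_lead_map()$IMI   # II, III, aVF
mi_lead_map <- function() {
  list(
    HC   = character(0),
    AMI  = .aspect_leads$anterior,
    ASMI = c(.aspect_leads$anterior, .aspect_leads$septal),
    ALMI = c(.aspect_leads$anterior, .aspect_leads$lateral),
    IMI  = .aspect_leads$inferior,
    ILMI = c(.aspect_leads$inferior, .aspect_leads$lateral),
    OMI  = character(0)
  )
}
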