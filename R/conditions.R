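#' Chemosensory stimulus conditions
#'
#' The five experimental conditions of the flavour paradigm: sweet and
#' savoury tastants (SweT, SavT), sweet and savoury retronasal odorants
#' (SweO, SavO), and the artificial-saliva control (ArtS). The mapping from
#' label to (modality, flavour) is fixed and bijective.
#'
#' @return data frame with columns `label`, `modality`
#'   (taste/odour/control) and `flavour` (sweet/savoury/none).
#' @export
flavour_conditions <- function() {
  data.frame(
    label    = c("SweT", "SavT", "SweO", "SavO", "ArtS"),
    modality = c("taste", "taste", "odour", "odour", "control"),
    flavour  = c("sweet", "savoury", "sweet", "savoury", "none"),
    stringsAsFactors = FALSE
  )
}

#' Modality of condition labels
#' @param label character vector of condition labels.
#' @return character vector of modalities.
#' @export
condition_modality <- function(label) {
  tab <- flavour_conditions()
  i <- match(label, tab$label)
  if (anyNA(i)) stop("unknown condition label: ",
                     paste(unique(label[is.na(i)]), collapse = ", "))
  tab$modality[i]
}

#' Flavour of condition labels
#' @param label character vector of condition labels.
#' @return character vector of flavours.
#' @export
condition_flavour <- function(label) {
  tab <- flavour_conditions()
  i <- match(label, tab$label)
  if (anyNA(i)) stop("unknown condition label: ",
                     paste(unique(label[is.na(i)]), collapse = ", "))
  tab$flavour[i]
}
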