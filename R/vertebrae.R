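#' Vertebra marker labels
#'
#' The twelve spinous processes carrying surface markers, ordered cephalad
#' (C7) to caudal (L5). T5, T7, T9, T11 and L3/L4 carry no marker; in
#' particular the thoracolumbar transition near T11 falls strictly between
#' the T10 and T12 markers, which is where the spine is split into its
#' thoracic and lumbar segments for the P8 angle.
#'
#' @return Character vector of the 12 labels in fixed cephalad-to-caudal
#'   order.
#' @export
#' @examples
#' vertebra_labels()
vertebra_labels <- function() {
  c("C7", "T1", "T2", "T3", "T4", "T6", "T8", "T10",
    "T12", "L1", "L2", "L5")
}

#' @rdname vertebra_labels
#' @export
thoracic_labels <- function() vertebra_labels()[1:8]

#' @rdname vertebra_labels
#' @export
lumbar_labels <- function() vertebra_labels()[9:12]
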