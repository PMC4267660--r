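#' Default dsDNA ruler lengths (bp)
#'
#' The ten double-stranded DNA ruler lengths used to calibrate the effective
#' Forster radius: 10, 13, 16, 19, 20, 21, 22, 25, 28 and 45 bp. At
#' 0.34 nm/bp these span inter-dye separations of 3.4-15.3 nm, bracketing
#' the half-transfer point of a typical Alexa 546/647 pair.
#'
#' @format Integer vector of length 10.
#' @export
ruler_lengths_bp <- c(10L, 13L, 16L, 19L, 20L, 21L, 22L, 25L, 28L, 45L)

#' Reference mRNA lengths (nt)
#'
#' Lengths of the eleven in-vitro transcribed mRNA molecules (two plant
#' viruses and a fungus) whose 5'-3' end separations the pipeline analyses:
#' monocistronic (574, 574, 1012, 1667, 2012, 3234, 2865, 2774 nt),
#' dicistronic (2117, 2177 nt) and a joined dicistronic construct (5345 nt).
#' Names give a sample identifier; the first entry is the antisense strand.
#'
#' @format Named integer vector of length 11.
#' @export
rna_lengths_nt <- c(
  "fgen1_antisense" = 574L,
  "fgen1"           = 574L,
  "triat1"          = 1012L,
  "chi18_4"         = 1667L,
  "phr1"            = 2012L,
  "BMV_RNA1"        = 3234L,
  "BMV_RNA2"        = 2865L,
  "CCMV_RNA2"       = 2774L,
  "BMV_RNA3"        = 2117L,
  "CCMV_RNA3"       = 2177L,
  "BMV_RNA1_3"      = 5345L
)

#' Cistron class of each reference mRNA
#'
#' @format Named character vector parallel to [rna_lengths_nt]:
#'   "mono", "di" or "antisense".
#' @export
rna_cistron_class <- c(
  "fgen1_antisense" = "antisense",
  "fgen1"           = "mono",
  "triat1"          = "mono",
  "chi18_4"         = "mono",
  "phr1"            = "mono",
  "BMV_RNA1"        = "mono",
  "BMV_RNA2"        = "mono",
  "CCMV_RNA2"       = "mono",
  "BMV_RNA3"        = "di",
  "CCMV_RNA3"       = "di",
  "BMV_RNA1_3"      = "di"
)
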